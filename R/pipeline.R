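#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the default
#' values used throughout: the four abundance-bin thresholds, the 25%
#' oligoclonal rule, Hill orders 0-5, template-weighted J-gene usage,
#' top-10 clonotype tracking, and edit-distance 1 for CDR3 sharing.
#'
#' @param bin_thresholds see [default_bin_thresholds()].
#' @param oligo_threshold expanded-fraction cutoff for the oligoclonal
#'   label.
#' @param q_grid Hill diversity orders.
#' @param usage_segment `"V"` or `"J"` for the usage stage.
#' @param usage_weighting `"template"` or `"clonotype"`.
#' @param track_top_n clones tracked per patient.
#' @param sharing_max_dist Levenshtein bound for CDR3 clustering.
#' @param sharing_min_freq frequency floor for the sharing stage:
#'   cross-patient clustering considers clones above this productive
#'   frequency (default 1e-3, the large-clone threshold — shared-clone
#'   reports concern clonotypes abundant enough to be reliably
#'   detected; set to 0 to cluster every observed clonotype).
#' @param neutral_band log2 selection band half-width.
#' @param key_level clonotype keying, `"aa"` or `"nt"`.
#' @param denominator frequency denominator, `"productive"` or `"all"`.
#' @param seed seed for the (deterministic) clustering restarts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(bin_thresholds = default_bin_thresholds(),
                            oligo_threshold = 0.25,
                            q_grid = 0:5,
                            usage_segment = "J",
                            usage_weighting = "template",
                            track_top_n = 10,
                            sharing_max_dist = 1,
                            sharing_min_freq = 1e-3,
                            neutral_band = 1,
                            key_level = "aa",
                            denominator = "productive",
                            seed = 1L) {
  stopifnot(!is.unsorted(bin_thresholds, strictly = TRUE))
  structure(
    list(bin_thresholds = bin_thresholds, oligo_threshold = oligo_threshold,
         q_grid = q_grid, usage_segment = usage_segment,
         usage_weighting = usage_weighting, track_top_n = track_top_n,
         sharing_max_dist = sharing_max_dist,
         sharing_min_freq = sharing_min_freq, neutral_band = neutral_band,
         key_level = key_level, denominator = denominator,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full repertoire analysis pipeline
#'
#' Orchestrates all stages on a directory of AIRR Rearrangement TSVs
#' (file names `<patient>_<timepoint>.tsv`) plus a cohort metadata
#' table: ingest and validation, per-sample diversity metrics, the
#' abundance spectrum with patient stratification, J/V gene usage with
#' the pairwise Jensen-Shannon divergence matrix, top-clonotype
#' tracking for patients with several timepoints, cross-patient CDR3
#' clustering, and the survival comparison of the stratified groups.
#' Each stage writes a CSV under `out_dir`; a `manifest.json` records
#' the full configuration echo, the input list and MD5 sums of every
#' output, so re-running an identical configuration on identical inputs
#' reproduces identical files.
#'
#' @param input_dir directory of AIRR TSV files named
#'   `<patient>_<timepoint>.tsv`.
#' @param cohort_path path to the cohort metadata CSV.
#' @param out_dir output directory (created if needed).
#' @param config a `pipeline_config`.
#' @return invisibly, a list with the stage outputs and the manifest.
#' @export
run_pipeline <- function(input_dir, cohort_path, out_dir,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(input_dir)) {
    stop("input directory not found: ", input_dir, call. = FALSE)
  }
  if (!file.exists(cohort_path)) {
    stop("cohort metadata file not found: ", cohort_path, call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- sort(list.files(input_dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0) {
    stop("stage ingest failed: no .tsv files in ", input_dir, call. = FALSE)
  }

  # -- ingest ---------------------------------------------------------
  message("stage ingest: ", length(files), " sample file(s)")
  reps <- lapply(files, function(f) {
    stem <- tools::file_path_sans_ext(basename(f))
    parts <- strsplit(stem, "_")[[1]]
    tp <- parts[length(parts)]
    pid <- paste(parts[-length(parts)], collapse = "_")
    if (!tp %in% TIMEPOINT_LEVELS) {
      stop("stage ingest failed: cannot parse timepoint from '", stem, "'",
           call. = FALSE)
    }
    filter_productive(read_airr_tsv(
      f, sample_id = stem, patient_id = pid, timepoint = tp,
      key_level = config$key_level, denominator = config$denominator))
  })
  names(reps) <- vapply(reps, function(r) r$sample_id, character(1))
  cohort <- read_cohort_csv(cohort_path)

  # -- diversity ------------------------------------------------------
  message("stage diversity: ", length(reps), " sample(s)")
  diversity <- dplyr::bind_rows(lapply(reps, diversity_summary,
                                       q_grid = config$q_grid))
  readr::write_csv(diversity, file.path(out_dir, "diversity.csv"))

  # -- spectrum / stratification -------------------------------------
  message("stage spectrum")
  profiles <- lapply(reps, spectrum_fractions,
                     thresholds = config$bin_thresholds)
  spectrum <- dplyr::bind_rows(lapply(profiles, function(p) {
    tibble::tibble(sample_id = p$sample_id, patient_id = p$patient_id,
                   timepoint = p$timepoint,
                   hyperexpanded = p$bin_fractions[["HYPEREXPANDED"]],
                   large = p$bin_fractions[["LARGE"]],
                   medium = p$bin_fractions[["MEDIUM"]],
                   small_rare = p$bin_fractions[["SMALL_RARE"]],
                   expanded_fraction = p$expanded_fraction,
                   patient_label = stratify_patient(p, config$oligo_threshold))
  }))
  readr::write_csv(spectrum, file.path(out_dir, "spectrum.csv"))
  baseline_profiles <- profiles[vapply(profiles, function(p) {
    identical(p$timepoint, "SCREENING")
  }, logical(1))]
  group_table <- cohort_spectrum_table(unname(baseline_profiles), cohort,
                                       threshold = config$oligo_threshold)
  readr::write_csv(group_table, file.path(out_dir, "oligoclonal_by_group.csv"))

  # -- gene usage -----------------------------------------------------
  message("stage usage (", config$usage_segment, " genes)")
  usage <- lapply(reps, usage_profile, segment_class = config$usage_segment,
                  weighting = config$usage_weighting)
  usage_tab <- dplyr::bind_rows(lapply(usage, function(u) {
    tibble::tibble(sample_id = u$sample_id, gene = names(u$frequencies),
                   frequency = unname(u$frequencies))
  }))
  readr::write_csv(usage_tab, file.path(out_dir, "usage.csv"))
  jsd <- jsd_matrix(unname(usage))
  readr::write_csv(tibble::as_tibble(jsd, rownames = "sample_id"),
                   file.path(out_dir, "usage_jsd.csv"))
  clusters <- if (length(usage) >= 3) {
    uc <- usage_cluster(unname(usage), method = "hierarchical", k = 2,
                        seed = config$seed)
    tibble::tibble(sample_id = names(uc$assignment),
                   cluster = unname(uc$assignment))
  } else {
    tibble::tibble(sample_id = character(), cluster = integer())
  }
  readr::write_csv(clusters, file.path(out_dir, "usage_clusters.csv"))

  # -- tracking -------------------------------------------------------
  message("stage tracking")
  by_patient <- split(reps, vapply(reps, function(r) r$patient_id, character(1)))
  tracked <- dplyr::bind_rows(lapply(by_patient, function(rs) {
    if (length(rs) < 2) return(NULL)
    tt <- track_clonotypes(unname(rs), n = config$track_top_n)
    mass <- top_clonotype_mass(tt)
    tibble::tibble(patient_id = tt$patient_id,
                   timepoint = names(mass),
                   top_clonotype_mass = unname(mass))
  }))
  readr::write_csv(tracked, file.path(out_dir, "tracking.csv"))

  # -- sharing --------------------------------------------------------
  message("stage sharing")
  share_tab_in <- dplyr::bind_rows(lapply(reps, function(r) {
    rec <- r$records[r$records$productive &
                       !is.na(r$records$frequency) &
                       r$records$frequency > config$sharing_min_freq, ]
    tibble::tibble(cdr3_aa = rec$cdr3_aa, v_gene = rec$v_gene,
                   patient_id = r$patient_id)
  }))
  share <- cluster_cdr3(share_tab_in, max_dist = config$sharing_max_dist)
  share_tab <- share |>
    dplyr::filter(.data$shared) |>
    dplyr::mutate(members = vapply(.data$members, paste, character(1),
                                   collapse = ";"),
                  patients = vapply(.data$patients, paste, character(1),
                                    collapse = ";"))
  readr::write_csv(share_tab, file.path(out_dir, "shared_clusters.csv"))

  # -- survival -------------------------------------------------------
  message("stage survival")
  labels <- spectrum |>
    dplyr::filter(.data$timepoint == "SCREENING") |>
    dplyr::select("patient_id", "patient_label")
  surv <- stratified_survival_report(cohort, labels, stratify_by = "p16_status")
  surv_tests <- dplyr::bind_rows(lapply(names(surv$strata), function(nm) {
    s <- surv$strata[[nm]]
    tibble::tibble(stratum = nm, n = s$n,
                   chisq = s$test$statistic, p_value = s$test$p_value)
  }))
  readr::write_csv(surv_tests, file.path(out_dir, "survival_tests.csv"))
  readr::write_csv(surv$covariates, file.path(out_dir, "covariates.csv"))

  outputs <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("tcrclonality")),
    config = unclass(config),
    inputs = basename(files),
    cohort = basename(cohort_path),
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(diversity = diversity, spectrum = spectrum,
                 group_table = group_table, usage = usage_tab, jsd = jsd,
                 clusters = clusters, tracking = tracked, sharing = share,
                 survival = surv, manifest = manifest))
}
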