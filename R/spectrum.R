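#' Default abundance-bin thresholds
#'
#' Clones are partitioned by relative frequency X into four bins:
#' hyperexpanded (X > 0.01), large (0.001 < X <= 0.01), medium
#' (1e-4 < X <= 0.001) and small/rare (X <= 1e-4). The boundary
#' X = 1e-4 closes downward into small/rare, consistent with the closed
#' upper bounds of the other bins.
#'
#' @return named numeric vector `c(small = 1e-4, large = 1e-3, hyper = 1e-2)`.
#' @export
default_bin_thresholds <- function() {
  c(small = 1e-4, large = 1e-3, hyper = 1e-2)
}

#' Classify clone frequencies into abundance bins
#'
#' @param x vector of clone relative frequencies in (0, 1].
#' @param thresholds strictly increasing thresholds, see
#'   [default_bin_thresholds()].
#' @return factor with levels `BIN_LEVELS`; every frequency maps to
#'   exactly one bin.
#' @export
classify_bin <- function(x, thresholds = default_bin_thresholds()) {
  if (length(x) == 0) stop("no frequencies to classify", call. = FALSE)
  if (anyNA(x) || any(x <= 0) || any(x > 1)) {
    stop("clone frequencies must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(length(thresholds) == 3, !is.unsorted(thresholds, strictly = TRUE))
  bin <- character(length(x))
  bin[x > thresholds[3]] <- "HYPEREXPANDED"
  bin[x > thresholds[2] & x <= thresholds[3]] <- "LARGE"
  bin[x > thresholds[1] & x <= thresholds[2]] <- "MEDIUM"
  bin[x <= thresholds[1]] <- "SMALL_RARE"
  factor(bin, levels = BIN_LEVELS)
}

#' Clonotype abundance spectrum of a repertoire
#'
#' For each abundance bin, the summed template frequency of the clones
#' falling in that bin, plus the expanded fraction (large +
#' hyperexpanded mass) that drives patient stratification. Computed on
#' the productive frequency vector.
#'
#' @param rep a `tcr_repertoire`.
#' @param thresholds bin thresholds, see [default_bin_thresholds()].
#' @return object of class `spectrum_profile`: list with `sample_id`,
#'   `patient_id`, `timepoint`, `bin_fractions` (named numeric summing
#'   to 1), `expanded_fraction`.
#' @export
spectrum_fractions <- function(rep, thresholds = default_bin_thresholds()) {
  f <- productive_frequencies(rep)
  f <- f[f > 0]
  bins <- classify_bin(f, thresholds)
  fractions <- vapply(BIN_LEVELS, function(b) sum(f[bins == b]), numeric(1))
  structure(
    list(sample_id = rep$sample_id,
         patient_id = rep$patient_id,
         timepoint = rep$timepoint,
         bin_fractions = fractions,
         expanded_fraction = unname(fractions["LARGE"] + fractions["HYPEREXPANDED"])),
    class = "spectrum_profile"
  )
}

#' @export
print.spectrum_profile <- function(x, ...) {
  cat(sprintf("<spectrum_profile> sample %s\n", x$sample_id))
  print(round(x$bin_fractions, 4))
  cat(sprintf("  expanded fraction: %.4f\n", x$expanded_fraction))
  invisible(x)
}

#' Stratify a patient as oligoclonal or polyclonal
#'
#' A patient is labelled OLIGOCLONAL when more than 25% of the
#' repertoire's template mass sits in large or hyperexpanded clones
#' (relative frequency > 0.001), and POLYCLONAL otherwise. An expanded
#' fraction exactly at the threshold is labelled POLYCLONAL, keeping
#' OLIGOCLONAL the strictly-greater-than claim.
#'
#' @param profile a `spectrum_profile`.
#' @param threshold expanded-fraction cutoff, default 0.25.
#' @return `"OLIGOCLONAL"` or `"POLYCLONAL"`.
#' @export
stratify_patient <- function(profile, threshold = 0.25) {
  stopifnot(inherits(profile, "spectrum_profile"))
  if (profile$expanded_fraction > threshold) "OLIGOCLONAL" else "POLYCLONAL"
}

#' Per-response-group oligoclonal proportions
#'
#' Joins baseline spectrum profiles to the cohort table and reports, per
#' response group (CR and PR pooled), the number of patients, the number
#' labelled oligoclonal, and the proportion.
#'
#' @param profiles list of baseline `spectrum_profile` objects, one per
#'   patient (an error is raised if a patient appears more than once,
#'   unless `baseline_selector` picks one).
#' @param cohort cohort tibble as returned by [read_cohort_csv()] (only
#'   `patient_id` and `best_response` are used).
#' @param threshold expanded-fraction cutoff, default 0.25.
#' @param baseline_selector optional function applied to a patient's
#'   profiles to select a single baseline when several are supplied.
#' @return tibble with `group`, `n`, `n_oligoclonal`, `proportion`.
#' @export
cohort_spectrum_table <- function(profiles, cohort, threshold = 0.25,
                                  baseline_selector = NULL) {
  ids <- vapply(profiles, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids)) {
    if (is.null(baseline_selector)) {
      stop("multiple baseline profiles for patient(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "),
           "; supply baseline_selector", call. = FALSE)
    }
    profiles <- lapply(split(profiles, ids), baseline_selector)
    ids <- vapply(profiles, function(p) p$patient_id, character(1))
  }
  labels <- vapply(profiles, stratify_patient, character(1),
                   threshold = threshold)
  tab <- tibble::tibble(patient_id = ids, patient_label = labels) |>
    dplyr::inner_join(cohort[c("patient_id", "best_response")],
                      by = "patient_id") |>
    dplyr::mutate(group = dplyr::case_when(
      .data$best_response %in% c("CR", "PR") ~ "CR/PR",
      TRUE ~ .data$best_response
    ))
  tab |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_oligoclonal = sum(.data$patient_label == "OLIGOCLONAL"),
      proportion = .data$n_oligoclonal / .data$n,
      .groups = "drop"
    )
}

#' Concordance of two spectrum profiles of the same sample
#'
#' Per-bin absolute differences between two profiles (e.g. survey-depth
#' versus deep sequencing of the same sample), plus the bin of maximal
#' discrepancy. When depths differ, the rarest bins are the expected
#' locus of discrepancy because rare-clone frequency estimates are the
#' most depth-sensitive.
#'
#' @param profile_a,profile_b `spectrum_profile` objects for the same
#'   sample identity.
#' @return tibble with `bin`, `fraction_a`, `fraction_b`, `abs_diff`,
#'   and attribute `max_discrepancy_bin`.
#' @export
spectrum_concordance <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "spectrum_profile"),
            inherits(profile_b, "spectrum_profile"))
  out <- tibble::tibble(
    bin = BIN_LEVELS,
    fraction_a = unname(profile_a$bin_fractions[BIN_LEVELS]),
    fraction_b = unname(profile_b$bin_fractions[BIN_LEVELS])
  )
  out$abs_diff <- abs(out$fraction_a - out$fraction_b)
  attr(out, "max_discrepancy_bin") <- out$bin[which.max(out$abs_diff)]
  out
}

#' Thin a repertoire to a lower sequencing depth
#'
#' Draws `depth` templates multinomially at the repertoire's current
#' clone proportions, emulating a lower-depth sequencing run of the same
#' library. Used for depth-robustness checks of the patient
#' stratification.
#'
#' @param rep a `tcr_repertoire`.
#' @param depth target total template count (must not exceed the current
#'   total).
#' @return a thinned `tcr_repertoire` (clones with zero remaining
#'   templates dropped).
#' @export
thin_repertoire <- function(rep, depth) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  total <- sum(rep$records$templates)
  if (depth > total) stop("depth exceeds available templates", call. = FALSE)
  counts <- as.vector(rmultinom(1, depth, rep$records$templates / total))
  rec <- rep$records[counts > 0, ]
  rec$templates <- counts[counts > 0]
  rep$records <- rec
  normalize_frequencies(rep)
}
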