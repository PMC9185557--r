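#' Construct a TCR-beta repertoire
#'
#' A repertoire is one sample's set of clonotype records (rearrangements)
#' with normalised relative frequencies. Each record carries the CDR3
#' amino-acid sequence, V/D/J gene calls, the template count (number of
#' sequenced input molecules supporting the rearrangement) and a
#' productive flag (whether the CDR3 encodes a functional peptide).
#'
#' Duplicate rows sharing the same clonotype key are merged with summed
#' template counts (with a warning), so a repertoire always holds one row
#' per clonotype. Relative frequencies are computed over productive
#' templates by default; set `denominator = "all"` to divide by all
#' templates instead.
#'
#' @param records data frame with columns `cdr3_aa`, `templates`,
#'   `productive`, and optionally `rearrangement_nt`, `v_gene`, `d_gene`,
#'   `j_gene`. Missing gene calls become the `"UNKNOWN"` sentinel.
#' @param sample_id sample identifier.
#' @param patient_id patient identifier (optional).
#' @param timepoint one of `TIMEPOINT_LEVELS`, or `NA`.
#' @param key_level `"aa"` (default) keys clonotypes by
#'   (cdr3_aa, v_gene, j_gene); `"nt"` keys by the nucleotide
#'   rearrangement. The amino-acid level is the default because clone
#'   tracking and sharing operate on amino-acid clonotypes.
#' @param denominator `"productive"` (default) or `"all"`: which template
#'   mass normalises the frequencies.
#' @return an object of class `tcr_repertoire`: a list with elements
#'   `sample_id`, `patient_id`, `timepoint`, `records` (a tibble with an
#'   added `clonotype_key` and `frequency` column) and the normalisation
#'   settings.
#' @export
repertoire <- function(records, sample_id, patient_id = NA_character_,
                       timepoint = NA_character_,
                       key_level = c("aa", "nt"),
                       denominator = c("productive", "all")) {
  key_level <- match.arg(key_level)
  denominator <- match.arg(denominator)
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    stop("empty repertoire: no clonotype records in sample '", sample_id, "'",
         call. = FALSE)
  }
  needed <- c("cdr3_aa", "templates", "productive")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (g in c("v_gene", "d_gene", "j_gene")) {
    if (!g %in% names(records)) records[[g]] <- "UNKNOWN"
    u <- unique(as.character(records[[g]]))
    cu <- canonical_gene(u)
    bad <- !is_valid_gene(cu)
    if (any(bad)) {
      stop("invalid gene label(s) in ", g, ": ",
           paste(unique(cu[bad]), collapse = ", "), call. = FALSE)
    }
    records[[g]] <- cu[match(as.character(records[[g]]), u)]
  }
  if (!"rearrangement_nt" %in% names(records)) {
    records$rearrangement_nt <- NA_character_
  }
  records$templates <- as.numeric(records$templates)
  if (anyNA(records$templates) || any(records$templates < 0)) {
    stop("templates must be non-negative and non-missing", call. = FALSE)
  }
  records$productive <- as.logical(records$productive)
  if (anyNA(records$productive)) {
    stop("productive flag must be TRUE/FALSE", call. = FALSE)
  }
  records$cdr3_aa <- toupper(as.character(records$cdr3_aa))
  records$cdr3_aa[is.na(records$cdr3_aa)] <- ""
  prod_cdr3 <- records$cdr3_aa[records$productive]
  bad_aa <- prod_cdr3 == "" |
    grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), prod_cdr3)
  if (any(bad_aa)) {
    stop("productive records must have a non-empty CDR3 over the 20-letter ",
         "amino-acid alphabet (offending rows: ",
         paste(utils::head(which(records$productive)[bad_aa], 5), collapse = ", "),
         ")", call. = FALSE)
  }

  records$clonotype_key <- clonotype_key(records, key_level)
  dup <- if (length(unique(records$productive)) == 1) {
    duplicated(records$clonotype_key)
  } else {
    duplicated(paste0(records$clonotype_key, "/", records$productive))
  }
  if (any(dup)) {
    warning(sum(dup), " duplicate clonotype row(s) merged (templates summed)",
            call. = FALSE)
    records <- records |>
      dplyr::group_by(.data$clonotype_key, .data$productive) |>
      dplyr::summarise(
        rearrangement_nt = dplyr::first(.data$rearrangement_nt),
        cdr3_aa = dplyr::first(.data$cdr3_aa),
        v_gene = dplyr::first(.data$v_gene),
        d_gene = dplyr::first(.data$d_gene),
        j_gene = dplyr::first(.data$j_gene),
        templates = sum(.data$templates),
        .groups = "drop"
      )
  }
  records <- records[c("clonotype_key", "rearrangement_nt", "cdr3_aa",
                       "v_gene", "d_gene", "j_gene", "templates", "productive")]
  if (!is.na(timepoint) && !timepoint %in% TIMEPOINT_LEVELS) {
    stop("timepoint must be one of: ", paste(TIMEPOINT_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  rep <- structure(
    list(sample_id = as.character(sample_id),
         patient_id = as.character(patient_id),
         timepoint = timepoint,
         key_level = key_level,
         denominator = denominator,
         records = records),
    class = "tcr_repertoire"
  )
  normalize_frequencies(rep)
}

# Construction fast path for records that are canonical by
# construction (generator output: uppercase CDR3s, valid gene labels,
# unique keys, all productive). Skips validation and duplicate
# merging; everything else matches repertoire().
fast_repertoire <- function(records, sample_id, patient_id = NA_character_,
                            timepoint = NA_character_) {
  records$clonotype_key <- paste(records$cdr3_aa, records$v_gene,
                                 records$j_gene, sep = "|")
  records <- records[c("clonotype_key", "rearrangement_nt", "cdr3_aa",
                       "v_gene", "d_gene", "j_gene", "templates",
                       "productive")]
  normalize_frequencies(structure(
    list(sample_id = as.character(sample_id),
         patient_id = as.character(patient_id),
         timepoint = timepoint,
         key_level = "aa",
         denominator = "productive",
         records = records),
    class = "tcr_repertoire"
  ))
}

# clonotype key for a record table at the requested level
clonotype_key <- function(records, key_level = c("aa", "nt")) {
  key_level <- match.arg(key_level)
  if (key_level == "nt") {
    if (anyNA(records$rearrangement_nt)) {
      stop("nucleotide-level keys require a rearrangement_nt for every record",
           call. = FALSE)
    }
    records$rearrangement_nt
  } else {
    paste(records$cdr3_aa, records$v_gene, records$j_gene, sep = "|")
  }
}

# recompute the frequency column under the repertoire's denominator
normalize_frequencies <- function(rep) {
  rec <- rep$records
  denom <- if (rep$denominator == "productive") {
    sum(rec$templates[rec$productive])
  } else {
    sum(rec$templates)
  }
  rec$frequency <- if (denom > 0) rec$templates / denom else NA_real_
  if (rep$denominator == "productive") rec$frequency[!rec$productive] <- NA_real_
  rep$records <- rec
  rep
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  n_prod <- sum(x$records$productive)
  cat(sprintf(
    "<tcr_repertoire> sample %s (patient %s, timepoint %s)\n  %d clonotypes (%d productive), %s templates, key level: %s\n",
    x$sample_id, x$patient_id, x$timepoint %||% NA,
    nrow(x$records), n_prod,
    format(sum(x$records$templates), big.mark = ","), x$key_level))
  invisible(x)
}

#' Productive frequency vector of a repertoire
#'
#' @param rep a `tcr_repertoire`.
#' @return named numeric vector of productive clonotype frequencies
#'   (names are clonotype keys), summing to 1 under the productive
#'   denominator.
#' @export
productive_frequencies <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  rec <- rep$records[rep$records$productive, ]
  if (nrow(rec) == 0) {
    stop("repertoire has no productive records", call. = FALSE)
  }
  if (rep$denominator != "productive") {
    f <- rec$templates / sum(rec$templates)
    return(stats::setNames(f, rec$clonotype_key))
  }
  stats::setNames(rec$frequency, rec$clonotype_key)
}

#' Keep only productive rearrangements
#'
#' Discards records whose CDR3 cannot encode a functional peptide and
#' renormalises frequencies over the retained templates. Idempotent.
#'
#' @param rep a `tcr_repertoire`.
#' @return the filtered `tcr_repertoire`.
#' @export
filter_productive <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  keep <- rep$records$productive
  if (!any(keep)) {
    stop("all records are non-productive; nothing to retain", call. = FALSE)
  }
  rep$records <- rep$records[keep, ]
  normalize_frequencies(rep)
}

#' Total rearrangements (repertoire richness)
#'
#' The number of unique detectable CDR3 rearrangements among productive
#' records — the richness of the repertoire. Uniqueness is evaluated at
#' the amino-acid clonotype key by default; pass `level = "nt"` to count
#' unique nucleotide rearrangements instead (both conventions are in use
#' for "total rearrangements" and the choice is configurable).
#'
#' @param rep a `tcr_repertoire`.
#' @param level `"aa"` or `"nt"`; defaults to the repertoire's key level.
#' @return integer count of unique productive clonotype keys.
#' @export
total_rearrangements <- function(rep, level = rep$key_level) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  rec <- rep$records[rep$records$productive, ]
  if (nrow(rec) == 0) {
    warning("no productive records; total rearrangements is 0", call. = FALSE)
    return(0L)
  }
  length(unique(clonotype_key(rec, level)))
}
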