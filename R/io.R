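#' Default immunoSEQ export column aliases
#'
#' immunoSEQ-style clone-table exports name their columns differently
#' across analyzer versions; parsing goes through this alias map rather
#' than hard-coded headers. Each element lists the accepted header
#' spellings for one canonical field (matching is case-insensitive).
#'
#' @return named list of character vectors.
#' @export
immunoseq_dialect <- function() {
  list(
    rearrangement_nt = c("rearrangement", "nucleotide", "nucleotide_sequence"),
    cdr3_aa    = c("amino_acid", "aminoacid", "cdr3_amino_acid", "aa_sequence"),
    v_gene     = c("v_resolved", "vgenename", "v_gene_name", "vmaxresolved"),
    d_gene     = c("d_resolved", "dgenename", "d_gene_name", "dmaxresolved"),
    j_gene     = c("j_resolved", "jgenename", "j_gene_name", "jmaxresolved"),
    templates  = c("templates", "count (templates/reads)", "count",
                   "template_count", "seq_reads", "reads"),
    productive = c("frame_type", "sequencestatus", "sequence_status")
  )
}

match_alias <- function(header, aliases) {
  hit <- which(tolower(header) %in% tolower(aliases))
  if (length(hit) == 0) NA_integer_ else hit[1]
}

parse_productive_flag <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("IN", "IN-FRAME", "INFRAME", "T", "TRUE", "1", "YES", "PRODUCTIVE")] <- TRUE
  out[x %in% c("OUT", "STOP", "OUT-OF-FRAME", "F", "FALSE", "0", "NO",
               "NON-PRODUCTIVE", "UNPRODUCTIVE")] <- FALSE
  out
}

read_clone_table <- function(path, colmap, sample_id, patient_id, timepoint,
                             key_level, denominator, format_name) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  header <- names(raw)
  idx <- vapply(colmap, function(al) match_alias(header, al), integer(1))
  mandatory <- c("cdr3_aa", "templates", "productive")
  for (field in mandatory) {
    if (is.na(idx[[field]])) {
      stop(format_name, " format error: no column matching '", field,
           "' (accepted: ", paste(colmap[[field]], collapse = ", "), ")",
           call. = FALSE)
    }
  }
  if (nrow(raw) == 0) {
    stop("empty repertoire file: ", path, call. = FALSE)
  }
  get <- function(field) {
    if (is.na(idx[[field]])) rep(NA_character_, nrow(raw)) else raw[[idx[[field]]]]
  }
  templates <- suppressWarnings(as.numeric(get("templates")))
  bad <- is.na(templates)
  if (any(bad)) {
    warning("rejected ", sum(bad), " row(s) with unparseable template counts ",
            "(rows: ", paste(utils::head(which(bad), 10), collapse = ", "), ")",
            call. = FALSE)
  }
  productive <- parse_productive_flag(get("productive"))
  bad_flag <- is.na(productive) & !bad
  if (any(bad_flag)) {
    warning("rejected ", sum(bad_flag), " row(s) with unparseable productive flag ",
            "(rows: ", paste(utils::head(which(bad_flag), 10), collapse = ", "), ")",
            call. = FALSE)
  }
  keep <- !bad & !bad_flag
  if (!any(keep)) stop("no parseable rows in ", path, call. = FALSE)
  records <- tibble::tibble(
    rearrangement_nt = get("rearrangement_nt")[keep],
    cdr3_aa = get("cdr3_aa")[keep],
    v_gene = get("v_gene")[keep],
    d_gene = get("d_gene")[keep],
    j_gene = get("j_gene")[keep],
    templates = templates[keep],
    productive = productive[keep]
  )
  records$cdr3_aa[is.na(records$cdr3_aa)] <- ""
  repertoire(records, sample_id = sample_id, patient_id = patient_id,
             timepoint = timepoint, key_level = key_level,
             denominator = denominator)
}

#' Read an immunoSEQ-style clone table
#'
#' Parses a tab-separated immunoSEQ export (one row per rearrangement)
#' into a [repertoire()]. Column headers are resolved through the alias
#' map in `dialect`, so exports from different analyzer versions parse
#' without renaming. Rows whose template count or frame status cannot be
#' parsed are rejected with a row-indexed warning.
#'
#' @param path path to the TSV file.
#' @param sample_id sample identifier; defaults to the file stem.
#' @param patient_id,timepoint optional provenance.
#' @param dialect column-alias map, see [immunoseq_dialect()].
#' @inheritParams repertoire
#' @return a `tcr_repertoire`.
#' @export
read_immunoseq_tsv <- function(path,
                               sample_id = tools::file_path_sans_ext(basename(path)),
                               patient_id = NA_character_,
                               timepoint = NA_character_,
                               dialect = immunoseq_dialect(),
                               key_level = c("aa", "nt"),
                               denominator = c("productive", "all")) {
  read_clone_table(path, dialect, sample_id, patient_id, timepoint,
                   match.arg(key_level), match.arg(denominator), "immunoSEQ")
}

airr_dialect <- function() {
  list(
    rearrangement_nt = c("sequence"),
    cdr3_aa    = c("junction_aa", "cdr3_aa"),
    v_gene     = c("v_call"),
    d_gene     = c("d_call"),
    j_gene     = c("j_call"),
    templates  = c("duplicate_count", "consensus_count"),
    productive = c("productive")
  )
}

#' Read an AIRR Rearrangement TSV
#'
#' Parses a table following the AIRR community Rearrangement schema
#' (columns `sequence`, `junction_aa`, `v_call`, `d_call`, `j_call`,
#' `duplicate_count`, `productive`). The productive column accepts the
#' `T`/`F` dialect as well as `TRUE`/`FALSE`.
#'
#' @inheritParams read_immunoseq_tsv
#' @return a `tcr_repertoire`.
#' @export
read_airr_tsv <- function(path,
                          sample_id = tools::file_path_sans_ext(basename(path)),
                          patient_id = NA_character_,
                          timepoint = NA_character_,
                          key_level = c("aa", "nt"),
                          denominator = c("productive", "all")) {
  read_clone_table(path, airr_dialect(), sample_id, patient_id, timepoint,
                   match.arg(key_level), match.arg(denominator), "AIRR")
}

#' Write a repertoire as an AIRR Rearrangement TSV
#'
#' Serialises the canonical fields (`sequence`, `junction_aa`, `v_call`,
#' `d_call`, `j_call`, `duplicate_count`, `productive`). Sentinel gene
#' calls (`AMBIGUOUS`/`UNKNOWN`) are written as empty calls per the AIRR
#' convention for unresolved assignments; reading the file back restores
#' the sentinels. A read-write-read round trip preserves clonotype keys,
#' template counts and gene calls exactly.
#'
#' @param rep a `tcr_repertoire`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(rep, path) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  rec <- rep$records
  strip_sentinel <- function(x) ifelse(x %in% GENE_SENTINELS, "", x)
  out <- tibble::tibble(
    sequence = ifelse(is.na(rec$rearrangement_nt), "", rec$rearrangement_nt),
    junction_aa = rec$cdr3_aa,
    v_call = strip_sentinel(rec$v_gene),
    d_call = strip_sentinel(rec$d_gene),
    j_call = strip_sentinel(rec$j_gene),
    duplicate_count = rec$templates,
    productive = ifelse(rec$productive, "T", "F")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a cohort metadata table
#'
#' One row per patient: `patient_id`, `best_response` (CR/PR/SD/PD/
#' NOT_ASSESSED), `p16_status` (POS/NEG; p16 immunohistochemistry is the
#' HPV surrogate), `smoking` (CURRENT/PREVIOUS/NEVER), `os_time` (days,
#' positive) and `os_event` (TRUE for death, FALSE for censoring).
#' Comma- or tab-delimited.
#'
#' @param path path to the CSV/TSV file.
#' @return a tibble with validated columns.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- if (grepl("\\.tsv$", path)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  needed <- c("patient_id", "best_response", "p16_status", "smoking",
              "os_time", "os_event")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    stop("cohort table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$patient_id)) {
    stop("duplicate patient_id in cohort table", call. = FALSE)
  }
  check_enum <- function(x, levels, what) {
    bad <- !x %in% levels
    if (any(bad)) {
      stop("invalid ", what, ": ", paste(unique(x[bad]), collapse = ", "),
           call. = FALSE)
    }
    x
  }
  tab$best_response <- check_enum(tab$best_response,
                                  c("CR", "PR", "SD", "PD", "NOT_ASSESSED"),
                                  "best_response")
  tab$p16_status <- check_enum(tab$p16_status, c("POS", "NEG"), "p16_status")
  tab$smoking <- check_enum(tab$smoking, c("CURRENT", "PREVIOUS", "NEVER"),
                            "smoking")
  tab$os_time <- as.numeric(tab$os_time)
  if (anyNA(tab$os_time) || any(tab$os_time <= 0)) {
    stop("os_time must be positive", call. = FALSE)
  }
  tab$os_event <- as.logical(tab$os_event)
  if (anyNA(tab$os_event)) stop("os_event must be TRUE/FALSE", call. = FALSE)
  tibble::as_tibble(tab)
}
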