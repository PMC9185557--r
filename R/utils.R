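#' @importFrom stats rexp rmultinom runif rnorm setNames pchisq rbinom
#' @importFrom utils adist head
#' @importFrom dplyr .data
NULL

#' The 20-letter amino-acid alphabet
#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Sentinel labels for unresolved gene calls
#' @keywords internal
GENE_SENTINELS <- c("AMBIGUOUS", "UNKNOWN")

#' Ordered clinical timepoint labels
#'
#' Sample collection events in treatment order: pre-therapy screening,
#' the cetuximab lead-in, cycle 1 day 1 and cycle 4 day 1 of the
#' combination, and end of treatment.
#' @export
TIMEPOINT_LEVELS <- c("SCREENING", "LEAD_IN", "C1D1", "C4D1", "EOT")

#' Abundance-bin labels, most to least expanded
#' @export
BIN_LEVELS <- c("HYPEREXPANDED", "LARGE", "MEDIUM", "SMALL_RARE")

`%||%` <- function(a, b) if (is.null(a)) b else a

# IMGT-style TRB gene label (e.g. TRBV12-1, TRBJ2-7, optional allele suffix)
is_valid_gene <- function(x) {
  grepl("^(TRB|TCRB)[VDJ][0-9]+(-[0-9]+)?(\\*[0-9]+)?$", x) | x %in% GENE_SENTINELS
}

# map NA / empty / unresolved spellings onto the sentinels
canonical_gene <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | toupper(x) == "UNRESOLVED" | toupper(x) == "UNKNOWN"] <- "UNKNOWN"
  x[toupper(x) == "AMBIGUOUS" | grepl(",", x, fixed = TRUE)] <- "AMBIGUOUS"
  x
}

check_frequencies <- function(freqs, tol = 1e-9) {
  if (length(freqs) == 0) {
    stop("frequency vector is empty", call. = FALSE)
  }
  if (anyNA(freqs) || any(freqs < 0)) {
    stop("frequencies must be non-negative and non-missing", call. = FALSE)
  }
  if (abs(sum(freqs) - 1) > tol) {
    stop(sprintf("frequencies must sum to 1 (got %.12f)", sum(freqs)), call. = FALSE)
  }
  invisible(freqs)
}

# vectorised random amino-acid strings of the given lengths
random_aa_strings <- function(lengths, prefix = "", suffix = "") {
  out <- character(length(lengths))
  for (L in unique(lengths)) {
    idx <- which(lengths == L)
    if (L <= 0) {
      out[idx] <- paste0(prefix, suffix)
      next
    }
    m <- matrix(sample(AA_ALPHABET, length(idx) * L, replace = TRUE), ncol = L)
    out[idx] <- do.call(paste0, c(list(prefix), asplit(m, 2), list(suffix)))
  }
  out
}
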