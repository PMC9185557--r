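#' Track clonotype frequencies across timepoints
#'
#' Builds a trajectory table for one patient: rows are clonotype keys,
#' columns are timepoints in treatment order, cells hold the productive
#' relative frequency (0 with a detected = FALSE flag when the clone is
#' not observed at that timepoint). Clone selection modes: the top-n
#' clones at the earliest timepoint (default, matching top-clonotype
#' trajectory plots), the union of per-timepoint top-n, or an explicit
#' key list.
#'
#' @param reps list of `tcr_repertoire` objects for one patient with
#'   distinct, non-missing timepoints (at least 2).
#' @param selection `"top_baseline"`, `"top_any"`, or `"explicit"`.
#' @param n number of clones for the top-n modes (default 10).
#' @param keys clonotype keys for `selection = "explicit"`.
#' @return object of class `trajectory_table`: list with `frequency`
#'   and `detected` matrices (clones x timepoints) and `timepoints`.
#' @export
track_clonotypes <- function(reps, selection = c("top_baseline", "top_any", "explicit"),
                             n = 10, keys = NULL) {
  selection <- match.arg(selection)
  if (length(reps) < 2) {
    stop("need repertoires from at least 2 timepoints", call. = FALSE)
  }
  tps <- vapply(reps, function(r) r$timepoint, character(1))
  if (anyNA(tps) || anyDuplicated(tps)) {
    stop("repertoires must carry distinct, non-missing timepoints",
         call. = FALSE)
  }
  pats <- unique(vapply(reps, function(r) r$patient_id, character(1)))
  if (length(pats) > 1) {
    stop("repertoires belong to different patients: ",
         paste(pats, collapse = ", "), call. = FALSE)
  }
  ord <- order(match(tps, TIMEPOINT_LEVELS))
  reps <- reps[ord]
  tps <- tps[ord]
  freq_list <- lapply(reps, productive_frequencies)
  keys <- switch(selection,
    top_baseline = names(sort(freq_list[[1]], decreasing = TRUE))[
      seq_len(min(n, length(freq_list[[1]])))],
    top_any = unique(unlist(lapply(freq_list, function(f)
      names(sort(f, decreasing = TRUE))[seq_len(min(n, length(f)))]))),
    explicit = {
      if (is.null(keys)) stop("explicit selection requires keys", call. = FALSE)
      keys
    }
  )
  freq <- vapply(freq_list, function(f) {
    out <- f[keys]
    out[is.na(out)] <- 0
    unname(out)
  }, numeric(length(keys)))
  freq <- matrix(freq, nrow = length(keys),
                 dimnames = list(keys, tps))
  detected <- freq > 0
  present <- rowSums(detected) > 0
  structure(
    list(frequency = freq[present, , drop = FALSE],
         detected = detected[present, , drop = FALSE],
         timepoints = tps,
         patient_id = pats),
    class = "trajectory_table"
  )
}

#' Summed frequency of tracked clones per timepoint
#'
#' The total repertoire mass held by the tracked clone set at each
#' timepoint (column sums of the trajectory table); never exceeds 1.
#'
#' @param table a `trajectory_table`.
#' @return named numeric vector, one value per timepoint.
#' @export
top_clonotype_mass <- function(table) {
  stopifnot(inherits(table, "trajectory_table"))
  if (nrow(table$frequency) == 0) {
    return(stats::setNames(rep(0, length(table$timepoints)), table$timepoints))
  }
  colSums(table$frequency)
}

#' Classify clones under positive or negative selection
#'
#' For every clonotype detected in the pre- or post-treatment
#' repertoire of a patient, computes the log2 fold-change of its
#' relative frequency (post over pre) and classifies it: POSITIVE when
#' log2FC exceeds the neutral band, NEGATIVE below its negation,
#' NEUTRAL inside the band. Clones detected on only one side are
#' INDETERMINATE by default; with `impute = TRUE` the missing side is
#' floored at one template (1 / total productive templates of that
#' repertoire) so a finite fold-change can be reported.
#'
#' @param pre,post `tcr_repertoire` objects of the same patient
#'   (baseline and end of treatment).
#' @param min_freq detection floor: frequencies at or below it count as
#'   undetected (default 0, i.e. any observed template counts).
#' @param neutral_band half-width of the neutral zone in log2 units
#'   (default 1, i.e. two-fold change).
#' @param impute impute one-template floors for one-sided detections.
#' @return tibble with `clonotype_key`, `f_pre`, `f_post`, `log2fc`,
#'   `selection`.
#' @export
selection_analysis <- function(pre, post, min_freq = 0, neutral_band = 1,
                               impute = FALSE) {
  stopifnot(inherits(pre, "tcr_repertoire"), inherits(post, "tcr_repertoire"))
  if (!is.na(pre$patient_id) && !is.na(post$patient_id) &&
      pre$patient_id != post$patient_id) {
    stop("pre and post repertoires belong to different patients", call. = FALSE)
  }
  fp <- productive_frequencies(pre)
  fq <- productive_frequencies(post)
  fp <- fp[fp > min_freq]
  fq <- fq[fq > min_freq]
  keys <- union(names(fp), names(fq))
  f_pre <- unname(fp[keys]); f_pre[is.na(f_pre)] <- 0
  f_post <- unname(fq[keys]); f_post[is.na(f_post)] <- 0
  floor_pre <- 1 / sum(pre$records$templates[pre$records$productive])
  floor_post <- 1 / sum(post$records$templates[post$records$productive])
  both <- f_pre > 0 & f_post > 0
  log2fc <- rep(NA_real_, length(keys))
  log2fc[both] <- log2(f_post[both] / f_pre[both])
  selection <- rep("INDETERMINATE", length(keys))
  if (impute) {
    only_post <- f_pre == 0 & f_post > 0
    only_pre <- f_post == 0 & f_pre > 0
    log2fc[only_post] <- log2(f_post[only_post] / floor_pre)
    log2fc[only_pre] <- log2(floor_post / f_pre[only_pre])
    both <- both | only_post | only_pre
  }
  selection[both & log2fc > neutral_band] <- "POSITIVE"
  selection[both & log2fc < -neutral_band] <- "NEGATIVE"
  selection[both & abs(log2fc) <= neutral_band] <- "NEUTRAL"
  tibble::tibble(clonotype_key = keys, f_pre = f_pre, f_post = f_post,
                 log2fc = log2fc, selection = selection)
}
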