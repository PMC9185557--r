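#' Simpson clonality of a frequency vector
#'
#' The square root of the Simpson index \eqn{\sum_i p_i^2}. Values lie
#' in (0, 1]: 1 for a monoclonal repertoire, \eqn{1/\sqrt{R}} for a
#' uniform repertoire of richness R. Simpson clonality is preferred over
#' Shannon clonality for cross-sample comparison because it is less
#' sensitive to the total number of sequences.
#'
#' @param freqs numeric vector of clone relative frequencies, summing to
#'   1 (tolerance 1e-9), all non-negative.
#' @return Simpson clonality in (0, 1].
#' @export
simpson_clonality <- function(freqs) {
  check_frequencies(freqs)
  sqrt(sum(freqs^2))
}

#' Shannon entropy and Shannon clonality
#'
#' Entropy is \eqn{H = -\sum_i p_i \ln p_i} in nats; clonality is the
#' normalised complement \eqn{1 - H/\ln R} where R is the richness
#' (number of clones with positive frequency). A monoclonal repertoire
#' (R = 1) has entropy 0 and clonality defined as 1.
#'
#' @inheritParams simpson_clonality
#' @return list with elements `entropy` (nats) and `clonality` in [0, 1].
#' @export
shannon_metrics <- function(freqs) {
  check_frequencies(freqs)
  p <- freqs[freqs > 0]
  entropy <- -sum(p * log(p))
  r <- length(p)
  clonality <- if (r <= 1) 1 else 1 - entropy / log(r)
  list(entropy = entropy, clonality = clonality)
}

#' Hill number of order Q
#'
#' The one-parameter family of effective-clone-number diversity indices
#' \eqn{{}^Q D = (\sum_i p_i^Q)^{1/(1-Q)}}. Q = 0 gives richness (total
#' rearrangements), Q = 1 is the analytic limit \eqn{\exp(H)} (the
#' exponential of Shannon entropy, handled exactly rather than by
#' numerical nearness), and Q = 2 is the inverse Simpson index. The
#' profile is non-increasing in Q.
#'
#' @inheritParams simpson_clonality
#' @param q non-negative diversity order.
#' @return the Hill number, between 1 and the richness.
#' @export
hill_number <- function(freqs, q) {
  check_frequencies(freqs)
  stopifnot(length(q) == 1, q >= 0)
  p <- freqs[freqs > 0]
  if (q == 0) return(as.numeric(length(p)))
  if (q == 1) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Hill diversity profile over a grid of orders
#'
#' @inheritParams hill_number
#' @param q_grid numeric vector of diversity orders (default 0 through
#'   5, covering richness at Q = 0 and the orders 1..5 used for
#'   between-group diversity comparison).
#' @return named numeric vector, one Hill number per order.
#' @export
hill_profile <- function(freqs, q_grid = 0:5) {
  vapply(q_grid, function(q) hill_number(freqs, q), numeric(1)) |>
    stats::setNames(as.character(q_grid))
}

#' Rank-based comparison of a metric between patient groups
#'
#' Two groups are compared with the Wilcoxon rank-sum test (or the
#' signed-rank test when `paired = TRUE`); three or more groups with the
#' Kruskal-Wallis test. All tests are two-sided. The unpaired rank-sum
#' is the default for two groups because the patient groups compared
#' (response, smoking, HPV strata) are independent samples; the paired
#' variant is exposed for designs with matched observations.
#'
#' @param values numeric metric values, one per sample.
#' @param labels group label per sample.
#' @param paired for two groups, use the signed-rank test on paired
#'   observations (requires equal group sizes in label order).
#' @return tibble with `method`, `statistic`, `p_value`, `n_groups`.
#' @export
compare_groups <- function(values, labels, paired = FALSE) {
  stopifnot(length(values) == length(labels))
  labels <- as.character(labels)
  counts <- table(labels)
  if (length(counts) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(counts < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  degenerate <- length(unique(values)) == 1
  if (length(counts) == 2) {
    grp <- names(counts)
    x <- values[labels == grp[1]]
    y <- values[labels == grp[2]]
    method <- if (paired) "wilcoxon_signed_rank" else "wilcoxon_rank_sum"
    if (degenerate) {
      # all observations tied: the statistic sits at its null centre and
      # every relabelling is equally extreme
      stat <- if (paired) 0 else length(x) * length(y) / 2
      return(tibble::tibble(method = method, statistic = stat,
                            p_value = 1, n_groups = 2L))
    }
    ht <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                              exact = FALSE))
  } else {
    method <- "kruskal_wallis"
    if (degenerate) {
      return(tibble::tibble(method = method, statistic = 0,
                            p_value = 1, n_groups = length(counts)))
    }
    ht <- stats::kruskal.test(values, factor(labels))
  }
  tibble::tibble(method = method,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 n_groups = length(counts))
}

#' Diversity summary of a repertoire
#'
#' Convenience wrapper computing richness, Simpson index/clonality,
#' Shannon entropy/clonality and the Hill profile on the productive
#' frequency vector of a repertoire.
#'
#' @param rep a `tcr_repertoire`.
#' @param q_grid Hill orders, default 0:5.
#' @return one-row tibble of metrics (Hill numbers in columns `hill_q<Q>`).
#' @export
diversity_summary <- function(rep, q_grid = 0:5) {
  f <- productive_frequencies(rep)
  sh <- shannon_metrics(f)
  hill <- hill_profile(f, q_grid)
  out <- tibble::tibble(
    sample_id = rep$sample_id,
    patient_id = rep$patient_id,
    timepoint = rep$timepoint,
    richness = sum(f > 0),
    total_rearrangements = total_rearrangements(rep),
    simpson_index = sum(f^2),
    simpson_clonality = simpson_clonality(f),
    shannon_entropy = sh$entropy,
    shannon_clonality = sh$clonality
  )
  for (q in q_grid) out[[paste0("hill_q", q)]] <- hill[[as.character(q)]]
  out
}
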