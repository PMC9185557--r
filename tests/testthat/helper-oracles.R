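# Independent reference implementations and fixture builders used as
# oracles across the suite. Kept deliberately naive: correctness over
# speed, and no code shared with the package's own computation paths.

# classic Wagner-Fischer dynamic-programming edit distance
ref_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  prev <- 0:length(cb)
  for (i in seq_along(ca)) {
    cur <- c(i, rep(0L, length(cb)))
    for (j in seq_along(cb)) {
      cur[j + 1] <- min(prev[j + 1] + 1L, cur[j] + 1L,
                        prev[j] + (ca[i] != cb[j]))
    }
    prev <- cur
  }
  prev[length(cb) + 1]
}

# brute-force connected components of the <= max_dist edit-distance
# graph, via repeated breadth-first search over the full pair matrix
ref_edit_components <- function(seqs, max_dist) {
  n <- length(seqs)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) d[i, j] <- d[j, i] <- ref_levenshtein(seqs[i], seqs[j])
    }
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(d[v, ] <= max_dist & is.na(comp)))
    }
  }
  comp
}

# naive summation-based diversity metrics
ref_simpson_clonality <- function(p) {
  s <- 0
  for (x in p) s <- s + x * x
  sqrt(s)
}
ref_shannon_entropy <- function(p) {
  h <- 0
  for (x in p) if (x > 0) h <- h - x * log(x)
  h
}
ref_hill <- function(p, q) {
  p <- p[p > 0]
  if (q == 1) return(exp(ref_shannon_entropy(p)))
  if (q == 0) return(length(p))
  s <- 0
  for (x in p) s <- s + x^q
  s^(1 / (1 - q))
}

# direct two-group log-rank O/E/V accumulation over distinct event times
ref_logrank <- function(times, events, groups) {
  g <- as.integer(factor(groups))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(times[events]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(times == t & events)
    d1 <- sum(times == t & events & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# random normalised frequency vector
random_freqs <- function(n) {
  w <- rexp(n)
  w / sum(w)
}

# small repertoire from parallel vectors
make_rep <- function(cdr3, templates, productive = TRUE,
                     v_gene = "TRBV12-1", j_gene = "TRBJ2-7",
                     sample_id = "S1", patient_id = "P1",
                     timepoint = "SCREENING", ...) {
  repertoire(
    tibble::tibble(cdr3_aa = cdr3, templates = templates,
                   productive = productive, v_gene = v_gene, j_gene = j_gene),
    sample_id = sample_id, patient_id = patient_id, timepoint = timepoint, ...
  )
}

# random CDR3-like sequences (CASS...F junction form)
random_cdr3 <- function(n, min_core = 4, max_core = 10) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  cores <- min_core:max_core
  vapply(cores[sample.int(length(cores), n, replace = TRUE)], function(L) {
    paste0("CASS", paste(sample(aa, L, replace = TRUE), collapse = ""), "F")
  }, character(1))
}

# write a small AIRR TSV fixture, returning its path
write_airr_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
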