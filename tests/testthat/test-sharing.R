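test_that("levenshtein distance matches hand cases and the DP oracle", {
  expect_equal(levenshtein("CASSARTGELFF", "CASSARTGELFF"), 0)
  expect_equal(levenshtein("CASSARTGELFF", "CASSARTGELFG"), 1)
  expect_equal(levenshtein("CASSF", "CAF"), 2)
  expect_error(levenshtein("", "CASSF"), "non-empty")
  set.seed(3)
  a <- random_cdr3(40, min_core = 1, max_core = 8)
  b <- random_cdr3(40, min_core = 1, max_core = 8)
  expect_equal(levenshtein(a, b),
               mapply(ref_levenshtein, a, b, USE.NAMES = FALSE))
})

test_that("levenshtein is a metric on random amino-acid strings", {
  set.seed(17)
  s <- random_cdr3(15, min_core = 1, max_core = 6)
  for (i in 1:15) {
    x <- sample(s, 3)
    expect_equal(levenshtein(x[1], x[2]), levenshtein(x[2], x[1]))
    expect_equal(levenshtein(x[1], x[1]), 0)
    expect_lte(levenshtein(x[1], x[3]),
               levenshtein(x[1], x[2]) + levenshtein(x[2], x[3]))
  }
})

test_that("shared clusters join identical sequences across patients", {
  p1 <- make_rep(c("CASSLGNQPQHF", "CASSAAAAF"), c(5, 5), patient_id = "P1",
                 sample_id = "s1")
  p2 <- make_rep(c("CASSLGNQPQHF", "CASSWWWWF"), c(5, 5), patient_id = "P2",
                 sample_id = "s2")
  cl <- cluster_cdr3(list(p1, p2), max_dist = 0)
  shared <- cl[cl$shared, ]
  expect_equal(nrow(shared), 1)
  expect_equal(shared$representative, "CASSLGNQPQHF")
  expect_setequal(shared$patients[[1]], c("P1", "P2"))
})

test_that("sequences pairwise further than the bound stay singletons", {
  tab <- tibble::tibble(cdr3_aa = c("CASSAAAAF", "CASSWWWWF", "CASSDDDDF"),
                        v_gene = "TRBV9", patient_id = c("P1", "P2", "P3"))
  cl <- cluster_cdr3(tab, max_dist = 1)
  expect_equal(nrow(cl), 3)
  expect_true(all(cl$n_members == 1))
  expect_false(any(cl$shared))
})

test_that("cluster membership equals the brute-force components oracle", {
  set.seed(29)
  seqs <- unique(random_cdr3(150, min_core = 2, max_core = 5))
  tab <- tibble::tibble(cdr3_aa = seqs, v_gene = "TRBV9",
                        patient_id = sample(paste0("P", 1:6), length(seqs),
                                            replace = TRUE))
  for (md in c(0, 1, 2)) {
    cl <- cluster_cdr3(tab, max_dist = md)
    got <- integer(length(seqs))
    for (i in seq_len(nrow(cl))) got[match(cl$members[[i]], seqs)] <- i
    want <- ref_edit_components(seqs, md)
    # same partition up to relabelling
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(got, want, function(x) length(unique(x))) == 1))
  }
})

test_that("clustering output is independent of input order", {
  set.seed(73)
  seqs <- unique(random_cdr3(60, min_core = 2, max_core = 4))
  tab <- tibble::tibble(cdr3_aa = seqs, v_gene = "TRBV9",
                        patient_id = rep_len(c("P1", "P2"), length(seqs)))
  cl1 <- cluster_cdr3(tab, max_dist = 1)
  cl2 <- cluster_cdr3(tab[sample(nrow(tab)), ], max_dist = 1)
  expect_equal(cl1$representative, cl2$representative)
  expect_equal(cl1$members, cl2$members)
})

test_that("same-V-gene mode splits clusters that sequence-level mode joins", {
  tab <- tibble::tibble(cdr3_aa = c("CASSAAAAF", "CASSAAAGF"),
                        v_gene = c("TRBV9", "TRBV12-1"),
                        patient_id = c("P1", "P2"))
  joined <- cluster_cdr3(tab, max_dist = 1, same_vgene = FALSE)
  expect_equal(nrow(joined), 1)
  split <- cluster_cdr3(tab, max_dist = 1, same_vgene = TRUE)
  expect_equal(nrow(split), 2)
})

test_that("composite library applies the more-than-min-clones filter", {
  mk <- function(n) tibble::tibble(cdr3_aa = random_cdr3(n), count = 1)
  set.seed(47)
  tables <- list(a = mk(2), b = mk(3), c = mk(4), d = mk(10), e = mk(1))
  lib <- build_composite_library(tables, min_clones = 3)
  expect_equal(lib$n_samples_retained, 2)
  expect_setequal(unique(lib$entries$source), c("c", "d"))
  # pooled duplicates collapse in the unique index
  dup <- build_composite_library(
    list(x = tibble::tibble(cdr3_aa = c("CASSAF", "CASSAF", "CASSGF", "CASSHF"))),
    min_clones = 3)
  expect_equal(nrow(dup$unique_index), 3)
  expect_lte(nrow(dup$unique_index), nrow(dup$entries))
  expect_error(build_composite_library(list(a = mk(2)), min_clones = 3),
               "minimum clone count")
})

test_that("a generated many-sample library keeps exactly the above-threshold samples", {
  set.seed(59)
  n_samples <- 60
  sizes <- sample(c(1:3, 4:30), n_samples, replace = TRUE,
                  prob = c(rep(0.05, 3), rep(0.85 / 27, 27)))
  tables <- lapply(sizes, function(n) {
    tibble::tibble(cdr3_aa = random_cdr3(n), count = sample(1:5, n, TRUE))
  })
  names(tables) <- sprintf("T%02d", 1:n_samples)
  lib <- build_composite_library(tables, min_clones = 3)
  expect_equal(lib$n_samples_retained, sum(sizes > 3))
  expect_equal(nrow(lib$entries), sum(sizes[sizes > 3]))
})

test_that("library queries equal a brute-force all-pairs scan", {
  set.seed(83)
  lib_seqs <- unique(random_cdr3(1000, min_core = 3, max_core = 8))
  lib <- build_composite_library(
    list(ref = tibble::tibble(cdr3_aa = lib_seqs)), min_clones = 3)
  queries <- c(sample(lib_seqs, 10), random_cdr3(40, min_core = 3, max_core = 8))
  for (md in c(0, 1)) {
    hits <- query_library(queries, lib, max_dist = md)
    # brute force: full distance matrix, no prefilter
    full <- utils::adist(queries, lib$unique_index$cdr3_aa)
    want <- which(full <= md, arr.ind = TRUE)
    expect_equal(nrow(hits), nrow(want))
    got_pairs <- paste(hits$query, hits$match)
    want_pairs <- paste(queries[want[, 1]],
                        lib$unique_index$cdr3_aa[want[, 2]])
    expect_setequal(got_pairs, want_pairs)
  }
  # verbatim queries self-match at distance 0
  self <- query_library(lib_seqs[1], lib, max_dist = 0)
  expect_equal(self$distance, 0L)
  expect_equal(self$match, lib_seqs[1])
  # nothing within reach
  far <- query_library("CWWWWWWWWWWWWWWWWWWWF", lib, max_dist = 1)
  expect_equal(nrow(far), 0)
})

test_that("motif matrices are column-stochastic position frequencies", {
  one <- motif_matrix("CASSF")
  expect_equal(colSums(one), rep(1, 5), ignore_attr = TRUE)
  expect_equal(one["C", 1], 1)
  expect_equal(sum(one == 1), 5) # one-hot columns
  two <- motif_matrix(c("CASSF", "CASTF"))
  expect_equal(two["S", 4], 0.5)
  expect_equal(two["T", 4], 0.5)
  set.seed(19)
  many <- motif_matrix(random_cdr3(20, min_core = 6, max_core = 6))
  expect_equal(colSums(many), rep(1, 11), ignore_attr = TRUE)
  expect_error(motif_matrix(c("CASSF", "CASSAF")), "mixed lengths")
  padded <- motif_matrix(c("CASSF", "CASSAF"), pad = "-")
  expect_equal(colSums(padded), rep(1, 6), ignore_attr = TRUE)
  expect_equal(padded["-", 6], 0.5)
})
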