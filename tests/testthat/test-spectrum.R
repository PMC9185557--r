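test_that("abundance bins follow the documented thresholds and closures", {
  expect_equal(as.character(classify_bin(0.02)), "HYPEREXPANDED")
  expect_equal(as.character(classify_bin(0.01)), "LARGE")   # closed upper bound
  expect_equal(as.character(classify_bin(0.001)), "MEDIUM") # closed upper bound
  expect_equal(as.character(classify_bin(1e-4)), "SMALL_RARE") # downward closure
  expect_equal(as.character(classify_bin(1)), "HYPEREXPANDED")
  expect_error(classify_bin(0), "\\(0, 1\\]")
  expect_error(classify_bin(1.2), "\\(0, 1\\]")
})

test_that("every clone frequency maps to exactly one bin (partition fuzz)", {
  set.seed(31)
  x <- c(10^runif(2000, -7, 0), 1e-4, 1e-3, 1e-2, 1)
  bins <- classify_bin(x)
  expect_false(anyNA(bins))
  # independent re-derivation of the partition, clause by clause
  manual <- ifelse(x > 0.01, "HYPEREXPANDED",
            ifelse(x > 0.001, "LARGE",
            ifelse(x > 1e-4, "MEDIUM", "SMALL_RARE")))
  expect_equal(as.character(bins), manual)
})

test_that("spectrum fractions sum the per-bin template mass", {
  hyper <- make_rep(c("CASSLGF", "CASSPDF", "CASSQRF"), c(50, 40, 10))
  sp <- spectrum_fractions(hyper)
  expect_equal(unname(sp$bin_fractions["HYPEREXPANDED"]), 1)
  expect_equal(sum(sp$bin_fractions), 1, tolerance = 1e-9)

  # 6-clone fixture spanning all bins; oracle = independent per-clone
  # classification then summation
  f <- c(0.5, 0.2, 0.005, 0.004, 0.0005, 0.2905)
  f <- f / sum(f)
  templates <- round(f * 2e6)
  rep6 <- make_rep(random_cdr3(6), templates)
  sp6 <- spectrum_fractions(rep6)
  p <- productive_frequencies(rep6)
  expected <- vapply(BIN_LEVELS, function(b) {
    s <- 0
    for (x in p) {
      bin <- if (x > 0.01) "HYPEREXPANDED" else if (x > 0.001) "LARGE"
             else if (x > 1e-4) "MEDIUM" else "SMALL_RARE"
      if (bin == b) s <- s + x
    }
    s
  }, numeric(1))
  expect_equal(sp6$bin_fractions, expected, tolerance = 1e-12)
  expect_equal(sp6$expanded_fraction,
               unname(expected["LARGE"] + expected["HYPEREXPANDED"]),
               tolerance = 1e-12)
})

test_that("a repertoire of 10,000 equal clones at 1e-4 is entirely small/rare", {
  rep <- make_rep(random_cdr3(10000, min_core = 8, max_core = 10),
                  rep(1, 10000))
  sp <- spectrum_fractions(rep)
  expect_equal(unname(sp$bin_fractions["SMALL_RARE"]), 1)
})

test_that("patient stratification applies the strict >25% rule", {
  prof <- function(ef) {
    structure(list(sample_id = "S", patient_id = "P", timepoint = "SCREENING",
                   bin_fractions = c(HYPEREXPANDED = ef, LARGE = 0,
                                     MEDIUM = 0, SMALL_RARE = 1 - ef),
                   expanded_fraction = ef),
              class = "spectrum_profile")
  }
  expect_equal(stratify_patient(prof(0.26)), "OLIGOCLONAL")
  expect_equal(stratify_patient(prof(0.10)), "POLYCLONAL")
  expect_equal(stratify_patient(prof(0.25)), "POLYCLONAL") # tie-break
})

test_that("stratification is invariant to record order and clone splitting", {
  set.seed(91)
  cdr3 <- random_cdr3(40)
  tmpl <- c(5000, 3000, sample(1:50, 38, replace = TRUE))
  rep1 <- make_rep(cdr3, tmpl)
  perm <- sample(40)
  rep2 <- make_rep(cdr3[perm], tmpl[perm])
  lab1 <- stratify_patient(spectrum_fractions(rep1))
  expect_equal(lab1, stratify_patient(spectrum_fractions(rep2)))
  # split the top clone's templates into two rows with the same key
  expect_warning(
    rep3 <- make_rep(c(cdr3[1], cdr3), c(2000, 3000, tmpl[-1])),
    "merged")
  expect_equal(lab1, stratify_patient(spectrum_fractions(rep3)))
})

test_that("cohort table reproduces per-group oligoclonal proportions", {
  mkprof <- function(pid, ef) {
    structure(list(sample_id = pid, patient_id = pid, timepoint = "SCREENING",
                   bin_fractions = c(HYPEREXPANDED = ef, LARGE = 0,
                                     MEDIUM = 0, SMALL_RARE = 1 - ef),
                   expanded_fraction = ef),
              class = "spectrum_profile")
  }
  efs <- c(0.4, 0.5, rep(0.1, 6), rep(0.05, 4))
  ids <- sprintf("P%02d", seq_along(efs))
  profs <- Map(mkprof, ids, efs)
  cohort <- tibble::tibble(
    patient_id = ids,
    best_response = c("CR", rep("PR", 4), rep("CR", 3), rep("SD", 4)),
    p16_status = "POS", smoking = "NEVER", os_time = 100, os_event = TRUE)
  tab <- cohort_spectrum_table(unname(profs), cohort)
  crpr <- tab[tab$group == "CR/PR", ]
  expect_equal(crpr$n, 8)
  expect_equal(crpr$n_oligoclonal, 2)
  expect_equal(crpr$proportion, 0.25)
  sd_row <- tab[tab$group == "SD", ]
  expect_equal(sd_row$proportion, 0) # all-polyclonal group
  # duplicated baselines require an explicit selector
  expect_error(cohort_spectrum_table(unname(c(profs, profs[1])), cohort),
               "baseline_selector")
})

test_that("spectrum concordance reports per-bin discrepancies", {
  rep <- make_rep(random_cdr3(20), c(4000, 800, sample(1:100, 18, replace = TRUE)))
  sp <- spectrum_fractions(rep)
  same <- spectrum_concordance(sp, sp)
  expect_equal(same$abs_diff, rep(0, 4))
  a <- structure(list(sample_id = "S", patient_id = "P", timepoint = NA,
                      bin_fractions = c(HYPEREXPANDED = 1, LARGE = 0,
                                        MEDIUM = 0, SMALL_RARE = 0),
                      expanded_fraction = 1), class = "spectrum_profile")
  b <- structure(list(sample_id = "S", patient_id = "P", timepoint = NA,
                      bin_fractions = c(HYPEREXPANDED = 0, LARGE = 0,
                                        MEDIUM = 0, SMALL_RARE = 1),
                      expanded_fraction = 0), class = "spectrum_profile")
  disjoint <- spectrum_concordance(a, b)
  expect_equal(max(disjoint$abs_diff), 1)
})

test_that("thinning a deep repertoire perturbs rare bins more than expanded ones", {
  set.seed(12)
  gen <- generate_repertoire("POLYCLONAL", cohort_config(), group = "SD",
                             seed = 77)
  deep <- spectrum_fractions(gen$repertoire)
  diffs <- replicate(30, {
    thin <- spectrum_fractions(thin_repertoire(gen$repertoire, 2000))
    spectrum_concordance(deep, thin)$abs_diff
  })
  mean_diff <- rowMeans(diffs)
  names(mean_diff) <- BIN_LEVELS
  expect_gt(mean_diff["SMALL_RARE"], mean_diff["HYPEREXPANDED"])
})
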