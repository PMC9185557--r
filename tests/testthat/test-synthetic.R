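small_cfg <- function(...) {
  cohort_config(templates_per_sample = 4000L, n_clones = 8000L, ...)
}

test_that("config validation rejects infeasible settings", {
  expect_error(cohort_config(templates_per_sample = 0), "positive")
  expect_error(cohort_config(oligo_expanded_range = c(0.1, 0.5),
                             poly_expanded_range = c(0.02, 0.2)), "disjoint")
  expect_error(cohort_config(oligo_expanded_range = c(0.5, 1.1)), "below 1")
  expect_error(cohort_config(oligo_prevalence = c(`CR/PR` = 1.5, SD = 0.4,
                                                  PD = 0.7)), "\\[0, 1\\]")
})

test_that("generation is deterministic under a fixed seed", {
  g1 <- generate_repertoire("OLIGOCLONAL", small_cfg(), group = "SD", seed = 9)
  g2 <- generate_repertoire("OLIGOCLONAL", small_cfg(), group = "SD", seed = 9)
  expect_identical(g1$repertoire$records, g2$repertoire$records)
  c1 <- generate_cohort(small_cfg(group_sizes = c(`CR/PR` = 3, SD = 3, PD = 3)))
  c2 <- generate_cohort(small_cfg(group_sizes = c(`CR/PR` = 3, SD = 3, PD = 3)))
  expect_identical(c1$cohort, c2$cohort)
  expect_identical(c1$truth$latent_state, c2$truth$latent_state)
})

test_that("realized expanded mass lands inside the configured state ranges", {
  set.seed(1)
  for (i in 1:15) {
    go <- generate_repertoire("OLIGOCLONAL", cohort_config(), group = "SD",
                              seed = 1000 + i)
    ef_o <- spectrum_fractions(go$repertoire)$expanded_fraction
    expect_gte(ef_o, 0.28)
    expect_lte(ef_o, 0.72)
    gp <- generate_repertoire("POLYCLONAL", cohort_config(), group = "SD",
                              seed = 2000 + i)
    ef_p <- spectrum_fractions(gp$repertoire)$expanded_fraction
    expect_lte(ef_p, 0.23)
  }
})

test_that("latent states are recovered by the spectrum classifier", {
  labels <- vapply(1:40, function(i) {
    state <- if (i %% 2 == 0) "OLIGOCLONAL" else "POLYCLONAL"
    g <- generate_repertoire(state, cohort_config(), group = "PD",
                             seed = 3000 + i)
    paste(state, stratify_patient(spectrum_fractions(g$repertoire)))
  }, character(1))
  expect_true(all(vapply(strsplit(labels, " "), function(x) x[1] == x[2],
                         logical(1))))
})

test_that("generated repertoires carry the configured TRBJ2-7 usage", {
  devs <- vapply(1:5, function(i) {
    g <- generate_repertoire("POLYCLONAL", cohort_config(), group = "CR/PR",
                             seed = 4000 + i)
    u <- usage_profile(g$repertoire, "J")
    u$frequencies[["TRBJ2-7"]] - 0.175
  }, numeric(1))
  expect_true(all(abs(devs) <= 0.02))
})

test_that("generated CDR3 lengths concentrate on 13-15 amino acids", {
  g <- generate_repertoire("POLYCLONAL", cohort_config(), group = "SD",
                           seed = 5001)
  rec <- g$repertoire$records
  w <- tapply(rec$templates, nchar(rec$cdr3_aa), sum) / sum(rec$templates)
  expect_gt(sum(w[c("13", "14", "15")]), 0.5)
  expect_true(all(grepl("^CASS[A-Z]*F$", rec$cdr3_aa)))
})

test_that("generated tables round-trip through AIRR write/read", {
  g <- generate_repertoire("POLYCLONAL", small_cfg(), group = "SD", seed = 5)
  path <- tempfile(fileext = ".tsv")
  write_airr(g$repertoire, path)
  back <- read_airr_tsv(path, sample_id = g$repertoire$sample_id,
                        patient_id = g$repertoire$patient_id,
                        timepoint = g$repertoire$timepoint)
  ord <- order(back$records$clonotype_key)
  ord0 <- order(g$repertoire$records$clonotype_key)
  expect_equal(back$records$clonotype_key[ord],
               g$repertoire$records$clonotype_key[ord0])
  expect_equal(back$records$templates[ord],
               g$repertoire$records$templates[ord0])
})

test_that("cohorts honour group sizes, prevalences and survival linkage", {
  cfg <- small_cfg(group_sizes = c(`CR/PR` = 4, SD = 4, PD = 4))
  out <- generate_cohort(cfg)
  expect_equal(nrow(out$cohort), 12)
  expect_equal(length(out$repertoires), 12)
  expect_true(all(out$cohort$os_time > 0))
  expect_false(anyNA(out$cohort$os_event))
  # prevalence 0 yields no oligoclonal ground truth in that group
  cfg0 <- small_cfg(group_sizes = c(`CR/PR` = 6, SD = 2, PD = 2),
                    oligo_prevalence = c(`CR/PR` = 0, SD = 0.45, PD = 0.7))
  out0 <- generate_cohort(cfg0, baselines = FALSE)
  crpr <- out0$truth[out0$truth$group == "CR/PR", ]
  expect_true(all(crpr$latent_state == "POLYCLONAL"))
  # cohort table passes the package's own metadata validation
  path <- tempfile(fileext = ".csv")
  readr::write_csv(out$cohort, path)
  expect_silent(read_cohort_csv(path))
})

test_that("observed oligoclonal fractions track the configured prevalence", {
  cfg <- cohort_config(group_sizes = c(`CR/PR` = 2, SD = 400, PD = 2))
  out <- generate_cohort(cfg, baselines = FALSE)
  sd_truth <- out$truth[out$truth$group == "SD", ]
  frac <- mean(sd_truth$latent_state == "OLIGOCLONAL")
  expect_lt(abs(frac - 0.45), 0.07) # binomial 99.5% CI at n = 400
})

test_that("zero drift and volatility freeze the longitudinal series", {
  g <- generate_repertoire("POLYCLONAL", small_cfg(), group = "SD", seed = 6)
  keys <- g$repertoire$records$clonotype_key
  lg <- generate_longitudinal(
    g$repertoire, small_cfg(), group = "SD",
    drift = setNames(rep(0, length(keys)), keys), volatility = 0, seed = 7)
  f0 <- lg$truth$f_SCREENING
  expect_equal(lg$truth$f_EOT, f0, tolerance = 1e-12)
  expect_equal(lg$truth$exact_log2fc, rep(0, length(f0)), tolerance = 1e-12)
})

test_that("positive drift on top clones raises the tracked top-clone mass", {
  g <- generate_repertoire("POLYCLONAL", small_cfg(), group = "CR/PR", seed = 8)
  lg <- generate_longitudinal(g$repertoire, small_cfg(), group = "CR/PR",
                              volatility = 0, seed = 9)
  top <- names(sort(productive_frequencies(g$repertoire),
                    decreasing = TRUE))[1:10]
  idx <- match(top, lg$truth$clonotype_key)
  mass <- c(sum(lg$truth$f_SCREENING[idx]), sum(lg$truth$f_C1D1[idx]),
            sum(lg$truth$f_C4D1[idx]), sum(lg$truth$f_EOT[idx]))
  expect_true(all(diff(mass) > 0))
})
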