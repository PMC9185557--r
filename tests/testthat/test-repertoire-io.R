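test_that("immunoSEQ parsing maps aliased columns and counts productive rows", {
  path <- write_airr_fixture(c(
    "nucleotide\taminoAcid\tvGeneName\tjGeneName\tcount (templates/reads)\tsequenceStatus",
    "TGTGCC\tCASSLGF\tTRBV12-1\tTRBJ2-7\t10\tIn",
    "TGTGCG\tCASSPDF\tTRBV19-1\tTRBJ2-1\t5\tIn",
    "TGTGCT\t\tTRBV2\tTRBJ1-1\t85\tOut"
  ))
  rep <- read_immunoseq_tsv(path)
  expect_s3_class(rep, "tcr_repertoire")
  expect_equal(nrow(rep$records), 3)
  expect_equal(sum(rep$records$productive), 2)
  # productive frequencies over productive templates
  expect_equal(sort(productive_frequencies(rep)), sort(c(10, 5) / 15),
               ignore_attr = TRUE)
})

test_that("duplicate clonotype rows are merged with summed templates and a warning", {
  path <- write_airr_fixture(c(
    "aminoAcid\tvGeneName\tjGeneName\ttemplates\tframe_type",
    "CASSLGF\tTRBV12-1\tTRBJ2-7\t10\tIn",
    "CASSLGF\tTRBV12-1\tTRBJ2-7\t7\tIn",
    "CASSPDF\tTRBV19-1\tTRBJ2-1\t3\tIn"
  ))
  expect_warning(rep <- read_immunoseq_tsv(path), "merged")
  expect_equal(nrow(rep$records), 2)
  # oracle: manual sum of the two duplicated rows
  expect_equal(rep$records$templates[rep$records$cdr3_aa == "CASSLGF"], 17)
})

test_that("missing mandatory columns and empty files raise named errors", {
  no_templates <- write_airr_fixture(c(
    "aminoAcid\tvGeneName\tframe_type",
    "CASSLGF\tTRBV12-1\tIn"
  ))
  expect_error(read_immunoseq_tsv(no_templates), "templates")
  empty <- write_airr_fixture(
    "aminoAcid\tvGeneName\tjGeneName\ttemplates\tframe_type")
  expect_error(read_immunoseq_tsv(empty), "empty")
})

test_that("rows with unparseable counts are rejected with row diagnostics", {
  path <- write_airr_fixture(c(
    "aminoAcid\ttemplates\tframe_type",
    "CASSLGF\tten\tIn",
    "CASSPDF\t5\tIn"
  ))
  expect_warning(rep <- read_immunoseq_tsv(path), "rejected 1 row")
  expect_equal(nrow(rep$records), 1)
})

test_that("AIRR reading handles the standard columns and the T/F dialect", {
  path <- write_airr_fixture(c(
    "sequence\tjunction_aa\tv_call\td_call\tj_call\tduplicate_count\tproductive",
    "TGT\tCASSAF\tTRBV9\tTRBD1\tTRBJ2-7\t4\tT",
    "TGA\tCASSGF\tTRBV9\t\tTRBJ2-1\t6\tT",
    "TGC\tCASSHF\tTRBV2\t\tTRBJ1-1\t2\tTRUE",
    "TGG\tCASSKF\tTRBV15\t\tTRBJ1-2\t1\tT",
    "TGT\t\tTRBV15\t\tTRBJ1-2\t3\tF"
  ))
  rep <- read_airr_tsv(path)
  expect_equal(nrow(rep$records), 5)
  expect_equal(sum(rep$records$productive), 4)
  expect_true(all(rep$records$d_gene[rep$records$cdr3_aa == "CASSGF"] == "UNKNOWN"))
})

test_that("write_airr / read_airr_tsv round trip preserves canonical fields", {
  rep <- make_rep(c("CASSLGF", "CASSPDF", "CASSQRF"), c(10, 5, 1),
                  v_gene = c("TRBV12-1", "UNKNOWN", "TRBV2"),
                  j_gene = c("TRBJ2-7", "TRBJ2-1", "UNKNOWN"))
  path <- tempfile(fileext = ".tsv")
  write_airr(rep, path)
  # sentinel gene calls serialise as empty v_call/j_call fields
  raw <- read.delim(path)
  expect_true(is.na(raw$v_call[raw$junction_aa == "CASSPDF"]) ||
                raw$v_call[raw$junction_aa == "CASSPDF"] == "")
  back <- read_airr_tsv(path, sample_id = "S1", patient_id = "P1",
                        timepoint = "SCREENING")
  ord <- order(back$records$clonotype_key)
  ord0 <- order(rep$records$clonotype_key)
  expect_equal(back$records$clonotype_key[ord], rep$records$clonotype_key[ord0])
  expect_equal(back$records$templates[ord], rep$records$templates[ord0])
  expect_equal(back$records$v_gene[ord], rep$records$v_gene[ord0])
  expect_equal(back$records$j_gene[ord], rep$records$j_gene[ord0])
  # second round trip is byte-stable on the canonical fields
  path2 <- tempfile(fileext = ".tsv")
  write_airr(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("filter_productive renormalises, is idempotent, and errors on empty", {
  rep <- make_rep(c("CASSLGF", "CASSPDF", ""), c(10, 10, 80),
                  productive = c(TRUE, TRUE, FALSE), denominator = "all")
  out <- filter_productive(rep)
  expect_equal(nrow(out$records), 2)
  expect_equal(unname(sort(productive_frequencies(out))), c(0.5, 0.5))
  again <- filter_productive(out)
  expect_equal(again$records, out$records)
  all_prod <- make_rep(c("CASSLGF", "CASSPDF"), c(1, 3))
  expect_equal(filter_productive(all_prod)$records, all_prod$records)
  all_bad <- make_rep(c("", "CASSX"), c(1, 2), productive = FALSE)
  expect_error(filter_productive(all_bad), "non-productive")
})

test_that("total_rearrangements counts distinct productive clonotype keys", {
  rep <- make_rep(c("CASSLGF", "CASSPDF", "CASSQRF", "CASSTTF"), c(5, 4, 3, 1))
  expect_identical(total_rearrangements(rep), 4L)
  # duplicates merged at construction: count of distinct keys, not rows
  expect_warning(
    dup <- make_rep(c("CASSLGF", "CASSLGF", "CASSPDF"), c(5, 2, 1)),
    "merged")
  expect_identical(total_rearrangements(dup),
                   length(unique(dup$records$clonotype_key)))
  mixed <- make_rep(c("CASSLGF", ""), c(5, 2), productive = c(TRUE, FALSE))
  mixed$records <- mixed$records[!mixed$records$productive, ]
  expect_warning(n <- total_rearrangements(mixed), "0")
  expect_identical(n, 0L)
})

test_that("productive frequencies always sum to one after normalization", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:50, 1)
    rep <- make_rep(random_cdr3(n), sample(1:100, n, replace = TRUE),
                    productive = runif(n) < 0.8)
    if (!any(rep$records$productive)) next
    expect_equal(sum(productive_frequencies(rep)), 1, tolerance = 1e-9)
  }
})

test_that("invalid inputs are rejected by the repertoire constructor", {
  expect_error(make_rep(character(0), numeric(0)), "empty")
  expect_error(make_rep("CASSLGF", -1), "non-negative")
  expect_error(make_rep("CASS1GF", 5), "amino-acid")
  expect_error(make_rep("CASSLGF", 5, v_gene = "NOTAGENE"), "invalid gene")
  expect_error(
    repertoire(tibble::tibble(cdr3_aa = "CASSF", productive = TRUE), "S"),
    "templates")
})

test_that("cohort metadata validation enforces enums and positive times", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,best_response,p16_status,smoking,os_time,os_event",
               "P1,CR,POS,NEVER,100,TRUE",
               "P2,SD,NEG,CURRENT,250,FALSE"), path)
  tab <- read_cohort_csv(path)
  expect_equal(nrow(tab), 2)
  writeLines(c("patient_id,best_response,p16_status,smoking,os_time,os_event",
               "P1,WONDERFUL,POS,NEVER,100,TRUE"), path)
  expect_error(read_cohort_csv(path), "best_response")
  writeLines(c("patient_id,best_response,p16_status,smoking,os_time,os_event",
               "P1,CR,POS,NEVER,0,TRUE"), path)
  expect_error(read_cohort_csv(path), "os_time")
})
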