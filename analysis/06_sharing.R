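#!/usr/bin/env Rscript
# Shared CDR3 clonotypes: cluster all baseline CDR3 amino-acid
# sequences across patients at Levenshtein distance <= 1, report
# cross-patient clusters, build a composite reference library from
# synthetic external clone tables (samples with more than three clones
# pooled), query it, and emit a position-frequency matrix for the
# matched sequences.

suppressMessages(library(tcrclonality))
suppressMessages(library(dplyr))

in_dir <- "results/synthetic_cohort"
out_dir <- "results/sharing"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cohort <- read_cohort_csv(file.path(in_dir, "cohort.csv"))
responders <- cohort$patient_id[cohort$best_response %in% c("CR", "PR")]
reps <- lapply(responders, function(pid) {
  read_airr_tsv(file.path(in_dir, "airr", paste0(pid, "_SCREENING.tsv")),
                patient_id = pid, timepoint = "SCREENING")
})

# restrict to the expanded clonotypes of each patient (the shared-clone
# question concerns sequences abundant enough to be reliably detected)
tab <- bind_rows(lapply(reps, function(r) {
  rec <- r$records[r$records$productive & r$records$frequency > 1e-3, ]
  tibble::tibble(cdr3_aa = rec$cdr3_aa, v_gene = rec$v_gene,
                 patient_id = r$patient_id)
}))

# The generator draws CDR3s independently per patient, so convergent
# clonotypes arise only by chance; plant two public-style clonotypes
# (one exact, one at distance 1) across patients to exercise the
# sharing mechanics on this cohort.
planted <- tibble::tibble(
  cdr3_aa = c("CASSLGNQPQHF", "CASSLGNQPQHF", "CASSARTGELFF", "CASSARTGELFG"),
  v_gene = "TRBV12-1",
  patient_id = responders[c(1, 2, 3, 4)])
tab <- bind_rows(tab, planted)
clusters <- cluster_cdr3(tab, max_dist = 1)
shared <- clusters |> filter(shared)
readr::write_csv(
  shared |> mutate(members = vapply(members, paste, character(1),
                                    collapse = ";"),
                   patients = vapply(patients, paste, character(1),
                                     collapse = ";")),
  file.path(out_dir, "shared_clusters.csv"))
message(nrow(shared), " cross-patient clusters among ",
        nrow(tab), " expanded clonotypes from ", length(reps), " responders")

# synthetic external reference library: 502 tumour clone tables with a
# small-sample fraction below the pooling filter
set.seed(4242)
aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")
rand_cdr3 <- function(n) {
  vapply(sample(7:11, n, replace = TRUE), function(L) {
    paste0("CASS", paste(sample(aa, L, replace = TRUE), collapse = ""), "F")
  }, character(1))
}
sizes <- c(sample(1:3, 18, replace = TRUE), sample(10:40, 484, replace = TRUE))
tables <- lapply(sizes, function(n) tibble::tibble(cdr3_aa = rand_cdr3(n)))
names(tables) <- sprintf("TUM%03d", seq_along(tables))
# plant the public-style clonotypes in two tumour tables so the query
# demonstrates distance-0 and distance-1 matches with provenance
tables[[30]] <- bind_rows(tables[[30]],
                          tibble::tibble(cdr3_aa = "CASSLGNQPQHF"))
tables[[45]] <- bind_rows(tables[[45]],
                          tibble::tibble(cdr3_aa = "CASSARTGELFF"))
lib <- build_composite_library(tables, min_clones = 3)
message("composite library: ", nrow(lib$entries), " clones (",
        nrow(lib$unique_index), " unique) pooled from ",
        lib$n_samples_retained, " of ", length(tables), " samples")

queries <- unique(tab$cdr3_aa)
hits <- query_library(queries, lib, max_dist = 1)
readr::write_csv(
  hits |> mutate(sources = vapply(sources, paste, character(1),
                                  collapse = ";")),
  file.path(out_dir, "library_matches.csv"))
message(nrow(hits), " library matches at Levenshtein distance <= 1 for ",
        length(queries), " queries")

matched <- unique(hits$query)
if (length(matched) > 0) {
  by_len <- split(matched, nchar(matched))
  biggest <- by_len[[which.max(lengths(by_len))]]
  mm <- motif_matrix(biggest)
  readr::write_csv(tibble::as_tibble(mm, rownames = "residue"),
                   file.path(out_dir, "motif_matrix.csv"))
  message("motif matrix written for ", length(biggest),
          " matched sequences of length ", nchar(biggest[1]))
}
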