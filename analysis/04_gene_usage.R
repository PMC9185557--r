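#!/usr/bin/env Rscript
# TRBJ gene usage as a response marker: template-weighted J-gene usage
# per baseline sample, pairwise Jensen-Shannon divergences, 2-D metric
# scaling and clustering (hierarchical, k-means and the eps-component
# density mode), plus a CDR3 spectratype matrix for one sample.

suppressMessages(library(tcrclonality))
suppressMessages(library(dplyr))

in_dir <- "results/synthetic_cohort"
out_dir <- "results/usage"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cohort <- read_cohort_csv(file.path(in_dir, "cohort.csv"))
files <- list.files(file.path(in_dir, "airr"), pattern = "_SCREENING\\.tsv$",
                    full.names = TRUE)
reps <- lapply(files, function(f) {
  pid <- sub("_SCREENING$", "", tools::file_path_sans_ext(basename(f)))
  read_airr_tsv(f, sample_id = pid, patient_id = pid, timepoint = "SCREENING")
})

usage <- lapply(reps, usage_profile, segment_class = "J")
usage_tab <- bind_rows(lapply(usage, function(u) {
  tibble::tibble(patient_id = u$sample_id, gene = names(u$frequencies),
                 frequency = unname(u$frequencies))
}))
readr::write_csv(usage_tab, file.path(out_dir, "j_usage.csv"))

groups <- cohort |>
  mutate(group = ifelse(best_response %in% c("CR", "PR"), "CR/PR",
                        best_response))
trbj27 <- usage_tab |>
  filter(gene == "TRBJ2-7") |>
  inner_join(groups[c("patient_id", "group")], by = "patient_id")
message("TRBJ2-7 usage by response group:")
print(trbj27 |> group_by(group) |>
        summarise(n = n(), median = median(frequency),
                  min = min(frequency), max = max(frequency)))

cl <- usage_cluster(usage, method = "hierarchical", k = 2)
km <- usage_cluster(usage, method = "kmeans", k = 2)
dens <- usage_cluster(usage, method = "density",
                      eps = stats::median(cl$jsd[upper.tri(cl$jsd)]) / 2)
assignments <- tibble::tibble(
  patient_id = names(cl$assignment),
  mds1 = cl$embedding[, 1], mds2 = cl$embedding[, 2],
  hierarchical = unname(cl$assignment),
  kmeans = unname(km$assignment),
  density = unname(dens$assignment)) |>
  inner_join(groups[c("patient_id", "group")], by = "patient_id")
readr::write_csv(assignments, file.path(out_dir, "clusters.csv"))
readr::write_csv(tibble::as_tibble(cl$jsd, rownames = "patient_id"),
                 file.path(out_dir, "jsd_matrix.csv"))
message("hierarchical cluster composition by response group:")
print(table(assignments$hierarchical, assignments$group))

spect <- spectratype(reps[[1]], "V")
readr::write_csv(tibble::as_tibble(spect, rownames = "cdr3_length"),
                 file.path(out_dir, "spectratype_example.csv"))
message("wrote usage tables, JSD matrix, clusters and spectratype to ", out_dir)
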