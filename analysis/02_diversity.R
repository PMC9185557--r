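#!/usr/bin/env Rscript
# Per-sample diversity and clonality: richness (total rearrangements),
# Simpson clonality, Shannon entropy/clonality and Hill profiles
# (orders 0-5) on every baseline sample, with rank-based comparisons of
# Simpson clonality between response groups, smoking strata and p16
# strata.

suppressMessages(library(tcrclonality))
suppressMessages(library(dplyr))

in_dir <- "results/synthetic_cohort"
out_dir <- "results/diversity"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cohort <- read_cohort_csv(file.path(in_dir, "cohort.csv"))
files <- list.files(file.path(in_dir, "airr"), pattern = "_SCREENING\\.tsv$",
                    full.names = TRUE)
reps <- lapply(files, function(f) {
  pid <- sub("_SCREENING$", "", tools::file_path_sans_ext(basename(f)))
  read_airr_tsv(f, patient_id = pid, timepoint = "SCREENING")
})

diversity <- bind_rows(lapply(reps, diversity_summary)) |>
  inner_join(cohort, by = "patient_id") |>
  mutate(group = ifelse(best_response %in% c("CR", "PR"), "CR/PR",
                        best_response),
         ever_smoker = ifelse(smoking == "NEVER", "never", "ever"))
readr::write_csv(diversity, file.path(out_dir, "diversity.csv"))

tests <- bind_rows(
  compare_groups(diversity$simpson_clonality, diversity$group) |>
    mutate(comparison = "simpson_clonality ~ response group"),
  compare_groups(diversity$simpson_clonality, diversity$ever_smoker) |>
    mutate(comparison = "simpson_clonality ~ smoking"),
  compare_groups(diversity$simpson_clonality, diversity$p16_status) |>
    mutate(comparison = "simpson_clonality ~ p16"),
  compare_groups(diversity$total_rearrangements, diversity$group) |>
    mutate(comparison = "total_rearrangements ~ response group")
)
readr::write_csv(tests, file.path(out_dir, "group_tests.csv"))

message("median Simpson clonality by response group:")
print(diversity |> group_by(group) |>
        summarise(n = n(), median_clonality = median(simpson_clonality),
                  median_rearrangements = median(total_rearrangements)))
message("group comparisons written to ", out_dir, "/group_tests.csv")
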