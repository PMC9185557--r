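#!/usr/bin/env Rscript
# The clonotype abundance spectrum: classify every baseline sample's
# clones into the four abundance bins, stratify patients with the >25%
# expanded-fraction rule, tabulate oligoclonal proportions per response
# group, and demonstrate the depth robustness of the labels under 10x
# template thinning.

suppressMessages(library(tcrclonality))
suppressMessages(library(dplyr))

in_dir <- "results/synthetic_cohort"
out_dir <- "results/spectrum"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cohort <- read_cohort_csv(file.path(in_dir, "cohort.csv"))
files <- list.files(file.path(in_dir, "airr"), pattern = "_SCREENING\\.tsv$",
                    full.names = TRUE)
reps <- lapply(files, function(f) {
  pid <- sub("_SCREENING$", "", tools::file_path_sans_ext(basename(f)))
  read_airr_tsv(f, patient_id = pid, timepoint = "SCREENING")
})

profiles <- lapply(reps, spectrum_fractions)
spectrum <- bind_rows(lapply(profiles, function(p) {
  tibble::tibble(patient_id = p$patient_id,
                 hyperexpanded = p$bin_fractions[["HYPEREXPANDED"]],
                 large = p$bin_fractions[["LARGE"]],
                 medium = p$bin_fractions[["MEDIUM"]],
                 small_rare = p$bin_fractions[["SMALL_RARE"]],
                 expanded_fraction = p$expanded_fraction,
                 patient_label = stratify_patient(p))
}))
readr::write_csv(spectrum, file.path(out_dir, "spectrum.csv"))

group_table <- cohort_spectrum_table(profiles, cohort)
readr::write_csv(group_table, file.path(out_dir, "oligoclonal_by_group.csv"))
message("oligoclonal proportions by response group:")
print(group_table)

# depth robustness: relabel each sample after thinning to 2,000 templates
set.seed(1)
robust <- bind_rows(lapply(seq_along(reps), function(i) {
  thin <- spectrum_fractions(thin_repertoire(reps[[i]], 2000))
  conc <- spectrum_concordance(profiles[[i]], thin)
  tibble::tibble(patient_id = profiles[[i]]$patient_id,
                 label_deep = stratify_patient(profiles[[i]]),
                 label_thin = stratify_patient(thin),
                 max_discrepancy_bin = attr(conc, "max_discrepancy_bin"))
}))
readr::write_csv(robust, file.path(out_dir, "depth_robustness.csv"))
message(sum(robust$label_deep == robust$label_thin), " of ", nrow(robust),
        " labels unchanged under 10x thinning; discrepancy concentrates in: ")
print(table(robust$max_discrepancy_bin))
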