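#!/usr/bin/env Rscript
# Longitudinal clonotype dynamics in responders: track the top-10
# baseline clonotypes across timepoints, report their summed mass per
# timepoint, and classify clones under positive/negative selection by
# the log2 fold-change of their frequency between end of treatment and
# screening (neutral band of one log2 unit).

suppressMessages(library(tcrclonality))
suppressMessages(library(dplyr))

in_dir <- "results/synthetic_cohort"
out_dir <- "results/tracking"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cohort <- read_cohort_csv(file.path(in_dir, "cohort.csv"))
responders <- cohort$patient_id[cohort$best_response %in% c("CR", "PR")]

mass_rows <- list()
sel_rows <- list()
for (pid in responders) {
  paths <- list.files(file.path(in_dir, "airr"),
                      pattern = paste0("^", pid, "_"), full.names = TRUE)
  if (length(paths) < 2) next
  reps <- lapply(paths, function(f) {
    tp <- sub(paste0("^", pid, "_"), "", tools::file_path_sans_ext(basename(f)))
    read_airr_tsv(f, patient_id = pid, timepoint = tp)
  })
  tt <- track_clonotypes(reps, selection = "top_baseline", n = 10)
  mass <- top_clonotype_mass(tt)
  mass_rows[[pid]] <- tibble::tibble(patient_id = pid,
                                     timepoint = names(mass),
                                     top10_mass = unname(mass))
  tps <- vapply(reps, function(r) r$timepoint, character(1))
  sel <- selection_analysis(reps[[which(tps == "SCREENING")]],
                            reps[[which(tps == "EOT")]], neutral_band = 1)
  sel_rows[[pid]] <- sel |> mutate(patient_id = pid)
}

mass_tab <- bind_rows(mass_rows)
sel_tab <- bind_rows(sel_rows)
readr::write_csv(mass_tab, file.path(out_dir, "top10_mass.csv"))
readr::write_csv(sel_tab, file.path(out_dir, "selection.csv"))

message("top-10 clonotype mass per timepoint (responders):")
print(mass_tab |> tidyr::pivot_wider(names_from = timepoint,
                                     values_from = top10_mass))
message("selection class counts per patient:")
print(sel_tab |> count(patient_id, selection) |>
        tidyr::pivot_wider(names_from = selection, values_from = n,
                           values_fill = 0))
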