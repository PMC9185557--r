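# tcrclonality

Analysis of peripheral-blood TCR-beta repertoires for
immunotherapy-response stratification, built around the *clonotype
abundance spectrum*: every productive CDR3 clone with relative
frequency X is placed in one of four bins —

| bin | frequency |
|---|---|
| hyperexpanded | X > 0.01 |
| large | 0.001 < X ≤ 0.01 |
| medium | 1e-4 < X ≤ 0.001 |
| small/rare | X ≤ 1e-4 |

— and a patient whose **expanded fraction** (large + hyperexpanded
template mass) exceeds 25% is labelled **oligoclonal**, otherwise
**polyclonal**. Because the expanded fraction rests on abundant
clones, the label is robust to sequencing depth, which is what makes
it a practical peripheral-blood biomarker. Around this sit the
standard repertoire analyses: Simpson clonality √(Σ pᵢ²), Shannon
entropy/clonality, Hill-number profiles ᵠD = (Σ pᵢᵠ)^(1/(1−Q)) for
Q = 0…5, V/J gene-segment usage with Jensen-Shannon divergence and
unsupervised clustering, longitudinal clonotype tracking with log2
fold-change selection calls, cross-patient CDR3 clustering and
reference-library queries at bounded Levenshtein distance, and
Kaplan-Meier / log-rank survival comparison of the stratified groups.

Input is AIRR Rearrangement TSV or immunoSEQ-style export TSV plus a
cohort metadata table. Since patient-level immunosequencing data in
this setting are rarely deposited, the package includes a calibrated
synthetic cohort generator (`cohort_config()`, `generate_cohort()`,
`generate_longitudinal()`) whose defaults encode the study conditions
— response-group sizes 8/20/10, latent oligoclonal prevalences
0.25/0.45/0.70, 20,000 productive templates per sample, disjoint
expanded-mass ranges, TRBJ2-7-skewed responder gene usage — so every
pipeline property is testable as a parameter-recovery experiment.

## Worked example

```r
library(tcrclonality)

cfg <- cohort_config(seed = 20220608)
cohort <- generate_cohort(cfg)

rep <- cohort$repertoires[[1]]
rep
#> <tcr_repertoire> sample SYN0001_SCREENING (patient SYN0001, timepoint SCREENING)
#>   11415 clonotypes (11415 productive), 20,000 templates, key level: aa

sp <- spectrum_fractions(rep)
sp
#> <spectrum_profile> sample SYN0001_SCREENING
#> HYPEREXPANDED         LARGE        MEDIUM    SMALL_RARE
#>        0.0693        0.0316        0.3031        0.5959
#>   expanded fraction: 0.1010
stratify_patient(sp)
#> [1] "POLYCLONAL"

f <- productive_frequencies(rep)
simpson_clonality(f)
#> [1] 0.03957032
round(hill_profile(f), 1)
#>       0       1       2       3       4       5
#> 11415.0  6355.3   638.6   208.4   137.8   111.2
```

A sample with ~10% of its template mass in expanded clones stays
polyclonal (the rule needs >25%); its Hill profile falls from richness
11,415 at Q=0 to an inverse-Simpson effective clone count of ~639 at
Q=2 — the signature of a diverse repertoire with a modest expanded
component.
The full cohort run (`cohort_spectrum_table`, `logrank_test`, …) is
orchestrated by the numbered drivers under `analysis/`:

```sh
Rscript analysis/01_simulate_cohort.R   # cohort + longitudinal AIRR TSVs
Rscript analysis/02_diversity.R         # clonality, Hill profiles, group tests
Rscript analysis/03_spectrum_stratify.R # four-bin spectrum, >25% rule, thinning
Rscript analysis/04_gene_usage.R        # TRBJ usage, JSD, MDS + clustering
Rscript analysis/05_tracking.R          # top-10 trajectories, selection calls
Rscript analysis/06_sharing.R           # shared CDR3 clusters, library queries
Rscript analysis/07_survival.R          # KM curves, log-rank by stratum
```

Each writes its tables under `results/`. `run_pipeline()` performs the
same stages programmatically on any directory of AIRR TSVs and writes
a manifest with MD5 sums so identical configurations reproduce
identical outputs.

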