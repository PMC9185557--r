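#' Default per-group V/J gene-usage profiles for the generator
#'
#' Responder-type (CR/PR) repertoires carry a skewed TRBJ usage
#' dominated by TRBJ2-7 (default mass 0.175, the middle of the 15-20%
#' range seen in most responders), followed by TRBJ2-1 and TRBJ2-3;
#' progressive-disease repertoires use a near-uniform spectrum (~0.10
#' per major gene); stable disease is an even blend of the two. V usage
#' is shared across groups with TRBV12-1 and TRBV19-1 the most used
#' segments.
#'
#' @param trbj27_mass TRBJ2-7 frequency in the responder profile.
#' @return list with elements `V` (one profile) and `J` (named list of
#'   per-group profiles), each a named frequency vector summing to 1.
#' @export
default_usage_profiles <- function(trbj27_mass = 0.175) {
  j_genes <- c("TRBJ1-1", "TRBJ1-2", "TRBJ1-3", "TRBJ1-4", "TRBJ1-5",
               "TRBJ1-6", "TRBJ2-1", "TRBJ2-2", "TRBJ2-3", "TRBJ2-4",
               "TRBJ2-5", "TRBJ2-6", "TRBJ2-7")
  responder <- stats::setNames(rep((1 - trbj27_mass - 0.14 - 0.12) / 10, 13), j_genes)
  responder["TRBJ2-7"] <- trbj27_mass
  responder["TRBJ2-1"] <- 0.14
  responder["TRBJ2-3"] <- 0.12
  uniformish <- stats::setNames(
    c(0.10, 0.10, 0.05, 0.04, 0.08, 0.05, 0.10, 0.03, 0.10, 0.04,
      0.10, 0.05, 0.16), j_genes)
  blend <- (responder + uniformish) / 2
  v_genes <- c("TRBV2", "TRBV3-1", "TRBV4-1", "TRBV5-1", "TRBV6-1",
               "TRBV7-2", "TRBV9", "TRBV10-3", "TRBV11-2", "TRBV12-1",
               "TRBV15", "TRBV18", "TRBV19-1", "TRBV20-1", "TRBV27",
               "TRBV28", "TRBV29-1", "TRBV30")
  v <- stats::setNames(rep(0.04, length(v_genes)), v_genes)
  v["TRBV12-1"] <- 0.12
  v["TRBV19-1"] <- 0.10
  v["TRBV20-1"] <- 0.06
  v["TRBV5-1"] <- 0.08
  v <- v / sum(v)
  list(V = v,
       J = list(`CR/PR` = responder / sum(responder),
                SD = blend / sum(blend),
                PD = uniformish / sum(uniformish)))
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of generated cohorts. The defaults
#' encode the study conditions the analyses assume: per-response-group
#' latent oligoclonal prevalences of 0.25 (CR/PR), 0.45 (SD) and 0.70
#' (PD); 20,000 productive templates per baseline sample; oligoclonal
#' patients carry 30-70% of repertoire mass in a handful of expanded
#' clones (each above the 0.001 large-clone threshold) versus 2-20% for
#' polyclonal patients — disjoint ranges, so the latent state is
#' recoverable from the spectrum; a truncated power-law tail (exponent
#' 2, floor 1e-7) of rare clones; CDR3 lengths centred on 13-15 amino
#' acids; group-specific TRBJ usage (see [default_usage_profiles()]);
#' exponential survival with hazard ratio 2 for oligoclonal patients
#' and independent exponential censoring; and per-clone log-frequency
#' drifts for longitudinal dynamics.
#'
#' @param seed integer RNG seed; per-patient substreams are derived
#'   from it deterministically, so generation is reproducible and
#'   independent of patient order.
#' @param group_sizes named integer vector of patients per response
#'   group (default: the study cohort sizes 8/20/10).
#' @param oligo_prevalence named probability of the latent OLIGOCLONAL
#'   state per group.
#' @param templates_per_sample productive templates per baseline sample.
#' @param n_clones number of distinct tail clones per repertoire.
#' @param n_expanded integer range (min, max) of expanded spike clones.
#' @param oligo_expanded_range,poly_expanded_range intervals from which
#'   the summed expanded-clone mass is drawn per latent state; must be
#'   disjoint.
#' @param tail_exponent power-law exponent of the rare-clone tail.
#' @param tail_fmin truncation floor of tail frequencies.
#' @param usage_profiles per-group V/J usage, see
#'   [default_usage_profiles()].
#' @param cdr3_length_probs named probability vector over CDR3
#'   amino-acid lengths.
#' @param survival list: `base_hazard` (per day), `hr_oligo` (hazard
#'   ratio oligoclonal vs polyclonal), `censor_hazard` (per day).
#' @param dynamics list: `drift_top` and `drift_other` (log2 frequency
#'   drift per timepoint step for top clones and the rest, per response
#'   group), `volatility` (sd of the per-step log2 noise), `top_k`.
#' @param emit_nt also generate random nucleotide rearrangement strings
#'   (slower; defaults to FALSE, amino-acid keys being the default
#'   keying level).
#' @return validated list of class `synthetic_cohort_config`.
#' @export
cohort_config <- function(seed = 20220608,
                          group_sizes = c(`CR/PR` = 8L, SD = 20L, PD = 10L),
                          oligo_prevalence = c(`CR/PR` = 0.25, SD = 0.45, PD = 0.70),
                          templates_per_sample = 20000L,
                          n_clones = 40000L,
                          n_expanded = c(2L, 8L),
                          oligo_expanded_range = c(0.30, 0.70),
                          poly_expanded_range = c(0.02, 0.20),
                          tail_exponent = 2,
                          tail_fmin = 1e-7,
                          usage_profiles = default_usage_profiles(),
                          cdr3_length_probs = c(`11` = 0.05, `12` = 0.10,
                                                `13` = 0.20, `14` = 0.25,
                                                `15` = 0.20, `16` = 0.12,
                                                `17` = 0.08),
                          survival = list(base_hazard = 1 / 500,
                                          hr_oligo = 2,
                                          censor_hazard = 1 / 900),
                          dynamics = list(
                            drift_top = c(`CR/PR` = 0.6, SD = 0, PD = -0.2),
                            drift_other = c(`CR/PR` = -0.1, SD = 0, PD = 0.1),
                            volatility = 0.15,
                            top_k = 10),
                          emit_nt = FALSE) {
  groups <- names(group_sizes)
  stopifnot(!is.null(groups), all(groups %in% names(oligo_prevalence)))
  if (any(oligo_prevalence < 0 | oligo_prevalence > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  if (templates_per_sample <= 0) {
    stop("templates_per_sample must be positive", call. = FALSE)
  }
  if (n_clones <= 0) stop("n_clones must be positive", call. = FALSE)
  # tail clones are held below the large-clone threshold (cap 3e-4), so
  # the tail must have room for the largest possible non-expanded mass
  max_tail_mass <- 1 - min(oligo_expanded_range[1], poly_expanded_range[1])
  if (n_clones * 3e-4 < max_tail_mass) {
    stop("n_clones too small: ", n_clones, " clones capped at 3e-4 cannot ",
         "hold a tail mass of ", signif(max_tail_mass, 3),
         "; need at least ", ceiling(max_tail_mass / 3e-4), call. = FALSE)
  }
  if (max(poly_expanded_range) >= min(oligo_expanded_range) &&
      max(oligo_expanded_range) >= min(poly_expanded_range)) {
    stop("oligo and poly expanded ranges must be disjoint", call. = FALSE)
  }
  if (max(oligo_expanded_range) >= 1) {
    stop("expanded mass range must stay below 1", call. = FALSE)
  }
  if (abs(sum(cdr3_length_probs) - 1) > 1e-9) {
    stop("cdr3_length_probs must sum to 1", call. = FALSE)
  }
  for (p in c(list(usage_profiles$V), usage_profiles$J)) {
    if (abs(sum(p) - 1) > 1e-9) {
      stop("usage profiles must sum to 1", call. = FALSE)
    }
  }
  structure(
    list(seed = as.integer(seed), group_sizes = group_sizes,
         oligo_prevalence = oligo_prevalence,
         templates_per_sample = as.integer(templates_per_sample),
         n_clones = as.integer(n_clones), n_expanded = as.integer(n_expanded),
         oligo_expanded_range = oligo_expanded_range,
         poly_expanded_range = poly_expanded_range,
         tail_exponent = tail_exponent, tail_fmin = tail_fmin,
         usage_profiles = usage_profiles,
         cdr3_length_probs = cdr3_length_probs,
         survival = survival, dynamics = dynamics, emit_nt = emit_nt),
    class = "synthetic_cohort_config"
  )
}

# deterministic per-patient substream seed, independent of patient order
patient_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483629)
}

# Assign one gene per clone so the template-weighted gene usage tracks
# the target profile: heavy clones (above `heavy` mass) are assigned
# greedily to the gene with the largest remaining mass deficit, the
# light bulk is drawn i.i.d. from the renormalised residual deficits.
# Keeps realised usage within multinomial noise of the profile while
# every clone still carries a single gene call.
assign_genes_by_mass <- function(templates, profile, heavy = 0.005) {
  w <- templates / sum(templates)
  genes <- character(length(w))
  deficit <- profile
  heavy_idx <- order(w, decreasing = TRUE)
  heavy_idx <- heavy_idx[w[heavy_idx] > heavy]
  for (i in heavy_idx) {
    g <- which.max(deficit)
    genes[i] <- names(profile)[g]
    deficit[g] <- deficit[g] - w[i]
  }
  light <- setdiff(seq_along(w), heavy_idx)
  resid <- pmax(deficit, 0)
  if (sum(resid) == 0) resid <- profile
  genes[light] <- sample(names(profile), length(light), replace = TRUE,
                         prob = resid / sum(resid))
  genes
}

# mean of a Pareto(exponent) truncated to [a, b]
truncated_pareto_mean <- function(a, b, exponent) {
  if (abs(exponent - 1) < 1e-12) {
    (b - a) / log(b / a)
  } else if (abs(exponent - 2) < 1e-12) {
    log(b / a) / (1 / a - 1 / b)
  } else {
    c0 <- (1 - exponent) / (b^(1 - exponent) - a^(1 - exponent))
    c0 * (b^(2 - exponent) - a^(2 - exponent)) / (2 - exponent)
  }
}

# Truncated power-law tail frequencies with total mass `mass`, held
# below the large-clone threshold (upper truncation 3e-4, leaving
# headroom for multinomial noise at the default depth). The lower
# truncation point is solved so that the expected per-clone frequency
# equals mass/n: the realised sum then only needs a ~1% rescale, so no
# probability mass piles up at the cap and the tail stays dust-like —
# the property behind the depth robustness of the patient labels.
sample_tail <- function(n, mass, exponent, fmin_floor, cap = 3e-4) {
  target <- mass / n
  if (target >= cap) {
    stop("tail mass per clone exceeds the sub-threshold cap; ",
         "increase n_clones", call. = FALSE)
  }
  lo_mean <- truncated_pareto_mean(fmin_floor, cap, exponent)
  fmin <- if (lo_mean >= target) {
    fmin_floor
  } else {
    stats::uniroot(function(a) truncated_pareto_mean(a, cap, exponent) - target,
                   lower = fmin_floor, upper = cap * 0.999,
                   tol = 1e-12)$root
  }
  u <- runif(n)
  x <- if (abs(exponent - 1) < 1e-12) {
    fmin * (cap / fmin)^u
  } else {
    (fmin^(1 - exponent) +
       u * (cap^(1 - exponent) - fmin^(1 - exponent)))^(1 / (1 - exponent))
  }
  x <- x / sum(x) * mass
  for (i in 1:50) {
    over <- x > cap
    if (!any(over) || all(over)) break
    excess <- sum(x[over] - cap)
    x[over] <- cap
    under <- !over
    x[under] <- x[under] + excess * x[under] / sum(x[under])
  }
  x
}

#' Generate one synthetic baseline repertoire
#'
#' Builds a clone frequency vector for the given latent clonal state —
#' a handful of expanded spike clones whose summed mass is drawn from
#' the state's expanded range (each spike at least 1.5e-3, so it lands
#' in the large/hyperexpanded bins) plus a truncated power-law tail —
#' then samples template counts multinomially at the configured depth.
#' CDR3 amino-acid sequences take the canonical `CASS...F` junction
#' form with a random core at the configured length distribution; V/J
#' genes are drawn from the group's usage profile.
#'
#' @param latent_state `"OLIGOCLONAL"` or `"POLYCLONAL"`.
#' @param config a `synthetic_cohort_config`.
#' @param group response group name (selects the J usage profile).
#' @param sample_id,patient_id,timepoint provenance for the repertoire.
#' @param seed integer seed for this repertoire's substream.
#' @return list with `repertoire` (a `tcr_repertoire`) and `truth`
#'   (one-row tibble: latent state, true expanded mass, spike count and
#'   the exact pre-sampling frequency vector as a list-column).
#' @export
generate_repertoire <- function(latent_state = c("OLIGOCLONAL", "POLYCLONAL"),
                                config = cohort_config(),
                                group = "SD",
                                sample_id = "S1",
                                patient_id = "P1",
                                timepoint = "SCREENING",
                                seed = config$seed) {
  latent_state <- match.arg(latent_state)
  stopifnot(inherits(config, "synthetic_cohort_config"))
  if (!group %in% names(config$usage_profiles$J)) {
    stop("no usage profile for group '", group, "'", call. = FALSE)
  }
  set.seed(seed)
  rng_range <- if (latent_state == "OLIGOCLONAL") {
    config$oligo_expanded_range
  } else {
    config$poly_expanded_range
  }
  mass <- runif(1, rng_range[1], rng_range[2])
  k_choices <- config$n_expanded[1]:config$n_expanded[2]
  k <- k_choices[sample.int(length(k_choices), 1)]
  spike_floor <- 1.5e-3
  k <- max(1L, min(k, as.integer(floor(mass / (2 * spike_floor)))))
  w <- stats::rgamma(k, shape = 2)
  spikes <- spike_floor + w / sum(w) * (mass - k * spike_floor)
  tail <- sample_tail(config$n_clones, 1 - mass, config$tail_exponent,
                      config$tail_fmin)
  freqs <- c(spikes, tail)
  counts <- as.vector(rmultinom(1, config$templates_per_sample, freqs))
  obs <- which(counts > 0)
  n_obs <- length(obs)
  len_choices <- as.integer(names(config$cdr3_length_probs))
  lens <- len_choices[sample.int(length(len_choices), n_obs, replace = TRUE,
                                 prob = config$cdr3_length_probs)]
  cdr3 <- random_aa_strings(pmax(lens - 5L, 1L), prefix = "CASS", suffix = "F")
  dup <- duplicated(cdr3)
  while (any(dup)) {
    cdr3[dup] <- random_aa_strings(pmax(lens[dup] - 5L, 1L),
                                   prefix = "CASS", suffix = "F")
    dup <- duplicated(cdr3)
  }
  jp <- config$usage_profiles$J[[group]]
  vp <- config$usage_profiles$V
  j_genes <- assign_genes_by_mass(counts[obs], jp)
  records <- tibble::tibble(
    rearrangement_nt = if (config$emit_nt) {
      vapply(nchar(cdr3) * 3L, function(L) {
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      }, character(1))
    } else NA_character_,
    cdr3_aa = cdr3,
    v_gene = sample(names(vp), n_obs, replace = TRUE, prob = vp),
    d_gene = "UNKNOWN",
    j_gene = j_genes,
    templates = counts[obs],
    productive = TRUE
  )
  rep <- fast_repertoire(records, sample_id = sample_id,
                         patient_id = patient_id, timepoint = timepoint)
  truth <- tibble::tibble(
    patient_id = patient_id,
    sample_id = sample_id,
    latent_state = latent_state,
    group = group,
    true_expanded_mass = mass,
    n_spikes = k,
    exact_freqs = list(stats::setNames(freqs[obs] / sum(freqs),
                                       rep$records$clonotype_key))
  )
  list(repertoire = rep, truth = truth)
}

#' Generate a synthetic patient cohort
#'
#' For each patient: draws the latent clonal state from the group's
#' prevalence, generates a baseline (screening) repertoire under that
#' state, and simulates overall survival as exponential with the
#' baseline hazard multiplied by the configured ratio for oligoclonal
#' patients, with independent exponential censoring. Clinical
#' covariates (p16 status, smoking, age) are drawn to match the study
#' cohort's marginals. Deterministic for a fixed config seed, with
#' per-patient substreams so results do not depend on patient order.
#'
#' @param config a `synthetic_cohort_config`.
#' @param baselines generate baseline repertoires (set FALSE to draw
#'   only latent states and outcomes, e.g. for large survival
#'   simulations).
#' @return list with `repertoires` (named list of `tcr_repertoire`),
#'   `cohort` (tibble in [read_cohort_csv()] layout plus `age`), and
#'   `truth` (tibble of per-patient ground truth; never consumed by the
#'   analysis stages).
#' @export
generate_cohort <- function(config = cohort_config(), baselines = TRUE) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  groups <- rep(names(config$group_sizes), config$group_sizes)
  n <- length(groups)
  ids <- sprintf("SYN%04d", seq_len(n))
  repertoires <- list()
  truth_rows <- vector("list", n)
  cohort_rows <- vector("list", n)
  for (i in seq_len(n)) {
    ps <- patient_seed(config$seed, i)
    set.seed(ps)
    state <- if (runif(1) < config$oligo_prevalence[[groups[i]]]) {
      "OLIGOCLONAL"
    } else {
      "POLYCLONAL"
    }
    hazard <- config$survival$base_hazard *
      if (state == "OLIGOCLONAL") config$survival$hr_oligo else 1
    t_death <- rexp(1, hazard)
    t_censor <- rexp(1, config$survival$censor_hazard)
    os_time <- max(1, round(min(t_death, t_censor)))
    os_event <- t_death <= t_censor
    p16 <- if (runif(1) < 0.56) "POS" else "NEG"
    smoking <- sample(c("CURRENT", "PREVIOUS", "NEVER"), 1,
                      prob = c(0.10, 0.51, 0.39))
    age <- round(min(max(rnorm(1, 61.6, 11.3), 24), 90))
    best_response <- if (groups[i] == "CR/PR") {
      sample(c("CR", "PR"), 1, prob = c(1 / 3, 2 / 3))
    } else {
      groups[i]
    }
    cohort_rows[[i]] <- tibble::tibble(
      patient_id = ids[i], best_response = best_response,
      p16_status = p16, smoking = smoking, age = age,
      os_time = os_time, os_event = os_event
    )
    if (baselines) {
      gen <- generate_repertoire(state, config, group = groups[i],
                                 sample_id = paste0(ids[i], "_SCREENING"),
                                 patient_id = ids[i],
                                 timepoint = "SCREENING",
                                 seed = patient_seed(ps, 1))
      repertoires[[gen$repertoire$sample_id]] <- gen$repertoire
      truth_rows[[i]] <- gen$truth
    } else {
      truth_rows[[i]] <- tibble::tibble(
        patient_id = ids[i], sample_id = NA_character_,
        latent_state = state, group = groups[i],
        true_expanded_mass = NA_real_, n_spikes = NA_integer_,
        exact_freqs = list(NULL)
      )
    }
  }
  list(repertoires = repertoires,
       cohort = dplyr::bind_rows(cohort_rows),
       truth = dplyr::bind_rows(truth_rows))
}

#' Generate a longitudinal repertoire series for one patient
#'
#' Starting from a baseline repertoire, evolves each clone's
#' log2-frequency by a per-clone drift (group-specific for the top-k
#' clones versus the rest, or an explicit per-clone vector) plus
#' Gaussian volatility per timepoint step, renormalises, and samples
#' template counts at each timepoint. The returned truth table holds
#' the exact (pre-sampling) frequencies per timepoint and the exact
#' realised log2 fold-change between the last and first timepoints, so
#' recovery checks compare observed calls against the true programmed
#' dynamics.
#'
#' @param baseline a `tcr_repertoire` (e.g. from
#'   [generate_repertoire()]).
#' @param config a `synthetic_cohort_config`.
#' @param group response group (selects default drifts).
#' @param timepoints ordered subset of `TIMEPOINT_LEVELS` starting at
#'   the baseline's timepoint.
#' @param drift optional explicit per-clone drift vector (log2 units
#'   per step), named by clonotype key; overrides the group defaults.
#' @param volatility per-step log2 noise sd; defaults to the config's.
#' @param seed substream seed.
#' @return list with `repertoires` (named list by timepoint, the first
#'   being the baseline itself) and `truth` (tibble: clonotype key,
#'   drift, exact frequency per timepoint, exact log2fc last vs first).
#' @export
generate_longitudinal <- function(baseline, config = cohort_config(),
                                  group = "SD",
                                  timepoints = c("SCREENING", "C1D1", "C4D1", "EOT"),
                                  drift = NULL, volatility = NULL,
                                  seed = config$seed) {
  stopifnot(inherits(baseline, "tcr_repertoire"))
  stopifnot(all(timepoints %in% TIMEPOINT_LEVELS), length(timepoints) >= 2)
  set.seed(seed)
  f0 <- productive_frequencies(baseline)
  keys <- names(f0)
  if (is.null(drift)) {
    dyn <- config$dynamics
    top <- names(sort(f0, decreasing = TRUE))[seq_len(min(dyn$top_k, length(f0)))]
    drift <- stats::setNames(rep(dyn$drift_other[[group]], length(keys)), keys)
    drift[top] <- dyn$drift_top[[group]]
  } else {
    stopifnot(all(keys %in% names(drift)))
    drift <- drift[keys]
  }
  vol <- volatility %||% config$dynamics$volatility
  n_steps <- length(timepoints) - 1
  exact <- matrix(0, length(keys), length(timepoints),
                  dimnames = list(keys, timepoints))
  exact[, 1] <- f0
  log2f <- log2(f0)
  reps <- stats::setNames(vector("list", length(timepoints)), timepoints)
  reps[[1]] <- baseline
  lookup <- baseline$records[baseline$records$productive, ]
  for (s in seq_len(n_steps)) {
    log2f <- log2f + drift + if (vol > 0) rnorm(length(keys), 0, vol) else 0
    f <- 2^log2f
    f <- f / sum(f)
    exact[, s + 1] <- f
    log2f <- log2(f)
    counts <- as.vector(rmultinom(1, config$templates_per_sample, f))
    obs <- counts > 0
    rec <- lookup[match(keys[obs], lookup$clonotype_key), ]
    rec$templates <- counts[obs]
    reps[[s + 1]] <- repertoire(
      rec[c("rearrangement_nt", "cdr3_aa", "v_gene", "d_gene", "j_gene",
            "templates", "productive")],
      sample_id = paste0(baseline$patient_id, "_", timepoints[s + 1]),
      patient_id = baseline$patient_id,
      timepoint = timepoints[s + 1]
    )
  }
  truth <- tibble::tibble(
    clonotype_key = keys,
    drift = unname(drift),
    exact_log2fc = unname(log2(exact[, length(timepoints)]) -
                            log2(exact[, 1]))
  )
  for (tp in timepoints) truth[[paste0("f_", tp)]] <- unname(exact[, tp])
  list(repertoires = reps, truth = truth)
}
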