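#' Kaplan-Meier survival curve
#'
#' Product-limit estimate \eqn{S(t) = \prod_{t_i \le t} (1 - d_i/n_i)}
#' of the survivor function, computed with the standard survival
#' machinery and returned as a tidy step-function table. Censoring at an
#' event time is ordered after the events at that time (the usual
#' convention); S is non-increasing with S(0) = 1 and constant between
#' event times.
#'
#' @param times positive follow-up durations.
#' @param events logical (or 0/1) event indicators; FALSE = censored.
#' @return tibble of class `km_curve` with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, beginning with the (0, 1) anchor row.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("need at least one subject", call. = FALSE)
  if (anyNA(times) || any(times <= 0)) {
    stop("times must be positive", call. = FALSE)
  }
  events <- as.logical(events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- tibble::tibble(
    time = c(0, fit$time),
    n_risk = c(length(times), fit$n.risk),
    n_event = c(0, fit$n.event),
    n_censor = c(0, fit$n.censor),
    survival = c(1, fit$surv)
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve a `km_curve`.
#' @param t times at which to read off S(t).
#' @return numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(t, function(x) {
    i <- findInterval(x, curve$time)
    curve$survival[max(i, 1)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic: observed minus expected events summed
#' over distinct event times with the hypergeometric variance (ties
#' handled with the multi-event form), referred to a chi-square with 1
#' degree of freedom; two-sided p value.
#'
#' @param times positive follow-up durations.
#' @param events event indicators.
#' @param groups group label per subject; exactly two distinct labels,
#'   each group with at least one subject and the comparison requires at
#'   least one event overall.
#' @return list with `statistic` (chi-square, 1 df), `p_value`,
#'   `observed` and `expected` (named per group).
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(factor(groups, levels = lev)) == 0)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  events <- as.logical(events)
  if (!any(events)) stop("no events observed", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  stat <- unname(sd$chisq)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = stats::setNames(sd$obs, sub("^groups=", "", names(sd$n))),
       expected = stats::setNames(sd$exp, sub("^groups=", "", names(sd$n))))
}

#' Survival comparison of oligoclonal vs polyclonal patients, by stratum
#'
#' Joins patient clonotype labels onto the cohort table and compares
#' overall survival between the two labels with Kaplan-Meier curves and
#' the log-rank test — overall and within each level of an optional
#' subgroup filter (`p16_status` or `smoking`). Strata with fewer than
#' two patients per label are skipped with a warning. Also emits the
#' per-patient covariate table (label, p16, smoking, and any extra
#' columns such as age or productive templates present in `cohort`)
#' ready for external Cox-regression fitting.
#'
#' @param cohort cohort tibble (see [read_cohort_csv()]); extra columns
#'   are carried into the covariate table.
#' @param labels tibble with `patient_id` and `patient_label`
#'   (OLIGOCLONAL/POLYCLONAL), e.g. derived via [stratify_patient()].
#' @param stratify_by `NULL` (overall only), `"p16_status"` or
#'   `"smoking"`.
#' @return list with `strata` (named list; each element has `curves`, a
#'   named list of `km_curve` per label, and `test`, the log-rank
#'   result) and `covariates` (tibble).
#' @export
stratified_survival_report <- function(cohort, labels, stratify_by = NULL) {
  tab <- dplyr::inner_join(cohort, labels, by = "patient_id")
  if (!is.null(stratify_by) &&
      !stratify_by %in% c("p16_status", "smoking")) {
    stop("stratify_by must be NULL, 'p16_status' or 'smoking'", call. = FALSE)
  }
  run_stratum <- function(dat, name) {
    counts <- table(dat$patient_label)
    if (length(counts) < 2 || any(counts < 2)) {
      warning("stratum '", name, "' skipped: fewer than 2 patients per label",
              call. = FALSE)
      return(NULL)
    }
    curves <- lapply(split(dat, dat$patient_label), function(g) {
      km_estimate(g$os_time, g$os_event)
    })
    test <- logrank_test(dat$os_time, dat$os_event, dat$patient_label)
    list(curves = curves, test = test, n = nrow(dat))
  }
  strata <- list(overall = run_stratum(tab, "overall"))
  if (!is.null(stratify_by)) {
    for (lv in unique(tab[[stratify_by]])) {
      strata[[paste0(stratify_by, "=", lv)]] <-
        run_stratum(tab[tab[[stratify_by]] == lv, ],
                    paste0(stratify_by, "=", lv))
    }
  }
  strata <- strata[!vapply(strata, is.null, logical(1))]
  covariates <- tab
  list(strata = strata, covariates = covariates)
}
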