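#' Harrell's concordance index
#'
#' The probability that, of a comparable pair of subjects, the one with the
#' higher risk score has the earlier event. A pair is comparable when the
#' ordering of event times is determinable under right censoring: the
#' earlier time belongs to a subject with an observed event and the times
#' differ. Tied scores on a comparable pair contribute 1/2.
#'
#' @param scores numeric risk scores (higher = riskier).
#' @param times follow-up times.
#' @param event_flags 0/1 event indicators.
#' @return A list with `c` (the index) and `n_pairs` (comparable pairs).
#' @export
concordance_index <- function(scores, times, event_flags) {
  n <- length(scores)
  stopifnot(length(times) == n, length(event_flags) == n,
            all(event_flags %in% 0:1))
  if (sum(event_flags) == 0) stop("no events: no comparable pairs", call. = FALSE)
  dt <- outer(times, times, `<`)                 # dt[i,j]: t_i < t_j
  ev <- matrix(event_flags == 1, n, n)           # by row: subject i had event
  comparable <- dt & ev                          # i event, strictly earlier
  ds <- outer(scores, scores, `-`)               # s_i - s_j
  concordant <- sum(comparable & ds > 0)
  tied <- sum(comparable & ds == 0)
  n_pairs <- sum(comparable)
  if (n_pairs == 0) stop("no comparable pairs", call. = FALSE)
  list(c = (concordant + 0.5 * tied) / n_pairs, n_pairs = n_pairs)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples subjects (indices `1..n_subjects`) with replacement,
#' recomputes `statistic` on each resample, and reports the 2.5/97.5
#' percentile interval around the full-data point estimate. A resample on
#' which the statistic fails (e.g. no comparable pairs) is redrawn, up to
#' 10 retries. Deterministic given `seed`.
#'
#' @param statistic function taking an integer index vector and returning a
#'   scalar.
#' @param n_subjects cohort size.
#' @param n_resamples number of bootstrap resamples (default 100, >= 2).
#' @param seed integer seed.
#' @return A list with `estimate`, `lower`, `upper`, `resamples` (the
#'   bootstrap statistics).
#' @export
bootstrap_ci <- function(statistic, n_subjects, n_resamples = 100, seed = 1) {
  if (n_resamples < 2) stop("`n_resamples` must be at least 2", call. = FALSE)
  estimate <- statistic(seq_len(n_subjects))
  stats_boot <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_resamples), function(b) {
      for (try in seq_len(10)) {
        idx <- sample.int(n_subjects, n_subjects, replace = TRUE)
        val <- tryCatch(statistic(idx), error = function(e) NA_real_)
        if (is.finite(val)) return(val)
      }
      stop("bootstrap statistic failed on 10 consecutive resamples", call. = FALSE)
    }, numeric(1))
  })
  q <- stats::quantile(stats_boot, c(0.025, 0.975), names = FALSE)
  list(estimate = estimate, lower = q[1], upper = q[2], resamples = stats_boot)
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood maximisation of the linear Cox model, reporting
#' hazard ratios with Wald 95% confidence intervals and p-values.
#'
#' @param covariates numeric matrix or data frame of covariates (no
#'   constant columns).
#' @param times follow-up times.
#' @param event_flags 0/1 event indicators (>= 1 event).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return An object of class `cox_fit`; see [tidy.cox_fit()] and
#'   [glance.cox_fit()].
#' @export
fit_cox <- function(covariates, times, event_flags, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(nrow(x) == length(times), length(times) == length(event_flags))
  if (sum(event_flags) == 0) stop("no events", call. = FALSE)
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    stop("constant covariate column(s): ",
         paste(colnames(x)[const], collapse = ", "), call. = FALSE)
  }
  fit <- survival::coxph(survival::Surv(times, event_flags) ~ x,
                         ties = ties,
                         control = survival::coxph.control(eps = 1e-10,
                                                           iter.max = 100))
  if (any(!is.finite(sqrt(diag(fit$var))))) {
    stop("non-finite standard errors (possible monotone likelihood / ",
         "perfect separation)", call. = FALSE)
  }
  beta <- stats::coef(fit)
  names(beta) <- colnames(x)
  se <- sqrt(diag(fit$var))
  z <- stats::qnorm(0.975)
  structure(list(
    coefficients = beta,
    se = stats::setNames(se, colnames(x)),
    hazard_ratios = exp(beta),
    ci_lower = exp(beta - z * se),
    ci_upper = exp(beta + z * se),
    p_values = stats::setNames(2 * stats::pnorm(-abs(beta / se)), colnames(x)),
    log_likelihood = fit$loglik[2],
    n = length(times), n_events = sum(event_flags),
    ties = ties, model = "cox"
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<%s fit> n = %d, events = %d, logLik = %.4f\n",
              if (x$model == "fine_gray") "Fine-Gray" else "Cox",
              x$n, x$n_events, x$log_likelihood))
  print(tidy.cox_fit(x))
  invisible(x)
}

#' Tidy a Cox or Fine-Gray fit
#'
#' @param x a `cox_fit`.
#' @param ... unused.
#' @return A tibble with one row per coefficient: `term`, `estimate` (log
#'   hazard), `std.error`, `hazard.ratio`, `conf.low`, `conf.high` (on the
#'   hazard-ratio scale), `p.value`.
#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    hazard.ratio = unname(x$hazard_ratios),
    conf.low = unname(x$ci_lower),
    conf.high = unname(x$ci_upper),
    p.value = unname(x$p_values)
  )
}

#' Glance at a Cox or Fine-Gray fit
#'
#' @inheritParams tidy.cox_fit
#' @return A one-row tibble: `n`, `n.events`, `logLik`, `ties`, `model`.
#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n.events = x$n_events, logLik = x$log_likelihood,
                 ties = x$ties, model = x$model)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with Greenwood variance and a log(-log) 95%
#' confidence band.
#'
#' @param times follow-up times.
#' @param event_flags 0/1 event indicators.
#' @return A tibble of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `survival`, `conf_low`, `conf_high`, one row per distinct observed
#'   time.
#' @export
kaplan_meier <- function(times, event_flags) {
  stopifnot(length(times) >= 1, length(times) == length(event_flags))
  fit <- survival::survfit(survival::Surv(times, event_flags) ~ 1,
                           conf.type = "log-log")
  out <- tibble::tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    survival = fit$surv,
    conf_low = ifelse(is.na(fit$lower), fit$surv, fit$lower),
    conf_high = ifelse(is.na(fit$upper), fit$surv, fit$upper)
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' Log-rank test
#'
#' @param times follow-up times.
#' @param event_flags 0/1 event indicators.
#' @param group group labels (>= 2 distinct values).
#' @return A list with `chi2`, `df`, `p`.
#' @export
log_rank_test <- function(times, event_flags, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2) stop("log-rank needs at least 2 groups", call. = FALSE)
  if (sum(event_flags) == 0) stop("no events in any group", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(times, event_flags) ~ group)
  df <- nlevels(group) - 1
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Fine-Gray competing-risks regression
#'
#' Subdistribution-hazard model for the cumulative incidence of the
#' primary event (code 1) with a competing event (code 2): subjects
#' failing from the competing cause remain in later risk sets with
#' censoring-distribution weights. Returns subhazard ratios with Wald 95%
#' intervals. With zero competing events the model reduces to the Cox
#' model with Breslow ties.
#'
#' @param covariates numeric matrix or data frame.
#' @param times follow-up times.
#' @param event_codes integer codes: 0 censored, 1 primary event,
#'   2 competing event.
#' @return A `cox_fit` object with `model = "fine_gray"`.
#' @export
fine_gray <- function(covariates, times, event_codes) {
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(all(event_codes %in% 0:2))
  if (sum(event_codes == 1) == 0) stop("no primary events", call. = FALSE)
  if (all(event_codes[event_codes != 0] == 2)) {
    stop("all events are competing events; nothing to model", call. = FALSE)
  }
  fit <- cmprsk::crr(ftime = times, fstatus = event_codes, cov1 = x,
                     failcode = 1, cencode = 0, gtol = 1e-12, maxiter = 50)
  beta <- stats::setNames(fit$coef, colnames(x))
  se <- stats::setNames(sqrt(diag(fit$var)), colnames(x))
  z <- stats::qnorm(0.975)
  structure(list(
    coefficients = beta, se = se,
    hazard_ratios = exp(beta),
    ci_lower = exp(beta - z * se),
    ci_upper = exp(beta + z * se),
    p_values = 2 * stats::pnorm(-abs(beta / se)),
    log_likelihood = fit$loglik,
    n = length(times), n_events = sum(event_codes == 1),
    ties = "breslow", model = "fine_gray"
  ), class = "cox_fit")
}

#' Continuous (category-free) net reclassification improvement
#'
#' `NRI = [P(up | event) - P(down | event)] + [P(down | non-event) -
#' P(up | non-event)]`, where "up" means the new score exceeds the old.
#' Ranges over `[-2, 2]`; 0 when the new score never moves.
#'
#' @param old_scores,new_scores numeric score vectors.
#' @param event_flags 0/1 event indicators (both classes must be present).
#' @return The NRI (scalar).
#' @export
nri_continuous <- function(old_scores, new_scores, event_flags) {
  n <- length(old_scores)
  stopifnot(length(new_scores) == n, length(event_flags) == n)
  ev <- event_flags == 1
  if (!any(ev) || all(ev)) {
    stop("need both event and non-event subjects", call. = FALSE)
  }
  up <- new_scores > old_scores
  down <- new_scores < old_scores
  (mean(up[ev]) - mean(down[ev])) + (mean(down[!ev]) - mean(up[!ev]))
}

#' Incidence rate per 100 person-years with exact Poisson interval
#'
#' @param n_events observed event count (>= 0).
#' @param person_years total follow-up (> 0).
#' @return A list with `rate` (per 100 person-years), `lower`, `upper`
#'   (exact Poisson 95% bounds from chi-square quantiles).
#' @export
incidence_rate <- function(n_events, person_years) {
  if (person_years <= 0) stop("`person_years` must be positive", call. = FALSE)
  if (n_events < 0) stop("`n_events` must be >= 0", call. = FALSE)
  lower <- if (n_events == 0) 0 else stats::qchisq(0.025, 2 * n_events) / 2
  upper <- stats::qchisq(0.975, 2 * n_events + 2) / 2
  list(rate = 100 * n_events / person_years,
       lower = 100 * lower / person_years,
       upper = 100 * upper / person_years)
}

#' Sample size for comparing two proportions
#'
#' Classical two-sided two-sample z-test formula with pooled variance under
#' the null: `n per group = (z_{1-alpha/2} sqrt(2 pbar (1-pbar)) +
#' z_{1-beta} sqrt(p1(1-p1) + p2(1-p2)))^2 / (p1-p2)^2`, `pbar = (p1+p2)/2`,
#' equal allocation, rounded up per group.
#'
#' @param p1,p2 the two proportions (e.g. event-free survival fractions of
#'   the groups being compared), distinct, in (0, 1).
#' @param alpha two-sided type-I error.
#' @param power target power (1 - beta).
#' @return A list with `n_per_group` and `n_total`.
#' @export
sample_size_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.90) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, alpha > 0, alpha < 1,
            power > 0, power < 1)
  if (p1 == p2) stop("`p1` and `p2` must differ", call. = FALSE)
  pbar <- (p1 + p2) / 2
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  n <- (za * sqrt(2 * pbar * (1 - pbar)) +
          zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / (p1 - p2)^2
  n_per_group <- as.integer(ceiling(n))
  list(n_per_group = n_per_group, n_total = 2L * n_per_group)
}

#' Split scores into low/high risk groups at a quantile
#'
#' Labels a subject `"low"` when the score is less than or equal to the
#' `q`-quantile of the scores (linear-interpolation quantile), otherwise
#' `"high"`. The default `q = 0.5` is a median split; `q = 0.25` isolates
#' the lowest-risk quartile.
#'
#' @param scores numeric scores (non-empty).
#' @param q quantile in (0, 1).
#' @return A factor with levels `low`, `high` and attribute `cutoff`.
#' @export
dichotomize_at_quantile <- function(scores, q = 0.5) {
  stopifnot(length(scores) >= 1, q > 0, q < 1)
  cutoff <- stats::quantile(scores, q, names = FALSE, type = 7)
  out <- factor(ifelse(scores <= cutoff, "low", "high"),
                levels = c("low", "high"))
  attr(out, "cutoff") <- cutoff
  out
}

#' Two-group baseline comparison
#'
#' Pearson's chi-squared test for categorical variables, Student's two-
#' sample t-test for parametric continuous variables, or the Mann-Whitney
#' U (Wilcoxon rank-sum) test for nonparametric continuous variables; all
#' two-sided.
#'
#' @param values the variable (categorical values or numbers).
#' @param group two-level group labels.
#' @param kind one of `"categorical"`, `"continuous_parametric"`,
#'   `"continuous_nonparametric"`.
#' @return The two-sided p-value.
#' @export
compare_baseline <- function(values, group,
                             kind = c("categorical", "continuous_parametric",
                                      "continuous_nonparametric")) {
  kind <- match.arg(kind)
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("exactly two groups required", call. = FALSE)
  if (min(table(group)) < 2) stop("each group needs >= 2 observations", call. = FALSE)
  if (kind == "categorical") {
    tab <- table(values, group)
    if (nrow(tab) < 2) stop("degenerate contingency table", call. = FALSE)
    stats::chisq.test(tab, correct = FALSE)$p.value
  } else if (kind == "continuous_parametric") {
    stats::t.test(values ~ group)$p.value
  } else {
    stats::wilcox.test(values ~ group, exact = FALSE)$p.value
  }
}
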