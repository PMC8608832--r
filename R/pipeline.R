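# Deterministic fan-out of the run seed into per-stage seeds, so each
# stage (fold assignment, per-fold extractor, per-fold/outcome risk
# training, evaluation bootstrap) is independently reproducible.
stage_seed <- function(seed, stage, fold = 0L, outcome = 0L) {
  as.integer((abs(as.integer(seed)) %% 100000L) * 10007L +
               stage * 1009L + fold * 101L + outcome * 13L) %% 2147483647L
}

#' Assign subjects to cross-validation folds
#'
#' Random partition into `k` folds whose sizes differ by at most one.
#' With `stratify_on` (a 0/1 event flag per subject), events and
#' non-events are dealt separately so per-fold event counts also differ by
#' at most one. Deterministic given `seed`.
#'
#' @param subject_ids character vector of ids (`k <= n`).
#' @param k number of folds (default 6).
#' @param seed integer seed.
#' @param stratify_on optional 0/1 vector aligned with `subject_ids`.
#' @return A tibble of class `fold_assignment` with columns `subject_id`,
#'   `fold` (integer in `1..k`).
#' @export
make_folds <- function(subject_ids, k = 6, seed = 1, stratify_on = NULL) {
  n <- length(subject_ids)
  if (k > n) stop("k = ", k, " folds for only ", n, " subjects", call. = FALSE)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  fold <- integer(n)
  withr::with_seed(as.integer(seed), {
    strata <- if (is.null(stratify_on)) rep(0L, n) else as.integer(stratify_on)
    stopifnot(length(strata) == n)
    load <- integer(k)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      m <- length(idx)
      base <- m %/% k
      assign <- rep(seq_len(k), base)
      extra <- m - base * k
      if (extra > 0) {
        # give the remainder to the currently lightest folds
        cand <- order(load + stats::runif(k) * 0.5)
        assign <- c(assign, cand[seq_len(extra)])
      }
      fold[idx] <- assign[seq_len(m)]
      load <- load + tabulate(assign[seq_len(m)], k)
    }
  })
  out <- tibble::tibble(subject_id = as.character(subject_ids),
                        fold = fold)
  attr(out, "k") <- as.integer(k)
  class(out) <- c("fold_assignment", class(out))
  out
}

#' Run the full two-network cross-validated pipeline
#'
#' For each fold `f`: trains the fingerprint extractor on all folds except
#' `f`, extracts fingerprints with that model, trains the risk predictor
#' (per outcome) on the training folds' fingerprints, and predicts the
#' held-out fold. Out-of-fold predictions are pooled with
#' [combine_fold_predictions()] — so no subject is ever scored by a model
#' that saw it — and each outcome is evaluated with [evaluate_outcome()].
#' A single fold assignment is shared across outcomes.
#'
#' @param sequences list of preprocessed [cine_sequence()] objects (one
#'   common shape; see [crop_and_resample()]).
#' @param cohort a [cohort_table()] covering the same subjects.
#' @param outcomes character vector of outcome labels to train for.
#' @param k_folds number of folds (default 6).
#' @param extractor an [extractor_config()] (its `seed` is overridden by
#'   the run's seed fan-out).
#' @param risk a [risk_config()] (seed likewise overridden).
#' @param seed single run seed; every stage seed derives from it.
#' @param stratify stratify folds on the first outcome's event flag.
#' @param evaluate run [evaluate_outcome()] per outcome.
#' @param n_resamples bootstrap resamples for evaluation.
#' @param n_repeats repetitions of the whole cross-validation with fresh
#'   fold assignments and initialisations; each subject's out-of-fold
#'   linear predictors are averaged across repetitions (every repetition
#'   honours the no-leak contract on its own). Repeated CV smooths the
#'   fold-model noise that a single assignment leaves in pooled scores.
#' @return A list of class `pipeline_result`: `predictions` (pooled
#'   out-of-fold tibble), `folds`, `evaluations` (per outcome), `config`.
#' @export
run_pipeline <- function(sequences, cohort, outcomes = "VA", k_folds = 6,
                         extractor = extractor_config(), risk = risk_config(),
                         seed = 1, stratify = TRUE, evaluate = TRUE,
                         n_resamples = 100, n_repeats = 1) {
  stopifnot(inherits(cohort, "cohort_table"), n_repeats >= 1)
  ids <- purrr::map_chr(sequences, "subject_id")
  if (!setequal(ids, cohort$subject_id)) {
    stop("subject ids of sequences and cohort do not match", call. = FALSE)
  }
  strat <- if (stratify) {
    event_indicator(cohort$event_code[match(ids, cohort$subject_id)], outcomes[1])
  } else NULL
  rep_results <- vector("list", n_repeats)
  folds1 <- NULL
  for (rep in seq_len(n_repeats)) {
    folds <- make_folds(ids, k_folds, seed = stage_seed(seed, 1L, fold = rep),
                        stratify_on = strat)
    if (rep == 1) folds1 <- folds
    fold_of <- stats::setNames(folds$fold, folds$subject_id)
    preds <- stats::setNames(
      replicate(length(outcomes), vector("list", k_folds), simplify = FALSE),
      outcomes)
    for (f in seq_len(k_folds)) {
      train_ids <- ids[fold_of[ids] != f]
      valid_ids <- ids[fold_of[ids] == f]
      ext_cfg <- extractor
      ext_cfg$seed <- stage_seed(seed, 2L, f + 17L * (rep - 1L))
      ext <- train_extractor(sequences, train_ids, ext_cfg, fold_id = f)
      fps <- extract_fingerprints(ext, sequences)
      for (oi in seq_along(outcomes)) {
        oc <- outcomes[oi]
        coh_oc <- cohort_table(tibble::as_tibble(cohort), oc)
        rk_cfg <- risk
        rk_cfg$seed <- stage_seed(seed, 3L, f + 17L * (rep - 1L), oi)
        rp <- train_risk_predictor(fps, coh_oc, train_ids, rk_cfg, fold_id = f)
        preds[[oc]][[f]] <- predict_risk(
          rp, fps[fps$subject_id %in% valid_ids, ])
      }
    }
    combined <- purrr::map(preds, combine_fold_predictions)
    for (oc in outcomes) {
      got <- sort(combined[[oc]]$subject_id)
      if (!identical(got, sort(ids))) {
        stop("out-of-fold coverage gap for outcome ", oc, call. = FALSE)
      }
    }
    rep_results[[rep]] <- combined
  }
  folds <- folds1
  # average out-of-fold linear predictors across repetitions (fold
  # provenance reported from the first repetition)
  combined <- purrr::map(stats::setNames(outcomes, outcomes), function(oc) {
    base <- rep_results[[1]][[oc]]
    if (n_repeats > 1) {
      lp <- rowMeans(vapply(rep_results, function(rr) {
        r1 <- rr[[oc]]
        r1$linear_predictor[match(base$subject_id, r1$subject_id)]
      }, numeric(nrow(base))))
      base$linear_predictor <- lp
      base$cine_risk_score <- 1 / (1 + exp(-lp))
    }
    base
  })
  all_preds <- dplyr::bind_rows(combined)
  evaluations <- NULL
  if (evaluate) {
    evaluations <- purrr::map(stats::setNames(outcomes, outcomes), function(oc) {
      evaluate_outcome(combined[[oc]],
                       cohort_table(tibble::as_tibble(cohort), oc),
                       n_resamples = n_resamples,
                       seed = stage_seed(seed, 4L,
                                         outcome = match(oc, outcomes)))
    })
  }
  structure(list(predictions = all_preds, folds = folds,
                 evaluations = evaluations,
                 config = list(outcomes = outcomes, k_folds = k_folds,
                               extractor = extractor, risk = risk,
                               seed = seed, stratify = stratify,
                               n_repeats = n_repeats)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects, %d folds, outcomes: %s\n",
              length(unique(x$predictions$subject_id)),
              attr(x$folds, "k"),
              paste(x$config$outcomes, collapse = ", ")))
  if (!is.null(x$evaluations)) {
    print(dplyr::bind_rows(purrr::map(x$evaluations, glance.outcome_evaluation)))
  }
  invisible(x)
}

#' Evaluate an outcome's pooled out-of-fold risk scores
#'
#' The full evaluation stack on one outcome: Harrell's C-index with a
#' 100-resample percentile bootstrap CI, the univariate Cox hazard ratio
#' of the cine risk score, a median-split Kaplan-Meier comparison with the
#' log-rank test, incidence rates (per 100 person-years, exact Poisson CI)
#' overall and in the low-risk subgroup below `quantile_cutoff`, a
#' Fine-Gray subdistribution model whenever competing events are present,
#' optional continuous NRI against a comparator covariate, and an optional
#' multivariable Cox fit with supplied covariate columns.
#'
#' For the NRI, both markers are placed on a common scale as linear
#' predictors of univariate Cox fits, so the comparison is invariant to
#' each marker's units; the comparator equal to the score itself gives an
#' NRI of exactly zero.
#'
#' @param predictions prediction tibble from [combine_fold_predictions()].
#' @param cohort a [cohort_table()] for the same outcome.
#' @param comparator optional name of a covariate column of `cohort` to
#'   compare against with continuous NRI.
#' @param covariates optional character vector of covariate columns for a
#'   multivariable Cox fit alongside the score.
#' @param quantile_cutoff quantile defining the low-risk subgroup for
#'   incidence rates (default 0.25).
#' @param n_resamples bootstrap resamples for the C-index CI.
#' @param seed integer seed (bootstrap only; everything else is exact).
#' @return A list of class `outcome_evaluation`.
#' @export
evaluate_outcome <- function(predictions, cohort, comparator = NULL,
                             covariates = NULL, quantile_cutoff = 0.25,
                             n_resamples = 100, seed = 1) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (nrow(predictions) == 0) stop("empty predictions", call. = FALSE)
  outcome <- unique(predictions$outcome_label)
  stopifnot(length(outcome) == 1)
  dat <- dplyr::inner_join(predictions, tibble::as_tibble(cohort),
                           by = "subject_id")
  if (nrow(dat) < nrow(cohort)) {
    stop("predictions do not cover the cohort", call. = FALSE)
  }
  status <- event_indicator(dat$event_code, outcome)
  score <- dat$cine_risk_score
  cidx <- concordance_index(score, dat$time, status)
  boot <- bootstrap_ci(function(idx) {
    concordance_index(score[idx], dat$time[idx], status[idx])$c
  }, nrow(dat), n_resamples = n_resamples, seed = seed)
  cox_uni <- fit_cox(matrix(score, dimnames = list(NULL, "cine_risk_score")),
                     dat$time, status)
  grp <- dichotomize_at_quantile(score, 0.5)
  km <- purrr::map(split(seq_len(nrow(dat)), grp), function(i) {
    kaplan_meier(dat$time[i], status[i])
  })
  lr <- log_rank_test(dat$time, status, grp)
  py_all <- sum(dat$time)
  low <- dichotomize_at_quantile(score, quantile_cutoff) == "low"
  rate_all <- incidence_rate(sum(status), py_all)
  rate_low <- incidence_rate(sum(status[low]), sum(dat$time[low]))
  fg <- NULL
  if (any(dat$event_code == 2L) && outcome == "VA") {
    fg <- fine_gray(matrix(score, dimnames = list(NULL, "cine_risk_score")),
                    dat$time, dat$event_code)
  }
  nri <- NULL
  if (!is.null(comparator)) {
    stopifnot(comparator %in% names(dat))
    lp_of <- function(x) {
      f <- fit_cox(matrix(x, dimnames = list(NULL, "m")), dat$time, status)
      unname(f$coefficients[1]) * (x - mean(x))
    }
    nri <- nri_continuous(lp_of(dat[[comparator]]), lp_of(score), status)
  }
  cox_multi <- NULL
  if (!is.null(covariates)) {
    stopifnot(all(covariates %in% names(dat)))
    xm <- cbind(cine_risk_score = score,
                as.matrix(dat[, covariates, drop = FALSE]))
    cox_multi <- fit_cox(xm, dat$time, status)
  }
  structure(list(outcome_label = outcome, n = nrow(dat),
                 n_events = sum(status),
                 c_index = cidx$c, c_index_ci = c(boot$lower, boot$upper),
                 cox_univariate = cox_uni,
                 km_by_group = km, log_rank = lr,
                 incidence_overall = rate_all, incidence_low = rate_low,
                 quantile_cutoff = quantile_cutoff,
                 fine_gray = fg, nri = nri, comparator = comparator,
                 cox_multivariable = cox_multi,
                 person_years = py_all, seed = seed),
            class = "outcome_evaluation")
}

#' @export
print.outcome_evaluation <- function(x, ...) {
  cat(sprintf("<outcome_evaluation> %s: n = %d, events = %d\n",
              x$outcome_label, x$n, x$n_events))
  cat(sprintf("  C-index %.3f (95%% CI %.3f-%.3f)\n",
              x$c_index, x$c_index_ci[1], x$c_index_ci[2]))
  cat(sprintf("  HR per unit score %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
              x$cox_univariate$hazard_ratios[1],
              x$cox_univariate$ci_lower[1], x$cox_univariate$ci_upper[1],
              x$cox_univariate$p_values[1]))
  cat(sprintf("  median-split log-rank chi2 = %.2f, p = %.3g\n",
              x$log_rank$chi2, x$log_rank$p))
  cat(sprintf("  incidence %.2f/100 PY overall, %.2f/100 PY below the %.0f%% cutoff\n",
              x$incidence_overall$rate, x$incidence_low$rate,
              100 * x$quantile_cutoff))
  if (!is.null(x$nri)) {
    cat(sprintf("  continuous NRI vs %s: %.3f\n", x$comparator, x$nri))
  }
  invisible(x)
}

#' Glance at an outcome evaluation
#'
#' @param x an `outcome_evaluation`.
#' @param ... unused.
#' @return A one-row tibble of headline metrics.
#' @method glance outcome_evaluation
#' @export
glance.outcome_evaluation <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome_label, n = x$n, n.events = x$n_events,
    c.index = x$c_index,
    c.conf.low = x$c_index_ci[1], c.conf.high = x$c_index_ci[2],
    hazard.ratio = unname(x$cox_univariate$hazard_ratios[1]),
    hr.p.value = unname(x$cox_univariate$p_values[1]),
    logrank.chi2 = x$log_rank$chi2, logrank.p = x$log_rank$p,
    incidence.rate = x$incidence_overall$rate,
    incidence.rate.low = x$incidence_low$rate,
    nri = if (is.null(x$nri)) NA_real_ else x$nri
  )
}
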