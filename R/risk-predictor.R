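#' Cox partial log-likelihood
#'
#' The partial likelihood of Cox's semi-parametric proportional-hazards
#' model, used here as the censoring-aware training loss of the risk
#' predictor: `sum over event subjects i of (eta_i - log sum_{j: t_j >=
#' t_i} exp(eta_j))`. Tied event times are handled with Breslow's
#' approximation (every tied event sees the same risk set). The value is
#' invariant to adding a constant to every linear predictor.
#'
#' @param eta numeric linear predictors.
#' @param time positive follow-up times.
#' @param status 0/1 event indicator (1 = event).
#' @param ties tie handling; only `"breslow"` is implemented for the loss
#'   (evaluation fits may use Efron via [fit_cox()]).
#' @return The partial log-likelihood (a scalar, <= 0 is typical).
#' @export
cox_partial_log_likelihood <- function(eta, time, status, ties = "breslow") {
  ties <- match.arg(ties, "breslow")
  n <- length(eta)
  stopifnot(length(time) == n, length(status) == n, all(status %in% 0:1))
  if (sum(status) == 0) {
    stop("the partial likelihood is undefined with zero events", call. = FALSE)
  }
  ord <- order(time, decreasing = TRUE)
  e_eta <- exp(eta[ord])
  cs <- cumsum(e_eta)
  t_sorted <- time[ord]
  # risk-set sum for each subject = cumsum up to the LAST subject sharing
  # its time (ties are all at risk together)
  last_of_tie <- vapply(seq_len(n), function(i) max(which(t_sorted == t_sorted[i])),
                        integer(1))
  risk_sum <- cs[last_of_tie]
  d <- status[ord] == 1
  sum(eta[ord][d] - log(risk_sum[d]))
}

#' Gradient of the Cox partial log-likelihood
#'
#' `d l / d eta_k = status_k - exp(eta_k) * sum over events i with t_i <=
#' t_k of 1 / riskset(t_i)` under Breslow ties. Used by the network
#' training loop and checked against central finite differences in the test
#' suite.
#'
#' @inheritParams cox_partial_log_likelihood
#' @return Numeric gradient vector, same length as `eta`.
#' @export
cox_pl_gradient <- function(eta, time, status, ties = "breslow") {
  ties <- match.arg(ties, "breslow")
  n <- length(eta)
  stopifnot(length(time) == n, length(status) == n)
  ord <- order(time, decreasing = TRUE)
  e_eta <- exp(eta[ord])
  cs <- cumsum(e_eta)
  t_sorted <- time[ord]
  last_of_tie <- vapply(seq_len(n), function(i) max(which(t_sorted == t_sorted[i])),
                        integer(1))
  risk_sum <- cs[last_of_tie]
  d <- as.numeric(status[ord] == 1)
  # cumulative (over increasing time) sum of d_i / risk_sum_i for events
  # with t_i <= t_k: accumulate on the reversed (ascending) scale
  inc <- d / risk_sum
  asc <- rev(inc)
  cum_asc <- cumsum(asc)
  t_asc <- rev(t_sorted)
  # for each subject (ascending), include all events with time <= its own,
  # i.e. up to the last ascending position sharing its time
  last_asc <- vapply(seq_len(n), function(i) max(which(t_asc == t_asc[i])),
                     integer(1))
  a_asc <- cum_asc[last_asc]
  a <- rev(a_asc)                       # back to descending order
  g_sorted <- d - e_eta * a
  g <- numeric(n)
  g[ord] <- g_sorted
  g
}

#' Configuration for the risk predictor network
#'
#' A small feed-forward network on fingerprint means: one tanh hidden
#' layer, a linear risk head producing the linear predictor, and an
#' optional linear reconstruction head back onto the fingerprint (weight
#' `aux_weight`; 0 disables it). Trained full-batch with Adam on the
#' negated Cox partial log-likelihood averaged over events, so risk sets
#' are exact.
#'
#' @param hidden_dim hidden width.
#' @param epochs training epochs (full-batch steps).
#' @param learning_rate Adam step size.
#' @param aux_weight weight of the auxiliary fingerprint-reconstruction L2
#'   term (>= 0, default 0).
#' @param weight_decay L2 penalty on the network weights (not biases);
#'   cohorts of a few hundred subjects with tens of events need this to
#'   keep the head from memorising its risk sets.
#' @param n_ensemble number of independently initialised heads trained and
#'   averaged (on the linear-predictor scale). Averaging over restarts
#'   stabilises the score when training events are few; 1 disables it.
#' @param seed integer seed.
#' @return A list of class `risk_config`.
#' @export
risk_config <- function(hidden_dim = 8, epochs = 300, learning_rate = 0.01,
                        aux_weight = 0, weight_decay = 0.05, n_ensemble = 5,
                        seed = 1) {
  stopifnot(hidden_dim >= 1, epochs >= 1, learning_rate > 0, aux_weight >= 0,
            weight_decay >= 0, n_ensemble >= 1)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 aux_weight = aux_weight,
                 weight_decay = weight_decay,
                 n_ensemble = as.integer(n_ensemble),
                 seed = as.integer(seed)),
            class = "risk_config")
}

risk_forward <- function(w, p) {
  h <- tanh(sweep(p %*% w$W1, 2, w$b1, `+`))
  eta <- as.vector(h %*% w$w2 + w$b2)
  list(h = h, eta = eta)
}

#' Train the risk predictor for one outcome
#'
#' Minimises the negated [cox_partial_log_likelihood()] (averaged over
#' events) of the network's linear predictor over the training subjects,
#' mapping event codes through [event_indicator()] for the cohort's
#' outcome label. Deterministic given `config$seed`.
#'
#' @param fingerprints fingerprint tibble from [extract_fingerprints()].
#' @param cohort a [cohort_table()]; its `outcome_label` decides which
#'   event codes count as events.
#' @param train_ids subject ids to train on (must have >= 5 events).
#' @param config a [risk_config()].
#' @param fold_id integer fold tag stored with the model.
#' @return An object of class `risk_predictor` with the ensemble's member
#'   weights, input scaling, config and per-epoch `history` (mean loss
#'   across members).
#' @export
train_risk_predictor <- function(fingerprints, cohort, train_ids = NULL,
                                 config = risk_config(), fold_id = 0L) {
  stopifnot(inherits(config, "risk_config"), inherits(cohort, "cohort_table"))
  outcome <- attr(cohort, "outcome_label")
  if (is.null(train_ids)) train_ids <- intersect(fingerprints$subject_id,
                                                 cohort$subject_id)
  miss <- setdiff(train_ids, fingerprints$subject_id)
  if (length(miss)) {
    stop("fingerprints missing for training subjects: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  fp <- fingerprints[match(train_ids, fingerprints$subject_id), ]
  surv <- cohort[match(train_ids, cohort$subject_id), ]
  if (anyNA(surv$subject_id)) {
    stop("survival records missing for some training subjects", call. = FALSE)
  }
  status <- event_indicator(surv$event_code, outcome)
  if (sum(status) < 5) {
    stop("need at least 5 events to train; outcome ", outcome, " has ",
         sum(status), call. = FALSE)
  }
  p_raw <- fingerprint_matrix(fp)
  if (!all(is.finite(p_raw))) stop("non-finite fingerprints", call. = FALSE)
  center <- colMeans(p_raw)
  scale <- apply(p_raw, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  p <- sweep(sweep(p_raw, 2, center), 2, scale, `/`)
  members <- lapply(seq_len(config$n_ensemble), function(m) {
    train_risk_member(p, surv$time, status, config,
                      seed = config$seed + 7L * (m - 1L))
  })
  history <- members[[1]]$history
  if (config$n_ensemble > 1) {
    history$loss <- rowMeans(do.call(cbind,
                                     lapply(members, function(m) m$history$loss)))
  }
  structure(list(members = members,
                 center = center, scale = scale,
                 config = config, outcome_label = outcome,
                 fold_id = as.integer(fold_id), history = history),
            class = "risk_predictor")
}

# One gradient-trained head; p is the standardised fingerprint matrix.
train_risk_member <- function(p, time, status, config, seed) {
  n <- nrow(p); L <- ncol(p); H <- config$hidden_dim
  n_ev <- sum(status)
  withr::with_seed(as.integer(seed), {
    w <- list(W1 = glorot(L, H), b1 = rep(0, H),
              w2 = matrix(glorot(H, 1), H, 1), b2 = 0)
    if (config$aux_weight > 0) w$W3 <- glorot(H, L)
    if (config$aux_weight > 0) w$b3 <- rep(0, L)
    opt <- adam_init(w)
    history <- tibble::tibble(epoch = integer(), loss = numeric())
    for (ep in seq_len(config$epochs)) {
      f <- risk_forward(w, p)
      pl <- cox_partial_log_likelihood(f$eta, time, status)
      loss <- -pl / n_ev
      g_eta <- matrix(-cox_pl_gradient(f$eta, time, status) / n_ev, n, 1)
      gw2 <- crossprod(f$h, g_eta); gb2 <- sum(g_eta)
      g_h <- g_eta %*% t(w$w2)
      grads <- list()
      if (config$aux_weight > 0) {
        recon <- sweep(f$h %*% w$W3, 2, w$b3, `+`)
        loss <- loss + config$aux_weight * base::mean((recon - p)^2)
        g_rec <- 2 * config$aux_weight * (recon - p) / (n * L)
        grads$W3 <- crossprod(f$h, g_rec); grads$b3 <- colSums(g_rec)
        g_h <- g_h + tcrossprod(g_rec, w$W3)
      }
      g_a <- g_h * (1 - f$h^2)
      grads$W1 <- crossprod(p, g_a); grads$b1 <- colSums(g_a)
      grads$w2 <- gw2; grads$b2 <- gb2
      if (config$weight_decay > 0) {
        wd <- config$weight_decay
        loss <- loss + wd * (sum(w$W1^2) + sum(w$w2^2))
        grads$W1 <- grads$W1 + 2 * wd * w$W1
        grads$w2 <- grads$w2 + 2 * wd * w$w2
      }
      if (!is.finite(loss)) {
        stop("NaN/Inf risk-predictor loss at epoch ", ep, call. = FALSE)
      }
      upd <- adam_step(w, grads[names(w)], opt, config$learning_rate)
      w <- upd$params; opt <- upd$state
      history <- dplyr::bind_rows(history, tibble::tibble(epoch = ep, loss = loss))
    }
    # the partial likelihood identifies eta only up to location (and the
    # penalised fit leaves its scale weakly determined), so standardise the
    # linear predictor on the TRAINING subjects: out-of-fold scores from
    # different fold models then live on one scale when pooled
    eta_tr <- risk_forward(w, p)$eta
    list(weights = w, eta_center = mean(eta_tr),
         eta_scale = max(stats::sd(eta_tr), 1e-8), history = history)
  })
}

#' @export
print.risk_predictor <- function(x, ...) {
  cat(sprintf("<risk_predictor> outcome %s, fold %d: %d-d input, final loss %.5f\n",
              x$outcome_label, x$fold_id, length(x$center),
              utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' Predict the cine risk score
#'
#' Maps fingerprints through the trained network to a linear predictor
#' `eta` and the cine risk score `1 / (1 + exp(-eta))` on the 0-1 scale.
#' The logistic map is monotone, so rankings (and hence concordance,
#' median splits and Cox fits on the score) are unaffected by it.
#'
#' @param model a trained `risk_predictor`.
#' @param fingerprints a fingerprint tibble ([extract_fingerprints()]) or a
#'   single `fingerprint`.
#' @return A tibble with columns `subject_id`, `outcome_label`,
#'   `linear_predictor`, `cine_risk_score`, `fold_id` (the model's fold).
#' @export
predict_risk <- function(model, fingerprints) {
  stopifnot(inherits(model, "risk_predictor"))
  if (inherits(fingerprints, "fingerprint")) {
    fingerprints <- tibble::tibble(subject_id = fingerprints$subject_id,
                                   fold_id = fingerprints$fold_id,
                                   mean = list(fingerprints$mean))
  }
  p_raw <- fingerprint_matrix(fingerprints)
  if (ncol(p_raw) != length(model$center)) {
    stop("fingerprint dimension ", ncol(p_raw),
         " does not match the model's ", length(model$center), call. = FALSE)
  }
  p <- sweep(sweep(p_raw, 2, model$center), 2, model$scale, `/`)
  eta_mat <- vapply(model$members, function(m) {
    (risk_forward(m$weights, p)$eta - m$eta_center) / m$eta_scale
  }, numeric(nrow(p)))
  if (is.null(dim(eta_mat))) eta_mat <- matrix(eta_mat, nrow = nrow(p))
  eta <- rowMeans(eta_mat)
  tibble::tibble(
    subject_id = fingerprints$subject_id,
    outcome_label = model$outcome_label,
    linear_predictor = eta,
    cine_risk_score = 1 / (1 + exp(-eta)),
    fold_id = model$fold_id
  )
}

#' Combine per-fold validation predictions into a full-cohort table
#'
#' Pools the out-of-fold risk predictions of a cross-validated run and
#' enforces the no-leak contract: every subject must appear exactly once
#' per outcome (scored by the one model whose training set excluded it).
#'
#' @param per_fold_results list of prediction tibbles from [predict_risk()].
#' @return One tibble of class `risk_result` covering the cohort.
#' @export
combine_fold_predictions <- function(per_fold_results) {
  out <- dplyr::bind_rows(per_fold_results)
  if (nrow(out) == 0) stop("no predictions to combine", call. = FALSE)
  dup <- out |>
    dplyr::count(.data$subject_id, .data$outcome_label) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("subjects predicted by more than one fold (leak): ",
         paste(utils::head(dup$subject_id, 5), collapse = ", "), call. = FALSE)
  }
  class(out) <- c("risk_result", class(out))
  out
}
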