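test_that("risk training reduces the Cox loss on a signal-bearing cohort", {
  fps <- synthetic_fingerprints(80, seed = 3)
  surv <- survival_from_lp(fps$signal, seed = 4)
  m <- train_risk_predictor(fps, surv, config = risk_config(epochs = 60, seed = 1))
  sm <- function(v) stats::filter(v, rep(1 / 3, 3), sides = 1)
  h <- m$history$loss
  expect_lt(h[60], h[1])
  # smoothed early trajectory is non-increasing overall
  expect_lt(mean(h[50:60]), mean(h[1:10]))
})

test_that("competing deaths are censored for the VA outcome", {
  fps <- synthetic_fingerprints(40, seed = 5)
  surv <- survival_from_lp(fps$signal, seed = 6)
  # flip some censorings to competing deaths: training must be identical
  idx <- which(surv$event_code == 0L)[1:5]
  surv2 <- tibble::as_tibble(surv)
  surv2$event_code[idx] <- 2L
  surv2 <- cohort_table(surv2, "VA")
  m1 <- train_risk_predictor(fps, surv, config = risk_config(epochs = 20, seed = 9))
  m2 <- train_risk_predictor(fps, surv2, config = risk_config(epochs = 20, seed = 9))
  expect_identical(m1$history$loss, m2$history$loss)
})

test_that("too few events aborts training", {
  fps <- synthetic_fingerprints(20, seed = 7)
  surv <- tibble::as_tibble(survival_from_lp(fps$signal, seed = 8))
  surv$event_code <- c(rep(1L, 3), rep(0L, 17))
  expect_error(
    train_risk_predictor(fps, cohort_table(surv, "VA"),
                         config = risk_config(epochs = 5)),
    "at least 5 events")
})

test_that("true labels beat permuted labels on held-out concordance", {
  n <- 240
  fps <- synthetic_fingerprints(n, seed = 11)
  surv <- survival_from_lp(fps$signal, seed = 12)
  train <- fps$subject_id[1:180]
  test_idx <- 181:240
  cidx_for <- function(cohort) {
    m <- train_risk_predictor(fps, cohort, train,
                              config = risk_config(epochs = 150, seed = 13))
    pr <- predict_risk(m, fps[test_idx, ])
    dat <- dplyr::inner_join(pr, tibble::as_tibble(cohort), by = "subject_id")
    concordance_index(dat$cine_risk_score, dat$time,
                      event_indicator(dat$event_code, "VA"))$c
  }
  perm <- tibble::as_tibble(surv)
  withr::with_seed(14, {
    sh <- sample.int(nrow(perm))
    perm$time <- perm$time[sh]
    perm$event_code <- perm$event_code[sh]
  })
  expect_gt(cidx_for(surv), cidx_for(cohort_table(perm, "VA")))
})

test_that("predictions apply the logistic map deterministically", {
  fps <- synthetic_fingerprints(30, seed = 21)
  surv <- survival_from_lp(fps$signal, seed = 22)
  m <- train_risk_predictor(fps, surv, config = risk_config(epochs = 30, seed = 23))
  p1 <- predict_risk(m, fps)
  p2 <- predict_risk(m, fps)
  expect_identical(p1, p2)
  expect_equal(p1$cine_risk_score, stats::plogis(p1$linear_predictor))
  expect_true(all(p1$cine_risk_score > 0 & p1$cine_risk_score < 1))
  # score ordering follows the linear predictor exactly
  expect_identical(order(p1$cine_risk_score), order(p1$linear_predictor))
  # single-fingerprint interface
  one <- extract_one <- structure(
    list(mean = fps$mean[[1]], log_variance = fps$log_variance[[1]],
         subject_id = fps$subject_id[1], fold_id = 0L), class = "fingerprint")
  expect_equal(predict_risk(m, one)$cine_risk_score, p1$cine_risk_score[1])
  # dimension mismatch is rejected
  short <- fps
  short$mean <- lapply(short$mean, function(v) v[1:3])
  expect_error(predict_risk(m, short), "dimension")
})

test_that("fold combination enforces exactly-once coverage", {
  fps <- synthetic_fingerprints(12, seed = 31)
  per_fold <- lapply(1:6, function(f) {
    tibble::tibble(subject_id = fps$subject_id[(2 * f - 1):(2 * f)],
                   outcome_label = "VA",
                   linear_predictor = c(0, 1),
                   cine_risk_score = stats::plogis(c(0, 1)),
                   fold_id = f)
  })
  combined <- combine_fold_predictions(per_fold)
  expect_equal(nrow(combined), 12)
  dup <- c(per_fold, per_fold[1])
  expect_error(combine_fold_predictions(dup), "leak")
  expect_error(combine_fold_predictions(list()), "no predictions")
})

test_that("auxiliary reconstruction head trains when enabled", {
  fps <- synthetic_fingerprints(60, seed = 41)
  surv <- survival_from_lp(fps$signal, seed = 42)
  m <- train_risk_predictor(fps, surv, config = risk_config(
    epochs = 40, aux_weight = 0.5, seed = 43))
  expect_true(all(is.finite(m$history$loss)))
  expect_lt(dplyr::last(m$history$loss), m$history$loss[1])
})
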