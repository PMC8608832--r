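# Independent pair-enumeration oracle for Harrell's C (loop-based, written
# separately from the vectorised implementation).
c_index_oracle <- function(scores, times, events) {
  conc <- 0; ties <- 0; pairs <- 0
  n <- length(scores)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (events[i] == 1 && times[i] < times[j]) {
      pairs <- pairs + 1
      if (scores[i] > scores[j]) conc <- conc + 1
      else if (scores[i] == scores[j]) ties <- ties + 1
    }
  }
  list(c = (conc + 0.5 * ties) / pairs, n_pairs = pairs)
}

test_that("concordance matches its examples and the enumeration oracle", {
  expect_equal(concordance_index(c(0.9, 0.7, 0.3, 0.1), 1:4, rep(1, 4))$c, 1.0)
  expect_equal(concordance_index(rep(0.5, 4), 1:4, rep(1, 4))$c, 0.5)
  # mixed censoring: comparable pairs {(2,1),(2,3)}, one concordant one not
  expect_equal(concordance_index(c(0.2, 0.8, 0.9), c(3, 1, 2), c(1, 1, 0))$c, 0.5)
  withr::with_seed(12, {
    for (rep in seq_len(200)) {
      n <- sample(4:15, 1)
      scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
      times <- sample(seq(1, 5, 0.5), n, replace = TRUE)
      events <- rbinom(n, 1, 0.6)
      if (sum(events) == 0) events[sample.int(n, 1)] <- 1
      got <- tryCatch(concordance_index(scores, times, events),
                      error = function(e) NULL)
      want <- tryCatch(c_index_oracle(scores, times, events),
                       error = function(e) NULL)
      if (is.null(want) || !is.finite(want$c)) {
        expect_null(got)
      } else {
        expect_equal(got$c, want$c)
        expect_equal(got$n_pairs, want$n_pairs)
      }
    }
  })
})

test_that("bootstrap intervals behave on degenerate and known inputs", {
  const <- bootstrap_ci(function(i) mean(rep(4, length(i))), 10, 50, seed = 1)
  expect_equal(c(const$lower, const$upper), c(4, 4))
  x <- 1:100
  bt <- bootstrap_ci(function(i) mean(x[i]), 100, 100, seed = 2)
  expect_equal(bt$estimate, 50.5)
  expect_lt(bt$lower, 50.5)
  expect_gt(bt$upper, 50.5)
  expect_error(bootstrap_ci(function(i) 1, 10, 1), "at least 2")
  # deterministic given seed
  bt2 <- bootstrap_ci(function(i) mean(x[i]), 100, 100, seed = 2)
  expect_identical(bt$resamples, bt2$resamples)
})

test_that("fit_cox maximises the hand-coded partial likelihood", {
  x <- c(1, 1, 1, 0, 0, 0)
  tm <- c(1, 3, 5, 2, 4, 6)
  st <- c(1, 1, 0, 1, 1, 1)
  fit <- fit_cox(matrix(x, dimnames = list(NULL, "z")), tm, st,
                 ties = "breslow")
  # independent route: maximise the Breslow partial likelihood numerically
  opt <- stats::optimize(function(b) cox_partial_log_likelihood(b * x, tm, st),
                         c(-5, 5), maximum = TRUE, tol = 1e-9)
  expect_equal(unname(fit$coefficients["z"]), opt$maximum, tolerance = 1e-4)
  expect_equal(unname(fit$hazard_ratios), exp(unname(fit$coefficients)))
  td <- tidy(fit)
  expect_equal(td$hazard.ratio, unname(fit$hazard_ratios))
  expect_true(all(td$conf.low < td$conf.high))
  expect_equal(glance(fit)$n.events, 5)
})

test_that("duplicating every subject leaves the Breslow estimate unchanged", {
  withr::with_seed(33, {
    x <- rnorm(40); tm <- rexp(40, exp(0.5 * x)); st <- rbinom(40, 1, 0.8)
  })
  st[1] <- 1
  f1 <- fit_cox(cbind(z = x), tm, st, ties = "breslow")
  f2 <- fit_cox(cbind(z = rep(x, 2)), rep(tm, 2), rep(st, 2), ties = "breslow")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
})

test_that("a covariate unrelated to outcome is rarely significant", {
  withr::with_seed(44, {
    flags <- vapply(seq_len(50), function(r) {
      x <- rnorm(200)
      tm <- rexp(200)           # independent of x
      st <- rbinom(200, 1, 0.5)
      if (sum(st) == 0) st[1] <- 1
      fit_cox(cbind(z = x), tm, st)$p_values["z"] > 0.05
    }, logical(1))
  })
  expect_gte(mean(flags), 0.9)
})

test_that("constant covariates and zero events are rejected", {
  expect_error(fit_cox(cbind(z = rep(1, 5)), 1:5, c(1, 0, 1, 0, 1)), "constant")
  expect_error(fit_cox(cbind(z = rnorm(5)), 1:5, rep(0, 5)), "no events")
})

test_that("Kaplan-Meier reproduces hand product-limit results", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 3], 0)
  # without censoring the curve is the empirical survival function
  tm <- c(1, 2, 2, 3, 5)
  km2 <- kaplan_meier(tm, rep(1, 5))
  emp <- vapply(km2$time, function(t) mean(tm > t), numeric(1))
  expect_equal(km2$survival, emp)
  # all censored: survival stays at 1
  km3 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km3$survival == 1))
  # the confidence band contains the point estimate
  expect_true(all(km2$conf_low <= km2$survival + 1e-12 &
                    km2$survival <= km2$conf_high + 1e-12))
})

# Independent small log-rank oracle from the observed/expected table.
log_rank_oracle <- function(times, events, group) {
  ev_times <- sort(unique(times[events == 1]))
  o <- e <- v <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    d <- sum(events == 1 & times == t)
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == levels(factor(group))[1])
    d1 <- sum(events == 1 & times == t & group == levels(factor(group))[1])
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

test_that("log-rank agrees with the observed/expected oracle", {
  tm <- c(1, 2, 3, 4, 5, 6, 7, 8)
  st <- c(1, 1, 0, 1, 1, 0, 1, 1)
  gr <- rep(c("a", "b"), 4)
  got <- log_rank_test(tm, st, gr)
  expect_equal(got$chi2, log_rank_oracle(tm, st, gr), tolerance = 1e-10)
  # identical groups: chi2 = 0, p = 1
  same <- log_rank_test(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1),
                        rep(c("a", "b"), each = 3))
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  # extreme separation at n = 20 + 20
  sep <- log_rank_test(c(seq(0.1, 2, length.out = 20), rep(10, 20)),
                       c(rep(1, 20), rep(0, 20)),
                       rep(c("early", "none"), each = 20))
  expect_lt(sep$p, 0.01)
  expect_error(log_rank_test(1:3, c(1, 1, 1), rep("a", 3)), "2 groups")
})

test_that("Fine-Gray reduces to Cox without competing events", {
  withr::with_seed(55, {
    for (rep in seq_len(5)) {
      n <- 80
      x <- rnorm(n)
      tm <- rexp(n, exp(0.4 * x))
      code <- ifelse(tm < 3, 1L, 0L)
      tm <- pmin(tm, 3)
      if (sum(code) < 2) code[1:2] <- 1L
      fg <- fine_gray(cbind(z = x), tm, code)
      cx <- fit_cox(cbind(z = x), tm, code, ties = "breslow")
      expect_equal(fg$coefficients, cx$coefficients, tolerance = 1e-6)
    }
  })
})

# Weighted-partial-likelihood oracle for Fine-Gray with no censoring:
# competing-event subjects stay in every later risk set with weight 1.
fg_loglik_nocens <- function(beta, x, times, codes) {
  eta <- beta * x
  ll <- 0
  for (i in which(codes == 1)) {
    riskset <- which(times >= times[i] | codes == 2)
    ll <- ll + eta[i] - log(sum(exp(eta[riskset])))
  }
  ll
}

test_that("Fine-Gray matches a direct weighted-likelihood maximiser", {
  withr::with_seed(66, {
    x <- rnorm(10)
    tm <- sort(rexp(10)) + 0.1
    codes <- c(1L, 1L, 2L, 1L, 0L, 1L, 2L, 1L, 1L, 1L)
  })
  # make code-0 rows actual events so no censoring distorts the weights
  codes[codes == 0L] <- 1L
  fg <- fine_gray(cbind(z = x), tm, codes)
  opt <- stats::optimize(function(b) fg_loglik_nocens(b, x, tm, codes),
                         c(-5, 5), maximum = TRUE, tol = 1e-9)
  expect_equal(unname(fg$coefficients["z"]), opt$maximum, tolerance = 1e-3)
})

test_that("subdistribution nulls and competing-risk directionality behave", {
  # a covariate independent of BOTH events is a true subdistribution null
  withr::with_seed(77, {
    covered <- vapply(seq_len(30), function(r) {
      n <- 300
      x <- rnorm(n)
      t1 <- rexp(n, 0.1)
      t2 <- rexp(n, 0.1)
      tm <- pmin(t1, t2, 8)
      code <- ifelse(t1 <= tm & t1 <= t2, 1L, ifelse(t2 <= tm, 2L, 0L))
      fg <- fine_gray(cbind(z = x), tm, code)
      fg$ci_lower["z"] <= 1 && 1 <= fg$ci_upper["z"]
    }, logical(1))
  })
  expect_gte(mean(covered), 0.9)
  # a covariate driving only the competing event depresses the primary
  # event's cumulative incidence: its subdistribution HR sits below 1
  # (this is what distinguishes Fine-Gray from a cause-specific fit)
  withr::with_seed(78, {
    n <- 2000
    x <- rnorm(n)
    t1 <- rexp(n, 0.1)              # primary: independent of x
    t2 <- rexp(n, 0.1 * exp(x))     # competing: driven by x
    tm <- pmin(t1, t2, 8)
    code <- ifelse(t1 <= tm & t1 <= t2, 1L, ifelse(t2 <= tm, 2L, 0L))
  })
  fg <- fine_gray(cbind(z = x), tm, code)
  cs <- fit_cox(cbind(z = x), tm, as.integer(code == 1L))
  expect_lt(fg$hazard_ratios["z"], 1)          # subdistribution sees it
  expect_lt(abs(cs$coefficients["z"]), 0.15)   # cause-specific does not
})

test_that("continuous NRI matches enumeration on a 6-subject example", {
  old <- c(0.1, 0.4, 0.5, 0.3, 0.8, 0.2)
  new <- c(0.3, 0.2, 0.9, 0.3, 0.6, 0.1)
  ev <- c(1, 1, 1, 0, 0, 0)
  # events: up, down, up -> (2 - 1)/3; non-events: same, down, down -> (2 - 0)/3
  expect_equal(nri_continuous(old, new, ev), (2 - 1) / 3 + (2 - 0) / 3)
  expect_equal(nri_continuous(old, old, ev), 0)
  expect_equal(nri_continuous(c(0, 0, 1, 1), c(1, 1, 0, 0), c(1, 1, 0, 0)), 2)
  expect_error(nri_continuous(old, new, rep(1, 6)), "non-event")
})

test_that("incidence rates use exact Poisson bounds", {
  r <- incidence_rate(10, 200)
  expect_equal(r$rate, 5)
  z <- incidence_rate(0, 100)
  expect_equal(z$rate, 0)
  expect_equal(z$lower, 0)
  expect_equal(z$upper, -log(0.025), tolerance = 1e-6)  # 3.6889 per 100 PY
  expect_error(incidence_rate(3, 0), "positive")
})

test_that("the two-proportion design reproduces textbook sample sizes", {
  got <- sample_size_two_proportions(0.877, 0.740, 0.05, 0.90)
  expect_equal(got$n_total, 344L)
  expect_equal(got$n_per_group, 172L)
  # cross-check against the stats reference implementation
  ref <- stats::power.prop.test(p1 = 0.9, p2 = 0.6, sig.level = 0.05,
                                power = 0.80)
  ours <- sample_size_two_proportions(0.9, 0.6, 0.05, 0.80)
  expect_lte(abs(ours$n_per_group - ceiling(ref$n)), 2)
  # monotone in power
  expect_gt(sample_size_two_proportions(0.9, 0.6, 0.05, 0.95)$n_total,
            sample_size_two_proportions(0.9, 0.6, 0.05, 0.80)$n_total)
  expect_error(sample_size_two_proportions(0.5, 0.5), "differ")
})

test_that("quantile dichotomisation follows the low-takes-ties convention", {
  g <- dichotomize_at_quantile(c(1, 2, 3, 4), 0.5)
  # quantile (type 7) of 1:4 at 0.5 is 2.5: {1,2} low, {3,4} high
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  same <- dichotomize_at_quantile(rep(3, 5), 0.5)
  expect_true(all(same == "low"))
  withr::with_seed(88, scores <- runif(350))
  lowq <- dichotomize_at_quantile(scores, 0.25)
  expect_lte(abs(sum(lowq == "low") - ceiling(0.25 * 350)), 1)
})

test_that("baseline comparisons dispatch to the right tests", {
  tab_vals <- rep(c("x", "y"), each = 100)
  grp <- rep(c("a", "b"), 100)
  expect_equal(compare_baseline(tab_vals, grp, "categorical"), 1)
  withr::with_seed(99, {
    a <- rnorm(50); b <- rnorm(50) + 2
  })
  expect_lt(compare_baseline(c(a, b), rep(c("g1", "g2"), each = 50),
                             "continuous_parametric"), 0.001)
  expect_lt(compare_baseline(c(a, b), rep(c("g1", "g2"), each = 50),
                             "continuous_nonparametric"), 0.001)
  # null calibration: p-values roughly uniform under no effect
  withr::with_seed(101, {
    ps <- vapply(seq_len(200), function(r) {
      compare_baseline(rnorm(40), rep(c("a", "b"), each = 20),
                       "continuous_parametric")
    }, numeric(1))
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
  expect_error(compare_baseline(rep("x", 10), rep(c("a", "b"), 5),
                                "categorical"), "degenerate")
})
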