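# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

# A tiny noiseless phantom sequence for geometry tests.
tiny_phantom <- function(lv_ef = 0.3, size_px = 32, n_frames = 8, seed = 1,
                         noise_sd = 0, id = "P1") {
  generate_phantom_sequence(
    phantom_params(lv_ef = lv_ef, noise_sd = noise_sd, n_frames = n_frames),
    size_px = size_px, seed = seed, subject_id = id)
}

# A small rendered cohort with simulated survival, shared across tests
# that only need "some cohort" (memoised per session).
small_cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function(n = 48, size_px = 24, seed = 5) {
  key <- paste(n, size_px, seed, sep = "_")
  if (is.null(small_cohort_cache[[key]])) {
    coh <- sample_cohort(n, seed = seed, size_px = size_px, n_frames = 8)
    surv <- simulate_survival(
      coh, survival_sim_config(baseline_hazard = 0.03,
                               log_hazard_coeffs = c(lv_ef = -1),
                               admin_censor_years = 10, seed = seed + 1))
    small_cohort_cache[[key]] <- list(cohort = coh, survival = surv)
  }
  small_cohort_cache[[key]]
}

# Synthetic fingerprint tibble whose first coordinate carries the hazard
# signal: isolates risk-predictor tests from extractor training.
synthetic_fingerprints <- function(n, d = 6, seed = 1, signal_sd = 1,
                                   noise_sd = 1) {
  withr::with_seed(seed, {
    signal <- stats::rnorm(n, sd = signal_sd)
    m <- cbind(signal,
               matrix(stats::rnorm(n * (d - 1), sd = noise_sd), n, d - 1))
    tibble::tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      fold_id = 0L,
      mean = lapply(seq_len(n), function(i) m[i, ]),
      log_variance = replicate(n, rep(-2, d), simplify = FALSE),
      signal = signal
    )
  })
}

# Exponential survival driven by a given linear predictor.
survival_from_lp <- function(lp, baseline = 0.05, admin = 15, seed = 1,
                             outcome = "VA") {
  withr::with_seed(seed, {
    t_event <- stats::rexp(length(lp), rate = baseline * exp(lp))
    time <- pmin(t_event, admin)
    cohort_table(tibble::tibble(
      subject_id = sprintf("S%04d", seq_along(lp)),
      time = time,
      event_code = as.integer(t_event <= admin)
    ), outcome)
  })
}
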