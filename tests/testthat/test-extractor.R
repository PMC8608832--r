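test_that("elbo_loss matches its closed forms and a brute-force oracle", {
  x <- array(runif(2 * 4 * 4), c(2, 4, 4))
  ident <- elbo_loss(x, x, rep(0, 3), rep(0, 3), 1)
  expect_equal(unlist(ident), c(total = 0, l2 = 0, kl = 0))
  # KL closed form: mu = 1, logvar = 0 -> 0.5 (1 + 1 - 1 - 0) = 0.5
  kl1 <- elbo_loss(x, x, 1, 0, 1)
  expect_equal(kl1$kl, 0.5)
  expect_equal(kl1$total, 0.5)
  # element-wise loop oracle for the L2 term on a random 4x8x8 pair
  withr::with_seed(5, {
    a <- array(runif(4 * 8 * 8), c(4, 8, 8))
    b <- array(runif(4 * 8 * 8), c(4, 8, 8))
  })
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  expect_equal(elbo_loss(a, b, 0, 0, 0)$l2, acc / length(a), tolerance = 1e-12)
  expect_error(elbo_loss(a, b[1:2, , ], 0, 0, 1), "shapes differ")
})

test_that("VAE gradients match central finite differences", {
  withr::with_seed(42, {
    n <- 4; D <- 10; H <- 6; L <- 3; kw <- 0.3
    gl <- cinesurv:::glorot
    w <- list(W1 = gl(D, H), b1 = rnorm(H) * .1, Wm = gl(H, L),
              bm = rnorm(L) * .1, Wv = gl(H, L), bv = rnorm(L) * .1,
              W2 = gl(L, H), b2 = rnorm(H) * .1, W3 = gl(H, D),
              b3 = rnorm(D) * .1)
    x <- matrix(runif(n * D), n, D)
    eps <- matrix(rnorm(n * L), n, L)
  })
  lossfun <- function(w) {
    f <- cinesurv:::vae_forward(w, x, eps)
    elbo_loss(f$xr, x, f$mu, f$lv, kw)$total
  }
  f <- cinesurv:::vae_forward(w, x, eps)
  g <- cinesurv:::vae_backward(w, x, f, eps, kw)
  for (k in c("W1", "Wm", "Wv", "W2", "W3", "b1", "bv")) {
    wk <- w[[k]]
    check <- sample(seq_along(wk), min(8, length(wk)))
    for (i in check) {
      h <- 1e-6
      wp <- w; wp[[k]][i] <- wp[[k]][i] + h
      wm <- w; wm[[k]][i] <- wm[[k]][i] - h
      expect_equal(g[[k]][i], (lossfun(wp) - lossfun(wm)) / (2 * h),
                   tolerance = 1e-5)
    }
  }
})

test_that("training reduces reconstruction error deterministically", {
  coh <- small_cohort(n = 30, size_px = 24, seed = 61)
  cfg <- extractor_config(latent_dim = 8, hidden_dim = 16, epochs = 20,
                          seed = 8)
  m1 <- train_extractor(coh$cohort$sequence, config = cfg)
  expect_lt(dplyr::last(m1$history$l2), m1$history$l2[1])
  m2 <- train_extractor(coh$cohort$sequence, config = cfg)
  expect_identical(dplyr::last(m1$history$total), dplyr::last(m2$history$total))
  expect_error(train_extractor(coh$cohort$sequence, character(0)), "empty")
})

test_that("a stronger KL weight shrinks the KL term at convergence", {
  coh <- small_cohort(n = 30, size_px = 24, seed = 61)
  seqs <- coh$cohort$sequence
  m_free <- train_extractor(seqs, config = extractor_config(
    latent_dim = 4, hidden_dim = 16, epochs = 30, kl_weight = 0, seed = 5))
  m_reg <- train_extractor(seqs, config = extractor_config(
    latent_dim = 4, hidden_dim = 16, epochs = 30, kl_weight = 1, seed = 5))
  expect_lt(dplyr::last(m_reg$history$kl), dplyr::last(m_free$history$kl))
})

test_that("fingerprints are deterministic with the configured dimension", {
  coh <- small_cohort(n = 30, size_px = 24, seed = 61)
  m <- train_extractor(coh$cohort$sequence, config = extractor_config(
    latent_dim = 16, hidden_dim = 16, epochs = 5, seed = 2))
  fp1 <- extract_fingerprint(m, coh$cohort$sequence[[1]])
  fp2 <- extract_fingerprint(m, coh$cohort$sequence[[1]])
  expect_identical(fp1$mean, fp2$mean)
  expect_length(fp1$mean, 16)
  expect_true(all(is.finite(fp1$log_variance)))
  bad <- tiny_phantom(size_px = 16)
  expect_error(extract_fingerprint(m, bad), "shape")
})

test_that("fingerprints separate phantoms by function and do not collapse", {
  # train on a modest cohort, then compare distances: two phantoms far
  # apart in EF must be farther in fingerprint space than two noise
  # replicates of one phantom
  coh <- small_cohort(n = 48, size_px = 24, seed = 5)
  m <- train_extractor(coh$cohort$sequence, config = extractor_config(
    latent_dim = 16, hidden_dim = 32, epochs = 120, seed = 3))
  mk <- function(ef, seed) generate_phantom_sequence(
    phantom_params(lv_ef = ef, noise_sd = 0.02, n_frames = 8),
    size_px = 24, seed = seed, subject_id = "x")
  f_low <- extract_fingerprint(m, mk(0.15, 1))
  f_high <- extract_fingerprint(m, mk(0.55, 1))
  f_rep1 <- extract_fingerprint(m, mk(0.15, 2))
  d_ef <- sqrt(sum((f_low$mean - f_high$mean)^2))
  d_noise <- sqrt(sum((f_low$mean - f_rep1$mean)^2))
  expect_gt(d_ef, d_noise)
  # no posterior collapse: fingerprint means vary across subjects
  fps <- extract_fingerprints(m, coh$cohort$sequence)
  pm <- do.call(rbind, fps$mean)
  expect_gt(mean(apply(pm, 2, stats::sd)), 0)
})

test_that("held-out reconstruction improves with training-set size", {
  big <- sample_cohort(108, seed = 71, size_px = 24, n_frames = 8)
  test_idx <- 97:108
  xs <- t(vapply(big$sequence[test_idx],
                 function(s) as.vector(cinesurv:::pool_frames(s$frames, 2)),
                 numeric(12 * 12 * 8)))
  heldout_l2 <- function(n_train) {
    m <- train_extractor(big$sequence[1:n_train], config = extractor_config(
      latent_dim = 8, hidden_dim = 16, epochs = 40, pool = 2, seed = 4))
    xstd <- sweep(xs, 2, m$center) / m$scale
    f <- cinesurv:::vae_forward(m$weights, xstd, eps = NULL)
    mean((f$xr - xstd)^2)
  }
  expect_lt(heldout_l2(96), heldout_l2(24))
})
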