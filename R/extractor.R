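#' Configuration for the cine fingerprint extractor
#'
#' The extractor is a probabilistic encoder-decoder (a variational
#' autoencoder): a dense encoder maps the flattened cine stack to a
#' Gaussian posterior (mean and log-variance) over a `latent_dim`-
#' dimensional fingerprint space, a dense decoder reconstructs the stack
#' from a reparameterised sample, and training minimises an L2
#' reconstruction term plus `kl_weight` times the KL divergence of the
#' posterior from a standard-normal prior. The encoder is affine (so
#' fingerprints extrapolate linearly to unseen subjects); the decoder has
#' a tanh hidden layer.
#'
#' @param latent_dim fingerprint dimension (>= 2).
#' @param hidden_dim width of the single hidden layer on each side.
#' @param pool spatial average-pooling factor applied to each frame before
#'   the dense encoder (1 = none). Pooling by 2 preserves the chamber-area
#'   signal the fingerprint targets while conditioning the wide input
#'   layer; frame sides must be divisible by it.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param kl_weight weight of the KL regulariser (>= 0). The reconstruction
#'   term is a per-pixel mean, so a weight of order `1/n_pixels` balances
#'   the two terms; the default 0.001 regularises noticeably at the
#'   package's phantom geometries without collapsing the posterior.
#' @param seed integer seed controlling initialisation, shuffling and the
#'   reparameterisation noise.
#' @return A list of class `extractor_config`.
#' @export
extractor_config <- function(latent_dim = 32, hidden_dim = 64, epochs = 100,
                             batch_size = 16, learning_rate = 1e-3,
                             kl_weight = 0.001, pool = 2, seed = 1) {
  stopifnot(latent_dim >= 2, hidden_dim >= 1, epochs >= 1, batch_size >= 1,
            learning_rate > 0, kl_weight >= 0, pool >= 1)
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_dim = as.integer(hidden_dim),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 kl_weight = kl_weight,
                 pool = as.integer(pool),
                 seed = as.integer(seed)),
            class = "extractor_config")
}

# Block-average spatial pooling of a (t, r, c) frame stack.
pool_frames <- function(frames, factor) {
  if (factor == 1) return(frames)
  d <- dim(frames)
  if (d[2] %% factor != 0 || d[3] %% factor != 0) {
    stop("frame sides (", d[2], "x", d[3], ") are not divisible by the ",
         "pooling factor ", factor, call. = FALSE)
  }
  nr <- d[2] %/% factor; nc <- d[3] %/% factor
  out <- array(0, c(d[1], nr, nc))
  for (i in seq_len(factor)) for (j in seq_len(factor)) {
    out <- out + frames[, seq(i, d[2], by = factor), seq(j, d[3], by = factor),
                        drop = FALSE]
  }
  out / factor^2
}

#' Evidence-lower-bound loss of the extractor
#'
#' `l2` is the mean squared intensity difference between reconstruction and
#' target over all elements; `kl` is the mean over subjects of the
#' closed-form KL divergence of a diagonal Gaussian posterior from the
#' standard normal, `sum_d 0.5 (mu_d^2 + exp(logvar_d) - 1 - logvar_d)`;
#' `total = l2 + kl_weight * kl`.
#'
#' @param reconstruction,target numeric arrays of identical shape.
#' @param mean,log_variance posterior parameters; vectors (one subject) or
#'   matrices with one row per subject.
#' @param kl_weight non-negative KL weight.
#' @return A list with components `total`, `l2`, `kl`.
#' @export
elbo_loss <- function(reconstruction, target, mean, log_variance,
                      kl_weight = 1.0) {
  if (!identical(dim(reconstruction), dim(target)) ||
      length(reconstruction) != length(target)) {
    stop("reconstruction and target shapes differ", call. = FALSE)
  }
  if (length(mean) != length(log_variance)) {
    stop("mean and log_variance shapes differ", call. = FALSE)
  }
  stopifnot(all(is.finite(reconstruction)), all(is.finite(target)),
            all(is.finite(mean)), all(is.finite(log_variance)))
  l2 <- base::mean((reconstruction - target)^2)
  mu <- if (is.matrix(mean)) mean else matrix(mean, nrow = 1)
  lv <- if (is.matrix(log_variance)) log_variance else matrix(log_variance, nrow = 1)
  kl <- base::mean(rowSums(0.5 * (mu^2 + exp(lv) - 1 - lv)))
  list(total = l2 + kl_weight * kl, l2 = l2, kl = kl)
}

# Flatten cine sequences into an n x D design matrix (rows = subjects),
# after optional spatial pooling.
stack_sequences <- function(sequences, pool = 1) {
  shapes <- unique(purrr::map(sequences, ~ dim(.x$frames)))
  if (length(shapes) != 1) {
    stop("all sequences must share one (frames, rows, cols) shape; found ",
         length(shapes), call. = FALSE)
  }
  d <- shapes[[1]]
  dp <- c(d[1], d[2] %/% pool, d[3] %/% pool)
  x <- t(vapply(sequences,
                function(s) as.vector(pool_frames(s$frames, pool)),
                numeric(prod(dp))))
  list(x = x, shape = d, ids = purrr::map_chr(sequences, "subject_id"))
}

# Glorot-uniform weight init.
glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

adam_init <- function(params) {
  list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Forward pass of the VAE on standardised intensities. The encoder hidden
# layer is affine (no squashing): fingerprints stay affine in the image, so
# the encoder extrapolates cleanly to held-out subjects; the decoder keeps
# a tanh hidden layer for expressive reconstruction, and its output layer
# is linear on the standardised scale. eps = NULL means deterministic
# inference (use the mean).
vae_forward <- function(w, x, eps = NULL) {
  h1 <- sweep(x %*% w$W1, 2, w$b1, `+`)
  mu <- sweep(h1 %*% w$Wm, 2, w$bm, `+`)
  lv <- sweep(h1 %*% w$Wv, 2, w$bv, `+`)
  z <- if (is.null(eps)) mu else mu + exp(lv / 2) * eps
  h2 <- tanh(sweep(z %*% w$W2, 2, w$b2, `+`))
  xr <- sweep(h2 %*% w$W3, 2, w$b3, `+`)
  list(h1 = h1, mu = mu, lv = lv, z = z, h2 = h2, xr = xr)
}

# Backward pass for loss = mean((xr-x)^2) + kw * mean_i KL_i.
vae_backward <- function(w, x, f, eps, kl_weight) {
  n <- nrow(x); D <- ncol(x)
  g_a3 <- 2 * (f$xr - x) / (n * D)
  gW3 <- crossprod(f$h2, g_a3); gb3 <- colSums(g_a3)
  g_h2 <- tcrossprod(g_a3, w$W3) * (1 - f$h2^2)
  gW2 <- crossprod(f$z, g_h2); gb2 <- colSums(g_h2)
  g_z <- tcrossprod(g_h2, w$W2)
  g_mu <- g_z + kl_weight * f$mu / n
  g_lv <- g_z * eps * 0.5 * exp(f$lv / 2) +
    kl_weight * 0.5 * (exp(f$lv) - 1) / n
  gWm <- crossprod(f$h1, g_mu); gbm <- colSums(g_mu)
  gWv <- crossprod(f$h1, g_lv); gbv <- colSums(g_lv)
  g_h1 <- tcrossprod(g_mu, w$Wm) + tcrossprod(g_lv, w$Wv)  # affine encoder
  gW1 <- crossprod(x, g_h1); gb1 <- colSums(g_h1)
  list(W1 = gW1, b1 = gb1, Wm = gWm, bm = gbm, Wv = gWv, bv = gbv,
       W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

#' Train the cine fingerprint extractor
#'
#' Trains the probabilistic encoder-decoder by minibatch Adam on the
#' subjects in `train_ids` only, fully unsupervised (no outcome data enter
#' this stage). Training is deterministic given `config$seed`.
#'
#' @param sequences list of [cine_sequence()] objects, all preprocessed to
#'   one common shape (see [crop_and_resample()]).
#' @param train_ids character vector of subject ids to train on.
#' @param config an [extractor_config()].
#' @param fold_id integer fold tag stored with the model (for
#'   cross-validated pipelines).
#' @return An object of class `cine_extractor`: weights, config, input
#'   shape, `fold_id` and a tibble `history` of per-epoch training losses.
#' @export
train_extractor <- function(sequences, train_ids = NULL, config = extractor_config(),
                            fold_id = 0L) {
  stopifnot(inherits(config, "extractor_config"))
  stk <- stack_sequences(sequences, config$pool)
  if (is.null(train_ids)) train_ids <- stk$ids
  if (length(train_ids) == 0) stop("empty training set", call. = FALSE)
  keep <- stk$ids %in% train_ids
  if (!any(keep)) stop("no sequences match `train_ids`", call. = FALSE)
  x_raw <- stk$x[keep, , drop = FALSE]
  # standardise: per-pixel centring removes the shared anatomy so the
  # latent path carries between-subject structure; one global scale keeps
  # relative contrast
  center <- colMeans(x_raw)
  scale <- stats::sd(x_raw)
  if (!is.finite(scale) || scale == 0) scale <- 1
  x <- sweep(x_raw, 2, center) / scale
  n <- nrow(x); D <- ncol(x)
  H <- config$hidden_dim; L <- config$latent_dim
  withr::with_seed(config$seed, {
    w <- list(W1 = glorot(D, H) * 0.3, b1 = rep(0, H),
              Wm = glorot(H, L), bm = rep(0, L),
              # start the posterior narrow (sigma ~ 0.14) so the decoder sees
              # the latent signal through the reparameterisation noise early on
              Wv = glorot(H, L), bv = rep(-4, L),
              W2 = glorot(L, H), b2 = rep(0, H),
              W3 = glorot(H, D), b3 = rep(0, D))
    opt <- adam_init(w)
    history <- tibble::tibble(epoch = integer(), total = numeric(),
                              l2 = numeric(), kl = numeric())
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_tot <- ep_l2 <- ep_kl <- 0; nb <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- x[idx, , drop = FALSE]
        eps <- matrix(stats::rnorm(length(idx) * L), length(idx), L)
        f <- vae_forward(w, xb, eps)
        loss <- elbo_loss(f$xr, xb, f$mu, f$lv, config$kl_weight)
        if (!is.finite(loss$total)) {
          stop("NaN/Inf training loss at epoch ", ep,
               "; reduce the learning rate", call. = FALSE)
        }
        g <- vae_backward(w, xb, f, eps, config$kl_weight)
        upd <- adam_step(w, g, opt, config$learning_rate)
        w <- upd$params; opt <- upd$state
        ep_tot <- ep_tot + loss$total; ep_l2 <- ep_l2 + loss$l2
        ep_kl <- ep_kl + loss$kl; nb <- nb + 1
      }
      history <- dplyr::bind_rows(history, tibble::tibble(
        epoch = ep, total = ep_tot / nb, l2 = ep_l2 / nb, kl = ep_kl / nb))
    }
    structure(list(weights = w, center = center, scale = scale,
                   config = config, input_shape = stk$shape,
                   fold_id = as.integer(fold_id), history = history),
              class = "cine_extractor")
  })
}

#' @export
print.cine_extractor <- function(x, ...) {
  cat(sprintf("<cine_extractor> fold %d: input %s, latent %d, final loss %.5f\n",
              x$fold_id, paste(x$input_shape, collapse = "x"),
              x$config$latent_dim, utils::tail(x$history$total, 1)))
  invisible(x)
}

#' Extract the cine fingerprint of a sequence
#'
#' Deterministic inference: the encoder's posterior mean and log-variance
#' are returned without sampling.
#'
#' @param model a trained `cine_extractor`.
#' @param seq a [cine_sequence()] with the shape the model was trained on.
#' @return A list of class `fingerprint` with `mean`, `log_variance`,
#'   `subject_id`, `fold_id`.
#' @export
extract_fingerprint <- function(model, seq) {
  stopifnot(inherits(model, "cine_extractor"), inherits(seq, "cine_sequence"))
  if (!identical(dim(seq$frames), model$input_shape)) {
    stop("sequence shape ", paste(dim(seq$frames), collapse = "x"),
         " does not match the trained input shape ",
         paste(model$input_shape, collapse = "x"), call. = FALSE)
  }
  pooled <- pool_frames(seq$frames, model$config$pool)
  x <- (matrix(as.vector(pooled), nrow = 1) -
          matrix(model$center, nrow = 1)) / model$scale
  f <- vae_forward(model$weights, x, eps = NULL)
  structure(list(mean = as.vector(f$mu), log_variance = as.vector(f$lv),
                 subject_id = seq$subject_id, fold_id = model$fold_id),
            class = "fingerprint")
}

#' Extract fingerprints for many sequences as a tibble
#'
#' @param model a trained `cine_extractor`.
#' @param sequences list of [cine_sequence()] objects.
#' @return A tibble with `subject_id`, `fold_id` and list-columns `mean`,
#'   `log_variance`.
#' @export
extract_fingerprints <- function(model, sequences) {
  fps <- purrr::map(sequences, ~ extract_fingerprint(model, .x))
  tibble::tibble(
    subject_id = purrr::map_chr(fps, "subject_id"),
    fold_id = purrr::map_int(fps, "fold_id"),
    mean = purrr::map(fps, "mean"),
    log_variance = purrr::map(fps, "log_variance")
  )
}

# Fingerprint means of a fingerprint tibble as an n x d matrix.
fingerprint_matrix <- function(fingerprints) {
  do.call(rbind, fingerprints$mean)
}
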