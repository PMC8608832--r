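#' Phantom parameters for a four-chamber beating-heart sequence
#'
#' The phantom encodes the chamber structure/function axes the risk models
#' are expected to pick up: left-ventricular size (`lv_edv_area`, the
#' end-diastolic LV cross-sectional area in the four-chamber plane),
#' LV and RV ejection fractions, left-atrial maximal area and total
#' emptying fraction, wall thickness and additive image noise. Defaults
#' describe a systolic-heart-failure population: severely reduced LVEF
#' (around 26%) with dilated ventricles and impaired atrial emptying.
#'
#' @param lv_edv_area LV end-diastolic cross-sectional area, mm^2.
#' @param lv_ef LV ejection fraction in (0, 1), volume scale.
#' @param rv_ef RV ejection fraction in (0, 1).
#' @param la_max_area LA maximal cross-sectional area, mm^2.
#' @param la_total_ef LA total emptying fraction in (0, 1).
#' @param wall_thickness_mm myocardial wall thickness, mm.
#' @param noise_sd additive Gaussian image noise SD (intensity units, image
#'   scale is roughly 0-1).
#' @param n_frames frames per cardiac cycle (>= 8).
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(lv_edv_area = 4500, lv_ef = 0.26, rv_ef = 0.40,
                           la_max_area = 2200, la_total_ef = 0.38,
                           wall_thickness_mm = 8, noise_sd = 0.02,
                           n_frames = 16) {
  p <- list(lv_edv_area = lv_edv_area, lv_ef = lv_ef, rv_ef = rv_ef,
            la_max_area = la_max_area, la_total_ef = la_total_ef,
            wall_thickness_mm = wall_thickness_mm, noise_sd = noise_sd,
            n_frames = as.integer(n_frames))
  for (f in c("lv_ef", "rv_ef", "la_total_ef")) {
    if (!is.finite(p[[f]]) || p[[f]] <= 0 || p[[f]] >= 1) {
      stop("`", f, "` must lie strictly in (0, 1)", call. = FALSE)
    }
  }
  for (f in c("lv_edv_area", "la_max_area", "wall_thickness_mm")) {
    if (!is.finite(p[[f]]) || p[[f]] <= 0) {
      stop("`", f, "` must be positive", call. = FALSE)
    }
  }
  if (p$noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (p$n_frames < 8) stop("`n_frames` must be at least 8", call. = FALSE)
  structure(p, class = "phantom_params")
}

# Names of the numeric generative fields, in a fixed order.
phantom_param_fields <- function() {
  c("lv_edv_area", "lv_ef", "rv_ef", "la_max_area", "la_total_ef",
    "wall_thickness_mm", "noise_sd")
}

# Area-scale ejection fraction implied by a volume-scale EF under the
# single-plane proxy volume ~ area^(3/2): A_es/A_ed = (1 - EF_vol)^(2/3).
area_ef_from_volume_ef <- function(ef) 1 - (1 - ef)^(2 / 3)

#' Chamber centres of the phantom layout
#'
#' Fixed anatomical layout of the four-chamber view used by the renderer:
#' ventricles in the upper half (rows towards 0), atria below, left-sided
#' chambers on the higher-column side. Positions are fractions of the field
#' of view, so they scale with `size_px * spacing_mm`.
#'
#' @param size_px image side in pixels.
#' @param spacing_mm isotropic pixel spacing, mm.
#' @return A tibble with columns `chamber`, `row_px`, `col_px` (0-based
#'   pixel coordinates of each chamber centre).
#' @export
phantom_chamber_centers <- function(size_px, spacing_mm) {
  fov <- size_px * spacing_mm
  frac <- tibble::tribble(
    ~chamber, ~y_frac, ~x_frac,
    "LV", -0.14,  0.13,
    "RV", -0.14, -0.15,
    "LA",  0.18,  0.13,
    "RA",  0.18, -0.15
  )
  ctr <- (size_px - 1) / 2
  tibble::tibble(
    chamber = frac$chamber,
    row_px = ctr + frac$y_frac * fov / spacing_mm,
    col_px = ctr + frac$x_frac * fov / spacing_mm
  )
}

# Per-chamber cross-sectional areas (mm^2) at a cycle phase in [0, 1).
# Ventricles contract with a raised cosine (end-diastole at phase 0);
# atria fill in anti-phase (reservoir maximum at phase 0.5).
phantom_chamber_areas <- function(params, phase) {
  contr <- (1 + cos(2 * pi * phase)) / 2    # 1 at ED, 0 at ES
  vent <- function(a_ed, ef) {
    a_es <- (1 - area_ef_from_volume_ef(ef)) * a_ed
    a_es + (a_ed - a_es) * contr
  }
  atr <- function(a_max, ef) {
    a_min <- (1 - area_ef_from_volume_ef(ef)) * a_max
    a_min + (a_max - a_min) * (1 - contr)
  }
  c(LV = vent(params$lv_edv_area, params$lv_ef),
    RV = vent(0.80 * params$lv_edv_area, params$rv_ef),
    LA = atr(params$la_max_area, params$la_total_ef),
    RA = atr(0.85 * params$la_max_area, 0.9 * params$la_total_ef))
}

# Render one noiseless frame at a given phase. Blood pools are bright
# (1.0), walls mid-gray (0.45), background dark (0.08). Each chamber is an
# ellipse with row:col semi-axis ratio 1.6, area set by the contraction
# curves; the wall is a ring of wall_thickness_mm drawn under the pools.
render_phantom_frame <- function(params, phase, size_px, spacing_mm) {
  areas <- phantom_chamber_areas(params, phase)
  centers <- phantom_chamber_centers(size_px, spacing_mm)
  w <- params$wall_thickness_mm
  fov <- size_px * spacing_mm
  elong <- 1.6
  # feasibility: every chamber's maximal extent (ED/max area plus wall)
  # must stay inside the field of view
  amax <- areas_ed(params)
  for (i in seq_len(nrow(centers))) {
    ch <- centers$chamber[i]
    b <- sqrt(amax[[ch]] / (pi * elong)) + w
    a <- elong * (b - w) + w
    cy <- centers$row_px[i] * spacing_mm
    cx <- centers$col_px[i] * spacing_mm
    if (cy - a < 0 || cy + a > fov || cx - b < 0 || cx + b > fov) {
      stop("chamber ", ch, " exceeds the frame extent; reduce chamber areas ",
           "or enlarge the field of view", call. = FALSE)
    }
  }
  img <- matrix(0.08, size_px, size_px)
  rows_mm <- (seq_len(size_px) - 1) * spacing_mm
  rr <- matrix(rows_mm, size_px, size_px)
  cc <- matrix(rows_mm, size_px, size_px, byrow = TRUE)
  for (pass in c("wall", "blood")) {
    for (i in seq_len(nrow(centers))) {
      area <- areas[[centers$chamber[i]]]
      b <- sqrt(area / (pi * elong))
      a <- elong * b
      if (pass == "wall") { a <- a + w; b <- b + w }
      cy <- centers$row_px[i] * spacing_mm
      cx <- centers$col_px[i] * spacing_mm
      inside <- ((rr - cy) / a)^2 + ((cc - cx) / b)^2 <= 1
      img[inside] <- if (pass == "wall") 0.45 else 1.0
    }
  }
  img
}

# End-diastolic/maximal chamber areas, used for the feasibility check.
areas_ed <- function(params) {
  c(LV = params$lv_edv_area, RV = 0.80 * params$lv_edv_area,
    LA = params$la_max_area, RA = 0.85 * params$la_max_area)
}

#' Generate a beating four-chamber phantom cine sequence
#'
#' Renders `n_frames` frames over one cardiac cycle (phases `0, 1/n, ...,
#' (n-1)/n`; the cycle is periodic, so phase 1 reproduces phase 0).
#' Ventricular areas follow a raised-cosine contraction from end-diastole
#' to an end-systolic area chosen so the implied single-plane volume EF
#' (`volume ~ area^1.5`) equals the requested EF; atria move in anti-phase
#' with the LA total emptying fraction. Gaussian noise with SD
#' `params$noise_sd` is added and intensities clipped at zero. Output is
#' deterministic given `seed`.
#'
#' @param params a [phantom_params()].
#' @param spacing_mm isotropic pixel spacing in mm; the default keeps the
#'   field of view at the production geometry (128 px at 2.2 mm) for any
#'   `size_px`.
#' @param size_px image side in pixels.
#' @param seed integer seed controlling the noise.
#' @param subject_id subject identifier.
#' @return A [cine_sequence()].
#' @export
generate_phantom_sequence <- function(params, spacing_mm = 2.2 * 128 / size_px,
                                      size_px = 128, seed = 1,
                                      subject_id = "phantom") {
  stopifnot(inherits(params, "phantom_params"))
  frames <- array(0, dim = c(params$n_frames, size_px, size_px))
  for (t in seq_len(params$n_frames)) {
    frames[t, , ] <- render_phantom_frame(params, (t - 1) / params$n_frames,
                                          size_px, spacing_mm)
  }
  if (params$noise_sd > 0) {
    frames <- withr::with_seed(as.integer(seed), {
      pmax(frames + stats::rnorm(length(frames), sd = params$noise_sd), 0)
    })
  }
  cine_sequence(frames, pixel_spacing_mm = spacing_mm,
                frame_interval_ms = 800 / params$n_frames,
                subject_id = subject_id)
}

# Connected component of `mask` containing the (1-based) seed pixel,
# grown by iterated 4-neighbour dilation restricted to the mask.
flood_component <- function(mask, seed_rc) {
  comp <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!mask[seed_rc[1], seed_rc[2]]) return(comp)
  comp[seed_rc[1], seed_rc[2]] <- TRUE
  nr <- nrow(mask); nc <- ncol(mask)
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | comp[, -nc]
    grown[, -nc] <- grown[, -nc] | comp[, -1]
    grown <- grown & mask
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

#' Measure per-frame chamber blood-pool areas of a rendered phantom
#'
#' Thresholds each frame at `threshold` and measures, for each chamber of
#' the standard layout, the connected component of the supra-threshold
#' mask containing that chamber's centre. Intended for noiseless or
#' lightly noisy phantoms, as a ground-truth check that the renderer
#' realises the requested ejection fractions.
#'
#' @param seq a phantom [cine_sequence()].
#' @param threshold blood-pool intensity threshold (pools render at 1.0,
#'   walls at 0.45).
#' @return A tibble with columns `frame`, `chamber`, `area_mm2`.
#' @export
measure_chamber_areas <- function(seq, threshold = 0.75) {
  stopifnot(inherits(seq, "cine_sequence"))
  d <- dim(seq$frames)
  centers <- phantom_chamber_centers(d[2], seq$pixel_spacing_mm[1])
  px_area <- prod(seq$pixel_spacing_mm)
  purrr::map_dfr(seq_len(d[1]), function(t) {
    mask <- seq$frames[t, , ] > threshold
    tibble::tibble(
      frame = t,
      chamber = centers$chamber,
      area_mm2 = purrr::map_dbl(seq_len(nrow(centers)), function(i) {
        seed <- round(c(centers$row_px[i], centers$col_px[i])) + 1
        sum(flood_component(mask, seed)) * px_area
      })
    )
  })
}

#' Implied LV volume ejection fraction from measured areas
#'
#' Applies the single-plane proxy `EF = 1 - (A_min / A_max)^1.5` to the
#' per-frame LV areas of [measure_chamber_areas()].
#'
#' @inheritParams measure_chamber_areas
#' @return A scalar EF estimate.
#' @export
measure_lv_ef <- function(seq, threshold = 0.75) {
  a <- measure_chamber_areas(seq, threshold)
  lv <- a$area_mm2[a$chamber == "LV"]
  1 - (min(lv) / max(lv))^1.5
}

#' Population distribution over phantom parameters
#'
#' Independent truncated normals per generative field. The default
#' population mirrors a primary-prevention ICD cohort with systolic heart
#' failure: median LVEF around 26% with wide spread, impaired LA emptying
#' around 38%, dilated chambers.
#'
#' @param fields optional tibble with columns `field`, `mean`, `sd`,
#'   `lower`, `upper` overriding the defaults for the listed fields.
#' @return A tibble describing the population, class `phantom_population`.
#' @export
phantom_population <- function(fields = NULL) {
  pop <- tibble::tribble(
    ~field,              ~mean, ~sd,   ~lower, ~upper,
    "lv_edv_area",        4500,  600,   2800,   6200,
    "lv_ef",              0.26,  0.08,  0.05,   0.60,
    "rv_ef",              0.40,  0.10,  0.10,   0.70,
    "la_max_area",        2200,  350,   1300,   3200,
    "la_total_ef",        0.38,  0.13,  0.05,   0.80,
    "wall_thickness_mm",     8,  0,        8,      8,
    "noise_sd",           0.02,  0,     0.02,   0.02
  )
  if (!is.null(fields)) {
    fields <- tibble::as_tibble(fields)
    stopifnot(all(fields$field %in% pop$field))
    pop <- dplyr::rows_update(pop, fields, by = "field")
  }
  bad <- pop$field[pop$mean < pop$lower | pop$mean > pop$upper]
  if (length(bad)) {
    stop("infeasible population: mean outside bounds for ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  class(pop) <- c("phantom_population", class(pop))
  pop
}

# Truncated-normal draw by rejection; sd = 0 returns the mean.
rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Sample a synthetic cohort of phantom subjects
#'
#' Draws `n` independent parameter sets from a [phantom_population()] and
#' (optionally) renders each subject's cine sequence. Ground-truth
#' parameters are returned alongside the images so downstream stages can be
#' validated against the generative truth.
#'
#' @param n number of subjects (>= 1).
#' @param population a [phantom_population()].
#' @param seed integer seed; draws and rendered noise are deterministic
#'   given it.
#' @param size_px,spacing_mm rendering geometry (see
#'   [generate_phantom_sequence()]).
#' @param n_frames frames per cycle.
#' @param render if `FALSE`, skip rendering and return parameters only.
#' @return A tibble with `subject_id`, one column per generative field and,
#'   when rendered, a `sequence` list-column of [cine_sequence()] objects.
#' @export
sample_cohort <- function(n, population = phantom_population(), seed = 1,
                          size_px = 64, spacing_mm = 2.2 * 128 / size_px,
                          n_frames = 8, render = TRUE) {
  if (!is.numeric(n) || n < 1) stop("`n` must be at least 1", call. = FALSE)
  n <- as.integer(n)
  draws <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(nrow(population)), function(i) {
      rtruncnorm1(n, population$mean[i], population$sd[i],
                  population$lower[i], population$upper[i])
    })
  })
  names(draws) <- population$field
  out <- tibble::as_tibble(draws)
  out <- dplyr::mutate(out,
                       subject_id = sprintf("S%04d", seq_len(n)),
                       .before = 1)
  if (render) {
    out$sequence <- purrr::map(seq_len(n), function(i) {
      p <- phantom_params(
        lv_edv_area = out$lv_edv_area[i], lv_ef = out$lv_ef[i],
        rv_ef = out$rv_ef[i], la_max_area = out$la_max_area[i],
        la_total_ef = out$la_total_ef[i],
        wall_thickness_mm = out$wall_thickness_mm[i],
        noise_sd = out$noise_sd[i], n_frames = n_frames)
      generate_phantom_sequence(p, spacing_mm = spacing_mm, size_px = size_px,
                                seed = as.integer(seed) + i,
                                subject_id = out$subject_id[i])
    })
  }
  out
}

#' Survival simulation configuration
#'
#' Primary-event times are exponential with a log-linear hazard
#' `baseline_hazard * exp(sum(beta_k * z_k))`, where `z_k` are the
#' population-standardised phantom parameters named in
#' `log_hazard_coeffs`. An independent exponential competing death and
#' administrative censoring at `admin_censor_years` complete the observed
#' follow-up. Defaults emulate the censoring regime of a 10-year
#' primary-prevention ICD study with roughly a quarter to a third of
#' subjects experiencing the primary event.
#'
#' @param baseline_hazard events per year at the covariate mean (> 0).
#' @param log_hazard_coeffs named numeric vector of log-hazard coefficients
#'   on standardised phantom fields.
#' @param admin_censor_years administrative censoring horizon (> 0; `Inf`
#'   for none).
#' @param competing_hazard competing-death rate per year (>= 0).
#' @param seed integer seed.
#' @return A list of class `survival_sim_config`.
#' @export
survival_sim_config <- function(baseline_hazard = 0.03,
                                log_hazard_coeffs = c(lv_ef = -1.0),
                                admin_censor_years = 10,
                                competing_hazard = 0,
                                seed = 1) {
  if (!is.finite(baseline_hazard) || baseline_hazard <= 0) {
    stop("`baseline_hazard` must be positive", call. = FALSE)
  }
  if (competing_hazard < 0) stop("`competing_hazard` must be >= 0", call. = FALSE)
  if (admin_censor_years <= 0) stop("`admin_censor_years` must be positive", call. = FALSE)
  if (length(log_hazard_coeffs) && is.null(names(log_hazard_coeffs))) {
    stop("`log_hazard_coeffs` must be named after phantom fields", call. = FALSE)
  }
  structure(list(baseline_hazard = baseline_hazard,
                 log_hazard_coeffs = log_hazard_coeffs,
                 admin_censor_years = admin_censor_years,
                 competing_hazard = competing_hazard,
                 seed = as.integer(seed)),
            class = "survival_sim_config")
}

#' Simulate right-censored outcomes for a synthetic cohort
#'
#' @param cohort a tibble of ground-truth parameters as returned by
#'   [sample_cohort()] (the `sequence` column, if present, is ignored).
#' @param config a [survival_sim_config()].
#' @param outcome_label label attached to the resulting [cohort_table()].
#' @return A [cohort_table()] with the generative parameter columns carried
#'   over as covariates.
#' @export
simulate_survival <- function(cohort, config, outcome_label = "VA") {
  stopifnot(inherits(config, "survival_sim_config"))
  cf <- config$log_hazard_coeffs
  unknown <- setdiff(names(cf), names(cohort))
  if (length(unknown)) {
    stop("log_hazard_coeffs name unknown fields: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- nrow(cohort)
  eta <- rep(0, n)
  for (k in names(cf)) {
    x <- cohort[[k]]
    s <- stats::sd(x)
    z <- if (is.na(s) || s == 0) rep(0, n) else (x - mean(x)) / s
    eta <- eta + cf[[k]] * z
  }
  rates <- config$baseline_hazard * exp(eta)
  sim <- withr::with_seed(config$seed, {
    t1 <- stats::rexp(n, rate = rates)
    t2 <- if (config$competing_hazard > 0) {
      stats::rexp(n, rate = config$competing_hazard)
    } else rep(Inf, n)
    list(t1 = t1, t2 = t2)
  })
  obs <- pmin(sim$t1, sim$t2, config$admin_censor_years)
  code <- ifelse(sim$t1 <= obs & sim$t1 <= sim$t2, 1L,
                 ifelse(sim$t2 <= obs, 2L, 0L))
  covars <- intersect(phantom_param_fields(), names(cohort))
  cohort_table(
    dplyr::bind_cols(
      tibble::tibble(subject_id = cohort$subject_id, time = obs, event_code = code),
      cohort[, covars]
    ),
    outcome_label
  )
}

#' Generate a late-gadolinium-enhancement phantom
#'
#' Builds an annular myocardium on a square grid with normal signal
#' intensity at or below `normal_peak_si` (the peak is attained at exactly
#' one normal pixel), plus a contiguous hyperenhanced scar patch with an
#' intensity gradient: exactly `scar_core_px` pixels above half the maximal
#' SI (the core, including one pixel at `max_si`) and exactly
#' `scar_gray_px` pixels strictly between the normal peak and half-maximal
#' SI (the gray zone, forming the rim of the patch). Construction therefore
#' guarantees that the half-max / normal-peak thresholding rule of
#' [quantify_scar()] recovers the requested pixel counts.
#'
#' @param scar_core_px requested core pixel count (>= 1 whenever
#'   `scar_gray_px > 0`: a non-empty enhanced patch always contains its own
#'   maximum, which exceeds half of itself).
#' @param scar_gray_px requested gray-zone pixel count.
#' @param normal_peak_si peak SI of normal myocardium.
#' @param max_si maximal SI of the scar; must exceed `2 * normal_peak_si`
#'   so the gray band is non-empty.
#' @param seed integer seed (normal-tissue texture and scar placement).
#' @param size_px grid side; the annulus has outer radius `0.42 * size_px`
#'   and inner radius `0.25 * size_px` pixels.
#' @return A list with `image` (matrix), `myocardium_mask`,
#'   `hyperenhanced_mask` (logical matrices) and the generation parameters.
#' @export
generate_lge_phantom <- function(scar_core_px, scar_gray_px,
                                 normal_peak_si = 0.3, max_si = 1.0,
                                 seed = 1, size_px = 48) {
  if (max_si <= 2 * normal_peak_si) {
    stop("`max_si` must exceed 2 * normal_peak_si so the gray band is non-empty",
         call. = FALSE)
  }
  if (scar_core_px == 0 && scar_gray_px > 0) {
    stop("a non-empty enhanced patch always contains a core pixel (its own ",
         "maximum exceeds half of itself); request scar_core_px >= 1",
         call. = FALSE)
  }
  ctr <- (size_px + 1) / 2
  rr <- row(matrix(0, size_px, size_px)) - ctr
  cc <- col(matrix(0, size_px, size_px)) - ctr
  rad <- sqrt(rr^2 + cc^2)
  myo <- rad <= 0.42 * size_px & rad >= 0.25 * size_px
  n_scar <- scar_core_px + scar_gray_px
  if (n_scar > sum(myo) - 1) {
    stop("requested scar (", n_scar, " px) exceeds the annulus capacity (",
         sum(myo) - 1, " px, one normal pixel reserved)", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    img <- matrix(0, size_px, size_px)
    img[!myo & rad < 0.25 * size_px] <- 0.15 * normal_peak_si  # cavity
    img[myo] <- stats::runif(sum(myo), 0.2, 0.95) * normal_peak_si
    scar <- matrix(FALSE, size_px, size_px)
    if (n_scar > 0) {
      idx <- which(myo, arr.ind = TRUE)
      start <- idx[sample.int(nrow(idx), 1), ]
      # breadth-first growth over the annulus: earliest pixels become core,
      # the rim becomes gray zone
      visited <- matrix(FALSE, size_px, size_px)
      order_rc <- matrix(NA_integer_, n_scar, 2)
      queue <- matrix(start, 1, 2)
      visited[start[1], start[2]] <- TRUE
      got <- 0L
      while (got < n_scar && nrow(queue) > 0) {
        cur <- queue[1, , drop = TRUE]
        queue <- queue[-1, , drop = FALSE]
        got <- got + 1L
        order_rc[got, ] <- cur
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          nb <- cur + d
          if (nb[1] >= 1 && nb[1] <= size_px && nb[2] >= 1 && nb[2] <= size_px &&
              myo[nb[1], nb[2]] && !visited[nb[1], nb[2]]) {
            visited[nb[1], nb[2]] <- TRUE
            queue <- rbind(queue, nb)
          }
        }
      }
      if (got < n_scar) {
        stop("scar patch could not grow to ", n_scar,
             " contiguous pixels from the sampled start", call. = FALSE)
      }
      scar[order_rc] <- TRUE
      half <- 0.5 * max_si
      if (scar_core_px > 0) {
        core_si <- seq(max_si, 0.55 * max_si + half * 0.05,
                       length.out = scar_core_px)
        img[order_rc[seq_len(scar_core_px), , drop = FALSE]] <- core_si
      }
      if (scar_gray_px > 0) {
        lo <- normal_peak_si + 0.02 * (half - normal_peak_si)
        hi <- half - 0.02 * (half - normal_peak_si)
        img[order_rc[scar_core_px + seq_len(scar_gray_px), , drop = FALSE]] <-
          seq(hi, lo, length.out = scar_gray_px)
      }
      # guarantee the normal peak is attained outside the patch
      normal_idx <- which(myo & !scar)
      img[normal_idx[1]] <- normal_peak_si
    } else {
      normal_idx <- which(myo)
      img[normal_idx[1]] <- normal_peak_si
    }
    list(image = img, myocardium_mask = myo, hyperenhanced_mask = scar,
         scar_core_px = as.integer(scar_core_px),
         scar_gray_px = as.integer(scar_gray_px),
         normal_peak_si = normal_peak_si, max_si = max_si)
  })
}
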