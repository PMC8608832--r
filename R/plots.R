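#' Plot a Kaplan-Meier curve
#'
#' Step-function survival estimate with its shaded 95% confidence band.
#'
#' @param object a `km_curve` from [kaplan_meier()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1, conf_low = 1, conf_high = 1),
    tibble::as_tibble(object)
  )
  # expand to explicit step corners so the ribbon follows the step function
  k <- nrow(df)
  steps <- df[rep(seq_len(k), each = 2)[seq_len(2 * k - 1)], ]
  steps$time <- rep(df$time, each = 2)[-1]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_ribbon(data = steps,
                         ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         alpha = 0.2) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years", y = "Event-free survival") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves by risk group
#'
#' Splits the cohort at a quantile of the cine risk score and draws one
#' survival curve per group.
#'
#' @param predictions prediction tibble ([combine_fold_predictions()]).
#' @param cohort a [cohort_table()] for the same outcome.
#' @param q split quantile (0.5 = median split).
#' @return A ggplot object.
#' @export
plot_risk_groups <- function(predictions, cohort, q = 0.5) {
  outcome <- unique(predictions$outcome_label)
  dat <- dplyr::inner_join(predictions, tibble::as_tibble(cohort),
                           by = "subject_id")
  status <- event_indicator(dat$event_code, outcome)
  grp <- dichotomize_at_quantile(dat$cine_risk_score, q)
  curves <- purrr::imap_dfr(split(seq_len(nrow(dat)), grp), function(i, g) {
    km <- kaplan_meier(dat$time[i], status[i])
    dplyr::bind_rows(tibble::tibble(time = 0, n_risk = length(i), n_event = 0L,
                                    survival = 1, conf_low = 1, conf_high = 1),
                     tibble::as_tibble(km)) |>
      dplyr::mutate(group = g)
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years", y = "Event-free survival",
                  colour = sprintf("Risk (split at q = %.2f)", q),
                  title = outcome) +
    ggplot2::theme_minimal()
}

#' Plot the score distribution by event status
#'
#' @param object a `risk_result` prediction tibble joined against its
#'   cohort via the `cohort` argument.
#' @param cohort the matching [cohort_table()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot risk_result
#' @export
autoplot.risk_result <- function(object, cohort, ...) {
  outcome <- unique(object$outcome_label)
  dat <- dplyr::inner_join(object, tibble::as_tibble(cohort), by = "subject_id")
  dat$event <- factor(event_indicator(dat$event_code, outcome),
                      levels = c(0, 1), labels = c("no event", "event"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$event,
                                    y = .data$cine_risk_score)) +
    ggplot2::geom_boxplot(width = 0.5, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "Cine risk score", title = outcome) +
    ggplot2::theme_minimal()
}

#' Display one frame of a cine sequence
#'
#' @param seq a [cine_sequence()].
#' @param frame frame index (1-based).
#' @return A ggplot object (raster heat map in physical mm coordinates).
#' @export
plot_cine_frame <- function(seq, frame = 1) {
  stopifnot(inherits(seq, "cine_sequence"))
  img <- seq$frames[frame, , ]
  df <- tibble::tibble(
    row_mm = rep((seq_len(nrow(img)) - 1) * seq$pixel_spacing_mm[1],
                 times = ncol(img)),
    col_mm = rep((seq_len(ncol(img)) - 1) * seq$pixel_spacing_mm[2],
                 each = nrow(img)),
    intensity = as.vector(img)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col_mm, y = .data$row_mm,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "mm", y = "mm",
                  title = sprintf("%s, frame %d", seq$subject_id, frame)) +
    ggplot2::theme_minimal()
}

#' Plot extractor training history
#'
#' @param model a trained `cine_extractor` or `risk_predictor`.
#' @return A ggplot of loss against epoch.
#' @export
plot_training_history <- function(model) {
  h <- model$history
  ycol <- if ("total" %in% names(h)) "total" else "loss"
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Training loss") +
    ggplot2::theme_minimal()
}
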