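#' Quantify LGE core scar and gray zone
#'
#' Applies the signal-intensity thresholding rule for late-gadolinium-
#' enhancement scar characterisation: with `max_si` the maximal SI within
#' the hyperenhanced region and `normal_peak_si` the peak SI of normal
#' (non-enhanced) myocardium, the core scar is every hyperenhanced pixel
#' with `SI > 0.5 * max_si`, and the gray zone is every myocardial pixel
#' with `normal_peak_si < SI < 0.5 * max_si`. Both inequalities are strict;
#' pixels exactly at the half-max threshold belong to neither class and are
#' reported in `unclassified_px`. Masses are `count * voxel_volume_mm3 *
#' density / 1000` grams.
#'
#' @param image numeric 2D SI array, or a list of 2D arrays (slices) to be
#'   quantified per slice and summed.
#' @param myocardium_mask logical mask of the myocardium (same shape).
#' @param hyperenhanced_mask logical mask of the hyperenhanced region; must
#'   be a subset of the myocardium.
#' @param voxel_volume_mm3 voxel volume in mm^3 (e.g. `1.5 * 2.3 * 8`).
#' @param density_g_per_ml myocardial density, default 1.05 g/mL.
#' @param gray_domain `"myocardium"` (default) searches the full myocardium
#'   for gray-zone pixels, since the rule's lower bound references normal
#'   tissue; `"hyperenhanced"` restricts the search to the enhanced patch.
#' @return A one-row tibble of class `scar_quantification`: `core_px`,
#'   `gray_px`, `unclassified_px`, `core_g`, `gray_g`, `total_g`, `max_si`,
#'   `normal_peak_si`.
#' @export
quantify_scar <- function(image, myocardium_mask, hyperenhanced_mask,
                          voxel_volume_mm3, density_g_per_ml = 1.05,
                          gray_domain = c("myocardium", "hyperenhanced")) {
  gray_domain <- match.arg(gray_domain)
  if (is.list(image) && !is.matrix(image)) {
    per_slice <- purrr::pmap(
      list(image, myocardium_mask, hyperenhanced_mask),
      quantify_scar,
      voxel_volume_mm3 = voxel_volume_mm3,
      density_g_per_ml = density_g_per_ml, gray_domain = gray_domain)
    out <- dplyr::bind_rows(per_slice) |>
      dplyr::summarise(dplyr::across(c("core_px", "gray_px", "unclassified_px",
                                       "core_g", "gray_g", "total_g"), sum),
                       max_si = max(.data$max_si),
                       normal_peak_si = max(.data$normal_peak_si))
    class(out) <- c("scar_quantification", class(out))
    return(out)
  }
  stopifnot(is.numeric(image), is.logical(myocardium_mask),
            is.logical(hyperenhanced_mask))
  if (!identical(dim(image), dim(myocardium_mask)) ||
      !identical(dim(image), dim(hyperenhanced_mask))) {
    stop("image and masks must share one shape", call. = FALSE)
  }
  if (!any(myocardium_mask)) stop("empty myocardium mask", call. = FALSE)
  if (any(hyperenhanced_mask & !myocardium_mask)) {
    stop("hyperenhanced mask must be a subset of the myocardium", call. = FALSE)
  }
  normal <- myocardium_mask & !hyperenhanced_mask
  if (any(hyperenhanced_mask) && !any(normal)) {
    stop("no normal myocardium left to reference the gray-zone lower bound",
         call. = FALSE)
  }
  vox_g <- voxel_volume_mm3 * density_g_per_ml / 1000
  if (!any(hyperenhanced_mask)) {
    out <- tibble::tibble(core_px = 0L, gray_px = 0L, unclassified_px = 0L,
                          core_g = 0, gray_g = 0, total_g = 0,
                          max_si = NA_real_,
                          normal_peak_si = max(image[normal]))
    class(out) <- c("scar_quantification", class(out))
    return(out)
  }
  max_si <- max(image[hyperenhanced_mask])
  normal_peak_si <- max(image[normal])
  half <- 0.5 * max_si
  core <- hyperenhanced_mask & image > half
  gray_dom <- if (gray_domain == "myocardium") myocardium_mask else hyperenhanced_mask
  gray <- gray_dom & image > normal_peak_si & image < half
  unclassified <- hyperenhanced_mask & image == half
  out <- tibble::tibble(
    core_px = sum(core), gray_px = sum(gray),
    unclassified_px = sum(unclassified),
    core_g = sum(core) * vox_g, gray_g = sum(gray) * vox_g,
    total_g = (sum(core) + sum(gray)) * vox_g,
    max_si = max_si, normal_peak_si = normal_peak_si
  )
  class(out) <- c("scar_quantification", class(out))
  out
}
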