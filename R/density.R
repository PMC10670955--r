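# Nuclear density of the epithelial band: area-threshold filtering of the
# detected nuclei, density as count per micrometre of band length, the
# threshold sensitivity analysis, and the automated-vs-manual comparison.

#' Filter nucleus records by area thresholds
#'
#' Restricts to in-band records, drops objects smaller than `a_min_um2`
#' (debris), computes the median area `A_med` of the survivors, and then
#' drops objects larger than `a_max_factor * A_med`. The median is computed
#' *after* both the in-band restriction and the lower cut so debris cannot
#' bias it. Oversized objects are excluded, not split into multiple counts.
#'
#' @param records Tibble from [segment_nuclei()].
#' @param a_min_um2 Lower area threshold in square micrometres, in `[0, 5]`
#'   (default 2.5).
#' @param a_max_factor Upper threshold as a multiple of the median survivor
#'   area, in `(3, 5)` (default 4).
#' @return A list with `kept` (the surviving records) and `a_med_um2`.
#' @export
filter_nuclei <- function(records, a_min_um2 = 2.5, a_max_factor = 4) {
  check_columns(records, c("area_um2", "in_band"), "records")
  check_number(a_min_um2, "a_min_um2", min = 0, max = 5)
  check_number(a_max_factor, "a_max_factor", min = 3, max = 5, strict_min = TRUE)
  if (a_max_factor >= 5) abort("`a_max_factor` must be < 5.")
  inb <- dplyr::filter(records, .data$in_band, .data$area_um2 >= a_min_um2)
  if (nrow(inb) == 0L) {
    abort("undefined median: no in-band nucleus passes `a_min_um2`.")
  }
  a_med <- median(inb$area_um2)
  kept <- dplyr::filter(inb, .data$area_um2 <= a_max_factor * a_med)
  list(kept = kept, a_med_um2 = a_med)
}

#' Nuclear density from a count and a band length
#'
#' @param n_nuclei Non-negative integer count of (filtered) nuclei.
#' @param band_length_um Band length in micrometres (> 0).
#' @param a_min_um2,a_max_factor Filter parameters used, carried as
#'   provenance.
#' @param id Image identifier, carried as provenance.
#' @return A one-row tibble: `id`, `n_nuclei`, `band_length_um`,
#'   `density_per_um`, `a_min_um2`, `a_max_factor`.
#' @export
compute_density <- function(n_nuclei, band_length_um, a_min_um2 = NA_real_,
                            a_max_factor = NA_real_, id = NA_character_) {
  n_nuclei <- check_count(n_nuclei, "n_nuclei", 0L)
  check_number(band_length_um, "band_length_um", 0, strict_min = TRUE)
  tibble(
    id = id,
    n_nuclei = n_nuclei,
    band_length_um = band_length_um,
    density_per_um = n_nuclei / band_length_um,
    a_min_um2 = a_min_um2,
    a_max_factor = a_max_factor
  )
}

#' End-to-end nuclear density of one micrograph
#'
#' Convenience pipeline: [segment_band()], [segment_nuclei()],
#' [filter_nuclei()], [estimate_band_length()], [compute_density()].
#'
#' @param x A [micrograph()].
#' @param a_min_um2,a_max_factor Filter thresholds, see [filter_nuclei()].
#' @param band_smoothing_sigma_um,closing_radius_um Passed to
#'   [segment_band()].
#' @param nuclei_smoothing_sigma_um,min_seed_distance_um Passed to
#'   [segment_nuclei()].
#' @return A one-row tibble as from [compute_density()].
#' @export
quantify_density <- function(x, a_min_um2 = 2.5, a_max_factor = 4,
                             band_smoothing_sigma_um = 1,
                             closing_radius_um = 2,
                             nuclei_smoothing_sigma_um = 0.25,
                             min_seed_distance_um = 2) {
  band <- segment_band(x, band_smoothing_sigma_um, closing_radius_um)
  recs <- segment_nuclei(x, band, nuclei_smoothing_sigma_um, min_seed_distance_um)
  flt <- filter_nuclei(recs, a_min_um2, a_max_factor)
  len <- estimate_band_length(band)
  compute_density(nrow(flt$kept), len, a_min_um2, a_max_factor, id = x$id)
}

#' Sensitivity of the density to the area-filter thresholds
#'
#' Segments once, then re-applies the area filter over the full grid of
#' `(a_min_um2, a_max_factor)` values and recomputes the density per grid
#' point. The summary statistic is the maximum relative deviation
#' `(max - min) / median` of the density over the grid; a small value means
#' the thresholds barely matter for the image at hand.
#'
#' @param x A [micrograph()].
#' @param a_min_grid Lower thresholds in square micrometres, within
#'   `[0, 5]`; default `c(0, 1.25, 2.5, 3.75, 5)`.
#' @param factor_grid Upper-threshold factors within `(3, 5)`; default
#'   `c(3.25, 3.75, 4.25, 4.75)`.
#' @param ... Segmentation arguments passed to [quantify_density()]'s
#'   underlying steps (see [segment_band()] / [segment_nuclei()]).
#' @return An object of class `sensitivity_result`: list with `grid` (tibble
#'   of `a_min_um2`, `a_max_factor`, `n_nuclei`, `density_per_um`),
#'   `max_rel_deviation`, `band_length_um` and `id`. `tidy()` returns the
#'   grid, `glance()` the one-row summary.
#' @export
run_sensitivity <- function(x, a_min_grid = c(0, 1.25, 2.5, 3.75, 5),
                            factor_grid = c(3.25, 3.75, 4.25, 4.75), ...) {
  if (!length(a_min_grid) || !length(factor_grid)) {
    abort("threshold grids must be non-empty.")
  }
  if (any(a_min_grid < 0 | a_min_grid > 5)) abort("`a_min_grid` must lie in [0, 5].")
  if (any(factor_grid <= 3 | factor_grid >= 5)) abort("`factor_grid` must lie in (3, 5).")
  dots <- list(...)
  band <- segment_band(
    x,
    smoothing_sigma_um = dots$band_smoothing_sigma_um %||% 1,
    closing_radius_um = dots$closing_radius_um %||% 2
  )
  recs <- segment_nuclei(
    x, band,
    smoothing_sigma_um = dots$nuclei_smoothing_sigma_um %||% 0.25,
    min_seed_distance_um = dots$min_seed_distance_um %||% 2
  )
  len <- estimate_band_length(band)
  grid <- tidyr::expand_grid(a_min_um2 = a_min_grid, a_max_factor = factor_grid) |>
    dplyr::mutate(purrr::map2_dfr(
      .data$a_min_um2, .data$a_max_factor,
      function(am, fx) {
        flt <- filter_nuclei(recs, am, fx)
        tibble(n_nuclei = nrow(flt$kept), density_per_um = nrow(flt$kept) / len)
      }
    ))
  dens <- grid$density_per_um
  mrd <- if (length(dens) > 1L) (max(dens) - min(dens)) / median(dens) else 0
  structure(
    list(
      grid = grid, max_rel_deviation = mrd,
      band_length_um = len, id = x$id
    ),
    class = "sensitivity_result"
  )
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_result '%s'> %d grid points, max relative deviation %.3g\n",
    x$id, nrow(x$grid), x$max_rel_deviation
  ))
  invisible(x)
}

#' @rdname run_sensitivity
#' @param x A `sensitivity_result`.
#' @method tidy sensitivity_result
#' @export
tidy.sensitivity_result <- function(x, ...) x$grid

#' @rdname run_sensitivity
#' @method glance sensitivity_result
#' @export
glance.sensitivity_result <- function(x, ...) {
  tibble(
    id = x$id,
    n_grid = nrow(x$grid),
    band_length_um = x$band_length_um,
    max_rel_deviation = x$max_rel_deviation
  )
}

#' @rdname run_sensitivity
#' @param object A `sensitivity_result`.
#' @method autoplot sensitivity_result
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  ggplot2::ggplot(
    object$grid,
    ggplot2::aes(
      x = factor(.data$a_min_um2), y = factor(.data$a_max_factor),
      fill = .data$density_per_um
    )
  ) +
    ggplot2::geom_tile() +
    ggplot2::labs(
      x = expression(A[min] ~ (mu * m^2)),
      y = expression(A[max] / A[med]),
      fill = "nuclei/µm",
      title = sprintf(
        "Threshold sensitivity (max rel. deviation %.2f%%)",
        100 * object$max_rel_deviation
      )
    ) +
    ggplot2::theme_minimal()
}

#' Compare automated with manual nucleus counts
#'
#' @param auto,manual Equal-length integer vectors of paired per-image
#'   counts.
#' @return A one-row tibble: `n`, `mean_signed_diff` (auto minus manual),
#'   `mean_abs_diff`, and `concordance` (Lin's concordance correlation
#'   coefficient; `NA` for a single pair or zero variance).
#' @export
compare_with_manual <- function(auto, manual) {
  if (length(auto) != length(manual)) {
    abort("`auto` and `manual` must have the same length.")
  }
  if (!length(auto)) abort("need at least one pair of counts.")
  d <- as.numeric(auto) - as.numeric(manual)
  ccc <- if (length(auto) < 2L) {
    NA_real_
  } else {
    sx <- stats::var(auto) * (length(auto) - 1) / length(auto)
    sy <- stats::var(manual) * (length(auto) - 1) / length(auto)
    sxy <- stats::cov(auto, manual) * (length(auto) - 1) / length(auto)
    denom <- sx + sy + (mean(auto) - mean(manual))^2
    if (denom == 0) {
      if (all(d == 0)) 1 else NA_real_
    } else {
      2 * sxy / denom
    }
  }
  tibble(
    n = length(auto),
    mean_signed_diff = mean(d),
    mean_abs_diff = mean(abs(d)),
    concordance = ccc
  )
}
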