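# Ussing-chamber TEER processing: Ohm's-law resistance, blank subtraction,
# area scaling, normalization to the 30 min equilibration anchor, and
# per-time-point group comparisons.

#' Area of a circular exposure window
#'
#' @param diameter_mm Window diameter in millimetres (>= 0).
#' @return Area in square centimetres: `pi * (d / 2)^2 / 100`.
#' @examples
#' circular_window_area(2) # 0.0314 cm^2 for the standard 2 mm aperture
#' @export
circular_window_area <- function(diameter_mm) {
  check_number(diameter_mm, "diameter_mm", min = 0)
  pi * (diameter_mm / 2)^2 / 100
}

#' Absolute TEER from chamber readings
#'
#' Takes a long table of chamber readings and computes the absolute TEER per
#' time point: total resistance from Ohm's law when raw potential/current
#' pairs are given (`R = dV / dI`, mV over uA giving kohm, converted to ohm),
#' then `teer = (R_total - blank) * window_area`. Resistances are treated as
#' magnitudes.
#'
#' @param trace Data frame with columns `chamber_id`, `time_min`, and either
#'   `resistance_ohm` or both `potential_mV` and `current_uA`; plus
#'   `blank_resistance_ohm` (per chamber; a constant column is fine).
#' @param window_area_cm2 Exposed tissue area in cm^2 (default the 2 mm
#'   circular window, 0.0314 cm^2).
#' @param blank_resistance_ohm Optional global fallback used where the
#'   column is absent.
#' @return The input tibble with `teer_ohm_cm2` added, ordered by chamber
#'   and time.
#' @export
teer_from_trace <- function(trace, window_area_cm2 = circular_window_area(2),
                            blank_resistance_ohm = NULL) {
  check_columns(trace, c("chamber_id", "time_min"), "trace")
  check_number(window_area_cm2, "window_area_cm2", 0, strict_min = TRUE)
  df <- as_tibble(trace)
  if (!"blank_resistance_ohm" %in% names(df)) {
    if (is.null(blank_resistance_ohm)) {
      abort("`trace` needs a `blank_resistance_ohm` column (or pass the global fallback).")
    }
    df$blank_resistance_ohm <- blank_resistance_ohm
  }
  if (!"resistance_ohm" %in% names(df)) {
    check_columns(df, c("potential_mV", "current_uA"), "trace")
    if (any(df$current_uA == 0)) {
      abort(sprintf(
        "zero current at time %s min: Ohm's law undefined.",
        paste(unique(df$time_min[df$current_uA == 0]), collapse = ", ")
      ))
    }
    # mV / uA = kohm
    df$resistance_ohm <- abs(df$potential_mV / df$current_uA) * 1000
  }
  bad <- df$blank_resistance_ohm > df$resistance_ohm + 1e-9
  if (any(bad)) {
    abort(sprintf(
      "blank resistance exceeds total resistance at time %s min.",
      paste(unique(df$time_min[bad]), collapse = ", ")
    ))
  }
  df |>
    dplyr::mutate(
      teer_ohm_cm2 = (abs(.data$resistance_ohm) - .data$blank_resistance_ohm) *
        window_area_cm2
    ) |>
    dplyr::arrange(.data$chamber_id, .data$time_min)
}

#' Relative TEER, normalized to the equilibration anchor
#'
#' Expresses each chamber's TEER as a percentage of its own value at the end
#' of the equilibration period (the `anchor_min` reading, 30 min by
#' default). If no reading exists exactly at the anchor, the nearest earlier
#' reading is used with a warning.
#'
#' @param series Data frame with `chamber_id`, `time_min`, `teer_ohm_cm2`
#'   (as produced by [teer_from_trace()]).
#' @param anchor_min Anchor time in minutes (default 30).
#' @return The input with `relative_pct` and `anchor_teer_ohm_cm2` added;
#'   `relative_pct` is exactly 100 at the anchor.
#' @export
relative_teer <- function(series, anchor_min = 30) {
  check_columns(series, c("chamber_id", "time_min", "teer_ohm_cm2"), "series")
  check_number(anchor_min, "anchor_min", 0)
  series |>
    as_tibble() |>
    dplyr::group_by(.data$chamber_id) |>
    dplyr::group_modify(function(d, key) {
      hit <- which(d$time_min == anchor_min)
      if (!length(hit)) {
        earlier <- which(d$time_min < anchor_min)
        if (!length(earlier)) {
          abort(sprintf(
            "chamber %s: no reading at or before the %g min anchor.",
            key$chamber_id, anchor_min
          ))
        }
        hit <- earlier[which.max(d$time_min[earlier])]
        warn(sprintf(
          "chamber %s: no reading at %g min; using %g min as anchor.",
          key$chamber_id, anchor_min, d$time_min[hit]
        ))
      }
      anchor <- d$teer_ohm_cm2[hit[1]]
      if (!is.finite(anchor) || anchor <= 0) {
        abort(sprintf(
          "chamber %s: anchor TEER must be positive.", key$chamber_id
        ))
      }
      d$anchor_teer_ohm_cm2 <- anchor
      d$relative_pct <- 100 * d$teer_ohm_cm2 / anchor
      d
    }) |>
    dplyr::ungroup()
}

#' End-to-end TEER processing
#'
#' [teer_from_trace()] followed by [relative_teer()].
#'
#' @inheritParams teer_from_trace
#' @inheritParams relative_teer
#' @return Tibble with absolute and relative TEER per chamber and time.
#' @export
process_teer <- function(trace, window_area_cm2 = circular_window_area(2),
                         blank_resistance_ohm = NULL, anchor_min = 30) {
  relative_teer(
    teer_from_trace(trace, window_area_cm2, blank_resistance_ohm),
    anchor_min
  )
}

#' Compare two groups' relative TEER at one time point
#'
#' Exact two-sided Mann-Whitney U comparison (see [mw_u_test()]) of the
#' per-chamber relative TEER values of two groups at a single time point.
#'
#' @param group_a,group_b Numeric vectors of relative TEER values (each
#'   n >= 2).
#' @param time_min The time point, carried into the result.
#' @return One-row tibble: `time_min`, group means, `n_a`, `n_b`, `method`,
#'   `statistic`, `p.value`.
#' @export
compare_timepoint <- function(group_a, group_b, time_min = NA_real_) {
  fit <- mw_u_test(group_a, group_b)
  tibble(
    time_min = time_min,
    mean_a = mean(group_a), mean_b = mean(group_b),
    n_a = fit$n1, n_b = fit$n2,
    method = fit$method, statistic = fit$statistic, p.value = fit$p.value
  )
}

#' Per-time-point group comparison of relative TEER
#'
#' Splits a processed TEER table by a grouping column (with exactly two
#' levels) and runs [compare_timepoint()] at each requested time.
#'
#' @param series Output of [process_teer()] (needs `relative_pct`).
#' @param group_col Name of the two-level grouping column (e.g. `"sex"` or
#'   `"treatment"`).
#' @param times Evaluation times in minutes (default the study's
#'   45, 60, 90, 120, 180, 360).
#' @return Tibble with one row per time point.
#' @export
compare_teer_timepoints <- function(series, group_col,
                                    times = c(45, 60, 90, 120, 180, 360)) {
  check_columns(series, c("time_min", "relative_pct", group_col), "series")
  lv <- sort(unique(series[[group_col]]))
  if (length(lv) != 2L) {
    abort(sprintf("`%s` must have exactly two levels.", group_col))
  }
  purrr::map_dfr(times, function(tm) {
    d <- dplyr::filter(series, .data$time_min == tm)
    a <- d$relative_pct[d[[group_col]] == lv[1]]
    b <- d$relative_pct[d[[group_col]] == lv[2]]
    out <- compare_timepoint(a, b, tm)
    out$group_a <- lv[1]
    out$group_b <- lv[2]
    out
  })
}

#' Plot relative TEER time courses
#'
#' @param series Output of [process_teer()].
#' @param colour_col Optional grouping column mapped to colour.
#' @return A ggplot object: one line per chamber, the treatment window
#'   (30-45 min) shaded.
#' @export
plot_teer <- function(series, colour_col = NULL) {
  check_columns(series, c("chamber_id", "time_min", "relative_pct"), "series")
  p <- ggplot2::ggplot(
    series,
    ggplot2::aes(.data$time_min, .data$relative_pct, group = .data$chamber_id)
  ) +
    ggplot2::annotate("rect",
      xmin = 30, xmax = 45, ymin = -Inf, ymax = Inf,
      alpha = 0.15
    ) +
    ggplot2::geom_hline(yintercept = 100, linetype = 3) +
    ggplot2::labs(
      x = "time (min)", y = "relative TEER (% of 30 min value)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(colour_col)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data[[colour_col]]))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p
}
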