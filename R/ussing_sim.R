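# Simulated Ussing-chamber traces: an equilibration plateau, a
# polycation-induced drop in barrier resistance ending at 45 min, and an
# exponential recovery toward a plateau, sampled on the study's schedule.

#' Standard Ussing-chamber sampling schedule
#'
#' Readings every 10 min during the 30 min equilibration, every 5 min from
#' 30 to 60 min, every 10 min from 60 to 120 min, and every 20 min
#' thereafter up to `end_min`.
#'
#' @param end_min Last time point in minutes (default 360).
#' @return Strictly increasing numeric vector of times in minutes.
#' @export
ussing_schedule <- function(end_min = 360) {
  check_number(end_min, "end_min", min = 120)
  unique(c(seq(0, 30, 10), seq(35, 60, 5), seq(70, 120, 10), seq(140, end_min, 20)))
}

#' Parameters for the Ussing-trace simulator
#'
#' Defaults reflect an ex vivo mouse bladder preparation: a baseline TEER of
#' 159 ohm cm^2, an exposure window of 0.0314 cm^2, a 60% drop in TEER after
#' a 15 min apical poly-L-lysine challenge ending at 45 min, and recovery
#' toward 85% of baseline.
#'
#' @param baseline_teer_ohm_cm2 TEER during equilibration (ohm cm^2).
#' @param blank_resistance_ohm Fluid-only resistance of the chamber (ohm),
#'   stored per chamber and added back into the simulated total resistance.
#' @param window_area_cm2 Exposed tissue area (cm^2).
#' @param pll_drop_fraction Fractional TEER drop at 45 min, in `[0, 1]`.
#' @param recovery_half_time_min Half-time of the exponential recovery (min).
#' @param recovery_plateau_fraction Late plateau as a fraction of baseline;
#'   must be at least `1 - pll_drop_fraction`.
#' @param noise_cv Multiplicative noise coefficient of variation (0 = exact).
#' @param schedule Sampling times in minutes, strictly increasing and
#'   containing the 30 min anchor.
#' @param seed Integer seed.
#' @return A validated list of class `ussing_sim_params`.
#' @export
ussing_sim_params <- function(baseline_teer_ohm_cm2 = 159,
                              blank_resistance_ohm = 100,
                              window_area_cm2 = circular_window_area(2),
                              pll_drop_fraction = 0.6,
                              recovery_half_time_min = 45,
                              recovery_plateau_fraction = 0.85,
                              noise_cv = 0,
                              schedule = ussing_schedule(),
                              seed = 1L) {
  check_number(baseline_teer_ohm_cm2, "baseline_teer_ohm_cm2", 0, strict_min = TRUE)
  check_number(blank_resistance_ohm, "blank_resistance_ohm", 0)
  check_number(window_area_cm2, "window_area_cm2", 0, strict_min = TRUE)
  check_number(pll_drop_fraction, "pll_drop_fraction", 0, max = 1)
  check_number(recovery_half_time_min, "recovery_half_time_min", 0, strict_min = TRUE)
  check_number(recovery_plateau_fraction, "recovery_plateau_fraction", 0, max = 1)
  check_number(noise_cv, "noise_cv", 0)
  if (any(diff(schedule) <= 0)) abort("`schedule` must be strictly increasing.")
  if (!30 %in% schedule) abort("`schedule` must contain the 30 min anchor.")
  if (recovery_plateau_fraction < 1 - pll_drop_fraction) {
    abort("`recovery_plateau_fraction` must be >= the post-drop floor (1 - pll_drop_fraction).")
  }
  structure(
    list(
      baseline_teer_ohm_cm2 = baseline_teer_ohm_cm2,
      blank_resistance_ohm = blank_resistance_ohm,
      window_area_cm2 = window_area_cm2,
      pll_drop_fraction = pll_drop_fraction,
      recovery_half_time_min = recovery_half_time_min,
      recovery_plateau_fraction = recovery_plateau_fraction,
      noise_cv = noise_cv,
      schedule = as.numeric(schedule),
      seed = check_count(seed, "seed", min = -2147483647L)
    ),
    class = "ussing_sim_params"
  )
}

# Noiseless TEER profile at time t (min), as a fraction of baseline.
teer_profile_fraction <- function(t, drop, t_half, plateau) {
  floor_frac <- 1 - drop
  frac <- rep(1, length(t))
  mid <- t > 30 & t < 45
  frac[mid] <- 1 - drop * (t[mid] - 30) / 15
  late <- t >= 45
  frac[late] <- plateau - (plateau - floor_frac) * 2^(-(t[late] - 45) / t_half)
  frac
}

#' Simulate a set of Ussing-chamber traces
#'
#' Each chamber carries the full sampling schedule; the stored reading is the
#' total resistance in ohms (tissue plus fluid blank), so the processing
#' stage must subtract the blank and scale by the window area to recover
#' TEER. With `noise_cv = 0` the relative TEER at the 30 min anchor is
#' exactly 100% and at 45 min exactly `100 * (1 - pll_drop_fraction)` %.
#'
#' @param params An [ussing_sim_params()] object.
#' @param n_chambers Number of chambers (>= 1).
#' @return A tibble with columns `chamber_id`, `time_min`, `resistance_ohm`,
#'   `blank_resistance_ohm`, ready for [teer_from_trace()].
#' @export
generate_ussing_traces <- function(params, n_chambers = 1L) {
  stopifnot(inherits(params, "ussing_sim_params"))
  n_chambers <- check_count(n_chambers, "n_chambers", 1L)
  p <- params
  with_seed(p$seed, {
    purrr::map_dfr(seq_len(n_chambers), function(ch) {
      frac <- teer_profile_fraction(
        p$schedule, p$pll_drop_fraction,
        p$recovery_half_time_min, p$recovery_plateau_fraction
      )
      teer <- p$baseline_teer_ohm_cm2 * frac
      if (p$noise_cv > 0) {
        teer <- pmax(teer * (1 + rnorm(length(teer), 0, p$noise_cv)), 0)
      }
      tibble(
        chamber_id = sprintf("ch%02d", ch),
        time_min = p$schedule,
        resistance_ohm = teer / p$window_area_cm2 + p$blank_resistance_ohm,
        blank_resistance_ohm = p$blank_resistance_ohm
      )
    })
  })
}
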