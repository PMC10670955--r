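# TEER processing: window area, Ohm's law, blank subtraction, anchor
# normalization, and the per-time-point comparisons.

mk_trace <- function(resistance, times = c(10, 20, 30, 45), blank = 1000,
                     chamber = "ch01") {
  tibble::tibble(
    chamber_id = chamber, time_min = times,
    resistance_ohm = resistance, blank_resistance_ohm = blank
  )
}

test_that("circular window area matches the printed aperture constant", {
  expect_equal(signif(circular_window_area(2), 3), 0.0314)
  expect_equal(circular_window_area(0), 0)
  expect_equal(circular_window_area(1), pi * 0.25 / 100, tolerance = 1e-12)
  expect_error(circular_window_area(-1), ">=")
})

test_that("absolute TEER is blank-subtracted and area-scaled", {
  tr <- mk_trace(rep(5000, 4))
  out <- teer_from_trace(tr, window_area_cm2 = 0.0314)
  expect_equal(unique(out$teer_ohm_cm2), (5000 - 1000) * 0.0314)
  # total equal to blank gives zero TEER
  out0 <- teer_from_trace(mk_trace(rep(1000, 4)), 0.0314)
  expect_equal(unique(out0$teer_ohm_cm2), 0)
})

test_that("raw potential/current readings go through Ohm's law", {
  tr <- tibble::tibble(
    chamber_id = "ch01", time_min = c(30, 45),
    potential_mV = c(10, 10), current_uA = c(2, 2),
    blank_resistance_ohm = 1000
  )
  out <- teer_from_trace(tr, window_area_cm2 = 0.0314)
  expect_equal(unique(out$resistance_ohm), 5000) # 10 mV / 2 uA = 5 kohm
  tr$current_uA[2] <- 0
  expect_error(teer_from_trace(tr, 0.0314), "zero current.*45")
})

test_that("a blank above the total resistance errors naming the time point", {
  tr <- mk_trace(c(5000, 5000, 800, 5000))
  expect_error(teer_from_trace(tr, 0.0314), "blank.*30")
})

test_that("relative TEER anchors at 100% and errors without a usable anchor", {
  tr <- mk_trace(c(3000, 4000, 5000, 4400))
  s <- process_teer(tr, window_area_cm2 = 0.0314)
  expect_equal(s$relative_pct[s$time_min == 30], 100)
  expect_equal(s$relative_pct[s$time_min == 45], 100 * 3400 / 4000)

  # missing 30 min reading: nearest earlier used, with a warning
  tr2 <- mk_trace(c(3000, 5000, 4400), times = c(10, 20, 45))
  expect_warning(s2 <- process_teer(tr2, 0.0314), "20 min")
  expect_equal(s2$relative_pct[s2$time_min == 20], 100)

  # zero anchor
  tr3 <- mk_trace(c(3000, 4000, 1000, 4400))
  expect_error(process_teer(tr3, 0.0314), "positive")
})

test_that("TEER is linear in window area and invariant to a common offset", {
  tr <- mk_trace(c(3000, 4000, 5000, 4400))
  a <- teer_from_trace(tr, 0.0314)
  b <- teer_from_trace(tr, 2 * 0.0314)
  expect_equal(b$teer_ohm_cm2, 2 * a$teer_ohm_cm2)
  tr_shift <- tr
  tr_shift$resistance_ohm <- tr$resistance_ohm + 500
  tr_shift$blank_resistance_ohm <- tr$blank_resistance_ohm + 500
  expect_equal(
    teer_from_trace(tr_shift, 0.0314)$teer_ohm_cm2,
    a$teer_ohm_cm2
  )
})

test_that("end-to-end round trip recovers the simulated baseline exactly", {
  p <- ussing_sim_params(noise_cv = 0, baseline_teer_ohm_cm2 = 212.5)
  s <- process_teer(generate_ussing_traces(p, 2), p$window_area_cm2)
  expect_equal(unique(s$anchor_teer_ohm_cm2), 212.5, tolerance = 1e-9)
  expect_equal(unique(s$relative_pct[s$time_min == 30]), 100)
})

test_that("group comparison at a time point uses the exact test", {
  cmp <- compare_timepoint(c(101, 99, 95, 97), c(80, 85, 83, 88), time_min = 45)
  expect_equal(cmp$p.value, 2 / 70)
  expect_equal(cmp$method, "mann_whitney_exact")

  # two groups of chambers with separated relative levels
  pa <- ussing_sim_params(noise_cv = 0.01, pll_drop_fraction = 0.4, seed = 1)
  pb <- ussing_sim_params(noise_cv = 0.01, pll_drop_fraction = 0.8, seed = 2)
  sa <- process_teer(generate_ussing_traces(pa, 4), pa$window_area_cm2)
  sb <- process_teer(generate_ussing_traces(pb, 4), pb$window_area_cm2)
  sa$sex <- "male"
  sb$sex <- "female"
  sb$chamber_id <- sub("ch", "cf", sb$chamber_id)
  cmps <- compare_teer_timepoints(dplyr::bind_rows(sa, sb), "sex",
    times = c(45, 60)
  )
  expect_equal(nrow(cmps), 2L)
  expect_true(all(cmps$p.value <= 2 / 70 + 1e-12))
})
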