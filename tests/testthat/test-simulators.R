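# Ussing-trace and assay-table simulators.

test_that("the sampling schedule follows the chamber protocol", {
  s <- ussing_schedule()
  expect_true(all(diff(s) > 0))
  expect_true(all(c(0, 10, 20, 30) %in% s)) # every 10 min to 30
  expect_true(all(seq(35, 60, 5) %in% s)) # every 5 min to 60
  expect_true(all(seq(70, 120, 10) %in% s)) # every 10 min to 120
  expect_true(all(seq(140, 360, 20) %in% s)) # every 20 min to 360
  expect_false(45 %in% setdiff(s, seq(35, 60, 5)))
})

test_that("noiseless traces hit the drop and anchor by construction", {
  p <- ussing_sim_params(noise_cv = 0, pll_drop_fraction = 0.6)
  tr <- generate_ussing_traces(p, n_chambers = 2)
  s <- process_teer(tr, window_area_cm2 = p$window_area_cm2)
  expect_equal(unique(s$relative_pct[s$time_min == 30]), 100)
  expect_equal(unique(s$relative_pct[s$time_min == 45]), 40, tolerance = 1e-9)
  expect_equal(
    unique(s$teer_ohm_cm2[s$time_min == 30]),
    p$baseline_teer_ohm_cm2,
    tolerance = 1e-9
  )
})

test_that("traces are deterministic in the seed and recover toward the plateau", {
  p <- ussing_sim_params(noise_cv = 0.05, seed = 9)
  expect_identical(
    generate_ussing_traces(p, 3),
    generate_ussing_traces(p, 3)
  )
  p0 <- ussing_sim_params(noise_cv = 0)
  tr <- generate_ussing_traces(p0, 1)
  s <- process_teer(tr, window_area_cm2 = p0$window_area_cm2)
  late <- s$relative_pct[s$time_min >= 45]
  expect_true(all(diff(late) > 0)) # monotone recovery
  expect_lt(max(late), 100 * p0$recovery_plateau_fraction)
})

test_that("invalid chamber parameters are rejected", {
  expect_error(ussing_sim_params(schedule = c(0, 10, 10, 30)), "increasing")
  expect_error(ussing_sim_params(schedule = c(0, 10, 20, 40)), "anchor")
  expect_error(
    ussing_sim_params(pll_drop_fraction = 0.6, recovery_plateau_fraction = 0.3),
    "floor"
  )
})

test_that("qPCR tables carry the planted group effect (and none when zero)", {
  t0 <- simulate_qpcr_table(group_effect = 0, noise_sd = 0, seed = 1)
  d0 <- qpcr_neg_delta_ct(t0)
  expect_equal(
    unique(d0$neg_delta_ct[d0$group == "F"]),
    unique(d0$neg_delta_ct[d0$group == "M"])
  )
  t1 <- simulate_qpcr_table(group_effect = -2, noise_sd = 0, seed = 1)
  d1 <- qpcr_neg_delta_ct(t1)
  expect_equal(
    mean(d1$neg_delta_ct[d1$group == "M"]) - mean(d1$neg_delta_ct[d1$group == "F"]),
    2
  )
})

test_that("DGE tables plant exactly the stated significant sets", {
  dge <- simulate_dge_table(
    n_genes = 150, contrasts = c("F", "M"),
    n_up = c(3, 5), n_down = c(3, 1), n_shared = 2, seed = 21
  )
  planted <- attr(dge, "planted")
  fs <- filter_deregulated(dge, 0.05)
  expect_equal(tidy(fs)$n_up, c(3, 5))
  expect_equal(tidy(fs)$n_down, c(3, 1))
  expect_setequal(
    fs$sets$F$up,
    planted$gene[planted$contrast == "F" & planted$direction == "up"]
  )
  g <- glance(fs)
  expect_equal(g$n_shared, 2)
  expect_equal(g$n_unique_1, 4)
  expect_equal(g$n_unique_2, 4)
})

test_that("assay dispatch is seeded-deterministic and rejects unknown kinds", {
  expect_identical(
    generate_assay_tables("urine", seed = 4),
    generate_assay_tables("urine", seed = 4)
  )
  expect_error(generate_assay_tables("metabolome"), "kind")
})
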