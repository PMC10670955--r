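# Area-threshold filtering, density arithmetic, sensitivity analysis and
# the automated-vs-manual comparison.

nucleus_records <- function(areas, in_band = TRUE) {
  tibble::tibble(
    label = seq_along(areas),
    area_um2 = areas,
    centroid_row = 1, centroid_col = 1,
    in_band = rep_len(in_band, length(areas))
  )
}

test_that("area filtering applies the lower cut before the median", {
  f <- filter_nuclei(nucleus_records(c(10, 12, 14)), 2.5, 4)
  expect_equal(f$a_med_um2, 12)
  expect_equal(nrow(f$kept), 3L)

  # debris below a_min is removed before the median is taken
  f2 <- filter_nuclei(nucleus_records(c(0.5, 10, 12, 14)), 2.5, 4)
  expect_equal(f2$a_med_um2, 12)
  expect_equal(nrow(f2$kept), 3L)

  # oversized objects above a_max_factor * A_med are excluded, not split
  f3 <- filter_nuclei(nucleus_records(c(10, 12, 14, 100)), 2.5, 4)
  expect_equal(f3$a_med_um2, 13)
  expect_equal(nrow(f3$kept), 3L)
  expect_false(100 %in% f3$kept$area_um2)
})

test_that("out-of-band records never enter the filter", {
  recs <- dplyr::bind_rows(
    nucleus_records(c(10, 12)),
    nucleus_records(c(11, 13), in_band = FALSE)
  )
  f <- filter_nuclei(recs, 2.5, 4)
  expect_equal(nrow(f$kept), 2L)
})

test_that("filtering with no survivor raises an undefined-median error", {
  expect_error(filter_nuclei(nucleus_records(c(0.5, 1)), 2.5, 4), "median")
  expect_error(filter_nuclei(nucleus_records(numeric()), 2.5, 4), "median")
})

test_that("kept count is monotone in the thresholds", {
  set.seed(42)
  areas <- c(runif(30, 5, 20), runif(5, 0.1, 2), runif(3, 60, 90))
  recs <- nucleus_records(areas)
  kept_by_amin <- vapply(
    c(0, 1.25, 2.5, 3.75, 5),
    function(am) nrow(filter_nuclei(recs, am, 4)$kept), numeric(1)
  )
  expect_true(all(diff(kept_by_amin) <= 0))
  kept_by_fac <- vapply(
    c(3.25, 3.75, 4.25, 4.75),
    function(fx) nrow(filter_nuclei(recs, 2.5, fx)$kept), numeric(1)
  )
  expect_true(all(diff(kept_by_fac) >= 0))
})

test_that("density arithmetic is count over length", {
  expect_equal(compute_density(50, 100)$density_per_um, 0.5)
  expect_equal(compute_density(0, 123)$density_per_um, 0)
  expect_error(compute_density(10, 0), "band_length")
  expect_error(compute_density(-1, 10), "n_nuclei")
})

test_that("sensitivity is negligible on clean phantoms and zero on one point", {
  p <- tissue_phantom_params(centerline_kind = "arc", seed = 6)
  ph <- generate_tissue_phantom(p)
  sr <- run_sensitivity(ph$micrograph)
  expect_equal(nrow(tidy(sr)), 20L) # default 5 x 4 grid
  expect_lte(sr$max_rel_deviation, 0.02)

  sr1 <- run_sensitivity(ph$micrograph, a_min_grid = 2.5, factor_grid = 4.25)
  expect_equal(sr1$max_rel_deviation, 0)
  expect_error(run_sensitivity(ph$micrograph, a_min_grid = numeric()), "grids")
  expect_error(run_sensitivity(ph$micrograph, a_min_grid = 7), "0, 5")
})

test_that("with debris present the density is non-increasing in a_min", {
  p <- tissue_phantom_params(seed = 13, debris_count = 12)
  ph <- generate_tissue_phantom(p)
  sr <- run_sensitivity(ph$micrograph)
  g <- tidy(sr)
  for (fx in unique(g$a_max_factor)) {
    d <- g$density_per_um[g$a_max_factor == fx][order(g$a_min_um2[g$a_max_factor == fx])]
    expect_true(all(diff(d) <= 1e-12))
  }
  # debris must actually register at a_min = 0 for the sweep to mean anything
  expect_gt(
    max(g$density_per_um[g$a_min_um2 == 0]),
    min(g$density_per_um[g$a_min_um2 == 5])
  )
})

test_that("manual comparison statistics follow their definitions", {
  same <- compare_with_manual(c(10, 12, 15), c(10, 12, 15))
  expect_equal(same$mean_signed_diff, 0)
  expect_equal(same$mean_abs_diff, 0)
  expect_equal(same$concordance, 1)

  mixed <- compare_with_manual(c(10, 12), c(11, 11))
  expect_equal(mixed$mean_signed_diff, 0)
  expect_equal(mixed$mean_abs_diff, 1)

  single <- compare_with_manual(10, 11)
  expect_equal(single$mean_signed_diff, -1)
  expect_true(is.na(single$concordance))

  expect_error(compare_with_manual(1:3, 1:2), "length")
})
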