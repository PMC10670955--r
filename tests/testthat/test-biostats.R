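# qPCR, urine and DGE statistics.

test_that("negative delta-Ct averages duplicates and is antisymmetric", {
  expect_equal(negative_delta_ct(25, 20), -5)
  expect_equal(negative_delta_ct(c(24, 26), c(19, 21)), -5)
  expect_equal(negative_delta_ct(c(20, 22), c(20, 22)), 0)
  expect_equal(
    negative_delta_ct(c(24, 26), c(19, 21)),
    -negative_delta_ct(c(19, 21), c(24, 26))
  )
  expect_error(negative_delta_ct(numeric(), 20), "non-empty")
})

test_that("potassium per creatinine follows its definition", {
  expect_equal(k_per_creatinine(50, 2), 25)
  expect_equal(k_per_creatinine(0, 2), 0)
  expect_error(k_per_creatinine(50, 0), "creatinine")
  expect_error(k_per_creatinine(-1, 2), "non-negative")
})

test_that("normality routing picks the t test for normal-looking samples", {
  set.seed(101)
  a <- rnorm(30)
  b <- rnorm(30)
  fit <- shapiro_route_test(a, b)
  expect_equal(fit$test_name, "t_unpaired")
  expect_true(fit$shapiro_p_a >= 0.05 && fit$shapiro_p_b >= 0.05)
  # pooled-variance t, not Welch
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(fit$p.value, ref$p.value)
})

test_that("normality routing picks the rank test for skewed samples", {
  set.seed(102)
  a <- exp(rnorm(30, sd = 1.5)) # heavily log-skewed
  b <- rnorm(30, 5)
  fit <- shapiro_route_test(a, b)
  expect_match(fit$test_name, "mann_whitney")
  expect_lt(fit$shapiro_p_a, 0.05)
  # routing is deterministic: same inputs, same route
  expect_identical(fit$test_name, shapiro_route_test(a, b)$test_name)
})

test_that("groups too small for normality testing are rejected with advice", {
  expect_error(shapiro_route_test(c(1, 2), c(1, 2, 3)), "n >= 3")
})

test_that("deregulated sets follow the adjusted-p threshold and sign rules", {
  tab <- tibble::tibble(
    gene = c("a", "b", "c", "d", "e", "a", "b", "f"),
    contrast = c(rep("F", 5), rep("M", 3)),
    log2fc = c(2, -1, 0.5, 0, -2, 1.5, -0.3, 0),
    p_adj = c(0.01, 0.04, 0.2, 0.03, 0.001, 0.02, 0.01, 0.04)
  )
  fs <- filter_deregulated(tab, 0.05)
  expect_equal(fs$sets$F$up, "a")
  expect_equal(sort(fs$sets$F$down), c("b", "e"))
  expect_equal(fs$sets$F$zero_fc, "d") # zero log2fc in neither set
  expect_equal(fs$sets$M$up, "a")
  expect_equal(fs$sets$M$down, "b")
  # |up| + |down| equals significant rows with nonzero fold change
  cnt <- tidy(fs)
  sig_nonzero <- with(tab, tapply(p_adj < 0.05 & log2fc != 0, contrast, sum))
  expect_equal(cnt$n_deregulated, as.integer(sig_nonzero[cnt$contrast]),
    ignore_attr = TRUE
  )
  # set arithmetic across the two contrasts
  expect_equal(sort(fs$shared), c("a", "b"))
  expect_equal(unname(fs$unique_counts), c(1L, 0L))
})

test_that("two 6-gene contrasts sharing 2 genes leave 4 unique per contrast", {
  tab <- tibble::tibble(
    gene = c(sprintf("g%d", 1:6), sprintf("g%d", c(1, 2, 7, 8, 9, 10))),
    contrast = rep(c("F", "M"), each = 6),
    log2fc = rep(c(1, 1, 1, -1, -1, -1), 2),
    p_adj = 0.01
  )
  fs <- filter_deregulated(tab)
  expect_equal(length(fs$shared), 2L)
  expect_equal(unname(fs$unique_counts), c(4L, 4L))
})

test_that("degenerate DGE inputs are handled", {
  empty <- tibble::tibble(
    gene = character(), contrast = character(),
    log2fc = double(), p_adj = double()
  )
  fs <- filter_deregulated(empty)
  expect_equal(nrow(tidy(fs)), 0L)
  expect_error(
    filter_deregulated(tibble::tibble(gene = "a", log2fc = 1, p_adj = 0.5)),
    "missing required column"
  )
  expect_error(
    filter_deregulated(tibble::tibble(
      gene = c("a", "a"), contrast = c("F", "F"), log2fc = 1:2, p_adj = 0.5
    )),
    "unique"
  )
})
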