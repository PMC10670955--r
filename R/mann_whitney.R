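# Exact small-sample Mann-Whitney U test. At the group sizes typical of
# animal experiments (2-6 per group) the asymptotic test is unreliable, so
# the two-sided p-value is obtained by full enumeration of the permutation
# distribution of the rank sum over all C(n1+n2, n1) group assignments of
# the pooled mid-ranks. This is exact also under ties. Above a combined
# sample size of `exact_limit` the usual tie- and continuity-corrected
# normal approximation takes over.

#' Exact / approximate two-sided Mann-Whitney U test
#'
#' For `n1 + n2 <= exact_limit` the two-sided p-value is
#' `P(|W - E W| >= |w_obs - E W|)` under the exact permutation distribution
#' of the rank sum of the first group (mid-ranks under ties); the
#' distribution is symmetric about `n1 (n1 + n2 + 1) / 2`, so under complete
#' separation the minimal attainable p is `2 / choose(n1 + n2, n1)`. For
#' larger samples the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param exact_limit Combined sample size up to which the exact enumeration
#'   is used (default 12, covering groups of up to 6 vs 6).
#' @return An object of class `mw_test`: `statistic` (the U statistic of
#'   `x`), `p.value`, `method` (`"mann_whitney_exact"` or
#'   `"mann_whitney_approx"`), `n1`, `n2`.
#' @export
mw_u_test <- function(x, y, exact_limit = 12L) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    abort("each group needs at least 2 observations.")
  }
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported.")
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  r <- rank(c(x, y)) # mid-ranks under ties
  w_obs <- sum(r[seq_len(n1)])
  u_obs <- w_obs - n1 * (n1 + 1) / 2
  if (n <= exact_limit) {
    mu <- n1 * (n + 1) / 2
    combs <- combn(n, n1)
    ws <- colSums(matrix(r[combs], nrow = n1))
    p <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
    method <- "mann_whitney_exact"
  } else {
    mu_u <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu_u - sign(u_obs - mu_u) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "mann_whitney_approx"
  }
  structure(
    list(
      statistic = u_obs, p.value = p, method = method,
      n1 = n1, n2 = n2
    ),
    class = "mw_test"
  )
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney U test (%s): U = %g, n = %d/%d, two-sided p = %.4g\n",
    sub("mann_whitney_", "", x$method), x$statistic, x$n1, x$n2, x$p.value
  ))
  invisible(x)
}

#' @rdname mw_u_test
#' @param x An `mw_test` object.
#' @param ... Unused.
#' @method tidy mw_test
#' @export
tidy.mw_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, p.value = x$p.value,
    method = x$method, n1 = x$n1, n2 = x$n2
  )
}
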