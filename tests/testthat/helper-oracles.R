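# Independent oracles used by the tests. These deliberately avoid the code
# paths of the package implementation: the component counter is a plain
# breadth-first flood fill, and the permutation oracle enumerates group
# labelings of the raw values and counts pairwise wins, not rank sums.

# Brute-force 8-connected component count of a logical matrix.
bf_count_components <- function(bw) {
  H <- nrow(bw)
  W <- ncol(bw)
  seen <- matrix(FALSE, H, W)
  count <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (bw[i, j] && !seen[i, j]) {
        count <- count + 1L
        queue <- matrix(c(i, j), ncol = 2)
        seen[i, j] <- TRUE
        while (nrow(queue) > 0) {
          cur <- queue[1, , drop = FALSE]
          queue <- queue[-1, , drop = FALSE]
          for (k in seq_len(nrow(offs))) {
            r <- cur[1] + offs$dr[k]
            c <- cur[2] + offs$dc[k]
            if (r >= 1 && r <= H && c >= 1 && c <= W && bw[r, c] && !seen[r, c]) {
              seen[r, c] <- TRUE
              queue <- rbind(queue, c(r, c))
            }
          }
        }
      }
    }
  }
  count
}

# Exhaustive two-sided permutation p-value of the Mann-Whitney U statistic,
# computed from pairwise wins (x_i > y_j counts 1, ties 0.5), enumerating
# all C(n1 + n2, n1) labelings of the pooled values.
bf_mw_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_stat(x, y)
  mu <- n1 * n2 / 2
  combs <- combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Rectangular band mask fixture: `len_px` x `thick_px` foreground centred
# in a padded canvas.
rect_band_mask <- function(len_px, thick_px, pad = 20L) {
  m <- matrix(FALSE, thick_px + 2L * pad, len_px + 2L * pad)
  m[pad + seq_len(thick_px), pad + seq_len(len_px)] <- TRUE
  m
}

# Half-annulus band mask: centerline radius `r_px`, thickness `thick_px`,
# opening downwards.
half_annulus_mask <- function(r_px, thick_px, pad = 20L) {
  sz <- 2L * (r_px + thick_px + pad)
  cy <- sz / 2 - r_px / 2
  cx <- sz / 2
  rr <- row(matrix(0, sz, sz))
  cc <- col(matrix(0, sz, sz))
  d <- sqrt((rr - cy)^2 + (cc - cx)^2)
  below <- rr >= cy
  d >= r_px - thick_px / 2 & d <= r_px + thick_px / 2 & below
}
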