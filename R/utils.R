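# Internal helpers shared across modules.

# scalar checks -------------------------------------------------------------

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) {
    abort(sprintf("`%s` must be > %g.", name, min))
  }
  if (!strict_min && x < min) {
    abort(sprintf("`%s` must be >= %g.", name, min))
  }
  if (x > max) {
    abort(sprintf("`%s` must be <= %g.", name, max))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
    abort(sprintf("`%s` must be a single integer.", name))
  }
  if (x < min) abort(sprintf("`%s` must be >= %d.", name, min))
  invisible(as.integer(x))
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      name, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# shift a logical matrix by (dr, dc), padding with FALSE; used by the thinner
shift_lgl <- function(m, dr, dc) {
  H <- nrow(m)
  W <- ncol(m)
  out <- matrix(FALSE, H, W)
  rs <- (1 + max(0, -dr)):(H - max(0, dr))
  cs <- (1 + max(0, -dc)):(W - max(0, dc))
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

# normalize a grey-level matrix to [0, 1] for EBImage ops
norm_grey <- function(m, bit_depth) {
  m / (2^bit_depth - 1)
}

# centroids + pixel areas from a labelled integer matrix (0 = background)
label_stats <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx)) {
    return(tibble(
      label = integer(), n_px = integer(),
      centroid_row = double(), centroid_col = double()
    ))
  }
  lv <- lab[idx]
  rr <- ((idx - 1L) %% nrow(lab)) + 1L
  cc <- ((idx - 1L) %/% nrow(lab)) + 1L
  n <- tapply(rep(1L, length(lv)), lv, sum)
  mr <- tapply(rr, lv, mean)
  mc <- tapply(cc, lv, mean)
  tibble(
    label = as.integer(names(n)),
    n_px = as.integer(n),
    centroid_row = as.numeric(mr),
    centroid_col = as.numeric(mc)
  )
}
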