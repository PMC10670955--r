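# Small-sample statistics and normalizations used around the imaging and
# electrophysiology stages: qPCR negative delta-Ct against an endogenous
# control, urinary potassium per creatinine, normality-routed two-group
# testing, and adjusted-p filtered deregulated-gene set logic.

#' Negative delta-Ct of a qPCR sample
#'
#' Duplicate wells are averaged per gene; the result is
#' `-(mean(target Ct) - mean(control Ct))`, so a *higher* value means more
#' transcript relative to the endogenous control (e.g. L32).
#'
#' @param target_cts,control_cts Non-empty numeric vectors of cycle
#'   thresholds (duplicates or more).
#' @return A single number.
#' @export
negative_delta_ct <- function(target_cts, control_cts) {
  if (!length(target_cts) || !length(control_cts)) {
    abort("both Ct vectors must be non-empty.")
  }
  if (anyNA(target_cts) || anyNA(control_cts)) abort("Ct values must not be missing.")
  -(mean(target_cts) - mean(control_cts))
}

#' Per-sample negative delta-Ct from a duplicate-well qPCR table
#'
#' @param qpcr Tibble as produced by [simulate_qpcr_table()] (columns
#'   `sample_id`, `group`, `target_ct_1`, `target_ct_2`, `control_ct_1`,
#'   `control_ct_2`).
#' @return The table with `neg_delta_ct` added.
#' @export
qpcr_neg_delta_ct <- function(qpcr) {
  check_columns(
    qpcr,
    c("target_ct_1", "target_ct_2", "control_ct_1", "control_ct_2"),
    "qpcr"
  )
  qpcr |>
    as_tibble() |>
    dplyr::mutate(
      neg_delta_ct = -((.data$target_ct_1 + .data$target_ct_2) / 2 -
        (.data$control_ct_1 + .data$control_ct_2) / 2)
    )
}

#' Urinary potassium normalized to creatinine
#'
#' @param k_mmol_per_l Urinary K+ concentration (mmol/L, >= 0).
#' @param creatinine_g_per_l Urinary creatinine (g/L, > 0).
#' @return K+ per creatinine in mmol/g.
#' @export
k_per_creatinine <- function(k_mmol_per_l, creatinine_g_per_l) {
  if (any(!is.finite(k_mmol_per_l)) || any(k_mmol_per_l < 0)) {
    abort("`k_mmol_per_l` must be non-negative.")
  }
  if (any(!is.finite(creatinine_g_per_l)) || any(creatinine_g_per_l <= 0)) {
    abort("`creatinine_g_per_l` must be > 0.")
  }
  k_mmol_per_l / creatinine_g_per_l
}

#' Normality-routed two-group comparison
#'
#' Shapiro-Wilk normality test per group at level `alpha`; when both groups
#' are compatible with normality the groups are compared by an unpaired
#' two-tailed pooled-variance t test, otherwise by the (exact, small-sample)
#' Mann-Whitney U test of [mw_u_test()]. Routing is deterministic given the
#' data and `alpha`.
#'
#' @param group_a,group_b Numeric vectors, each n >= 3 (the Shapiro-Wilk
#'   test needs 3 observations; pick a test directly for smaller groups).
#' @param alpha Routing level for the normality tests (default 0.05).
#' @return An object of class `route_test`: `test_name` (one of
#'   `"t_unpaired"`, `"mann_whitney_exact"`, `"mann_whitney_approx"`),
#'   `statistic`, `p.value`, `shapiro_p_a`, `shapiro_p_b`, `n1`, `n2`.
#' @export
shapiro_route_test <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) < 3L || length(group_b) < 3L) {
    abort(paste(
      "each group needs n >= 3 for the Shapiro-Wilk routing;",
      "for smaller groups call mw_u_test() or t.test() directly."
    ))
  }
  check_number(alpha, "alpha", 0, max = 1, strict_min = TRUE)
  sw_a <- shapiro.test(group_a)$p.value
  sw_b <- shapiro.test(group_b)$p.value
  if (sw_a >= alpha && sw_b >= alpha) {
    fit <- t.test(group_a, group_b, var.equal = TRUE)
    out <- list(
      test_name = "t_unpaired",
      statistic = unname(fit$statistic), p.value = fit$p.value
    )
  } else {
    fit <- mw_u_test(group_a, group_b)
    out <- list(
      test_name = fit$method,
      statistic = fit$statistic, p.value = fit$p.value
    )
  }
  structure(
    c(out, list(
      shapiro_p_a = sw_a, shapiro_p_b = sw_b,
      n1 = length(group_a), n2 = length(group_b)
    )),
    class = "route_test"
  )
}

#' @export
print.route_test <- function(x, ...) {
  cat(sprintf(
    "Two-group comparison routed to %s (Shapiro p: %.3g / %.3g)\n  statistic = %g, two-sided p = %.4g\n",
    x$test_name, x$shapiro_p_a, x$shapiro_p_b, x$statistic, x$p.value
  ))
  invisible(x)
}

#' @rdname shapiro_route_test
#' @param x A `route_test` object.
#' @param ... Unused.
#' @method tidy route_test
#' @export
tidy.route_test <- function(x, ...) {
  tibble(
    test_name = x$test_name, statistic = x$statistic, p.value = x$p.value,
    shapiro_p_a = x$shapiro_p_a, shapiro_p_b = x$shapiro_p_b,
    n1 = x$n1, n2 = x$n2
  )
}

#' Deregulated-gene sets from a differential-expression table
#'
#' A gene is deregulated in a contrast when `p_adj < threshold`; the up set
#' additionally requires `log2fc > 0` and the down set `log2fc < 0`. Genes
#' with `log2fc == 0` belong to neither set and are counted separately.
#' With exactly two contrasts the shared and per-contrast unique gene
#' counts are reported.
#'
#' @param table Data frame with columns `gene`, `contrast`, `log2fc`,
#'   `p_adj`.
#' @param threshold Adjusted-p cutoff (default 0.05).
#' @return An object of class `dge_sets`: per-contrast lists `up` / `down`
#'   of gene ids, a `counts` tibble, and for two contrasts `shared` genes
#'   and per-contrast `unique` counts. `tidy()` returns per-contrast
#'   counts; `glance()` a one-row summary.
#' @export
filter_deregulated <- function(table, threshold = 0.05) {
  check_columns(table, c("gene", "contrast", "log2fc", "p_adj"), "table")
  check_number(threshold, "threshold", 0, max = 1, strict_min = TRUE)
  tab <- as_tibble(table)
  if (anyNA(tab$p_adj) || any(tab$p_adj < 0 | tab$p_adj > 1)) {
    abort("`p_adj` must lie in [0, 1].")
  }
  if (anyNA(tab$gene) || anyNA(tab$contrast)) {
    abort("`gene` and `contrast` must not be missing.")
  }
  if (anyDuplicated(tab[c("gene", "contrast")])) {
    abort("(gene, contrast) pairs must be unique.")
  }
  contrasts <- unique(tab$contrast)
  sets <- lapply(stats::setNames(contrasts, contrasts), function(ct) {
    d <- tab[tab$contrast == ct & tab$p_adj < threshold, ]
    list(
      up = sort(d$gene[d$log2fc > 0]),
      down = sort(d$gene[d$log2fc < 0]),
      zero_fc = sort(d$gene[d$log2fc == 0])
    )
  })
  counts <- purrr::imap_dfr(sets, function(s, ct) {
    tibble(
      contrast = ct,
      n_up = length(s$up), n_down = length(s$down),
      n_zero_fc = length(s$zero_fc),
      n_deregulated = length(s$up) + length(s$down)
    )
  })
  out <- list(sets = sets, counts = counts, threshold = threshold)
  if (length(contrasts) == 2L) {
    g1 <- c(sets[[1]]$up, sets[[1]]$down)
    g2 <- c(sets[[2]]$up, sets[[2]]$down)
    out$shared <- sort(intersect(g1, g2))
    out$unique_counts <- stats::setNames(
      c(length(setdiff(g1, g2)), length(setdiff(g2, g1))),
      contrasts
    )
  }
  structure(out, class = "dge_sets")
}

#' @export
print.dge_sets <- function(x, ...) {
  cat(sprintf("<dge_sets> p_adj < %g\n", x$threshold))
  print(x$counts)
  if (!is.null(x$shared)) {
    cat(sprintf(
      "shared: %d; unique: %s\n",
      length(x$shared),
      paste(sprintf("%s = %d", names(x$unique_counts), x$unique_counts),
        collapse = ", "
      )
    ))
  }
  invisible(x)
}

#' @rdname filter_deregulated
#' @param x A `dge_sets` object.
#' @param ... Unused.
#' @method tidy dge_sets
#' @export
tidy.dge_sets <- function(x, ...) x$counts

#' @rdname filter_deregulated
#' @method glance dge_sets
#' @export
glance.dge_sets <- function(x, ...) {
  out <- tibble(
    threshold = x$threshold,
    n_contrasts = nrow(x$counts),
    n_deregulated_total = sum(x$counts$n_deregulated)
  )
  if (!is.null(x$shared)) {
    out$n_shared <- length(x$shared)
    out$n_unique_1 <- unname(x$unique_counts[1])
    out$n_unique_2 <- unname(x$unique_counts[2])
  }
  out
}
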