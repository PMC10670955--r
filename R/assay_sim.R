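# Simulated assay tables with planted truth: duplicate-well qPCR Ct tables,
# paired urinary potassium / creatinine measurements, and differential
# expression tables in which exactly the planted genes are significant.

#' Simulate a duplicate-well qPCR Ct table
#'
#' Two groups, one target gene and one endogenous control measured in
#' duplicate per sample. `group_effect` is added to the *target* Ct of the
#' second group only, so a negative value means higher expression there
#' (fewer cycles to threshold). With `group_effect = 0` and `noise_sd = 0`
#' both groups have identical negative delta-Ct.
#'
#' @param n_per_group Samples per group (>= 1).
#' @param group_effect Ct shift added to the second group's target wells.
#' @param groups Two group labels.
#' @param target_base_ct,control_base_ct Baseline cycle thresholds.
#' @param noise_sd Per-well Gaussian Ct noise SD.
#' @param seed Integer seed.
#' @return A tibble with columns `sample_id`, `group`, `target_ct_1`,
#'   `target_ct_2`, `control_ct_1`, `control_ct_2`.
#' @export
simulate_qpcr_table <- function(n_per_group = 4L, group_effect = -1,
                                groups = c("F", "M"),
                                target_base_ct = 27, control_base_ct = 20,
                                noise_sd = 0.25, seed = 1L) {
  n_per_group <- check_count(n_per_group, "n_per_group", 1L)
  if (length(groups) != 2L) abort("`groups` must contain exactly two labels.")
  with_seed(seed, {
    grp <- rep(groups, each = n_per_group)
    shift <- ifelse(grp == groups[2], group_effect, 0)
    n <- length(grp)
    tibble(
      sample_id = sprintf("s%02d", seq_len(n)),
      group = grp,
      target_ct_1 = target_base_ct + shift + rnorm(n, 0, noise_sd),
      target_ct_2 = target_base_ct + shift + rnorm(n, 0, noise_sd),
      control_ct_1 = control_base_ct + rnorm(n, 0, noise_sd),
      control_ct_2 = control_base_ct + rnorm(n, 0, noise_sd)
    )
  })
}

#' Simulate paired urinary potassium / creatinine measurements
#'
#' @param n_per_group Samples per group (>= 1).
#' @param group_effect Multiplier applied to the second group's K+ level
#'   (e.g. 1.5 means 50% higher potassium at equal creatinine).
#' @param groups Two group labels.
#' @param k_base_mmol_per_l Baseline urinary potassium (mmol/L).
#' @param creatinine_base_g_per_l Baseline urinary creatinine (g/L).
#' @param noise_cv Coefficient of variation of both analytes.
#' @param seed Integer seed.
#' @return A tibble with `sample_id`, `group`, `k_mmol_per_l`,
#'   `creatinine_g_per_l`.
#' @export
simulate_urine_table <- function(n_per_group = 5L, group_effect = 1.5,
                                 groups = c("F", "M"),
                                 k_base_mmol_per_l = 80,
                                 creatinine_base_g_per_l = 1.5,
                                 noise_cv = 0.15, seed = 1L) {
  n_per_group <- check_count(n_per_group, "n_per_group", 1L)
  if (length(groups) != 2L) abort("`groups` must contain exactly two labels.")
  with_seed(seed, {
    grp <- rep(groups, each = n_per_group)
    mult <- ifelse(grp == groups[2], group_effect, 1)
    n <- length(grp)
    tibble(
      sample_id = sprintf("u%02d", seq_len(n)),
      group = grp,
      k_mmol_per_l = pmax(k_base_mmol_per_l * mult * (1 + rnorm(n, 0, noise_cv)), 0),
      creatinine_g_per_l = pmax(
        creatinine_base_g_per_l * (1 + rnorm(n, 0, noise_cv)), 0.05
      )
    )
  })
}

#' Simulate a differential-expression table with planted deregulated genes
#'
#' Every gene appears once per contrast with a log2 fold change and an
#' adjusted p-value. Exactly `n_up[i] + n_down[i]` genes are planted
#' significant (`p_adj < 0.05`) in contrast `i` with the stated sign pattern;
#' all other rows have `p_adj >= 0.05`. `n_shared` planted genes are common
#' to both contrasts (same direction), so the per-contrast unique counts are
#' exact set arithmetic on known names.
#'
#' @param n_genes Total genes per contrast.
#' @param contrasts Character vector of contrast names (1 or 2).
#' @param n_up,n_down Planted up-/down-regulated gene counts per contrast
#'   (recycled to `length(contrasts)`).
#' @param n_shared For two contrasts, how many planted genes are shared.
#' @param log2fc_effect Magnitude of the planted log2 fold change.
#' @param noise_sd SD of the null log2 fold changes.
#' @param seed Integer seed.
#' @return A tibble with `gene`, `contrast`, `log2fc`, `p_adj`, plus an
#'   attribute `"planted"` (tibble of gene, contrast, direction).
#' @export
simulate_dge_table <- function(n_genes = 200L, contrasts = c("F", "M"),
                               n_up = c(3L, 5L), n_down = c(3L, 1L),
                               n_shared = 2L, log2fc_effect = 2,
                               noise_sd = 0.2, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", 10L)
  nc <- length(contrasts)
  if (!nc %in% 1:2) abort("`contrasts` must name one or two contrasts.")
  n_up <- rep_len(as.integer(n_up), nc)
  n_down <- rep_len(as.integer(n_down), nc)
  if (any(n_up + n_down > n_genes)) abort("planted genes exceed `n_genes`.")
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    planted <- list()
    if (nc == 2L) {
      shared_up <- min(n_up[1], n_up[2], n_shared)
      shared_down <- min(n_shared - shared_up, n_down[1], n_down[2])
      pool <- genes
      take <- function(k) {
        if (k == 0L) return(character())
        out <- pool[seq_len(k)]
        pool <<- pool[-seq_len(k)]
        out
      }
      su <- take(shared_up)
      sd_ <- take(shared_down)
      for (i in 1:2) {
        up_i <- c(su, take(n_up[i] - shared_up))
        down_i <- c(sd_, take(n_down[i] - shared_down))
        planted[[i]] <- tibble(
          gene = c(up_i, down_i),
          contrast = contrasts[i],
          direction = rep(c("up", "down"), c(length(up_i), length(down_i)))
        )
      }
    } else {
      planted[[1]] <- tibble(
        gene = genes[seq_len(n_up[1] + n_down[1])],
        contrast = contrasts[1],
        direction = rep(c("up", "down"), c(n_up[1], n_down[1]))
      )
    }
    planted <- dplyr::bind_rows(planted)
    tab <- tidyr::expand_grid(contrast = contrasts, gene = genes) |>
      dplyr::mutate(
        log2fc = rnorm(dplyr::n(), 0, noise_sd),
        p_adj = runif(dplyr::n(), 0.051, 1)
      ) |>
      dplyr::left_join(planted, by = c("gene", "contrast")) |>
      dplyr::mutate(
        log2fc = dplyr::case_when(
          .data$direction == "up" ~ log2fc_effect + abs(.data$log2fc),
          .data$direction == "down" ~ -log2fc_effect - abs(.data$log2fc),
          TRUE ~ .data$log2fc
        ),
        p_adj = ifelse(is.na(.data$direction), .data$p_adj,
          runif(dplyr::n(), 1e-6, 0.049)
        )
      ) |>
      dplyr::select("gene", "contrast", "log2fc", "p_adj")
    attr(tab, "planted") <- planted
    tab
  })
}

#' Generate an assay table of a given kind
#'
#' Thin dispatcher over [simulate_qpcr_table()], [simulate_urine_table()] and
#' [simulate_dge_table()]; convenient when the table kind is configuration
#' data rather than code.
#'
#' @param kind `"qpcr"`, `"urine"` or `"dge"`.
#' @param ... Passed to the kind-specific simulator.
#' @return A tibble (see the kind-specific simulator).
#' @export
generate_assay_tables <- function(kind, ...) {
  if (length(kind) != 1L || !kind %in% c("qpcr", "urine", "dge")) {
    abort('`kind` must be one of "qpcr", "urine", "dge".')
  }
  switch(kind,
    qpcr = simulate_qpcr_table(...),
    urine = simulate_urine_table(...),
    dge = simulate_dge_table(...)
  )
}
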