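# uroquant

Quantification toolkit for ex vivo studies of the bladder blood–urine
barrier. Experiments of this kind combine fluorescence micrographs of the
urothelium, Ussing-chamber electrophysiology, qPCR, urine chemistry and
differential-expression tables, and the quantitative steps between raw
readouts and group statistics are usually one-off scripts. `uroquant`
implements those steps as tested, reusable R functions for researchers who
need the same numbers to come out of the same data twice:

* **Urothelial nuclear density (hyperplasia).** From a two-channel
  micrograph (band marker such as Cytokeratin 7, plus DAPI): segment the
  urothelial band (Gaussian smoothing → Otsu threshold → closing → largest
  component), detect nuclei and split touching ones (watershed on the
  distance transform), filter them by area
  (A<sub>min</sub> ≤ A ≤ f·A<sub>med</sub>), measure the band's centerline
  length by medial-axis skeletonization, and report the density
  ρ = n / L in nuclei/µm — together with a sensitivity analysis over the
  full (A<sub>min</sub>, f) threshold grid and an automated-vs-manual
  count comparison.
* **TEER processing.** Ohm's-law resistance, per-chamber blank
  subtraction, scaling by the exposed window area
  (π·(d/2)², 0.0314 cm² for the standard 2 mm aperture), and
  normalization of each chamber to its own 30 min equilibration anchor;
  group comparisons at standard time points.
* **Exact small-sample statistics.** A Mann–Whitney U test computed by
  full enumeration of the permutation distribution for combined n ≤ 12
  (exact under ties; minimal attainable two-sided p is
  2/C(n₁+n₂, n₁) under complete separation), Shapiro–Wilk-routed
  two-group testing (pooled-variance t vs exact rank test), qPCR −ΔCt,
  urinary K⁺/creatinine, and p<sub>adj</sub>-filtered
  deregulated-gene set logic with shared/unique counts across contrasts.
* **ROI fluorescence densitometry.** Mean intensity per polygonal ROI,
  fold change against a negative control, and summed grey values
  normalized per 10,000 µm².
* **Synthetic data with exact ground truth.** Tissue phantoms whose
  centerline length and in-band nucleus count are exact by construction,
  simulated chamber traces, and assay tables with planted effects — every
  downstream stage is testable without a microscope or an animal.

## Worked example

Generate a calibrated phantom and recover its density:

```r
library(uroquant)

p  <- tissue_phantom_params(centerline_kind = "sinusoid", gaussian_noise_sd = 8,
                            debris_count = 8, clutter_count = 4, seed = 42)
ph <- generate_tissue_phantom(p)
ph$truth
#> <phantom_truth> length 134.82 um, 40 nuclei, true density 0.2967 /um

quantify_density(ph$micrograph)
#> # A tibble: 1 × 6
#>   id                      n_nuclei band_length_um density_per_um a_min_um2 a_max_factor
#>   <chr>                      <int>          <dbl>          <dbl>     <dbl>        <dbl>
#> 1 phantom-sinusoid-seed42       40           133.          0.300       2.5            4
```

All 40 planted nuclei are found despite noise, debris and clutter; the
estimated length (133.1 µm) is within 1.3% of the true 134.8 µm, and the
density lands within ~1% of the planted 0.2967 nuclei/µm. The
sensitivity analysis re-applies the area filter over the whole threshold
grid:

```r
glance(run_sensitivity(ph$micrograph))
#> # A tibble: 1 × 4
#>   id                      n_grid band_length_um max_rel_deviation
#> 1 phantom-sinusoid-seed42     20           133.             0.075
```

With debris planted, the loosest thresholds admit a few specks and the
density moves by 7.5% across the grid; on clean tissue the deviation stays
below 2% (that contrast is exactly what the analysis is for).

Process simulated chamber traces and compare groups with the exact test:

```r
pp <- ussing_sim_params(noise_cv = 0.05, seed = 1)
s  <- process_teer(generate_ussing_traces(pp, 4), pp$window_area_cm2)
s[s$time_min %in% c(30, 45), c("chamber_id", "time_min", "teer_ohm_cm2", "relative_pct")]
#>   chamber_id time_min teer_ohm_cm2 relative_pct
#> 1 ch01             30        172.         100
#> 2 ch01             45         65.2         37.9  # ~60% drop after the challenge
#> ...

mw_u_test(c(101, 99, 95, 97), c(80, 85, 83, 88))
#> Mann-Whitney U test (exact): U = 16, n = 4/4, two-sided p = 0.02857
```

The p-value 2/70 ≈ 0.0286 is the smallest a 4 vs 4 design can produce —
the exact enumeration makes that floor explicit instead of hiding it
behind an asymptotic approximation.

## Documentation

The methods vignette (`vignettes/uroquant-methods.Rmd`) describes the
models and their assumptions, the parameter defaults and why they were
chosen, what the phantom generator does and does not emulate, and the
numerical corrections inside the band-length estimator.
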