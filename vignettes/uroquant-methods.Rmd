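---
title: "Methods: quantifying the urothelial barrier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the urothelial barrier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uroquant)
```

`uroquant` packages the quantitative procedures that recur in ex vivo studies
of the bladder blood–urine barrier: estimating urothelial hyperplasia as a
nuclear density from two-channel micrographs, processing Ussing-chamber
resistance traces into normalized TEER time courses, ROI fluorescence
densitometry, and the small-sample statistics used to compare experimental
groups. This vignette explains each model, its assumptions, the tunable
parameters, and the numerical choices made where the design was genuinely
open.

## Nuclear density of the urothelial band

Hyperplasia is quantified as *nuclei per micrometre of urothelial length*.
The estimate has three parts.

**Band segmentation.** The band-marker channel (e.g. Cytokeratin 7) is
smoothed with a Gaussian kernel (`smoothing_sigma_um`, default 1 µm), then
thresholded with Otsu's global criterion. Morphological closing
(`closing_radius_um`, default 2 µm) bridges staining gaps, holes are filled,
and the largest 8-connected component is kept, so the mask is one connected
band by construction. This route is fully deterministic: two runs on the
same image always agree, which is what makes the threshold sensitivity
analysis below meaningful. An interactively trained pixel classifier could
be more faithful to difficult tissue, but it cannot be reproduced from a
written description, so determinism was preferred.

**Nucleus detection.** The nuclear channel (DAPI) is smoothed at
`smoothing_sigma_um = 0.25` µm, Otsu-thresholded, and touching nuclei are
split by a watershed on the Euclidean distance transform with seeds at
local maxima at least `min_seed_distance_um` (default 2 µm) apart. The
nuclear smoothing default is deliberately finer than the band's: the area
filter below sweeps its lower threshold from 0 µm² upwards, which is only
informative if sub-micrometre debris survives smoothing and is actually
detected; a kernel at the nucleus scale (0.5–1 µm) erases exactly the
objects the sweep is about. A nucleus belongs to the band iff its centroid
pixel lies inside the band mask — the simplest unambiguous rule, and stable
when nuclei at the band edge are partially occluded.

**Area filtering.** Detected in-band objects are filtered by area:
objects below `a_min_um2` (default 2.5 µm², swept over [0, 5]) are debris;
the median area $A_\mathrm{med}$ of the survivors then defines an upper
bound $A_\mathrm{max} = f \cdot A_\mathrm{med}$ with
`a_max_factor` $f$ (default 4, swept over (3, 5)). $A_\mathrm{med}$ is
computed *after* the in-band restriction and the lower cut, so debris
cannot bias it. Objects above $A_\mathrm{max}$ are excluded rather than
split into multiple counts: the bound exists to remove under-segmented
clumps and imaging artefacts, and inventing a count from an area ratio
would trade a visible failure for an invisible one (a split-count mode is
easy to add but is not the default for this reason).

**Band length.** The mask is thinned to its medial-axis skeleton
(Zhang–Suen two-subcycle thinning). Because the band is a ribbon, the
skeleton should be a single curve; side branches shorter than the band
thickness (estimated once as mask area / skeleton length) are pruned, and
the centerline is the longest geodesic through what remains. Two numerical
corrections matter here:

* *Staircase bias.* Summing raw chain-code steps (1 per orthogonal step,
  $\sqrt 2$ per diagonal) overestimates the length of oblique or curved
  digital curves by up to ~8%. The centerline is therefore measured as a
  polyline through every 5th path pixel (Euclidean chord lengths), a
  standard digital-length estimator whose bias on smooth curves is well
  below 1%.
* *End retraction.* The medial axis of a capped ribbon stops about half a
  band-thickness short of each flat end. Each end is extended by the
  distance-transform value at the terminal skeleton pixel minus one pixel —
  exactly the retraction for a flat cap, and zero for a one-pixel-wide
  line, so a 41-pixel straight line still measures exactly 40 pixel
  lengths.

On rectangle and half-circle fixtures these choices recover the analytic
centerline length to ~1.5% and ~0.4% respectively; the raw chain-code sum
fails the half-circle by more than 5%.

**Density and sensitivity.** The density is the filtered count divided by
the band length. `run_sensitivity()` re-applies the area filter over the
full threshold grid (segmentation is computed once — the thresholds are
filter parameters, not segmentation parameters) and reports
$(\max - \min)/\mathrm{median}$ of the density over the grid. On clean
phantoms with unimodal nucleus areas this deviation is at most 2%, i.e.
the exact threshold values barely matter; with planted debris the density
is monotone non-increasing in the lower threshold, as a pure removal
filter must be.

## The tissue phantom generator

Every image-analysis claim above is tested against synthetic phantoms with
*exact* ground truth. The generator renders a band of known centerline
(straight, sinusoid, or circular arc; length known in closed form, or by
adaptive quadrature for the sinusoid) and places
$n = \mathrm{round}(\rho \cdot L)$ nuclei at deterministic arc-length
spacing $L/n$ with seeded jitter bounded so every centroid stays inside the
band — the true density is exact by construction, not in expectation, which
is what makes a 10% recovery criterion sharp. Successive nuclei alternate
across the band's normal direction, as urothelial nuclei sit in layers
rather than single file; the stagger also keeps neighbours from merging
when the along-band spacing is shorter than a nucleus. Debris is rendered
as 1–2 pixel specks (< 1 µm² at the default 0.5 µm pixels) inside the band,
clutter as nucleus-sized ellipses outside it, and noise as additive
Gaussian grey-level noise clipped to the bit depth — the simplest model
that measurably degrades a global Otsu threshold.

Defaults emulate a 20× field: 128 × 128 µm at 0.5 µm/px, a 12 µm-thick
gently curved band, 2 × 1.5 µm nucleus semi-axes, 0.3 nuclei/µm. The
phantoms deliberately do **not** model optical point-spread, uneven
illumination, staining gradients, 3-D sectioning effects, or realistic
chromatin texture. Passing the recovery tests therefore shows the
*algorithmic* pipeline is correct and calibrated; it does not certify
performance on difficult real tissue, where segmentation quality is the
binding constraint.

## TEER processing

Chamber readings are converted to TEER as
$(R_\mathrm{total} - R_\mathrm{blank}) \times A$, with the total resistance
taken directly from the instrument or from Ohm's law ($\Delta V/\Delta I$,
mV over µA) when raw deflections are recorded. The blank (fluid-only)
resistance is per chamber, with an optional global fallback. The exposed
area of the standard 2 mm circular aperture is
$\pi(1\,\mathrm{mm})^2 = 0.0314\ \mathrm{cm}^2$.

Because absolute TEER varies strongly between preparations, series are
normalized to each chamber's own reading at the end of the 30 min
equilibration period (the *anchor*); the relative series passes through
100% there by definition. If no reading exists exactly at 30 min the
nearest earlier reading is used with a warning, since a silently shifted
anchor would change every downstream number. Group comparisons at the
standard evaluation times (45, 60, 90, 120, 180, 360 min) use the exact
Mann–Whitney test below.

The trace simulator reproduces the sampling schedule (every 10 min to
30 min, every 5 min to 60, every 10 min to 120, every 20 min to 360), a
linear drop during the 15 min challenge window ending at 45 min, and an
exponential recovery toward a plateau; with zero noise the processing
stage recovers the simulated baseline exactly, which pins down every
algebraic step of the chain.

## Small-sample statistics

**Exact Mann–Whitney U.** With 2–6 animals per group the asymptotic rank
test is unreliable, so for combined $n \le 12$ the two-sided p-value is
computed by full enumeration: all $\binom{n_1+n_2}{n_1}$ assignments of the
pooled mid-ranks, $p = P(|W - EW| \ge |w_\mathrm{obs} - EW|)$. The mid-rank
permutation distribution is symmetric about $n_1(n+1)/2$ (ranks map to
ranks under $r \mapsto n+1-r$), so under complete separation the minimal
attainable p is exactly $2/\binom{n_1+n_2}{n_1}$ — $2/70 \approx 0.0286$
at 4 vs 4 and $2/462 \approx 0.0043$ at 5 vs 6, the smallest p-values such
designs can produce. The cutoff of 12 covers all group sizes these
experiments use; above it, the tie- and continuity-corrected normal
approximation takes over. Enumeration is exact under ties as well, which
`wilcox.test` is not.

**Normality routing.** Two-group comparisons follow the convention of
testing each group with Shapiro–Wilk at $\alpha = 0.05$: both compatible
with normality → unpaired two-tailed *pooled-variance* t test ("Student's"
read literally, not Welch); otherwise → the exact Mann–Whitney test. When
exactly one group is non-normal the rank test is used — the conservative
reading. The routing needs $n \ge 3$ per group (Shapiro–Wilk's minimum);
smaller groups must pick a test explicitly rather than have one silently
chosen.

**Normalizations.** qPCR expression is $-\Delta C_t = -(\bar C_t^\mathrm{target}
- \bar C_t^\mathrm{control})$ with duplicate wells plainly averaged (no
outlier rule, since none can be justified from two replicates). Urinary
potassium is reported per creatinine (mmol/L over g/L, i.e. mmol/g) to
remove urine-concentration differences.

**Deregulated-gene sets.** A gene is deregulated in a contrast when
$p_\mathrm{adj} < 0.05$; sign of $\log_2$ fold change assigns it to the up
or down set, genes with exactly zero fold change to neither. For two
contrasts the shared and per-contrast unique counts are simple set
arithmetic. The module consumes adjusted p-values as given; no additional
correction is applied, because the table's $p_\mathrm{adj}$ already comes
from the upstream RNA-seq pipeline, which this package does not reimplement.

## ROI fluorescence quantification

ROIs are simple polygons in pixel coordinates; a pixel belongs to an ROI
iff its *centre* lies inside the polygon. This half-open convention is
deterministic and makes region totals additive when an ROI is split along
a line between pixel centres — the property the densitometry tests rely
on. Two summaries are provided: the arithmetic mean intensity (used for
antibody stainings, reported as fold change over a negative control with
the primary antibody omitted), and a densitometric total normalized to a
reference area of 10,000 µm² (used for lectin stainings). Instruments
disagree on whether a "gray value" is a mean or a total; the total is the
default because it is the quantity that is additive over regions, and a
mean mode is available behind a flag.

## Problem sizes and runtimes

The test suite and the acceptance script run entirely on generated data:
50 phantoms of 256 × 256 px for parameter recovery, three phantoms for the
20-point threshold-sensitivity grid, 64 × 64 px fixtures for the
brute-force counting oracle, and enumeration up to 6 vs 6 for the exact
test. These sizes were chosen so a full run completes in about a minute on
one core while still exercising all three centerline geometries and every
branch of the statistics.

## Known limitations

* Segmentation is global-threshold based; strongly uneven illumination or
  weak staining will need preprocessing the package does not provide.
* The band mask must be one connected ribbon; fragmented urothelium would
  need stitching before length estimation.
* Phantom realism is limited as described above; the noise level and
  clutter rates are plausible choices, not fits to real micrographs.
* The skeleton length measures the medial axis, not the apical surface;
  for a ribbon of near-constant thickness the two differ by well under the
  5% oracle tolerance, but strongly wedge-shaped tissue would bias it.
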