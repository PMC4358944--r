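---
title: "Methods: quantitative imaging of airway vitronectin expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative imaging of airway vitronectin expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitroquant)
```

## Scope and rationale

Vitronectin is a matrix glycoprotein expressed by serous cells of airway
submucosal glands, and its glandular expression is reduced in asthma and
COPD. Measuring that claim quantitatively requires a chain of image
analyses: background thresholding and voxel summation on dual-channel
confocal z-stacks, colocalization coefficients relating vitronectin to
cell-type markers, point-grid stereology on stained sections,
western-blot densitometry, and a nonparametric statistics layer that
compares subject groups. `vitroquant` implements that chain as reusable,
tested functions, together with a synthetic-data generator that produces
every input class with known ground truth — so the whole pipeline can be
validated without access to tissue images, which are not publicly
deposited for studies of this kind.

All randomness is seed-controlled and explicit; there is no hidden global
random state. Identical specs and seeds reproduce outputs bit for bit.

## Voxel quantification

The background rule sets the lower threshold of a channel at the second
standard deviation above the mean voxel intensity:
$t = \mu + 2\sigma$, computed over the whole channel (or a supplied ROI).
Three numerical choices are pinned because exact tests depend on them:

* $\sigma$ is the **population** SD (divide by $n$); at $10^6$ voxels the
  sample/population difference is negligible, but the convention must be
  fixed.
* "Above threshold" is **strict** (`>`), so a constant channel retains no
  voxels.
* The rule is applied per channel per stack; applying one threshold per
  imaging session would require session metadata the data model does not
  carry.

On pure Gaussian background this rule retains the one-sided tail beyond
2 SD, i.e. about 2.28% of voxels — a useful calibration check that the
acceptance script recomputes on a $10^6$-voxel stack.

`intensity_per_area()` divides the above-threshold intensity sum inside a
compartment mask by the compartment area in $\mu m^2$, the
per-visual-field normalization used for epithelial vitronectin signal.

## Colocalization coefficients

Pearson's coefficient over the voxels of the (optional) ROI,

$$R_p = \frac{\sum_i (G_i - G_A)(R_i - R_A)}
{\sqrt{\sum_i (G_i-G_A)^2 \, \sum_i (R_i-R_A)^2}},$$

is computed on **unthresholded** intensities: it is invariant to detector
gain and offset (asserted numerically to $10^{-12}$ in the tests), though
sensitive to noise. A constant channel makes $R_p$ undefined and raises
an explicit error rather than returning 0 or NaN.

Manders' coefficients use the standard M1/M2 convention: a green voxel's
intensity counts as colocalized when its red partner exceeds the red
threshold,

$$M_G = \frac{\sum G_{coloc}}{\sum_{G_i > t_G} G_i}, \qquad
  M_R = \frac{\sum R_{coloc}}{\sum_{R_i > t_R} R_i},$$

with denominators restricted to above-threshold voxels of the channel
itself. The thresholds default to the mean+2SD rule. By the package's
channel-role convention green carries the cell-type marker and red
carries vitronectin, so $M_G$ is the marker fraction overlapping
vitronectin and $M_R$ the vitronectin fraction overlapping the marker.

`coloc_map()` bins the $(G_i, R_i)$ pairs on the full $256\times256$
8-bit grid (green on x, red on y) with quadrant totals at the two
thresholds; its grand total always equals the voxel count.

## Stereology

`point_grid()` defaults to the classical 81-point systematic grid: a
$9\times9$ tiling of the image with one point per tile. With
`offset = "random"` a single uniform offset is shared by all points
(systematic uniform random sampling), which makes the expected hit
fraction of any compartment exactly its area fraction — the Cavalieri
argument for unbiased volume-fraction estimation. Both a fixed centered
grid and a fully random scatter are provided since either placement is
defensible; systematic-random is the default. Points are classified by
the pixel containing them — boundary points are never split fractionally.

From the per-class counts, the gland volume fraction is
$G_{vf} = P_{gland}/P_{tissue}$ (all non-background points; "tissue"
includes gland and epithelium) and the vitronectin volume fraction is
$V_{vf} = P_{positive}/P_{gland}$. Zero denominators yield flagged
missing values with warnings, never silent zeros. Pixel-exact area
measures (`area_fraction()`) complement the point estimates: gland area
in mm² and percent of gland area vitronectin-positive.

The tests verify unbiasedness empirically (mean of $10^4$ random-offset
estimates within 0.01 of the pixel-exact fraction on a $512^2$ map) and
that estimator variance falls as the grid densifies (81, 324, 1296
points). Note the ratio $V_{vf}$ is a ratio of two unbiased counts, so
it is only asymptotically unbiased; at 81 points its bias is measurably
below 0.01, which is why the check is stated at that tolerance.

## Densitometry

Lane profiles are per-row means across the lane width, inverted when
blots are digitized dark-on-light so bands become peaks. Band volume is
the windowed sum above a baseline with the total clipped at zero.
Two baseline models are provided:

* `"linear-endpoints"` — the line joining the profile values at the
  window endpoints. Simple and exact on clean profiles, but each endpoint
  is a single noisy sample whose error is multiplied by the window length:
  at realistic profile noise its volume error makes faint bands
  unquantifiable (simulated relative errors of 10–40% at the lowest
  abundances tested).
* `"global-linear"` (default in `quantify_gel()`) — a least-squares line
  through **all** band-free samples of the lane. Pooling ~150 samples
  makes the baseline essentially noise-free; simulated ratio recovery is
  then within 10% across a 16-fold abundance range (sd ≈ 1.6%).

Band windows are explicit configuration, not auto-detected peaks, and
abundance comparisons are always expressed relative to the β-actin
loading-control band of the same lane, which cancels loading and exposure
differences.

## Cohort statistics

The subject is the unit of analysis: per-image measures are collapsed to
per-subject medians before any test, and group tables report median
(Q1–Q3) with linear-interpolation quartiles (`quantile` type 7) — the
rule is pinned because published-style summary tables depend on it.

* **D'Agostino–Pearson** $K^2$: transformed skewness (D'Agostino 1970)
  and kurtosis (Anscombe–Glynn 1983) Z scores, $K^2 = Z_1^2 + Z_2^2
  \sim \chi^2_2$. The approximations are unreliable below $n = 8$, so
  smaller samples error out. Implemented from the published formulas, as
  no installed package provides the omnibus version.
* **Kruskal–Wallis** with tie-corrected $H$, delegated to
  `stats::kruskal.test()` behind the module interface; the tests verify
  it against an independent rank-sum computation, including ties.
* **Dunn's post test**: pairwise
  $z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}$
  with tie term $T = \sum_t (t^3 - t)/(12(N-1))$, two-sided p-values
  Bonferroni-multiplied over all pairs and capped at 1 — the convention
  of the mainstream GUI statistics packages; unadjusted p-values are
  available by option.
* **Two-group comparisons** use the classical pooled-variance t test
  ($df = n_a + n_b - 2$).

No covariate adjustment (e.g. for age imbalance between groups) is
applied; group comparisons are deliberately unadjusted, mirroring common
practice in this literature.

## The synthetic-data generator

The generator is the package's substitute for tissue: every downstream
stage is validated against its known truth.

**Dual-channel stacks.** Green structure is a set of non-overlapping
ellipsoidal blobs with lognormal in-plane radius (median 6 voxels,
sdlog 0.2, z semi-axis halved for axial anisotropy) — ellipsoids because
they have analytic volume and trivially verifiable placement, not because
glands look like them. Colocalization is defined voxel-wise **before**
blurring: a fraction $f$ of green-object voxels also carries red signal,
and an equal number of red-only blobs (disjoint from green) provides
non-colocalized red structure, so both Manders denominators are
well-defined at every $f$. Rendering applies a separable Gaussian PSF
approximation (default $\sigma = 0.7$ voxels), Poisson shot noise plus
Gaussian read noise (sd 2), and 8-bit quantization — a structural
emulation of photomultiplier acquisition, not an optics model: no
measured PSF, no wavelength dependence, no bleed-through. The realized
(post-discretization) colocalized fraction is reported and is the
reference truth for recovery tests; in the low-noise, low-blur regime
estimated $M_G$ tracks it within 0.05 and monotonically in $f$.

**Section label maps.** Compartments are carved from smoothed Gaussian
random fields by rank thresholding: the gland compartment takes the
top-$k$ field values among tissue pixels with $k$ set by the target
fraction, and vitronectin-positive regions are carved the same way inside
gland. This makes realized fractions pixel-exact up to rounding (so no
iteration is needed) while keeping compartments spatially coherent and
blobby. The maps have no histological texture — no staining gradients,
no nuclei, no section artifacts — so passing tests demonstrate estimator
correctness on clean geometry, not segmentation robustness.

**Cohorts.** Groups default to the three-group airway design: healthy
controls at $V_{vf}$ location 0.29 versus asthma 0.07 and COPD 0.04
(beta distributions with concentration 12), at $n = 14/7/10$ subjects —
the ratio structure of the motivating study's summary table, used as
location parameters rather than as numbers to reproduce. Each subject
contributes $1 + \mathrm{Poisson}(\bar m - 1)$ images ($\bar m = 5$ by
default), since real per-subject image counts vary around the average;
per-image positive fractions are beta draws around the subject's truth
(concentration 80). Group labels never reach the quantification
functions — they join only at the statistics stage, the pipeline analog
of observer blinding.

**Gels.** Bands are Gaussian peaks whose integral equals abundance times
a fixed scale, on a linear baseline drift with additive noise
(sd 0.3 intensity units, the level expected after averaging a ~25-pixel
lane width of 8-bit pixel noise); band overlap within a lane is rejected
at spec construction.

## Problem sizes and runtime choices

The validation suite uses deliberately modest sizes, chosen so the full
suite runs in minutes on one core while keeping Monte-Carlo error small
relative to the tolerances checked: oracle comparisons on stacks of at
most $10^3$ voxels (exactness does not depend on size), recovery at
$12\times48\times48$ voxels with 20 replicates per level, threshold
calibration at $10^6$ voxels, grid bias at $10^4$ random offsets on a
$512^2$ map, test calibration at 2000 null cohorts, and end-to-end power
at 200 replicate studies with $64\times64$-pixel sections (the 81-point
grid, not pixel resolution, dominates the sampling error of each image).
Defaults for interactive use are larger where it matters
(e.g. $96\times96$ sections, $16\times64\times64$ stacks).

## Known limitations

* The generator's realism is structural, not photometric: recovery
  results bound estimator error on clean synthetic geometry and say
  nothing about segmentation or staining variability in real sections.
* $R_p$ degrades with noise by construction; the package exposes ROIs
  but never silently thresholds before computing it.
* Stack IO stores channel identity and voxel size in a YAML sidecar next
  to the TIFF (the TIFF writer used does not emit custom description
  tags); a stack TIFF without its sidecar is unreadable by design rather
  than mis-read.
* Molecular-weight calibration from ladder lanes, Costes randomization
  p-values, object-based colocalization and automated gland segmentation
  are out of scope.
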