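# vitroquant

Quantitative image analysis of vitronectin expression in airway tissue.

Vitronectin, a multifunctional matrix glycoprotein, is expressed by the
serous cells of airway submucosal glands, and its glandular expression is
reduced in obstructive airway disease (asthma, COPD). Testing that kind of
claim requires a chain of quantitative image analyses, and `vitroquant`
implements that chain for R users working with confocal stacks, stained
sections and western blots:

- **Voxel quantification** — background thresholding at the second standard
  deviation above the mean voxel intensity (t = μ + 2σ, population σ,
  strict `>`), voxel/intensity summation, and above-threshold intensity per
  compartment area.
- **Colocalization** — Pearson's coefficient on unthresholded voxels,

      R_p = Σ(G_i − G_A)(R_i − R_A) / √( Σ(G_i − G_A)² · Σ(R_i − R_A)² ),

  and Manders' coefficients on thresholded ones,
  M_G = ΣG_coloc / ΣG_i and M_R = ΣR_coloc / ΣR_i (a voxel's intensity is
  colocalized when the partner channel exceeds its threshold), plus
  256×256 joint-intensity scatter maps.
- **Stereology** — 81-point (9×9) systematic uniform-random grids and
  Cavalieri point counting: glandular volume fraction
  G_vf = P_gland / P_tissue, vitronectin volume fraction
  V_vf = P_positive / P_gland, gland area in mm², percent positive area.
- **Densitometry** — western-blot lane profiles, baseline-subtracted band
  volumes and vitronectin/β-actin loading-control ratios.
- **Cohort statistics** — D'Agostino–Pearson K² normality test,
  Kruskal–Wallis H with Dunn's Bonferroni-adjusted post test, pooled
  t test, and median (Q1–Q3) group summaries, with the subject (median
  across its images) as the unit of analysis.
- **Synthetic data** — generators for dual-channel stacks with a known
  colocalized fraction, section label maps with known gland/positive
  fractions, multi-group cohorts, and gel lanes with known abundances, so
  every stage is testable against ground truth without tissue images.
- **Pipeline** — `run_stereology_study()` / `run_coloc_study()` run
  simulate → quantify → summarize → test end to end from one seeded
  config, writing per-image, per-subject and group-level CSVs. A thin CLI
  wrapper lives in `inst/cli/vitroquant.R`.

## Worked example

Simulate a dual-channel stack whose true colocalized fraction is 0.6, then
analyze it; and run a whole synthetic three-group stereology study:

```r
library(vitroquant)

sim <- sim_coloc_stack(coloc_sim_spec(coloc_fraction = 0.6, seed = 11))
sim$realized_fraction
#> [1] 0.5999
coloc_analysis(sim$stack)
#> colocalization analysis
#>   R_p = 0.5048 over 65536 voxels
#>   M_G (Mx) = 0.6367   M_R (My) = 0.3635
#>   thresholds: green 68.45, red 73.84 (mean + 2 SD unless supplied)
```

M_G ≈ 0.64 recovers the simulated marker fraction overlapping vitronectin
(0.60, up to blur and noise); M_R is lower because red-only objects dilute
the vitronectin channel; R_p sits between the two, as a covariance-based
measure should on partially overlapping signals.

```r
res <- run_stereology_study(study_config(seed = 2024))
subset(res$group_summary, measure == "V_vf")
#>    measure  group  n     median         q1         q3
#> 4     V_vf asthma  7 0.04347826 0.01612903 0.10114581
#> 8     V_vf   COPD 10 0.00000000 0.00000000 0.06274038
#> 12    V_vf     HC 14 0.25000000 0.23047855 0.31463602
subset(res$tests, measure == "V_vf")[c("test", "comparison", "statistic", "p.value")]
#>              test     comparison statistic  p.value
#> 13 kruskal_wallis        omnibus    16.829 0.000222
#> 14           dunn asthma vs COPD     0.383 1.000000
#> 15           dunn   asthma vs HC    -2.945 0.009699
#> 16           dunn     COPD vs HC    -3.748 0.000535
```

The simulated healthy controls (V_vf location 0.29) separate cleanly from
both disease groups (0.07 and 0.04): the omnibus Kruskal–Wallis test
rejects, Dunn's post test flags both disease-vs-control pairs, and the two
disease groups — close by construction — are not distinguished.

## Vignette

`vignettes/quantifying-airway-vitronectin.Rmd` documents the models, the
pinned numerical conventions (population SD, strict thresholds, quartile
rule, tie corrections, baseline models), what the synthetic generator does
and does not emulate, and known limitations.
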