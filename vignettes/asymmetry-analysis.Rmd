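---
title: "Measuring hemispheric asymmetry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hemispheric asymmetry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymkit)
```

## The problem

Left–right asymmetry of the human cortex is usually quantified pairwise: a
homologous region is compared with its contralateral twin, either as a
weighted difference (the laterality index) or as a raw difference (the
subtraction index). Both views are blind to a different kind of asymmetry:
the two hemispheres may differ not in any single homologous pair but in how
the *proportions among regions* are preserved across the midline. `asymkit`
implements a distance index that targets exactly this global coherence, next
to the two pairwise indices, and the full battery of analyses used to compare
them as biomarkers of sexual dimorphism: random-forest classification,
image-quality-stratified robustness tests, and group statistics.

All computations run on tables of raw per-region values for the 34 cortical
parcels of the FreeSurfer `aparc` (Desikan–Killiany) parcellation, one table
per measure (gray-matter volume in mm³, pial surface area in mm², average
thickness in mm, mean curvature in 1/mm). The atlas order is fixed by
`dk_atlas()` and identical for both hemispheres; every index profile and
difference profile is built in that order.

## The indices

For subject-level vectors $a_{L}, a_{R} \in \mathbb{R}^{34}$:

$$\mathrm{DI}_i = 1 - \left| \mathrm{corr}\!\left( \left[\,|a_{i,L} - a_{j,L}|\,\right]_{j \ne i},\; \left[\,|a_{i,R} - a_{j,R}|\,\right]_{j \ne i} \right) \right|$$

$$\mathrm{LI}_i = \left| \frac{a_{i,L} - a_{i,R}}{a_{i,L} + a_{i,R}} \right|, \qquad
  \mathrm{SI}_i = \left| a_{i,L} - a_{i,R} \right|$$

Key properties (all property-tested):

- DI and LI are dimensionless and invariant under a common rescaling of both
  hemispheres; SI scales with the data.
- A perfectly mirrored or exactly proportional right hemisphere
  ($a_R = c\,a_L$) gives $\mathrm{DI}_i = 0$ for every ROI while SI stays
  positive for $c \ne 1$: DI measures coherence, not size.
- DI $\in [0,1]$; LI $\in [0,1]$ whenever both raw values are positive.

Three decisions were genuinely open and are resolved as follows:

- **Difference-profile support.** A literal upper-triangular reading
  ($j = i+1,\dots,34$) gives variable-length profiles that are empty for the
  last region. The package uses all 33 differences $j \ne i$ by default,
  which matches the verbal definition ("the other regions ipsilaterally")
  and treats every ROI symmetrically; the upper-triangular variant is kept
  behind `distance_index(..., scheme = "upper")` (ROIs whose profile has
  fewer than 3 elements are undefined there).
- **Absolute value placement.** DI is computed as $1 - |r|$, not $|1 - r|$,
  which keeps DI inside $[0,1]$ and treats an anti-correlated profile as
  maximal decoherence.
- **Sign-mixed measures.** Mean curvature can be negative; raw values are
  used as-is, so LI can exceed 1 when the homologous pair mixes signs. Such
  values are counted in the QC report (`compute_index_tables()$qc`) and never
  clipped. Undefined entries (zero-variance difference profiles, zero LI
  denominator) are flagged `NA`, excluded pairwise downstream, and counted —
  never silently zeroed.

Pearson correlation enters DI in its ratio form (centered cross-products over
the root of the centered sums of squares), so degrees-of-freedom conventions
cancel. The vectorized implementation is checked to $10^{-12}$ against an
explicit double-loop reference.

## The synthetic cohort generator

Real acquisition pipelines (FreeSurfer reconstruction and friends) are out of
scope; the package consumes their tabular outputs. To make every stage
testable without protected data, `generate_cohort()` draws cohorts with the
statistical structure the analyses assume. For subject $s$ of sex $g$ and ROI
$i$ with template mean $m_i$ (`dk_roi_means()`, realistic FreeSurfer-scale
magnitudes):

$$a_{i,L} = m_i e^{u_s} + \varepsilon_{i,s}, \quad u_s \sim N(0, \tau^2),\ \varepsilon_{i,s} \sim N(0, (c_v m_i)^2)$$
$$a_{i,R} = a_{i,L}\,(1 + \delta_{i,g}) + \zeta_{i,s}, \quad \zeta_{i,s} \sim N(0, (\sigma_g m_i)^2)$$

- The multiplicative subject factor $e^{u_s}$ reproduces between-subject
  scaling; the additive ROI noise preserves the strong inter-ROI magnitude
  differences that make DI's difference profiles informative.
- The right hemisphere is generated *conditionally on the left*, so the two
  asymmetry channels have independent knobs: the per-sex coherence noise
  $\sigma_g$ degrades the cross-hemisphere profile correlation and drives DI;
  the fractional offsets $\delta_{i,g}$ drive LI and SI while an exactly
  proportional right hemisphere leaves DI at zero.
- Image-quality metrics are drawn $N(\mu_g, s_g)$ per metric with sex-shifted
  defaults (males slightly noisier CJV/EFC, females higher CNR/INU/WM2MAX and
  a deliberately homogeneous female EFC spread); ages are uniform on 19–26
  years, matching a homogeneous young-adult cohort; all subjects are
  right-handed.

Default parameter choices, used as the study conditions throughout the tests
and the acceptance script: $n = 396$ males / $430$ females; $\tau = 0.10$;
$c_v = 0.03$; null configuration $\sigma_M = \sigma_F = 0.02$ with
$\delta \equiv 0$; dimorphism configuration $\sigma_M = 0.04 = 2\sigma_F$;
offset configuration $\delta_M = 0.05$, $\delta_F = 0$. The coherence SD of
0.02 puts mean DI near $1.6 \times 10^{-3}$ — small, as real hemispheres are
highly coherent — while remaining two orders of magnitude above floating
point noise. Scaled-down cohorts (25–60 subjects per sex) are used where a
test only needs structure, not power.

What the generator does *not* emulate: empirical ROI covariance (measures are
generated independently, with no cross-measure correlation), spatial
autocorrelation between neighbouring parcels, non-Gaussian tails, and any
linkage between image quality and morphometry (IQMs are independent of the
brain values by default). Passing tests therefore show that the pipeline
recovers the effects its generative model encodes — not that those effects
exist in any real population.

## Classification

For each (index, measure) pair the predictors are the 34 per-ROI index values
plus age. The data are split 80/20, stratified by sex with a
largest-remainder allocation so the overall training count is exactly
`round(0.8 n)`. The forest (`randomForest`, 500 trees by default) can have
its per-split predictor-subset size (`mtry`) selected by k-fold
cross-validated grid search — on the *training partition only*, since tuning
on test data would leak the evaluation; the final forest is refit on the full
training set. Evaluation reports the 2×2 confusion matrix (targets on
columns, predictions on rows, male first, with row and column percentages),
accuracy, Cohen's kappa $(p_o - p_e)/(1 - p_e)$, the no-information rate
(majority-class prevalence of the test set) and the one-sided exact binomial
tail $P(X \ge \text{correct})$ under NIR. Predictor ranking uses out-of-bag
permutation importance (mean decrease in accuracy), with impurity importance
carried alongside and ties broken alphabetically for determinism; class
probability ties at 0.5 go to the lexicographically first label. Kappa band
labels (fair above 0.20, good above 0.40, ...) are reported as annotations
only.

## Robustness and group statistics

For each of the five quality metrics (CJV, CNR, EFC, INU, WM2MAX) subjects
are sorted within sex and the per-sex extremes form a lower and an upper
subsample (default 80 per sex per level; EFC defaults to 35 because its
female distribution is much tighter than the male one, so only strongly
polarized subsamples separate the levels). Equal per-sex counts are the
matching device; achieved per-sex metric means are attached for audit and a
warning fires when they diverge by more than one metric SD. Within each
subsample, the male and female per-ROI mean profiles are compared by a paired
t-test across the 34 ROI pairs, and the p-value is tiered: `*` below 0.001,
`x` in [0.001, 0.05), `ns` otherwise. An index is a *robust* biomarker for a
metric when both extremes are significant, *quality-sensitive* when only the
better-quality extreme is (lower for CJV/EFC, upper for CNR/INU/WM2MAX), and
*not-robust* otherwise.

Group statistics use the same profile t-test on the whole cohort, plus
per-ROI point-biserial correlations of index values with sex coded
male = 0 / female = 1. Since higher male asymmetry then yields negative
coefficients, both signed and absolute grand means are reported, the
absolute being the headline. No multiplicity correction is applied in the
headline columns (the tier convention is reported as-is); a Bonferroni
column over the 12 (index × measure) contrasts is emitted alongside.
Degenerate paired differences (numerically zero spread) are reported as a
signed infinite t with p = 0 and a degeneracy flag rather than overflowing.

## Numerical and statistical caveats

- **The ROI-profile paired t-test is anticonservative.** The 34 ROI-pair
  differences are treated as independent observations, but per-subject index
  values are correlated across ROIs — for DI strongly so, because every
  ROI's difference profile shares the same cross-hemisphere noise draws
  (mean inter-ROI correlation ≈ 0.5 under the generative model). Under null
  cohorts the test rejects at far above its nominal 5% level (≈ 40–45% in
  replicate simulations, invariant to the noise scale and cohort size). The
  package implements the test as the field uses it, and the acceptance suite
  records the measured rejection rate honestly; significant profile t-tests
  should be read as descriptive tiers, not calibrated error rates. The
  subject-level two-sample t-test on mean index (used in the generator's
  null-symmetry test) does not share this defect.
- **A constant pairwise offset perturbs DI slightly downward.** With
  $a_R = (1+\delta) a_L + \zeta$ and the $\zeta$ scale fixed, the offset
  rescales the noise-to-signal ratio of the right profile by
  $(1+\delta)^{-2}$, so the shifted group's DI is *lowered* by a few percent
  of its mean. DI never reads a pairwise offset as increased asymmetry —
  which is the separation that matters — but its distribution is not exactly
  offset-invariant; the exact invariance holds in the noise-free limit.
- Tiny negative DI values from floating-point rounding (order $10^{-16}$ at
  $|r| \to 1$) are clamped to 0; exact-mirror checks in the tests use a
  $10^{-12}$ tolerance for DI and exact equality for LI/SI.
- Validation follows a complete-case policy: subjects failing any input check
  are excluded from all stages with a logged manifest, never imputed.
- The atlas is recorded in the run manifest as the 34-parcel FreeSurfer
  `aparc` set; the Desikan–Killiany and Desikan–Killiany–Tourville labelings
  overlap on these parcels and the label normalizer accepts both spellings.

## Problem sizes

The test suite generates its cohorts at runtime: 200 replicate null cohorts
of 60 subjects per sex for the calibration measurement, 20 seeds of 400 per
sex for the effect-recovery checks, 20 seeds of 200 per sex for the
offset-regime checks, and 25–60 per sex elsewhere. The acceptance script
runs the full pipeline once at the 396/430 study scale. These sizes give
Monte-Carlo standard errors comfortably inside the asserted bands while the
whole suite completes in about a minute on a single core.

```{r quick-demo}
cfg <- sim_config(n_male = 40, n_female = 40,
                  coherence_sd = c(male = 0.04, female = 0.02),
                  measures = "volume")
cohort <- generate_cohort(cfg, seed = 7)
ix <- compute_index_tables(cohort$morphometry$volume)
summary(ix)
group_contrast(ix$DI, cohort$meta, "DI", "volume")
```
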