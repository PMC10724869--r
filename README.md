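# asymkit

Hemispheric asymmetry statistics for bilateral cortical morphometry.

`asymkit` is for neuroimaging researchers who work with FreeSurfer-style
per-region morphometry tables (34 Desikan–Killiany cortical parcels per
hemisphere, with gray-matter volume, surface area, cortical thickness and
mean curvature) and want to quantify left–right asymmetry per subject and
compare it between groups — in particular between males and females.

## The three indices

For a subject with raw values `a_{i,L}` and `a_{i,R}` for ROI `i` in the left
and right hemisphere, the package computes, per ROI:

- **Distance index (DI)** — a *global coherence* measure. Build the profile of
  absolute differences between ROI `i` and every other ipsilateral ROI in each
  hemisphere,

  `V_L = [|a_{i,L} − a_{j,L}|]_{j≠i}`, `V_R = [|a_{i,R} − a_{j,R}|]_{j≠i}`,

  correlate the two 33-element profiles (Pearson `r`) and set
  `DI_i = 1 − |r|`. DI is 0 when the right hemisphere preserves the left
  hemisphere's inter-ROI proportional structure (including any exact global
  rescaling), and grows as that structure decoheres. DI ∈ [0, 1].
- **Laterality index (LI)** — the classic weighted pairwise asymmetry, in
  magnitude: `LI_i = |(a_{i,L} − a_{i,R}) / (a_{i,L} + a_{i,R})|`.
- **Subtraction index (SI)** — the raw pairwise asymmetry
  `SI_i = |a_{i,L} − a_{i,R}|`, in measure units.

Around the indices the package provides the full comparison pipeline:
random-forest sex classification from the 34 per-ROI index values plus age
(confusion matrix, accuracy, Cohen's kappa, one-sided exact binomial test
against the no-information rate, ranked predictor importances), an
image-quality robustness analysis (male–female paired profile t-tests within
the lower and upper extremes of CJV, CNR, EFC, INU and WM2MAX), group
contrasts and point-biserial sex-correlation summaries, and a seeded
synthetic cohort generator with independent knobs for global coherence noise
(drives DI) and pairwise left–right offsets (drive LI/SI).

## Worked example

```r
library(asymkit)

cfg <- sim_config(n_male = 100, n_female = 100,
                  coherence_sd = c(male = 0.04, female = 0.02))
cohort <- generate_cohort(cfg, seed = 42)

ix <- compute_index_tables(cohort$morphometry$volume)
summary(ix)
#>   index measure         mean           sd          min          max n_undefined
#> 1    DI  volume 3.856627e-03 5.617178e-03 1.464433e-04 7.682206e-02           0
#> 2    LI  volume 1.224673e-02 1.091100e-02 1.681174e-06 8.372527e-02           0
#> 3    SI  volume 1.657110e+02 2.203246e+02 7.604431e-03 2.902017e+03           0

group_contrast(ix$DI, cohort$meta, "DI", "volume")
#> Group contrast DI volume: paired t(33) = 9.392, p = 7.604e-11 [*], male > female

classify_sex(ix$DI, cohort$meta, seed = 42)
#> Confusion matrix (rows = prediction, cols = target):
#>           target
#> prediction male female
#>     male     18      0
#>     female    2     20
#> Accuracy 0.950 | NIR 0.500 | P(Acc > NIR) 7.467e-10 | Kappa 0.900 (very good)
#> Top predictors: parstriangularis, paracentral, superiorfrontal, parsopercularis, cuneus, rostralanteriorcingulate
```

The cohort was generated with the male coherence noise set to twice the
female value, so male hemispheres decohere more: mean DI is higher in males,
the paired profile t-test over the 34 ROI pairs is highly significant with a
male > female direction, and a random forest on the DI profile separates the
sexes far above the 0.5 no-information rate (here 95% test accuracy,
kappa 0.90). With real tables, replace the generator with the readers:
`read_morphometry()` (long/wide CSV-TSV or FreeSurfer `aparc.stats` pairs),
`read_participants()` (BIDS `participants.tsv` dialect) and `read_quality()`
(MRIQC-style IQM tables). `run_pipeline()` executes all stages and writes
deterministic CSV outputs plus a JSON manifest; `inst/scripts/asymkit.R` is a
shell wrapper around it.

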