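# bonephen

Multi-scale cortical bone phenomics for inbred founder and Diversity
Outbred (DO) mouse cohorts.

Skeletal phenotypes span scales: whole-body composition, whole-bone
morphology and mechanics, tissue-level material behavior, bone-matrix
chemistry, and osteocyte lacunar microarchitecture. Panels of inbred mouse
strains — in particular the 8 founder strains of the Diversity Outbred
population (A/J, C57BL/6J, 129S1, NOD, NZO, CAST, PWK, WSB) — let you ask
how much of the variation at each scale is genetic, how traits co-vary,
and where outbred animals fall relative to the inbred extremes. `bonephen`
implements the full analysis chain for such studies, plus a synthetic
cohort generator with known ground truth so every stage can be validated
end to end without animal data.

## What it computes

**Mechanical phenotyping.** Three-point-bending force-displacement curves
are reduced to stiffness *K* (maximal-slope sliding linear window), yield
force *F<sub>y</sub>* (offset-line criterion), ultimate force
*F<sub>u</sub>*, post-yield displacement (PYD, yield to fracture), and
work-to-fracture (trapezoidal integral). With section properties from
microCT, engineering beam theory gives material estimates

    Su = Fu·L·c / (4I)      Sy = Fy·L·c / (4I)      E = K·L³ / (48I)

for span *L*, second moment of area *I* and outer-fiber distance *c*.

**Broad-sense heritability.** From a two-factor (strain × sex) ANOVA,
variance components are the sum-of-squares quotients used for inbred
panels,

    σ²_strain = SS_strain / n_avg     σ²_sex = SS_sex / df_sex
    σ²_res    = SS_res / df_res       H² = σ²_strain / (σ²_strain + σ²_sex + σ²_res)

with `n_avg` the average strain group size. H² is always in [0, 1].

**Allometric adjustment.** Per-strain regression of each trait on body
mass; slopes with p > 0.20 are set to 0; animals are adjusted by
`Trait − slope·(mass − mean mass)` with the mean mass taken as the mean of
the strain means.

**Multivariate structure.** Pairwise Pearson correlation matrices with a
nonsignificance mask (p > 0.05), Ward.D2 hierarchical clustering of traits
on `1 − r`, PCA fitted on founders (centered/scaled, SVD), projection of
DO animals into the founder PC space, and 1-SD normal data ellipses per
strain.

**Raman matrix composition.** Iterative polynomial baseline subtraction
(order 11, optional background-reference removal), band-area integration,
mineral:matrix ratios (v2 phosphate:amide III, v1 phosphate:proline),
carbonate:phosphate, and crystallinity = 1 / FWHM of the v1 phosphate
band.

**Synthetic cohorts.** `simulate_founder_cohort()` /
`simulate_do_cohort()` generate 8 strains × 2 sexes × 9 animals plus
25 DO/sex with controllable strain/sex/residual variance fractions,
latent-factor trait correlations, allometric mass coupling,
strain-sex-specific hyperglycemia, and per-animal bending curves and
Raman spectra consistent with each animal's traits.

## Worked example

```r
library(bonephen)
cfg      <- sim_config(seed = 42)            # 8 strains x 2 sexes x 9 + 25 DO/sex
founders <- simulate_founder_cohort(cfg)
do_mice  <- simulate_do_cohort(cfg, founders)

h2_table(founders, c("bmc", "ct_th", "tmd", "stiffness", "ult_force", "pyd"))
#>       trait sigma2_strain sigma2_sex sigma2_res    H2   n
#>         tmd      2.53e+04   4.32e+02   4.32e+02 0.967 144
#>       ct_th      1.91e-02   2.98e-04   4.29e-04 0.963 144
#>         bmc      5.66e+04   9.25e+02   1.90e+03 0.953 144
#>   ult_force      2.03e+01   7.14e-01   3.20e+00 0.838 144
#>   stiffness      1.19e+03   6.08e+01   3.73e+02 0.732 144
#>         pyd      2.77e-03   2.65e-04   1.02e-02 0.209 144
```

Tissue mineral density and cortical thickness are almost entirely
strain-determined (H² ≈ 0.96); post-yield displacement, a ductility
measure, is mostly non-genetic (H² ≈ 0.21) — the typical multi-scale
pattern in founder panels.

```r
curve <- simulate_bend_curve(mechanical_truth(K = 100, Fy = 6, Fu = 8, PYD = 0.3),
                             noise_sd = 0.05, seed = 1)
analyze_curve(curve, geometry = beam_geometry(I = 0.05, c = 0.5, L = 7))
#> <mechanical_result> K = 100.5 N/mm, Fy = 6.476 N, Fu = 8.051 N,
#>                     PYD = 0.262 mm, work = 2.37 mJ, E = 1.436e+04 MPa
```

Stiffness and ultimate force are recovered to ~0.5%; the yield point sits
slightly above the true kink because, with geometry supplied, the
conventional 0.2%-strain offset line (here 0.033 mm) is used — pass
`offset_displacement` to tighten it.

```r
pca <- fit_pca(founders, c("body_mass", "bmc", "ct_ar", "ct_th", "tmd",
                           "stiffness", "ult_force", "pyd"))
pca
#> <pca_model> 8 traits, 144 rows; PC1-PC4 explain 59.7%, 13.7%, 12.5%, 6.2%
do_scores <- project_onto_pca(pca, do_mice)
range(do_scores[, 1]); range(pca$scores[, 1])
#> [1] -4.15  4.70
#> [1] -4.78  6.05
```

Projected DO animals occupy a smaller, more central region of the founder
PC space — the admixture of founder effects attenuates inbred extremes.

```r
sp <- simulate_raman_spectrum(c(v1_phosphate = 10, proline = 2, v2_phosphate = 4,
                                amideIII = 4, v1_carbonate = 3),
                              fwhm_v1 = 20, baseline_coeffs = c(2, 1, 0.5),
                              noise_sd = 0.005, seed = 3)
compute_ratios(subtract_baseline(sp))
#> <raman_result> v2:amideIII = 0.987, v1:proline = 5, carb:phos = 0.294,
#>                crystallinity = 0.05012 1/cm
classify_glycemia(c(120, 310))
#> [1] "normal"        "hyperglycemic"
```

The whole chain — simulate, mechanics, heritability, adjustment,
correlations, clustering, PCA + projection, Raman, post hoc tables — runs
from one call:

```r
report <- run_pipeline(pipeline_config(simulation = cfg,
                                       out_dir = "bonephen_out", seed = 42))
```

A thin CLI with the same stages is in `inst/cli/bonephen`
(`bonephen all --seed 42 --out runs/demo`).

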