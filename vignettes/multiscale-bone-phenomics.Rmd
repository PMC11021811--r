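---
title: "Methods: multi-scale cortical bone phenomics in bonephen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale cortical bone phenomics in bonephen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonephen)
```

`bonephen` analyzes cortical-bone trait panels measured across an inbred
founder strain panel (8 strains x 2 sexes) and a Diversity Outbred (DO)
cohort bred from those founders. This vignette documents the statistical
models, the numerical choices, and — because the package ships its own
synthetic-cohort generator — exactly what that generator does and does not
emulate, so that the reader can judge what a passing test suite implies
about real data.

## 1. Broad-sense heritability from strain-panel ANOVA

For each trait we fit a two-factor least-squares ANOVA with strain and sex
as factors and form variance components from the sums of squares:

$$\sigma^2_{strain} = \frac{SS_{strain}}{n_{avg}},\qquad
\sigma^2_{sex} = \frac{SS_{sex}}{df_{sex}},\qquad
\sigma^2_{res} = \frac{SS_{res}}{df_{res}},$$

$$H^2 = \frac{\sigma^2_{strain}}
{\sigma^2_{strain}+\sigma^2_{sex}+\sigma^2_{res}},$$

where $n_{avg}$ is the average group size. This is the classical
inbred-panel estimator: because every animal within a strain is
genetically identical, the between-strain variance share approximates the
fraction of phenotypic variance due to genetic differences. All
components are nonnegative quotients, so $H^2 \in [0,1]$ by construction.

Choices the estimator leaves open, and our defaults:

* **Model.** `additive` (strain + sex), so the three-way partition matches
  the component formulas exactly. An `interaction` model is available for
  significance testing; its interaction SS is reported separately and does
  not enter $H^2$.
* **SS type for unbalanced data.** Type III with sum-to-zero contrasts
  (the default of the commercial packages typically used for such
  analyses); Types I and II are selectable. For balanced panels all types
  coincide, and for the additive model Types II and III are identical.
* **Group size.** `n_avg` = animals-with-trait / number of strains
  (strain-level groups, 8 in the default design); a strain-by-sex variant
  (`group = "cell"`) is provided.
* **Missing data.** Listwise per trait, with the per-trait n reported.

It is worth being explicit that this estimator is a *convention*, not an
unbiased variance-component estimator: $E[SS_{strain}/n_{avg}]$ scales
with the number of strains times the per-animal between-strain variance,
and the sex term is divided by its single degree of freedom rather than a
group size. The package reproduces the convention faithfully; the
synthetic generator is calibrated to it (section 6) so that recovery
tests are exact rather than approximate.

## 2. Mechanical curve analysis

Whole-bone properties come from monotonic-to-failure three-point bending
records (displacement mm, force N):

* **Stiffness** is the maximum least-squares slope over all contiguous
  windows spanning 20% (`window_frac`) of the pre-ultimate samples. The
  maximal sliding window is robust to the compliance toe created by the
  small compressive preload; the winning window is reported.
* **Yield** uses the offset-line criterion: the first sample at/after the
  elastic window, and strictly before failure, whose force falls below
  $K(d - d_{offset})$. With section geometry available the default offset
  is $0.002\,L^2/(6c)$ — the 0.2% strain offset mapped to displacement
  through beam theory — otherwise a fixed 0.01 mm. Curves that never
  violate the offset line are flagged brittle with $F_y = F_u$ and
  PYD = 0.
* **Failure** is the first post-ultimate sample below 10% of $F_u$
  (`drop_frac`), else the last sample; PYD is failure minus yield
  displacement.
* **Work-to-fracture** is the trapezoidal integral of force to the failure
  displacement, with preload (negative force) samples clipped at zero and
  the displacement origin re-zeroed at the first force zero-crossing.
* **Material properties** follow standard three-point-bending beam theory,
  $S_u = F_uLc/4I$, $S_y = F_yLc/4I$, $E = KL^3/48I$ (MPa for N and mm
  units). $I$ and $c$ are inputs (from microCT), never estimated here.

The offset convention matters quantitatively: on simulated curves the
0.2%-strain offset overestimates the yield force of a sharply kinked
curve by several percent (it reads the hardening branch slightly late),
while a 0.005–0.01 mm offset recovers it to ~1–3% under realistic noise.
Both the offset and the drop fraction are explicit parameters because
published studies rarely state them.

## 3. Body-mass adjustment and covariate screening

Size differences between strains (a NZO mouse can weigh three times a
CAST mouse) confound bone traits. The adjustment is allometric and
per-strain: within each strain, ordinary least squares of trait on body
mass gives a slope; slopes from regressions with $p > 0.20$ (strictly)
are set to zero to avoid adjusting through noise, as are slopes from
strains with fewer than 3 usable animals (flagged separately). Every
animal is then adjusted with its own strain's slope,

$$\mathrm{Trait}_{adj} = \mathrm{Trait} - b_{strain}\,(\mathrm{mass} -
\overline{\mathrm{mass}}),$$

where $\overline{\mathrm{mass}}$ is the unweighted mean of the 8 strain
mean masses ("mean of means"), so the adjustment target does not depend
on group sizes. Under the null the p > 0.20 rule retains ~20% of slopes;
the suite verifies this calibration. A separate screen,
`covariate_significance()`, reports the p-value of body mass in
`trait ~ strain + sex + mass`.

Adjustment is idempotent (re-fitted slopes on noiselessly adjusted data
are zero) and OLS orthogonality guarantees the adjusted trait is exactly
uncorrelated with mass within every non-zeroed strain.

## 4. Correlation, clustering, PCA and projection

Correlation matrices are pairwise-complete Pearson with two-sided t-test
p-values; entries with p > 0.05 are masked (the "X" in the heatmap).
Pairwise completion maximizes per-panel n under missingness; PCA, by
contrast, uses complete cases only, since a projection needs every trait.

Trait clustering is agglomerative with the Ward.D2 criterion on the
distance $d = 1 - r$. We deliberately use the *signed* correlation (not
$1-|r|$): traits whose biology agrees correlate positively, and merging
anti-correlated traits into one cluster would obscure that. The unsigned
variant is one switch away.

PCA is fitted on founder animals only: each trait is centered and scaled
(mean 0, SD 1) and the standardized matrix is decomposed by SVD. Loading
signs are fixed so each component's largest-magnitude loading is
positive, making runs comparable (signs are otherwise arbitrary). DO
animals are *projected*: centered and scaled with the founder parameters
and linearly combined with the founder loadings — never refitted — so
projecting the training rows reproduces the fitted scores exactly, a row
equal to the founder trait means maps to the origin, and the projection
is affine. Group dispersion is drawn as the 1-SD normal data ellipse
(the Mahalanobis-radius-1 contour of the fitted bivariate normal), with
degenerate (collinear) groups flagged. Four PCs are retained for
reporting; all are stored.

## 5. Raman bone-matrix composition

Spectra (300–1800 cm⁻¹) are baseline-corrected in two steps. If a
background reference (e.g. the embedding medium) is supplied, it is
subtracted first after least-squares scaling over the regions outside all
analysis bands. Then an order-11 polynomial baseline is estimated by
iterative masked fitting: fit to the currently retained points, exclude
points more than two residual SDs above the fit as peaks, refit, for up
to 20 iterations. Fitting to the retained points' *center* (rather than
taking the lower envelope, as plain modified-polyfit does) avoids the
systematic under-subtraction of wide shallow bands by roughly the noise
envelope; at 1% peak-height noise this halves the error of the
v2-phosphate:amide-III ratio in our recovery tests. Remaining negative
intensities are clipped at zero, with a warning when the clipped mass
exceeds 15% of the retained signal (a sign of a bad fit, not of noise).

Band areas are trapezoidal integrals over fixed windows. The windows are
configuration, not constants of nature; defaults follow standard bone
Raman assignments: v2 phosphate 410–460, proline/hydroxyproline 840–898,
v1 phosphate 930–980, v1 carbonate 1050–1100, amide III
1215–1300 cm⁻¹. Ratios v2:amide III, v1:proline (mineral:matrix) and
v1 carbonate:v1 phosphate (carbonate:phosphate) are guarded against
zero denominators. Crystallinity is the inverse FWHM of the v1 phosphate
band, with the FWHM taken from a single-Gaussian least-squares fit to the
v1 window (robust to noise; a direct half-maximum search is available for
cross-checks). Spot-level metrics from a measurement grid are aggregated
per sample by the median (configurable — the aggregation statistic used
by any given lab is rarely stated).

All ratios are invariant to uniform intensity rescaling, and
crystallinity is independent of band amplitude; both are asserted in the
suite.

## 6. The synthetic cohort generator

The generator emulates the study design the analyses target: 8 founder
strains x 2 sexes x 9 animals, and a DO cohort of 25 per sex. Each trait
is built as

`grand_mean + strain effect + sex effect + mass_slope * (mass − mean mass)
+ residual`,

with strain effects shared by strain-mates, body mass simulated first so
other traits can couple to it allometrically, latent factors ("size" for
morphology/mechanics, "material" for mineral/material traits) inducing
the block correlation structure typical of founder panels, and optional
strain-sex hyperglycemia shifts (defaults: NOD females +250, NZO males
+300 mg/dL — magnitudes are free parameters) feeding the fasting-glucose
trait and its >250 mg/dL classification rule.

**Estimator calibration.** The defining feature is *how* effect sizes are
realized. In the default `variance_mode = "anova"`, the drawn strain
effects are exactly centered and rescaled, the sex effect is set
deterministically, and the residual vector is orthogonalized against the
strain x sex design and rescaled, such that (i) the ANOVA decomposition
of section 1 returns exactly the requested variance fractions, and (ii)
the total sample variance equals exactly `total_sd²` (both for traits
without mass coupling). This makes recovery tests sharp: a bias in any
downstream stage shows up immediately rather than hiding inside
Monte-Carlo error. Orthogonalizing and norm-fixing the residuals does not
distort null-calibration checks — t statistics are scale-invariant and
depend only on the residual direction, which remains spherically
distributed — and the suite verifies the p > 0.20 retention rate and the
covariate type-I error empirically. A `"population"` mode with plain
per-animal variance fractions and fully stochastic realizations is also
provided.

The default trait panel's strain-fraction targets follow the heritability
spectrum characteristic of founder panels (bone mineral content ~0.99,
cortical thickness ~0.985, down to post-yield displacement ~0.21), with
plausible grand means and dispersions; within-strain SDs are placeholders
in the honest sense that per-strain dispersions are rarely published, and
all of them are user-configurable. A fixed-effects mode accepts a
per-strain effect table verbatim for replication against published
strain means.

**DO cohort.** Each DO animal draws one Dirichlet(α = 0.5) weight vector
over the 8 founders, shared across traits, and its strain-level effect is
the corresponding convex combination of founder effects; residuals reuse
the founder latent-factor covariance so the outbred environmental
covariance matches the founders'. Convexity guarantees — exactly, per
animal — that every DO strain-effect component lies inside the founder
effect range, which is the model's rendering of "hybrid phenotypes with
attenuated extremes". What convexity does *not* guarantee is that every
*observed* DO value or every projected DO score stays inside the founder
sample's range or convex hull: residual noise is unshrunken, and with
α = 0.5 many weight vectors are nearly one-hot, so a DO animal can sit
next to an extreme founder cluster and its noise can step outside a
144-point hull. Measured under the defaults, ~98.5% of projected DO
animals fall inside the founder PC1–PC2 hull, but the probability that
*all* 50 do so in a given cohort is only ~0.5; for residual-dominated
traits the chance that a 50-animal DO range is contained in a 144-animal
founder range has a hard iid ceiling near $(144/194)^2 \approx 0.55$.
Tests therefore assert the exact convexity invariant, the pooled
containment, and range containment for strain-dominated (target ≥ 0.95)
traits, where it genuinely holds.

**Raw records.** Bending curves are piecewise (linear elastic at slope K,
linear hardening to $F_u$ at half the PYD, softening to 90% $F_u$ at
fracture, abrupt drop to 2% $F_u$) with breakpoints inserted into the
sampling grid so noiseless curves attain $F_u$ exactly, plus Gaussian
force noise. Spectra are sums of Gaussian bands at canonical centers with
requested integrated areas, the v1 width set from the requested FWHM, a
polynomial baseline in a scaled coordinate, and Gaussian noise.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: genomes (admixture weights are a phenotypic
proxy; real DO haplotype proportions are far more balanced than
Dirichlet(0.5), so real DO cohorts should be *more* central than the
simulated ones); growth trajectories and age structure; non-Gaussian
residuals, outliers and measurement batch effects; curve artifacts such
as slipping, multiple micro-fractures or machine compliance; and Raman
cosmic rays or fluorescence saturation. Mortality is available only as
uniform thinning (off by default).

## 7. Numerical choices and degenerate inputs

* ANOVA on a design where strain and sex are aliased raises a design
  error; zero-variance traits return an all-zero decomposition with a
  degenerate flag and $H^2 = 0$.
* `car::Anova` declines exactly-perfect fits (zero residual SS); the
  package then computes the identical marginal SS directly as RSS
  differences on the sum-to-zero design.
* Stiffness fitting requires ≥3 pre-ultimate samples and a positive best
  slope; constant-force curves are rejected as degenerate.
* Sidak adjustment $p_{adj} = 1-(1-p)^m$ is applied within each declared
  contrast family (per sex); it is monotone in $m$ and the identity at
  $m = 1$.
* Correlation entries with <3 complete pairs or a constant trait are NA
  ("unavailable"), and clustering refuses matrices containing them rather
  than silently imputing.
* PCA requires complete cases and positive SDs, and names the offending
  constant trait.
* The Gaussian v1 fit falls back to a flagged `NA` crystallinity when the
  optimizer fails or the width collapses.
* All simulation operations are deterministic given (config, seed); the
  DO stage derives its stream from seed + 1 so founder and DO draws never
  overlap.

## 8. Validation problem sizes

The shipped validation (tests and `scripts/acceptance.R`) uses 100
simulated cohorts per heritability target, 500 random small ANOVA
designs against a pseudo-inverse projection oracle, 200 noisy bending
curves, 480 null slope regressions, 50 cohorts for projection
containment, and 20 noisy spectra — sizes chosen so the whole validation
runs in well under a minute on a laptop while keeping Monte-Carlo error
far below the tolerances being asserted.

## 9. Known limitations

* The heritability quotients are a reporting convention (section 1); they
  are not REML variance components and no narrow-sense decomposition or
  QTL mapping is attempted.
* Beam theory treats the radius as a prismatic beam; $I$ and $c$ must
  come from imaging and their error propagates linearly into the material
  properties.
* The yield criterion and stiffness window are conventions; comparisons
  across studies require matching them, which is why both are explicit
  parameters.
* Multi-peak deconvolution of overlapping Raman bands is out of scope;
  windowed areas attribute overlap tails to whichever window contains
  them.
* The DO generator is a phenotypic admixture proxy, not a pedigree or
  genome simulation.
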