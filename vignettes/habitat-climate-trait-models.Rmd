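---
title: "Habitat-specific climate-trait models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat-specific climate-trait models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habclim)
```

## The scientific problem

Trait-based community ecology asks how macroclimate shapes the functional
composition of plant communities. The working response variable is the
community-weighted mean (CWM): the cover-weighted average of a species-level
trait across the species of a vegetation plot. Globally, climate predicts CWMs
only weakly, plausibly because local factors — soil, land use, disturbance,
biotic interactions — vary enormously *across* habitats and mask climatic
signal. Classifying plots into a hierarchy of increasingly narrow habitat
types (broad level 1, intermediate level 2, narrow level 3) holds those local
factors progressively more constant, so the climate signal, and its
habitat-specificity, can be separated from the habitat signal.

`habclim` implements that analysis as a tested pipeline: plot-level CWMs of
four traits (plant height, specific leaf area, seed mass, specific root
length), principal components of 19 bioclimatic variables as climate
gradients, and a hierarchy of linear mixed models that place habitat random
intercepts and habitat-specific random climate slopes at the three
classification levels. Because continental vegetation-plot archives are
access-restricted, the package ships a synthetic-data generator with known
mixed-model ground truth; every statistical claim the package makes is
validated by parameter recovery against that truth.

## The model

For one trait and a set of plots \(i\) with habitat \(h(i)\) at a given
level, the log-transformed CWM is modelled as

\[
\log y_i \;=\; \beta_0 + \sum_{j=1}^{4} \beta_j x_{ij}
 \;+\; a_{h(i)} \;+\; \sum_{j=1}^{4} b_{h(i),j}\, x_{ij}
 \;+\; s(\mathrm{lat}_i, \mathrm{lon}_i) \;+\; \varepsilon_i ,
\]

where \(x_{ij}\) is plot \(i\)'s score on climate PC \(j\),
\(a_h \sim N(0, \tau_0^2)\) are habitat random intercepts,
\(b_{hj} \sim N(0, \tau_{1j}^2)\) are habitat-specific random slopes,
\(s(\cdot)\) is a spatial smooth over the sphere absorbing residual spatial
dependence, and \(\varepsilon_i \sim N(0, \sigma^2 / w_i)\) with optional
observation weights \(w_i\) (the trait-coverage sensitivity analysis).

The five-model hierarchy (`build_design()`, `model_id` 1–5):

1. fixed climate effects only, fitted on a balanced subsample (the minimum
   broad-habitat group size drawn from every broad habitat) so that unequal
   habitat sampling does not distort the across-habitat slopes;
2. plus random intercepts of the broad habitats;
3. plus random climate-PC slopes of the broad habitats;
4. as 3 with the intermediate habitats carrying intercepts and slopes;
5. as 3 with the narrow habitats carrying intercepts and slopes.

Random intercepts and slopes are modelled as independent i.i.d. Gaussian
blocks, one variance each — the random-effect-as-penalized-term construction
of the GAMM toolchain this analysis style comes from. This gives the same
marginal covariance structure as an uncorrelated random-coefficients model
while keeping REML simple. No intercept–slope correlation is estimated; the
synthetic generator exposes such a correlation (`intercept_slope_cor`) so the
robustness of the independence assumption can be probed, and defaults to 0.

### Estimation

`fit_mixed_reml()` maximises the restricted likelihood profiled over the
fixed effects and the residual variance, parameterised by the log variance
ratios \(\log(\tau_k^2/\sigma^2)\). All linear algebra runs on cached
cross-products of the sparse random-effect matrix, so one evaluation costs
\(O(q^3)\) in the total number of random coefficients \(q\), independent of
the number of plots after the initial pass. Analytic gradients drive a
projected BFGS with a backtracking (Armijo) line search inside the box
\([10^{-8}, 10^{8}]\) on the variance ratios, followed by a damped-Newton
polish (finite-difference Hessian of the analytic gradient,
Levenberg–Marquardt damping) that tightens the optimum to a projected
gradient below \(10^{-6}\) — in practice to \(10^{-9}\)–\(10^{-12}\), which
is what lets a balanced one-way fixture reproduce the closed-form ANOVA
estimators to \(10^{-6}\) relative error. The accepted-step criterion trace
is recorded and is monotone by construction; non-convergence raises an error
carrying the trace. Variance components are floored at
\(10^{-10}\,\mathrm{var}(y)\). Fixed effects, BLUPs, their conditional SEs
and the joint fixed-effect/BLUP covariance come from the Henderson
mixed-model equations at the optimum.

The test suite cross-checks the whole fitter against `lme4` (fixed effects,
SEs, variance components, BLUPs, REML log-likelihood, observation weights) on
non-trivial fixtures; `lme4` is never used as the implementation.

### The spatial smooth

The spline-on-the-sphere term is implemented as a low-rank Gaussian-process
basis: \(k\) knots (default 100) chosen by a seeded farthest-point design
over the observed plot locations under great-circle distance; basis entries
\(\exp(-d/\rho)\) with \(d\) the great-circle distance to the knots and
\(\rho\) defaulting to the median inter-knot distance; the penalty is the
same kernel among the knots. After a Cholesky reparameterisation the smooth
enters REML as one more i.i.d. block with a single variance parameter. The
contract of this term is to absorb spatial dependence, not to reproduce any
particular spline family: the suite verifies that a generated spatial field
is captured by the smooth's variance component without disturbing the
climate slopes, and that a superfluous smooth (no spatial signal in the
generator) moves the fixed slopes by less than one standard error.

### Marginal slopes, significance and suppression

For models 3–5, the habitat-specific marginal slope for PC \(j\) in habitat
\(h\) is \(\hat\beta_j + \hat b_{hj}\); its SE combines the fixed-effect
variance, the BLUP conditional variance and twice their covariance from the
joint Henderson system (the SE formula used is recorded per row). Confidence
intervals are \(\pm 1.96\,\mathrm{SE}\) and an interval excluding zero is
flagged significant (approximately \(p < 0.05\), two-sided, per slope — no
multiple-testing correction across habitats or PCs, matching the separate-t-test
convention of this analysis style; a Benjamini–Hochberg step could be added
downstream but is deliberately not applied by default). Slopes from habitats
with fewer than 100 plots are suppressed: reported, but stripped of
significance claims. `classify_and_tally()` counts significantly positive,
significantly negative, nonsignificant and suppressed child habitats per
broad-habitat parent — the narrow-habitat summary figure of the analysis.

### Variance partition

`r2_partition()` computes the marginal and conditional \(R^2\) from the
variance components: the fixed component is the population variance of
\(X\hat\beta\) over the analysis rows; a random intercept contributes
\(\hat\tau_0^2\); a random slope contributes \(\hat\tau_{1j}^2 \cdot
\overline{x_j^2}\) (the mean diagonal of its induced covariance — validated
against a Monte-Carlo redraw oracle to within 2%); the spatial smooth
contributes \(\hat\tau_s^2\) times the mean squared row norm of its
reparameterised basis. Marginal \(R^2\) is fixed over total; conditional adds
every random component. The climate share (fixed plus slope components) and
habitat share (intercept component) reproduce the blue/red decomposition of
the hierarchy figures. Convention: the spatial component counts toward the
conditional \(R^2\) but not toward the climate share, because the smooth
models spatial dependence, not climate; the source analysis does not state
its treatment, so the choice is explicit and reversible
(`spatial_in_climate = TRUE`).

## Preprocessing conventions

Six exclusion rules run in a fixed order, each logged with its removal count:
presence/absence-only plots; missing coordinates; an optional bounding-box
region exclusion (the hook generalising region lists such as Greenland;
off by default on synthetic landscapes); latitude strictly below 34° N or
strictly above 82° N (boundary values retained); trait coverage strictly
below 0.80 (exactly 0.80 retained); missing climate. The coverage criterion
is the minimum across the four traits, making the filter a single per-plot
rule — with gap-filled trait tables all four traits are typically present or
absent together, so the four coverages coincide at full fidelity; a per-trait
mode exists (`cwm_coverage(mode = <trait>)`). Whether removal counts were
sequential in the source analysis is unknowable from the text, so the report
makes the order auditable.

Deduplication retains, among plots sharing *exactly* identical coordinates,
the one with the largest survey year (ties broken by a seeded uniform draw);
a coordinate tolerance is deliberately not applied. Stratification bins
plots into half-open `floor(lat/0.01) x floor(lon/0.01)` cells (lower-left
inclusive — the binning rule must be stated for reproducibility and floor on
signed coordinates is the convention chosen) and keeps one seeded draw per
cell. At 51.5° N a 0.01° cell measures about 1.11 km north–south by 0.69 km
east–west on a 6371-km sphere.

CWMs are computed on the arithmetic scale and then natural-log transformed;
the log base only rescales slopes, so \(e\) is used. Weights renormalise over
trait-bearing species; the coverage fraction (trait-bearing cover over total
cover) doubles as the filter criterion and as the optional observation
weight. Species names are merged at the species level by truncating to the
first two name tokens, summing covers and capping at 100% — the cap is this
package's convention; how merged covers jointly exceeding 100% were treated
upstream is not stated in the source material.

## Climate PCA

The 19 bioclimatic variables mix units (°C, mm, dimensionless indices), so
the PCA runs on the correlation matrix (z-scored variables); covariance
versus correlation is not stated in the source analysis and correlation is
the defensible default for incommensurate units. Loading signs are fixed so
each column's largest-magnitude entry is positive, giving the synthetic
gradients a stable orientation across runs. Plots are projected with the
stored standardisation and loadings; the first four components serve as the
climate gradients.

## The synthetic generator

`generate_dataset()` emulates the study conditions at desk scale. Defaults,
chosen once as a realistic miniature and not revisited: 4000 plots uniform
over 35–70° N, −10–30° E; a 6 → 18 → 54 nested habitat hierarchy (the
8 → 40 → 216 full-scale ratio at roughly quarter scale — note the full-scale
counts are not divisibly nested, the generator requires divisibility);
19 climate variables as linear mixtures of four latent spatial gradients
(latitudinal, longitudinal, a smooth sinusoidal field and an interaction
field) with orthonormal mixing, decreasing gradient weights and independent
noise, so a PCA recovers at most four dominant axes; fixed slopes
\(\beta = (0.3, -0.2, 0.1, 0)\) in log-trait units per unit PC score —
effects of realistic magnitude, one null; \(\tau_0^2 = 0.5\) (habitat
explains more than climate, as observed in real plot archives);
\(\tau_1^2 = 0\) unless a study injects heterogeneity; \(\sigma^2 = 1\);
spatial field off unless requested, otherwise a low-rank exponential-kernel
Gaussian process (≤ 200 knots, great-circle distance) rescaled to its nominal
marginal standard deviation. Trait intercepts are natural-log baselines of
typical CWMs (0.5 m height, 20 mm²/mg SLA, 1.5 mg seed mass, 100 m/g SRL).

Responses are built on the generator's *own* PCA scores standardised to unit
variance, and that score matrix is stored in the dataset, so recovery
studies fit exactly the generating design; the closed-form variance examples
(e.g. a fixed-part share of 1/3 when \(\beta = (1,0,0,0)\),
\(\tau_0^2 = \sigma^2 = 1\)) hold on the unit-variance score scale. One
master seed drives everything through per-stage derived seeds (stage-name
hashing), and the truth record stores the realized habitat deviations,
spatial fields and stage seeds, so `reconstruct_responses()` rebuilds the
response table byte-identically.

Two fidelity modes. *Direct mode* emits the log-CWMs themselves — the mode
for exact parameter recovery, since the statistics of the analysis operate on
CWMs. *Community mode* (`generate_communities()`) inverts each plot's 4-trait
log-CWM target into a species community: per-habitat species pools with
log-normal traits whose log-scale cloud is centred on the habitat's mean
target and carries the covariance of the habitat's own targets, widened by a
configurable factor (default 2, with 120 species per pool) so that the
targets sit inside the pools' trait hulls; and percent covers from
exponential tilting — a softmax over species suitability whose tilting
vector is found by damped Newton on the convex dual, so the cover-weighted
*arithmetic* trait means (the scale on which a CWM is defined) hit the
plot's targets within a configurable tolerance (0.05 log units by default).
Targets outside the convex hull of a pool's trait values
are flagged, never silently dropped (a one-species pool flags every plot and
emits that species). Configurable fractions of species are emitted without
species-level trait rows (genus fallback) or with no trait information at
all, to exercise the coverage logic; both default to 0 so that the tolerance
contract is exact by default. Community mode is an integration fixture: an
exact 4-trait inversion is over-constrained, which is why recovery statistics
are made in direct mode.

What the generator does *not* emulate: phylogenetic trait structure,
intraspecific variation, gap-filling error, climate–habitat confounding
(habitats are placed independently of climate, unlike real vegetation), and
raster climate extraction. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated model, not robustness to every
failure mode of real archive data.

## Validation studies and problem sizes

The suite's simulation studies, sized to run comfortably on one CPU:

- **Fixed-slope recovery** (`recovery_study()`): 200 replicates at
  \(n = 4000\), \(\beta = (0.30, -0.20, 0.10, 0)\), \(\tau_0^2 = 0.5\),
  \(\tau_1^2 = 0.2\) on PC1 at the narrow level, \(\sigma^2 = 1\); asserts
  per-slope absolute bias below 0.01 and 95%-CI coverage, pooled over the
  four slopes (800 intervals), inside [0.93, 0.97]. Per-slope coverage at 200
  replicates has a binomial SE of ~0.015 — wider than that band — so the
  pooled estimate is the statistically meaningful check; per-slope values are
  still reported.
- **Induced-variance oracle** (`r2_slope_oracle()`): the analytic slope
  component \(\tau^2 \overline{x^2}\) against the pooled variance of
  simulated group-deviation contributions over 10,000 redraws on a 50-group
  fixture, within 2% relative error.
- **Closed-form REML check** (`anova_reml_check()`): balanced one-way
  fixture, REML equals the ANOVA moment estimators to \(10^{-6}\) relative.
- **Hierarchy pattern** (`r2_pattern_study()`): with slope heterogeneity
  injected only at the narrow level (\(\tau_1^2 = 0.2\) on all four PCs —
  heterogeneity on several gradients at once, which is also what makes the
  per-replicate ordering statistically crisp), the climate share of the
  variance partition is non-decreasing across models 3 → 4 → 5 in at least
  95% of 50 replicates at \(n = 2000\); with no heterogeneity the three
  shares are statistically flat.

## Known limitations

- The spatial smooth is a low-rank kernel basis, not a full thin-plate
  spline on the sphere; its basis dimension `k` is configurable and reported,
  and its adequacy is validated behaviourally, not spectrally.
- Habitat labels are inputs; the expert classification system that produces
  them is out of scope, as are taxonomic harmonisation and trait gap-filling.
- Significance uses the normal 1.96 multiplier throughout; with few habitat
  groups the slope-variance uncertainty makes intervals slightly
  conservative or liberal depending on the component, visible in the
  recovery study's per-slope coverages.
- Model 1's balanced subsample makes its \(R^2\) not directly comparable to
  models 2–5 row counts; the decomposition table records the model id so
  downstream summaries can separate them.
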