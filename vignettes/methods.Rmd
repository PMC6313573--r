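---
title: "Methods: from censored monitoring data to mapped excess risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from censored monitoring data to mapped excess risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`geoexpose` implements a complete chain from raw, heavily left-censored
environmental monitoring data to mapped lifetime cancer-risk indicators for
benzo[a]pyrene (B[a]P), the conventional indicator PAH. The chain has five
computational stages:

1. **Imputation** of left-censored drinking-water concentration panels by
   bootstrap-EM multiple imputation;
2. **Water spatialization**: segments-of-influence temporal weighting,
   population-weighted aggregation through the distribution network,
   rasterization to a 3 × 3 km reference grid;
3. **Soil mapping**: indicator kriging of detection-limit exceedance, a
   polluted-site source proxy with AIC-selected buffer radius, out-of-bag
   covariate selection, and random-forest residual kriging;
4. **Air mapping**: a distance-weighted emission proxy (20 km buffer),
   LOOCV-based drift-term selection among emissions/altitude/population,
   exponential-variogram regression kriging, and an accuracy-weighted
   combination of two monitoring years with a validity mask;
5. **Exposure**: a multimedia dose model yielding per-pathway Lifetime
   Average Daily Doses (LADD, mg·kg⁻¹·day⁻¹) and Excess Individual Risk
   (EIR, reported ×10⁶) for two age classes (children 0–17 y, adults
   17–70 y).

The real inputs of such an analysis (regulatory water panels, a national
soil survey, air-quality annual means, emission inventories, population
grids) are closed databases. The package therefore ships a first-class
synthetic scenario generator that reproduces their *statistical* structure,
so that every stage is testable offline and method properties (bias
orderings, parameter recovery, selection behavior) can be demonstrated by
simulation.

# The synthetic scenario generator

`scenario_config()` fixes the study conditions. Defaults mirror the
situation the pipeline was designed for:

* a two-substance water panel over 200 distribution units sampled
  irregularly (homogeneous point process, ~2 obs/unit/year) over
  2000–2012, with ~88% of records below the detection limit and a
  cross-substance correlation of 0.9;
* a regular coarse topsoil survey with ~68% censoring;
* 76 air monitoring stations over the reference grid.

Concentrations are generated on the log scale and exponentiated —
environmental trace concentrations are positive and right-skewed. For the
water panel the marginal log-sd is 1.6 (a geometric standard deviation of
about 5, typical of trace organic contaminants); nothing in the source
material fixes this marginal, so it is a generator design choice made
once. The requested `substance_correlation` is realized as the correlation
of the *total* log-latent values: the generator decomposes each
log-concentration into a shared smooth time trend, a shared per-unit
level (sd 0.5), and substance-specific noise whose correlation is
calibrated so that the total matches the request. Water concentrations are
centered at ~2 ng/L (log-mean −13 on the mg/L scale), soil at ~0.14 mg/kg
before covariate and source effects, air at ~1.2 ng/m³, which places the
relative pathway magnitudes in a realistic regime.

Gaussian random fields on the grid are simulated by circulant embedding
(FFT): the covariance implied by the target variogram is laid out on a
doubled torus, its eigenvalues obtained by FFT, and negative eigenvalues
(possible for the spherical family) clipped to zero — the standard
approximation, immaterial at these grid sizes (verified by the white-noise
and variance tests). Scattered-point fields (stations, validation sets) use
a Cholesky factorization of the exact covariance. The nugget is always
added as independent noise.

The soil field is built as a *thresholded* nonlinear function of three of
fourteen smooth candidate covariates (`1.2·1{C1>0.5} + 0.8·max(C2,0) +
0.6·C1·C3`), plus a polluted-site term of truncated inverse-distance form
(1/max(d, half-cell) within 3 km, zero beyond), plus a correlated residual.
The truncated form makes "a known 3 km decay" well defined: the source
support *is* 3 km, which is what the buffer-selection study must recover.
The air station means are additive-linear in the emission proxy, altitude
and population (`year_effect` switches the altitude term, emulating the
observed between-year contrast), plus an exponential-variogram residual.

What the generator does *not* emulate: real geography (coordinates are
planar km on a synthetic domain; municipality footprints are Voronoi cells
of random seeds), reporting artifacts (varying detection limits across
laboratories and years — a single DL per substance is used), seasonality
within a year, and measurement error structure beyond the nugget. Passing
tests therefore demonstrate method correctness and the claimed comparative
properties under controlled conditions, not performance on any real
national database.

# Multiple imputation of left-censored panels

The panel is reshaped to one row per sampling event with one log-column per
substance; a cubic polynomial of scaled time is appended as fully observed
columns (time trends without an assumed functional form). For each of `m`
bootstrap resamples, an EM algorithm estimates the joint mean and
covariance; censored cells are then drawn from their conditional normal
given the observed cells under the resample's parameters, truncated to
(0, DL]. Eight imputations are the default; five is usually the floor for
stable pooling. Uncensored cells are bit-identical across the `m` panels,
and the across-imputation spread is the imputation-uncertainty diagnostic
carried downstream.

**Censoring-aware E-step.** A plain missing-data EM treats "below DL" as
missing at random. At 82–88% censoring this is badly wrong: missingness is
selection on the response itself, the estimated means drift toward the
observed (upper) tail, conditional predictions pile up near the DL, and the
imputation is *worse* than DL/2 substitution — we measured exactly this
ordering failure on every seed. The E-step here therefore uses the moments
of the conditional normal *truncated at the censoring bound*: exact
univariate truncated-normal moments when one coordinate of a row is
censored (the dominant pattern), and a two-sweep deterministic-Gibbs
approximation (univariate truncation given the current expectations of the
other censored coordinates) when several are censored jointly. With this
E-step the imputation AME is roughly a third of the DL/2 AME at 82%
censoring, reproducing the qualitative ordering the method is known for.

Numerical policies: covariance updates are symmetrized and
ridge-regularized whenever the smallest eigenvalue falls below 1e-6 of the
largest (with a warning); solves against the nearly collinear
time-polynomial block are jittered; truncated-normal draws use inverse-CDF
sampling, switching to a translated-exponential rejection sampler beyond
six standard deviations into the tail. Each bootstrap replicate runs on an
independent seeded substream.

`artificial_censor()` + `evaluate_imputation()` form the validation
harness: a complete panel is thresholded (the threshold becomes the DL),
and AME/RMSE are computed on the originally censored cells only, scoring
the across-imputation mean for multiple imputations.

# Water spatialization

`segment_weights()` assigns each observation the fraction of the analysis
window between the midpoints of its flanking gaps (window edges at the
extremes); weights form a partition of unity by construction.
`unit_mean()` applies them per imputation and pools by the mean, with the
across-imputation sd as uncertainty; pooling at the unit-mean stage rather
than the panel stage is immaterial for the (linear) mean but defines the
uncertainty layer. Municipality concentrations are the population-weighted
means over serving units, normalized per municipality; municipalities with
zero served population are flagged missing. Rasterization assigns each
cell its municipality's value exactly (no smoothing); cells of missing
municipalities carry `mask_missing`, which propagates to the final risk
map as the grey-border overlay.

# The geostatistics engine

No geostatistics library is used: variograms and kriging are implemented in
the package. The empirical variogram is the Matheron estimator on
half-open lag bins \[a, b); model fitting is weighted least squares with
pair-count weights over (nugget, partial sill, range), bounded at zero,
initialized from the empirical curve, for the spherical and exponential
(practical-range) families. The fitting criterion and binning are not
dictated by any source; pair-count WLS is the common default. Recovery
tests use quasi-geometric lag spacing — dense near the origin — because
nugget/range identification degrades badly with coarse equal-width bins.

Ordinary kriging solves the full covariance system with a Lagrange
multiplier (global neighborhood: with n ≤ ~2000 synthetic observations
there is no need for search neighborhoods, which removes a tuning axis).
Exactness at data points, weight normalization (checked as affine
equivariance), and nonnegative kriging variance are asserted in tests
against a hand-assembled small-system oracle. Duplicate coordinates are
averaged with a warning. Anisotropy is not modelled.

Indicator kriging kriges 1{value > DL} and clips to [0, 1]; it *is*
ordinary kriging of the indicator vector before clipping, and a test
asserts that identity. Residual kriging fits a trend (OLS or a seeded
500-tree random forest with permutation importance), kriges the residuals
with a freshly fitted variogram, and adds the two; with a constant trend it
reduces to ordinary kriging (tested). LOOCV refits the trend in every fold
but keeps the residual variogram fixed by default (folds stay comparable;
a refit flag exists).

# Soil mapping decisions

Censoring information enters the soil map through the indicator-kriged
exceedance-probability covariate; the censored observations themselves
enter the value model at DL/2. Nothing in the source material specifies
the substituted value, and the probability covariate is the designed
channel for censoring information, so a simple substitution inside the
trend model is deliberate.

The source proxy sums 1/max(d, d_min) over polluted sites within the
buffer (summing over sites, rather than nearest-site-only, is our choice);
d_min is half a cell width. The buffer radius is selected by AIC of a
Gaussian linear regression of log-concentration on the proxy — AIC needs a
likelihood, so the auxiliary regression, not the random forest, is the
vehicle — adjusted for a few leading soil covariates so trend variance does
not drown the proxy signal. Ties go to the smaller radius.

Covariate selection is backward elimination on permutation importance,
keeping the subset with minimum OOB mean-squared error. The forest is
seeded and single-threaded, making the whole soil stage reproducible.
Predictions are made on the log scale and exponentiated (hence nonnegative
by construction).

# Air mapping decisions

The emission proxy aggregates emission-raster cells within 20 km of each
location, weighted 1/max(d, half-cell). Drift candidates are all subsets
of {proxy, altitude, population} plus the intercept-only fallback,
compared by LOOCV RMSE with a 2% parsimony band: among subsets within 2%
of the best RMSE, the smallest wins. Without the band, irrelevant terms
survive selection roughly half the time at n = 76 (LOOCV RMSE differences
between nested models are noise at that size); with it, the altitude term
is retained in ~100% of simulated years with a real altitude effect and
dropped in ~90% of years without one. Station-type metadata stratifies the
LOOCV report.

Yearly maps are combined cellwise with inverse-RMSE² (inverse-variance)
weights normalized to one — the accuracy-weighting formula is our stated
policy. The validity mask flags cells with altitude above 1800 m AND
population density below 30 persons/km² (density = population raster /
cell area); flagged cells carry `mask_invalid` into the risk map as the
cross-hatch overlay.

# Exposure model

Pathways: drinking-water ingestion, incidental soil ingestion, inhalation,
homegrown-vegetable ingestion, commercial-food ingestion. Dermal uptake,
smoking, and animal-product chains are out of scope. For each pathway,

LADD = C × intake × ED / (BW × LT),

with ED the age-class exposure duration (17 y children, 53 y adults,
summing to the 70 y lifetime), BW body weight, and unit conversions
(ng→mg for air, mg→kg for soil ingestion, g→kg for food intakes).
Homegrown intake is the vegetable intake scaled by the self-consumption
fraction; commercial intake by its complement at spatially constant
commercial concentrations.

The homegrown-vegetable transfer is a deliberately minimal stand-in for a
full multimedia transfer model: C_veg = C_air·v_dep·f_int/(Y·k_w) +
C_soil·BCF, linear in both media. Its parameters, the commercial
concentrations (2 µg/kg across categories, of the order of whole-diet
B[a]P markers), the intake rates and the slope factors (7.3 and 3.9
(mg·kg⁻¹·day⁻¹)⁻¹ for ingestion and inhalation) are package defaults for
demonstration, not values endorsed by any toxicological authority; real
assessments must supply their own configuration. With these defaults the
commercial-food pathway dominates mean contributions (~50–55%), followed
by homegrown vegetables, with water, soil and inhalation in the low
percent range — the qualitative regime such national assessments report.

Risk uses the linear no-threshold form EIR = SF × ΣLADD per route (at
doses of 1e-7–1e-5 mg·kg⁻¹·day⁻¹ the difference from 1−exp(−SF·LADD) is
far below every other uncertainty); total EIR is ingestion + inhalation,
reported ×10⁶. The two age classes are computed independently, never
spliced into a lifetime-weighted composite. Masks are strict: a cell
missing in water or invalid in air is flagged in every dose and risk
output, never silently filled.

# Problem sizes and reproducibility

All randomness flows from one master seed through fixed offsets; reruns of
`run_pipeline()` with the same config are bit-identical (tested). The
simulation studies in the test suite use: 200 units × 13 years (~5200
events) over 20 seeds for the imputation bias ordering; 500 scattered
points × 20 seeds for variogram recovery; a 66×66-cell domain with 16 km
survey spacing (~170 points) × 20 seeds for the RF-vs-linear comparison; a
60×60-cell domain with 6 km spacing (400 points) and 30 sites × 20 seeds
for buffer-radius recovery; 76 stations × 20 seed pairs for drift-term
selection; and a 20×20-cell full-pipeline scenario with m = 5. These sizes
were chosen once, as the smallest designs with adequate statistical power
for the respective recovery questions.

# Known limitations

* The deterministic-Gibbs truncation used when all substances of an event
  are censored slightly underestimates within-row cross-covariance; with
  two substances and ≤90% censoring the effect is not detectable in the
  bias harness.
* Variogram fitting is WLS, not REML; at very small n (< ~50 points) the
  range is weakly identified, and the residual-variogram fallback (pure
  nugget at the residual variance) takes over.
* The exceedance-probability covariate is used as a point estimate;
  its own kriging variance is not propagated into the soil map.
* Exposure uncertainty carries the water imputation spread only; kriging
  variances of soil and air are reported in diagnostics but not composed
  into the risk layer.
* GeoTIFF I/O is intentionally absent; rasters are serialized as
  plain-text CSV with explicit masks and cell geometry.
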