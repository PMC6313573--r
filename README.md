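# geoexpose

Mapping population exposure to an environmental carcinogen — benzo[a]pyrene
(B[a]P), the conventional indicator PAH — from sparse, heavily left-censored
monitoring data in three media: drinking water, topsoil and ambient air.
The package is written for environmental-health and geostatistics
practitioners who need a complete, testable chain from raw monitoring
panels to mapped risk indicators on a 3 × 3 km reference grid, together
with a synthetic-scenario generator that stands in for the closed national
databases such analyses are normally built on.

## What it computes

**Censored-panel imputation.** Water panels with 80–90% of records below
the detection limit (DL) are completed by bootstrap-EM multiple
imputation: the panel is modelled as a multivariate normal on log
concentrations (one column per co-measured substance, plus a cubic time
polynomial); for each of *m* bootstrap resamples EM estimates the joint
moments with a censoring-aware E-step (truncated-normal conditional
moments), and censored cells are drawn from their conditional
distribution truncated to (0, DL]. Naive DL/2 and DL/√2 substitution are
provided as baselines, with an artificial-censoring harness that scores
AME and RMSE on cells whose truth is known.

**Water spatialization.** Multi-annual unit means use segments-of-influence
weights (each observation owns the window fraction between the midpoints
of its flanking gaps); the distribution network aggregates unit means to
municipalities weighted by served population; municipalities map onto grid
cells exactly, with a missing-data mask and an across-imputation
uncertainty layer.

**Geostatistics engine.** Matheron empirical variograms, pair-count-WLS
fitting of spherical/exponential models, global-neighborhood ordinary
kriging (BLUP, weights summing to 1), indicator kriging of DL exceedance
(clipped to [0,1]), residual kriging with linear or random-forest trends,
and leave-one-out cross-validation with per-station-type breakdowns.

**Soil and air mapping.** Soil: exceedance-probability covariate from
indicator kriging, inverse-distance source proxy around polluted sites
with AIC-selected buffer radius, out-of-bag backward covariate selection,
random-forest residual kriging (spherical variogram). Air: emission proxy
disaggregated in a 20 km buffer, drift-term selection among
{emissions, altitude, population} by LOOCV with a parsimony band,
exponential-variogram regression kriging, inverse-RMSE² combination of two
monitoring years, and a validity mask (altitude > 1800 m and density
< 30 persons/km²).

**Exposure model.** Per-pathway Lifetime Average Daily Doses

    LADD = C · intake · ED / (BW · 70 y)        [mg·kg⁻¹·day⁻¹]

for drinking water, soil ingestion, inhalation, homegrown vegetables (via
a simplified air-deposition + root-uptake transfer) and commercial food,
for children (0–17 y) and adults (17–70 y); Excess Individual Risk
EIR = SF·ΣLADD per route, totalled over ingestion and inhalation and
reported ×10⁶, with strict mask propagation into the final maps.

## Worked example

```r
library(geoexpose)

cfg <- scenario_config(grid_nx = 20, grid_ny = 20, cell_size_km = 3,
                       n_units = 60, n_municipalities = 40,
                       n_stations = 50, n_polluted_sites = 8,
                       soil_spacing_km = 6, seed = 42)
run <- run_pipeline(cfg, m = 5, num_trees = 200)

run$manifest$water_censoring   # realized water censoring rate
#> [1] 0.8776202
run$manifest$soil_radius_km    # AIC-selected source-buffer radius (truth: 3)
#> [1] 3
run$exposure$adult_17_70$contributions
#>           pathway mean_share
#> 1           water 0.02224585
#> 2            soil 0.02461012
#> 3  air_inhalation 0.01619000
#> 4   homegrown_veg 0.38974930
#> 5 commercial_food 0.54720472

render_risk_map(run$exposure$adult_17_70$eir$total, "risk.png")
```

The panel came out 87.8% censored (the generator's target regime); the
buffer selection recovered the generator's 3 km source decay; and the
pathway table shows the commercial-food pathway dominating mean
contributions (~55%), with homegrown vegetables second and water, soil and
inhalation in the low percent range. The rendered map draws total EIR
(×10⁶) with grey borders where water data are missing and a cross-hatch
where the air estimate is outside its validity limits.

The `analysis/` directory holds the same workflow as numbered narrative
drivers (`01_simulate.R` … `06_exposure.R`), each writing its tables and
rasters under `results/`; run them from the repository root, e.g.
`Rscript analysis/02_imputation_bias.R`.

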