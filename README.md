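# kelpDSWT

Quantifies how **dense shelf water transport (DSWT)** exports negatively
buoyant kelp detritus past the continental shelf edge. In cold months a band
of cooler, denser water forms along the coast; when the water column is
stratified and wind does not mix it away, the resulting gravitational
circulation drives offshore flow along the seabed — an effective conveyor
for sinking detritus (golden kelp, *Ecklonia radiata*) that otherwise rides
alongshore currents indefinitely. The package is aimed at coastal
oceanographers and blue-carbon researchers who want the full analysis chain
as tested, reusable functions.

## What it computes

* **Synthetic shelf scenarios** (`shelf_config()`, `make_bathymetry()`,
  `make_forcing()`, `make_kelp_probability()`): an idealized mid-latitude
  shelf channel with a seasonal cross-shore density gradient, square-wave
  DSWT pulses (~0.15 m/s offshore bottom flow) in stratified cold-season
  windows, seabreeze/storm wind regimes and a depth-limited kelp
  probability map — all reproducible from one seed, written/read as
  CF-style NetCDF (`write_fields_nc()` / `load_fields()`).
* **DSWT suitability** (`classify_dswt()`): per-snapshot test of the three
  conditions
  `suitable = (∂ρ/∂x < 0) & (φ > 5 J/m³) & (gravitational > wind mixing | onshore wind)`,
  where φ is the potential energy anomaly
  `φ = (1/h) ∫ (ρ̄ − ρ) g z dz` and the mixing criterion compares
  `(1/320) g²h⁴/(ρ K_mz) (∂ρ/∂x)²` against `δ κ_s ρ_a W³/h` with
  `κ_s = 0.03(0.63 + 0.066 W^{1/3})/1000`.
* **Release scheduling** (`build_schedule()`): a particle budget spread over
  the year by a monthly detrital-production curve (largest-remainder, exact
  budget) and placed probability-proportionally on kelp cells.
* **Bottom-layer particle tracking** (`advect()`): classical RK4 advection
  of the bilinearly interpolated bottom velocity plus a Brownian walk with
  `K_h = 10 m²/s` (per-axis s.d. `√(2 K_h dt)`), with beaching,
  open-boundary handling, optional threshold-velocity gating
  (`v_crit = 0.045 m/s`) and an optional log-profile velocity correction.
* **Export accounting** (`first_crossing()`, `decayed_export()`,
  `monthly_export()`, `pixel_contribution()`,
  `export_suitability_correlation()`): shelf-edge (200 m) crossings,
  export-vs-age curves for the 200–1000 m levels, decay weighting
  `P(t) = e^{−kt}` with `k = 0.075 ± 0.031 /day` (half-life 9.2 d), monthly
  decomposition, per-reef per-mille attribution, and the Pearson
  correlation between monthly export and monthly DSWT suitability.
* **Carbon budget** (`areal_carbon_export()`): converts an exported
  fraction into Mg C per hectare of kelp forest per year.

`run_pipeline()` chains all stages under one seed; the numbered scripts in
`analysis/` run the same stages as a file-based workflow writing into
`results/`.

## Worked example

```r
library(kelpDSWT)
run <- run_pipeline(cfg = shelf_config(), n_particles = 10000, seed = 1)
print(run)
#> <dswt_run>
#>   released 10000 particles (seed 1)
#>   export past 200 m: 66.8% undecayed, 42.0% decayed (35.4-50.4%)
#>   export-suitability Pearson r = 0.95 (p = 2.9e-06)
#>   carbon: 1.25 (1.05-1.50) Mg C/ha/yr
```

Reading: of 10,000 particles released over the year in proportion to kelp
probability and seasonal detrital production, 66.8% eventually crossed the
200 m shelf edge; weighting each crossing by exponential decomposition over
its transit age leaves 42.0% of the released mass exported (35.4–50.4% for
the decay rate ± one s.d.). Monthly decayed export tracks the monthly
percentage of time with DSWT-suitable conditions at r = 0.95 — export on
this synthetic shelf happens almost entirely through the cold-season DSWT
windows (warm-season share ≈ 0.01%) — and the simulated decayed fraction
corresponds to 1.25 Mg C/ha/yr for default kelp-forest parameters. With the
17–29% export range reported for real shelf studies, the same arithmetic
gives 0.50–0.86 Mg C/ha/yr.

Individual stages work standalone, e.g.:

```r
cfg   <- shelf_config()
bathy <- make_bathymetry(cfg)
flds  <- make_forcing(cfg, bathy)
states <- classify_dswt(flds)
monthly_suitability(states)      # percent of time suitable, per month
```

## Layout

```
R/                  package code (scenario, grid I/O + interpolation, DSWT
                    classifier, release scheduler, tracker, export
                    accounting, carbon budget, pipeline)
analysis/01..06     numbered workflow drivers writing into results/
scripts/acceptance.R  headline-quantity reproduction
tests/testthat/     unit, property and end-to-end tests
vignettes/          methods vignette (model, assumptions, parameters)
```
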