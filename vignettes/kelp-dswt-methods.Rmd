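---
title: "Modelling cross-shelf export of sinking kelp detritus by dense shelf water transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cross-shelf export of sinking kelp detritus by dense shelf water transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Kelp forests release most of the carbon they fix as particulate detritus.
For that carbon to be sequestered it must cross the continental shelf and
sink below the depth of exchange with surface waters — in this framework,
past the 200 m isobath that defines the shelf edge. Alongshore currents
dominate coastal flow, so the question is which *cross*-shelf mechanism can
carry negatively buoyant detritus (golden kelp, *Ecklonia radiata*, sinks
and travels along the seabed) off the shelf before it decomposes.

Dense shelf water transport (DSWT) is the candidate mechanism this package
models: in the cold season, differential heat loss leaves a band of cooler,
denser water along the coast; when the water column is stratified and winds
do not mix it away, that density contrast drives a gravitational circulation
with offshore flow along the seabed. `kelpDSWT` implements the full chain —
synthetic shelf forcing, DSWT suitability classification, bottom-layer
Lagrangian particle tracking, decay-weighted export accounting, and an areal
carbon-flux conversion — as testable, reusable functions, with numbered
drivers under `analysis/` as the narrative workflow.

## The DSWT suitability criterion

A forcing snapshot is classified *suitable* for DSWT
(`classify_dswt()`) when three conditions hold:

1. **Negative cross-shore density gradient.** Bottom density must increase
   towards the coast: $\partial\rho/\partial x < 0$ with $x$ positive
   offshore. The gradient is estimated as the ordinary-least-squares slope
   of bottom density against offshore distance along each coast-to-edge
   transect, averaged over alongshore rows. OLS is a choice — the criterion
   only requires a sign — but it is deterministic, testable against the
   normal equations, and robust to cell-level noise.

2. **Stratification.** The potential energy anomaly
   $$\phi = \frac{1}{h}\int_{-h}^{0}(\bar\rho - \rho)\,g\,z\,\mathrm{d}z,
   \qquad \bar\rho = \frac{1}{h}\int_{-h}^0 \rho\,\mathrm{d}z,$$
   the energy per unit volume needed to mix the column ($\mathrm{J/m^3}$),
   must exceed 5 J/m³ as a *region mean* over the shelf (wet cells
   shallower than 200 m). The regional-mean threshold, rather than a
   per-cell one, reflects that suitability is judged for the shelf as a
   whole; 5 J/m³ is the configurable default in `dswt_constants()`.

3. **Gravitational circulation beats wind mixing.** The stratifying
   tendency of the gravitational circulation must exceed the destratifying
   tendency of the wind,
   $$\frac{1}{320}\frac{g^2 h^4}{\rho K_{mz}}
     \Big(\frac{\partial\rho}{\partial x}\Big)^2
     \;>\; \delta\,\kappa_s\,\rho_a \frac{W^3}{h},$$
   with vertical eddy diffusivity $K_{mz} = 10^{-2}\,\mathrm{m^2/s}$,
   mixing efficiency $\delta = 3\times10^{-3}$, air density
   $\rho_a = 1.2\,\mathrm{kg/m^3}$, and drag coefficient
   $\kappa_s = 0.03\,(0.63 + 0.066\,W^{1/3})/1000$ — evaluated with
   region-mean depth, density and wind speed. Onshore wind (direction-from
   within 225–315°, bounds inclusive since the interval is stated without
   open/closed qualification) *overrides* this condition: onshore storms
   reinforce rather than destroy the coastal density wedge.

Combined: `suitable = gradient & stratified & (mixing | onshore)`. Tidal
mixing is omitted (microtidal setting) and salinity-driven gradients are
out of scope — temperature drives the density contrast here.

### Numerical note on the PEA integral

Density profiles are supplied as layer samples and treated as piecewise
linear in $z$. The integrand $(\bar\rho-\rho)\,g\,z$ is then quadratic on
each segment, so the integral is closed exactly by a per-segment
three-point rule; $\bar\rho$ itself comes from the (exact) trapezoid. This
makes the two analytic anchors — $\phi = g\,\Delta\rho\,h/8$ for a
two-layer column (encode the interface as a duplicated sample) and
$g\,\Delta\rho\,h/12$ for a linear profile — hold to machine precision at
any layer count, rather than to the $O(1/n^2)$ accuracy of a plain
product-trapezoid. Within the synthetic scenarios the water column is
linearly stratified between a surface and a bottom density, so the
`field_series` stores that pair per cell instead of a full
`(time, y, x, layer)` profile block; the layer expansion is performed where
the integral is taken. Real profile data can still be fed to
`potential_energy_anomaly()` sample-by-sample.

## The synthetic shelf

`shelf_config()` defines the study conditions; its defaults are fixed and
are what every test and the acceptance script use.

* **Geometry.** A local Cartesian frame, $x$ offshore and $y$ alongshore,
  60 × 30 km with 2 km spacing. Depth is piecewise linear: 0 at the coast,
  50 m at 20 km (gentle inner shelf), 200 m at 40 km (the shelf edge),
  1200 m at the open boundary — the canonical mid-latitude profile of a
  narrow shelf that steepens past 50 m. The coast column is land. The
  alongshore axis is **periodic** (an idealized channel): with a 30 km open
  channel most particles would exit alongshore, an artifact of the finite
  domain rather than of shelf physics, and the forcing is
  alongshore-uniform anyway.
* **Seasons.** Months are tagged warm (Nov–Mar), transition (Apr, Sep,
  Oct) and cold (May–Aug), austral-style.
* **Density.** Bottom density has a seasonal cross-shore gradient:
  $-10^{-5}\,\mathrm{kg/m^4}$ (0.4 kg/m³ denser at the coast over the
  40 km shelf) outside the warm season, $+10^{-5}$ within it. During pulse
  windows the column is stratified (surface 0.3 kg/m³ lighter,
  region-mean $\phi \approx 18$ J/m³); otherwise near-mixed
  (0.05 kg/m³, $\phi \approx 3$ J/m³ — below threshold).
* **DSWT pulses.** Square-wave events (`dswt_event_windows()`): in cold
  windows ~3 days on / ~2 days off (≈60 % occupancy, the winter suitability
  plateau); in transition windows the gap stretches to ~12 days (≈20 %).
  Durations and gaps are jittered ±20 % under the scenario seed. During a
  pulse the offshore bottom speed is 0.15 m/s over the shelf — the typical
  cold-season cross-shelf bottom speed of an active cascade — continuing at
  70 % seaward of the edge (the cascade running downslope). Warm-season
  bottom flow is 0.02 m/s *onshore*, the interior return flow under
  upwelling-favourable seabreezes. An alongshore current of 0.1 m/s runs
  year-round, and cell-level Gaussian noise (0.005 m/s, 0.002 kg/m³) roughs
  up the fields.
* **Wind.** Warm season: a diurnal seabreeze from the south peaking at
  12 m/s. Cold/transition: 15 m/s onshore (270°) storms occupying the
  first half of each inter-pulse gap, 7 m/s background otherwise.
* **Kelp.** Occurrence probability $e^{-\mathrm{depth}/30\,\mathrm{m}}$,
  zero on land and beyond 50 m — kelp reefs thin with depth and end at the
  deepest reefs.
* **Production.** The monthly detrital-production curve (relative units
  `0.3, 0.35, 1.0, 1.0, 1.0, 0.8, 0.8, 0.7, 0.45, 0.35, 0.3, 0.3`) encodes
  the described seasonality — production rising from March, peaking
  March–May, elevated through August, low over summer. The exact values are
  configuration, documented as an approximation; a monthly step function is
  used because a smoothed daily curve is not identifiable from a seasonal
  description.

What the generator deliberately does **not** emulate: realistic topography
(canyons, islands), boundary currents and eddies, tides, 3-D sigma-layer
physics, or resuspension. Passing tests therefore demonstrate that the
*pipeline* — classification, tracking, accounting — behaves correctly under
controlled forcing with known ground truth, not that any particular real
shelf exports a particular fraction.

## Release scheduling

`build_schedule()` apportions the particle budget (default 10,000; each
particle is an equal quantum of detrital mass) over days of the release
year by the largest-remainder method — deterministic, budget-exact, ties to
the earliest date — with daily weights from the production curve. Positions
are drawn with probability proportional to the kelp raster, uniform within
the chosen cell. Chi-square tests confirm the empirical release density
converges to the raster.

## Particle tracking

`advect()` moves every particle with classical fourth-order Runge–Kutta
advection on the bottom velocity field (bilinear in space with
wet-cell-only weight renormalization next to land, linear in time between
snapshots) plus an uncorrelated Gaussian random walk with per-axis standard
deviation $\sqrt{2 K_h \Delta t}$, applied after the RK4 displacement.
Defaults: $\Delta t = 900$ s against 3-hourly forcing snapshots (stable
sub-sampling of a 2 km grid at ≤ 0.3 m/s), $K_h = 10\,\mathrm{m^2/s}$.
The diffusivity is diffusivity-dimensioned ($\mathrm{m^2/s}$); sources
that print it as "m/s²" are dimensionally inconsistent for a random walk
and are read as $\mathrm{m^2/s}$.

Fates are one-way: a step that would land on land (or cross the coast)
**beaches** the particle at its last wet position — there is no refloating,
which makes export estimates conservative; depth beyond `stop_depth`
(1100 m, past the deepest 1000 m accounting level) **deactivates** it as
exported; leaving the open offshore boundary marks it **out-of-domain**
(such particles count as exported only if the record shows they crossed the
edge first). Conservation — released = active + beached + exported +
out-of-domain — is asserted exactly.

Two sensitivity switches are off by default, mirroring the baseline
configuration they were found not to change materially:

* **Threshold velocity** `v_crit` (0.045 m/s for small fragments): below
  it the particle rests on the seabed. The gate suppresses diffusion too —
  a resting particle does not random-walk — with `gate_diffusion = FALSE`
  available to gate advection only.
* **Log-profile correction**: rescales the bottom-layer velocity from
  mid-layer height to a target height above the bed by
  $\ln(z_t/z_0)/\ln(z_m/z_0)$. Reference heights and roughness are not
  pinned by any source here; defaults (layer 10 m, target 1 m,
  $z_0 = 1$ mm) are documented configuration.

Positions are recorded every `record_dt` (default daily) with each
particle's final position and time kept exactly; crossing ages are thus
resolved to the record interval, which at one day is fine relative to the
9.2-day decay half-life.

## Export accounting

A particle crosses a depth level when the bilinearly interpolated
bathymetry at its position first reaches the level — a definition that
works identically on any grid and needs no contour polylines. Per level
(200–1000 m by 200), `export_fraction_vs_age()` gives cumulative export
fractions; deeper levels are pointwise contained in shallower ones.

Decay is a **post-processing weight**, never particle removal: an exported
particle contributes $e^{-k\,a}$ of its released mass, with $a$ the age at
first crossing of the 200 m edge and $k = 0.075 \pm 0.031\,/\mathrm{day}$
(`decay_model()`; half-life $\ln 2/k = 9.24$ d). The uncertainty band
re-evaluates the weights at $k \mp \sigma_k$. No decay is applied beyond
the 200 m crossing, because decomposition rates below shelf depths are not
constrained by the shallow-water measurements the default rate comes from.

Monthly export attributes each particle's decayed mass to its **crossing**
month (release-month attribution is a toggle); the monthly percentages sum
exactly to the annual decayed percentage. Per-pixel attribution groups
decayed exported mass by release cell, in per mille of the total released
mass, so the raster sums to 1000 × the annual decayed fraction.
`export_suitability_correlation()` is the sample Pearson correlation of
monthly decayed export against monthly suitability, with the two-sided
p-value from the $t$-transform on $n-2$ degrees of freedom.

## Carbon budget

`areal_carbon_export()` multiplies detrital production
(2.15 g FW kelp⁻¹ day⁻¹) × kelp density (6.3 m⁻²) × fresh-to-dry (0.20)
× carbon content (0.30) × 365 days × 10⁴ m²/ha × exported fraction,
g → Mg. A 365-day year reproduces the standard 0.50–0.86 Mg C ha⁻¹ yr⁻¹
range from the 17–29 % export interval; the pipeline also reports the flux
implied by its own simulated decayed export band.

## Problem sizes and determinism

The default experiment is one release year (2017, a 13-month forcing span
so December releases can still transit), 3168 forcing snapshots on a
31 × 16 grid, 10,000 particles at a 900 s step — about a minute of
compute — used by both the end-to-end tests and `scripts/acceptance.R`.
One master seed drives everything: the scenario uses `seed`, the release
sampler `seed + 1`, the random walk `seed + 2`; reruns are bit-identical,
and with $K_h = 0$ trajectories are seed-independent. Generator functions
save and restore the global RNG state, so library calls do not perturb a
user's session.

## Known limitations

* The synthetic shelf is statistically, not dynamically, realistic: pulses
  are imposed, not emergent, so the export–suitability correlation tests
  the accounting chain, not ocean physics.
* Beached particles never refloat; retention in reef structure, burial and
  dissolved organic carbon pathways are out of scope.
* The tracker is 2-D in the bottom layer: no sinking-speed model, no
  vertical shear beyond the optional log-profile factor, no tides or waves.
* Curvilinear-grid support is read-only and synthetic tests stay
  rectilinear; geographic (lon/lat) handling is limited to what
  `load_fields()`'s variable mapping provides.
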