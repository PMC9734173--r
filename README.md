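# larvalconn

Biophysical simulation of reef-fish larval dispersal and inter-region
connectivity on an idealized, climate-index-forced shelf sea, with the
statistics used to link connectivity to the El Niño Southern Oscillation
(ENSO).

## Who this is for

Marine ecologists and biophysical modellers who want a fully testable,
single-machine implementation of the classic larval-connectivity pipeline:
gridded currents → Lagrangian particle tracking → mortality and
sensory-zone settlement → annual connectivity matrices → temporal and
climate-linkage statistics. The hydrodynamics are synthetic (an
ENSO-index-forced jet with tides, cross-shelf intrusions and stochastic
eddies), so the whole study runs from a seed in minutes; real reef
geometry and velocity fields can be supplied through the file interfaces.

## The model in brief

- **Forcing.** Hourly currents on a 96 × 600 km shelf grid,
  `v = s_d r(x) [ (v₀ + γI) p(x) + A_T sin(2πt/T) + v_eddy ]`, where `I`
  is the yearly Southern Oscillation Index (SOI) mean. With `γ > 0` the
  along-shelf flow is poleward for weak/negative SOI (El Niño) and
  reverses equatorward above `I = −v₀/γ = +10` (very strong La Niña); a
  shoreward intrusion grows with `|I|`. Eddies come from a seeded,
  divergence-free streamfunction.
- **Larvae.** 141 seed cells in 29 latitude-ordered regions (inshore and
  offshore bands, three sectors); releases October–December; classical
  RK4 advection (compiled core) with depth-by-age behaviour (day 1 at
  1 m, days 2–20 at 3 m, days 21–25 at 6 m) over a 25-day pelagic larval
  duration; 18 %/day pelagic mortality as multiplicative weights; 4 km
  reef sensory zones; 13 % settlement mortality.
- **Statistics.** Annual 29×29 matrices `C[i,j]` = P(spawned in *i*
  settles in *j*), retention on the diagonal; mean, per-cell CV
  (sd/mean) and anomaly matrices across years; directional
  (poleward/equatorward/across-shelf) means from central–southern
  sources regressed on the SOI (linear, linear, quadratic); mean-vs-CV
  exponential-decay fit `mean = a·exp(−b·CV)`.

The packaged 2010–2017 monthly SOI (Oct–Jan per dispersal year) drives
the eight study seasons; yearly means span −13.6 (strong 2015 El Niño)
to +20.4 (very strong 2010 La Niña).

## Worked example

```r
library(larvalconn)
cfg <- study_config(rate = 2, seed = 1)  # desk-scale release rate
st  <- run_study(cfg, verbose = FALSE)
summary(st)
```

```
Per-year directional connectivity (sources: central/southern minus southernmost exclusions):
 year index_mean mean_poleward mean_equatorward mean_across_shelf
 2010     20.425      0.00e+00         2.83e-04          5.13e-04
 2011     13.375      3.38e-06         1.05e-04          4.02e-04
 2012     -0.200      1.02e-03         0.00e+00          5.71e-05
 2013      5.025      4.55e-04         2.85e-05          1.52e-04
 2014     -7.825      9.78e-04         0.00e+00          2.11e-04
 2015    -13.575      7.52e-04         0.00e+00          2.78e-04
 2016     -0.275      9.01e-04         2.00e-06          7.55e-05
 2017      7.100      2.65e-04         1.94e-05          2.02e-04
 ...
Regressions on the yearly index mean:
  poleward      linear     r^2 = 0.70, p = 0.00975
  equatorward   linear     r^2 = 0.65, p = 0.015
  across_shelf  quadratic  r^2 = 0.90, p = 0.00344
  mean vs CV    exp decay  r^2 = 0.60 (Spearman rho = -0.74)
CV of realized connections: 0.68-2.83, median 1.92
```

Reading it: poleward transport dominates in El Niño and neutral years
(e.g. 2014/2015: 100 % of realized along-shelf connections poleward) and
collapses in the very strong 2010 La Niña, when the flow reverses and
equatorward connectivity peaks — the poleward mean falls with the SOI
(negative slope, r² = 0.70) while the equatorward mean rises (r² = 0.65).
Across-shelf connectivity is strongest at both SOI extremes (convex
quadratic, r² = 0.90). Strong connections are temporally steady: mean
connectivity decays exponentially with CV (r² = 0.60, Spearman ρ =
−0.74). Connection-level CVs reach 2.83 = √8, the bound attained by a
connection realized in a single year of eight.

Individual stages are exposed as functions (`generate_domain()`,
`generate_velocity_field()`, `track_particles()`, `settlement_records()`,
`build_connectivity_matrix()`, `directional_summary()`, …) and every
object has print/summary/plot methods; see the methods vignette
(`vignettes/larval-connectivity-methods.Rmd`) for the model's assumptions
and design decisions.

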