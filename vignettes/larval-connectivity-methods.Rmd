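---
title: "Methods: simulating ENSO-driven larval connectivity on an idealized shelf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating ENSO-driven larval connectivity on an idealized shelf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvalconn)
```

## The scientific problem

Coral-reef fish populations are connected by pelagic larvae drifting on
shelf currents for a few weeks before settling. On a shelf sea bordering a
western-boundary-current system, interannual variability of the along-shelf
flow is dominated by the El Niño Southern Oscillation (ENSO): El Niño
(strongly negative Southern Oscillation Index, SOI) conditions favour
poleward transport, while very strong La Niña conditions (large positive
SOI) can reverse the predominant flow equatorward. `larvalconn` simulates
this system end to end — ocean forcing, Lagrangian larval transport, larval
mortality and settlement, and the connectivity statistics used to quantify
ENSO linkage — so that every step of the analysis is testable against
closed-form oracles and the headline climate-connectivity relationships can
be recovered from first principles.

The package deliberately replaces the data-assimilating hydrodynamic
reanalysis such a study would use in production with a *synthetic ocean*
whose statistical structure carries exactly the features the analysis
relies on. That makes the whole study reproducible on one CPU in minutes,
at the cost of numeric fidelity to any real coastline (see *What the
synthetic ocean does not emulate*).

## The idealized shelf and its regions

Coordinates are local Cartesian kilometres: `x` across-shelf (the coast is
a land strip at low `x`), `y` along-shelf, increasing northward. The study
area is Southern-Hemisphere-like, so *poleward* means southward
(decreasing `y`) and *equatorward* northward. The default domain is a
96 x 600 km shelf on an 8 km grid with 29 reef regions in three
latitudinal sectors (9 northern, 10 central, 10 southern), alternating
between an inshore band (12-28 km offshore) and an offshore band
(48-88 km, representing mid- to outer-shelf reefs). Regions are strictly
ordered north to south by `latitude_rank`; each holds 4-5 square 4-km
reefs (141 in total), and each reef carries one release (seed) cell.

```{r domain}
dom <- generate_domain(domain_config(), seed = 1)
dom
```

## The climate-index-forced flow model

Hourly currents at the three behavioural depth layers are generated as

$$v(x,y,t) = s_d\, r(x)\left[(v_0 + \gamma I)\,p(x) +
  A_T \sin(2\pi t/T) + v_{\mathrm{eddy}}\right], \qquad
u(x,y,t) = s_d\, r(x)\left[-\eta\,|I|\,q(x) + u_{\mathrm{eddy}}\right],$$

where $I$ is the yearly SOI mean, $r$ a coastal taper, $p$ a mid-shelf jet
profile, $q$ an intrusion profile growing offshore, $A_T\sin(2\pi t/T)$ an
M2-period tide, and $s_d$ a per-layer shear factor (surface amplified:
1.15 / 1.00 / 0.85 at 1 / 3 / 6 m). The eddy term is the curl of a
streamfunction built from 12 travelling sinusoidal modes (wavelengths
40-150 km, periods 5-20 days), so it is divergence-free, spatially and
temporally correlated, and reproducible under a seed. Because the eddy
realization does not depend on $I$, the domain-mean along-shelf velocity is
exactly linear — hence monotone — in the index, a property the test suite
asserts.

Two defaults deserve justification:

* **Jet amplitude and sensitivity** (`jet_v0 = -0.025` m/s,
  `jet_gamma = 0.0025` m/s per SOI unit). The flow reverses at
  $I = -v_0/\gamma = +10$: predominantly poleward in all but very strong
  La Niña seasons, as observed in the real system. Over the observed index
  range ($-13.6$ to $+20.4$) mean 25-day displacements span roughly 20-130
  km — one to six region spacings — and eddy transport contributes a
  comparable spread. We chose this scale, rather than one matching the
  longest real-world connection distances (several hundred km), because on
  a 600-km shelf with 20-km region spacing a faster jet *saturates* the
  directional statistics: nearly every year connects every poleward pair,
  and the directional means respond to the index as a step function rather
  than the graded response the regression analysis is designed to detect.
* **Eddy amplitude** (`eddy_amp = 0.07` m/s, comparable to the jet at
  extreme index values). This keeps both transport directions realized in
  most years — as in the real system, where poleward shares of along-shelf
  connections vary between roughly 50% and 80% rather than hitting 0 or
  100 — while leaving the index signal clearly detectable across seeds.

The season window is 123 days (releases 1 October - 31 December, tracking
through 31 January), hourly, matching a spring-summer spawning season plus
a 25-day pelagic larval duration (PLD).

## Particle tracking

Particles are released at 100 per cell per day in the full study design
(reduced in desk runs; connectivity is a per-release probability, so its
expectation is rate-invariant), spread within each 4-km seed cell by a
deterministic low-discrepancy sequence — so zero-diffusion runs are
RNG-free and seed-independent. Advection uses the classical fourth-order
Runge-Kutta scheme on velocities interpolated bilinearly in space and
linearly in time, with a 0.5 h step against hourly fields (the step
resolves the 12.42 h tide; halving it further changes end positions at the
$O(\Delta t^4)$ level, which the convergence test quantifies). The depth
layer follows age: day 1 at 1 m, days 2-20 at 3 m, days 21-25 at 6 m.
Depth is purely behavioural — there is no vertical advection.

Boundary handling: velocities are zero on land and interpolation tapers to
zero approaching the coast, so particles stall rather than beach; a step
that would put a particle on a land cell is undone. Particles crossing the
open (offshore or along-shelf) boundary are flagged `lost` and excluded
downstream, consistent with excluding non-settlers. Horizontal diffusion
defaults to zero (the stochastic eddies provide dispersion); an optional
constant-diffusivity random walk of per-axis standard deviation
$\sqrt{2K\Delta t}$ is available.

The inner loop is compiled (Rcpp); a pure-R reference tracker and the
single-step `rk4_step()` are kept as an independent oracle and verified
against the compiled path step by step.

## Larval biology

Pelagic mortality (18 %/day) is applied as a deterministic per-particle
weight $(1-m)^{\mathrm{age}}$ rather than stochastic removal: identical in
expectation, far lower Monte-Carlo variance at desk scale. The
Bernoulli-thinning counterpart (`simulate_survival()`) is provided and
tested to agree within sampling error. Settlement uses 4-km *sensory
zones* around each reef, represented exactly as distance-to-rectangle
buffers; a larva settles at its first recorded state (at age at or above
the competency age) inside any zone, to the reef with the nearest
boundary (lower reef id on ties), with weight
$(1-m)^{\mathrm{age}} \times (1 - 0.13)$ for the 13% settlement-predation
mortality. Survival is evaluated at contact age, not fixed at the full
PLD; both this and stochastic-removal mortality are switchable.

One default is a genuine design decision: the operation-level competency
age is 0 (the most literal "first contact" reading), but release cells sit
inside their own reef's sensory zone, so a study run with competency 0
settles every larva instantly at its source. The study configuration
therefore defaults `competency_start = 20` days — larvae become competent
when they descend to the 6 m layer for days 21-25 — which realizes the
"reached the sensory zones by the end of the pelagic larval duration"
behaviour while leaving the literal rule available for trajectory-level
analysis.

## Connectivity statistics

The annual connectivity matrix entry $C_{ij}$ is the summed settled weight
from region $i$ to region $j$ divided by the number of particles
*released* from $i$ (mortality therefore depresses probabilities; a
settler-conditioned mode exists). The diagonal is larval retention. With
default mortality, row sums are bounded by 0.87. Across the eight annual
matrices the package derives the elementwise mean, the per-cell
coefficient of variation CV = sd/mean (sample sd, $n-1$, appropriate for
an 8-year sample; zero-mean cells are masked, not 0 or Inf), and per-year
anomaly matrices (annual minus mean, whose per-cell sums vanish by
construction) with sign classifications.

Directional analysis classifies each source-sink pair as retention,
poleward, equatorward (same band, by latitude rank), across-shelf
(offshore to inshore) or inshore-to-offshore (reported, but excluded from
the three directional metrics). Directional means average $C_{ij}$ over
each class with sources restricted to the central and southern sectors
minus the two southernmost regions (whose directionality differs, being at
the domain edge); the poleward share counts realized (nonzero) poleward
cells against realized along-shelf cells, so poleward and equatorward
shares are complementary. Poleward and equatorward means are regressed
linearly on the yearly SOI mean; the across-shelf mean quadratically
(capturing intensified shoreward intrusion at both index extremes); and
mean connectivity is fitted against CV as $a\,e^{-b\,\mathrm{CV}}$ by
nonlinear least squares seeded from a log-linear fit, with $r^2$ reported
on the original scale.

## A worked desk-scale run

The full-scale acceptance run (rate 5, 8 years, ~520k particles) takes a
few minutes; here is a reduced configuration with the same structure:

```{r study, eval = FALSE}
cfg <- study_config(rate = 2, seed = 1)
st <- run_study(cfg, verbose = FALSE)
summary(st)
```

At rate 5 and seed 1 the 8-year study yields a negative poleward-vs-SOI
slope with $r^2 = 0.70$, a positive equatorward slope with $r^2 = 0.65$, a
convex across-shelf response ($r^2 = 0.90$), poleward shares of 100% in
both El Niño years with the equatorward share maximal in 2010, a
mean-vs-CV decay $r^2 = 0.60$ with Spearman $\rho = -0.75$, and realized
CVs of 0.68-2.83 (median 1.95). These are the numbers
`scripts/acceptance.R` recomputes; run it to regenerate them under any
seed.

## Numerical choices, degenerate inputs, tie-breaks

* Interpolation is exact at grid nodes and snapshot times; queries outside
  the grid hull or time span are errors (in bulk tracking, a stage outside
  the hull marks the particle lost).
* Depth-layer switching happens at the step following the age threshold —
  no mid-step blending.
* Overlapping sensory zones resolve by nearest reef boundary, then lower
  reef id; the tie-break is deterministic and geometry-driven.
* All-zero connectivity series yield masked (NA) CVs; single-year stacks
  refuse CV/anomaly computation; a single-year `run_study()` logs that the
  stage was skipped.
* The constant-mean degenerate case of the decay fit returns $b = 0$ with
  an undefined $r^2$ rather than failing.
* Per-year RNG substreams are derived from the master seed
  (`master * 1009 + 101 * year_index`, mod $2^{31}-1$), so years are
  independently reproducible.

## What the synthetic ocean does not emulate

The generator reproduces the *statistical* structure the analysis needs —
index-linear mean flow with reversal, index-magnitude-driven shoreward
intrusion, tidal oscillation, correlated mesoscale noise, vertical shear —
but not: real coastline or reef geometry, wind- and river-forced
circulation, salinity or temperature effects, data-assimilated interannual
detail beyond the index response, or vertical current structure. Passing
tests therefore demonstrate that the *pipeline* recovers the imposed
climate-connectivity relationships from particle-level simulation; they do
not validate the magnitudes of any particular real shelf's connectivity,
and the package's regression statistics are not expected to equal those of
a reanalysis-driven study. Real geometry and velocity fields can be
supplied through the GeoJSON and velocity-file interfaces to close that
gap.

## Problem sizes

The packaged study conditions are 141 seed cells x 92 release days x 8
years. The full design rate (100/cell/day, 1.3M particles/year) is the
documented default; the shipped acceptance analysis uses rate 5 (64,860
particles/year, ~520k total), which leaves the per-release connectivity
expectations unchanged and keeps every statistic's Monte-Carlo error well
inside the margins the tests assert. Unit tests run on 2-4-region domains
with minutes-long seasons.
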