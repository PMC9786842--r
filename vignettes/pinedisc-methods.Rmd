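---
title: "Methods: leaf-level 13C discrimination, iWUE inversion and carry-over analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leaf-level 13C discrimination, iWUE inversion and carry-over analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinedisc)
```

## The scientific problem

The carbon isotope composition (delta13C) of leaf carbon pools is widely
used to reconstruct physiological signals — above all intrinsic water-use
efficiency (iWUE = A/gs, the ratio of net assimilation to stomatal
conductance, in umol CO2 per mol H2O, i.e. ppm). The reconstruction chain
has three independent routes to the delta13C of *new assimilates*:

1. **Chamber route**: a shoot chamber coupled to an isotope spectrometer
   yields 12CO2 and 13CO2 fluxes; their ratio, expressed against V-PDB,
   is the delta13C of the net CO2 flux.
2. **Model route**: the steady-state discrimination model predicts the
   photosynthetic 13C discrimination from gas-exchange quantities.
3. **Pool route**: delta13C measured in leaf sucrose, water-soluble
   carbohydrates (WSC), starch, pinitol or total organic matter (TOM),
   each of which integrates the assimilate signal over its own turnover
   time and may be offset by metabolically distinct components.

`pinedisc` implements all three routes plus the inversions that turn a
delta13C value into iWUE, and a synthetic-season generator with known
ground truth so the whole chain can be validated end to end.

## Models

### Vapor pressure

Saturation vapor pressure uses the Tetens form
es = 610.7 x 10^(7.5 T / (237.3 + T)) / 1000 kPa, and
VPD = es (100 - RH)/100.

### Discrimination model

For C3 leaves,

Delta = a + (b - a) ci/ca - (b - a_m) A/(g_m ca) - f Gamma*/ca
        - [Rd/(A + Rd)] e (ci - Gamma*)/ca

with stomatal diffusion a = 4.4 permil, carboxylation b = 29 permil,
mesophyll transfer a_m = 1.8 permil, photorespiration f = 8 permil
(11 permil as a sensitivity option), day respiration e = -6 permil, and a
constant mesophyll conductance g_m = 0.127 mol m-2 s-1. All rates and
conductances are expressed per *all-sided* needle area, the convention for
conifer shoots. The CO2 compensation point Gamma* and dark respiration Rd
follow exponential temperature responses normalised at 25 degC;
(R_d0, H_alpha) are fitted to night-time chamber fluxes by nonlinear least
squares (`fit_respiration`), started from R_d0 = mean efflux and
H_alpha = 5e4 J mol-1. Leaf temperature is taken equal to chamber air
temperature. Two sensitivity switches mirror common practice: `g_m = Inf`
drops the mesophyll term, and `light_inhibited = TRUE` sets Rd = 0 during
daytime. The defaults are f = 8 permil and non-light-inhibited Rd.

Delta converts to the delta13C of assimilates via
deltaA = 1000 (delta_air - Delta)/(Delta + 1000); the inverse is exact.

### Chamber closure model

The shoot chambers are non-airtight: sample air drawn to the analysers
(flow q) is replaced by ambient air leaking in. The head-space
concentration therefore obeys dC/dt = (q/V)(C_amb - C) - F S/(V rho) and
relaxes exponentially, C(t) = C_eq + (C0 - C_eq) exp(-(q/V) t), toward
C_eq = C_amb - F S/(q rho), with rho = P/(R T_K) the molar density of air.
`fit_closure_flux` fits (C_eq, C0, k) by nonlinear least squares — over
5–50 s for the 0.5 s isotopologue channels and 5–35 s for the 5 s bulk
CO2/H2O channels — and evaluates the flux from the fitted *equilibrium
deficit*, F = q rho (C_amb - C_eq)/S, which is more robust over a 65 s
closure than an initial-slope estimate and algebraically equivalent on the
model class. The fit window bounds and the two QC rules are strict
inequalities: delta13C is discarded where the CO2 flux is *lower than*
0.5 umol m-2 s-1, and the H2O flux where RH *exceeds* 75 %.

Daily values are flux-weighted daytime means, with daytime defined as
2 h after sunrise to 2 h before sunset. Sunrise/sunset are configuration
inputs, not computed from solar geometry, to keep the stage free of
location dependencies.

### iWUE inversions

From gas exchange: gs = E P_amb/(es - ea) and iWUE = A/gs. From
discrimination, two inversions are provided:

* `iwue_iso_complex` is *defined* as the exact algebraic inverse of the
  full discrimination model solved for iWUE = (ca - ci)/1.6. Its printed
  closed form is, with k = Rd/(A + Rd),

  iWUE = ca/1.6 x [b - Delta - f Gamma*/ca - (b - a_m) A/(g_m ca)
         + k e Gamma*/ca - k e] / (b - a - k e).

  The round-trip identity with the forward model (machine precision over
  random physical inputs) is the authoritative contract and fixes every
  grouping ambiguity; note the final "- k e" term in the numerator, which
  careless typesetting of the closed form easily loses.
* `iwue_iso_simple` inverts the two-term model with the net carboxylation
  fractionation b' = 27 permil: iWUE' = ca (b' - Delta)/[1.6 (b' - a)].

For pool-based inversions, ca and delta13C of air are the ambient values
measured before chamber closure (the environment series), not the
in-chamber drawdown. Nonphysical results (iWUE outside [0, ca/1.6]) are
flagged with warnings, never clipped.

Because WSC carries a large share of isotopically near-invariant pinitol,
`correct_wsc_for_pinitol` recovers the sugar signal by two-member mixing
inversion, delta_corr = (delta_WSC - p delta_pinitol)/(1 - p), with
defaults p = 0.40 and delta_pinitol = -31 permil.

### Carry-over integration and grid search

A pool that retains the fraction lambda of its carbon from one day to the
next mixes the daily assimilate signal X with geometric weights:

X*_t = sum_{i=0..n} lambda^i X_{t-i} / sum_{i=0..n} lambda^i.

We read the per-day retention as a geometric decay lambda^i because lambda
is defined as the fraction of the pool carried into the following day; a
`flat = TRUE` switch provides equal weights (a plain moving average) so
the alternative reading remains testable. n = 0 is the identity and
lambda = 1 the unweighted moving average — both serve as exact limits in
the tests. `carryover_grid_search` scans n = 0..12 d by 1 d and
lambda = 0.1..1 by 0.1 (lambda = 0 is excluded; n = 0 provides the
no-carry-over baseline), correlating the integrated driver against the
pool series by Spearman rank correlation (average ranks for ties; p from
the t approximation). Because neighbouring cells are strongly correlated
— a geometric tail truncated at n = 5 differs little from n = 4 — the full
surface is always returned; the argmax alone is reported with ties broken
toward smaller n, then larger lambda (the most parsimonious memory).

Needle-generation series are combined only where the generations agree:
sucrose by a simple average; WSC after subtracting the stable 0.6 permil
0N-1N offset from the current-year series (so the combination represents
the one-year-old needles the chambers measure); starch, pinitol and TOM
are refused unless forced, because their generation offsets drift.

## The synthetic-season generator

The generator emulates a boreal Scots pine season so every stage can be
tested against known truth:

* **Drivers** — half-sine diurnal PAR (clear-sky peak 1500 umol m-2 s-1)
  with a uniform daily cloudiness factor on [0.35, 1]; temperature as a
  seasonal arc (mean 12 degC, amplitude 6) plus a diel cycle (amplitude
  5 degC, warmest mid-afternoon) and 0.5 degC noise; RH anti-correlated
  with temperature; constant pressure, ca = 400 ppm and air delta13C
  -8.5 permil; optional dry spell pulling soil moisture to 0.1 m3 m-3.
* **Physiology** — saturating light response (half-saturation 250
  umol m-2 s-1, Amax 6 umol m-2 s-1 per all-sided area) with a mild
  Gaussian temperature modifier; a per-day iWUE schedule (base 82 ppm,
  seasonal amplitude 20 ppm, daily jitter 15 ppm, constant within a day)
  chosen so the season reproduces field-scale statistics for mature Scots
  pine (seasonal iWUE roughly 95 +/- 16 ppm and daily assimilate delta13C
  spread near 1.6 permil). gs, E, and ci follow from the schedule, and
  Delta/deltaA from the forward model — so truth is self-consistent by
  construction. Nights respire at -Rd(T).
* **Closures** — the exponential dilution model above, with the 13CO2
  trace constructed so the isotopologue flux ratio encodes the record's
  true assimilate delta13C (R_VPDB = 0.0111802); additive Gaussian noise.
  The sample flow is not a measured quantity of the field system, so it
  is a free configuration parameter; the default 2 dm3 min-1 puts the
  closure time constant (V/q = 30 s for the 1 dm3 chamber) well inside
  the fit window.
* **Pools** — sucrose integrates the daily assimilate signal with
  (n = 4, lambda = 0.8) and 0.24 permil noise; pinitol is invariant at
  -31 permil (1N; -30.1 permil 0N) with 0.19 permil noise; WSC is a 40/60
  pinitol/sugar mixture with a +0.6 permil 0N offset; starch is
  invariant; TOM tracks the weighted assimilate signal only during the
  needle growth window and freezes at the window-end value. Noise
  defaults are the respective measurement precisions. A hypothesised
  two-compartment (cytosol/vacuole) sucrose pool is *not* part of the
  default generator; the carry-over weighting is its single-pool
  surrogate.

What the generator does **not** emulate: radiative transfer, soil-water
dynamics, reserve remobilisation (e.g. starch-to-sugar conversion under
drought), phloem export fractionation, instrument drift, or any specific
historical weather trajectory. Passing tests therefore demonstrate the
numerical integrity and statistical identifiability of the analysis
chain under its stated assumptions — not that field data are free of
those confounders.

## Numerical choices and degenerate inputs

* Closure fits run Levenberg–Marquardt (`minpack.lm::nlsLM`) from a
  linear pre-fit in the basis {1, exp(-(q/V) t)}. The rate constant is
  fixed at the chamber turnover q/V by default — it is a property of the
  hardware, and freeing it on a 7-point bulk-channel window inflates the
  flux variance considerably; `fit_rate = TRUE` frees it (bounded below
  at (q/V)/50) as a diagnostic of the chamber metadata. A trace whose
  range is indistinguishable from zero returns flux 0 with a `flat` flag
  instead of fitting.
* The respiration fit demands at least 5 night records spanning at least
  5 degC; constant-temperature designs are rejected as rank-deficient.
* `integrate_carryover` refuses dates whose look-back window the driver
  does not cover; the grid search vectorises the same arithmetic through
  a lag matrix and refuses fewer than 8 usable sampling dates.
* The daytime window requires day length above 4 h; days whose weights
  sum to zero yield NA with a warning rather than an error, so one bad
  day cannot abort a season.
* QC filtering only removes (sets NA); retained values are never altered.
* All delta/Delta quantities are carried in permil throughout; the
  delta-to-Delta conversion assumes this convention.

## Validation problem sizes

The test suite validates on deliberately compact problems: a 45-day
zero-noise season at 30-min resolution with closures every 2 h for the
end-to-end agreement check (chamber, model and truth daily series agree
within 0.05 permil; the truth series is evaluated at the closure
timestamps, i.e. what the chambers actually saw); 200-replicate
Monte-Carlo checks for flux and respiration recovery; and 100 replicates
of the carry-over grid search on a 153-day season sampled every 3 days.
The end-to-end checks use a drier-air season (RH base 55 %) in which no
daytime record trips the RH filter, so all three routes are computed from
identical record sets; with QC removals the routes legitimately diverge
by within-day sampling differences, which is expected behaviour rather
than numerical error. The zero-noise iWUE chain (sucrose generated with
n = 0, inverted through the full model with daily flux-weighted inputs)
recovers the scheduled iWUE within 1 ppm; the residual reflects
within-day covariance of A and Delta under flux weighting, not algebra.

## Known limitations

* g_m is constant over the season; a temperature-dependent g_m can be
  emulated only by re-running with different `disc_params`.
* The chamber model ignores wall sorption (handled in practice by the RH
  filter), water-vapor dilution cross-sensitivity, and ternary diffusion
  corrections.
* Sunrise/sunset are season-constant configuration values rather than
  per-day solar geometry; at high latitudes the daytime window therefore
  drifts slightly relative to the true solar day across a long season.
* The carry-over surface is descriptive: neighbouring (n, lambda) cells
  are not statistically distinguishable on 20-50 sampling dates, which is
  why the argmax ships together with the full surface.
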