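# pinedisc

Leaf-level carbon isotope discrimination and intrinsic water-use
efficiency (iWUE) analysis for conifer shoots — an R implementation of the
full chain from chamber gas-exchange measurements and leaf carbon-pool
delta13C to iWUE, with a synthetic-season generator for end-to-end
validation against known ground truth.

## Who this is for

Ecophysiologists working with shoot chambers coupled to isotope
spectrometers (e.g. cavity ring-down analysers) and/or compound-specific
delta13C of leaf carbohydrates, who want a tested, reproducible pipeline
for three independent estimates of the delta13C of new assimilates and the
iWUE they imply:

* **chamber route** — 12CO2/13CO2 fluxes from 65 s closure curves of a
  non-airtight chamber, delta13C from the isotopologue flux ratio vs V-PDB;
* **model route** — the steady-state photosynthetic discrimination model

  `Delta = a + (b - a)·ci/ca - (b - a_m)·A/(g_m·ca) - f·Gamma*/ca
           - [Rd/(A+Rd)]·e·(ci - Gamma*)/ca`

  with a = 4.4‰, b = 29‰, a_m = 1.8‰, f = 8‰, e = −6‰,
  g_m = 0.127 mol m⁻² s⁻¹ (all-sided needle area), temperature-dependent
  Gamma* and Rd, and `deltaA = 1000(delta_air − Delta)/(Delta + 1000)`;
* **pool route** — delta13C of sucrose, water-soluble carbohydrates (WSC),
  starch, pinitol or bulk organic matter, inverted to iWUE either through
  the exact algebraic inverse of the model above
  (`iwue_iso_complex`) or through the two-term form
  `iWUE' = ca(b' − Delta)/[1.6(b' − a)]` with b' = 27‰
  (`iwue_iso_simple`), including a pinitol-unmixing correction for WSC
  and a carry-over (previous-day weighting) grid search
  `X*_t = Σ λ^i X_{t−i} / Σ λ^i` over n = 0–12 d, λ = 0.1–1.

## Worked example

Simulate a 153-day growing season with a late-summer dry spell, chamber
closures every 2 h with 0.2 ppm trace noise, and run the whole analysis:

```r
library(pinedisc)
cfg <- pipeline_config(
  season = season_config(start_date = "2018-05-01", end_date = "2018-09-30",
                         dry_period = list(start = "2018-08-16",
                                           end   = "2018-09-10")),
  closure_interval_minutes = 120,
  trace_noise_sd = 0.2,
  rng_seed = 2018)
res <- run_pipeline(cfg)
print(res)
```

```
[pinedisc] simulate: 7344 environment records over 153 days
[pinedisc] traces: 1836 chamber closures
[pinedisc] respiration: refit from 612 night closures (R_d0 = 0.790, H_alpha = 39361)
[pinedisc] qc: removed 612 delta13C and 113 H2O flux records
[pinedisc] pools: 5 series x 20 sampling dates
[pinedisc] carryover: best n = 4 d, lambda = 0.9 (rho = 0.967)
pinedisc pipeline result
  153 days; delta13C_A_Picarro -25.4 +/- 1.6 permil; model -25.4 +/- 1.5 permil
  iWUE_gas 93 +/- 16 ppm
  carry-over best: n = 4 d, lambda = 0.9 (rho = 0.97)
  sucrose iWUE_iso vs iWUE_gas: r = 0.96, mean offset 0.4 ppm
```

Reading the output: the chamber-derived and modeled daily delta13C of
assimilates agree (−25.4‰ both, a check of the two instrument-independent
routes against each other); the respiration refit from night-time closures
recovers the generating temperature response (truth: R_d0 = 0.8,
H_alpha = 40000); QC removed the night-time delta13C records (CO2 flux
below 0.5 µmol m⁻² s⁻¹) and the high-RH H2O fluxes; the carry-over grid
search on the sucrose series lands next to the generating cell
(n = 4 d, λ = 0.8); and sucrose-derived iWUE tracks gas-exchange iWUE
(r = 0.96) with a sub-ppm mean offset. `res$daily`, `res$pools`,
`res$iwue` and `res$surface$surface` hold the underlying tables; with
`out_dir` set, each is written as CSV.

Individual stages are plain functions — `fit_closure_flux()`,
`model_discrimination()`, `iwue_iso_complex()`, `carryover_grid_search()`,
… — and accept user data with the documented column contracts, so the
pipeline is not tied to the simulator.

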