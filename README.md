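# tcddrisk

Quantifying how much of a population's rising cancer risk from
2,3,7,8-TCDD (the most toxic dioxin congener) is driven by changes in
*dietary patterns* rather than by changes in *emissions*. The package is
aimed at exposure modellers and environmental epidemiologists who want a
fully testable, desk-scale implementation of the coupled model chain used
for this kind of attribution:

```
emissions ──> multimedia fate ──> food web ──> 14-pathway exposure ──> CR
  (gridded)    (air/soil/water)    (pg/g food)    (pg/kg bw/d)    (dimensionless)
```

* **Fate**: donor-cell upwind advection and eddy diffusion on a gridded
  domain, K_OA-based gas–particle partitioning, dry/wet deposition, a
  dynamic three-layer soil column and surface water coupled to air by
  two-film fugacity exchange (`D = 1/(1/D_air + 1/D_water)`), exact
  exponential degradation, and a yearly mass ledger that must close.
* **Food web**: level-III fugacity fish model
  (`C_fish = k1 C_w/(k2 + kG + kM)`, equilibrium limit `lipid · K_OW`),
  three-term plant accumulation (gas + intercepted particles + root
  uptake), and biotransfer factors `C_product = BTF · Σ intake_i C_i` into
  meat, milk and eggs.
* **Exposure/risk**: total exposure dose as the exact sum of 14 pathways
  (2 inhalation, 9 ingestion, 3 dermal), `CR = TED × slope factor`,
  population-weighted CR (`CR · density / mean density`) and population
  above the 10⁻⁴ acceptable-risk level.
* **Attribution**: five scenarios factorially fixing emissions and/or diet
  at 1980; `Con_diet = 100 · CR_scenario3 / CR_scenario1`; annual average
  increasing rate `100·((end−start)/start)/29` for 1980–2009.
* **Spectral**: singular spectrum analysis of risk and consumption series;
  foods classified against the 0.04 cycles/yr critical risk frequency.
* **Uncertainty**: ±10 % sensitivities, lognormal confidence factors
  `Cf = exp(1.96·√ln(1+CV²))`, first-order propagation
  `ln Cf_out = √Σ(S_i ln Cf_i)²`, with a Monte Carlo cross-check.

Because the original study's emission inventory, reanalysis meteorology
and consumption statistics are not publicly deposited, the package ships
synthetic generators that reproduce their structure (east-biased hotspot
plumes accelerating after 2000, declining grain / rising animal-food
trajectories with distinct urban and rural slopes, heterogeneous
population grids) and the published endpoint values where those are
printed. See `vignettes/dietary-dioxin-risk-methods.Rmd` for the model,
parameter and design details.

## Worked example

The numbered scripts under `analysis/` run the study workflow; each is a
thin driver over package functions and writes its tables under `results/`.
`analysis/02_run_scenarios.R` runs the full five-scenario experiment
(about half a minute) and prints:

```
Scenario 1: mean CR 1.04e-07 (1980) -> 5.98e-07 (2009), +16.35 %/yr, Cf 2.1
Scenario 2: mean CR 1.04e-07 (1980) -> 1.12e-07 (2009), +0.27 %/yr, Cf 2.1
Scenario 3: mean CR 1.04e-07 (1980) -> 1.55e-07 (2009), +1.68 %/yr, Cf 2.1
Scenario 4: mean CR 1.44e-07 (1980) -> 2.23e-07 (2009), +1.89 %/yr, Cf 2.1
Scenario 5: mean CR 7.38e-08 (1980) -> 1.39e-07 (2009), +3.04 %/yr, Cf 2.1
```

Read: with both emissions and diet varying (scenario 1) the mean risk
rises about sixfold; freezing both at 1980 (scenario 2) leaves only the
slow spin-up of soil and water stocks; letting only the diet vary
(scenario 3) still raises risk — the dietary signal isolated from the
emission signal — and does so faster for rural residents (scenario 5),
whose meat consumption nearly triples, than for urban residents
(scenario 4). `Cf` is the propagated 95 % confidence factor of the
final-year mean CR. The same experiment classifies consumption series
against the 0.04 cycles/yr critical risk frequency (staples below, animal
foods above) and closes its transport mass ledger to better than 1e-12
relative each simulated year.

In code:

```r
library(tcddrisk)
res <- run_full_experiment(load_run_config(overrides = list(out_dir = "results/run")))
res$summary                      # the table above
con_diet(1.1e-7, 6.6e-7)         # 16.7: published 2009 dietary contribution (%)
annual_avg_increase_rate(7.3e-8, 6.6e-7, 29)   # 27.7 %/yr, published scenario-1 rate
```

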