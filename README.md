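# moorbloom

Bloom phenology, stoichiometry and carbon-export budgets from year-round
moored ocean observatories in seasonally ice-covered seas.

## The problem

In marginal ice zones, the timing and fate of the spring phytoplankton bloom
is set by how the upper ocean stratifies. Two end-member regimes occur at the
same location in different years:

* **Meltwater (MW) regime** — heavy sea-ice export leaves a lens of fresh
  meltwater behind. Salinity stratification is extreme (surface salinities
  down to 30.5; buoyancy frequency N² ≈ 10⁻⁴ s⁻²), the productive layer is a
  thin (~10 m) film above the uppermost sensors, nitrate is never fully
  depleted at depth, and export to the seafloor is retained until fall — a
  *retention* system.
* **Mixed-layer (ML) regime** — with the ice edge far away, a weakly
  stratified ~50 m mixed layer hosts a short, intense diatom bloom: nitrate
  (winter value ~12 µmol l⁻¹) is used up within ~1.5 months, chlorophyll
  reaches 7 µg l⁻¹ with e-folding growth ~0.2 day⁻¹, and a pulse of organic
  carbon reaches the 2600-m seafloor within 4–7 weeks of the onset — an
  *export* system.

The regime shift slows the biological carbon pump (BCP) by about 4 months.

`moorbloom` implements the full derived-variable and budget chain needed to
make that comparison from moored sensor records, plus a synthetic generator
that emulates both regimes so every stage can be exercised without any
external data download.

## What is in the package

| Area | Functions (selection) |
|---|---|
| Series conditioning | `mooring_series()`, `burst_average()`, `mask_blowdowns()`, `lowpass_filter()`, `daily_mean()` |
| Seawater physics | `potential_density()` (EOS-80), `buoyancy_frequency()` with N²_T/N²_S split, `aou()`, `meltwater_fraction()` |
| Mixed layer depth | `hourly_mld_min()` (minimum-MLD estimator with percentile offset correction), `daily_mld()` (3-shallower/21-deeper order statistic) |
| Light | `shortwave_to_par()`, `par_at_depth()`, `par_available()`, `euphotic_depth()`, `day_length()` |
| Carbonate system | `alkalinity_from_salinity()` (Alk = 736 + 45.2·S), `dic_from_pco2()`, `pco2_from_dic()`, `carbon_takeup()`, `apply_pco2_bias()` |
| Nutrients & budgets | `nstar()`, `sistar()`, `suna_drift_correct()`, `column_stock()`, `redfield_carbon()`, `chl_carbon()`, `bloom_budget()` |
| Phenology | `detect_bloom_onset()`, `detect_bloom_end()`, `efolding_growth_rate()`, `stoichiometry_regressions()`, `classify_regime()`, `regime_area()`, `export_lag()`, `bloom_summary()` |
| Sea ice | `pct_ice_days()`, `distance_to_ice_edge()`, `ice_area_export()` |
| 1-D mixed layer model | `pwp_profile()` (P17/P18), `pwp_step()`, `pwp_run()` (Price–Weller–Pinkel) |
| Export & benthos | `normalized_mvbs()`, `sediment_volume_flux()`, `lander_poc_flux()`, `benthic_o2_to_poc()`, `detritus_coverage()` |
| Synthetic data | `scenario_config()`, `generate_scenario()`, `generate_forcing()`, `synthetic_growth_series()`, `write_scenario()` |

## Worked example

Generate the default mixed-layer scenario without noise and summarize its
bloom season:

```r
library(moorbloom)

ml <- generate_scenario(scenario_config("ML"), noise = FALSE)
bloom_summary(ml)
```

```
Bloom summary
  regime:          ML
  start:           2018-05-01
  end:             2018-06-15
  duration:        1.5 months
  growth rate:     0.19 day-1
  O2:NO3 slope:    7.00 (r2 1.00)
  chl:NO3 slope:   -0.60 (r2 1.00)
  retention:       1.4 months (deepest trap)
```

The onset is the first date the net surface heat flux stays positive for five
days; the end is the first nitrate-depleted day; the slopes are ordinary
least-squares fits of the daily biogeochemical state over the bloom window
(7 µmol O₂ produced and 0.6 µg chlorophyll formed per µmol nitrate consumed —
near-Redfield coupling). The same call on `scenario_config("MW")` reports no
detectable bloom end (nitrate at 30 m never depletes), a ~3-month duration,
and a seafloor export peak five months after onset:

```r
mw <- generate_scenario(scenario_config("MW"), noise = FALSE)
bloom_summary(mw)$retention_months   # ~5 months (ML: ~1.4)
```

Nutrient budget arithmetic works standalone:

```r
column_stock(12, 50)                  # 0.6 mol NO3 m-2 standing stock
redfield_carbon(column_stock(12, 50)) # 47.7 g C m-2 potential new production
euphotic_depth(4)                     # 19.8 m euphotic depth at 4 ug/l chl
```

And the 1-D mixed-layer simulator shows that identical summer forcing cannot
erode the meltwater stratification:

```r
f   <- generate_forcing("ML", span = c("2018-05-15", "2018-08-01"), seed = 2)
r17 <- pwp_run(pwp_profile("P17"), f, days = 75)  # meltwater profile
r18 <- pwp_run(pwp_profile("P18"), f, days = 75)  # weakly stratified profile
max(r17$mld); max(r18$mld)                        # P17 stays far shallower
```

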