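Package: moorbloom
Title: Bloom Phenology and Carbon Export Regimes from Moored Ocean Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive phytoplankton bloom phenology, stoichiometry and
    carbon/nitrate budgets from year-round moored sensor time series in
    seasonally ice-covered seas. Includes conditioning of burst-sampled
    mooring records (blow-down masking, zero-phase lowpass filtering, daily
    aggregation), seawater physics (EOS-80 potential density, buoyancy
    frequency with temperature/salinity decomposition, apparent oxygen
    utilization, meltwater fraction), a minimum mixed-layer-depth estimator
    for discrete-depth moorings, light and euphotic-depth parameterizations,
    a carbonate-system solver for DIC drawdown from pCO2 and alkalinity,
    nutrient tracers and production estimates, sea-ice concentration metrics
    and gate area export, a Price-Weller-Pinkel one-dimensional mixed-layer
    simulator, sediment-trap and benthic flux normalizations, and a
    synthetic-data generator that emulates a meltwater-stratified and a
    mixed-layer bloom regime so the full pipeline can be exercised without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
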