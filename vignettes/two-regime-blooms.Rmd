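---
title: "Two stratification regimes and the biological carbon pump: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two stratification regimes and the biological carbon pump: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moorbloom)
```

This vignette documents the models, parameter choices and numerical
decisions behind `moorbloom`, and what the synthetic scenarios can and
cannot demonstrate about real mooring data.

## Sensor conditioning

Moored optical sensors sample in short bursts (5–10 one-second samples per
hour); `burst_average()` reduces a burst to its unmasked arithmetic mean.
Strong currents drag instruments below their nominal depth (excursions up
to ~200 m); since a sensor traversing a vertical property gradient records
spurious temporal change, `mask_blowdowns()` flags samples more than a
threshold below nominal depth. The threshold defaults to **10 m**: real
blow-downs are tens to hundreds of metres, ordinary mooring motion a few
metres, so 10 m separates the populations cleanly while remaining
configurable.

`lowpass_filter()` realizes the "5-day cutoff" as an order-4 Butterworth
filter applied forward and backward (zero phase). Because two passes square
the amplitude response, the design frequency is shifted by
$(\sqrt2-1)^{1/2n}$ so the **half-power point lands exactly at
1/cutoff_days**. Edges are padded by reflection about the end points, and
the filter operates on deviations from the series mean so the DC component
passes exactly. Gaps of at most 6 h are bridged by linear interpolation
before filtering (a conservative bound: hourly records, and the filter
memory is days); longer gaps propagate as missing. `daily_mean()` requires
at least 6 valid hourly samples per UTC day — enough to constrain a daily
mean without letting a single burst represent a day.

## Seawater physics

Densities use the UNESCO **EOS-80** equation of state with
Fofonoff–Millard potential temperature — the same family as the classic
Seawater toolbox used in moored-CTD processing, and consistent with
practical-salinity sensor output. The two-sensor buoyancy frequency is

$$N^2 = -\frac{g}{\rho_0}\frac{\Delta\rho}{\Delta z},\qquad
  N_T^2 = g\,\alpha\frac{\Delta T}{\Delta z},\qquad
  N_S^2 = -g\,\beta\frac{\Delta S}{\Delta z},$$

with $\alpha,\beta$ evaluated (by centred finite differences of potential
density) at the mean temperature and salinity of the pair. The
decomposition closes to within 5 % of $N^2$ for $|\Delta T|\le 3$ °C,
$|\Delta S|\le 1$ — the EOS nonlinearity tolerance tested in the suite.

Oxygen saturation follows **Weiss (1970)** (ml l⁻¹ × 44.6596 → µmol l⁻¹),
matching the `sw_satO2` lineage of the processing this package mirrors;
Garcia & Gordon (1992) is available as an alternative formulation and
doubles as the independent oracle in the tests (the two agree to ~0.5 %
in cold water). AOU is saturation minus measurement; negative AOU means
net photosynthetic oxygen production.

The meltwater fraction is a two-member salinity balance. Neither end-member
salinity is a measured quantity here, so they are parameters:
**35.1** (Atlantic Water) and **8** (bulk sea ice) reproduce the observed
~1/6 meltwater contribution at a 30.5 surface salinity and are exposed as
arguments.

## Minimum mixed-layer depth

Without profiling instruments only a *minimum* MLD can be bounded from
discrete-depth recorders. For each underlying instrument the potential
density difference to the uppermost (~30 m) recorder is corrected by
removing that pair's per-deployment **0.5th percentile** — absorbing small
relative calibration offsets that otherwise produce systematically negative
(or positive) density differences. We implement the correction as
subtraction of the (typically negative) percentile, the only sign for which
the corrected differences are non-negative for 99.5 % of samples; the
opposite convention is available as `offset_sign = "add"` for fidelity
experiments. The hourly minimum MLD is the deepest instrument with
corrected $\Delta\sigma < 0.05$ kg m⁻³, or 0 when no instrument qualifies
(the estimator can then only say the mixed layer is shallower than the
shallowest pair). Output is always 0 or an instrument depth — never
interpolated.

The daily value is the **4th-smallest** of the 24 hourly values (exactly
three shallower, 21 deeper), deliberately biased towards conditions that
keep phytoplankton in the surface layer. For partial days with $n \ge 4$
valid hours we scale the order statistic to $\lceil 3n/24\rceil + 1$; this
partial-day rule is our extension, chosen to preserve the 3/24 fraction.

## Light and euphotic depth

PAR constants: detection floor $10^{-1.32}$ µmol m⁻² s⁻¹, shortwave
conversion 2.1 µmol m⁻² s⁻¹ per W m⁻², clear-water diffuse attenuation
$k_d = 0.02$ m⁻¹. The mixed-layer-average PAR uses the closed form
$PAR_{surf}(1-e^{-k_d\,MLD})/(k_d\,MLD)$ with the $MLD \to 0$ limit handled
by series expansion below $k_d\,MLD < 10^{-8}$.

The euphotic-depth relation is a power law $z_{eu} = a\,\mathrm{chl}^b$
with defaults $a = 34.0$, $b = -0.39$. The literature relations this
parameterizes are published as coefficient families rather than a single
formula, so the defaults were back-fitted once to the two anchor pairs
(4 µg l⁻¹ → 20 m; 7 µg l⁻¹ → ~16 m) and are exposed in the signature.
Day length uses the standard sunrise equation with the low-precision solar
declination approximation and no refraction; at 79° N it correctly yields
24 h (polar day) and 0 h (polar night).

## Carbonate system

DIC is computed from pCO₂ and alkalinity, with alkalinity from the regional
relation $Alk = 736 + 45.2\,S$ and fixed nutrient concentrations
(phosphate 0.5, silicate 5 µmol l⁻¹). The solver fixes
$[\mathrm{CO_2^*}] = K_0\,p\mathrm{CO_2}$ and root-brackets the
total-alkalinity equation for $[\mathrm{H^+}]$ over pH 4–12
(`uniroot`, tolerance 10⁻¹⁸ mol kg⁻¹). Constants, all on the total scale:
K₀ Weiss 1974, K₁/K₂ Lueker et al. 2000 (valid in cold, S 30–35 water),
K_B Dickson 1990, K_W and phosphate/silicate constants Millero 1995, total
borate from salinity. The inverse (`pco2_from_dic()`) uses the
DIC-parameterized alkalinity equation; the forward–inverse round trip
reproduces pCO₂ to better than 1 µatm across the tested ranges, which —
together with a hand-speciated reference value — is the correctness
argument for the solver.

Bloom **carbon takeup** is the DIC difference between the bloom start and
the post-onset pCO₂ minimum. The known high bias of one pCO₂ deployment is
handled by `apply_pco2_bias()` as an explicit, window-restricted constant
subtraction (e.g. 130 µatm) — configuration, not auto-detection.

## Phenology and budgets

The bloom **onset** is the first date the net surface heat flux remains
positive for ≥ 5 consecutive days. The persistence window is needed because
early-season warming can be interrupted intermittently; 5 days rejects
synoptic excursions without delaying a genuine transition. The **end** is
the first post-onset day with nitrate < 1 µmol l⁻¹ ("depleted" made
operational); blooms that never deplete nitrate — the meltwater regime as
seen at 30 m — return no end date rather than a spurious one. Durations are
reported in 30.44-day months. Stoichiometric couplings are ordinary
least-squares fits on daily averages over the bloom window (and a post-bloom
window), including AOU-vs-nitrate — the oxygen produced per nitrate
consumed. Regime classification follows MLD < 50 m with surface-to-100-m
salinity difference ΔS > 1 (MW) or ΔS ≤ 1 (ML), else unstratified; the
ΔS = 1 boundary goes to ML since the definitions use strict inequalities.

Production budgets: Redfield new production uses C:N = 106:16 and a carbon
molar mass of 12.011 g mol⁻¹ (so 0.6 mol NO₃ m⁻² supports 47.7 ≈ "~50"
g C m⁻²); the DIC route converts per-kg drawdown to volumetric units with
the in-situ density; the chlorophyll route uses a carbon:chlorophyll mass
ratio of 50 (plausible range 6–60 across a bloom).

## Sea ice

Distances are great circles on a sphere of radius 6371 km. Percent ice
days and the signed edge distance use strict exceedance of the 20 %
concentration threshold; the distance is positive in open water and
negative inside the ice. Gate area export discretizes each gate segment
into ≤ 25 km sub-segments, takes drift and concentration from the nearest
cell, and integrates the normal drift × concentration × length over days;
the positive direction is the right-hand normal of the gate's direction of
travel (southward for a west-to-east zonal gate), with an explicit
`flip_normal` switch. Sub-segments with missing drift are skipped and the
data coverage is reported alongside the flux.

## The 1-D mixed-layer model

`pwp_step()`/`pwp_run()` implement the canonical Price–Weller–Pinkel
scheme: surface deposition of non-penetrating heat and freshwater, two-band
shortwave absorption (62 % at 0.6 m, the rest at 20 m e-folding),
convective adjustment, wind-stress acceleration of the mixed layer
(quadratic drag, $C_d = 1.2\times10^{-3}$, air density 1.22 kg m⁻³) with
inertial rotation, bulk-Richardson deepening at $Ri_b < 0.65$, and
gradient-Richardson partial mixing at $Ri_g < 0.25$ (pairs stirred towards
$Ri_g = 0.3$). Defaults: dz = 1 m over 0–250 m, dt = 15 min, reference
density 1026 kg m⁻³, heat capacity 4000 J kg⁻¹ K⁻¹ — all exposed in
`pwp_params()` since the published model description leaves them to the
implementation. The two idealized initial profiles are piecewise linear:
P17 (meltwater, 30.5 → 35 over 0–50 m, 35 → 35.1 over 50–200 m) and P18
(34.8 → 35 over 0–50 m, identical below). Column heat and salt content
close against the time-integrated surface inputs to machine precision by
construction (the conservation tests require < 0.1 %), static stability
holds after every step, and halving dz moves the example-run MLD by < 2 m.
Model MLD uses the same 0.05 kg m⁻³ criterion as the observational
estimator, applied to the model grid. Runs driven by the synthetic summer
forcing show the defining contrast: the meltwater profile's stratification
cannot be overcome by wind mixing, so P17 keeps a mixed layer shallower
than P18 at every output step.

## Acoustics, traps, benthos

Vertical MVBS averaging is done on the dB values (matching the
deployment-median normalization it feeds); acoustically conventional
linear-power averaging is available via `db_average = FALSE`. The
per-deployment median subtraction makes each deployment's normalized series
median-zero, absorbing hardware differences. Trap normalizations follow the
instrument geometry (4-cm cups against a 0.5 m² water-column trap area;
0.25 m² lander trap with split factors), and benthic oxygen uptake converts
to POC flux at a respiratory quotient of 1.

## The synthetic scenarios

`generate_scenario()` emulates the statistical structure of the two
regimes, not the ocean: a logistic nitrate-drawdown backbone at the 0.2
day⁻¹ e-folding rate, timed so depletion (ML) falls on the configured end
date, with AOU, pCO₂ and chlorophyll all *derived from the same backbone*
through the couplings 7 µmol O₂, 180 µatm (via the drawdown amplitude) and
0.6 µg chl per µmol NO₃; a seasonal heat flux crossing zero on the onset
date; seasonal PAR with two-orders-of-magnitude bloom self-shading at
30 m; a meltwater lens (surface salinity down to 30.5, ΔS up to ~4.5) in
the MW case; and export as a constant background plus one Gaussian pulse
per trap depth, with peak dates, widths and integrals set to the regime's
observed timing (ML seafloor peak six weeks after onset, ~1 g C m⁻² event
lasting about a month; MW peak mid-October) and the March–August /
September–November integrals. Noise is AR(1) (coefficient 0.8), additive
for signed channels and multiplicative log-normal for positive ones, and
every draw is controlled by the config seed. Both default scenarios share
one calendar template with the bloom in the final spring, so the MW-minus-ML
seafloor peak difference (~4.1 months) is a phase difference between
regimes.

What passing tests on these scenarios **do** show: the estimators recover
known couplings, rates and timings through the full pipeline, including
under realistic autocorrelated noise. What they **do not** show: skill on
real records — the generator has no advection events, no internal waves or
tides, no sensor drift or fouling, no ice-algal production, a single bloom
per template, and channel noise that is stationary. Conclusions about real
moorings still require the real data.

## Problem sizes and numerical conventions

Test and acceptance runs use desk-scale sizes chosen to exercise every code
path: two-year daily/hourly scenarios, 75-day PWP integrations at dt = 15
min and dz = 1 m, 100-seed slope-recovery ensembles, and 1000 random
density stacks against the brute-force MLD oracle. Degenerate inputs are
defined rather than accidental: empty bursts are missing; a uniform ice
field has no defined edge distance (warning + `NA`); a constant chlorophyll
window has zero growth rate; `par_available(0)` returns the surface value
by its limit; equality at classification thresholds is resolved as
documented above.
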