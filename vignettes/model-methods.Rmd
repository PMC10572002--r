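---
title: "Methods: a steady-state heat and mass balance model of dairy cattle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a steady-state heat and mass balance model of dairy cattle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovitherm)
```

## The model in one paragraph

`bovitherm` asks a single question, hour by hour: *how much heat can this
cow shed into this microenvironment, and how much milk does that leave
room for?* A cow producing milk must dissipate the heat increment of milk
synthesis on top of maintenance. The package solves the steady-state
balance

$$Q_{in} + Q_{gen} = Q_{out} + Q_{stored},\qquad Q_{stored}=0,$$

for the endogenous generation $Q_{gen}$ that holds core temperature,
where $Q_{in}$ is absorbed solar plus incoming thermal radiation and
$Q_{out}$ is convection, conduction, evaporation (cutaneous and
respiratory) and emitted thermal radiation. Coupled mass balances
($M_{in} = M_{ox} + M_{out} + M_{stored}$) then convert the energy
solution into feed dry matter, as-fed mass and drinking water.

## Geometry and exchange surfaces

The cow is an assembly of simple solids — a horizontal torso cylinder,
spheroid head, neck, four leg cylinders and a tail — with dimensions
solved so the 682 kg reference animal's total skin area matches the
Meeh-type allometry $A = 0.14\,M^{0.57}$ m² and fixed per-part area
fractions (torso 56%, legs 4 × 6%, head + neck 12%, tail 3%; these are
modelling choices, not measurements). Other masses scale isometrically:
lengths with $M^{1/3}$, areas with $M^{2/3}$. A measured shoulder height
can override the scaled one. Convection per part uses Hilpert
cylinder-in-crossflow correlations with a 1.5× turbulence enhancement and
a free-convection floor ($Nu = 0.53\,Ra^{1/4}$), blended through a cubic
norm so $h$ is strictly increasing in wind. The solar silhouette is the
projection of the assembly onto the beam with the animal broadside to it;
sun-orienting behaviour is not modelled.

## Haircoat

The coat is a porous slab: conduction through still air and hair keratin
in parallel, plus a radiative-diffusion term $16\sigma T^3/(3\beta)$ with
extinction coefficient $\beta$ = hair density × hair diameter
(defaults $5\times10^7$ m⁻² and 60 µm). Curved parts use the
cylindrical-shell log correction. Piloerection multiplies the effective
depth (cap 1.35). Coat colours are mixed by area percentage into a single
solar absorptivity (black 16% reflective, white 48%, at the default
reflectivities).

## Physiology and the regulation cascade

Resting heat production is $a\,M^{0.75}$ with $a = 3.10$ W kg⁻⁰·⁷⁵. The
active target adds the milk heat increment
$E_{milk}(1/\eta - 1)$ at thermodynamic milk efficiency $\eta = 0.65$,
plus rumen fermentation heat (a diet-specific fraction of ME intake).
When the environment cannot absorb the target generation, responses
engage in a fixed order — shade (free), vasodilation, sweating (capped at
400 g m⁻² h⁻¹ of skin), panting (ventilation up to 4.6× resting, tied to
oxygen demand at 20.1 J mL⁻¹ O₂ and 15% extraction), then a core rise
from 39.0 to 39.4 °C. Only after the full cascade is exhausted is the
milk target reduced, by bisection to the feasibility boundary: the model
cow maximises milk production, so its estimates are upper bounds under
heat stress (real cows cut intake and yield earlier). Cold defenses are
vasoconstriction and piloerection; past them, generation rises above
target (cold-stressed beyond +5%, hypothermic past 10× resting). Stages
are engaged minimally, which also minimises water use; among equal
states, the first (cheapest) one along the cascade is chosen.

The per-hour solve is a scalar root find on $Q_{gen}$: skin temperatures
follow the distributed-generation conduction solution
($\Delta T = q_v R^2/4k$ for cylinders, $R^2/6k$ for spheroids; the
vasomotor conductivity band is 1.05–5.0 W m⁻¹ K⁻¹), each part's
coat-surface node is solved with exact $T^4$ radiation by iterated exact
linearisation, and respiration feeds back on $Q_{gen}$ itself. Closure is
enforced to 10⁻³ W.

## Calibration: one parameter set

Several constants the model needs are not published measurements
(vasomotor conductivity band, hair-solid conduction effectiveness, coat
vapour-transfer efficiency, panting cap, resting coefficient). They were
calibrated **once**, jointly, against the chamber behaviour of a standard
643 kg black Holstein, and frozen as the package defaults:
thermoregulatory sweating onset ≈ 26 °C without solar and ≈ 18.5 °C under
a 500 W m⁻² beam, lower critical temperature ≈ 16 °C, full 50 kg/day milk
at 25 °C (1 m/s, 50% RH), production reaching zero near 36 °C, and a milk
cliff near 22 °C at 0.1 m/s wind. No scenario re-tunes them. Two
consequences are worth stating plainly:

* The dilated flesh conductivity (5.0 W m⁻¹ K⁻¹) is an *effective*,
  perfusion-inclusive value, higher than bare-tissue conductivity — with
  the measured 0.336 cm coat, a lower value cannot pass enough heat to
  reproduce the observed upper thermal-neutral boundary.
* Under the $M^{0.75}$ resting law and isometric area scaling, the lower
  critical temperature *decreases weakly with mass*. A 364 kg animal
  therefore comes out with an LCT ≈ 18.5 °C, about 2 °C above the 643 kg
  animal — mechanistically forced by surface-to-volume scaling. Published
  chamber figures that place a small cow's LCT *below* a mid-sized cow's
  imply a steeper-than-$M^{0.75}$ load scaling that this model does not
  adopt.

## Microclimate

Monthly site records (Tmin, Tmax, wind, RH, cloud) become 24 hourly
paired sun/shade microhabitats for the average day of each month. Solar
position is closed-form (Cooper declination + hour angle); the clear-sky
beam is $S_0\tau^m$ with $\tau = 0.70$ and Kasten–Young air mass
(overhead, sea level: ≈ 957 W m⁻²); diffuse is 10% of $S_0\cos z$; cloud
removes the beam linearly and returns 35% of it as diffuse. Air
temperature is a sinusoid pinned to Tmin at sunrise and Tmax one hour
after solar noon. Sky emissivity follows the Swinbank form
$9.2\times10^{-6}\,T_{aK}^2$, raised linearly to 1 under cloud. The
ground surface temperature closes its own energy balance (root-found per
hour, sun patch and shade patch separately) against a deep substrate at
the monthly mean through a single 5 W m⁻² K⁻¹ conductance — a deliberate
simplification of a full soil-profile solver. Wind at animal mid-height
follows the log profile (z₀ = 1 cm). Full shade removes the beam and 90%
of total flux; shade and sun share the same air temperature, so shade
seeking changes only radiation and ground temperature. Warming scenarios
offset Tmin/Tmax only, holding RH, wind and cloud — consistent with the
expectation that relative humidity stays roughly constant as climates
warm.

## Lactation, diet and water

Daily milk targets follow the Wood gamma curve $a\,t^b e^{-ct}$
($b = 0.2$, $c = 0.004$ d⁻¹, peak near day 50), normalised so the maximum
equals the animal's target, zero after 305 days. Within a month the
target for the average day is the mean of the daily curve over the
month's in-milk days, so a no-stress year reproduces the 305-day integral
to well under 0.5%. Milk energy uses 38.7 kJ/g fat, 23.9 kJ/g protein and
a fixed 4.8% lactose at 16.5 kJ/g. Feed requirement divides maintenance
(at $k_m = 0.65$) plus milk energy (at $\eta$) by the mix-weighted ME
density of five diet archetypes; only the two forage dry-matter fractions
(HPF 77.5%, HEF 31.5%) are measured fixture values, the rest are
representative feed-table magnitudes, editable via CSV. Diet influences
milk only through water balance and fermentation heat — the
milk-feasibility solve itself is diet-independent. The water budget
closes drinking = milk water + fecal water (fecal DM × f/(1−f)) + urine
(3.7 kg/d + 3 kg per kg CP intake) + evaporation − feed water − metabolic
water (0.6 kg per kg DM oxidised), floored at zero.

## The synthetic climate generator

Tests and scenario defaults use a deterministic synthetic generator, not
a real climate database: a latitude-driven seasonal sinusoid (annual mean
$28.5 - 26.5(|lat|/60)^{1.4}$ °C, amplitude $13(|lat|/60)^{1.3}$ °C, 9 °C
diurnal range, seeded ±0.2 °C jitter), warmest in July poleward of the
tropics and in April within them (the pre-monsoon heat peak of tropical
lowlands). It emulates the *structure* of monthly climate normals — not
any particular dataset's values — and omits day-to-day weather
variability, humidity seasonality and terrain effects. Passing tests on
these sites therefore demonstrate internal consistency and qualitative
climate response, not agreement with any specific location. One
consequence: on the April-peaked tropical preset a July calving slightly
out-performs September (both beat January and March), because it parks
the dry period over the hottest weeks.

## Sensitivity analysis

`yates_effects()` implements the classical Yates sweep for $2^k$
factorials in standard order (first factor fastest): $k$ passes of
pairwise sums/differences; mean = first entry / $2^k$, effects = contrast
/ $2^{k-1}$, with half-effects (saturated ±1 regression coefficients)
reported alongside since both conventions appear in practice.
`run_design()` adds the centre replicate and reports the
centre-minus-corner-mean curvature gap. Equivalence with `lm()` on
±1-coded saturated models is enforced in the tests to machine precision.

## Numerical choices and degenerate inputs

All root finding is Brent's method (`uniroot`). The generation bracket is
[0, 10× resting]; a required generation below zero flags a hot-infeasible
state (consumed by the cascade as "reduce milk / hyperthermic"), above
the bracket a cold-infeasible one. The coat-surface node converges to the
exact quartic root by iterating the factorised radiation coefficient
$\epsilon\sigma(T_f^2+T_r^2)(T_f+T_r)$; bare skin (zero coat depth)
short-circuits the node. Zero wind falls back to the free-convection
floor. A zero milk target makes the lactating and nonlactating paths
identical. Problem sizes in the shipped tests and acceptance script —
0.5 °C sweep steps, a 1020-point chamber grid, 12 average days per
simulated year — were chosen as the coarsest grids that resolve the
reported quantities to their printed precision.

## Known limitations

Steady state only: no within-hour storage dynamics, and core temperature
drift between hours is quasi-static. Posture is fixed standing in all
shipped scenarios (lying geometry — reduced silhouette, ground contact
conduction — is implemented and tested, but not auto-selected by the
cascade). Sweating is uniform over the skin; respiratory heat loss
ignores the sensible component; feed intake has no physical ceiling and
no empirical heat-stress depression; milk composition is constant through
lactation. The model maximises milk at every hour, so heat-stress losses
are lower bounds on real losses.
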