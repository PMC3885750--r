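---
title: "Modelling population PAH inhalation exposure and intervention impact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling population PAH inhalation exposure and intervention impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahpopex)
```

## The problem

Interventions against air-pollutant exposure — banning indoor smoking,
switching cooking fuel, cleaning the atmosphere — are slow and expensive to
evaluate in the field. `pahpopex` evaluates them *in silico* for the 16
USEPA priority PAH congeners: it simulates a population of individuals, each
with a household, a workplace and a 24-hour time budget over three
microenvironments (home indoor, work/school indoor, outdoor), computes every
individual's inhalation exposure standardized to benzo[a]pyrene equivalents
(B[a]Peq), converts lifetime exposure into lung cancer relative risk, and
compares counterfactual scenarios by population attributable fraction (PAF)
and potential impact fraction (PIF). The packaged defaults describe the
Beijing population of 2006 (84% urban, 31.1% smokers, 81% employed or in
school) and its 2005–2007 ambient PAH measurements.

## Outdoor concentrations

The packaged seasonal table gives a median and SD for each congener and
season. Concentrations are strictly positive and strongly right-skewed (SDs
often exceed medians several-fold), so each cell is sampled from a lognormal
fitted in closed form: with $w = e^{\sigma^2}$ the reported SD satisfies
$sd^2 = m^2\, w (w - 1)$, a quadratic in $w$; $\mu = \ln m$. A zero-median
cell is a point mass at zero. By default all congeners within one replicate
and season share a single lognormal quantile (perfect rank correlation),
reflecting their common combustion origin; `correlated_congeners = FALSE`
switches to independent sampling. Whether the correlated or independent
choice is "right" is not identifiable from seasonal summary tables; the
switch exposes the assumption.

Each congener is split into a gas and a particle-bound phase by an editable,
season-independent particle fraction (1.0 for the five-ring-and-heavier
congeners BbF–BghiP, 0.5 for Chry and BaA, 0.05 for the lighter ones). Only
the particle phase is subject to penetration losses, surface deposition and
cleaner removal; the split therefore matters only for those pathways.

## Indoor mass balance

Indoor air is treated as one well-mixed zone at steady state, with linear
instantaneous gas–particle equilibrium and indoor emissions averaged evenly
over 24 h. Per phase $p$,

$$C_{in,p} = \frac{P_p\, a\, C_{out,p}}{L_p} + \frac{E_p / V}{L_p},
  \qquad L_p = a + k_p + \mathrm{CADR}_p / V ,$$

with $P = 1$, $k = 0$ and no CADR effect for the gas phase. The first term
is the outdoor-origin component and the second the indoor-origin component;
their sum is exact by construction, which is what makes the IN-in / OUT-in /
OUT-out decomposition well defined. Defaults: particle deposition
$k = 0.2\,/h$; cleaner CADR 134 m³/h (the market-share-weighted average of
Chinese consumer units) operated 16 h/day, converted to a time-averaged
$\mathrm{CADR}_{\mathrm{eff}} = 134 \cdot 16/24 \approx 89.3$ m³/h so that
sources and sinks share the same 24-h averaging convention.

Indoor emissions come from household smoking (cigarettes/day) and cooking
fuel (kg/day of coal, biomass or LPG), scaled by per-unit emission factors
and a cooking emission-remaining factor (ERF): 0.10 for rural coal users
(chimneys), 0.50 for urban exhaust-hood users (30% of urban households at
baseline), 1 otherwise. Per-congener emission factors for this region are
not public; the packaged CSV carries literature-plausible placeholder
values — a common combustion congener profile scaled per source (BaP: 30
ng/cigarette; 30,000 ng/kg coal; 2,500 ng/kg biomass; 100 ng/kg LPG) —
chosen once, within plausible ranges, so that the baseline reproduces the
qualitative structure reported for this population (rural exposure above
urban; outdoor-origin exposure dominating on average; the intervention
ordering atmospheric cleaning > indoor cleaners > clean fuel > exhaust >
smoking bans). All deterministic identities in the package (the PAF/PIF
calculus, the steady-state closed form, the scenario algebra) are
independent of these values, and the CSV is an explicit editable interface.

The workplace is a simpler per-occupant zone (30 m³, 1.0/h air exchange, no
cooking; smoking present unless the workplace prohibits it) entered only by
the employed/in-school; others' work hours are reallocated to home.

## The synthetic population

Distribution families are not reported for the housing and behaviour
parameters, so the generator uses truncated normals for air-exchange rate,
floor area, penetration and time at work/school (positivity, and an upper
bound of 1 for penetration), and lognormals matched to (mean, SD) for
smoking and fuel quantities, whose reported SDs exceed their means
(smoking: 9 (19) cigarettes/day) and therefore demand a heavy right tail.
Further defaults where no value is reported: ceiling height 2.7 m (typical
Chinese residential construction); a minimum infiltration of 0.05/h (the
steady-state model diverges as $a \to 0$, and occupied dwellings are never
perfectly sealed); minimum floor area 5 m²; coal quantity 2.0 (1.5) kg/day
among the 69% of rural households using coal (11% of the whole population);
urban LPG use 0.4 (0.2) kg/day; breathing 16 m³/day allocated by activity
multipliers 0.8x (home), 1.0x (work), 1.5x (outdoor) of the mean hourly
rate. Commuting is folded into the outdoor microenvironment.

Time budgets centre on 16 h/day at home; work/school hours are drawn from
5.45 (3.01) h truncated to $[0, 8]$ so outdoor time, the remainder, is
never negative; the three components sum to 24 exactly.

What the generator does *not* emulate: household composition, intra-city
geography, seasonal time-budget changes, day-to-day concentration
variability (draws are seasonal averages), and behavioural feedback of
indoor/outdoor pollution on time allocation. Tests passing on this
synthetic population validate the model machinery and its stated
distributional conditions — not the fidelity of any particular input to
field reality.

## Risk model

A lifetime exposure concentration $C$ (ug/m³·year; time-weighted B[a]Peq
over the 24-h day and four equal 91.3-day seasons, times a 70-year
lifetime) maps to relative risk via the unit relative risk:
$RR = \mathrm{URR}^{C/100}$, URR = 4.49 by default (Chinese population),
1.30 as the Asian-population alternative, and ±20% variants in the risk
table. This power-law form is the one consistent with the URR definition
(the RR after 100 ug/m³·year): re-evaluating a PAF fixed at URR 4.49 under
the other URR values reproduces the published cross-URR PAF columns, which
a linear excess-risk form does not. Risk uses concentration-years rather
than ventilation-weighted dose because the URR is defined against a
concentration; the inhaled dose is reported separately. $RR$ is computed
per individual and averaged (the over-bar in the PAF/PIF definitions);
urban and rural sub-populations are simulated and scored separately.

## Scenarios and common random numbers

The 15 scenarios (2 baselines + 13 interventions) are declarative edits of
the baseline draws: each run samples the population and outdoor field first
and applies the scenario transform afterwards, so paired runs with the same
seed differ only through the intervention. The samplers consume a fixed
number of random draws regardless of parameter values to keep this pairing
exact. Notable encodings:

* **Ex-80/50/20-r** multiplies *current* cooking emissions by 0.8/0.5/0.2
  (so a coal household's chimney factor 0.10 becomes 0.08/0.05/0.02); this
  guarantees per-individual monotonicity of the exhaust chain.
* **Ex-u** is quantified as all urban households reaching hood-level
  ERF 0.5 (no numeric air-exchange increase is reported, so the ERF route
  uses only reported numbers).
* **Atm-WHO** rescales each replicate's field uniformly per season so that
  seasonal B[a]Peq equals 1.2/0.381 ≈ 3.15 ng/m³ (the BaP guideline divided
  by BaP's average share of B[a]Peq), preserving the congener profile.
* **CF** re-assigns a seeded random half (or all) of solid-fuel households
  to LPG at equal delivered cooking energy (23, 15.5, 46.1 MJ/kg for coal,
  biomass, LPG).
* **SF** removes smoking from homes *and* workplaces.

## Numerical choices

Quantiles use linear interpolation between order statistics (type 7);
exposure-pattern dominance ties are broken by the fixed priority OUT-in >
IN-in > OUT-out (ties are measure-zero under continuous sampling);
truncated normals are sampled by inverse-CDF so truncation never distorts
the random stream; sensitivity sweeps shift a parameter's central value by
±1 SD while keeping its SD, under common random numbers. Default run size
is 10,000 individuals per scenario — the replication count the study design
calls for — which the vectorized engine completes for all 15 scenarios in
about a second; the test suite uses 10,000 for the headline checks and
smaller sizes (300–4,000) for properties that do not need tight Monte Carlo
error.

## Limitations

Single-stage Monte Carlo only: variability and parameter uncertainty are
not separated (the one-at-a-time sweep is the uncertainty instrument).
Seasonal-average concentrations support chronic-risk estimates only, not
acute effects; phase-specific concentrations are diagnostic internals, not
suitable for dermal/ingestion pathways; IN-out exposure (one's own
emissions met outdoors) is ignored. Absolute PAF/PIF levels depend on the
placeholder emission inventory and should be read as illustrative; the
qualitative intervention ordering is the robust output, and the published
cross-URR risk table is reproduced exactly from its own PAF columns by the
package's PAF/PIF identities (see `scripts/acceptance.R`).
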