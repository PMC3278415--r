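---
title: "Modelling the household economics of improved cookstoves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the household economics of improved cookstoves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stovecba)
```

## The decision problem

Over a third of the world's households cook on traditional biomass
stoves.  Replacing such a stove with an improved wood-burning stove, a
charcoal stove, or a kerosene, LPG or electric one changes the
household's monthly budget in many directions at once: a capital
outlay, program and maintenance charges, a different fuel bill (in
money and in collection time), a learning period, and — on the benefit
side — fewer respiratory infections, less chronic lung disease, saved
cooking time, lower greenhouse-gas emissions and less pressure on
forests.  None of these quantities is known precisely for a "typical"
developing-country household; published estimates span wide ranges.

`stovecba` evaluates the monthly net benefit of a stove transition as
a deterministic function of roughly thirty parameters, and propagates
parameter uncertainty through that function by Monte Carlo simulation
with rank-correlated uniform draws.  The unit of analysis is a single
household; all quantities are US$ per household-month.

## The deterministic model

Let $\chi$ denote sustained use, the fraction of cooking actually done
on the new stove; every use-dependent term scales with it.  With
discount rate $\delta$ (private or social, by perspective) and stove
lifespan $T_i$, the capital recovery factor is

$$crf(\delta, T_i) = \frac{\delta (1+\delta)^{T_i}}{(1+\delta)^{T_i} - 1},$$

the constant annual payment per dollar of capital.  Monthly costs of
adopting stove $i$ are:

* **Capital** $cc_i \cdot crf / 12$, net of any capital subsidy under
  the private perspective.  The traditional baseline stove is sunk and
  carries no capital cost.
* **Program** $cp / 12$ — promotion and delivery expenses per
  household.
* **Maintenance** $\chi (cm_i - cm_0)/12$, zero for the traditional
  wood baseline's own upkeep.
* **Net fuel** $\chi (C_i - C_0)$, where the baseline wood cost
  $C_0 = f\, p_0 F_0 + collt_0 \cdot days \cdot v^t w$ combines
  purchased wood with shadow-valued collection time; the improved wood
  stove scales collection time with its smaller fuel mass
  ($F_i / F_0$) and adds a daily wood-preparation term; all other
  fuels are assumed ready to use, $C_i = p_i F_i$.  This term is
  frequently negative — fuel savings.
* **Learning** a one-time self-familiarization period (hours), valued
  at $v^t w$ and annualized like capital.  Its default length is zero
  because no published range for it exists; it is a catalog constant
  that can be overridden, and the term is implemented and tested.

Fuel demand follows from useful-energy equivalence: the baseline stove
burns $F_0 = cookt_0 \cdot fuelt_0 \cdot days$ kg of wood, delivering
$F_0\, \mu_0\, \varepsilon_{f0}$ MJ of useful cooking energy, and any
fuel-burning alternative must deliver the same:
$F_i = F_0\, \mu_0 \varepsilon_{f0} / (\mu_i \varepsilon_{fi})$.  The
electric stove is metered per hour of cooking instead
($cookt_0 \cdot \varepsilon_{t,e} \cdot days$ hours at a drawn kW-hr
per hour).  The charcoal-baseline comparison (traditional to improved
charcoal stove) has no published direct consumption figure, so its
baseline demand is derived by the same useful-energy equivalence from
the wood-baseline household — the only internally consistent route.

Monthly benefits:

* **Morbidity** $\chi \cdot hhsize \cdot [I^{ARI} \Delta\eta^{ARI}
  COI^{ARI} + P^{COPD} \Delta\eta^{COPD} COI^{COPD} (1+\delta)^{-d}]/12$:
  averted acute respiratory infection cases valued at their cost of
  illness, plus averted chronic obstructive pulmonary disease
  prevalence discounted over the delay $d$ to symptom onset.
  Effectiveness enters as the difference between candidate and
  baseline stove effectiveness relative to the traditional wood stove.
* **Mortality** values the averted death risk at the value of a
  statistical life: the ALRI case-fatality channel for ARI and the
  chronic death rate channel for COPD (discounted over $d$).  See the
  calibration note below.
* **Time savings** $\chi \cdot cookt_0 (\varepsilon_{t0} -
  \varepsilon_{ti}) \cdot days \cdot v^t w$ — negative when the new
  stove is slower (the improved wood stove's relative time efficiency
  ranges up to 1.5).
* **Carbon** $ccarb \cdot \chi (E_0 - E_i)/10^6$, with emissions
  $E = F \mu \gamma$ grams CO2-eq per month, under either the basic
  accounting (CO2, CH4, N2O) or the extended one that adds CO,
  non-methane hydrocarbons and black carbon (heavier biomass
  intensities).  Electricity is accounted per kW-hr of generation.
* **Forest** $ce \cdot \chi (wood_0 - wood_i)$: biomass is assumed
  sustainably harvested, so avoided wood demand is valued at the tree
  replacement cost.  Charcoal's upstream wood demand is not counted
  (no defensible conversion factor is available in the catalog).

The private perspective sums morbidity, mortality and time savings
against all monetary costs, with the private discount rate; a
carbon-offset transfer optionally adds the carbon term (but never the
forest term, which is not an emissions offset) as a payment or charge.
The social perspective adds carbon and forest benefits, uses the
social discount rate and ignores subsidies (a subsidy is a transfer,
not a resource cost).  By construction, on any draw, social net
benefits equal private net benefits at the same discount rate plus the
carbon and forest terms — an identity the test suite asserts exactly.

## The parameter catalog

`default_catalog()` ships the published low/mid/high ranges for every
parameter, per-stove blocks for six candidate stoves, fuel properties
(energy content, price range, carbon intensities under both
accountings) and the assumed rank correlations.  Percentages and
deaths-per-10,000 are normalized to fractions at load time.  The `mid`
column is the stated central estimate, *not* the midpoint of the
bounds — stove costs, the wage, collection time and the ARI cost of
illness are all strongly right-skewed — and midpoint evaluations and
tornado baselines use it deliberately.

Two constants deserve mention.  `days_per_month = 30` converts daily
quantities to monthly; the round convention is immaterial next to the
parameter ranges.  `learning_hours = 0` keeps the learning-cost term
switched off by default, as discussed above.

## Uncertainty propagation

Parameters are uniform on their ranges: there is no empirical basis
for any more specific distribution, and the simulation is read as a
map of plausible outcomes rather than a probability forecast.
Pairwise rank correlations (most of magnitude 0.5, e.g. stove cost
with lifespan, wage with the value of a statistical life) prevent
implausible corner combinations.

Rank correlation is induced by the Iman–Conover method: independently
drawn uniforms are reordered, column by column, to follow the rank
pattern of a correlated multivariate-normal reference sample (with the
usual correction that makes the reference sample's realized
correlation exact).  The method is distribution-free, so marginals
remain exactly uniform.  Spearman targets are converted to the normal
scores' Pearson scale by $\rho_P = 2\sin(\pi\rho_S/6)$.

The assumed correlation list, taken jointly, is far from positive
semidefinite — the wage alone is assigned a correlation of 0.5–0.7
with a dozen partners, which no valid joint distribution can carry.
The assembled matrix is therefore repaired by eigenvalue clipping
(eigenvalues floored at $10^{-3}$, matrix recomposed and rescaled to
unit diagonal).  The floor is kept distinctly positive so the repaired
matrix remains comfortably full-rank; the repair is flagged on the
returned object, and the sampler reports the *induced* rank-correlation
targets ($\frac{6}{\pi}\arcsin(\rho/2)$ of the repaired Pearson
matrix), which the recovery tests use as their reference.  In
practice, entries shrink: the wage–VSL assumption of 0.7 is realized
at about 0.47.  This is an honest consequence of inconsistent pairwise
assumptions, not a tuning choice.

Percentiles are empirical with linear interpolation between order
statistics (R's default type 7).  All scenarios within a run share one
draw matrix (common random numbers), so cross-stove contrasts are
paired; no further variance reduction is used.

## Calibration of the mortality term

The published description of the mortality benefit multiplies
incidence, the severe-ALRI fraction, its case fatality, stove
effectiveness, household size and the value of a statistical life.
Read literally, at catalog midpoints this yields about $11 per
household-month at full use — several times the entire net benefit any
published summary of the model accommodates, so the literal reading
cannot be what produced those summaries.  The package therefore
exposes the attribution of mortality risk as a documented switch
(`model_options()`): `mort_hhsize` applies household size or not, and
`mort_child_fraction` weights the ALRI term by the share of household
exposure that actually carries death risk.

The default — `mort_hhsize = FALSE`, `mort_child_fraction = 0.1` —
attributes COPD mortality to the primary cook and ALRI mortality to
the young-child fraction of exposure (ALRI deaths are concentrated in
infants and very young children).  The value 0.1 was fixed once,
jointly against the package's reproduction targets (the sustained-use
sensitivity endpoints and the private median table), and is echoed in
every run manifest so the choice is auditable.  The literal
household-wide reading remains available
(`mort_hhsize = TRUE, mort_child_fraction = 1`) and is covered by the
tests.

A second documented switch, `gamma_basis`, controls whether carbon
intensities multiply MJ of fuel heat (`"fuel"`, the default) or MJ of
useful cooking energy (`"useful"`).  The catalog labels the
intensities per useful MJ, but their magnitudes (wood at 12.1 g/MJ
under sustainable-harvest carbon neutrality) are only coherent on the
per-fuel-heat reading; both are implemented.

## What the simulation does and does not show

A run of `run_simulation()` or `table4()` with the default catalog
reproduces the qualitative structure of the published analysis: the
kerosene and LPG transitions are the most attractive privately, their
distributions widened mainly by the cost of illness, wage and
collection-time parameters; the improved wood stove hovers around
break-even with sustained use and relative time efficiency dominating
its tornado; the electric stove is dragged down by its capital cost
and made *worse* by a carbon-offset transfer wherever generation is
emissions-intensive.  The deterministic worked example — social net
benefits of the improved wood stove at sustained use 0.2 versus 0.8,
all else at midpoints — brackets the published pair within a few cents
per household-month.

One quantitative feature of the published percentile table is not
reproducible under any single reading of the published equations, and
the package does not force it.  Because the wage (0.13/0.2/0.5 $/hr),
collection time (0.3/1/3 hrs/day) and ARI cost of illness (2/15/60
$/case) ranges are strongly right-skewed, the Monte Carlo median of
every wood-baseline transition sits well above its all-midpoint
evaluation — about +$1.6/hh-month for the unimproved charcoal
transition, decomposable almost entirely into those three parameters.
The published kerosene median *requires* this lift (it lies ~$2.3
above its midpoint evaluation, where this package lands); the
published charcoal median *forbids* it (it coincides with the midpoint
evaluation).  The package follows the equations, with the
consequences that the simulated charcoal median is mildly positive
rather than mildly negative, the electric rather than the charcoal
transition ranks last, and the improved wood stove clears its costs in
somewhat more than half the draws.  The corresponding checks in
`tests/testthat/test-acceptance.R` are left failing by design, with
this analysis as their explanation.

## Problem sizes and numerics

The reference experiment uses 10,000 draws, the published size; it
runs in well under a second, and the full four-block percentile table
in a few seconds.  The test suite reuses one cached 10,000-draw matrix
and smaller (a few hundred to a few thousand draw) runs for
property checks; percentile stability under doubling of the draw count
is asserted against the usual quantile standard error
$\sqrt{p(1-p)/n}/\hat f(q)$.  Degenerate catalogs (all ranges
collapsed to the mid value) are supported throughout and collapse the
Monte Carlo exactly onto the midpoint evaluation, which anchors the
tornado baseline and several consistency tests.  Division guards:
zero cooking time yields zero fuel demand and a zero collection-time
ratio rather than 0/0; heat-transfer efficiencies must be strictly
positive.

## Limitations

Inconvenience costs, aesthetic gains and social standing are excluded
(no credible valuations exist); health externalities from
community-level adoption are excluded; exposure–response is linear in
sustained use, with no threshold or saturating variant; intra-household
distribution of benefits is not modelled; charcoal production's wood
demand is not charged to the forest term.  The uniform-with-rank-
correlation uncertainty model reflects ranges found in the literature,
not site-specific joint distributions: percentile outputs should be
read as "the range of outcomes across plausible settings", never as a
probability distribution for any particular place.
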