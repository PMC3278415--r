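# Default parameter catalog for the household cookstove cost-benefit model.
#
# Every uncertain quantity is a low/mid/high triple: the support of a
# uniform distribution plus the central estimate used for midpoint and
# one-way sensitivity evaluations (the mid value is the stated central
# estimate, not necessarily (low+high)/2).  Values are recorded in their
# originally published units; entries with units `percent` or `per_10000`
# are rescaled to fractions/probabilities when the catalog is loaded.
#
# The traditional wood stove is the reference technology: its capital and
# learning costs are sunk (no cc/lifespan entries) and its time efficiency
# is 1 by definition.  Maintenance cost `cm` applies to every stove except
# the traditional wood baseline, for which it is zero.

constants:
  days_per_month: 30     # daily-to-monthly conversion used throughout
  learning_hours: 0      # one-time self-learning period for a new stove (hrs)

globals:
  delta_s:    {low: 3,     mid: 4.5,   high: 6,     units: percent}          # social discount rate, /yr
  delta_p:    {low: 10,    mid: 15,    high: 20,    units: percent}          # private rate of time preference, /yr
  cp:         {low: 0.2,   mid: 2.0,   high: 3.8,   units: US$/hh-yr}        # stove promotion (program) cost
  chi:        {low: 0.2,   mid: 0.5,   high: 0.8,   units: fraction}         # sustained use of the new stove
  cm:         {low: 1.4,   mid: 1.4,   high: 1.4,   units: US$/hh-yr}        # maintenance, all non-traditional stoves
  cookt0:     {low: 2,     mid: 3,     high: 4,     units: hrs/day}          # baseline daily cooking time
  fuelt0:     {low: 0.3,   mid: 0.6,   high: 1.0,   units: kg/hr}            # wood burned per hour of baseline cooking
  collt0:     {low: 0.3,   mid: 1.0,   high: 3.0,   units: hrs/day}          # baseline wood collection/preparation time
  prep:       {low: 0.17,  mid: 0.33,  high: 0.50,  units: hrs/day}          # wood preparation time for the improved wood stove
  f_purch:    {low: 0,     mid: 25,    high: 50,    units: percent}          # fraction of wood purchased rather than collected
  hhsize:     {low: 4,     mid: 5,     high: 6,     units: persons/hh}
  inc_ari:    {low: 0.1,   mid: 0.5,   high: 1.0,   units: cases/person-yr}  # ARI incidence
  prev_copd:  {low: 1,     mid: 4.5,   high: 8,     units: percent}          # COPD prevalence
  coi_ari:    {low: 2,     mid: 15,    high: 60,    units: US$/case}         # cost of illness, non-severe ARI
  coi_copd:   {low: 30,    mid: 35,    high: 40,    units: US$/yr}           # cost of illness, COPD
  copd_delay: {low: 10,    mid: 15,    high: 20,    units: yrs}              # delay to COPD symptom onset
  vsl:        {low: 10000, mid: 30000, high: 50000, units: US$}              # value of a statistical life
  f_alri:     {low: 0.04,  mid: 0.15,  high: 0.25,  units: fraction}         # share of ARI that is severe ALRI
  cfr_alri:   {low: 0.01,  mid: 0.03,  high: 0.05,  units: deaths/case}      # ALRI case fatality rate
  drate_copd: {low: 0,     mid: 1,     high: 2,     units: per_10000}        # COPD death rate, /person-yr
  vt:         {low: 0.1,   mid: 0.3,   high: 0.5,   units: fraction}         # shadow value of time (fraction of wage)
  w:          {low: 0.13,  mid: 0.2,   high: 0.5,   units: US$/hr}           # unskilled market wage
  ccarb:      {low: 5,     mid: 20,    high: 35,    units: US$/ton}          # cost of carbon, CO2-eq
  ce:         {low: 0.002, mid: 0.01,  high: 0.02,  units: US$/kg}           # tree replacement cost per kg wood

stoves:
  wood_traditional:
    fuel: wood
    eps_t:   {low: 1,    mid: 1,    high: 1,    units: fraction}
    eps_f:   {low: 7,    mid: 11,   high: 15,   units: percent}
    eta_ari: {low: 0,    mid: 0,    high: 0,    units: percent}
    eta_copd: {low: 0,   mid: 0,    high: 0,    units: percent}
  wood_ics:
    fuel: wood
    cc:      {low: 5,    mid: 15,   high: 50,   units: US$}
    lifespan: {low: 2,   mid: 3,    high: 4,    units: yrs}
    eps_t:   {low: 0.7,  mid: 0.95, high: 1.5,  units: fraction}
    eps_f:   {low: 13,   mid: 25,   high: 40,   units: percent}
    eta_ari: {low: 10,   mid: 40,   high: 70,   units: percent}
    eta_copd: {low: 0,   mid: 15,   high: 30,   units: percent}
  charcoal_traditional:
    fuel: charcoal
    cc:      {low: 3,    mid: 4.5,  high: 6,    units: US$}
    lifespan: {low: 2,   mid: 3,    high: 4,    units: yrs}
    eps_t:   {low: 0.6,  mid: 0.75, high: 1.0,  units: fraction}
    eps_f:   {low: 18,   mid: 20,   high: 21,   units: percent}
    eta_ari: {low: 0,    mid: 20,   high: 40,   units: percent}
    eta_copd: {low: 0,   mid: 5,    high: 10,   units: percent}
  charcoal_ics:
    fuel: charcoal
    cc:      {low: 3,    mid: 14,   high: 50,   units: US$}
    lifespan: {low: 2,   mid: 3,    high: 4,    units: yrs}
    eps_t:   {low: 0.6,  mid: 0.75, high: 1.0,  units: fraction}
    eps_f:   {low: 15,   mid: 26,   high: 37,   units: percent}
    eta_ari: {low: 10,   mid: 40,   high: 70,   units: percent}
    eta_copd: {low: 0,   mid: 15,   high: 30,   units: percent}
  kerosene:
    fuel: kerosene
    cc:      {low: 10,   mid: 30,   high: 60,   units: US$}
    lifespan: {low: 4,   mid: 5,    high: 6,    units: yrs}
    eps_t:   {low: 0.5,  mid: 0.7,  high: 0.9,  units: fraction}
    eps_f:   {low: 40,   mid: 45,   high: 50,   units: percent}
    eta_ari: {low: 45,   mid: 60,   high: 75,   units: percent}
    eta_copd: {low: 0,   mid: 20,   high: 40,   units: percent}
  lpg:
    fuel: propane
    cc:      {low: 60,   mid: 90,   high: 120,  units: US$}
    lifespan: {low: 5,   mid: 10,   high: 15,   units: yrs}
    eps_t:   {low: 0.45, mid: 0.67, high: 0.9,  units: fraction}
    eps_f:   {low: 50,   mid: 55,   high: 60,   units: percent}
    eta_ari: {low: 45,   mid: 60,   high: 75,   units: percent}
    eta_copd: {low: 0,   mid: 20,   high: 40,   units: percent}
  electric:
    fuel: electricity
    cc:      {low: 100,  mid: 300,  high: 500,  units: US$}
    lifespan: {low: 10,  mid: 15,   high: 20,   units: yrs}
    eps_t:   {low: 0.35, mid: 0.63, high: 0.9,  units: fraction}
    # for the electric stove this is consumption per hour of cooking,
    # not a heat-transfer ratio
    eps_f:   {low: 1.10, mid: 1.65, high: 2.20, units: kW-hr/hr}
    eta_ari: {low: 45,   mid: 60,   high: 75,   units: percent}
    eta_copd: {low: 0,   mid: 20,   high: 40,   units: percent}

fuels:
  wood:
    energy_content: 16         # MJ/kg
    price: {low: 0.03, mid: 0.12, high: 0.2, units: US$/kg}
    gamma_basic: 12.1          # g CO2-eq/MJ: CO2, CH4, N2O only
    gamma_extended: 225        # adds CO, NMHC and black carbon
  charcoal:
    energy_content: 30
    price: {low: 0.1, mid: 0.45, high: 0.8, units: US$/kg}
    gamma_basic: 5.6
    gamma_extended: 410
  kerosene:
    energy_content: 35
    price: {low: 0.3, mid: 0.5, high: 0.7, units: US$/kg}
    gamma_basic: 157.4
    gamma_extended: 157.4
  propane:
    energy_content: 45
    price: {low: 0.4, mid: 0.7, high: 1.0, units: US$/kg}
    gamma_basic: 107.9
    gamma_extended: 107.9
  electricity:
    energy_content: 3.6        # MJ/kW-hr
    price: {low: 0.03, mid: 0.065, high: 0.10, units: US$/kW-hr}
    # generation mix varies by location; same range under both accountings
    gamma_basic: {low: 70, mid: 170, high: 270, units: g/kW-hr}
    gamma_extended: {low: 70, mid: 170, high: 270, units: g/kW-hr}
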