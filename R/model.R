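# Deterministic monthly cost-benefit model for one stove transition.
#
# All component functions are vectorized over the rows of a draw matrix
# (a data frame with one column per parameter id, as produced by
# midpoint_draw() or sample_draws()), so a full Monte Carlo experiment is
# a single vectorized evaluation.

#' Model options
#'
#' Switches controlling the documented modelling ambiguities.  Defaults
#' reproduce the package's reference configuration and are echoed in
#' every run manifest.
#'
#' @param gamma_basis Basis on which fuel carbon intensities are applied:
#'   `"fuel"` (grams CO2-eq per MJ of fuel heat, the default) or
#'   `"useful"` (per MJ of useful cooking energy, i.e. additionally
#'   multiplied by the stove's heat-transfer efficiency).  Electricity is
#'   always accounted per kW-hr delivered.
#' @param mort_hhsize Multiply mortality risk by household size
#'   (`FALSE` by default: mortality is attributed to the exposed
#'   individual — the young child for ALRI, the primary cook for COPD —
#'   rather than to every household member).
#' @param mort_child_fraction Weight applied to the ALRI mortality term
#'   for the share of household exposure that carries mortality risk
#'   (ALRI deaths are concentrated in infants and very young children;
#'   default 0.1).  Together with `mort_hhsize` this is the package's
#'   documented calibration of the mortality term, whose exact published
#'   form is not recoverable; the choice is echoed in run manifests.
#' @return A list of class `cba_options`.
#' @export
model_options <- function(gamma_basis = c("fuel", "useful"),
                          mort_hhsize = FALSE,
                          mort_child_fraction = 0.1) {
  gamma_basis <- match.arg(gamma_basis)
  stopifnot(is.logical(mort_hhsize), length(mort_hhsize) == 1,
            is.numeric(mort_child_fraction), mort_child_fraction >= 0,
            mort_child_fraction <= 1)
  structure(list(gamma_basis = gamma_basis, mort_hhsize = mort_hhsize,
                 mort_child_fraction = mort_child_fraction),
            class = "cba_options")
}

#' Stove transition scenario
#'
#' @param candidate Stove adopted by the household; one of
#'   `wood_ics`, `charcoal_traditional`, `charcoal_ics`, `kerosene`,
#'   `lpg`, `electric`.
#' @param baseline Stove given up: `wood_traditional` (default) or
#'   `charcoal_traditional` (the latter only for the move to the
#'   improved charcoal stove).
#' @param perspective `"private"` (household costs and benefits only) or
#'   `"social"` (adds carbon and forest benefits, uses the social
#'   discount rate, ignores subsidies).
#' @param accounting Carbon accounting variant: `"basic"` (CO2, CH4,
#'   N2O) or `"extended"` (adds CO, NMHC and black carbon).
#' @param capital_subsidy Fraction of the stove's capital cost paid by a
#'   subsidy; applied under the private perspective only.
#' @param carbon_offset Transfer the monetized emissions change to the
#'   household as a private payment or charge (the carbon-offset
#'   subsidy).  Forest-replacement benefits are never transferred.
#' @param discount Discount-rate override: `"default"` picks the rate
#'   matching the perspective; `"social"`/`"private"` force one (used for
#'   the algebraic perspective identity).
#' @return An object of class `cba_scenario`.
#' @examples
#' scenario("wood_ics", perspective = "social")
#' @export
scenario <- function(candidate,
                     baseline = "wood_traditional",
                     perspective = c("private", "social"),
                     accounting = c("basic", "extended"),
                     capital_subsidy = 0,
                     carbon_offset = FALSE,
                     discount = c("default", "social", "private")) {
  perspective <- match.arg(perspective)
  accounting <- match.arg(accounting)
  discount <- match.arg(discount)
  if (!candidate %in% STOVE_IDS) {
    stop(sprintf("unknown candidate stove '%s'; valid ids: %s", candidate,
                 paste(setdiff(STOVE_IDS, "wood_traditional"), collapse = ", ")),
         call. = FALSE)
  }
  if (!baseline %in% BASELINE_IDS) {
    stop(sprintf("baseline must be one of: %s",
                 paste(BASELINE_IDS, collapse = ", ")), call. = FALSE)
  }
  if (candidate == baseline) {
    stop("candidate and baseline stove must differ", call. = FALSE)
  }
  if (baseline == "charcoal_traditional" && candidate != "charcoal_ics") {
    stop("the charcoal baseline is only compared with the improved charcoal stove",
         call. = FALSE)
  }
  if (capital_subsidy < 0 || capital_subsidy > 1) {
    stop("capital_subsidy must lie in [0, 1]", call. = FALSE)
  }
  structure(list(candidate = candidate, baseline = baseline,
                 perspective = perspective, accounting = accounting,
                 capital_subsidy = capital_subsidy,
                 carbon_offset = isTRUE(carbon_offset),
                 discount = discount),
            class = "cba_scenario")
}

#' @export
print.cba_scenario <- function(x, ...) {
  cat(sprintf("%s -> %s | %s perspective, %s accounting%s%s\n",
              x$baseline, x$candidate, x$perspective, x$accounting,
              if (x$capital_subsidy > 0)
                sprintf(", %d%% capital subsidy", round(100 * x$capital_subsidy))
              else "",
              if (x$carbon_offset) ", carbon offset transferred" else ""))
  invisible(x)
}

#' Short identifier for a scenario
#' @param s A `cba_scenario`.
#' @return A single string naming the scenario.
#' @export
scenario_id <- function(s) {
  paste0(s$candidate,
         if (s$baseline == "charcoal_traditional") "_from_charcoal" else "",
         "_", s$perspective, "_", s$accounting,
         if (s$carbon_offset) "_offset" else "",
         if (s$capital_subsidy > 0)
           paste0("_sub", round(100 * s$capital_subsidy)) else "")
}

.col <- function(draws, id) {
  x <- draws[[id]]
  if (is.null(x)) {
    stop(sprintf("draw matrix has no column '%s'", id), call. = FALSE)
  }
  x
}

.discount_rate <- function(draws, scn) {
  switch(scn$discount,
         default = if (scn$perspective == "private") .col(draws, "delta_p")
                   else .col(draws, "delta_s"),
         private = .col(draws, "delta_p"),
         social = .col(draws, "delta_s"))
}

#' Capital recovery factor
#'
#' The constant annual payment, per dollar of capital, that repays the
#' capital over `lifespan` years at discount rate `rate`:
#' \deqn{crf = \delta (1+\delta)^T / ((1+\delta)^T - 1),}
#' with the undiscounted limit \eqn{1/T} at \eqn{\delta = 0}.
#'
#' @param rate Discount rate, fraction per year (>= 0).
#' @param lifespan Stove lifespan in years (>= 1).
#' @return Fraction of the capital cost per year; vectorized.
#' @examples
#' capital_recovery_factor(0.045, 3)   # ~0.3638
#' capital_recovery_factor(0, 4)       # 0.25
#' @export
capital_recovery_factor <- function(rate, lifespan) {
  if (any(lifespan <= 0)) stop("lifespan must be positive", call. = FALSE)
  if (any(rate < 0)) stop("discount rate must be non-negative", call. = FALSE)
  g <- (1 + rate)^lifespan
  ifelse(rate == 0, 1 / lifespan, rate * g / (g - 1))
}

#' Baseline fuel demand and useful cooking energy
#'
#' Monthly fuel consumption of the baseline stove and the useful cooking
#' energy it delivers.  For the wood baseline, fuel is cooking time
#' multiplied by the hourly wood requirement; for the charcoal baseline
#' (which has no direct consumption data) demand is derived by
#' useful-energy equivalence with the same household's wood requirement.
#'
#' @param draws Draw matrix (data frame of parameter columns).
#' @param catalog A `stove_catalog`.
#' @param baseline `"wood_traditional"` or `"charcoal_traditional"`.
#' @return Data frame with columns `fuel_kg` (kg/month) and `useful_mj`
#'   (MJ/month), one row per draw.
#' @export
baseline_energy_and_fuel <- function(draws, catalog,
                                     baseline = "wood_traditional") {
  stopifnot(baseline %in% BASELINE_IDS)
  eps_f0 <- .col(draws, "wood_traditional.eps_f")
  if (any(eps_f0 <= 0)) {
    stop("baseline heat-transfer efficiency must be positive", call. = FALSE)
  }
  days <- catalog$constants$days_per_month
  mu_wood <- catalog$fuels$wood$energy_content
  wood_kg <- .col(draws, "cookt0") * .col(draws, "fuelt0") * days
  useful <- wood_kg * mu_wood * eps_f0
  if (baseline == "wood_traditional") {
    fuel_kg <- wood_kg
  } else {
    eps_fc <- .col(draws, "charcoal_traditional.eps_f")
    if (any(eps_fc <= 0)) {
      stop("baseline heat-transfer efficiency must be positive", call. = FALSE)
    }
    fuel_kg <- useful / (catalog$fuels$charcoal$energy_content * eps_fc)
  }
  data.frame(fuel_kg = fuel_kg, useful_mj = useful)
}

#' Monthly fuel use of a stove
#'
#' Fuel required by stove `stove` to deliver the household's baseline
#' useful cooking energy: `useful_mj / (mu_i * eps_f_i)` for fuel-burning
#' stoves.  The electric stove is metered per hour of cooking instead:
#' `cookt0 * eps_t_electric * days * (kW-hr per cooking hour)`.
#'
#' @inheritParams baseline_energy_and_fuel
#' @param stove Stove id.
#' @return Numeric vector: kg/month (kW-hr/month for the electric stove).
#' @export
candidate_fuel_use <- function(draws, catalog, stove) {
  stopifnot(stove %in% names(catalog$stoves))
  days <- catalog$constants$days_per_month
  if (catalog$stoves[[stove]]$fuel == "electricity") {
    return(.col(draws, "cookt0") * .col(draws, paste0(stove, ".eps_t")) *
             days * .col(draws, paste0(stove, ".eps_f")))
  }
  eps_f <- .col(draws, paste0(stove, ".eps_f"))
  if (any(eps_f <= 0)) {
    stop("heat-transfer efficiency must be positive", call. = FALSE)
  }
  useful <- baseline_energy_and_fuel(draws, catalog, "wood_traditional")$useful_mj
  mu <- catalog$fuels[[catalog$stoves[[stove]]$fuel]]$energy_content
  useful / (mu * eps_f)
}

#' Net monthly fuel cost of a stove transition
#'
#' Difference between the candidate's and the baseline's monthly fuel
#' cost — in money for purchased fuel and in shadow-valued time for
#' collected and prepared wood — scaled by the sustained-use fraction.
#' Negative values are fuel-cost savings.  The wood baseline cost
#' combines purchased wood (`f * p_wood * F0`) with collection time; the
#' improved wood stove scales collection time with its (smaller) fuel
#' mass and adds a wood-preparation term; non-wood fuels are assumed
#' ready to use, so their cost is purely monetary.
#'
#' @inheritParams baseline_energy_and_fuel
#' @param scn A `cba_scenario` (only the stove pairing is used).
#' @return Numeric vector, US$/hh-month.
#' @export
net_fuel_cost <- function(draws, catalog, scn) {
  base <- scn$baseline; cand <- scn$candidate
  if (cand == base) return(rep(0, nrow(draws)))
  days <- catalog$constants$days_per_month
  chi <- .col(draws, "chi")
  vt_w <- .col(draws, "vt") * .col(draws, "w")
  bef <- baseline_energy_and_fuel(draws, catalog, base)

  if (base == "wood_traditional") {
    c0 <- .col(draws, "f_purch") * .col(draws, "price.wood") * bef$fuel_kg +
      .col(draws, "collt0") * days * vt_w
  } else {
    c0 <- .col(draws, "price.charcoal") * bef$fuel_kg
  }

  fi <- candidate_fuel_use(draws, catalog, cand)
  cand_fuel <- catalog$stoves[[cand]]$fuel
  if (cand_fuel == "wood") {
    f0_wood <- baseline_energy_and_fuel(draws, catalog, "wood_traditional")$fuel_kg
    ratio <- ifelse(f0_wood > 0, fi / f0_wood, 0)
    ci <- .col(draws, "f_purch") * .col(draws, "price.wood") * fi +
      .col(draws, "collt0") * ratio * days * vt_w +
      .col(draws, "prep") * days * vt_w
  } else {
    ci <- .col(draws, paste0("price.", cand_fuel)) * fi
  }
  chi * (ci - c0)
}

#' Fixed monthly costs of a stove transition
#'
#' Annualized capital (net of any subsidy under the private
#' perspective), program, maintenance and learning costs.  The baseline
#' stove's capital and learning costs are sunk, hence zero; maintenance
#' is the use-weighted difference against the baseline's upkeep cost
#' (zero for the traditional wood stove).
#'
#' @inheritParams net_fuel_cost
#' @param options A `cba_options` list.
#' @return Data frame with columns `cap`, `prog`, `om`, `learn`
#'   (US$/hh-month).
#' @export
fixed_costs <- function(draws, catalog, scn, options = model_options()) {
  delta <- .discount_rate(draws, scn)
  cand <- scn$candidate
  crf <- capital_recovery_factor(delta, .col(draws, paste0(cand, ".lifespan")))
  subsidy <- if (scn$perspective == "private") scn$capital_subsidy else 0
  cap <- .col(draws, paste0(cand, ".cc")) * crf / 12 * (1 - subsidy)
  prog <- .col(draws, "cp") / 12
  cm_base <- if (scn$baseline == "wood_traditional") 0 else .col(draws, "cm")
  om <- .col(draws, "chi") * (.col(draws, "cm") - cm_base) / 12
  learn <- catalog$constants$learning_hours * .col(draws, "vt") *
    .col(draws, "w") * crf / 12
  data.frame(cap = cap, prog = prog, om = om, learn = learn)
}

#' Monthly health benefits of a stove transition
#'
#' Morbidity benefits value averted ARI cases at their cost of illness
#' and the averted COPD prevalence at its annual cost of illness,
#' discounted over the delay to disease onset.  Mortality benefits value
#' the averted risk of death — ALRI case fatality for ARI, the chronic
#' death rate for COPD — at the value of a statistical life.  Stove
#' effectiveness enters as the difference between candidate and baseline
#' effectiveness relative to the traditional wood stove, and all terms
#' scale with sustained use.  The attribution of mortality risk
#' (household-wide or to the exposed individual, with an under-five
#' weight on ALRI deaths) is controlled by [model_options()].
#'
#' @inheritParams fixed_costs
#' @return Data frame with columns `morb` and `mort` (US$/hh-month).
#' @export
health_benefits <- function(draws, catalog, scn, options = model_options()) {
  delta <- .discount_rate(draws, scn)
  chi <- .col(draws, "chi")
  hh <- .col(draws, "hhsize")
  d_eta_ari <- .col(draws, paste0(scn$candidate, ".eta_ari")) -
    .col(draws, paste0(scn$baseline, ".eta_ari"))
  d_eta_copd <- .col(draws, paste0(scn$candidate, ".eta_copd")) -
    .col(draws, paste0(scn$baseline, ".eta_copd"))
  onset_disc <- (1 + delta)^(-.col(draws, "copd_delay"))

  morb <- chi * hh *
    (.col(draws, "inc_ari") * d_eta_ari * .col(draws, "coi_ari") +
       .col(draws, "prev_copd") * d_eta_copd * .col(draws, "coi_copd") *
       onset_disc) / 12

  exposed <- if (options$mort_hhsize) hh else 1
  mort <- chi * exposed * .col(draws, "vsl") *
    (options$mort_child_fraction * .col(draws, "inc_ari") *
       .col(draws, "f_alri") * .col(draws, "cfr_alri") * d_eta_ari +
       .col(draws, "drate_copd") * d_eta_copd * onset_disc) / 12
  data.frame(morb = morb, mort = mort)
}

#' Monthly cooking-time savings
#'
#' Time freed by the candidate stove relative to the baseline, valued at
#' the shadow price of time.  Negative when the candidate is slower than
#' the stove it replaces (possible for the improved wood stove, whose
#' relative time efficiency ranges up to 1.5).
#'
#' @inheritParams fixed_costs
#' @return Numeric vector, US$/hh-month.
#' @export
time_savings <- function(draws, catalog, scn, options = model_options()) {
  days <- catalog$constants$days_per_month
  .col(draws, "chi") * .col(draws, "cookt0") *
    (.col(draws, paste0(scn$baseline, ".eps_t")) -
       .col(draws, paste0(scn$candidate, ".eps_t"))) *
    days * .col(draws, "vt") * .col(draws, "w")
}

# emissions of one stove in g CO2-eq per month, given its monthly fuel use
.emissions <- function(draws, catalog, stove, fuel_qty, accounting, options) {
  fuel <- catalog$stoves[[stove]]$fuel
  if (fuel == "electricity") {
    return(fuel_qty * .col(draws, "gamma.electricity"))
  }
  gkey <- if (accounting == "basic") "gamma_basic" else "gamma_extended"
  gamma <- catalog$fuels[[fuel]][[gkey]]$mid
  e <- fuel_qty * catalog$fuels[[fuel]]$energy_content * gamma
  if (options$gamma_basis == "useful") {
    e <- e * .col(draws, paste0(stove, ".eps_f"))
  }
  e
}

#' Monthly greenhouse-gas emissions of a stove
#'
#' Emissions (g CO2-eq per month) implied by the fuel a stove burns to
#' deliver the household's baseline useful cooking energy, under the
#' basic (CO2, CH4, N2O) or extended (plus CO, NMHC, black carbon)
#' accounting.
#'
#' @inheritParams candidate_fuel_use
#' @param accounting `"basic"` or `"extended"`.
#' @param options A `cba_options` list (carbon-intensity basis).
#' @return Numeric vector, g CO2-eq per month.
#' @examples
#' d <- midpoint_draw(default_catalog())
#' monthly_emissions(d, default_catalog(), "wood_traditional")  # ~10454 g
#' @export
monthly_emissions <- function(draws, catalog, stove,
                              accounting = c("basic", "extended"),
                              options = model_options()) {
  accounting <- match.arg(accounting)
  qty <- candidate_fuel_use(draws, catalog, stove)
  .emissions(draws, catalog, stove, qty, accounting, options)
}

#' Monthly environmental benefits of a stove transition
#'
#' Carbon benefits value the change in emissions at the cost of carbon;
#' forest benefits value the change in wood mass burned at the tree
#' replacement cost (biomass is assumed sustainably harvested, so wood
#' carbon is largely recycled and forest loss is valued separately).
#' Charcoal's upstream wood demand is not counted.  Both scale with
#' sustained use.
#'
#' @inheritParams fixed_costs
#' @return Data frame with columns `carb` and `bio` (US$/hh-month).
#' @export
environmental_benefits <- function(draws, catalog, scn,
                                   options = model_options()) {
  bef <- baseline_energy_and_fuel(draws, catalog, scn$baseline)
  fi <- candidate_fuel_use(draws, catalog, scn$candidate)
  e0 <- .emissions(draws, catalog, scn$baseline, bef$fuel_kg,
                   scn$accounting, options)
  ei <- .emissions(draws, catalog, scn$candidate, fi, scn$accounting, options)
  chi <- .col(draws, "chi")
  carb <- .col(draws, "ccarb") * chi * (e0 - ei) / 1e6
  wood0 <- if (catalog$stoves[[scn$baseline]]$fuel == "wood") bef$fuel_kg else 0
  woodi <- if (catalog$stoves[[scn$candidate]]$fuel == "wood") fi else 0
  bio <- .col(draws, "ce") * chi * (wood0 - woodi)
  data.frame(carb = carb, bio = bio)
}

#' Evaluate the full monthly cost-benefit breakdown
#'
#' Composes every cost and benefit component for one scenario over a
#' draw matrix.  The private perspective counts morbidity, mortality and
#' time savings (plus carbon, when the offset transfer is on) against
#' all monetary costs, with capital net of any subsidy; the social
#' perspective additionally counts carbon and forest benefits, uses the
#' social discount rate and ignores subsidies.  Component columns hold
#' the amounts actually entering the net, so excluded components are
#' zero and `net` always equals benefits minus costs column-wise.
#'
#' @inheritParams fixed_costs
#' @return Data frame with columns `cap`, `prog`, `om`, `fuel_net`,
#'   `learn`, `morb`, `mort`, `timesav`, `carb`, `bio`, `net`
#'   (US$/hh-month), one row per draw.
#' @examples
#' cat <- default_catalog()
#' evaluate(midpoint_draw(cat), cat, scenario("wood_ics", perspective = "social"))
#' @export
evaluate <- function(draws, catalog, scn, options = model_options()) {
  stopifnot(inherits(scn, "cba_scenario"))
  fc <- fixed_costs(draws, catalog, scn, options)
  fuel_net <- net_fuel_cost(draws, catalog, scn)
  hb <- health_benefits(draws, catalog, scn, options)
  ts <- time_savings(draws, catalog, scn, options)
  env <- environmental_benefits(draws, catalog, scn, options)

  include_carb <- scn$perspective == "social" || scn$carbon_offset
  include_bio <- scn$perspective == "social"
  carb <- if (include_carb) env$carb else rep(0, nrow(draws))
  bio <- if (include_bio) env$bio else rep(0, nrow(draws))

  net <- hb$morb + hb$mort + ts + carb + bio -
    (fc$cap + fc$prog + fc$om + fuel_net + fc$learn)
  out <- data.frame(cap = fc$cap, prog = fc$prog, om = fc$om,
                    fuel_net = fuel_net, learn = fc$learn,
                    morb = hb$morb, mort = hb$mort, timesav = ts,
                    carb = carb, bio = bio, net = net)
  if (any(!is.finite(as.matrix(out)))) {
    stop("non-finite value in cost-benefit breakdown", call. = FALSE)
  }
  out
}
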