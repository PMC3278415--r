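# Deterministic cost-benefit core: each component against independently
# computed values, plus the model's algebraic identities.

test_that("capital recovery factor matches an amortization oracle", {
  # oracle: the constant annual payment whose discounted sum repays 1
  crf_oracle <- function(rate, lifespan) {
    if (rate == 0) return(1 / lifespan)
    stats::uniroot(function(a) sum(a / (1 + rate)^seq_len(lifespan)) - 1,
                   c(1e-9, 2), tol = 1e-12)$root
  }
  for (case in list(c(0.045, 3), c(0.15, 3), c(0.15, 10), c(0.03, 20))) {
    expect_equal(capital_recovery_factor(case[1], case[2]),
                 crf_oracle(case[1], case[2]), tolerance = 1e-9,
                 label = sprintf("crf(%g, %g)", case[1], case[2]))
  }
  expect_equal(capital_recovery_factor(0.045, 3), 0.3637734,
               tolerance = 1e-6)
  # single-period repayment and undiscounted amortization
  for (d in c(0.01, 0.1, 0.5)) {
    expect_equal(capital_recovery_factor(d, 1), 1 + d)
  }
  expect_equal(capital_recovery_factor(0, 7), 1 / 7)
  expect_error(capital_recovery_factor(0.05, 0), "lifespan")
})

test_that("baseline fuel demand and useful energy follow the midpoints", {
  bef <- baseline_energy_and_fuel(mid_draw, the_catalog)
  expect_equal(bef$fuel_kg, 3 * 0.6 * 30)          # 54 kg/month
  expect_equal(bef$useful_mj, 54 * 16 * 0.11)      # 95.04 MJ/month
  # no cooking, no fuel
  d0 <- set_col(mid_draw, cookt0 = 0)
  bef0 <- baseline_energy_and_fuel(d0, the_catalog)
  expect_equal(bef0$fuel_kg, 0)
  expect_equal(bef0$useful_mj, 0)
  # charcoal baseline by useful-energy equivalence
  befc <- baseline_energy_and_fuel(mid_draw, the_catalog,
                                   "charcoal_traditional")
  expect_equal(befc$fuel_kg, 95.04 / (30 * 0.20))
  expect_equal(befc$useful_mj, 95.04)
  expect_error(
    baseline_energy_and_fuel(set_col(mid_draw, `wood_traditional.eps_f` = 0),
                             the_catalog),
    "efficiency")
})

test_that("candidate fuel use scales by relative energy and efficiency", {
  expect_equal(candidate_fuel_use(mid_draw, the_catalog, "wood_ics"),
               54 * (0.11 / 0.25))                 # 23.76 kg/month
  expect_equal(candidate_fuel_use(mid_draw, the_catalog, "lpg"),
               95.04 / (45 * 0.55))                # ~3.84 kg/month
  # identical energy content x efficiency reproduces the baseline amount
  d <- set_col(mid_draw, `wood_ics.eps_f` = 0.11)
  expect_equal(candidate_fuel_use(d, the_catalog, "wood_ics"), 54)
  # electric metering is per cooking hour
  expect_equal(candidate_fuel_use(mid_draw, the_catalog, "electric"),
               3 * 0.63 * 30 * 1.65)
})

test_that("net fuel cost reproduces the hand-computed midpoint case", {
  scn <- scenario("wood_ics")
  c0 <- 0.25 * 0.12 * 54 + 1.0 * 30 * 0.3 * 0.2           # 3.42
  ci <- 0.25 * 0.12 * 23.76 + (23.76 / 54) * 30 * 0.06 + 0.33 * 30 * 0.06
  expect_equal(net_fuel_cost(mid_draw, the_catalog, scn), 0.5 * (ci - c0))
  expect_equal(net_fuel_cost(mid_draw, the_catalog, scn), -0.6606,
               tolerance = 1e-6)
  # no sustained use, no net change; identity stove, no change either
  expect_equal(net_fuel_cost(set_col(mid_draw, chi = 0), the_catalog, scn), 0)
  ident <- scn
  ident$candidate <- "wood_traditional"
  expect_equal(net_fuel_cost(mid_draw, the_catalog, ident), 0)
  # non-wood candidates pay a purely monetary fuel bill
  expect_equal(net_fuel_cost(mid_draw, the_catalog, scenario("kerosene")),
               0.5 * (0.5 * 95.04 / (35 * 0.45) - c0))
})

test_that("fuel cost change can take either sign within the ranges", {
  scn <- scenario("wood_ics")
  expect_lt(net_fuel_cost(mid_draw, the_catalog, scn), 0)   # savings
  costly <- set_col(mid_draw, collt0 = 0.3, f_purch = 0, prep = 0.5,
                    `wood_ics.eps_f` = 0.13)
  expect_gt(net_fuel_cost(costly, the_catalog, scn), 0)     # net cost
})

test_that("fixed costs annualize capital and apply subsidies privately", {
  scn <- scenario("wood_ics")
  fc <- fixed_costs(mid_draw, the_catalog, scn)
  expect_equal(fc$cap, 15 * capital_recovery_factor(0.15, 3) / 12)
  expect_equal(fc$cap, 0.5475, tolerance = 1e-3)
  expect_equal(fc$prog, 2 / 12)
  expect_equal(fc$om, 0.5 * 1.4 / 12)
  expect_equal(fc$learn, 0)                 # learning period defaults to 0
  # full subsidy removes private capital cost but not social
  fc_sub <- fixed_costs(mid_draw, the_catalog,
                        scenario("wood_ics", capital_subsidy = 1))
  expect_equal(fc_sub$cap, 0)
  fc_soc <- fixed_costs(mid_draw, the_catalog,
                        scenario("wood_ics", perspective = "social",
                                 capital_subsidy = 1))
  expect_equal(fc_soc$cap, 15 * capital_recovery_factor(0.045, 3) / 12)
  # maintenance nets out when both stoves carry the common upkeep cost
  fc_cc <- fixed_costs(mid_draw, the_catalog,
                       scenario("charcoal_ics",
                                baseline = "charcoal_traditional"))
  expect_equal(fc_cc$om, 0)
  # a configured learning period is valued at the shadow price of time
  cat_l <- the_catalog
  cat_l$constants$learning_hours <- 10
  fc_l <- fixed_costs(mid_draw, cat_l, scn)
  expect_equal(fc_l$learn,
               10 * 0.3 * 0.2 * capital_recovery_factor(0.15, 3) / 12)
})

test_that("health benefits reproduce the hand-computed component terms", {
  # isolate the ARI morbidity term: 0.5 * 5 * 0.5 * 0.4 * 15 / 12
  d_ari <- set_col(mid_draw, prev_copd = 0, f_alri = 0, drate_copd = 0)
  hb <- health_benefits(d_ari, the_catalog, scenario("wood_ics"))
  expect_equal(hb$morb, 0.625, tolerance = 1e-9)
  # isolate the COPD morbidity term under the private rate
  d_copd <- set_col(mid_draw, inc_ari = 0, drate_copd = 0)
  hb2 <- health_benefits(d_copd, the_catalog, scenario("wood_ics"))
  expect_equal(hb2$morb, 0.5 * 5 * 0.045 * 0.15 * 35 / (1.15^15) / 12,
               tolerance = 1e-9)
  # zero effectiveness, zero benefit (improved stove equal to baseline)
  d0 <- set_col(mid_draw, `wood_ics.eta_ari` = 0, `wood_ics.eta_copd` = 0)
  hb0 <- health_benefits(d0, the_catalog, scenario("wood_ics"))
  expect_equal(hb0$morb, 0)
  expect_equal(hb0$mort, 0)
  # mortality calibration switches: the literal household-wide reading
  lit <- model_options(mort_hhsize = TRUE, mort_child_fraction = 1)
  hb_lit <- health_benefits(set_col(mid_draw, drate_copd = 0), the_catalog,
                            scenario("wood_ics"), lit)
  expect_equal(hb_lit$mort, 0.5 * 5 * 30000 * 0.5 * 0.15 * 0.03 * 0.4 / 12,
               tolerance = 1e-9)
  # default reading scales the ALRI term by the exposed-child weight only
  hb_def <- health_benefits(set_col(mid_draw, drate_copd = 0), the_catalog,
                            scenario("wood_ics"))
  expect_equal(hb_def$mort, hb_lit$mort * 0.1 / 5, tolerance = 1e-9)
})

test_that("time savings follow relative time efficiency and its sign", {
  expect_equal(time_savings(mid_draw, the_catalog, scenario("lpg")),
               0.5 * 3 * (1 - 0.67) * 30 * 0.3 * 0.2)
  d_eq <- set_col(mid_draw, `wood_ics.eps_t` = 1)
  expect_equal(time_savings(d_eq, the_catalog, scenario("wood_ics")), 0)
  d_slow <- set_col(mid_draw, `wood_ics.eps_t` = 1.5)
  expect_lt(time_savings(d_slow, the_catalog, scenario("wood_ics")), 0)
  # charcoal-to-charcoal uses the baseline stove's own time efficiency
  d_c <- set_col(mid_draw, `charcoal_traditional.eps_t` = 0.9,
                 `charcoal_ics.eps_t` = 0.6)
  expect_equal(time_savings(d_c, the_catalog,
                            scenario("charcoal_ics",
                                     baseline = "charcoal_traditional")),
               0.5 * 3 * (0.9 - 0.6) * 30 * 0.06)
})

test_that("emissions and environmental benefits match the midpoint algebra", {
  expect_equal(monthly_emissions(mid_draw, the_catalog, "wood_traditional"),
               54 * 16 * 12.1)                       # ~10454 g CO2-eq
  env <- environmental_benefits(mid_draw, the_catalog,
                                scenario("wood_ics", perspective = "social"))
  e0 <- 54 * 16 * 12.1
  ei <- 23.76 * 16 * 12.1
  expect_equal(env$carb, 20 * 0.5 * (e0 - ei) / 1e6)
  expect_equal(env$bio, 0.01 * 0.5 * (54 - 23.76))
  # non-biomass candidate frees the full baseline wood demand
  env_lpg <- environmental_benefits(mid_draw, the_catalog,
                                    scenario("lpg", perspective = "social"))
  expect_equal(env_lpg$bio, 0.01 * 0.5 * 54)
  # extended accounting swaps in the heavier biomass intensities
  env_ext <- environmental_benefits(mid_draw, the_catalog,
                                    scenario("lpg", perspective = "social",
                                             accounting = "extended"))
  e0_ext <- 54 * 16 * 225
  ei_lpg <- (95.04 / (45 * 0.55)) * 45 * 107.9
  expect_equal(env_ext$carb, 20 * 0.5 * (e0_ext - ei_lpg) / 1e6)
  # per-useful-MJ basis multiplies by heat-transfer efficiency
  env_useful <- environmental_benefits(
    mid_draw, the_catalog, scenario("wood_ics", perspective = "social"),
    model_options(gamma_basis = "useful"))
  expect_equal(env_useful$carb, 20 * 0.5 * (e0 * 0.11 - ei * 0.25) / 1e6)
  # electric stove accounted per kW-hr delivered
  env_e <- environmental_benefits(mid_draw, the_catalog,
                                  scenario("electric", perspective = "social"))
  expect_equal(env_e$carb,
               20 * 0.5 * (e0 - 3 * 0.63 * 30 * 1.65 * 170) / 1e6)
})

test_that("evaluate obeys its accounting identities", {
  scn_p <- scenario("wood_ics")
  # with no sustained use, only capital, program and learning remain
  bd0 <- evaluate(set_col(mid_draw, chi = 0), the_catalog, scn_p)
  expect_equal(bd0$net, -(bd0$cap + bd0$prog + bd0$learn))
  expect_equal(bd0$om, 0)
  expect_equal(bd0$fuel_net, 0)
  # net always equals benefits minus costs column-wise
  d <- test_draws(500, seed = 11)
  for (scn in list(scn_p, scenario("electric", carbon_offset = TRUE),
                   scenario("kerosene", perspective = "social"))) {
    bd <- evaluate(d, the_catalog, scn)
    expect_equal(bd$net,
                 bd$morb + bd$mort + bd$timesav + bd$carb + bd$bio -
                   (bd$cap + bd$prog + bd$om + bd$fuel_net + bd$learn))
  }
  # private breakdown excludes environmental components unless offset
  bd_p <- evaluate(d, the_catalog, scn_p)
  expect_true(all(bd_p$carb == 0) && all(bd_p$bio == 0))
  bd_o <- evaluate(d, the_catalog, scenario("wood_ics", carbon_offset = TRUE))
  expect_true(any(bd_o$carb != 0) && all(bd_o$bio == 0))
})

test_that("social net equals same-rate private net plus carbon and forest", {
  d <- test_draws(500, seed = 11)
  for (cand in c("wood_ics", "kerosene", "electric")) {
    soc <- evaluate(d, the_catalog, scenario(cand, perspective = "social"))
    priv <- evaluate(d, the_catalog, scenario(cand, discount = "social"))
    expect_equal(soc$net, priv$net + soc$carb + soc$bio, tolerance = 1e-12)
  }
})

test_that("net benefits are affine in sustained use", {
  d <- test_draws(200, seed = 12)
  scn <- scenario("wood_ics", perspective = "social")
  n0 <- evaluate(set_col(d, chi = 0.2), the_catalog, scn)$net
  n1 <- evaluate(set_col(d, chi = 0.5), the_catalog, scn)$net
  n2 <- evaluate(set_col(d, chi = 0.8), the_catalog, scn)$net
  expect_equal(n1, (n0 + n2) / 2, tolerance = 1e-12)
  # and increasing over the tornado endpoints at midpoints
  expect_lt(evaluate(set_col(mid_draw, chi = 0.2), the_catalog, scn)$net,
            evaluate(set_col(mid_draw, chi = 0.8), the_catalog, scn)$net)
})

test_that("net responds monotonically to costs and health parameters", {
  scn <- scenario("wood_ics")
  net_at <- function(...) evaluate(set_col(mid_draw, ...), the_catalog, scn)$net
  expect_gt(net_at(`wood_ics.cc` = 5), net_at(`wood_ics.cc` = 50))
  expect_lt(net_at(coi_ari = 2), net_at(coi_ari = 60))
  expect_lt(net_at(inc_ari = 0.1), net_at(inc_ari = 1.0))
  # a pricier candidate fuel lowers net benefits (kerosene buys its fuel;
  # for the wood ICS a pricier wood raises the larger baseline bill
  # instead, so the candidate-fuel direction is tested on kerosene)
  net_k <- function(...) evaluate(set_col(mid_draw, ...), the_catalog,
                                  scenario("kerosene"))$net
  expect_gt(net_k(`price.kerosene` = 0.3), net_k(`price.kerosene` = 0.7))
})

test_that("scenario construction enforces the stove pairing rules", {
  expect_error(scenario("hovercraft"), "valid ids")
  expect_error(scenario("wood_ics", baseline = "wood_ics"), "baseline")
  expect_error(scenario("kerosene", baseline = "charcoal_traditional"),
               "improved charcoal")
  expect_error(scenario("wood_traditional"), "differ")
  expect_error(scenario("wood_ics", capital_subsidy = 1.2), "capital_subsidy")
})
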