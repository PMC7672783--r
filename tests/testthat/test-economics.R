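test_that("discounting is annual with cycle 0 undiscounted", {
  expect_equal(discount_factor(0, 0:10), rep(1, 11))
  expect_equal(sum(discount_factor(0.04, 0:2)), 2.8861, tolerance = 1e-4)
  expect_equal(discount_factor(0.015, 1), 1 / 1.015)
  expect_error(discount_factor(-0.1, 1))
})

test_that("annual treatment costs follow the dispensing-fee schedule", {
  ps <- reference_parameter_set()
  ec <- ps$economics
  dmf <- ps$dmds[ps$dmds$name == "dimethyl_fumarate", ]
  y1 <- cycle_treatment_costs(dmf, 0L, ec)
  yn <- cycle_treatment_costs(dmf, 1L, ec)
  # first year: 14 + 11 * 7 = 91 in fees plus pretreatment monitoring
  expect_equal(y1, dmf$annual_drug_cost + dmf$monitoring_annual +
                 dmf$monitoring_pretreatment + 91)
  expect_equal(yn, dmf$annual_drug_cost + dmf$monitoring_annual + 84)

  nat <- ps$dmds[ps$dmds$name == "natalizumab", ]
  expect_equal(cycle_treatment_costs(nat, 0L, ec),
               nat$annual_drug_cost + nat$admin_cost_first_year +
                 nat$monitoring_annual + nat$monitoring_pretreatment)
  expect_equal(cycle_treatment_costs(nat, 3L, ec),
               nat$annual_drug_cost + nat$admin_cost_subsequent +
                 nat$monitoring_annual)
})

test_that("person costs respect the costing perspective", {
  ps <- reference_parameter_set()
  ec <- ps$economics
  hc <- cycle_person_costs("RRMS", 4, "healthcare", ec)
  sf <- cycle_person_costs("RRMS", 4, "societal_friction", ec)
  sh <- cycle_person_costs("RRMS", 4, "societal_human_capital", ec)
  row <- ec$state_costs[ec$state_costs$course == "RRMS" &
                          ec$state_costs$edss == 4, ]
  expect_equal(hc, row$healthcare * (1 + ec$ae_cost_fraction))
  expect_true(sf >= hc && sh >= hc)
  expect_equal(sh - sf,
               row$productivity_human_capital - row$productivity_friction)
  expect_error(cycle_person_costs("DEAD", NA, "healthcare", ec))
  expect_error(cycle_person_costs("RRMS", 4, "martian", ec))
})

test_that("zero utilities produce zero QALYs but unchanged life years", {
  ps <- toy_parameter_set()
  u <- ps$economics$utilities
  u$utility <- 0
  ps$economics$utilities <- u
  ps$economics$relapse_disutility_mild <- 0
  ps$economics$relapse_disutility_severe <- 0
  ps$dmds$ae_disutility <- 0
  o <- evaluate_strategy(ps$strategies$CAU, ps)
  expect_equal(unname(o$qalys), c(0, 0))
  expect_gt(o$life_years[["undiscounted"]], 0)
})

test_that("zero discount rates make discounted equal undiscounted", {
  ps <- toy_parameter_set()
  ps$economics$discount_effects <- 0
  ps$economics$discount_costs <- 0
  o <- evaluate_strategy(ps$strategies$SDM, ps)
  expect_equal(o$qalys[["discounted"]], o$qalys[["undiscounted"]])
  expect_equal(o$cost_disc, o$cost_undisc)
  expect_equal(o$relapses[["discounted"]], o$relapses[["undiscounted"]])
})

test_that("discounted streams never exceed undiscounted ones", {
  ps <- toy_parameter_set()
  o <- evaluate_strategy(ps$strategies$SDM, ps)
  expect_lt(o$qalys[["discounted"]], o$qalys[["undiscounted"]])
  expect_true(all(o$cost_disc <= o$cost_undisc + 1e-12))
})

test_that("costs are linear in the unit-cost tables", {
  ps <- toy_parameter_set()
  double_costs <- function(ps) {
    d <- ps$dmds
    for (cl in c("annual_drug_cost", "admin_cost_first_year",
                 "admin_cost_subsequent", "monitoring_pretreatment",
                 "monitoring_annual", "monitoring_post_discontinuation")) {
      d[[cl]] <- d[[cl]] * 2
    }
    ps$dmds <- d
    sc <- ps$economics$state_costs
    for (cl in setdiff(names(sc), c("course", "edss"))) sc[[cl]] <- sc[[cl]] * 2
    ps$economics$state_costs <- sc
    for (k in c("relapse_cost_mild", "relapse_cost_severe",
                "dispensing_fee_first", "dispensing_fee_subsequent")) {
      ps$economics[[k]] <- ps$economics[[k]] * 2
    }
    for (nm in names(ps$strategies)) {
      ps$strategies[[nm]]$sdm_cost_per_decision <-
        ps$strategies[[nm]]$sdm_cost_per_decision * 2
    }
    ps
  }
  o1 <- evaluate_strategy(ps$strategies$SDM, ps)
  o2 <- evaluate_strategy(double_costs(ps)$strategies$SDM, double_costs(ps))
  expect_equal(unname(o2$cost_disc), unname(2 * o1$cost_disc),
               tolerance = 1e-12)
  expect_equal(o2$qalys, o1$qalys)   # effects untouched
})

test_that("perspective totals nest and equal their category sums", {
  ps <- toy_parameter_set()
  o <- evaluate_strategy(ps$strategies$CAU, ps)
  tot <- outcomes_totals(o)
  hc <- tot$discounted[tot$perspective == "healthcare"]
  sf <- tot$discounted[tot$perspective == "societal_friction"]
  sh <- tot$discounted[tot$perspective == "societal_human_capital"]
  expect_true(hc <= sf && hc <= sh)
  cdf <- outcomes_costs(o)
  expect_equal(sf, sum(cdf$discounted[cdf$category %in% c(
    "drug", "administration", "monitoring", "dispensing", "adverse_events",
    "health_state_healthcare", "relapse", "sdm_delivery", "community",
    "equipment", "informal_care", "productivity_friction")]),
    tolerance = 1e-6)
  expect_equal(total_cost(o, "societal_friction"), sf)
})

test_that("accrued adverse-event costs equal the configured fraction of health care costs", {
  ps <- toy_parameter_set()
  o <- evaluate_strategy(ps$strategies$CAU, ps)
  expect_equal(o$cost_disc[["adverse_events"]],
               o$cost_disc[["health_state_healthcare"]] *
                 ps$economics$ae_cost_fraction,
               tolerance = 1e-9)
})
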