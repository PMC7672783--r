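# helper: a bare outcomes object with chosen discounted totals
mk_outcomes <- function(cost, qaly) {
  o <- sdmcea:::.empty_outcomes()
  o$cost_disc[["health_state_healthcare"]] <- cost
  o$cost_undisc[["health_state_healthcare"]] <- cost
  o$qalys <- c(discounted = qaly, undiscounted = qaly)
  o
}

test_that("incremental comparison classifies dominance as printed", {
  base <- mk_outcomes(100000, 7.67)
  # cheaper and more effective: dominant
  ce <- compare(mk_outcomes(100000 - 807, 7.67 + 0.33), base)
  expect_equal(ce$delta_cost, -807)
  expect_equal(ce$delta_qaly, 0.33)
  expect_equal(ce$classification, "DOMINANT")

  ce2 <- compare(mk_outcomes(101000, 8.67), base)
  expect_equal(ce2$classification, "ICER")
  expect_equal(ce2$icer, 1000)

  ce3 <- compare(mk_outcomes(101000, 7.67), base)
  expect_equal(ce3$classification, "DOMINATED")

  ce4 <- compare(mk_outcomes(99000, 7.0), base)
  expect_equal(ce4$classification, "COST_SAVING_QALY_LOSING")
  expect_equal(ce4$icer, -1000 / -0.67)
})

test_that("swapping arms negates both increments", {
  a <- mk_outcomes(123456, 8.1)
  b <- mk_outcomes(120000, 7.9)
  ab <- compare(a, b)
  ba <- compare(b, a)
  expect_equal(ab$delta_cost, -ba$delta_cost)
  expect_equal(ab$delta_qaly, -ba$delta_qaly)
})

test_that("the threshold delivery cost reproduces the target ICER on re-run", {
  ps <- toy_parameter_set()
  for (wtp in c(20000, 50000)) {
    th <- threshold_sdm_cost(ps, wtp)
    expect_true(th$achievable)
    expect_lt(th$check_rel_error, 1e-6)
    ps2 <- ps
    ps2$strategies$SDM$sdm_cost_per_decision <- th$max_cost
    ce <- sdmcea:::.run_pair(ps2)
    expect_equal(ce$icer, wtp, tolerance = 1e-6)
  }
  # the linear solve matches first principles: c* scales with the decision count
  th0 <- threshold_sdm_cost(ps, 20000)
  p0 <- ps
  p0$strategies$SDM$sdm_cost_per_decision <- 0
  ce0 <- sdmcea:::.run_pair(p0)
  d0 <- ce0$intervention$decisions[["discounted"]]
  expect_equal(th0$max_cost, (20000 * ce0$delta_qaly - ce0$delta_cost) / d0)
})

test_that("the threshold reports non-achievability when SDM gains no QALYs", {
  ps <- toy_parameter_set()
  ps$strategies$SDM <- ps$strategies$CAU
  ps$strategies$SDM$label <- "SDM"
  th <- threshold_sdm_cost(ps, 20000)
  expect_false(th$achievable)
  expect_true(is.na(th$max_cost))
})

test_that("the one-way sensitivity preset covers the registry and keeps identities", {
  ps <- toy_parameter_set()
  reg <- owsa_registry(ps)
  expect_true(all(c("base_case", "sdm_cost_0", "drug_costs_plus20",
                    "discount_0", "perspective_healthcare",
                    "transitions_minus10", "entry_100_edss1") %in% names(reg)))

  sub <- reg[c("base_case", "sdm_cost_0", "drug_costs_plus20",
               "transitions_plus10")]
  res <- one_way_sensitivity(sub, ps)
  base <- sdmcea:::.run_pair(ps)
  expect_equal(res$icer[res$scenario == "base_case"], base$icer)
  # removing the delivery cost can only improve the intervention's ICER
  expect_lt(res$delta_cost[res$scenario == "sdm_cost_0"], base$delta_cost)
  # +20% drug costs leaves QALYs untouched
  expect_equal(res$delta_qaly[res$scenario == "drug_costs_plus20"],
               base$delta_qaly)

  # transition scaling keeps every row stochastic
  ps10 <- reg$transitions_plus10$transform(ps)
  expect_equal(nrow(validate_parameter_set(ps10)), 0L)
  ps90 <- reg$transitions_minus10$transform(ps)
  expect_equal(nrow(validate_parameter_set(ps90)), 0L)

  # a parameter-path scenario with an unknown path errors
  bad <- scenario_set("broken", c("economics", "no_such_field"), 1)
  expect_error(one_way_sensitivity(list(bad), ps), "unknown parameter path")
  good <- scenario_set("discount0", c("economics", "discount_costs"), 0)
  res2 <- one_way_sensitivity(list(good), ps)
  expect_equal(nrow(res2), 1L)
})

test_that("probabilistic analysis is seed-reproducible and degenerates correctly", {
  ps <- toy_parameter_set()
  p1 <- run_psa(ps, n = 8, seed = 123)
  p2 <- run_psa(ps, n = 8, seed = 123)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(ps, n = 8, seed = 124)
  expect_false(identical(p1$draws, p3$draws))

  # zero-variance configuration reproduces the deterministic pair exactly
  det <- sdmcea:::.run_pair(ps)
  p0 <- run_psa(ps, n = 4, seed = 1, config = psa_config(sd_prop = 0))
  expect_true(all(p0$draws$delta_cost == det$delta_cost))
  expect_true(all(p0$draws$delta_qaly == det$delta_qaly))

  # sampled parameter sets remain valid
  set.seed(5)
  for (i in 1:3) {
    expect_equal(nrow(validate_parameter_set(sample_parameter_set(ps))), 0L)
  }
})

test_that("the acceptability curve equals brute-force net-benefit counting", {
  ps <- toy_parameter_set()
  psa <- run_psa(ps, n = 40, seed = 99)
  grid <- seq(0, 100000, by = 1000)
  curve <- ceac(psa, grid)
  expect_true(all(curve$probability_ce >= 0 & curve$probability_ce <= 1))
  brute <- vapply(grid, function(l)
    mean(l * psa$draws$delta_qaly - psa$draws$delta_cost >= 0), numeric(1))
  expect_identical(curve$probability_ce, brute)

  # lambda = 0 counts cost-saving draws; the large-lambda limit counts
  # QALY-gaining draws (with ties resolved by cost sign)
  expect_equal(curve$probability_ce[curve$wtp == 0],
               mean(psa$draws$delta_cost <= 0))
  far <- ceac(psa, 1e12)$probability_ce
  expect_equal(far, mean(psa$draws$delta_qaly > 0 |
                           (psa$draws$delta_qaly == 0 &
                              psa$draws$delta_cost <= 0)))

  # monotone when every draw gains QALYs
  pos <- psa
  pos$draws <- psa$draws[psa$draws$delta_qaly > 0, , drop = FALSE]
  if (nrow(pos$draws) > 1) {
    cv <- ceac(pos, grid)
    expect_true(all(diff(cv$probability_ce) >= 0))
  }
  expect_error(ceac(psa, numeric(0)), "non-empty")
})
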