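test_that("the generator is deterministic, valid and in published ranges", {
  a <- generate_parameter_set(generator_config(11))
  b <- generate_parameter_set(generator_config(11))
  expect_true(isTRUE(all.equal(a, b, tolerance = 0)))
  expect_false(isTRUE(all.equal(
    a, generate_parameter_set(generator_config(12)), tolerance = 0)))

  for (seed in c(2, 19, 77, 101, 4005)) {
    ps <- generate_parameter_set(generator_config(seed, n_dmds = 5))
    expect_equal(nrow(validate_parameter_set(ps)), 0L)
    # real-world first-year discontinuation within the reported 10-31% range
    expect_true(all(ps$dmds$cau_discontinuation >= 0.10 &
                      ps$dmds$cau_discontinuation <= 0.31))
    expect_true(all(ps$dmds$rr_progression > 0.3 &
                      ps$dmds$rr_progression < 1))
    # adherent proportions: 0.589 for self-administered, 1 for infused
    app <- ps$dmds$adherence_applicable
    adher <- ps$strategies$CAU$adherent_proportion[ps$dmds$name]
    expect_true(all(adher[app] == 0.589))
    expect_true(all(adher[!app] == 1))
    # infused drugs are never flagged adherence-applicable
    expect_true(all(!(ps$dmds$route == "infusion" & app)))
  }
})

test_that("generated sets round-trip through the parameter file format", {
  dir <- withr::local_tempdir()
  ps <- generate_parameter_set(generator_config(55, n_dmds = 4))
  write_parameter_set(ps, dir)
  expect_true(isTRUE(all.equal(ps, load_parameter_set(dir), tolerance = 0)))
})

test_that("the printed strategy table halves discontinuation rates and keeps shares", {
  fx <- table2_fixture()
  t2 <- fx$table
  expect_equal(sum(t2$initiation_cau), 100.0, tolerance = 1e-9)
  expect_equal(t2$initiation_sdm[t2$treatment == "best_supportive_care"], 20.0)
  # all 14 printed SDM rates are the halved CAU rates, one-decimal,
  # round-half-up
  half_up <- function(x) floor(x / 2 * 10 + 0.5) / 10
  on_dmd <- !is.na(t2$discontinuation_cau)
  expect_equal(t2$discontinuation_sdm[on_dmd],
               half_up(t2$discontinuation_cau[on_dmd]))
  expect_equal(sum(on_dmd), 14L)
  # strategy objects are renormalised probability vectors
  expect_equal(sum(fx$CAU$initiation), 1, tolerance = 1e-12)
  expect_equal(sum(fx$SDM$initiation), 1, tolerance = 1e-12)
  expect_equal(fx$SDM$discontinuation_multiplier, 0.5)
  expect_equal(unname(fx$CAU$adherent_proportion[["dimethyl_fumarate"]]),
               0.589)
  expect_equal(unname(fx$SDM$adherent_proportion[["dimethyl_fumarate"]]),
               0.639)
})

test_that("the delivery-cost decomposition is internally consistent", {
  cc <- sdm_cost_components()
  expect_equal(cc[["total"]] - cc[["consultation_time"]],
               cc[["decision_aid_headroom"]])
})

test_that("the microsimulation oracle is seed-stable and honours null inputs", {
  ps <- toy_parameter_set()
  m1 <- microsim_oracle(ps$strategies$CAU, ps, 500, seed = 3)
  m2 <- microsim_oracle(ps$strategies$CAU, ps, 500, seed = 3)
  expect_identical(m1$estimate, m2$estimate)

  # forced-death, zero-utility input: no QALYs accrue
  ps0 <- ps
  lt <- ps0$natural_history$life_table
  lt$annual_death_prob <- 1
  ps0$natural_history$life_table <- lt
  u <- ps0$economics$utilities; u$utility <- 0
  ps0$economics$utilities <- u
  ps0$economics$relapse_disutility_mild <- 0
  ps0$economics$relapse_disutility_severe <- 0
  ps0$dmds$ae_disutility <- 0
  m0 <- microsim_oracle(ps0$strategies$CAU, ps0, 1, seed = 1)
  expect_equal(m0$estimate[["qalys"]], 0)
  expect_equal(m0$estimate[["life_years"]], 1)  # alive at entry only
})

test_that("engine and oracle agree on generated parameter sets", {
  for (seed in c(3, 14, 28, 41, 90)) {
    ps <- generate_parameter_set(generator_config(seed, n_dmds = 4))
    o <- evaluate_strategy(ps$strategies$CAU, ps)
    m <- microsim_oracle(ps$strategies$CAU, ps, 30000, seed = seed + 1000)
    eng <- c(qalys = o$qalys[["discounted"]],
             total_cost = total_cost(o, ps$settings$perspective),
             life_years = o$life_years[["undiscounted"]],
             relapses = o$relapses[["undiscounted"]])
    z <- (eng - m$estimate) / m$se
    expect_true(all(abs(z) < 4),
                info = paste0("seed ", seed, ": z = ",
                              paste(round(z, 2), collapse = ", ")))
  }
})
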