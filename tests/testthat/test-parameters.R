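test_that("EDSS cost interpolation is linear inside anchors, constant outside", {
  expect_equal(interpolate_state_costs(c("0" = 1000, "2" = 3000))[["1"]], 2000)
  expect_equal(interpolate_state_costs(c("0" = 1000, "2" = 3000))[["0"]], 1000)
  expect_equal(interpolate_state_costs(c("3" = 5000, "9" = 20000))[["6"]],
               12500)
  # constant extrapolation beyond the outermost anchors
  out <- interpolate_state_costs(c("3" = 5000, "6" = 8000))
  expect_equal(unname(out[c("0", "1", "2")]), rep(5000, 3))
  expect_equal(unname(out[c("7", "8", "9")]), rep(8000, 3))
  expect_error(interpolate_state_costs(c("4" = 100)), "at least 2")
})

test_that("interpolated costs are monotone when anchors are monotone", {
  set.seed(99)
  for (i in 1:20) {
    lv <- sort(sample(0:9, sample(2:5, 1)))
    anchors <- setNames(cumsum(runif(length(lv), 0, 5000)), lv)
    out <- interpolate_state_costs(anchors)
    expect_true(all(diff(out) >= -1e-12))
  }
})

test_that("trial-based discontinuation scaling is proportional and capped", {
  expect_equal(scale_discontinuation_from_trials(0.13, 0.10, 0.10), 0.13)
  expect_equal(scale_discontinuation_from_trials(0.13, 0.10, 0.05), 0.065)
  expect_equal(scale_discontinuation_from_trials(0.5, 0.1, 0.3), 1.0)
  expect_error(scale_discontinuation_from_trials(0.13, 0, 0.05))
})

test_that("adverse-event costs are a proportion of health care costs", {
  expect_equal(ae_costs(10000, 0.01), 100)
  expect_equal(ae_costs(12345, 0), 0)
  expect_error(ae_costs(-1, 0.1))
  expect_error(ae_costs(100, 1.5))
})

test_that("generated and reference parameter sets pass validation", {
  expect_equal(nrow(validate_parameter_set(reference_parameter_set())), 0L)
  for (seed in c(1, 7, 123)) {
    ps <- generate_parameter_set(generator_config(seed))
    expect_equal(nrow(validate_parameter_set(ps)), 0L)
  }
})

test_that("validation reports name the offending table, row and rule", {
  ps <- reference_parameter_set()
  ps$natural_history$rrms_transitions[3, ] <-
    ps$natural_history$rrms_transitions[3, ] * 0.9
  rep <- validate_parameter_set(ps)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$table, "transitions_rrms")
  expect_equal(rep$row, "3")
  expect_equal(rep$rule, "row_sum")

  ps2 <- reference_parameter_set()
  u <- ps2$economics$utilities
  u$utility[u$course == "RRMS" & u$edss == 7] <-
    u$utility[u$course == "RRMS" & u$edss == 6] + 0.1
  ps2$economics$utilities <- u
  rep2 <- validate_parameter_set(ps2)
  expect_true(any(rep2$rule == "monotone_nonincreasing"))

  # idempotent and side-effect free
  ps3 <- reference_parameter_set()
  r1 <- validate_parameter_set(ps3)
  r2 <- validate_parameter_set(ps3)
  expect_identical(r1, r2)
})

test_that("parameter sets round-trip through the file format exactly", {
  dir <- withr::local_tempdir()
  ps <- generate_parameter_set(generator_config(31, n_dmds = 4))
  write_parameter_set(ps, dir, extra_manifest = list(seed = 31))
  ps2 <- load_parameter_set(dir)
  expect_true(isTRUE(all.equal(ps, ps2, tolerance = 0)))
  expect_identical(ps$natural_history$rrms_transitions,
                   ps2$natural_history$rrms_transitions)
  expect_identical(ps$dmds$annual_drug_cost, ps2$dmds$annual_drug_cost)
})

test_that("the packaged fixture loads and carries the printed profiles", {
  dir <- system.file("extdata", "synthetic_reference", package = "sdmcea")
  ps <- load_parameter_set(dir)
  expect_equal(nrow(validate_parameter_set(ps)), 0L)
  expect_equal(ps$strategies$CAU$initiation[["best_supportive_care"]], 0.25)
  expect_equal(ps$strategies$SDM$sdm_cost_per_decision, 100)
  expect_equal(ps$economics$discount_effects, 0.015)
  expect_equal(ps$economics$discount_costs, 0.040)
})

test_that("a missing table raises an error naming its role", {
  dir <- withr::local_tempdir()
  write_parameter_set(reference_parameter_set(), dir)
  file.remove(file.path(dir, "life_table.csv"))
  expect_error(load_parameter_set(dir), "life_table")
})
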