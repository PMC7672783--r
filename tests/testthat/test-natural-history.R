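test_that("relative risk rescales worsening through the stay probability", {
  ps <- reference_parameter_set()
  nh <- ps$natural_history
  # toy row: RRMS EDSS 8 with stay 0.6 / worsen 0.4, halved risk -> 0.8 / 0.2
  nh$rrms_transitions[9, ] <- 0
  nh$rrms_transitions[9, 9] <- 0.6
  nh$rrms_transitions[9, 10] <- 0.4
  M <- sdmcea:::base_transition_matrix(nh, rr_progression = 0.5)
  expect_equal(M[9, 9], 0.8)
  expect_equal(M[9, 10], 0.2)

  # identity relative risk reproduces natural history with mortality only
  M1 <- build_transition_matrix(nh, 1, age = 50, ps$settings)
  p <- sdmcea:::death_probability_states(50, ps$settings, nh)
  base <- sdmcea:::base_transition_matrix(nh, 1)
  expect_equal(M1[1, 1:19], base[1, 1:19] * (1 - p[1]))
  expect_equal(M1[1, 20], base[1, 20] * (1 - p[1]) + p[1])

  # vanishing relative risk moves all worsening/conversion mass to stay
  M0 <- sdmcea:::base_transition_matrix(nh, rr_progression = 0)
  expect_equal(M0[1, 1], 1 - sum(nh$rrms_transitions[1, ] * 0))  # EDSS 0
  expect_true(all(M0[1, 2:19] == 0))
  expect_error(build_transition_matrix(nh, 0, 50, ps$settings), "rr")
})

test_that("transition matrices are row-stochastic with absorbing death and no SPMS improvement", {
  ps <- reference_parameter_set()
  for (rr in c(0.4, 1, 1.6)) {
    for (age in c(40, 70, 95)) {
      M <- build_transition_matrix(ps$natural_history, rr, age, ps$settings)
      expect_equal(unname(rowSums(M)), rep(1, 20), tolerance = 1e-9)
      expect_true(all(M >= 0 & M <= 1))
      expect_equal(unname(M[20, ]), c(rep(0, 19), 1))
      # SPMS rows put no mass on RRMS states or lower SPMS states
      for (i in 11:19) {
        expect_equal(sum(M[i, 1:10]), 0)
        if (i > 11) expect_equal(sum(M[i, 11:(i - 1)]), 0)
      }
    }
  }
  # generated sets keep the same structure
  ps2 <- generate_parameter_set(generator_config(5))
  M2 <- build_transition_matrix(ps2$natural_history, 0.7, 55, ps2$settings)
  expect_equal(unname(rowSums(M2)), rep(1, 20), tolerance = 1e-9)
})

test_that("death probability blends sexes, applies multipliers and caps at 1", {
  ps <- reference_parameter_set()
  nh <- ps$natural_history
  lt <- nh$life_table
  se <- ps$settings

  se_male <- se; se_male$proportion_male <- 1
  pm <- lt$annual_death_prob[lt$sex == "male" & lt$age == 60]
  nh1 <- nh; nh1$mortality_multiplier <- rep(1, 10)
  expect_equal(death_probability(60, se_male, 0, nh1), pm)

  pf <- lt$annual_death_prob[lt$sex == "female" & lt$age == 60]
  expect_equal(death_probability(60, se, 3, nh),
               (0.29 * pm + 0.71 * pf) * nh$mortality_multiplier[4])

  nh2 <- nh
  nh2$mortality_multiplier <- rep(50, 10)
  lt2 <- lt; lt2$annual_death_prob <- 0.05
  nh2$life_table <- lt2
  expect_equal(death_probability(60, se, 5, nh2), 1)

  expect_error(death_probability(-3, se, 0, nh), "life table")
})

test_that("relapse model applies treatment and nonadherence multipliers", {
  ps <- reference_parameter_set()
  nh <- ps$natural_history
  nh$relapse_rates$relapse_rate[nh$relapse_rates$course == "RRMS" &
                                  nh$relapse_rates$edss == 2] <- 0.5
  nh$relapse_rates$severe_fraction[nh$relapse_rates$course == "RRMS" &
                                     nh$relapse_rates$edss == 2] <- 0.2
  r_na <- relapse_outcomes("RRMS", 2, 1, "nonadherent", ps$settings, nh)
  expect_equal(r_na[["total"]], 0.71)                 # 0.5 * 1.42
  expect_equal(r_na[["severe"]] / r_na[["total"]], 0.215)  # 0.2 * 1.075
  r_ad <- relapse_outcomes("RRMS", 2, 0.6, "adherent", ps$settings, nh)
  expect_equal(r_ad[["total"]], 0.3)
  nh$relapse_rates$relapse_rate[] <- 0
  r0 <- relapse_outcomes("RRMS", 2, 1, "nonadherent", ps$settings, nh)
  expect_equal(unname(r0), c(0, 0))
  expect_error(relapse_outcomes("DEAD", NA, 1, "adherent", ps$settings, nh))
})
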