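# Shared fixtures: a small, fast toy parameter set (4 DMDs, 10-year horizon)
# and a degenerate single-state set with closed-form outcomes.

toy_parameter_set <- function(start_age = 60, max_age = 70,
                              flat_death = NULL) {
  ps <- generate_parameter_set(generator_config(seed = 424242, n_dmds = 4))
  ps$settings$start_age <- start_age
  ps$settings$max_age <- max_age
  if (!is.null(flat_death)) {
    lt <- ps$natural_history$life_table
    lt$annual_death_prob <- flat_death
    ps$natural_history$life_table <- lt
  }
  ps
}

# One occupied RRMS state (EDSS 0), no movement, flat death probability,
# constant utility, so QALYs follow a geometric series in closed form.
degenerate_parameter_set <- function(p_death = 0.1, utility = 0.8,
                                     n_cycles = 3) {
  ps <- toy_parameter_set(start_age = 60, max_age = 60 + n_cycles,
                          flat_death = p_death)
  rt <- ps$natural_history$rrms_transitions
  rt[] <- 0
  diag(rt[, 1:10]) <- 1
  ps$natural_history$rrms_transitions <- rt
  st <- ps$natural_history$spms_transitions
  st[] <- 0
  diag(st) <- 1
  ps$natural_history$spms_transitions <- st
  ps$natural_history$mortality_multiplier <- rep(1, 10)
  ps$natural_history$relapse_rates$relapse_rate <- 0
  u <- ps$economics$utilities
  u$utility <- utility
  ps$economics$utilities <- u
  ps$economics$discount_effects <- 0
  ps$economics$discount_costs <- 0
  ps$settings$entry_distribution <-
    stats::setNames(c(1, rep(0, 9)), paste0("edss", 0:9))
  ps
}

# strip every treatment-related cost and effect so a DMD pathway must equal
# best supportive care
neutralise_treatment <- function(ps) {
  d <- ps$dmds
  d$rr_progression <- 1
  d$rr_relapse <- 1
  d$annual_drug_cost <- 0
  d$admin_cost_first_year <- 0
  d$admin_cost_subsequent <- 0
  d$monitoring_pretreatment <- 0
  d$monitoring_annual <- 0
  d$monitoring_post_discontinuation <- 0
  d$prescriptions_per_year <- 0L
  d$ae_disutility <- 0
  ps$dmds <- d
  for (nm in names(ps$strategies)) {
    ps$strategies[[nm]]$sdm_cost_per_decision <- 0
    ps$strategies[[nm]]$adherent_proportion[] <- 1
  }
  ps
}

expect_outcomes_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$qalys, b$qalys, tolerance = tol)
  expect_equal(a$life_years, b$life_years, tolerance = tol)
  expect_equal(a$relapses, b$relapses, tolerance = tol)
  expect_equal(a$cost_disc, b$cost_disc, tolerance = tol)
  expect_equal(a$cost_undisc, b$cost_undisc, tolerance = tol)
}

# per-cycle total occupancy mass of a pathway trace
trace_cycle_mass <- function(tr) {
  occ <- matrix(as.numeric(tr$trace), nrow = tr$n_cycles)
  rowSums(occ)
}
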