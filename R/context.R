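# Precomputed evaluation context shared by every pathway of a parameter set:
# per-cycle death probabilities, per-treatment no-mortality transition
# matrices, and flat per-state / per-DMD lookup vectors. Rebuilding these
# once per parameter set (instead of once per pathway) dominates the speed of
# the probabilistic sensitivity analysis.

.build_context <- function(params) {
  se <- params$settings
  ec <- params$economics
  nh <- params$natural_history
  H <- .N_STATES
  n_cycles <- as.integer(se$max_age - se$start_age)
  if (n_cycles <= 0L) stop("horizon of 0 cycles: start_age must be < max_age")

  # blended background mortality by age, then state-specific multipliers
  lt <- nh$life_table
  ages <- se$start_age + seq_len(n_cycles) - 1L
  qm <- lt$annual_death_prob[lt$sex == "male"][match(floor(ages),
                                                     lt$age[lt$sex == "male"])]
  qf <- lt$annual_death_prob[lt$sex == "female"][
    match(floor(ages), lt$age[lt$sex == "female"])]
  if (anyNA(qm) || anyNA(qf)) {
    stop("life table does not cover ages ", min(ages), "..", max(ages))
  }
  p_bg <- se$proportion_male * qm + (1 - se$proportion_male) * qf
  edss <- state_edss()
  mult <- numeric(H)
  alive <- alive_states()
  mult[alive] <- nh$mortality_multiplier[edss[alive] + 1L]
  death_prob <- pmin(outer(p_bg, mult), 1)     # T x H; DEAD column stays 0

  # no-mortality transition matrices per treatment
  P <- list(`__bsc__` = base_transition_matrix(nh, 1, 1))
  for (k in seq_len(nrow(params$dmds))) {
    d <- params$dmds[k, ]
    rr_sp <- if (isTRUE(se$rr_applies_spms)) d$rr_progression else 1
    P[[d$name]] <- base_transition_matrix(nh, d$rr_progression, rr_sp)
  }

  # per-state lookup vectors (0 for DEAD)
  hs <- health_states()
  key <- paste(hs$course, hs$edss)
  u_key <- paste(ec$utilities$course, ec$utilities$edss)
  c_key <- paste(ec$state_costs$course, ec$state_costs$edss)
  r_key <- paste(nh$relapse_rates$course, nh$relapse_rates$edss)
  iu <- match(key, u_key)
  ic <- match(key, c_key)
  ir <- match(key, r_key)
  pick <- function(v, idx) { out <- v[idx]; out[is.na(out)] <- 0; out }
  state <- list(
    util = pick(ec$utilities$utility, iu),
    hc = pick(ec$state_costs$healthcare, ic),
    comm = pick(ec$state_costs$community_services, ic),
    eq = pick(ec$state_costs$equipment_aids, ic),
    inf = pick(ec$state_costs$informal_care, ic),
    pf = pick(ec$state_costs$productivity_friction, ic),
    ph = pick(ec$state_costs$productivity_human_capital, ic),
    rate = pick(nh$relapse_rates$relapse_rate, ir),
    sf = pick(nh$relapse_rates$severe_fraction, ir)
  )

  # per-DMD named lookup vectors
  d <- params$dmds
  nm <- d$name
  dmd <- list(
    line = setNames(d$line, nm),
    rr_relapse = setNames(d$rr_relapse, nm),
    drug = setNames(d$annual_drug_cost, nm),
    admin1 = setNames(d$admin_cost_first_year, nm),
    admin2 = setNames(d$admin_cost_subsequent, nm),
    mon_pre = setNames(d$monitoring_pretreatment, nm),
    mon_ann = setNames(d$monitoring_annual, nm),
    mon_post = setNames(d$monitoring_post_discontinuation, nm),
    presc = setNames(d$prescriptions_per_year, nm),
    aedu = setNames(d$ae_disutility, nm),
    cau_disc = setNames(d$cau_discontinuation, nm),
    adherence_applicable = setNames(d$adherence_applicable, nm)
  )

  list(n_cycles = n_cycles, death_prob = death_prob, P = P, state = state,
       dmd = dmd,
       d_eff = discount_factor(ec$discount_effects, seq_len(n_cycles) - 1L),
       d_cost = discount_factor(ec$discount_costs, seq_len(n_cycles) - 1L))
}
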