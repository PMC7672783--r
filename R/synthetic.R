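# Seeded synthetic parameter-set generator and the individual-level
# microsimulation oracle used to verify the cohort engine.

#' Configuration for the synthetic parameter generator
#'
#' @param seed Integer seed; fixes every generated value.
#' @param n_dmds Number of DMDs to generate (>= 4: at least two first-line
#'   and two second-line drugs so every switch set is non-empty).
#' @param severity_scale Multiplier on progression/conversion probabilities.
#' @param cost_scale Multiplier on all unit costs.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed, n_dmds = 6, severity_scale = 1,
                             cost_scale = 1) {
  stopifnot(n_dmds >= 4, severity_scale > 0, cost_scale > 0)
  list(seed = as.integer(seed), n_dmds = as.integer(n_dmds),
       severity_scale = severity_scale, cost_scale = cost_scale)
}

#' Generate a random, valid synthetic parameter set
#'
#' Emulates the statistical structure of the model inputs: row-stochastic
#' RRMS transition rows with stay/improve/worsen/convert mass, worsening-only
#' SPMS rows, EDSS-increasing mortality multipliers and health care costs,
#' EDSS-decreasing utilities, per-DMD relative risks in (0.3, 1.0), and
#' real-world first-year discontinuation probabilities drawn from the
#' reported 10--31\% range. Output is deterministic given the seed and always
#' passes [validate_parameter_set()].
#'
#' @param config A [generator_config()].
#' @return An `ms_parameter_set`.
#' @export
generate_parameter_set <- function(config) {
  set.seed(config$seed)
  sev <- config$severity_scale
  csc <- config$cost_scale

  rt <- matrix(0, 10, 11,
               dimnames = list(paste0("RRMS_EDSS", 0:9),
                               c(paste0("RRMS_EDSS", 0:9), "SPMS_CONVERT")))
  for (i in 1:10) {
    e <- i - 1
    improve <- if (e > 0) runif(1, 0.03, 0.09) else 0
    worsen <- if (e < 9) min(0.4, sev * (runif(1, 0.08, 0.15) + 0.008 * e))
              else 0
    convert <- min(0.3, sev * (runif(1, 0.008, 0.025) + 0.008 * e))
    stay <- 1 - improve - worsen - convert
    if (stay < 0.05) {            # keep rows comfortably stochastic
      scl <- (1 - 0.05 - improve) / (worsen + convert)
      worsen <- worsen * scl; convert <- convert * scl
      stay <- 1 - improve - worsen - convert
    }
    if (e > 0) rt[i, i - 1] <- improve
    if (e < 9) rt[i, i + 1] <- worsen
    rt[i, 11] <- convert
    rt[i, i] <- stay
  }
  st <- matrix(0, 9, 9, dimnames = list(paste0("SPMS_EDSS", 1:9),
                                        paste0("SPMS_EDSS", 1:9)))
  for (i in 1:9) {
    worsen <- if (i < 9) min(0.5, sev * (runif(1, 0.12, 0.2) + 0.008 * i))
              else 0
    if (i < 9) st[i, i + 1] <- worsen
    st[i, i] <- 1 - worsen
  }

  relapse <- rbind(
    data.frame(course = "RRMS", edss = 0:9,
               relapse_rate = pmax(0.05, runif(1, 0.35, 0.5) - 0.03 * (0:9)),
               severe_fraction = runif(1, 0.1, 0.3)),
    data.frame(course = "SPMS", edss = 1:9,
               relapse_rate = runif(1, 0.05, 0.15),
               severe_fraction = runif(1, 0.1, 0.25))
  )
  mm <- cumsum(c(1, runif(9, 0.05, 0.6)))   # EDSS-increasing, >= 1

  n <- config$n_dmds
  n_second <- max(2L, as.integer(round(n / 3)))
  n_first <- n - n_second
  nm <- c(paste0("first_line_", seq_len(n_first)),
          paste0("second_line_", seq_len(n_second)))
  line <- c(rep("first", n_first), rep("second", n_second))
  route <- ifelse(line == "second" & seq_len(n) %% 2 == 0,
                  "infusion", "self_administered")
  route[n] <- "infusion"                    # at least one infused DMD
  rrp <- ifelse(line == "first", runif(n, 0.65, 0.95), runif(n, 0.4, 0.7))
  rrp <- pmin(0.99, pmax(0.31, rrp))
  rrr <- pmin(0.99, pmax(0.31, rrp * runif(n, 0.6, 1.0)))
  dmds <- data.frame(
    name = nm, line = line, route = route,
    rr_progression = rrp, rr_relapse = rrr,
    rr_progression_low = pmax(0.3, rrp * 0.8),
    rr_progression_high = pmin(1.1, rrp * 1.25),
    annual_drug_cost = csc * ifelse(line == "first", runif(n, 5000, 14000),
                                    runif(n, 16000, 24000)),
    admin_cost_first_year = ifelse(route == "infusion",
                                   csc * runif(n, 2000, 6000), 0),
    admin_cost_subsequent = 0,
    monitoring_pretreatment = csc * runif(n, 150, 900),
    monitoring_annual = csc * runif(n, 100, 700),
    monitoring_post_discontinuation = csc * runif(n, 80, 250),
    prescriptions_per_year = ifelse(route == "infusion", 0L, 12L),
    cau_discontinuation = runif(n, 0.10, 0.31),
    trial_discontinuation = runif(n, 0.03, 0.10),
    adherence_applicable = route != "infusion",
    ae_disutility = runif(n, 0.002, 0.012),
    stringsAsFactors = FALSE
  )
  dmds$admin_cost_subsequent <- ifelse(route == "infusion",
                                       dmds$admin_cost_first_year *
                                         runif(n, 0.4, 1.0), 0)

  u0 <- runif(1, 0.82, 0.9)
  dec <- runif(9, 0.04, 0.12)
  u_rrms <- u0 - c(0, cumsum(dec)) / sum(dec) * (u0 - runif(1, 0, 0.05))
  utilities <- rbind(
    data.frame(course = "RRMS", edss = 0:9, utility = u_rrms),
    data.frame(course = "SPMS", edss = 1:9,
               utility = u_rrms[-1] - runif(1, 0.02, 0.06))
  )
  hc <- csc * (1500 + cumsum(runif(10, 300, 3500)))
  mkcost <- function(base, grow) csc * (base + cumsum(runif(10, 0, grow)))
  state_costs <- rbind(
    data.frame(course = "RRMS", edss = 0:9, healthcare = hc,
               community_services = mkcost(0, 1200),
               equipment_aids = mkcost(50, 700),
               informal_care = mkcost(200, 3200),
               productivity_friction = csc * runif(10, 0, 3000),
               productivity_human_capital = mkcost(5000, 3000)),
    data.frame(course = "SPMS", edss = 1:9, healthcare = hc[-1] * 1.1,
               community_services = mkcost(0, 1200)[-1],
               equipment_aids = mkcost(50, 700)[-1],
               informal_care = mkcost(200, 3200)[-1],
               productivity_friction = csc * runif(9, 0, 3000),
               productivity_human_capital = mkcost(5000, 3000)[-1])
  )
  economics <- list(
    utilities = utilities, state_costs = state_costs,
    relapse_cost_mild = csc * runif(1, 300, 900),
    relapse_cost_severe = csc * runif(1, 3000, 8000),
    relapse_disutility_mild = runif(1, 0.02, 0.06),
    relapse_disutility_severe = runif(1, 0.08, 0.15),
    ae_cost_fraction = runif(1, 0.005, 0.02),
    dispensing_fee_first = 14, dispensing_fee_subsequent = 7,
    discount_effects = 0.015, discount_costs = 0.040
  )

  init_raw <- c(best_supportive_care = runif(1, 0.1, 0.3),
                setNames(runif(n, 0.02, 1) * ifelse(line == "first", 1, 0.1),
                         nm))
  init_cau <- init_raw / sum(init_raw)
  shift <- runif(n + 1, 0.8, 1.25)
  init_sdm <- init_cau * shift / sum(init_cau * shift)
  adher_cau <- setNames(ifelse(dmds$adherence_applicable, 0.589, 1), nm)
  adher_sdm <- setNames(ifelse(dmds$adherence_applicable, 0.639, 1), nm)
  strategies <- list(
    CAU = strategy_profile("CAU", init_cau, 1, adher_cau, 0),
    SDM = strategy_profile("SDM", init_sdm, 0.5, adher_sdm, 100)
  )

  entry <- c(runif(7, 0, 1) * exp(-0.45 * (0:6)), 0, 0, 0)
  settings <- .ref_settings()
  settings$entry_distribution <- setNames(entry / sum(entry),
                                          paste0("edss", 0:9))

  new_parameter_set(
    natural_history = list(rrms_transitions = rt, spms_transitions = st,
                           relapse_rates = relapse,
                           mortality_multiplier = mm,
                           life_table = .ref_life_table()),
    dmds = dmds, economics = economics, strategies = strategies,
    settings = settings
  )
}

#' Cost decomposition of one shared decision making decision
#'
#' The assumed EUR 100 delivery cost per decision covers a 50\% increase in
#' consultation time (EUR 51.77), leaving EUR 48.23 of headroom per patient
#' for training, development and implementation of a patient decision aid.
#'
#' @return Named vector `total`, `consultation_time`, `decision_aid_headroom`.
#' @export
sdm_cost_components <- function() {
  c(total = 100, consultation_time = 51.77, decision_aid_headroom = 48.23)
}

# ---------------------------------------------------------------------------
# Microsimulation oracle
# ---------------------------------------------------------------------------

#' Individual-level Monte-Carlo oracle for the cohort engine
#'
#' Simulates `n_patients` independent patient trajectories with the same
#' event order as the cohort engine (accrual on start-of-cycle state, then
#' death, health-state transition, forced stop above the EDSS stop level,
#' voluntary discontinuation routed by the switch rule) but by per-patient
#' sampling rather than cohort mass propagation. Relapse counts are drawn
#' from Poisson/binomial distributions. Returns mean discounted QALYs and
#' total costs (settings perspective), undiscounted life years and relapse
#' counts, with Monte-Carlo standard errors, for verification of
#' [evaluate_strategy()].
#'
#' @param strategy An `ms_strategy`.
#' @param params An `ms_parameter_set`.
#' @param n_patients Number of simulated patients.
#' @param seed Integer RNG seed.
#' @return List with `estimate` and `se` (named vectors: `qalys`,
#'   `total_cost`, `life_years`, `relapses`) and `n_patients`.
#' @export
microsim_oracle <- function(strategy, params, n_patients, seed) {
  stopifnot(n_patients >= 1)
  set.seed(seed)
  se_ <- params$settings
  ec <- params$economics
  nh <- params$natural_history
  n_cyc <- as.integer(se_$max_age - se_$start_age)
  H <- .N_STATES
  hs <- health_states()
  edss <- state_edss()
  persp <- se_$perspective

  dmd_names <- params$dmds$name
  nD <- length(dmd_names)

  # cumulative no-mortality transition matrices: group 0 = off treatment
  cumP <- vector("list", nD + 1L)
  M0 <- base_transition_matrix(nh, 1, 1)
  cumP[[1L]] <- t(apply(M0, 1, cumsum))
  for (k in seq_len(nD)) {
    d <- params$dmds[k, ]
    rr_sp <- if (isTRUE(se_$rr_applies_spms)) d$rr_progression else 1
    Mk <- base_transition_matrix(nh, d$rr_progression, rr_sp)
    cumP[[k + 1L]] <- t(apply(Mk, 1, cumsum))
  }

  death_mat <- t(vapply(seq_len(n_cyc) - 1L, function(t)
    death_probability_states(se_$start_age + t, se_, nh), numeric(H)))

  # per-state lookups
  util <- rate <- sf <- numeric(H)
  person_cost <- numeric(H)
  for (h in which(alive_states())) {
    crs <- as.character(hs$course[h])
    util[h] <- ec$utilities$utility[ec$utilities$course == crs &
                                      ec$utilities$edss == edss[h]][1L]
    r <- nh$relapse_rates[nh$relapse_rates$course == crs &
                            nh$relapse_rates$edss == edss[h], ]
    rate[h] <- r$relapse_rate[1L]
    sf[h] <- r$severe_fraction[1L]
    person_cost[h] <- cycle_person_costs(crs, edss[h], persp, ec)
  }

  # per-DMD scalars (index 0 = off treatment)
  d <- params$dmds
  rr_rel <- c(1, d$rr_relapse)
  y1_cost <- c(0, vapply(seq_len(nD), function(k)
    cycle_treatment_costs(d[k, ], 0L, ec), numeric(1)))
  yn_cost <- c(0, vapply(seq_len(nD), function(k)
    cycle_treatment_costs(d[k, ], 1L, ec), numeric(1)))
  mon_post <- c(0, d$monitoring_post_discontinuation)
  aedu <- c(0, d$ae_disutility)
  adh_app <- c(FALSE, d$adherence_applicable)
  q_disc <- c(0, vapply(seq_len(nD), function(k)
    effective_discontinuation(d[k, ], strategy, 0, se_), numeric(1)))

  # cumulative switch-destination tables per DMD (first-treatment stops)
  sw_dest <- sw_cum <- vector("list", nD)
  for (k in seq_len(nD)) {
    sw <- switch_distribution(list(stage = "ON_FIRST_DMD", dmd = dmd_names[k]),
                              strategy, params)
    sw_dest[[k]] <- match(names(sw), dmd_names, nomatch = 0L)  # 0 = BSC
    sw_cum[[k]] <- cumsum(sw)
  }

  # initial option, adherence class, entry state
  init <- strategy$initiation
  opts <- names(init)
  opt_idx <- sample.int(length(opts), n_patients, replace = TRUE,
                        prob = init)
  cur_dmd <- match(opts, dmd_names, nomatch = 0L)[opt_idx]  # 0 = BSC
  phase <- ifelse(cur_dmd > 0L, 1L, 0L)  # 0 none/BSC, 1 first DMD, 2 second
  adherent <- rep(TRUE, n_patients)
  for (k in seq_len(nD)) {
    sel <- cur_dmd == k
    if (any(sel) && isTRUE(d$adherence_applicable[k])) {
      pa <- strategy$adherent_proportion[[dmd_names[k]]]
      adherent[sel] <- runif(sum(sel)) < pa
    }
  }
  state <- sample.int(10L, n_patients, replace = TRUE,
                      prob = se_$entry_distribution)
  entry_cycle <- rep(0L, n_patients)
  alive <- rep(TRUE, n_patients)

  qaly <- cost <- relapses <- ly <- numeric(n_patients)
  d_eff <- discount_factor(ec$discount_effects, seq_len(n_cyc) - 1L)
  d_cst <- discount_factor(ec$discount_costs, seq_len(n_cyc) - 1L)
  sdm_c <- strategy$sdm_cost_per_decision
  cost <- cost + sdm_c                      # initiation decision, cycle 0

  for (t in seq_len(n_cyc) - 1L) {
    idx <- which(alive)
    if (!length(idx)) break
    st_t <- state[idx]
    dm <- cur_dmd[idx]
    on_tx <- dm > 0L

    # relapses on start-of-cycle state; nonadherence multipliers apply only
    # on adherence-applicable DMDs (infusions stay optimally adherent)
    na_now <- adh_app[dm + 1L] & !adherent[idx]
    r_mult <- rr_rel[dm + 1L] *
      ifelse(na_now, se_$nonadherent_relapse_multiplier, 1)
    lam <- rate[st_t] * r_mult
    n_rel <- rpois(length(idx), lam)
    sf_eff <- pmin(sf[st_t] *
                     ifelse(na_now, se_$nonadherent_severe_multiplier, 1), 1)
    n_sev <- rbinom(length(idx), n_rel, sf_eff)
    n_mild <- n_rel - n_sev
    relapses[idx] <- relapses[idx] + n_rel

    # QALYs and costs on start-of-cycle occupancy
    uq <- util[st_t] - ec$relapse_disutility_mild * n_mild -
      ec$relapse_disutility_severe * n_sev - aedu[dm + 1L]
    qaly[idx] <- qaly[idx] + d_eff[t + 1L] * uq
    ly[idx] <- ly[idx] + 1

    tx_cost <- ifelse(entry_cycle[idx] == t, y1_cost[dm + 1L],
                      yn_cost[dm + 1L])
    rel_cost <- n_mild * ec$relapse_cost_mild + n_sev * ec$relapse_cost_severe
    cost[idx] <- cost[idx] + d_cst[t + 1L] *
      (person_cost[st_t] + tx_cost + rel_cost)

    # death
    dies <- runif(length(idx)) < death_mat[t + 1L, st_t]
    alive[idx[dies]] <- FALSE
    state[idx[dies]] <- .STATE_DEAD
    idx <- idx[!dies]
    if (!length(idx)) next

    # health-state transition by treatment group
    for (k in 0:nD) {
      sel <- idx[cur_dmd[idx] == k]
      if (!length(sel)) next
      cm <- cumP[[k + 1L]][state[sel], , drop = FALSE]
      state[sel] <- 1L + as.integer(rowSums(cm < runif(length(sel))))
    }
    dead_now <- state[idx] == .STATE_DEAD
    alive[idx[dead_now]] <- FALSE
    idx <- idx[!dead_now]
    if (!length(idx)) next

    # forced stop above the EDSS stop level (no switch, no decision)
    on_i <- idx[cur_dmd[idx] > 0L]
    stop_f <- on_i[edss[state[on_i]] > se_$edss_stop_level]
    if (length(stop_f)) {
      cost[stop_f] <- cost[stop_f] + d_cst[t + 1L] *
        mon_post[cur_dmd[stop_f] + 1L]
      cur_dmd[stop_f] <- 0L
      phase[stop_f] <- 0L
    }

    # voluntary discontinuation, effective next cycle
    on_i <- idx[cur_dmd[idx] > 0L]
    if (length(on_i)) {
      stops <- on_i[runif(length(on_i)) < q_disc[cur_dmd[on_i] + 1L]]
      if (length(stops)) {
        cost[stops] <- cost[stops] + d_cst[t + 1L] *
          mon_post[cur_dmd[stops] + 1L]
        first <- stops[phase[stops] == 1L]
        second <- stops[phase[stops] == 2L]
        if (length(second)) {
          cur_dmd[second] <- 0L
          phase[second] <- 0L
        }
        if (length(first)) {
          # a new shared decision is made at the first-DMD stop
          cost[first] <- cost[first] + d_cst[t + 1L] * sdm_c
          grp <- cur_dmd[first]       # snapshot before reassignment
          for (k in unique(grp)) {
            sel <- first[grp == k]
            u <- runif(length(sel))
            pick <- 1L + as.integer(rowSums(outer(u, sw_cum[[k]], ">")))
            dest <- sw_dest[[k]][pick]
            cur_dmd[sel] <- dest
            phase[sel] <- ifelse(dest > 0L, 2L, 0L)
            entry_cycle[sel] <- t + 1L
          }
        }
      }
    }
  }

  est <- c(qalys = mean(qaly), total_cost = mean(cost),
           life_years = mean(ly), relapses = mean(relapses))
  se_out <- c(qalys = stats::sd(qaly), total_cost = stats::sd(cost),
              life_years = stats::sd(ly), relapses = stats::sd(relapses)) /
    sqrt(n_patients)
  list(estimate = est, se = se_out, n_patients = n_patients)
}
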