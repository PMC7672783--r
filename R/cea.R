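# Strategy comparison, one-way sensitivity registry, SDM-cost threshold
# analysis, and probabilistic sensitivity analysis.

#' Compare two strategies on incremental cost-effectiveness
#'
#' Computes incremental costs and QALYs on the discounted totals and
#' classifies the result: an ICER when the intervention adds both QALYs and
#' costs, `DOMINANT` when it is cheaper and more effective, `DOMINATED` when
#' it is costlier and no more effective, and `COST_SAVING_QALY_LOSING` (with
#' the southwest-quadrant ICER) when it saves money but loses QALYs.
#'
#' @param intervention,comparator `ms_outcomes` objects.
#' @param perspective Costing perspective for the totals.
#' @param labels Character pair naming the two arms.
#' @return An object of class `ms_ce_result` with `delta_cost`, `delta_qaly`,
#'   `icer` (`NA` when undefined) and `classification`.
#' @export
compare <- function(intervention, comparator,
                    perspective = "societal_friction",
                    labels = c("SDM", "CAU")) {
  dc <- total_cost(intervention, perspective) -
    total_cost(comparator, perspective)
  dq <- intervention$qalys[["discounted"]] - comparator$qalys[["discounted"]]
  icer <- if (dq != 0) dc / dq else NA_real_
  classification <-
    if (dq > 0 && dc < 0) "DOMINANT"
    else if (dq <= 0 && dc > 0) "DOMINATED"
    else if (dq < 0 && dc <= 0) "COST_SAVING_QALY_LOSING"
    else if (dq == 0) "DOMINANT"          # cheaper or equal, equal QALYs
    else "ICER"
  out <- list(
    labels = labels, perspective = perspective,
    intervention = intervention, comparator = comparator,
    delta_cost = dc, delta_qaly = dq, icer = icer,
    classification = classification
  )
  class(out) <- "ms_ce_result"
  out
}

#' @export
print.ms_ce_result <- function(x, ...) {
  cat(sprintf("%s vs %s (%s perspective)\n", x$labels[1], x$labels[2],
              x$perspective))
  cat(sprintf("  dCost: %0.2f EUR   dQALY: %0.4f\n", x$delta_cost,
              x$delta_qaly))
  if (x$classification %in% c("ICER", "COST_SAVING_QALY_LOSING")) {
    cat(sprintf("  %s, ICER %0.2f EUR/QALY\n", x$classification, x$icer))
  } else {
    cat(sprintf("  %s\n", x$classification))
  }
  invisible(x)
}

# evaluate both arms and compare them under the settings' perspective
.run_pair <- function(params, intervention = "SDM", comparator = "CAU") {
  context <- .build_context(params)
  o_int <- evaluate_strategy(params$strategies[[intervention]], params,
                             context)
  o_cmp <- evaluate_strategy(params$strategies[[comparator]], params, context)
  compare(o_int, o_cmp, perspective = params$settings$perspective,
          labels = c(intervention, comparator))
}

#' Maximum cost of shared decision making at a willingness-to-pay threshold
#'
#' The delivery cost enters total costs linearly through the expected number
#' of (discounted) decision epochs, so the cost `c*` at which the ICER equals
#' the willingness-to-pay threshold is found by a linear solve
#' `c* = (wtp * dQALY - dCost_excluding_delivery) / E[discounted decisions]`,
#' then verified by one re-run of the model at `c*`.
#'
#' @param params An `ms_parameter_set`.
#' @param wtp Willingness-to-pay threshold (EUR/QALY).
#' @param intervention,comparator Strategy names in `params$strategies`.
#' @return List with `max_cost` (EUR per decision; `NA` if not achievable),
#'   `achievable`, `wtp`, `delta_qaly`, `check_rel_error`.
#' @export
threshold_sdm_cost <- function(params, wtp, intervention = "SDM",
                               comparator = "CAU") {
  p0 <- params
  p0$strategies[[intervention]]$sdm_cost_per_decision <- 0
  ce0 <- .run_pair(p0, intervention, comparator)
  if (ce0$delta_qaly <= 0) {
    return(list(max_cost = NA_real_, achievable = FALSE, wtp = wtp,
                delta_qaly = ce0$delta_qaly, check_rel_error = NA_real_))
  }
  decisions <- ce0$intervention$decisions[["discounted"]]
  if (decisions <= 0) stop("zero expected decision epochs in the ",
                           intervention, " arm")
  c_star <- (wtp * ce0$delta_qaly - ce0$delta_cost) / decisions

  p1 <- params
  p1$strategies[[intervention]]$sdm_cost_per_decision <- c_star
  ce1 <- .run_pair(p1, intervention, comparator)
  rel_err <- abs(ce1$icer - wtp) / wtp
  if (!is.finite(rel_err) || rel_err >= 1e-6) {
    stop("threshold re-run check failed: |ICER(c*) - wtp|/wtp = ", rel_err)
  }
  list(max_cost = c_star, achievable = TRUE, wtp = wtp,
       delta_qaly = ce0$delta_qaly, check_rel_error = rel_err)
}

# ---------------------------------------------------------------------------
# One-way sensitivity analysis
# ---------------------------------------------------------------------------

#' Build a scenario that replaces one value at a parameter path
#'
#' @param name Scenario label.
#' @param path Character vector addressing a element of the parameter set,
#'   e.g. `c("economics", "discount_costs")`.
#' @param value Replacement value.
#' @return A scenario usable in [one_way_sensitivity()].
#' @export
scenario_set <- function(name, path, value) {
  force(path); force(value)
  list(name = name, transform = function(ps) {
    ref <- paste0("ps", paste0("[['", path, "']]", collapse = ""))
    # walk the path
    node <- ps
    for (k in path[-length(path)]) {
      if (is.null(node[[k]])) stop("unknown parameter path: ", ref)
      node <- node[[k]]
    }
    if (!(path[length(path)] %in% names(node))) {
      stop("unknown parameter path: ", ref)
    }
    ps[[path]] <- value
    ps
  })
}

#' Run a registry of one-way sensitivity scenarios
#'
#' Each scenario transforms the parameter set; both strategies are re-run and
#' compared. Use [owsa_registry()] for the shipped preset covering drug
#' costs, progression relative-risk ranges, delivery cost, discounting,
#' perspectives, demographics, entry distribution, treatment-choice variants
#' and transition-probability scaling.
#'
#' @param registry List of scenarios (`name`, `transform`).
#' @param params An `ms_parameter_set`.
#' @param intervention,comparator Strategy names.
#' @return Data frame with per-scenario costs, QALYs, increments, ICER and
#'   classification.
#' @export
one_way_sensitivity <- function(registry, params, intervention = "SDM",
                                comparator = "CAU") {
  rows <- lapply(registry, function(sc) {
    ps <- sc$transform(params)
    ce <- .run_pair(ps, intervention, comparator)
    data.frame(
      scenario = sc$name,
      comparator_cost = total_cost(ce$comparator, ce$perspective),
      comparator_qalys = ce$comparator$qalys[["discounted"]],
      intervention_cost = total_cost(ce$intervention, ce$perspective),
      intervention_qalys = ce$intervention$qalys[["discounted"]],
      delta_cost = ce$delta_cost, delta_qaly = ce$delta_qaly,
      icer = ce$icer, classification = ce$classification,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# scale movement probabilities (worsening, improvement, conversion) by f and
# re-normalise through the stay probability
.scale_transitions <- function(ps, f) {
  rt <- ps$natural_history$rrms_transitions
  for (i in seq_len(10L)) {
    move <- rt[i, ]
    move[i] <- 0
    move <- move * f
    if (sum(move) >= 1) stop("transition scaling makes row mass exceed 1")
    rt[i, ] <- move
    rt[i, i] <- 1 - sum(move)
  }
  st <- ps$natural_history$spms_transitions
  for (i in seq_len(9L)) {
    move <- st[i, ]
    move[i] <- 0
    move <- move * f
    if (sum(move) >= 1) stop("transition scaling makes row mass exceed 1")
    st[i, ] <- move
    st[i, i] <- 1 - sum(move)
  }
  ps$natural_history$rrms_transitions <- rt
  ps$natural_history$spms_transitions <- st
  ps
}

.entry_named <- function(x) setNames(x, paste0("edss", 0:9))

# replace the SDM arm's initiation with equal first-line shares
.sdm_first_line_equal <- function(ps, bsc_share) {
  fl <- ps$dmds$name[ps$dmds$line == "first"]
  init <- setNames(rep(0, nrow(ps$dmds) + 1L),
                   c("best_supportive_care", ps$dmds$name))
  init["best_supportive_care"] <- bsc_share
  init[fl] <- (1 - bsc_share) / length(fl)
  ps$strategies$SDM$initiation <- init
  ps
}

#' The shipped one-way sensitivity preset
#'
#' Covers: drug costs +/-20\%; per-DMD progression relative risk at its lower
#' and upper range; zero delivery cost; discount rates 0\% and 3\% for both
#' costs and effects; health care and human-capital perspectives; onset age
#' 29 and 45; proportion male 18\% and 40\%; entry distribution concentrated
#' at EDSS 1, at EDSS 4, uniform, and shifted (-3.75 percentage points at
#' EDSS 0--3, +5 at EDSS 4--6); initial-choice variants (equal first-line
#' shares with 0\% or 25\% best supportive care); switch-destination variants
#' (second-line only, or first- and second-line, with equal shares); and
#' transition probabilities +/-10\%.
#'
#' @param params The base `ms_parameter_set` (used for DMD names).
#' @return A scenario registry for [one_way_sensitivity()].
#' @export
owsa_registry <- function(params) {
  tf <- function(name, f) list(name = name, transform = f)
  reg <- list(
    tf("base_case", identity),
    tf("drug_costs_plus20", function(ps) {
      ps$dmds$annual_drug_cost <- ps$dmds$annual_drug_cost * 1.2; ps
    }),
    tf("drug_costs_minus20", function(ps) {
      ps$dmds$annual_drug_cost <- ps$dmds$annual_drug_cost * 0.8; ps
    }),
    tf("rr_progression_lower", function(ps) {
      ps$dmds$rr_progression <- ps$dmds$rr_progression_low; ps
    }),
    tf("rr_progression_upper", function(ps) {
      ps$dmds$rr_progression <- ps$dmds$rr_progression_high; ps
    }),
    tf("sdm_cost_0", function(ps) {
      ps$strategies$SDM$sdm_cost_per_decision <- 0; ps
    }),
    tf("discount_0", function(ps) {
      ps$economics$discount_effects <- 0; ps$economics$discount_costs <- 0; ps
    }),
    tf("discount_3", function(ps) {
      ps$economics$discount_effects <- 0.03
      ps$economics$discount_costs <- 0.03; ps
    }),
    tf("perspective_healthcare", function(ps) {
      ps$settings$perspective <- "healthcare"; ps
    }),
    tf("perspective_human_capital", function(ps) {
      ps$settings$perspective <- "societal_human_capital"; ps
    }),
    tf("onset_age_29", function(ps) { ps$settings$start_age <- 29; ps }),
    tf("onset_age_45", function(ps) { ps$settings$start_age <- 45; ps }),
    tf("proportion_male_40", function(ps) {
      ps$settings$proportion_male <- 0.40; ps
    }),
    tf("proportion_male_18", function(ps) {
      ps$settings$proportion_male <- 0.18; ps
    }),
    tf("entry_100_edss1", function(ps) {
      ps$settings$entry_distribution <-
        .entry_named(c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0)); ps
    }),
    tf("entry_100_edss4", function(ps) {
      ps$settings$entry_distribution <-
        .entry_named(c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0)); ps
    }),
    tf("entry_equal", function(ps) {
      ps$settings$entry_distribution <- .entry_named(rep(0.1, 10)); ps
    }),
    tf("entry_shift_to_mid", function(ps) {
      e <- ps$settings$entry_distribution
      e[1:4] <- e[1:4] - 0.0375
      e[5:7] <- e[5:7] + 0.05
      if (any(e < 0)) stop("entry shift produces negative mass")
      ps$settings$entry_distribution <- e; ps
    }),
    tf("sdm_choice_first_line_equal_no_bsc",
       function(ps) .sdm_first_line_equal(ps, 0)),
    tf("sdm_choice_first_line_equal_25_bsc",
       function(ps) .sdm_first_line_equal(ps, 0.25)),
    tf("switch_second_line_only_equal", function(ps) {
      for (nm in names(ps$strategies)) {
        ps$strategies[[nm]]$switch_override <- "second_only_equal"
      }
      ps
    }),
    tf("switch_first_and_second_equal", function(ps) {
      for (nm in names(ps$strategies)) {
        ps$strategies[[nm]]$switch_override <- "first_second_equal"
      }
      ps
    }),
    tf("transitions_plus10", function(ps) .scale_transitions(ps, 1.1)),
    tf("transitions_minus10", function(ps) .scale_transitions(ps, 0.9))
  )
  names(reg) <- vapply(reg, `[[`, character(1), "name")
  reg
}

# ---------------------------------------------------------------------------
# Probabilistic sensitivity analysis
# ---------------------------------------------------------------------------

# moment-matched samplers; zero spread returns the mean
.rgamma_m <- function(n, mean, sd) {
  if (mean <= 0 || sd <= 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  rgamma(n, shape = shape, rate = shape / mean)
}
.rbeta_m <- function(n, mean, sd) {
  if (sd <= 0 || mean <= 0 || mean >= 1) return(rep(mean, n))
  v <- min(sd^2, mean * (1 - mean) * 0.99)
  k <- mean * (1 - mean) / v - 1
  rbeta(n, mean * k, (1 - mean) * k)
}
.rlnorm_m <- function(n, mean, sd) {
  if (mean <= 0 || sd <= 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}
.rdirichlet_row <- function(p, strength) {
  g <- vapply(p * strength, function(a) if (a > 0) rgamma(1, a) else 0,
              numeric(1))
  if (sum(g) <= 0) p else g / sum(g)
}

#' Default probabilistic sensitivity analysis configuration
#'
#' Distribution families follow common practice: beta for probabilities,
#' proportions and (rescaled) utilities, gamma for costs and rates, lognormal
#' for relative risks, Dirichlet rows for transition probabilities. Moments
#' are matched to the point estimate with a standard error of `sd_prop` times
#' the mean (10\% by default). Unit drug prices and tariff-based fees are
#' treated as known and not sampled.
#'
#' @param sd_prop Proportional standard error for sampled parameters.
#' @param sample_transitions Sample transition rows from Dirichlet
#'   distributions?
#' @param transition_strength Dirichlet concentration (pseudo-count) per row.
#' @return A PSA configuration list.
#' @export
psa_config <- function(sd_prop = 0.1, sample_transitions = TRUE,
                       transition_strength = 200) {
  list(sd_prop = sd_prop, sample_transitions = sample_transitions,
       transition_strength = transition_strength)
}

#' Draw one random parameter set for probabilistic sensitivity analysis
#'
#' @param params Base `ms_parameter_set` (point estimates).
#' @param config A [psa_config()].
#' @return A sampled `ms_parameter_set`.
#' @export
sample_parameter_set <- function(params, config = psa_config()) {
  sp <- config$sd_prop
  if (sp <= 0) return(params)
  ps <- params

  d <- ps$dmds
  d$rr_progression <- pmin(2, .mapply_num(.rlnorm_m, d$rr_progression, sp))
  d$rr_relapse <- pmin(2, .mapply_num(.rlnorm_m, d$rr_relapse, sp))
  d$cau_discontinuation <- .mapply_num(.rbeta_m, d$cau_discontinuation, sp)
  ps$dmds <- d

  u <- ps$economics$utilities
  resc <- (u$utility + 1) / 2
  resc <- .mapply_num(.rbeta_m, resc, sp)
  u$utility <- 2 * resc - 1
  # keep EDSS-monotonicity within course (sorted draws preserve realism)
  for (crs in c("RRMS", "SPMS")) {
    i <- which(u$course == crs)
    u$utility[i] <- sort(u$utility[i], decreasing = TRUE)
  }
  ps$economics$utilities <- u

  sc <- ps$economics$state_costs
  for (cl in setdiff(names(sc), c("course", "edss"))) {
    sc[[cl]] <- .mapply_num(.rgamma_m, sc[[cl]], sp)
  }
  for (crs in c("RRMS", "SPMS")) {          # healthcare stays monotone
    i <- which(sc$course == crs)
    sc$healthcare[i] <- sort(sc$healthcare[i])
  }
  ps$economics$state_costs <- sc

  rr <- ps$natural_history$relapse_rates
  rr$relapse_rate <- .mapply_num(.rgamma_m, rr$relapse_rate, sp)
  rr$severe_fraction <- .mapply_num(.rbeta_m, rr$severe_fraction, sp)
  ps$natural_history$relapse_rates <- rr

  for (k in c("relapse_cost_mild", "relapse_cost_severe",
              "relapse_disutility_mild", "relapse_disutility_severe")) {
    ps$economics[[k]] <- .rgamma_m(1, params$economics[[k]],
                                   sp * params$economics[[k]])
  }

  if (isTRUE(config$sample_transitions)) {
    rt <- ps$natural_history$rrms_transitions
    for (i in seq_len(10L)) {
      rt[i, ] <- .rdirichlet_row(rt[i, ], config$transition_strength)
    }
    st <- ps$natural_history$spms_transitions
    for (i in seq_len(9L)) {
      st[i, ] <- .rdirichlet_row(st[i, ], config$transition_strength)
    }
    ps$natural_history$rrms_transitions <- rt
    ps$natural_history$spms_transitions <- st
  }

  # intervention-effect parameters: discontinuation multiplier and the
  # adherent proportions (the SDM proportion keeps its absolute improvement)
  cau_ad <- ps$strategies$CAU$adherent_proportion
  sdm_gain <- ps$strategies$SDM$adherent_proportion - cau_ad
  cau_ad <- vapply(cau_ad, function(m) .rbeta_m(1, m, sp * m), numeric(1))
  ps$strategies$CAU$adherent_proportion <- cau_ad
  ps$strategies$SDM$adherent_proportion <- pmin(cau_ad + sdm_gain, 1)
  m <- ps$strategies$SDM$discontinuation_multiplier
  ps$strategies$SDM$discontinuation_multiplier <- .rbeta_m(1, m, sp * m)

  ps
}

.mapply_num <- function(f, means, sp) {
  vapply(means, function(m) f(1, m, sp * abs(m)), numeric(1))
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` random parameter sets, re-runs the full model for both
#' strategies per draw, and stores the incremental cost and QALY pairs.
#' Deterministic given `seed`.
#'
#' @param params Base `ms_parameter_set`.
#' @param n Number of iterations.
#' @param seed Integer RNG seed.
#' @param config A [psa_config()].
#' @param intervention,comparator Strategy names.
#' @return An object of class `ms_psa_result` with element `draws`
#'   (data frame `delta_cost`, `delta_qaly`), `n_iterations` and `seed`.
#' @export
run_psa <- function(params, n, seed, config = psa_config(),
                    intervention = "SDM", comparator = "CAU") {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  dc <- dq <- numeric(n)
  for (i in seq_len(n)) {
    psi <- sample_parameter_set(params, config)
    ce <- .run_pair(psi, intervention, comparator)
    dc[i] <- ce$delta_cost
    dq[i] <- ce$delta_qaly
  }
  out <- list(draws = data.frame(delta_cost = dc, delta_qaly = dq),
              n_iterations = n, seed = seed,
              perspective = params$settings$perspective,
              labels = c(intervention, comparator))
  class(out) <- "ms_psa_result"
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that the intervention
#' is cost-effective is the fraction of draws with non-negative net monetary
#' benefit, `wtp * dQALY - dCost >= 0`.
#'
#' @param result An `ms_psa_result`.
#' @param wtp_grid Numeric vector of willingness-to-pay values (EUR/QALY);
#'   defaults to 0--100,000 in steps of 1,000.
#' @return Data frame with columns `wtp` and `probability_ce`.
#' @export
ceac <- function(result, wtp_grid = seq(0, 100000, by = 1000)) {
  if (!length(wtp_grid)) stop("wtp_grid must be non-empty")
  if (!nrow(result$draws)) stop("PSA result contains no draws")
  dq <- result$draws$delta_qaly
  dc <- result$draws$delta_cost
  p <- vapply(wtp_grid, function(l) mean(l * dq - dc >= 0), numeric(1))
  data.frame(wtp = wtp_grid, probability_ce = p)
}
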