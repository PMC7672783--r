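# Conversion of cohort traces into discounted QALYs, life years, relapses and
# cost components under each costing perspective.

.COST_CATEGORIES <- c("drug", "administration", "monitoring", "dispensing",
                      "adverse_events", "health_state_healthcare", "relapse",
                      "community", "equipment", "informal_care",
                      "productivity_friction", "productivity_human_capital",
                      "sdm_delivery")

.HEALTHCARE_CATEGORIES <- c("drug", "administration", "monitoring",
                            "dispensing", "adverse_events",
                            "health_state_healthcare", "relapse",
                            "sdm_delivery")

#' Discount factor for a cycle
#'
#' Annual discounting with cycle 0 undiscounted: `1 / (1 + rate)^cycle`.
#' Effects are discounted at 1.5\% per year and costs at 4.0\% in the Dutch
#' base case.
#'
#' @param rate Annual discount rate (>= 0).
#' @param cycle Cycle index (0-based); vectorised.
#' @return Discount factor(s).
#' @export
discount_factor <- function(rate, cycle) {
  if (any(rate < 0) || any(cycle < 0)) stop("rate and cycle must be >= 0")
  1 / (1 + rate)^cycle
}

#' Annual treatment cost of a DMD for one cycle on treatment
#'
#' Sums drug acquisition, administration (first year vs subsequent),
#' monitoring (pretreatment monitoring in the first year only) and pharmacy
#' dispensing fees: the first prescription of a course costs EUR 14 and each
#' subsequent one EUR 7, with `prescriptions_per_year` fills per year for
#' self-administered DMDs and none for infusions.
#'
#' @param dmd One-row DMD profile.
#' @param cycle_in_treatment 0-based cycle index within the treatment course.
#' @param inputs Economic inputs (dispensing fees).
#' @return EUR for the cycle.
#' @export
cycle_treatment_costs <- function(dmd, cycle_in_treatment, inputs) {
  first <- cycle_in_treatment == 0L
  n_rx <- dmd$prescriptions_per_year
  fees <- if (n_rx > 0) {
    if (first) inputs$dispensing_fee_first + (n_rx - 1) * inputs$dispensing_fee_subsequent
    else n_rx * inputs$dispensing_fee_subsequent
  } else 0
  admin <- if (first) dmd$admin_cost_first_year else dmd$admin_cost_subsequent
  pre <- if (first) dmd$monitoring_pretreatment else 0
  dmd$annual_drug_cost + admin + dmd$monitoring_annual + pre + fees
}

#' Annual health-state cost of a living patient under a perspective
#'
#' Health care costs (plus adverse-event costs as a configured proportion of
#' them) are counted in every perspective. The limited societal perspective
#' with friction-cost productivity losses adds community services, equipment
#' and aids, informal care and friction-method productivity losses; the
#' human-capital variant swaps the productivity method.
#'
#' @param course `"RRMS"` or `"SPMS"`.
#' @param edss Integer EDSS level.
#' @param perspective One of `"healthcare"`, `"societal_friction"`,
#'   `"societal_human_capital"`.
#' @param inputs Economic inputs (state cost table, AE fraction).
#' @return EUR per person-year.
#' @export
cycle_person_costs <- function(course, edss, perspective, inputs) {
  if (course == "DEAD") stop("cycle_person_costs is undefined for DEAD")
  perspective <- match.arg(perspective, c("healthcare", "societal_friction",
                                          "societal_human_capital"))
  sc <- inputs$state_costs
  row <- sc[sc$course == course & sc$edss == edss, ]
  if (nrow(row) != 1L) stop("no state costs for ", course, " EDSS ", edss)
  hc <- row$healthcare + ae_costs(row$healthcare, inputs$ae_cost_fraction)
  if (perspective == "healthcare") return(hc)
  extra <- row$community_services + row$equipment_aids + row$informal_care
  prod <- if (perspective == "societal_friction") row$productivity_friction
          else row$productivity_human_capital
  hc + extra + prod
}

# empty outcomes skeleton; cost components are named vectors for speed
.empty_outcomes <- function() {
  zero2 <- c(discounted = 0, undiscounted = 0)
  zc <- setNames(numeric(length(.COST_CATEGORIES)), .COST_CATEGORIES)
  out <- list(
    qalys = zero2, life_years = zero2, relapses = zero2,
    severe_relapses = zero2,
    cost_disc = zc, cost_undisc = zc,
    decisions = zero2
  )
  class(out) <- "ms_outcomes"
  out
}

.perspective_categories <- function(perspective) {
  switch(perspective,
    healthcare = .HEALTHCARE_CATEGORIES,
    societal_friction = c(.HEALTHCARE_CATEGORIES, "community", "equipment",
                          "informal_care", "productivity_friction"),
    societal_human_capital = c(.HEALTHCARE_CATEGORIES, "community",
                               "equipment", "informal_care",
                               "productivity_human_capital"),
    stop("unknown perspective '", perspective, "'")
  )
}

#' Scale an outcomes object by a weight
#' @param o An `ms_outcomes`.
#' @param w Non-negative weight.
#' @return Scaled `ms_outcomes`.
#' @export
outcomes_scale <- function(o, w) {
  for (f in c("qalys", "life_years", "relapses", "severe_relapses",
              "decisions", "cost_disc", "cost_undisc")) o[[f]] <- o[[f]] * w
  o
}

#' Add two outcomes objects
#' @param a,b `ms_outcomes` objects with identical category layout.
#' @return Their sum as an `ms_outcomes`.
#' @export
outcomes_add <- function(a, b) {
  stopifnot(identical(names(a$cost_disc), names(b$cost_disc)))
  for (f in c("qalys", "life_years", "relapses", "severe_relapses",
              "decisions", "cost_disc", "cost_undisc")) {
    a[[f]] <- a[[f]] + b[[f]]
  }
  a
}

#' Cost components of an outcomes object as a data frame
#' @param o An `ms_outcomes`.
#' @return Data frame with columns `category`, `discounted`, `undiscounted`.
#' @export
outcomes_costs <- function(o) {
  data.frame(category = names(o$cost_disc),
             discounted = unname(o$cost_disc),
             undiscounted = unname(o$cost_undisc),
             stringsAsFactors = FALSE)
}

#' Total costs per perspective as a data frame
#' @param o An `ms_outcomes`.
#' @return Data frame with columns `perspective`, `discounted`,
#'   `undiscounted`.
#' @export
outcomes_totals <- function(o) {
  persp <- c("healthcare", "societal_friction", "societal_human_capital")
  data.frame(
    perspective = persp,
    discounted = vapply(persp, function(p)
      sum(o$cost_disc[.perspective_categories(p)]), numeric(1)),
    undiscounted = vapply(persp, function(p)
      sum(o$cost_undisc[.perspective_categories(p)]), numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Total cost of an outcomes object under a perspective
#' @param o An `ms_outcomes`.
#' @param perspective Perspective name.
#' @param discounted Use discounted totals? Default `TRUE`.
#' @return EUR.
#' @export
total_cost <- function(o, perspective = "societal_friction",
                       discounted = TRUE) {
  v <- if (discounted) o$cost_disc else o$cost_undisc
  sum(v[.perspective_categories(perspective)])
}

#' Accrue outcomes over a cohort trace
#'
#' Converts a pathway trace into QALYs, life years, relapses and cost
#' components. All quantities accrue on start-of-cycle occupancy: utilities
#' minus relapse and adverse-event disutilities for QALYs; relapse counts from
#' state rates scaled by the treatment's relapse relative risk and, for
#' nonadherent patients, the nonadherence multipliers; drug, administration,
#' monitoring and dispensing costs on on-treatment mass (first-year components
#' on entrant mass, post-discontinuation monitoring once on stopping mass);
#' health-state costs by category; adverse-event costs as a proportion of the
#' health-state health care costs; and the shared decision making delivery
#' cost on decision mass. Effects are discounted at the effect rate, costs at
#' the cost rate; undiscounted twins are kept.
#'
#' @param trace An `ms_cohort_trace` from [run_pathway()].
#' @param strategy The `ms_strategy` the trace was run under.
#' @param params An `ms_parameter_set`.
#' @param context Optional precomputed evaluation context (internal reuse).
#' @return An `ms_outcomes` object.
#' @export
accrue <- function(trace, strategy, params, context = NULL) {
  both <- .accrue_pathway(trace, strategy, params, context)
  both[[trace$adherence_class]]
}

# Accrue one pathway trace for both adherence classes in a single pass. The
# trace is identical for the two classes (nonadherence affects relapse risks
# only, not transitions), so every cost and occupancy series except the
# relapse-dependent ones is shared.
.accrue_pathway <- function(trace, strategy, params, context = NULL) {
  if (is.null(context)) context <- .build_context(params)
  se <- params$settings
  ec <- params$economics
  stages <- trace$stages
  S <- stages$n
  H <- .N_STATES
  T_ <- trace$n_cycles
  occ <- matrix(as.numeric(trace$trace), nrow = T_)  # T x (S*H), h-major
  if (ncol(occ) != S * H) stop("trace/parameter shape mismatch")

  alive <- alive_states()
  cs <- context$state
  util <- cs$util; rate <- cs$rate; sf <- cs$sf

  # per-stage scalars
  on_dmd <- stages$kind %in% c("ON_FIRST_DMD", "ON_SECOND_DMD")
  rr_rel <- rep(1, S)
  drug <- admin_sub <- admin_extra <- mon_annual <- mon_pre <- mon_post <-
    fee_sub <- fee_extra <- aedu <- numeric(S)
  adh_app <- logical(S)
  cd <- context$dmd
  for (s in which(on_dmd)) {
    nm <- stages$dmd[s]
    rr_rel[s] <- cd$rr_relapse[[nm]]
    adh_app[s] <- cd$adherence_applicable[[nm]]
    drug[s] <- cd$drug[[nm]]
    admin_sub[s] <- cd$admin2[[nm]]
    admin_extra[s] <- cd$admin1[[nm]] - cd$admin2[[nm]]
    mon_annual[s] <- cd$mon_ann[[nm]]
    mon_pre[s] <- cd$mon_pre[[nm]]
    mon_post[s] <- cd$mon_post[[nm]]
    n_rx <- cd$presc[[nm]]
    if (n_rx > 0) {
      fee_sub[s] <- n_rx * ec$dispensing_fee_subsequent
      fee_extra[s] <- ec$dispensing_fee_first +
        (n_rx - 1) * ec$dispensing_fee_subsequent - fee_sub[s]
    }
    aedu[s] <- cd$aedu[[nm]]
  }

  # one weight matrix over the flattened (state-major) S*H space, so that a
  # single T x (S*H) by (S*H) x k product yields every per-cycle series;
  # flattened index (s, h) -> (h - 1) * S + s, matching the trace layout
  ones_h <- as.numeric(alive)
  ones_s <- rep(1, S)
  # relapse weights per adherence class; the nonadherence multipliers apply
  # only on DMD stages where adherence is applicable (infusions are taken as
  # fully adherent even for a nonadherent-class patient who switched to one)
  w_total_ad <- outer(rr_rel, rate * ones_h)
  mult_total <- ifelse(adh_app, se$nonadherent_relapse_multiplier, 1)
  sf_mult <- ifelse(adh_app, se$nonadherent_severe_multiplier, 1)
  w_total_na <- outer(rr_rel * mult_total, rate * ones_h)
  w_severe_ad <- w_total_ad * pmin(outer(ones_s, sf), 1)
  w_severe_na <- w_total_na * pmin(outer(sf_mult, sf), 1)

  W <- cbind(
    alive = as.numeric(outer(ones_s, ones_h)),
    util = as.numeric(outer(ones_s, util * ones_h)),
    rel_ad = as.numeric(w_total_ad),
    sev_ad = as.numeric(w_severe_ad),
    rel_na = as.numeric(w_total_na),
    sev_na = as.numeric(w_severe_na),
    aedu = as.numeric(outer(aedu, ones_h)),
    drug = as.numeric(outer(drug, ones_h)),
    admin = as.numeric(outer(admin_sub, ones_h)),
    mon = as.numeric(outer(mon_annual, ones_h)),
    fee = as.numeric(outer(fee_sub, ones_h)),
    hc = as.numeric(outer(ones_s, cs$hc * ones_h)),
    comm = as.numeric(outer(ones_s, cs$comm * ones_h)),
    eq = as.numeric(outer(ones_s, cs$eq * ones_h)),
    inf = as.numeric(outer(ones_s, cs$inf * ones_h)),
    pf = as.numeric(outer(ones_s, cs$pf * ones_h)),
    ph = as.numeric(outer(ones_s, cs$ph * ones_h))
  )
  SM <- occ %*% W                              # T x k series matrix

  # event-based streams
  entr <- trace$entrants                      # T x S
  stop_mass <- trace$vol_disc + trace$forced  # treatment-stopping mass
  EV <- cbind(admin_x = admin_extra, mon_pre = mon_pre, fee_x = fee_extra)
  ES <- entr %*% EV
  s_admin <- SM[, "admin"] + ES[, "admin_x"]
  s_mon <- SM[, "mon"] + ES[, "mon_pre"] + as.numeric(stop_mass %*% mon_post)
  s_fee <- SM[, "fee"] + ES[, "fee_x"]
  s_hc <- SM[, "hc"]
  s_ae <- ae_costs(s_hc, ec$ae_cost_fraction)

  # decision epochs: initiation (cycle 0) + voluntary first-DMD stops
  first_stage <- which(stages$kind %in% c("ON_FIRST_DMD", "BSC_INITIAL"))
  s_dec <- rowSums(trace$vol_disc[, which(stages$kind == "ON_FIRST_DMD"),
                                  drop = FALSE])
  s_dec[1L] <- s_dec[1L] + sum(entr[1L, first_stage])
  s_sdm <- s_dec * strategy$sdm_cost_per_decision

  d_eff <- context$d_eff
  d_cost <- context$d_cost
  hw <- if (isTRUE(se$half_cycle_correction) && T_ >= 2L) {
    c(0.5, rep(1, T_ - 2L), 0.5)
  } else rep(1, T_)
  wde <- hw * d_eff
  wdc <- hw * d_cost

  eff <- function(x) c(discounted = sum(x * wde), undiscounted = sum(x * hw))
  cst <- function(x) c(discounted = sum(x * wdc), undiscounted = sum(x * hw))

  # cost components shared by both classes (all but relapse costs)
  CM <- cbind(
    drug = SM[, "drug"], administration = s_admin, monitoring = s_mon,
    dispensing = s_fee, adverse_events = s_ae,
    health_state_healthcare = s_hc, community = SM[, "comm"],
    equipment = SM[, "eq"], informal_care = SM[, "inf"],
    productivity_friction = SM[, "pf"],
    productivity_human_capital = SM[, "ph"]
  )
  shared_disc <- as.numeric(crossprod(CM, wdc))
  shared_undisc <- as.numeric(crossprod(CM, hw))
  names(shared_disc) <- names(shared_undisc) <- colnames(CM)

  build <- function(cls) {
    sfx <- if (cls == "adherent") "_ad" else "_na"
    s_rel <- SM[, paste0("rel", sfx)]
    s_sev <- SM[, paste0("sev", sfx)]
    s_mild <- s_rel - s_sev
    s_qaly <- SM[, "util"] - ec$relapse_disutility_mild * s_mild -
      ec$relapse_disutility_severe * s_sev - SM[, "aedu"]
    s_relcost <- s_mild * ec$relapse_cost_mild +
      s_sev * ec$relapse_cost_severe
    out <- .empty_outcomes()
    out$qalys <- eff(s_qaly)
    out$life_years <- eff(SM[, "alive"])
    out$relapses <- eff(s_rel)
    out$severe_relapses <- eff(s_sev)
    out$decisions <- c(discounted = sum(s_dec * d_cost),
                       undiscounted = sum(s_dec))
    out$cost_disc[names(shared_disc)] <- shared_disc
    out$cost_undisc[names(shared_undisc)] <- shared_undisc
    rc <- cst(s_relcost)
    out$cost_disc[["relapse"]] <- rc[["discounted"]]
    out$cost_undisc[["relapse"]] <- rc[["undiscounted"]]
    out$cost_disc[["sdm_delivery"]] <- sum(s_sdm * d_cost)
    out$cost_undisc[["sdm_delivery"]] <- sum(s_sdm)
    out
  }
  list(adherent = build("adherent"), nonadherent = build("nonadherent"))
}

#' Flatten an outcomes object to a tidy data frame
#' @param o An `ms_outcomes`.
#' @return Data frame with one row per quantity.
#' @export
outcomes_to_df <- function(o) {
  eff <- data.frame(
    quantity = c("qalys", "life_years", "relapses", "severe_relapses"),
    discounted = c(o$qalys[["discounted"]], o$life_years[["discounted"]],
                   o$relapses[["discounted"]],
                   o$severe_relapses[["discounted"]]),
    undiscounted = c(o$qalys[["undiscounted"]], o$life_years[["undiscounted"]],
                     o$relapses[["undiscounted"]],
                     o$severe_relapses[["undiscounted"]])
  )
  cdf <- outcomes_costs(o)
  tdf <- outcomes_totals(o)
  costs <- data.frame(quantity = paste0("cost_", cdf$category),
                      discounted = cdf$discounted,
                      undiscounted = cdf$undiscounted)
  totals <- data.frame(quantity = paste0("total_", tdf$perspective),
                       discounted = tdf$discounted,
                       undiscounted = tdf$undiscounted)
  rbind(eff, costs, totals)
}
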