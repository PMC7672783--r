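# The packaged synthetic reference parameter set.
#
# The strategy profiles (initiation mix, real-world first-year
# discontinuation rates, adherent proportions) and the behavioural constants
# are the published usual-care and shared decision making profiles. All other
# inputs -- natural history, relative risks, utilities, unit costs and the
# life table -- live in unpublished supplementary tables of the source model
# and are SYNTHETIC stand-ins here: values chosen once to be realistic for
# Dutch RRMS health-economic modelling, labelled as such, and not calibrated
# to reproduce any published result.

.ref_life_table <- function() {
  # Gompertz-Makeham, tuned to Dutch-like life expectancy (~84.7 female,
  # ~81.3 male at birth)
  ages <- 0:99
  q_f <- pmin(1, 1.5e-4 + 1.1e-5 * exp(0.105 * ages))
  q_m <- pmin(1, 2.5e-4 + 1.6e-5 * exp(0.105 * ages))
  rbind(
    data.frame(age = ages, sex = "male", annual_death_prob = q_m),
    data.frame(age = ages, sex = "female", annual_death_prob = q_f)
  )
}

.ref_natural_history <- function() {
  rt <- matrix(0, 10, 11,
               dimnames = list(paste0("RRMS_EDSS", 0:9),
                               c(paste0("RRMS_EDSS", 0:9), "SPMS_CONVERT")))
  for (i in 1:10) {
    e <- i - 1
    improve <- if (e > 0) 0.06 else 0
    worsen <- if (e < 9) 0.11 + 0.008 * e else 0
    convert <- 0.015 + 0.009 * e
    if (e > 0) rt[i, i - 1] <- improve
    if (e < 9) rt[i, i + 1] <- worsen
    rt[i, 11] <- convert
    rt[i, i] <- 1 - improve - worsen - convert
  }
  st <- matrix(0, 9, 9, dimnames = list(paste0("SPMS_EDSS", 1:9),
                                        paste0("SPMS_EDSS", 1:9)))
  for (i in 1:9) {
    worsen <- if (i < 9) 0.16 + 0.008 * i else 0
    if (i < 9) st[i, i + 1] <- worsen
    st[i, i] <- 1 - worsen
  }
  relapse <- rbind(
    data.frame(course = "RRMS", edss = 0:9,
               relapse_rate = 0.42 - 0.03 * (0:9), severe_fraction = 0.20),
    data.frame(course = "SPMS", edss = 1:9,
               relapse_rate = 0.10, severe_fraction = 0.15)
  )
  list(
    rrms_transitions = rt,
    spms_transitions = st,
    relapse_rates = relapse,
    mortality_multiplier = c(1.0, 1.2, 1.3, 1.5, 1.7, 2.0, 2.4, 3.0, 3.9, 5.0),
    life_table = .ref_life_table()
  )
}

# Published strategy profiles: initiation shares (percent), real-world
# first-year discontinuation rates (percent) and adherent proportions
# (percent) per treatment, for usual care (CAU) and shared decision making
# (SDM).
.table2 <- function() {
  data.frame(
    treatment = c("best_supportive_care", "alemtuzumab", "dimethyl_fumarate",
                  "fingolimod", "glatiramer_20_generic", "glatiramer_20_brand",
                  "glatiramer_40_brand", "interferon_b1a",
                  "interferon_b1a_22", "interferon_b1a_44", "interferon_b1b",
                  "natalizumab", "ocrelizumab", "peginterferon_b1a",
                  "teriflunomide"),
    initiation_cau = c(25.0, 0.2, 33.6, 0.0, 0.2, 10.6, 0.2, 1.0, 0.5, 0.5,
                       1.0, 4.0, 0.8, 1.0, 21.4),
    initiation_sdm = c(20.0, 0.3, 41.3, 0.0, 0.1, 3.5, 0.1, 0.3, 0.2, 0.2,
                       0.3, 6.0, 1.2, 0.3, 26.3),
    discontinuation_cau = c(NA, 10.4, 21.4, 10.6, 26.7, 26.7, 21.5, 26.8,
                            27.1, 30.1, 25.9, 13.0, 13.1, 26.4, 20.8),
    discontinuation_sdm = c(NA, 5.2, 10.7, 5.3, 13.4, 13.4, 10.8, 13.4, 13.6,
                            15.1, 13.0, 6.5, 6.6, 13.2, 10.4),
    adherent_cau = c(100.0, 100.0, 58.9, 58.9, 58.9, 58.9, 58.9, 58.9, 58.9,
                     58.9, 58.9, 100.0, 100.0, 58.9, 58.9),
    adherent_sdm = c(100.0, 100.0, 63.9, 63.9, 63.9, 63.9, 63.9, 63.9, 63.9,
                     63.9, 63.9, 100.0, 100.0, 63.9, 63.9),
    stringsAsFactors = FALSE
  )
}

.ref_dmds <- function() {
  t2 <- .table2()
  t2 <- t2[t2$treatment != "best_supportive_care", ]
  second <- c("natalizumab", "fingolimod", "alemtuzumab", "ocrelizumab")
  infused <- c("natalizumab", "alemtuzumab", "ocrelizumab")
  d <- data.frame(
    name = t2$treatment,
    line = ifelse(t2$treatment %in% second, "second", "first"),
    route = ifelse(t2$treatment %in% infused, "infusion",
                   "self_administered"),
    stringsAsFactors = FALSE
  )
  # SYNTHETIC efficacy and cost stand-ins (supplementary values unpublished)
  rrp <- c(alemtuzumab = 0.58, dimethyl_fumarate = 0.78, fingolimod = 0.72,
           glatiramer_20_generic = 0.85, glatiramer_20_brand = 0.85,
           glatiramer_40_brand = 0.85, interferon_b1a = 0.84,
           interferon_b1a_22 = 0.86, interferon_b1a_44 = 0.83,
           interferon_b1b = 0.84, natalizumab = 0.62, ocrelizumab = 0.60,
           peginterferon_b1a = 0.84, teriflunomide = 0.80)
  rrr <- c(alemtuzumab = 0.31, dimethyl_fumarate = 0.56, fingolimod = 0.46,
           glatiramer_20_generic = 0.72, glatiramer_20_brand = 0.72,
           glatiramer_40_brand = 0.70, interferon_b1a = 0.74,
           interferon_b1a_22 = 0.73, interferon_b1a_44 = 0.70,
           interferon_b1b = 0.72, natalizumab = 0.33, ocrelizumab = 0.35,
           peginterferon_b1a = 0.71, teriflunomide = 0.70)
  cost <- c(alemtuzumab = 21000, dimethyl_fumarate = 13000,
            fingolimod = 19000, glatiramer_20_generic = 5200,
            glatiramer_20_brand = 7800, glatiramer_40_brand = 8200,
            interferon_b1a = 10800, interferon_b1a_22 = 10200,
            interferon_b1a_44 = 11500, interferon_b1b = 9800,
            natalizumab = 17500, ocrelizumab = 23000,
            peginterferon_b1a = 11000, teriflunomide = 12000)
  admin1 <- c(alemtuzumab = 6500, natalizumab = 2600, ocrelizumab = 2200)
  admin2 <- c(alemtuzumab = 3200, natalizumab = 2600, ocrelizumab = 2200)
  mon_pre <- c(alemtuzumab = 900, dimethyl_fumarate = 350, fingolimod = 800,
               glatiramer_20_generic = 200, glatiramer_20_brand = 200,
               glatiramer_40_brand = 200, interferon_b1a = 300,
               interferon_b1a_22 = 300, interferon_b1a_44 = 300,
               interferon_b1b = 300, natalizumab = 600, ocrelizumab = 500,
               peginterferon_b1a = 300, teriflunomide = 400)
  mon_ann <- c(alemtuzumab = 700, dimethyl_fumarate = 250, fingolimod = 400,
               glatiramer_20_generic = 150, glatiramer_20_brand = 150,
               glatiramer_40_brand = 150, interferon_b1a = 220,
               interferon_b1a_22 = 220, interferon_b1a_44 = 220,
               interferon_b1b = 220, natalizumab = 450, ocrelizumab = 400,
               peginterferon_b1a = 220, teriflunomide = 280)
  aedu <- c(alemtuzumab = 0.012, dimethyl_fumarate = 0.006,
            fingolimod = 0.008, glatiramer_20_generic = 0.004,
            glatiramer_20_brand = 0.004, glatiramer_40_brand = 0.004,
            interferon_b1a = 0.008, interferon_b1a_22 = 0.008,
            interferon_b1a_44 = 0.008, interferon_b1b = 0.008,
            natalizumab = 0.010, ocrelizumab = 0.008,
            peginterferon_b1a = 0.008, teriflunomide = 0.005)
  d$rr_progression <- unname(rrp[d$name])
  d$rr_relapse <- unname(rrr[d$name])
  d$rr_progression_low <- pmax(0.3, d$rr_progression * 0.8)
  d$rr_progression_high <- pmin(1.1, d$rr_progression * 1.25)
  d$annual_drug_cost <- unname(cost[d$name])
  d$admin_cost_first_year <- ifelse(d$route == "infusion",
                                    unname(admin1[d$name]), 0)
  d$admin_cost_subsequent <- ifelse(d$route == "infusion",
                                    unname(admin2[d$name]), 0)
  d$monitoring_pretreatment <- unname(mon_pre[d$name])
  d$monitoring_annual <- unname(mon_ann[d$name])
  d$monitoring_post_discontinuation <- ifelse(d$route == "infusion", 200, 120)
  d$prescriptions_per_year <- ifelse(d$route == "infusion", 0L, 12L)
  d$cau_discontinuation <- t2$discontinuation_cau / 100
  d$trial_discontinuation <- round(pmin(1, 0.6 * d$cau_discontinuation), 4)
  d$adherence_applicable <- d$route != "infusion"
  d$ae_disutility <- unname(aedu[d$name])
  d
}

.ref_economics <- function() {
  # SYNTHETIC utilities: ~0.87 at EDSS 0 declining to ~0 at EDSS 9; SPMS
  # slightly below RRMS at equal EDSS
  u_rrms <- c(0.870, 0.820, 0.760, 0.690, 0.610, 0.520, 0.420, 0.300,
              0.170, 0.030)
  utilities <- rbind(
    data.frame(course = "RRMS", edss = 0:9, utility = u_rrms),
    data.frame(course = "SPMS", edss = 1:9, utility = u_rrms[-1] - 0.045)
  )
  # SYNTHETIC annual state costs (EUR), EDSS-increasing health care costs;
  # SPMS health care costs 10% above RRMS at equal EDSS
  hc <- c(1800, 2200, 2800, 3600, 4800, 6500, 9000, 13000, 19000, 27000)
  comm <- c(0, 100, 250, 500, 900, 1500, 2600, 4200, 6500, 9000)
  eq <- c(50, 100, 200, 350, 600, 1000, 1700, 2600, 3800, 5200)
  inf <- c(300, 600, 1100, 1900, 3200, 5200, 8200, 12500, 18000, 24000)
  pf <- c(2600, 2600, 2400, 2200, 1900, 1500, 1000, 500, 150, 0)
  ph <- c(6000, 7500, 9500, 12000, 15000, 18000, 21000, 23000, 24000, 24500)
  state_costs <- rbind(
    data.frame(course = "RRMS", edss = 0:9, healthcare = hc,
               community_services = comm, equipment_aids = eq,
               informal_care = inf, productivity_friction = pf,
               productivity_human_capital = ph),
    data.frame(course = "SPMS", edss = 1:9, healthcare = hc[-1] * 1.1,
               community_services = comm[-1], equipment_aids = eq[-1],
               informal_care = inf[-1], productivity_friction = pf[-1],
               productivity_human_capital = ph[-1])
  )
  list(
    utilities = utilities,
    state_costs = state_costs,
    relapse_cost_mild = 600,
    relapse_cost_severe = 5000,
    relapse_disutility_mild = 0.04,
    relapse_disutility_severe = 0.11,
    ae_cost_fraction = 0.012,
    dispensing_fee_first = 14,
    dispensing_fee_subsequent = 7,
    discount_effects = 0.015,
    discount_costs = 0.040
  )
}

.ref_settings <- function() {
  list(
    start_age = 37,
    proportion_male = 0.29,
    max_age = 100,
    cycle_length = 1,
    perspective = "societal_friction",
    nonadherent_relapse_multiplier = 1.42,
    nonadherent_severe_multiplier = 1.075,
    edss_stop_level = 6,
    half_cycle_correction = FALSE,
    rr_applies_spms = TRUE,
    entry_distribution = setNames(
      c(0.30, 0.25, 0.15, 0.10, 0.10, 0.05, 0.05, 0, 0, 0),
      paste0("edss", 0:9)
    )
  )
}

#' The published usual-care and shared decision making strategy profiles
#'
#' Returns the printed per-treatment profile table (initiation shares,
#' real-world first-year discontinuation rates and adherent proportions, all
#' in percent) together with ready-to-use [strategy_profile()] objects. The
#' printed shared decision making initiation column sums to 100.1 because of
#' one-decimal rounding; the strategy objects carry the renormalised
#' probability vectors, while the `table` element keeps the figures exactly
#' as printed.
#'
#' @return List with elements `CAU`, `SDM` (strategy profiles) and `table`
#'   (the printed percentages).
#' @export
table2_fixture <- function() {
  t2 <- .table2()
  init_cau <- setNames(t2$initiation_cau, t2$treatment)
  init_sdm <- setNames(t2$initiation_sdm, t2$treatment)
  adh_cau <- setNames(t2$adherent_cau, t2$treatment)
  adh_sdm <- setNames(t2$adherent_sdm, t2$treatment)
  dmds <- setdiff(t2$treatment, "best_supportive_care")
  cau <- strategy_profile(
    label = "CAU",
    initiation = init_cau / sum(init_cau),
    discontinuation_multiplier = 1,
    adherent_proportion = adh_cau[dmds] / 100,
    sdm_cost_per_decision = 0
  )
  sdm <- strategy_profile(
    label = "SDM",
    initiation = init_sdm / sum(init_sdm),
    discontinuation_multiplier = 0.5,
    adherent_proportion = adh_sdm[dmds] / 100,
    sdm_cost_per_decision = 100
  )
  list(CAU = cau, SDM = sdm, table = t2)
}

#' The packaged synthetic reference parameter set
#'
#' A complete, validated parameter set combining the published strategy
#' profiles ([table2_fixture()]), discounting, demographic and behavioural
#' constants with synthetic stand-ins for the unpublished natural-history,
#' efficacy, utility and unit-cost tables. Intended as the default input of
#' the analysis scripts and as a realistic test bed; it is not a
#' reconstruction of the source model's supplementary data.
#'
#' @return An `ms_parameter_set`.
#' @export
reference_parameter_set <- function() {
  fx <- table2_fixture()
  ps <- new_parameter_set(
    natural_history = .ref_natural_history(),
    dmds = .ref_dmds(),
    economics = .ref_economics(),
    strategies = list(CAU = fx$CAU, SDM = fx$SDM),
    settings = .ref_settings()
  )
  ps
}
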