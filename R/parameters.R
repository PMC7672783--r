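#' @useDynLib sdmcea, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbeta rgamma rlnorm rpois runif rbinom setNames
#' @importFrom utils read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# Constructors
# ---------------------------------------------------------------------------

#' Assemble a model parameter set
#'
#' Bundles every input of the cost-effectiveness model: the natural history of
#' EDSS progression and SPMS conversion, disease-modifying drug (DMD)
#' profiles, utilities and costs, the background life table, the two
#' decision-making strategy profiles, and run settings. The object is a plain
#' list with class `ms_parameter_set`; use [validate_parameter_set()] to check
#' all invariants.
#'
#' @param natural_history List with elements `rrms_transitions` (10 x 11
#'   matrix: annual probabilities from each RRMS EDSS state to RRMS EDSS 0--9
#'   plus an `spms_convert` column), `spms_transitions` (9 x 9 matrix,
#'   worsening-or-stay only), `relapse_rates` (data frame `course`, `edss`,
#'   `relapse_rate`, `severe_fraction`), `mortality_multiplier` (length-10
#'   vector indexed by EDSS 0--9), and `life_table` (data frame `age`, `sex`,
#'   `annual_death_prob`).
#' @param dmds Data frame of DMD profiles (one row per drug).
#' @param economics List of utility/cost inputs (see [default_parameter_set()]
#'   for the full element list).
#' @param strategies Named list of [strategy_profile()] objects; must contain
#'   at least `CAU` and `SDM`.
#' @param settings List of run settings (start age, proportion male, entry
#'   distribution over RRMS EDSS, horizon, behavioural multipliers, flags).
#' @return An object of class `ms_parameter_set`.
#' @export
new_parameter_set <- function(natural_history, dmds, economics, strategies,
                              settings) {
  ps <- list(
    natural_history = natural_history,
    dmds = dmds,
    economics = economics,
    strategies = strategies,
    settings = settings
  )
  class(ps) <- "ms_parameter_set"
  ps
}

#' Define a decision-making strategy profile
#'
#' A strategy (usual care or shared decision making) is described by the mix
#' of initial treatment choices, a relative factor on the real-world
#' discontinuation rates, the proportion of optimally adherent patients per
#' DMD, and the cost of delivering shared decision making at each treatment
#' decision.
#'
#' @param label Strategy label, e.g. `"CAU"` or `"SDM"`.
#' @param initiation Named probability vector over
#'   `"best_supportive_care"` and DMD names; must sum to 1.
#' @param discontinuation_multiplier Relative factor applied to each DMD's
#'   usual-care annual discontinuation probability (1 for usual care, 0.5 in
#'   the shared decision making base case).
#' @param adherent_proportion Named vector of per-DMD probabilities of optimal
#'   adherence (>80\% of days covered). Infused DMDs are always treated as
#'   fully adherent regardless of this value.
#' @param sdm_cost_per_decision EUR charged at every treatment decision
#'   (initiation and each voluntary first-DMD switch); 0 for usual care.
#' @param switch_to_dmd_share Probability that a patient voluntarily stopping
#'   the first DMD switches to another DMD rather than best supportive care.
#' @param side_effect_share Of switchers from a first-line DMD, the proportion
#'   stopping for side effects (who pick another first-line DMD); the
#'   remainder stop for perceived lack of efficacy and pick a second-line DMD.
#' @return An object of class `ms_strategy`.
#' @export
strategy_profile <- function(label, initiation, discontinuation_multiplier = 1,
                             adherent_proportion,
                             sdm_cost_per_decision = 0,
                             switch_to_dmd_share = 0.95,
                             side_effect_share = 0.79) {
  stopifnot(is.numeric(initiation), !is.null(names(initiation)))
  out <- list(
    label = label,
    initiation = initiation,
    discontinuation_multiplier = discontinuation_multiplier,
    adherent_proportion = adherent_proportion,
    sdm_cost_per_decision = sdm_cost_per_decision,
    switch_to_dmd_share = switch_to_dmd_share,
    side_effect_share = side_effect_share
  )
  class(out) <- "ms_strategy"
  out
}

# ---------------------------------------------------------------------------
# Small input-preparation calculations
# ---------------------------------------------------------------------------

#' Linear interpolation of EDSS health-state cost anchors
#'
#' Annual health-state costs are often published for a few EDSS anchor levels
#' only; the model needs a cost for every integer EDSS level. Costs between
#' adjacent anchors are interpolated linearly; anchor levels are returned
#' exactly; levels outside the outermost anchors are held constant at the
#' nearest anchor (no extrapolation).
#'
#' @param anchors Named numeric vector: names are EDSS levels, values are
#'   non-negative costs. At least two anchors required.
#' @param levels Integer EDSS levels to fill in (default 0--9).
#' @return Named numeric vector of costs for `levels`.
#' @export
#' @examples
#' interpolate_state_costs(c("0" = 1000, "2" = 3000))
interpolate_state_costs <- function(anchors, levels = 0:9) {
  if (length(anchors) < 2L) stop("at least 2 EDSS cost anchors are required")
  x <- as.numeric(names(anchors))
  if (anyNA(x)) stop("anchor names must be numeric EDSS levels")
  if (any(anchors < 0)) stop("anchor costs must be non-negative")
  o <- order(x)
  x <- x[o]
  y <- as.numeric(anchors)[o]
  out <- stats::approx(x, y, xout = levels, method = "linear", rule = 2)$y
  names(out) <- as.character(levels)
  out
}

#' Scale a real-world discontinuation rate by trial discontinuation rates
#'
#' Real-world first-year discontinuation data are missing for some DMDs; their
#' rates are derived from a reference drug's real-world rate, scaled
#' proportionately by the ratio of the drugs' trial discontinuation rates, and
#' capped at 1.
#'
#' @param reference_real_world Real-world annual discontinuation probability
#'   of the reference DMD, in (0, 1].
#' @param trial_reference Trial discontinuation probability of the reference
#'   DMD, in (0, 1].
#' @param trial_target Trial discontinuation probability of the target DMD,
#'   in (0, 1].
#' @return Annual discontinuation probability for the target DMD.
#' @export
#' @examples
#' scale_discontinuation_from_trials(0.13, 0.10, 0.05)
scale_discontinuation_from_trials <- function(reference_real_world,
                                              trial_reference, trial_target) {
  vals <- c(reference_real_world, trial_reference, trial_target)
  if (any(vals <= 0) || any(vals > 1)) {
    stop("all rates must lie in (0, 1]")
  }
  min(1, reference_real_world * trial_target / trial_reference)
}

#' Adverse-event costs as a proportion of health care costs
#'
#' Adverse-event costs are not separately tariffed; they are computed as a
#' fixed proportion of the health-state health care costs.
#'
#' @param healthcare_cost Non-negative health care cost (EUR).
#' @param fraction Proportion in \[0, 1\].
#' @return EUR of adverse-event costs.
#' @export
ae_costs <- function(healthcare_cost, fraction) {
  if (any(healthcare_cost < 0) || any(fraction < 0) || any(fraction > 1)) {
    stop("healthcare_cost must be >= 0 and fraction in [0, 1]")
  }
  healthcare_cost * fraction
}

# ---------------------------------------------------------------------------
# Validation
# ---------------------------------------------------------------------------

.violation <- function(table, row, rule, detail = "") {
  data.frame(table = table, row = as.character(row), rule = rule,
             detail = detail, stringsAsFactors = FALSE)
}

#' Validate a parameter set against all model invariants
#'
#' Checks row-stochasticity of the transition tables, the worsening-only
#' structure of SPMS, probability and sign ranges, EDSS-monotonicity of
#' utilities and health care costs, strategy initiation mass, cross-references
#' between strategies and the DMD table, and settings sanity. Violations are
#' returned as data, not raised as errors, so that deliberately perturbed
#' inputs can be inspected.
#'
#' @param params An `ms_parameter_set`.
#' @return Data frame with columns `table`, `row`, `rule`, `detail`; zero rows
#'   when every invariant holds.
#' @export
validate_parameter_set <- function(params) {
  v <- list()
  nh <- params$natural_history
  tol <- 1e-9

  # RRMS transitions: 10 x 11, rows sum to 1, probabilities in [0, 1]
  rt <- nh$rrms_transitions
  if (!is.matrix(rt) || nrow(rt) != 10L || ncol(rt) != 11L) {
    v[[length(v) + 1L]] <- .violation("transitions_rrms", NA, "shape",
                                      "expected 10 x 11 matrix")
  } else {
    for (i in seq_len(10L)) {
      if (any(rt[i, ] < 0) || any(rt[i, ] > 1)) {
        v[[length(v) + 1L]] <- .violation("transitions_rrms", i, "prob_range")
      }
      if (abs(sum(rt[i, ]) - 1) > tol) {
        v[[length(v) + 1L]] <- .violation(
          "transitions_rrms", i, "row_sum",
          sprintf("sums to %.12f", sum(rt[i, ]))
        )
      }
    }
  }

  # SPMS transitions: 9 x 9, worsening-or-stay only
  st <- nh$spms_transitions
  if (!is.matrix(st) || nrow(st) != 9L || ncol(st) != 9L) {
    v[[length(v) + 1L]] <- .violation("transitions_spms", NA, "shape",
                                      "expected 9 x 9 matrix")
  } else {
    for (i in seq_len(9L)) {
      if (any(st[i, ] < 0) || any(st[i, ] > 1)) {
        v[[length(v) + 1L]] <- .violation("transitions_spms", i, "prob_range")
      }
      if (abs(sum(st[i, ]) - 1) > tol) {
        v[[length(v) + 1L]] <- .violation(
          "transitions_spms", i, "row_sum",
          sprintf("sums to %.12f", sum(st[i, ]))
        )
      }
      if (i > 1L && any(st[i, seq_len(i - 1L)] > 0)) {
        v[[length(v) + 1L]] <- .violation("transitions_spms", i,
                                          "no_improvement")
      }
    }
  }

  # relapse model
  rr <- nh$relapse_rates
  if (any(rr$relapse_rate < 0)) {
    v[[length(v) + 1L]] <- .violation("relapse_rates",
                                      which(rr$relapse_rate < 0)[1L],
                                      "rate_nonnegative")
  }
  if (any(rr$severe_fraction < 0 | rr$severe_fraction > 1)) {
    v[[length(v) + 1L]] <- .violation(
      "relapse_rates", which(rr$severe_fraction < 0 | rr$severe_fraction > 1)[1L],
      "severe_fraction_range"
    )
  }

  # mortality multipliers
  mm <- nh$mortality_multiplier
  if (length(mm) != 10L) {
    v[[length(v) + 1L]] <- .violation("mortality_multipliers", NA, "shape",
                                      "expected one multiplier per EDSS 0-9")
  } else if (any(mm < 1)) {
    v[[length(v) + 1L]] <- .violation("mortality_multipliers",
                                      which(mm < 1)[1L], "multiplier_ge_1")
  }

  # life table
  lt <- nh$life_table
  if (any(lt$annual_death_prob < 0 | lt$annual_death_prob > 1)) {
    v[[length(v) + 1L]] <- .violation("life_table", NA, "prob_range")
  }
  need_age <- seq(floor(params$settings$start_age), params$settings$max_age - 1L)
  for (sx in c("male", "female")) {
    have <- lt$age[lt$sex == sx]
    if (!all(need_age %in% have)) {
      v[[length(v) + 1L]] <- .violation(
        "life_table", sx, "age_coverage",
        "life table must cover start_age .. max_age - 1 for both sexes"
      )
    }
  }

  # DMD profiles
  d <- params$dmds
  for (i in seq_len(nrow(d))) {
    if (d$rr_progression[i] <= 0 || d$rr_progression[i] > 2 ||
        d$rr_relapse[i] <= 0 || d$rr_relapse[i] > 2) {
      v[[length(v) + 1L]] <- .violation("dmd_profiles", d$name[i], "rr_range")
    }
    costs <- c(d$annual_drug_cost[i], d$admin_cost_first_year[i],
               d$admin_cost_subsequent[i], d$monitoring_pretreatment[i],
               d$monitoring_annual[i], d$monitoring_post_discontinuation[i])
    if (any(costs < 0)) {
      v[[length(v) + 1L]] <- .violation("dmd_profiles", d$name[i],
                                        "cost_nonnegative")
    }
    if (d$cau_discontinuation[i] < 0 || d$cau_discontinuation[i] > 1) {
      v[[length(v) + 1L]] <- .violation("dmd_profiles", d$name[i],
                                        "discontinuation_range")
    }
    if (d$route[i] == "infusion" && isTRUE(d$adherence_applicable[i])) {
      v[[length(v) + 1L]] <- .violation(
        "dmd_profiles", d$name[i], "infusion_optimal_adherence",
        "infused DMDs are assumed fully adherent"
      )
    }
  }

  # utilities: in [-1, 1], non-increasing in EDSS within each course
  u <- params$economics$utilities
  if (any(u$utility < -1 | u$utility > 1)) {
    v[[length(v) + 1L]] <- .violation("utilities", NA, "utility_range")
  }
  for (crs in c("RRMS", "SPMS")) {
    uu <- u[u$course == crs, ]
    uu <- uu[order(uu$edss), ]
    if (any(diff(uu$utility) > tol)) {
      bad <- which(diff(uu$utility) > tol)[1L]
      v[[length(v) + 1L]] <- .violation(
        "utilities", paste0(crs, "_EDSS", uu$edss[bad + 1L]),
        "monotone_nonincreasing"
      )
    }
  }

  # state costs: non-negative, healthcare non-decreasing in EDSS
  sc <- params$economics$state_costs
  cost_cols <- setdiff(names(sc), c("course", "edss"))
  if (any(as.matrix(sc[cost_cols]) < 0)) {
    v[[length(v) + 1L]] <- .violation("state_costs", NA, "cost_nonnegative")
  }
  for (crs in c("RRMS", "SPMS")) {
    cc <- sc[sc$course == crs, ]
    cc <- cc[order(cc$edss), ]
    if (any(diff(cc$healthcare) < -tol)) {
      bad <- which(diff(cc$healthcare) < -tol)[1L]
      v[[length(v) + 1L]] <- .violation(
        "state_costs", paste0(crs, "_EDSS", cc$edss[bad + 1L]),
        "healthcare_monotone_nondecreasing"
      )
    }
  }

  # economics scalars
  ec <- params$economics
  if (ec$discount_effects < 0 || ec$discount_effects >= 1 ||
      ec$discount_costs < 0 || ec$discount_costs >= 1) {
    v[[length(v) + 1L]] <- .violation("economics", NA, "discount_range")
  }
  if (ec$ae_cost_fraction < 0 || ec$ae_cost_fraction > 1) {
    v[[length(v) + 1L]] <- .violation("economics", NA, "ae_fraction_range")
  }

  # strategies
  for (nm in names(params$strategies)) {
    s <- params$strategies[[nm]]
    if (abs(sum(s$initiation) - 1) > tol) {
      v[[length(v) + 1L]] <- .violation(
        paste0("strategy_", tolower(nm)), NA, "initiation_sum",
        sprintf("sums to %.12f", sum(s$initiation))
      )
    }
    if (any(s$initiation < 0 | s$initiation > 1)) {
      v[[length(v) + 1L]] <- .violation(paste0("strategy_", tolower(nm)), NA,
                                        "initiation_range")
    }
    ref <- setdiff(names(s$initiation), "best_supportive_care")
    missing_dmd <- setdiff(ref, d$name)
    if (length(missing_dmd)) {
      v[[length(v) + 1L]] <- .violation(
        paste0("strategy_", tolower(nm)), missing_dmd[1L], "unknown_dmd"
      )
    }
    if (any(s$adherent_proportion < 0 | s$adherent_proportion > 1)) {
      v[[length(v) + 1L]] <- .violation(paste0("strategy_", tolower(nm)), NA,
                                        "adherence_range")
    }
  }

  # settings
  se <- params$settings
  if (abs(sum(se$entry_distribution) - 1) > tol) {
    v[[length(v) + 1L]] <- .violation("settings", NA, "entry_sum")
  }
  if (!(se$start_age > 0 && se$start_age < se$max_age)) {
    v[[length(v) + 1L]] <- .violation("settings", NA, "age_order")
  }
  if (se$nonadherent_relapse_multiplier < 1 ||
      se$nonadherent_severe_multiplier < 1) {
    v[[length(v) + 1L]] <- .violation("settings", NA, "multiplier_ge_1")
  }

  if (length(v)) do.call(rbind, v) else .violation("", "", "")[0, ]
}

# ---------------------------------------------------------------------------
# File I/O
# ---------------------------------------------------------------------------

.ps_files <- c(
  transitions_rrms = "transitions_rrms.csv",
  transitions_spms = "transitions_spms.csv",
  relapse_rates = "relapse_rates.csv",
  mortality_multipliers = "mortality_multipliers.csv",
  life_table = "life_table.csv",
  dmd_profiles = "dmd_profiles.csv",
  utilities = "utilities.csv",
  state_costs = "state_costs.csv",
  strategy_cau = "strategy_cau.csv",
  strategy_sdm = "strategy_sdm.csv",
  economics = "economics.csv",
  settings = "settings.csv"
)

.num <- function(x) {
  # full-precision text representation that round-trips doubles exactly
  formatC(x, format = "g", digits = 17)
}

.strategy_to_df <- function(s) {
  rows <- list(
    data.frame(parameter = "label", item = "", value = s$label),
    data.frame(parameter = "initiation", item = names(s$initiation),
               value = .num(s$initiation)),
    data.frame(parameter = "adherent_proportion",
               item = names(s$adherent_proportion),
               value = .num(s$adherent_proportion)),
    data.frame(parameter = "discontinuation_multiplier", item = "",
               value = .num(s$discontinuation_multiplier)),
    data.frame(parameter = "sdm_cost_per_decision", item = "",
               value = .num(s$sdm_cost_per_decision)),
    data.frame(parameter = "switch_to_dmd_share", item = "",
               value = .num(s$switch_to_dmd_share)),
    data.frame(parameter = "side_effect_share", item = "",
               value = .num(s$side_effect_share))
  )
  do.call(rbind, rows)
}

.strategy_from_df <- function(df) {
  get_scalar <- function(p) df$value[df$parameter == p][1L]
  get_vec <- function(p) {
    sel <- df$parameter == p
    setNames(as.numeric(df$value[sel]), df$item[sel])
  }
  strategy_profile(
    label = get_scalar("label"),
    initiation = get_vec("initiation"),
    discontinuation_multiplier = as.numeric(get_scalar("discontinuation_multiplier")),
    adherent_proportion = get_vec("adherent_proportion"),
    sdm_cost_per_decision = as.numeric(get_scalar("sdm_cost_per_decision")),
    switch_to_dmd_share = as.numeric(get_scalar("switch_to_dmd_share")),
    side_effect_share = as.numeric(get_scalar("side_effect_share"))
  )
}

#' Write a parameter set to a directory of delimited text files
#'
#' Writes one plain CSV per input table plus a YAML manifest binding file
#' names to their roles. Numeric values are written with 17 significant
#' digits so that a write/load round trip reproduces every double exactly.
#'
#' @param params An `ms_parameter_set`.
#' @param dir Target directory (created if absent).
#' @param extra_manifest Optional named list merged into the manifest (e.g.
#'   a generator seed).
#' @return `dir`, invisibly.
#' @export
write_parameter_set <- function(params, dir, extra_manifest = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, file) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], .num)
    write.csv(df, file.path(dir, file), row.names = FALSE, quote = FALSE)
  }
  nh <- params$natural_history

  rt <- as.data.frame(nh$rrms_transitions)
  names(rt) <- c(paste0("to_rrms_edss", 0:9), "spms_convert")
  rt <- cbind(data.frame(from_edss = 0:9), rt)
  w(rt, .ps_files["transitions_rrms"])

  st <- as.data.frame(nh$spms_transitions)
  names(st) <- paste0("to_spms_edss", 1:9)
  st <- cbind(data.frame(from_edss = 1:9), st)
  w(st, .ps_files["transitions_spms"])

  w(nh$relapse_rates, .ps_files["relapse_rates"])
  w(data.frame(edss = 0:9, multiplier = nh$mortality_multiplier),
    .ps_files["mortality_multipliers"])
  w(nh$life_table, .ps_files["life_table"])
  w(params$dmds, .ps_files["dmd_profiles"])
  w(params$economics$utilities, .ps_files["utilities"])
  w(params$economics$state_costs, .ps_files["state_costs"])
  w(.strategy_to_df(params$strategies$CAU), .ps_files["strategy_cau"])
  w(.strategy_to_df(params$strategies$SDM), .ps_files["strategy_sdm"])

  ec <- params$economics
  ec_scalars <- c("relapse_cost_mild", "relapse_cost_severe",
                  "relapse_disutility_mild", "relapse_disutility_severe",
                  "ae_cost_fraction", "dispensing_fee_first",
                  "dispensing_fee_subsequent", "discount_effects",
                  "discount_costs")
  w(data.frame(key = ec_scalars,
               value = vapply(ec_scalars, function(k) ec[[k]], numeric(1))),
    .ps_files["economics"])

  se <- params$settings
  se_rows <- data.frame(
    key = c("start_age", "proportion_male", "max_age", "cycle_length",
            "perspective", "nonadherent_relapse_multiplier",
            "nonadherent_severe_multiplier", "edss_stop_level",
            "half_cycle_correction", "rr_applies_spms",
            paste0("entry_edss", 0:9)),
    value = c(.num(se$start_age), .num(se$proportion_male), .num(se$max_age),
              .num(se$cycle_length), se$perspective,
              .num(se$nonadherent_relapse_multiplier),
              .num(se$nonadherent_severe_multiplier), .num(se$edss_stop_level),
              as.character(se$half_cycle_correction),
              as.character(se$rr_applies_spms),
              .num(se$entry_distribution))
  )
  write.csv(se_rows, file.path(dir, .ps_files["settings"]),
            row.names = FALSE, quote = FALSE)

  manifest <- c(list(format = "sdmcea-parameter-set",
                     version = 1L,
                     files = as.list(.ps_files)),
                extra_manifest)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Load a parameter set from a directory of delimited text files
#'
#' Reads the manifest, loads every table, rebuilds the `ms_parameter_set`,
#' and validates it. Missing files raise an error naming the missing role;
#' invariant violations raise a validation error naming table, row and rule.
#'
#' @param dir Directory containing `manifest.yaml` and the parameter tables.
#' @param validate Raise an error on invariant violations? Default `TRUE`.
#' @return A validated `ms_parameter_set`.
#' @export
load_parameter_set <- function(dir, validate = TRUE) {
  mf_path <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf_path)) stop("missing manifest.yaml in ", dir)
  manifest <- yaml::read_yaml(mf_path)
  files <- manifest$files
  for (role in names(.ps_files)) {
    f <- files[[role]]
    if (is.null(f) || !file.exists(file.path(dir, f))) {
      stop("parameter directory is missing file for role '", role, "'")
    }
  }
  rd <- function(role) read.csv(file.path(dir, files[[role]]),
                                stringsAsFactors = FALSE)

  rt_df <- rd("transitions_rrms")
  rt <- as.matrix(rt_df[, -1, drop = FALSE])
  dimnames(rt) <- list(paste0("RRMS_EDSS", 0:9),
                       c(paste0("RRMS_EDSS", 0:9), "SPMS_CONVERT"))

  st_df <- rd("transitions_spms")
  st <- as.matrix(st_df[, -1, drop = FALSE])
  dimnames(st) <- list(paste0("SPMS_EDSS", 1:9), paste0("SPMS_EDSS", 1:9))

  mm <- rd("mortality_multipliers")$multiplier

  se_df <- rd("settings")
  sv <- setNames(se_df$value, se_df$key)
  settings <- list(
    start_age = as.numeric(sv[["start_age"]]),
    proportion_male = as.numeric(sv[["proportion_male"]]),
    max_age = as.numeric(sv[["max_age"]]),
    cycle_length = as.numeric(sv[["cycle_length"]]),
    perspective = unname(sv[["perspective"]]),
    nonadherent_relapse_multiplier = as.numeric(sv[["nonadherent_relapse_multiplier"]]),
    nonadherent_severe_multiplier = as.numeric(sv[["nonadherent_severe_multiplier"]]),
    edss_stop_level = as.numeric(sv[["edss_stop_level"]]),
    half_cycle_correction = as.logical(sv[["half_cycle_correction"]]),
    rr_applies_spms = as.logical(sv[["rr_applies_spms"]]),
    entry_distribution = setNames(as.numeric(sv[paste0("entry_edss", 0:9)]),
                                  paste0("edss", 0:9))
  )

  ec_df <- rd("economics")
  ec <- c(list(utilities = rd("utilities"), state_costs = rd("state_costs")),
          as.list(setNames(as.numeric(ec_df$value), ec_df$key)))

  dmds <- rd("dmd_profiles")
  dmds$adherence_applicable <- as.logical(dmds$adherence_applicable)

  ps <- new_parameter_set(
    natural_history = list(
      rrms_transitions = rt,
      spms_transitions = st,
      relapse_rates = rd("relapse_rates"),
      mortality_multiplier = mm,
      life_table = rd("life_table")
    ),
    dmds = dmds,
    economics = ec,
    strategies = list(CAU = .strategy_from_df(rd("strategy_cau")),
                      SDM = .strategy_from_df(rd("strategy_sdm"))),
    settings = settings
  )
  if (validate) {
    rep <- validate_parameter_set(ps)
    if (nrow(rep)) {
      stop("parameter set failed validation: ",
           paste(sprintf("[%s/%s: %s]", rep$table, rep$row, rep$rule),
                 collapse = " "))
    }
  }
  ps
}
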