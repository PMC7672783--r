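# Cohort engine: expanded (treatment stage x adherence class x health state)
# state space, annual cycles over the lifetime horizon, discontinuation,
# switching and stopping rules.

.dmd_row <- function(params, name) {
  i <- match(name, params$dmds$name)
  if (is.na(i)) stop("unknown DMD '", name, "'")
  params$dmds[i, , drop = FALSE]
}

.line_set <- function(params, line) params$dmds$name[params$dmds$line == line]

#' Effective annual discontinuation probability under a strategy
#'
#' Below the EDSS stop level the usual-care real-world discontinuation rate is
#' scaled by the strategy's discontinuation multiplier (0.5 in the shared
#' decision making base case). Patients who progress beyond the stop level
#' (EDSS > 6) stop treatment with certainty and do not switch.
#'
#' @param dmd One-row DMD profile (or a DMD name with `params` supplied).
#' @param strategy An `ms_strategy`.
#' @param edss Current integer EDSS level.
#' @param settings Model settings (`edss_stop_level`).
#' @param params Optional parameter set used to resolve `dmd` by name.
#' @return Annual probability in \[0, 1\].
#' @export
effective_discontinuation <- function(dmd, strategy, edss, settings,
                                      params = NULL) {
  if (is.character(dmd)) dmd <- .dmd_row(params, dmd)
  if (edss > settings$edss_stop_level) return(1)
  p <- dmd$cau_discontinuation * strategy$discontinuation_multiplier
  if (p < 0 || p > 1) {
    stop("effective discontinuation probability ", p, " outside [0, 1]")
  }
  p
}

#' Distribution over next treatment stages after voluntary discontinuation
#'
#' Patients voluntarily stopping their first DMD switch to another DMD with
#' probability `switch_to_dmd_share` (5\% go to best supportive care). Of the
#' switchers from a first-line DMD, `side_effect_share` stop for side effects
#' and pick another first-line DMD; the rest stop for perceived lack of
#' efficacy and pick a second-line DMD. Switchers from a second-line DMD pick
#' another second-line DMD. Within each eligible set (current drug excluded)
#' the destination is proportional to the strategy's initiation shares,
#' renormalised; a zero-share eligible set falls back to a uniform split.
#' Patients stopping their second DMD always move to best supportive care.
#'
#' @param current List with `stage` (`"ON_FIRST_DMD"` or `"ON_SECOND_DMD"`)
#'   and `dmd` (drug name).
#' @param strategy An `ms_strategy`.
#' @param params An `ms_parameter_set`.
#' @return Named probability vector over `"best_supportive_care"` and DMD
#'   names; sums to 1.
#' @export
switch_distribution <- function(current, strategy, params) {
  if (current$stage == "ON_SECOND_DMD") {
    return(c(best_supportive_care = 1))
  }
  if (current$stage != "ON_FIRST_DMD") {
    stop("switch_distribution applies to on-treatment stages only")
  }
  i <- match(current$dmd, params$dmds$name)
  if (is.na(i)) stop("unknown DMD '", current$dmd, "'")
  d <- list(name = current$dmd, line = params$dmds$line[i])
  p_switch <- strategy$switch_to_dmd_share
  out <- c(best_supportive_care = 1 - p_switch)

  # sensitivity-analysis override of the switch destination rule
  if (!is.null(strategy$switch_override)) {
    set <- if (strategy$switch_override == "second_only_equal") {
      setdiff(.line_set(params, "second"), d$name)
    } else {
      setdiff(params$dmds$name, d$name)
    }
    if (!length(set)) stop("eligible switch set is empty")
    out <- c(out, setNames(rep(p_switch / length(set), length(set)), set))
    return(out / sum(out))
  }

  share_over <- function(set) {
    if (!length(set)) stop("eligible switch set is empty")
    sh <- strategy$initiation[set]
    sh[is.na(sh)] <- 0
    if (sum(sh) <= 0) sh <- rep(1, length(set))
    setNames(sh / sum(sh), set)
  }

  if (d$line == "first") {
    first_others <- setdiff(.line_set(params, "first"), d$name)
    second_all <- .line_set(params, "second")
    se <- strategy$side_effect_share
    w1 <- share_over(first_others) * p_switch * se
    w2 <- share_over(second_all) * p_switch * (1 - se)
    out <- c(out, w1, w2)
  } else {
    second_others <- setdiff(.line_set(params, "second"), d$name)
    out <- c(out, share_over(second_others) * p_switch)
  }
  # merge duplicates defensively (a drug cannot be in both sets, but keep tidy)
  if (anyDuplicated(names(out))) {
    tn <- tapply(out, names(out), sum)
    out <- setNames(as.numeric(tn), names(tn))
  }
  out / sum(out)
}

# Build the stage table for one pathway. Kinds: BSC_INITIAL, ON_FIRST_DMD,
# ON_SECOND_DMD, BSC_AFTER_DMD.
.pathway_stages <- function(initial, strategy, params, sw = NULL) {
  if (initial == "best_supportive_care") {
    return(list(kind = "BSC_INITIAL", dmd = NA_character_, n = 1L))
  }
  if (is.null(sw)) {
    sw <- switch_distribution(list(stage = "ON_FIRST_DMD", dmd = initial),
                              strategy, params)
  }
  seconds <- setdiff(names(sw), "best_supportive_care")
  list(
    kind = c("ON_FIRST_DMD", rep("ON_SECOND_DMD", length(seconds)),
             "BSC_AFTER_DMD"),
    dmd = c(initial, seconds, NA_character_),
    n = length(seconds) + 2L
  )
}

#' Run one treatment pathway over the lifetime horizon
#'
#' Propagates a cohort of mass 1 that starts on one initial option (a DMD or
#' best supportive care) through annual cycles until age `max_age`. Within a
#' cycle, in order: death, EDSS/SPMS transition under the current stage's
#' progression relative risk (1 on best supportive care), forced stop above
#' the EDSS stop level, then voluntary discontinuation routed by
#' [switch_distribution()], effective at the start of the next cycle. The
#' adherence class is fixed for the whole pathway and only affects accrual
#' (relapse risks), not transitions.
#'
#' @param initial `"best_supportive_care"` or a DMD name.
#' @param adherence_class `"adherent"` or `"nonadherent"`.
#' @param strategy An `ms_strategy`.
#' @param params An `ms_parameter_set`.
#' @param context Optional precomputed evaluation context (internal reuse).
#' @return An object of class `ms_cohort_trace`: start-of-cycle occupancy
#'   `trace[cycle, stage, state]`, per-cycle entrant/discontinuation/forced
#'   stop/death event streams, and the stage table.
#' @export
run_pathway <- function(initial, adherence_class, strategy, params,
                        context = NULL) {
  se <- params$settings
  if (is.null(context)) context <- .build_context(params)
  n_cycles <- context$n_cycles
  if (!adherence_class %in% c("adherent", "nonadherent")) {
    stop("adherence_class must be 'adherent' or 'nonadherent'")
  }
  sw_first <- if (initial != "best_supportive_care") {
    switch_distribution(list(stage = "ON_FIRST_DMD", dmd = initial),
                        strategy, params)
  }
  stages <- .pathway_stages(initial, strategy, params, sw_first)
  S <- stages$n
  H <- .N_STATES

  # per-stage no-mortality transition matrices
  on_dmd <- stages$kind %in% c("ON_FIRST_DMD", "ON_SECOND_DMD")
  P_list <- lapply(seq_len(S), function(s) {
    if (on_dmd[s]) context$P[[stages$dmd[s]]] else context$P[["__bsc__"]]
  })

  # discontinuation rates, routing, forced stop
  disc_rate <- numeric(S)
  route <- matrix(0, S, S)
  forced_mask <- matrix(0L, S, H)
  forced_dest <- rep(-1L, S)
  bsc_after <- match("BSC_AFTER_DMD", stages$kind)
  edss <- state_edss()
  stop_states <- which(!is.na(edss) & edss > se$edss_stop_level)

  for (s in seq_len(S)) {
    kind <- stages$kind[s]
    if (!on_dmd[s]) next
    q <- context$dmd$cau_disc[[stages$dmd[s]]] *
      strategy$discontinuation_multiplier
    if (q < 0 || q > 1) {
      stop("effective discontinuation probability ", q, " outside [0, 1]")
    }
    disc_rate[s] <- q
    forced_mask[s, stop_states] <- 1L
    forced_dest[s] <- bsc_after - 1L
    if (kind == "ON_FIRST_DMD") {
      sw <- sw_first
      for (dest in names(sw)) {
        j <- if (dest == "best_supportive_care") bsc_after
             else which(stages$kind == "ON_SECOND_DMD" & stages$dmd == dest)
        route[s, j] <- route[s, j] + sw[[dest]]
      }
    } else {
      route[s, bsc_after] <- 1
    }
  }

  # initial occupancy: entry distribution over RRMS EDSS in the initial stage
  init_occ <- matrix(0, S, H)
  init_occ[1L, .RRMS_IDX] <- se$entry_distribution

  core <- run_pathway_core(init_occ, P_list, context$death_prob, disc_rate,
                           route, forced_mask, forced_dest, n_cycles,
                           .STATE_DEAD)
  out <- list(
    trace = core$trace, entrants = core$entrants, vol_disc = core$vol_disc,
    forced = core$forced, deaths = core$deaths, stages = stages,
    initial = initial, adherence_class = adherence_class,
    strategy_label = strategy$label, n_cycles = n_cycles
  )
  class(out) <- "ms_cohort_trace"
  out
}

#' Evaluate a strategy as a weighted mixture of treatment pathways
#'
#' Enumerates the strategy's initial options, splits each adherence-applicable
#' DMD into adherent and nonadherent branches with weight
#' `adherent_proportion` (infused DMDs are fully adherent), accrues outcomes
#' per branch with [accrue()], and returns the initiation- and
#' adherence-weighted mixture. The shared decision making delivery cost is
#' charged at every decision epoch (initiation at cycle 0 and each voluntary
#' first-DMD discontinuation), discounted at the cost rate.
#'
#' @param strategy An `ms_strategy`.
#' @param params An `ms_parameter_set`.
#' @param context Optional precomputed evaluation context (internal reuse).
#' @return An `ms_outcomes` object.
#' @export
evaluate_strategy <- function(strategy, params, context = NULL) {
  if (is.null(context)) context <- .build_context(params)
  init <- strategy$initiation
  init <- init[init > 0 | names(init) == "best_supportive_care"]
  unknown <- setdiff(setdiff(names(init), "best_supportive_care"),
                     params$dmds$name)
  if (length(unknown)) {
    stop("initiation references unknown DMD '", unknown[1L], "'")
  }
  total <- NULL
  for (opt in names(init)) {
    w <- init[[opt]]
    if (w <= 0) next
    tr <- run_pathway(opt, "adherent", strategy, params, context)
    if (opt == "best_supportive_care") {
      branch <- accrue(tr, strategy, params, context)
    } else {
      if (isTRUE(context$dmd$adherence_applicable[[opt]])) {
        pa <- strategy$adherent_proportion[[opt]]
        if (is.null(pa) || is.na(pa)) pa <- 1
        both <- .accrue_pathway(tr, strategy, params, context)
        branch <- outcomes_add(outcomes_scale(both$adherent, pa),
                               outcomes_scale(both$nonadherent, 1 - pa))
      } else {
        branch <- accrue(tr, strategy, params, context)
      }
    }
    piece <- outcomes_scale(branch, w)
    total <- if (is.null(total)) piece else outcomes_add(total, piece)
  }
  total
}

#' Undiscounted life expectancy from model entry per initial option
#'
#' External-validity check: runs one pathway per initial treatment option and
#' reports undiscounted life years from model entry. For a plausible
#' parameter set these should fall a few years below general-population
#' remaining life expectancy at the entry age.
#'
#' @param params An `ms_parameter_set`.
#' @param strategy Strategy whose pathways to run (default CAU).
#' @return Data frame with columns `option` and `life_years`.
#' @export
life_expectancy_by_option <- function(params,
                                      strategy = params$strategies$CAU) {
  opts <- c("best_supportive_care", params$dmds$name)
  ly <- vapply(opts, function(opt) {
    tr <- run_pathway(opt, "adherent", strategy, params)
    accrue(tr, strategy, params)$life_years[["undiscounted"]]
  }, numeric(1))
  data.frame(option = opts, life_years = unname(ly))
}

#' Export a cohort trace as a long data frame
#'
#' @param trace An `ms_cohort_trace` from [run_pathway()].
#' @return Data frame with columns `cycle`, `stage_kind`, `dmd`,
#'   `adherence_class`, `course`, `edss`, `mass`.
#' @export
trace_to_df <- function(trace) {
  hs <- health_states()
  dims <- dim(trace$trace)
  grid <- expand.grid(cycle = seq_len(dims[1]) - 1L, stage = seq_len(dims[2]),
                      state = seq_len(dims[3]))
  data.frame(
    cycle = grid$cycle,
    stage_kind = trace$stages$kind[grid$stage],
    dmd = trace$stages$dmd[grid$stage],
    adherence_class = trace$adherence_class,
    course = as.character(hs$course[grid$state]),
    edss = hs$edss[grid$state],
    mass = as.numeric(trace$trace)
  )
}
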