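# Transition structure: EDSS progression, SPMS conversion, mortality, relapses.

# Apply a progression relative risk to the no-mortality transition structure
# and return the 20 x 20 row-stochastic matrix over all health states.
# Worsening and RRMS->SPMS conversion probabilities are multiplied by the
# relative risk; improvement probabilities are untouched; each row is
# re-normalised through its stay probability. SPMS worsening is scaled by
# `rr_spms` (equal to the DMD's relative risk while treatment continues in
# SPMS, 1 otherwise).
base_transition_matrix <- function(nat_hist, rr_progression = 1,
                                   rr_spms = rr_progression,
                                   spms_landing_offset = 0L) {
  if (rr_progression < 0 || rr_spms < 0) stop("relative risks must be >= 0")
  rt <- nat_hist$rrms_transitions
  st <- nat_hist$spms_transitions
  M <- matrix(0, .N_STATES, .N_STATES)
  hs <- health_states()
  dimnames(M) <- list(hs$label, hs$label)

  for (i in seq_len(10L)) {            # RRMS EDSS e = i - 1
    e <- i - 1L
    improve <- if (i > 1L) rt[i, seq_len(i - 1L)] else numeric(0)
    worsen <- if (i < 10L) rt[i, (i + 1L):10L] else numeric(0)
    convert <- rt[i, 11L]
    sc_worsen <- worsen * rr_progression
    sc_convert <- convert * rr_progression
    if (any(c(sc_worsen, sc_convert) > 1)) {
      stop("relative-risk scaling pushes a transition probability above 1 ",
           "(RRMS EDSS ", e, ")")
    }
    stay <- 1 - sum(improve) - sum(sc_worsen) - sc_convert
    if (stay < -1e-12) {
      stop("relative-risk scaling makes RRMS EDSS ", e,
           " row mass exceed 1; invalid parameter set")
    }
    stay <- max(stay, 0)
    if (i > 1L) M[i, seq_len(i - 1L)] <- improve
    if (i < 10L) M[i, (i + 1L):10L] <- sc_worsen
    M[i, i] <- stay
    landing <- min(9L, max(1L, e + spms_landing_offset))
    M[i, 10L + landing] <- M[i, 10L + landing] + sc_convert
  }

  for (i in seq_len(9L)) {             # SPMS EDSS e = i
    row <- 10L + i
    worsen <- if (i < 9L) st[i, (i + 1L):9L] else numeric(0)
    sc_worsen <- worsen * rr_spms
    if (any(sc_worsen > 1)) {
      stop("relative-risk scaling pushes a transition probability above 1 ",
           "(SPMS EDSS ", i, ")")
    }
    stay <- 1 - sum(sc_worsen)
    if (stay < -1e-12) {
      stop("relative-risk scaling makes SPMS EDSS ", i, " row mass exceed 1")
    }
    if (i < 9L) M[row, (10L + i + 1L):(10L + 9L)] <- sc_worsen
    M[row, row] <- max(stay, 0)
  }

  M[.STATE_DEAD, .STATE_DEAD] <- 1
  M
}

#' Annual death probability for a health state
#'
#' Background mortality is taken from the life table, blended between sexes
#' with the cohort's proportion male, and multiplied by the EDSS-specific
#' mortality multiplier (identical for RRMS and SPMS at equal EDSS). The
#' result is capped at 1.
#'
#' @param age Age in years at the start of the cycle; must be covered by the
#'   life table.
#' @param settings Model settings (uses `proportion_male`, `max_age`).
#' @param edss Integer EDSS level 0--9.
#' @param nat_hist Natural-history inputs (life table and multipliers).
#' @return Annual probability of death.
#' @export
death_probability <- function(age, settings, edss, nat_hist) {
  a <- floor(age)
  lt <- nat_hist$life_table
  pm <- lt$annual_death_prob[lt$sex == "male" & lt$age == a]
  pf <- lt$annual_death_prob[lt$sex == "female" & lt$age == a]
  if (length(pm) != 1L || length(pf) != 1L) {
    if (a < settings$max_age) {
      stop("age ", a, " not covered by the life table")
    }
    pm <- pf <- 1
  }
  p_bg <- settings$proportion_male * pm + (1 - settings$proportion_male) * pf
  mult <- nat_hist$mortality_multiplier[edss + 1L]
  min(1, p_bg * mult)
}

# death probability for every alive state at one age (vectorised over states)
death_probability_states <- function(age, settings, nat_hist) {
  a <- floor(age)
  lt <- nat_hist$life_table
  pm <- lt$annual_death_prob[lt$sex == "male" & lt$age == a]
  pf <- lt$annual_death_prob[lt$sex == "female" & lt$age == a]
  if (length(pm) != 1L || length(pf) != 1L) {
    stop("age ", a, " not covered by the life table")
  }
  p_bg <- settings$proportion_male * pm + (1 - settings$proportion_male) * pf
  edss <- state_edss()
  p <- numeric(.N_STATES)
  alive <- alive_states()
  p[alive] <- pmin(1, p_bg * nat_hist$mortality_multiplier[edss[alive] + 1L])
  p
}

#' Per-cycle transition matrix with mortality for one treatment context
#'
#' Builds the full 20 x 20 annual transition matrix: the progression relative
#' risk is applied to worsening and RRMS-to-SPMS conversion probabilities
#' (improvement untouched, rows re-normalised through the stay probability),
#' then the age- and EDSS-specific death probability is applied first within
#' the cycle, scaling the remaining transition mass by one minus the death
#' probability. Death is absorbing.
#'
#' @param nat_hist Natural-history inputs.
#' @param rr_progression Relative risk on worsening/conversion (> 0; 1 off
#'   treatment).
#' @param age Age in years at the start of the cycle.
#' @param settings Model settings.
#' @param rr_spms Relative risk applied to SPMS worsening (defaults to
#'   `rr_progression`; set to 1 if treatment effect is assumed lost in SPMS).
#' @return A 20 x 20 row-stochastic matrix in the package state order.
#' @export
build_transition_matrix <- function(nat_hist, rr_progression, age, settings,
                                    rr_spms = rr_progression) {
  if (rr_progression <= 0) stop("rr_progression must be > 0")
  M <- base_transition_matrix(nat_hist, rr_progression, rr_spms)
  p_death <- death_probability_states(age, settings, nat_hist)
  out <- M * (1 - p_death)
  out[, .STATE_DEAD] <- out[, .STATE_DEAD] + p_death
  out[.STATE_DEAD, ] <- 0
  out[.STATE_DEAD, .STATE_DEAD] <- 1
  out
}

#' Expected relapses per person-year in a health state
#'
#' The state's annual relapse rate is scaled by the treatment's relapse
#' relative risk (1 off treatment). Nonadherent patients have a 42\% higher
#' overall relapse risk and a 7.5\% higher severe-relapse risk; the severe
#' count is capped at the total.
#'
#' @param course `"RRMS"` or `"SPMS"`.
#' @param edss Integer EDSS level.
#' @param rr_relapse Relapse relative risk of the current treatment.
#' @param adherence_class `"adherent"` or `"nonadherent"`.
#' @param settings Model settings (nonadherence multipliers).
#' @param nat_hist Natural-history inputs (relapse table).
#' @return Named vector `c(total = , severe = )` of expected relapses per
#'   person-year.
#' @export
relapse_outcomes <- function(course, edss, rr_relapse, adherence_class,
                             settings, nat_hist) {
  if (course == "DEAD") stop("relapse_outcomes is undefined for DEAD")
  adherence_class <- match.arg(adherence_class, c("adherent", "nonadherent"))
  rr_tab <- nat_hist$relapse_rates
  sel <- rr_tab$course == course & rr_tab$edss == edss
  if (!any(sel)) stop("no relapse rate for ", course, " EDSS ", edss)
  rate <- rr_tab$relapse_rate[sel][1L]
  sf <- rr_tab$severe_fraction[sel][1L]
  total <- rate * rr_relapse
  if (adherence_class == "nonadherent") {
    total <- total * settings$nonadherent_relapse_multiplier
    sf <- sf * settings$nonadherent_severe_multiplier
  }
  severe <- min(total, total * sf)
  c(total = total, severe = severe)
}
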