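---
title: "An EDSS-based cohort model for the cost-effectiveness of shared decision making in RRMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An EDSS-based cohort model for the cost-effectiveness of shared decision making in RRMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmcea)
```

## The decision problem

Up to a third of people with relapsing-remitting multiple sclerosis (RRMS)
stop their disease-modifying drug (DMD) within the first year, and many who
continue take it irregularly. Shared decision making (SDM) — eliciting the
patient's preferences and choosing the drug together — plausibly changes
which DMD is started, how long patients persist with it, and how well they
adhere to it, but it costs consultation time and decision-support
infrastructure. This package quantifies that trade-off: lifetime costs and
QALYs of an SDM strategy versus usual care (CAU), from a Dutch limited
societal perspective.

## Model structure

The disease is represented by 20 health states: RRMS at EDSS 0–9, secondary
progressive MS (SPMS) at EDSS 1–9, and death. The model runs annual cycles
from the entry age (37 years by default) until death or age 100 (63
cycles). Within a cycle, in this order:

1. **Death.** The background annual death probability is a
   proportion-male-weighted blend of the male and female life-table values
   (29% male by default), multiplied by an EDSS-specific mortality
   multiplier that is identical for RRMS and SPMS at equal EDSS, and capped
   at 1.
2. **Disease transition.** RRMS states can improve, stay, worsen, or
   convert to SPMS at the same EDSS level (floored at SPMS's minimum level
   1); SPMS states can only stay or worsen. A DMD multiplies the worsening
   and conversion probabilities by its progression relative risk; the row
   is re-normalised through the stay probability, leaving improvement
   probabilities untouched. Treatment (and its relative risk) continues
   after SPMS conversion; a flag (`rr_applies_spms`) can switch the SPMS
   effect off.
3. **Forced stop.** On-treatment occupancy above the EDSS stop level
   (EDSS > 6) moves to best supportive care without a switch and without a
   new treatment decision.
4. **Voluntary discontinuation.** Applied at the drug's real-world annual
   rate times the strategy's discontinuation multiplier; the stopping mass
   is routed by the switch rule and becomes occupancy of its destination at
   the start of the next cycle, so mass that switches within a cycle is not
   exposed to the destination's discontinuation in the same cycle.

The treatment pathway expands the state space: first DMD, each reachable
second DMD, and best supportive care (initial choice or post-treatment) —
at most two active treatment stages, after which patients remain on best
supportive care. Of voluntary first-DMD stoppers, 95% switch to another
DMD and 5% to best supportive care; of the switchers from a first-line
drug, 79% (side-effect stoppers) pick another first-line drug and 21%
(efficacy stoppers) pick a second-line drug. Within each eligible set the
destination is proportional to the strategy's own initiation shares,
renormalised after excluding the current drug; if every eligible share is
zero the split is uniform. Switchers from a second-line first drug pick
another second-line drug. This makes strategy evaluation *not* exactly
linear in initiation shares (the shares also steer the switch mix) — the
package's linearity test therefore pins the destination mix with the
`switch_override` used by the sensitivity scenarios.

Accrual (utilities, relapses, costs) happens on start-of-cycle occupancy;
there is no half-cycle correction by default (an optional flag applies
0.5 weights to the first and last cycle). Drug costs accrue for the full
cycle in which discontinuation occurs, consistent with the real-world
definition of discontinuation as an interruption of more than 90 days.

## The three SDM effects

* **Effect 1 — initial choice:** SDM uses its own initiation distribution
  over best supportive care and the DMDs (more oral first-line and
  second-line use, less best supportive care).
* **Effect 2 — persistence:** every drug's discontinuation rate is halved
  (multiplier 0.5; 0.25 and 0.75 in sensitivity analyses).
* **Effect 3 — adherence:** the adherent proportion for self-administered
  DMDs rises from 58.9% to 63.9% — read directly from the printed profile
  table as a 5-percentage-point absolute increase. Infused DMDs
  (natalizumab, ocrelizumab, alemtuzumab) are always fully adherent, and a
  nonadherent-class patient who switches onto an infusion is treated as
  adherent while on it.

Adherence is a fixed per-pathway class: each adherence-applicable initial
DMD splits into an adherent and a nonadherent branch, weighted by the
adherent proportion, and outcomes are the initiation- and
adherence-weighted mixture. Nonadherence leaves the progression benefit
intact and inflates only relapse risks (total x1.42, severe fraction
x1.075, capped at the total) — the source model quantified only relapse
consequences of nonadherence.

SDM delivery costs €100 per decision, charged at initiation (cycle 0, all
patients including those choosing best supportive care) and at every
voluntary first-DMD discontinuation (where a second choice is made), using
expected decision mass and the cost discount rate. Discontinuation of the
second DMD leads to best supportive care without a choice, so no delivery
cost is charged there. The €100 decomposes as €51.77 for a 50% increase in
consultation time plus €48.23 headroom for decision-aid development
(`sdm_cost_components()`).

## Economics

Cost categories: drug acquisition, administration (first-year versus
subsequent, infusions only), monitoring (pretreatment in the first
treatment year; annual; one-off post-discontinuation, charged in the cycle
of stopping), pharmacy dispensing fees (€14 first prescription, €7
subsequent; 12 prescriptions/year for self-administered drugs, none for
infusions), adverse-event costs as a fixed proportion of the health-state
health care costs, EDSS-dependent health-state costs by category
(healthcare, community services, equipment/aids, informal care,
productivity), relapse costs (mild/severe), and SDM delivery. Relapse costs
get their own category — the accounting accrues them explicitly and folding
them into health-state healthcare costs would hide them from the
decomposition. Perspectives nest: healthcare; societal with friction-cost
productivity losses (the Dutch-guideline base case); societal with
human-capital productivity losses. QALYs are utilities minus relapse and
adverse-event disutilities (annualised decrements per expected event —
durations are folded into the decrement), discounted at 1.5%/year; costs at
4.0%/year; undiscounted twins are kept throughout. Utilities may be
negative at high EDSS; no floor is imposed.

EDSS health-state cost anchors are interpolated linearly to all integer
levels; beyond the outermost anchors the cost is held constant rather than
extrapolated, which avoids negative or exploding values at the extremes.

## Analyses

`compare()` classifies a strategy pair by ΔCost and ΔQALY (ICER, dominant,
dominated, or cost-saving-but-QALY-losing). `threshold_sdm_cost()` exploits
the linearity of the delivery cost in the totals: with delivery cost zero,
`c* = (λ·ΔQALY − ΔCost₀) / E[discounted decisions]` solves `ICER(c*) = λ`
exactly, verified by one re-run (relative error < 1e-6 enforced).
`one_way_sensitivity()` runs a registry of scenario transforms;
`owsa_registry()` ships the standard preset (drug costs ±20%, progression
relative-risk ranges, zero delivery cost, discounting 0%/3%, perspectives,
onset age 29/45, proportion male 18%/40%, entry-distribution variants,
initial-choice and switch-destination variants, transition probabilities
±10% with re-normalised stay probabilities).

`run_psa()` draws parameters, re-runs the full model per draw, and stores
(ΔCost, ΔQALY) pairs; `ceac()` counts positive net monetary benefit
`λ·ΔQ − ΔC ≥ 0` on the stored pairs. Default distribution families follow
standard practice — beta for probabilities, proportions and rescaled
utilities `(u+1)/2`, gamma for costs and rates, lognormal for relative
risks, Dirichlet rows (concentration 200 per row) for transition
probabilities — moment-matched to the point estimate with a 10%
proportional standard error, because the original distribution
specifications are unpublished. Monotonicity of utilities and healthcare
costs in EDSS is preserved by sorting draws within a course; unit drug
prices and tariff fees are treated as known and not sampled; the SDM
adherence gain keeps its absolute 5-point size around the sampled CAU
proportion. Everything is overridable through `psa_config()`.

## Synthetic data and what passing tests mean

The published inputs are the two strategy profiles (initiation shares,
real-world first-year discontinuation rates between 10% and 31%, adherent
proportions), the behavioural constants (95/5 and 79/21 switch splits,
nonadherence multipliers), demographics, discounting, fees and the €100
delivery cost. Everything else — natural history, per-DMD relative risks,
prices, utilities, state costs, the life table — lives in unpublished
supplementary material, so the package ships synthetic stand-ins chosen
once to be realistic for Dutch RRMS modelling: annual worsening
probabilities around 0.11–0.17 rising with EDSS, SPMS conversion 1.5–9.6%,
utilities from 0.87 (EDSS 0) to 0.03 (EDSS 9) with SPMS 0.045 lower,
healthcare costs rising from €1,800 to €27,000 per year, first-line drug
prices €5,200–€13,000 and second-line €17,500–€23,000, and a
Gompertz–Makeham life table tuned to Dutch-like life expectancy. The printed
note in `inst/extdata/synthetic_reference/manifest.yaml` labels the set as
synthetic.

Consequently the test suite demonstrates *structural* correctness — mass
conservation, treatment-neutrality and null-input identities, closed-form
occupancy, exact threshold inversion, CEAC-by-counting, seeded
reproducibility, and agreement of the cohort engine with an independent
individual-level microsimulation within Monte-Carlo error (3 SE at
n = 200,000 across five seeds) — and *plausibility* (life expectancy from
entry of 30–40 years, consistent with Dutch population values minus the
reported 7–14-year MS reduction). It does not reproduce the original
study's incremental results: the dedicated acceptance test that compares
against the published ICERs documents, and is expected to show, the gap
between the stand-in and the unpublished inputs. On the stand-in, SDM gains
fewer QALYs (≈0.4) at higher incremental cost than published, mainly
because the synthetic progression relative risks are closer to 1 and the
synthetic drug prices are high relative to the synthetic health-state
savings.

## Numerical choices

* Event order death → transition → forced stop → voluntary
  discontinuation, with switching effective at the next cycle start; each
  is a deliberate convention (the source description does not fix them) and
  the first-year cost components (pretreatment monitoring, first-year
  administration, first-prescription fee) accrue on entrant mass in its
  entry cycle.
* Discontinuation rates printed for the first year are applied every cycle
  (a stationary rate), consistent with the second DMD inheriting the same
  rate.
* The RRMS→SPMS conversion lands at the same EDSS floored at 1; the offset
  is configurable.
* Transition rows must sum to 1 within 1e-9; relative-risk scaling that
  pushes any probability above 1 (or stay below 0) is an error, not a
  silent cap.
* The cohort cycle loop runs in C++ over the expanded
  (stage × health-state) space with sparse transition rows; per-cycle
  series are recovered in R by a single occupancy-by-weights matrix
  product. The 10,000-iteration PSA runs in roughly ten minutes on one
  CPU; test problem sizes (10-year toy horizons, oracle sizes of
  30,000–200,000 patients) were chosen to keep the suite in the minutes
  range.

## Known limitations

* No re-initiation after best supportive care, constant nonadherence over
  time, no treatment waning, no EDSS half-steps, and at most two active
  DMDs per pathway — inherited simplifications of the source model.
* The adherent/nonadherent split is the only individual-level
  heterogeneity; everything else is cohort-homogeneous.
* The stand-in parameter set is not a calibration target: none of its
  values were adjusted to move results toward published numbers, so
  absolute results differ from the original study and should be read as
  illustrations of the method.
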