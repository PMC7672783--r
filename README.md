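# sdmcea

Cost-effectiveness modelling of **shared decision making (SDM)** versus
usual care for choosing between **disease-modifying drugs (DMDs)** in
relapsing-remitting multiple sclerosis (RRMS), from a Dutch (limited)
societal perspective over a lifetime horizon.

The package is aimed at health-economic modellers: it implements the full
decision-analytic pipeline — a Markov cohort state-transition model over
EDSS-defined health states with treatment sequencing, real-world
discontinuation and adherence mixing, Dutch-style cost and QALY accounting,
incremental cost-effectiveness analysis, one-way and threshold sensitivity
analyses, and a seeded probabilistic sensitivity analysis (PSA) — together
with a synthetic parameter generator and an individual-level
microsimulation oracle used to verify the cohort engine.

## The model

Disease course is represented by 20 health states: RRMS at EDSS 0–9, SPMS
at EDSS 1–9 (worsening only), and death. In annual cycles a patient can
improve or worsen within RRMS, convert to SPMS at the same EDSS level,
relapse, or die; background mortality is blended across sexes and multiplied
by an EDSS-specific hazard multiplier. A DMD slows progression by applying a
relative risk `RR_prog` to worsening and conversion probabilities (rows are
re-normalised through the stay probability) and reduces relapses by
`RR_relapse`. Patients stop treatment with a real-world annual probability
(forced above EDSS 6); 95% of voluntary first-DMD stoppers switch — 79% to
another first-line DMD (side effects), 21% to a second-line DMD (lack of
efficacy) — and second-DMD stoppers move to best supportive care.
Nonadherent patients (fewer than 80% of days covered) keep the progression
benefit but have a 42% higher relapse risk and a 7.5% higher severe-relapse
risk.

Shared decision making is modelled as three effects relative to usual care:
a changed initial treatment mix, a halved discontinuation rate, and a
5-percentage-point increase in the adherent proportion (58.9% → 63.9% for
self-administered DMDs), at a delivery cost of €100 per treatment decision.
QALYs are discounted at 1.5%/year and costs at 4.0%/year; strategies are
compared by the incremental cost-effectiveness ratio
`ICER = ΔCost / ΔQALY`.

The published strategy profiles and behavioural constants are built in; the
remaining inputs (natural history, DMD efficacy and prices, utilities, unit
costs, life table) ship as a clearly-labelled **synthetic stand-in**
(`inst/extdata/synthetic_reference/`, regenerable with
`reference_parameter_set()`), since the original model's full parameter
tables are unpublished. Results below therefore illustrate the machinery,
not the original study's numbers.

## Worked example

```r
library(sdmcea)

ps <- reference_parameter_set()          # validated parameter set
ce <- compare(
  evaluate_strategy(ps$strategies$SDM, ps),
  evaluate_strategy(ps$strategies$CAU, ps),
  perspective = "societal_friction"
)
print(ce)
#> SDM vs CAU (societal_friction perspective)
#>   dCost: 46279.11 EUR   dQALY: 0.4217
#>   ICER, ICER 109741.66 EUR/QALY
```

Shared decision making adds 0.42 discounted QALYs per patient (driven by
longer treatment persistence) at €46,279 additional discounted societal
cost (driven by higher drug use), an ICER of about €110,000/QALY on the
synthetic stand-in inputs. The threshold analysis inverts the question —
the maximum delivery cost per decision at which SDM stays cost-effective:

```r
threshold_sdm_cost(ps, wtp = 50000)$max_cost
#> [1] -16041.15
```

Negative here: on the stand-in inputs the non-delivery costs alone exceed
€50,000/QALY, so no delivery price makes SDM cost-effective at that
threshold (the published model, with its own inputs, reported a positive
headroom). The probabilistic analysis and the analysis scripts follow the
same pattern:

```sh
Rscript analysis/01_build_parameters.R   # inputs + validation report
Rscript analysis/02_base_case.R          # effect-wise and combined results
Rscript analysis/03_sensitivity.R        # one-way + threshold analyses
Rscript analysis/04_psa.R                # 10,000-draw PSA, CE plane, CEAC
Rscript analysis/05_validation.R         # oracle check, life expectancy
```

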