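#!/usr/bin/env Rscript
# One-way sensitivity analyses of the combined-effects comparison and the
# threshold analysis for the maximum delivery cost of shared decision making
# at EUR 20,000 and EUR 50,000 per QALY.

library(sdmcea)
dir.create("results", showWarnings = FALSE)

ps <- reference_parameter_set()

owsa <- one_way_sensitivity(owsa_registry(ps), ps)
write.csv(owsa, "results/owsa.csv", row.names = FALSE)
cat("One-way sensitivity (combined effects):\n")
print(owsa[, c("scenario", "delta_cost", "delta_qaly", "icer",
               "classification")], digits = 4)

effects <- list(
  choice_only = function(p) {
    p$strategies$SDM$discontinuation_multiplier <- 1
    p$strategies$SDM$adherent_proportion <- p$strategies$CAU$adherent_proportion
    p
  },
  discontinuation_only = function(p) {
    p$strategies$SDM$initiation <- p$strategies$CAU$initiation
    p$strategies$SDM$adherent_proportion <- p$strategies$CAU$adherent_proportion
    p
  },
  adherence_only = function(p) {
    p$strategies$SDM$initiation <- p$strategies$CAU$initiation
    p$strategies$SDM$discontinuation_multiplier <- 1
    p
  },
  combined = identity
)
rows <- lapply(names(effects), function(nm) {
  p <- effects[[nm]](ps)
  t20 <- threshold_sdm_cost(p, 20000)
  t50 <- threshold_sdm_cost(p, 50000)
  data.frame(effect = nm,
             max_cost_wtp20k = t20$max_cost,
             max_cost_wtp50k = t50$max_cost)
})
th <- do.call(rbind, rows)
write.csv(th, "results/thresholds.csv", row.names = FALSE)
cat("\nMaximum delivery cost of shared decision making (EUR/decision):\n")
print(th, digits = 6)
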