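#!/usr/bin/env Rscript
# Probabilistic sensitivity analysis of the combined-effects comparison:
# 10,000 parameter draws, cost-effectiveness plane and acceptability curve.
# Usage: Rscript analysis/04_psa.R [n_iterations] [seed]

library(sdmcea)
dir.create("results", showWarnings = FALSE)

args <- commandArgs(trailingOnly = TRUE)
n_iter <- if (length(args) >= 1) as.integer(args[1]) else 10000L
seed <- if (length(args) >= 2) as.integer(args[2]) else 20200929L

ps <- reference_parameter_set()
psa <- run_psa(ps, n = n_iter, seed = seed)
write.csv(psa$draws, "results/psa_draws.csv", row.names = FALSE)

curve <- ceac(psa)
write.csv(curve, "results/ceac.csv", row.names = FALSE)

for (wtp in c(20000, 50000)) {
  p <- ceac(psa, wtp)$probability_ce
  cat(sprintf("P(cost-effective at %d EUR/QALY) = %.1f%%\n", wtp, 100 * p))
}

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  g1 <- ggplot(psa$draws, aes(delta_qaly, delta_cost)) +
    geom_point(alpha = 0.2, size = 0.5) +
    geom_hline(yintercept = 0, linetype = 2) +
    geom_vline(xintercept = 0, linetype = 2) +
    geom_abline(slope = 20000, intercept = 0, colour = "grey40") +
    geom_abline(slope = 50000, intercept = 0, colour = "grey70") +
    labs(x = "Incremental QALYs", y = "Incremental costs (EUR)",
         title = "Cost-effectiveness plane, SDM vs usual care")
  ggsave("results/ce_plane.pdf", g1, width = 6, height = 5)
  g2 <- ggplot(curve, aes(wtp, probability_ce)) +
    geom_line() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "Willingness to pay (EUR/QALY)",
         y = "P(SDM cost-effective)",
         title = "Cost-effectiveness acceptability curve")
  ggsave("results/ceac.pdf", g2, width = 6, height = 4)
  cat("Wrote results/ce_plane.pdf and results/ceac.pdf\n")
}
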