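#!/usr/bin/env Rscript
# Stage 3: Monte-Carlo power of the cross-section, difference-score and
# ANCOVA strategies on each assay track, for a d = 0.5 effect on attrition
# applied to half the cohort, over n = 20-1,000.
# Usage: Rscript analysis/03_power_curves.R [seed]

suppressPackageStartupMessages({
  library(telosim)
  library(ggplot2)
})
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 20210210L
dir.create("results", showWarnings = FALSE)

params <- cohort_params(exposure_effect_d = 0.5)
pc <- estimate_power(params, n_replicates = 1000, seed = seed)
print(pc)

cat("\nHeadline comparisons:\n")
cat(sprintf("  truth difference-score at n = 250:  %.3f\n",
            power_at(pc, "difference_score", "truth", 250)))
cat(sprintf("  proxy difference-score at n = 1000: %.3f\n",
            power_at(pc, "difference_score", "proxy", 1000)))
cat(sprintf("  proxy cross-section at n = 500:     %.3f\n",
            power_at(pc, "cross_section", "proxy", 500)))
cat(sprintf("  truth cross-section at n = 250:     %.3f\n",
            power_at(pc, "cross_section", "truth", 250)))

out_csv <- "results/power_curves.csv"
write.csv(pc$power, out_csv, row.names = FALSE)

fig <- ggplot(pc$power,
              aes(n, power, colour = strategy, shape = strategy)) +
  geom_line() + geom_point() +
  facet_wrap(~assay, labeller = as_labeller(
    c(truth = "gold-standard track (SB-like)",
      proxy = "error-prone track (qPCR-like)"))) +
  labs(x = "total sample size", y = sprintf("power at alpha = %.2f", pc$alpha),
       title = sprintf("Power to detect a d = %.1f effect on attrition",
                       pc$effect_d)) +
  ylim(0, 1) + theme_bw()
out_png <- "results/power_curves.png"
ggsave(out_png, fig, width = 8, height = 4, dpi = 150)

write_run_manifest("results/power_curves_manifest.json", "power",
                   params, seed, outputs = c(out_csv, out_png),
                   extra = list(alpha = pc$alpha,
                                n_replicates = pc$n_replicates))
cat("wrote", out_csv, "and", out_png, "\n")
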