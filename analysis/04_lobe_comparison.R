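#!/usr/bin/env Rscript
# Lobe-level reduction of the posterior contrasts: per draw, average the
# pooled atypical-AD-vs-controls contrast over the member ROIs of each of
# the 8 lobes, then tabulate for every lobe pair the posterior
# probability that the column lobe changes faster than the row lobe.
# Because the comparison is a per-draw event probability, p[i,j] and
# p[j,i] are exact complements.
#
# Outputs: results/lobes/comparison_{tau,volume}.csv (raw probabilities)
#          results/lobes/comparison_{tau,volume}_display.csv (clipped)

library(taulong)

dir.create("results/lobes", showWarnings = FALSE, recursive = TRUE)
seed <- 20L

for (m in c("tau", "volume")) {
  coh <- read_cohort_csv(file.path("results/cohort", paste0(m, ".csv")))
  design <- build_model_input(coh, compute_annualized_changes(coh))
  spec <- hier_spec("desk", seed = seed + if (m == "tau") 10L else 20L)
  fit <- fit_mcmc(spec, design)
  contrast <- relative_to_controls(
    pooled_atypical_effect(fit, sum(coh$subjects$group == "LPA"),
                           sum(coh$subjects$group == "PCA")), fit)
  cmp <- comparison_matrix(lobe_average(contrast, default_lobe_map()))
  write_comparison_csv(cmp, file.path("results/lobes",
                                      paste0("comparison_", m, ".csv")))
  write_comparison_csv(cmp,
                       file.path("results/lobes",
                                 paste0("comparison_", m,
                                        "_display.csv")),
                       formatted = TRUE)
  cat(sprintf("\n%s lobe comparison (col lobe changes faster than row):\n",
              m))
  print(format_comparison(cmp), quote = FALSE)
  off <- upper.tri(cmp$p)
  cat(sprintf("complement identity max deviation: %.2g\n",
              max(abs(cmp$p[off] + t(cmp$p)[off] - 1))))
}
cat("\nwrote results/lobes/comparison_{tau,volume}[_display].csv\n")
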