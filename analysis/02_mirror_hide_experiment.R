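#!/usr/bin/env Rscript
# Mirror-reversed feedback crossed with mid-movement cursor elimination
# (2 x 2 within-subject): are the two long-latency attenuations additive
# (no interaction), as expected if both act through the same state-estimate
# uncertainty?  Writes results under results/exp2.

library(reflexvf)

b <- run_experiment(experiment_config(2, seed = 20260940L,
                                      out_dir = "results/exp2"))
st <- b$stats$table
for (m in c("ll", "endpoint_sd", "bga", "peak_vel_dps")) {
  rows <- st[st$measure == m & st$analysis == "rm_anova_twoway", ]
  if (nrow(rows) == 0) next
  cat(sprintf("[exp2] %s:\n", m))
  for (j in seq_len(nrow(rows))) {
    cat(sprintf("  %-22s F(%d,%d) = %6.2f, p = %.3g, pes = %.2f\n",
                rows$effect[j], rows$df1[j], rows$df2[j], rows$statistic[j],
                rows$p[j], rows$effect_size[j]))
  }
}
cr <- b$stats$correlation
cat(sprintf("[exp2] LL vs endpoint-SD across the 4 cells: mean r = %.2f, CI [%.2f, %.2f]\n",
            cr$mean_r, cr$ci[1], cr$ci[2]))
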