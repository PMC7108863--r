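#!/usr/bin/env Rscript
# Target jumps under pro/anti instructions and normal/mirror vision: the
# anti task remaps the target-to-action rule without touching hand-state
# estimation, so it should abolish the reflexive visuomotor response
# (delta v-EMG) while sparing the stretch reflex; mirror reversal should
# suppress both.  Detects response latencies with the successive t-test,
# recomputes the visuomotor window from the cohort, and writes results
# under results/exp4.

library(reflexvf)

b <- run_experiment(experiment_config(4, seed = 20260960L,
                                      out_dir = "results/exp4"))
emg <- b$latencies[b$latencies$signal == "emg", ]
pro <- cohort_shortest_latency(emg$onset_s[emg$block == "Pro"])
anti <- cohort_shortest_latency(emg$onset_s[emg$block == "Anti"])
cat(sprintf("[exp4] shortest EMG latencies: Pro %.1f ms, Anti %.1f ms\n",
            1000 * pro, 1000 * anti))
cat(sprintf("[exp4] visuomotor window: %.1f-%.1f ms\n",
            1000 * b$windows$v_emg[1], 1000 * b$windows$v_emg[2]))
st <- b$stats$table
for (m in c("dv_emg_flexor", "ll")) {
  rows <- st[st$measure == m & st$analysis == "paired_t", ]
  for (j in seq_len(nrow(rows))) {
    cat(sprintf("[exp4] %-14s %-18s t(%d) = %6.2f, p = %.3g, d = %.2f\n",
                m, rows$effect[j], rows$df1[j], rows$statistic[j],
                rows$p[j], rows$effect_size[j]))
  }
}
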