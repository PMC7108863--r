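#!/usr/bin/env Rscript
# Graded cursor elimination (Show / Short- / Middle- / Long-hide): the
# longer the cursor has been gone when the perturbation arrives, the more
# uncertain the hand-state estimate should be -- does the long-latency
# reflex shrink monotonically while endpoint SD grows?  Writes results
# under results/exp3.

library(reflexvf)

b <- run_experiment(experiment_config(3, seed = 20260950L,
                                      out_dir = "results/exp3"))
st <- b$stats$table
ll <- st[st$measure == "ll" & st$analysis == "rm_anova_oneway", ]
es <- st[st$measure == "endpoint_sd" & st$analysis == "rm_anova_oneway", ]
cat(sprintf("[exp3] LL elimination effect: F(%d,%d) = %.2f, p = %.2e\n",
            ll$df1, ll$df2, ll$statistic, ll$p))
cat(sprintf("[exp3] endpoint-SD effect:    F(%d,%d) = %.2f, p = %.2e\n",
            es$df1, es$df2, es$statistic, es$p))
elim <- tapply(b$measures$cursor_elim_duration[b$measures$trial_type == "MP"],
               b$measures$cursor[b$measures$trial_type == "MP"], mean,
               na.rm = TRUE)
cat("[exp3] mean cursor-off time before the perturbation (s):\n")
print(round(elim, 3))
cr <- b$stats$correlation
cat(sprintf("[exp3] LL vs endpoint-SD: mean r = %.2f, CI [%.2f, %.2f]\n",
            cr$mean_r, cr$ci[1], cr$ci[2]))
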