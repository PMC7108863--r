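# small cohort configurations used across test files

tiny_cfg <- function(experiment_id, seed = 1L, ...) {
  generator_config(experiment_id, n_participants = 2, block_reps = 1,
                   seed = seed, ...)
}

# deterministic generator: no carrier, no noise, no trial-to-trial gain or
# latency variability, fixed movement duration and endpoints on target
exact_cfg <- function(experiment_id, seed = 1L, condition_effects = NULL,
                      ...) {
  if (is.null(condition_effects)) {
    condition_effects <- reflexvf:::default_condition_effects(experiment_id)
    condition_effects$endpoint_sd <-
      stats::setNames(rep(0, length(condition_effects$conditions)),
                      condition_effects$conditions)
  }
  generator_config(
    experiment_id, n_participants = 1, block_reps = 1, seed = seed,
    stochastic = FALSE,
    emg = list(gain_cv = 0, participant_scale_sd = 0, ll_between_sd = 0,
               latency_trial_jitter = 0, noise_sd = 0),
    endpoint = list(duration_sd = 0, participant_sd_cv = 0),
    condition_effects = condition_effects,
    jump = list(latency_jitter_max = 0),
    isometric = list(ref_mean = 1, duration = 1, noise_sd = 0),
    ...)
}

# brute-force per-sample successive t-test oracle built on stats::t.test
oracle_successive_latency <- function(a, b, times, alpha = 0.05,
                                      n_consecutive = 10,
                                      tail = "greater", search = c(0, 0.4)) {
  sel <- which(times >= search[1] & times <= search[2])
  p <- vapply(sel, function(j) {
    x <- a[, j]; y <- b[, j]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      m <- mean(x) - mean(y)
      if (tail == "greater") return(if (m > 0) 0 else 1)
      return(if (m < 0) 0 else 1)
    }
    stats::t.test(x, y, alternative = tail)$p.value
  }, numeric(1))
  ok <- p < alpha
  run <- 0L
  for (j in seq_along(ok)) {
    run <- if (ok[j]) run + 1L else 0L
    if (run == n_consecutive) return(times[sel[j - n_consecutive + 1L]])
  }
  NA_real_
}

# random small participant x condition long table
random_rm_table <- function(n, k, seed) {
  set.seed(seed)
  expand.grid(participant = seq_len(n), condition = letters[seq_len(k)],
              KEEP.OUT.ATTRS = FALSE) |>
    transform(value = stats::rnorm(n * k) +
                rep(stats::rnorm(n), k) + rep(stats::rnorm(k), each = n))
}

# one-way RM-ANOVA oracle via base aov with an Error stratum
oracle_rm_anova_F <- function(tbl) {
  fit <- stats::aov(value ~ condition + Error(factor(participant)),
                    data = tbl)
  s <- summary(fit)[["Error: Within"]][[1]]
  list(F = s["condition", "F value"], p = s["condition", "Pr(>F)"],
       df1 = s["condition", "Df"], df2 = s["Residuals", "Df"])
}
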