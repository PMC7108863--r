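# add a Gaussian bump to an envelope in place (evaluated within +/- 6 SD)
add_bump <- function(env, t, center, sd, peak) {
  if (peak == 0) return(env)
  fs <- 1 / (t[2L] - t[1L])
  lo <- max(1L, floor((center - 6 * sd) * fs) + 1L)
  hi <- min(length(t), ceiling((center + 6 * sd) * fs) + 1L)
  if (lo > hi) return(env)
  idx <- lo:hi
  env[idx] <- env[idx] + peak * exp(-0.5 * ((t[idx] - center) / sd)^2)
  env
}

# add a burst with a hard onset: gamma-like rise (t-t0)^2 exp(-(t-t0)/tau),
# zero before t0, unit peak at t0 + 2*tau -- used for corrective responses
# whose onset latency is itself an analysis target
add_onset_burst <- function(env, t, onset, tau, peak) {
  if (peak == 0) return(env)
  fs <- 1 / (t[2L] - t[1L])
  lo <- max(1L, floor(onset * fs) + 1L)
  hi <- min(length(t), ceiling((onset + 12 * tau) * fs) + 1L)
  if (lo > hi) return(env)
  idx <- lo:hi
  u <- pmax(t[idx] - onset, 0) / tau
  env[idx] <- env[idx] + peak * (u^2 * exp(-u)) / (4 * exp(-2))
  env
}

# trial-level gain: nonnegative Gaussian perturbation around the nominal value
draw_gain <- function(nominal, cv) {
  if (nominal == 0) return(0)
  max(0, stats::rnorm(1, nominal, cv * nominal))
}

#' Simulate two-channel surface EMG for one trial
#'
#' Builds nonnegative flexor and extensor envelopes (baseline + movement
#' burst + reflex bumps + corrective burst) and, in stochastic mode,
#' multiplies them by a unit-variance broadband carrier and adds sensor
#' noise, emulating raw surface EMG whose rectified mean tracks the envelope.
#'
#' @param kin output of [simulate_trajectory()] (uses `t0` and `duration` for
#'   the movement-related burst).
#' @param cfg a [generator_config()].
#' @param condition condition key (long-latency multiplier lookup).
#' @param mp_onset_time perturbation onset (s) or `NA`.
#' @param jump list with `onset_time`, `muscle` (`"flexor"`/`"extensor"`),
#'   `latency` (s, EMG onset after the jump), or `NULL`.
#' @param participant list with `emg_scale` and `ll_scale` (defaults 1).
#' @return list with `flexor` and `extensor` series at `fs_emg`.
#' @export
simulate_emg <- function(kin, cfg, condition, mp_onset_time = NA,
                         jump = NULL,
                         participant = list(emg_scale = 1, ll_scale = 1)) {
  if (!condition %in% cfg$condition_effects$conditions) {
    stop("unknown condition label: ", condition)
  }
  p <- cfg$emg
  t <- emg_time_axis(cfg)
  n <- length(t)

  env_f <- rep(p$bga_mean, n)
  env_e <- rep(p$bga_mean, n)

  # movement-related agonist (flexor) burst, evaluated inside the movement
  mv <- draw_gain(p$mv_gain, p$gain_cv)
  if (mv > 0) {
    dt <- t[2L] - t[1L]
    i0 <- max(1L, floor(kin$t0 / dt) + 1L)
    i1 <- min(n, ceiling((kin$t0 + kin$duration) / dt) + 1L)
    idx <- i0:i1
    env_f[idx] <- env_f[idx] +
      mv * min_jerk_speed_norm(t[idx], kin$t0, kin$duration)
  }

  if (!is.na(mp_onset_time)) {
    mult <- cfg$condition_effects$ll_mult[[condition]]
    jit <- stats::rnorm(1, 0, p$latency_trial_jitter)
    sl <- draw_gain(p$sl_gain, p$gain_cv)
    ll <- draw_gain(p$ll_gain * mult * participant$ll_scale, p$gain_cv)
    vol <- draw_gain(p$vol_gain, p$gain_cv)
    if (cfg$mp$direction == "extension") {
      # extension MP stretches the flexor
      env_f <- add_bump(env_f, t, mp_onset_time + p$sl_latency + jit,
                        p$sl_width, sl)
      env_f <- add_bump(env_f, t, mp_onset_time + p$ll_latency + jit,
                        p$ll_width, ll)
      env_f <- add_bump(env_f, t, mp_onset_time + p$vol_latency + jit,
                        p$vol_width, vol)
    } else {
      env_e <- add_bump(env_e, t, mp_onset_time + p$sl_latency + jit,
                        p$sl_width, sl)
      env_e <- add_bump(env_e, t, mp_onset_time + p$ll_latency + jit,
                        p$ll_width, ll)
      env_e <- add_bump(env_e, t, mp_onset_time + p$vol_latency + jit,
                        p$vol_width, vol)
    }
  }

  if (!is.null(jump)) {
    g <- draw_gain(cfg$jump$response_gain, p$gain_cv)
    # corrective burst rises at the configured response latency and peaks
    # 2 tau later
    onset <- jump$onset_time + jump$latency
    if (jump$muscle == "flexor") {
      env_f <- add_onset_burst(env_f, t, onset, cfg$jump$width, g)
    } else {
      env_e <- add_onset_burst(env_e, t, onset, cfg$jump$width, g)
    }
  }

  scale <- participant$emg_scale
  if (isTRUE(cfg$stochastic)) {
    # envelope-scaled carrier plus independent sensor noise, drawn as one
    # Gaussian per sample with the combined SD
    flexor <- scale * sqrt(env_f^2 + p$noise_sd^2) * stats::rnorm(n)
    extensor <- scale * sqrt(env_e^2 + p$noise_sd^2) * stats::rnorm(n)
  } else {
    flexor <- scale * env_f
    extensor <- scale * env_e
  }
  list(flexor = flexor, extensor = extensor)
}

# Isometric reference contraction (1 Nm hold) for one participant, one
# channel; same envelope-times-carrier construction as the trial EMG so that
# normalization cancels the rectification constant.
simulate_isometric_reference <- function(cfg, emg_scale = 1) {
  n <- round(cfg$isometric$duration * cfg$fs_emg)
  env <- rep(cfg$isometric$ref_mean, n)
  if (isTRUE(cfg$stochastic)) {
    emg_scale * sqrt(env^2 + cfg$isometric$noise_sd^2) * stats::rnorm(n)
  } else {
    emg_scale * env
  }
}
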