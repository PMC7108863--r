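#' Minimum-jerk position profile
#'
#' @param t time vector (s).
#' @param start start position (deg).
#' @param amplitude movement amplitude (deg).
#' @param t0 movement start time (s).
#' @param duration movement duration (s).
#' @return position at `t`; held at `start` before `t0` and at
#'   `start + amplitude` after `t0 + duration`.
#' @export
min_jerk_pos <- function(t, start, amplitude, t0, duration) {
  s <- pmin(pmax((t - t0) / duration, 0), 1)
  start + amplitude * (10 * s^3 - 15 * s^4 + 6 * s^5)
}

# same profile for a uniformly sampled axis, evaluating the polynomial only
# inside the movement window (hot path of the generator)
min_jerk_pos_fast <- function(t, start, amplitude, t0, duration) {
  n <- length(t)
  dt <- t[2L] - t[1L]
  i0 <- max(1L, floor((t0 - t[1L]) / dt) + 1L)
  i1 <- min(n, ceiling((t0 + duration - t[1L]) / dt) + 1L)
  if (i0 > n) return(rep(start, n))
  out <- numeric(n)
  if (i0 > 1L) out[seq_len(i0 - 1L)] <- start
  if (i1 < n) out[(i1 + 1L):n] <- start + amplitude
  idx <- i0:i1
  s <- pmin(pmax((t[idx] - t0) / duration, 0), 1)
  out[idx] <- start + amplitude * (10 * s^3 - 15 * s^4 + 6 * s^5)
  out
}

# normalized minimum-jerk speed profile (peak 1), zero outside the movement
min_jerk_speed_norm <- function(t, t0, duration) {
  s <- (t - t0) / duration
  v <- numeric(length(t))
  inside <- s > 0 & s < 1
  si <- s[inside]
  v[inside] <- 16 * si^2 * (1 - si)^2
  v
}

#' Simulate one unperturbed wrist-flexion trajectory
#'
#' Minimum-jerk flexion from the start angle to an endpoint drawn from
#' `Normal(target, endpoint_sd)`, with small Gaussian jitter on movement
#' duration; the angle is held constant before movement onset and after
#' movement end.
#'
#' @param cfg a [generator_config()].
#' @param condition condition key (must appear in
#'   `cfg$condition_effects$conditions`), used to look up the endpoint SD.
#' @param target_angle target angle (deg); defaults to the standard target.
#' @param sd_scale multiplier on the condition endpoint SD (per-participant
#'   heterogeneity).
#' @param seed optional integer; if given, the trajectory is drawn under a
#'   local seed.
#' @return list with `time`, `angle` (deg at `fs_kin`), `endpoint`,
#'   `duration`, `t0`.
#' @export
simulate_trajectory <- function(cfg, condition, target_angle = NULL,
                                sd_scale = 1, seed = NULL) {
  if (!condition %in% cfg$condition_effects$conditions) {
    stop("unknown condition label: ", condition)
  }
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  if (is.null(target_angle)) target_angle <- cfg$movement$target_angle
  sd_cond <- cfg$condition_effects$endpoint_sd[[condition]] * sd_scale
  endpoint <- stats::rnorm(1, target_angle, sd_cond)
  duration <- cfg$movement$duration +
    stats::rnorm(1, 0, cfg$endpoint$duration_sd)
  duration <- min(max(duration, 0.6 * cfg$movement$duration),
                  1.4 * cfg$movement$duration)
  time <- kin_time_axis(cfg)
  angle <- min_jerk_pos_fast(time, cfg$movement$start_angle,
                             endpoint - cfg$movement$start_angle,
                             cfg$move_onset, duration)
  list(time = time, angle = angle, endpoint = endpoint,
       duration = duration, t0 = cfg$move_onset)
}

# Deflection of the wrist plant I*phi'' + b*phi' = tau(t) to a half-sine
# torque pulse, integrated with RK4 at 1/fs and returned in deg.  The plant is
# linear and time-invariant, so the response is computed once per
# (mp, wrist, fs, n) and cached.
.mp_cache <- new.env(parent = emptyenv())

mp_deflection <- function(mp, wrist, fs, n_samples) {
  key <- paste(mp$peak_torque, mp$duration, mp$direction, wrist$inertia,
               wrist$damping, fs, sep = "|")
  hit <- .mp_cache[[key]]
  if (!is.null(hit) && length(hit) >= n_samples) {
    return(hit[seq_len(n_samples)])
  }
  # integrate a little beyond the longest request so the cache is reusable
  n_int <- max(n_samples, length(hit), 2L)
  sgn <- if (mp$direction == "extension") -1 else 1
  tau <- function(t) {
    if (t >= 0 && t <= mp$duration) {
      sgn * mp$peak_torque * sin(pi * t / mp$duration)
    } else 0
  }
  I <- wrist$inertia; b <- wrist$damping
  dt <- 1 / fs
  phi <- numeric(n_int)
  x <- c(0, 0)  # rad, rad/s
  deriv <- function(t, x) c(x[2], (tau(t) - b * x[2]) / I)
  for (i in seq_len(n_int - 1L)) {
    t <- (i - 1L) * dt
    k1 <- deriv(t, x)
    k2 <- deriv(t + dt / 2, x + dt / 2 * k1)
    k3 <- deriv(t + dt / 2, x + dt / 2 * k2)
    k4 <- deriv(t + dt, x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    phi[i + 1L] <- x[1]
  }
  out <- phi * 180 / pi
  .mp_cache[[key]] <- out
  out[seq_len(n_samples)]
}

#' Superimpose a mechanical-perturbation response on a trajectory
#'
#' The perturbation onset is the first sample at which the angle crosses the
#' trigger angle in the movement direction; from that sample on, the response
#' of a second-order rotational plant (inertia + damping) to the half-sine
#' torque pulse is added.  Samples before the onset are unchanged.
#'
#' @param angle angle series (deg) at `fs`.
#' @param fs sampling rate (Hz).
#' @param mp an [mp_params()] object.
#' @param wrist list with `inertia` and `damping`.
#' @return list with `angle` (perturbed series), `onset_index`, `onset_time`
#'   and `triggered` (FALSE, series unchanged, when the trigger angle is
#'   never crossed).
#' @export
apply_perturbation <- function(angle, fs, mp, wrist) {
  idx <- which(angle >= mp$trigger_angle)
  if (length(idx) == 0L) {
    return(list(angle = angle, onset_index = NA_integer_,
                onset_time = NA_real_, triggered = FALSE))
  }
  onset <- idx[1L]
  n_rest <- length(angle) - onset + 1L
  defl <- mp_deflection(mp, wrist, fs, n_rest)
  out <- angle
  out[onset:length(angle)] <- out[onset:length(angle)] + defl
  list(angle = out, onset_index = onset, onset_time = (onset - 1L) / fs,
       triggered = TRUE)
}

#' Map a wrist angle to the on-screen cursor position
#'
#' The base cursor position is `(-alpha * theta, 0)` cm; the whole workspace
#' may be rotated about the origin (positive rotation clockwise on screen,
#' i.e. the standard rotation matrix in the screen frame with y pointing
#' down) or mirror-reversed (x negated).  When the mapping's elimination rule
#' is active the cursor is flagged hidden.
#'
#' @param theta wrist angle(s) in deg (flexion positive).
#' @param mapping a [cursor_mapping()].
#' @return data frame with columns `x`, `y` (cm) and `visible`.
#' @export
cursor_transform <- function(theta, mapping) {
  x <- -mapping$alpha * theta
  y <- rep(0, length(theta))
  if (isTRUE(mapping$mirror)) x <- -x
  r <- mapping$rotation * pi / 180
  xr <- x * cos(r) - y * sin(r)
  yr <- x * sin(r) + y * cos(r)
  visible <- switch(mapping$visibility,
    "show" = rep(TRUE, length(theta)),
    "hide-at-onset" = rep(FALSE, length(theta)),
    "hide-at-angle" = theta < mapping$hide_angle)
  data.frame(x = xr, y = yr, visible = visible)
}

# Angle at which the cursor disappears for a cursor-condition label, deg
# (experiment 3 thresholds are flexion offsets from the -22.5 deg start).
hide_angle_for <- function(cursor, start_angle = -22.5) {
  switch(cursor,
    "Short-hide"  = start_angle + 33.8,
    "Middle-hide" = start_angle + 16.9,
    "Long-hide"   = start_angle + 1.0,
    NULL)
}

# cached kinematic time axis for a configuration
.axis_cache <- new.env(parent = emptyenv())

kin_time_axis <- function(cfg) {
  key <- paste("kin", cfg$trial_duration, cfg$fs_kin, sep = "|")
  hit <- .axis_cache[[key]]
  if (is.null(hit)) {
    n <- round(cfg$trial_duration * cfg$fs_kin)
    hit <- seq.int(0, n - 1L) / cfg$fs_kin
    .axis_cache[[key]] <- hit
  }
  hit
}

emg_time_axis <- function(cfg) {
  key <- paste("emg", cfg$trial_duration, cfg$fs_emg, sep = "|")
  hit <- .axis_cache[[key]]
  if (is.null(hit)) {
    n <- round(cfg$trial_duration * cfg$fs_emg)
    hit <- seq.int(0, n - 1L) / cfg$fs_emg
    .axis_cache[[key]] <- hit
  }
  hit
}
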