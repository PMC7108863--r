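#' Derive velocity and acceleration from a wrist-angle series
#'
#' Velocity is the first difference of the angle scaled by the sampling rate,
#' low-pass filtered at 40 Hz with a zero-phase fourth-order Butterworth
#' filter; acceleration is obtained from the filtered velocity by the same
#' rule (difference first, then filter).
#'
#' @param angle angle series in deg, uniformly sampled.
#' @param fs sampling rate in Hz (500 in the recordings emulated here).
#' @param cutoff low-pass cutoff in Hz.
#' @param acceleration derive acceleration as well (skip when only velocity
#'   is needed).
#' @return a data frame of class `kinematic_trace` with columns `time`,
#'   `angle`, `velocity` (deg/s) and `acceleration` (deg/s^2, `NA` when not
#'   derived), and attribute `fs`.
#' @export
derive_kinematics <- function(angle, fs, cutoff = 40, acceleration = TRUE) {
  n <- length(angle)
  if (n < 32L) {
    stop("angle series too short to differentiate and filter (", n,
         " samples; need >= 32)")
  }
  diff_scaled <- function(x) {
    d <- diff(x) * fs
    c(d, d[length(d)])
  }
  velocity <- butter_zerophase(diff_scaled(angle), fs, cutoff, "low")
  accel <- if (acceleration) {
    butter_zerophase(diff_scaled(velocity), fs, cutoff, "low")
  } else {
    rep(NA_real_, n)
  }
  out <- data.frame(time = seq.int(0, n - 1L) / fs, angle = angle,
                    velocity = velocity, acceleration = accel)
  attr(out, "fs") <- fs
  class(out) <- c("kinematic_trace", "data.frame")
  out
}

#' Detect movement start and end from the velocity profile
#'
#' Start is the first sample whose absolute velocity exceeds 5% of the peak
#' velocity; end is the first sample after the peak whose absolute velocity
#' falls below that threshold and stays below it continuously for 300 ms.
#' Peak velocity is the signed flexion-direction maximum; absolute values are
#' used only in the threshold tests.  The first and last `edge_exclude`
#' seconds are excluded from the search (filter edges).
#'
#' @param trace a `kinematic_trace` from [derive_kinematics()].
#' @param threshold_frac threshold as a fraction of peak velocity.
#' @param settle_time time (s) the velocity must remain below threshold.
#' @param edge_exclude time (s) ignored at both ends of the series.
#' @return list with `start_time`, `end_time`, `peak_time`, `peak_velocity`
#'   and `unterminated` (TRUE when the settle criterion is never met; then
#'   `end_time` is `NA`).
#' @export
detect_movement_bounds <- function(trace, threshold_frac = 0.05,
                                   settle_time = 0.3, edge_exclude = 0.05) {
  fs <- attr(trace, "fs")
  v <- trace$velocity
  n <- length(v)
  lo <- max(1L, ceiling(edge_exclude * fs) + 1L)
  hi <- min(n, n - ceiling(edge_exclude * fs))
  idx <- lo:hi
  if (all(v[idx] <= 0)) stop("no positive (flexion-direction) velocity peak")
  peak_i <- idx[which.max(v[idx])]
  v_peak <- v[peak_i]
  thr <- threshold_frac * v_peak

  above <- which(abs(v[idx]) > thr)
  if (length(above) == 0L) stop("velocity never exceeds threshold")
  start_i <- idx[above[1L]]

  need <- ceiling(settle_time * fs)
  below <- abs(v) < thr
  end_i <- NA_integer_
  j <- peak_i + 1L
  while (j <= hi) {
    if (below[j]) {
      run_end <- min(j + need - 1L, n)
      if (run_end - j + 1L >= need && all(below[j:run_end])) {
        end_i <- j
        break
      }
      # skip past the run: to the first non-below sample inside it, or past
      # its end when the series ran out before the criterion was met
      bad <- which(!below[j:run_end])
      j <- if (length(bad) == 0L) run_end + 1L else j + bad[1L]
    } else {
      j <- j + 1L
    }
  }
  list(start_time = (start_i - 1L) / fs,
       end_time = if (is.na(end_i)) NA_real_ else (end_i - 1L) / fs,
       peak_time = (peak_i - 1L) / fs, peak_velocity = v_peak,
       unterminated = is.na(end_i))
}

#' Per-trial movement metrics
#'
#' @param trace a `kinematic_trace`.
#' @param mp_onset_time perturbation onset in s, or `NA`; when present,
#'   `velocity_at_mp` and `angle_at_mp` are read from the sample immediately
#'   preceding the onset.
#' @inheritParams detect_movement_bounds
#' @return list with `start_time`, `end_time`, `duration`, `endpoint` (deg,
#'   angle at the movement end), `peak_velocity` (deg/s), `velocity_at_mp`
#'   and `angle_at_mp` (`NA` when unperturbed) and `unterminated`.
#' @export
movement_metrics <- function(trace, mp_onset_time = NA,
                             threshold_frac = 0.05, settle_time = 0.3,
                             edge_exclude = 0.05) {
  fs <- attr(trace, "fs")
  b <- detect_movement_bounds(trace, threshold_frac, settle_time, edge_exclude)
  endpoint <- if (b$unterminated) NA_real_ else {
    trace$angle[round(b$end_time * fs) + 1L]
  }
  vel_mp <- ang_mp <- NA_real_
  if (!is.na(mp_onset_time)) {
    i <- max(1L, round(mp_onset_time * fs))  # sample immediately before onset
    vel_mp <- trace$velocity[i]
    ang_mp <- trace$angle[i]
  }
  list(start_time = b$start_time, end_time = b$end_time,
       duration = if (b$unterminated) NA_real_ else b$end_time - b$start_time,
       endpoint = endpoint, peak_velocity = b$peak_velocity,
       velocity_at_mp = vel_mp, angle_at_mp = ang_mp,
       unterminated = b$unterminated)
}

#' Endpoint variability per participant and condition
#'
#' Sample standard deviation (n-1 denominator) of movement endpoints of
#' unperturbed trials, per grouping cell.  Cells with fewer than two
#' surviving trials are returned as `NA` with a warning.
#'
#' @param endpoints numeric vector of endpoint angles (deg).
#' @param by data frame (or list) of grouping columns, same length.
#' @return data frame with the grouping columns, `endpoint_sd` and `n_trials`.
#' @export
endpoint_sd <- function(endpoints, by) {
  by <- as.data.frame(by, stringsAsFactors = FALSE)
  stopifnot(nrow(by) == length(endpoints))
  key <- interaction(by, drop = TRUE, lex.order = TRUE)
  split_e <- split(endpoints, key)
  split_by <- split(by, key)
  out <- do.call(rbind, lapply(names(split_e), function(k) {
    e <- split_e[[k]]
    row <- split_by[[k]][1L, , drop = FALSE]
    row$endpoint_sd <- if (length(e) >= 2L) stats::sd(e) else NA_real_
    row$n_trials <- length(e)
    row
  }))
  rownames(out) <- NULL
  if (any(is.na(out$endpoint_sd))) {
    warning("endpoint SD undefined for ", sum(is.na(out$endpoint_sd)),
            " cell(s) with fewer than 2 trials")
  }
  out
}
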