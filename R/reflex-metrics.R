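#' Event-relative analysis windows
#'
#' Fixed windows (s, relative to the event onset) in which rectified EMG is
#' averaged: background activity −50-0 ms before the perturbation,
#' short-latency 30-50 ms, long-latency 50-100 ms after it, and the
#' visuomotor-response window 115-175 ms after a target jump.  All windows
#' are half-open `[lo, hi)` so the 50 ms sample is not counted in both the
#' short- and long-latency components.
#'
#' @param v_emg visuomotor window; override with [v_emg_window()] output when
#'   recomputing it from cohort latencies.
#' @return named list of two-element numeric vectors.
#' @export
analysis_windows <- function(v_emg = c(0.115, 0.175)) {
  list(bga = c(-0.050, 0), short_latency = c(0.030, 0.050),
       long_latency = c(0.050, 0.100), v_emg = v_emg)
}

#' Mean of an event-aligned signal inside a half-open time window
#'
#' @param x numeric signal.
#' @param times event-relative times (s) of the samples of `x`.
#' @param window two-element numeric `(lo, hi)`; samples with
#'   `lo <= t < hi` are averaged.
#' @return arithmetic mean of the in-window samples.
#' @export
window_mean <- function(x, times, window) {
  stopifnot(length(x) == length(times), length(window) == 2L)
  eps <- 1e-9
  dt <- if (length(times) > 1L) times[2L] - times[1L] else 0
  # half-open upper bound: the last required sample is the one just below hi
  if (window[1] < min(times) - eps || window[2] - dt > max(times) + eps) {
    stop("window [", window[1], ", ", window[2],
         ") is outside the available data range [",
         min(times), ", ", max(times), "]")
  }
  sel <- times >= window[1] - eps & times < window[2] - eps
  if (!any(sel)) stop("no samples inside window")
  mean(x[sel])
}

#' Isometric reference amplitude for EMG normalization
#'
#' Mean rectified amplitude of the reference recording (a static hold
#' against the 1 Nm reference torque), used to normalize all window means so
#' that participants are comparable.  The reference epoch is rectified and
#' averaged directly: a static calibration hold carries no movement
#' artifact, and a constant reference must normalize to its own amplitude.
#'
#' @param reference raw reference EMG recording (one channel).
#' @param fs sampling rate in Hz (kept in the signature for interface
#'   symmetry with the trial pipeline).
#' @return reference amplitude (a.u., > 0).
#' @export
isometric_reference <- function(reference, fs) {
  amp <- mean(abs(reference))
  if (!is.finite(amp) || amp <= 0) {
    stop("isometric reference amplitude is not positive; ",
         "participant cannot be normalized")
  }
  amp
}

#' Quantify stretch-reflex components of one perturbed trial
#'
#' Means of the rectified EMG of the stretched muscle in the background,
#' short-latency and long-latency windows relative to the perturbation
#' onset, divided by the participant's isometric reference amplitude.
#'
#' @param rect an `emg_trace` with `stage = "rectified"`.
#' @param mp_onset_time perturbation onset (s from trial start); the trial
#'   must be perturbed.
#' @param mp_direction `"extension"` (flexor stretched) or `"flexion"`
#'   (extensor stretched).
#' @param reference_amplitude output of [isometric_reference()] for the
#'   stretched muscle.
#' @param windows list from [analysis_windows()].
#' @return list with `muscle`, `bga`, `sl`, `ll` (normalized units).
#' @export
quantify_stretch_reflex <- function(rect, mp_onset_time, mp_direction,
                                    reference_amplitude,
                                    windows = analysis_windows()) {
  stopifnot(inherits(rect, "emg_trace"))
  if (rect$stage != "rectified") {
    stop("window statistics are computed on rectified EMG, got stage '",
         rect$stage, "'")
  }
  if (is.na(mp_onset_time)) {
    stop("trial carries no perturbation; stretch-reflex windows undefined")
  }
  muscle <- if (mp_direction == "extension") "flexor" else "extensor"
  x <- rect[[muscle]]
  rel <- rect$time - mp_onset_time
  list(muscle = muscle,
       bga = window_mean(x, rel, windows$bga) / reference_amplitude,
       sl = window_mean(x, rel, windows$short_latency) / reference_amplitude,
       ll = window_mean(x, rel, windows$long_latency) / reference_amplitude)
}

#' Quantify the reflexive visuomotor response of one target-jump trial
#'
#' Mean rectified EMG of one muscle in the visuomotor window relative to the
#' jump onset, normalized by the isometric reference.  By design the window
#' mean is not background-subtracted (set `subtract_bga = TRUE` for the
#' alternative reading).
#'
#' @param rect an `emg_trace` with `stage = "rectified"`.
#' @param jump_onset_time target-jump onset (s from trial start).
#' @param muscle `"flexor"` or `"extensor"`.
#' @inheritParams quantify_stretch_reflex
#' @param subtract_bga subtract the pre-jump background window mean.
#' @return normalized v-EMG amplitude.
#' @export
quantify_v_emg <- function(rect, jump_onset_time, muscle,
                           reference_amplitude,
                           windows = analysis_windows(),
                           subtract_bga = FALSE) {
  stopifnot(inherits(rect, "emg_trace"), rect$stage == "rectified",
            muscle %in% c("flexor", "extensor"))
  if (is.na(jump_onset_time)) stop("trial carries no target jump")
  rel <- rect$time - jump_onset_time
  v <- window_mean(rect[[muscle]], rel, windows$v_emg) / reference_amplitude
  if (subtract_bga) {
    v <- v - window_mean(rect[[muscle]], rel, windows$bga) /
      reference_amplitude
  }
  v
}

#' Difference of forward- and backward-jump visuomotor responses
#'
#' @param v_forward,v_backward mean v-EMG for forward and backward target
#'   jumps (same participant, condition and muscle).
#' @return `v_forward - v_backward` (delta v-EMG).
#' @export
delta_v_emg <- function(v_forward, v_backward) v_forward - v_backward

#' Visuomotor analysis window from cohort response latencies
#'
#' The window runs from 5 ms before the shortest pro-task EMG latency to
#' 5 ms before the shortest anti-task EMG latency, reproducing the
#' 120/180 ms to 115-175 ms mapping.
#'
#' @param pro_latency,anti_latency shortest cohort EMG response latencies in
#'   s for the pro and anti tasks.
#' @param margin safety margin in s subtracted from both latencies.
#' @return two-element numeric window (s).
#' @export
v_emg_window <- function(pro_latency, anti_latency, margin = 0.005) {
  stopifnot(pro_latency < anti_latency)
  c(pro_latency - margin, anti_latency - margin)
}
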