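#' Create a raw EMG trace object
#'
#' @param flexor,extensor raw EMG series in arbitrary units.
#' @param fs sampling rate in Hz (2000 in the recordings emulated here).
#' @return an `emg_trace` list with `time`, `flexor`, `extensor`, `fs` and
#'   `stage = "raw"`.
#' @export
emg_trace <- function(flexor, extensor, fs) {
  stopifnot(length(flexor) == length(extensor))
  structure(list(time = seq.int(0, length(flexor) - 1L) / fs,
                 flexor = flexor, extensor = extensor, fs = fs,
                 stage = "raw"),
            class = "emg_trace")
}

#' High-pass filter and rectify raw EMG
#'
#' Applies a zero-phase fourth-order Butterworth high-pass at 50 Hz to remove
#' motion artifacts, then full-wave rectifies.  The result (rEMG) is the
#' signal on which all window statistics are computed.
#'
#' @param trace an `emg_trace` with `stage = "raw"`.
#' @param cutoff high-pass cutoff in Hz.
#' @return the trace with both channels rectified and `stage = "rectified"`.
#' @export
preprocess_emg <- function(trace, cutoff = 50) {
  stopifnot(inherits(trace, "emg_trace"))
  if (trace$stage != "raw") {
    stop("preprocess_emg expects a raw trace, got stage '", trace$stage, "'")
  }
  trace$flexor <- rectify_channel(trace$flexor, trace$fs, cutoff)
  trace$extensor <- rectify_channel(trace$extensor, trace$fs, cutoff)
  trace$stage <- "rectified"
  trace
}

#' Low-pass envelope of rectified EMG
#'
#' Zero-phase fourth-order Butterworth low-pass at 100 Hz, clipped at zero
#' (backward-forward filtering of sharp transients can ring slightly
#' negative).  The envelope is used for visualization and for response-onset
#' detection; window statistics stay on the rectified signal.
#'
#' @param trace an `emg_trace` with `stage = "rectified"`.
#' @param cutoff low-pass cutoff in Hz.
#' @return the trace with `stage = "envelope"`.
#' @export
emg_envelope <- function(trace, cutoff = 100) {
  stopifnot(inherits(trace, "emg_trace"))
  if (trace$stage != "rectified") {
    stop("emg_envelope expects a rectified trace, got stage '",
         trace$stage, "'")
  }
  trace$flexor <- pmax(0, butter_zerophase(trace$flexor, trace$fs, cutoff,
                                           "low"))
  trace$extensor <- pmax(0, butter_zerophase(trace$extensor, trace$fs,
                                             cutoff, "low"))
  trace$stage <- "envelope"
  trace
}

#' Align single-channel trial series on an event
#'
#' Extracts a fixed event-relative window from each trial series (all trials
#' share the sampling rate, so no interpolation is involved) and stacks them
#' into a trials-by-time matrix together with the ensemble mean.  Trials
#' whose event is missing, or whose window is not fully covered by data, are
#' excluded and reported.
#'
#' @param series list of numeric vectors (one per trial).
#' @param event_times numeric vector of event times (s from trial start);
#'   `NA` marks a missing event.
#' @param fs sampling rate in Hz.
#' @param window two-element numeric, window around the event in s
#'   (default `c(-0.1, 0.3)`).
#' @param trial_ids optional identifiers for the rows.
#' @return an `aligned_ensemble` list: `time` (relative axis, 0 at the
#'   event), `data` (matrix, one row per surviving trial), `mean` (ensemble
#'   average), `trial_ids`, `excluded` (ids dropped).
#' @export
align_to_event <- function(series, event_times, fs, window = c(-0.1, 0.3),
                           trial_ids = seq_along(series)) {
  stopifnot(length(series) == length(event_times),
            length(window) == 2L, window[1] < window[2])
  rel_idx <- seq.int(round(window[1] * fs), round(window[2] * fs))
  keep <- logical(length(series))
  rows <- vector("list", length(series))
  for (i in seq_along(series)) {
    if (is.na(event_times[[i]])) next
    ev <- round(event_times[[i]] * fs) + 1L
    idx <- ev + rel_idx
    if (idx[1L] < 1L || idx[length(idx)] > length(series[[i]])) next
    rows[[i]] <- series[[i]][idx]
    keep[i] <- TRUE
  }
  if (!any(keep)) stop("no trial covers the requested window")
  data <- do.call(rbind, rows[keep])
  rownames(data) <- trial_ids[keep]
  structure(list(time = rel_idx / fs, data = data, mean = colMeans(data),
                 trial_ids = trial_ids[keep],
                 excluded = trial_ids[!keep]),
            class = "aligned_ensemble")
}
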