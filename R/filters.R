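#' Zero-phase Butterworth filtering with reflective padding
#'
#' Applies a Butterworth filter forward and backward (zero phase lag) after
#' extending the series by odd-symmetric reflection at both ends, so that the
#' filter state settles outside the data and edge transients do not leak into
#' the returned samples.  This is the filtering primitive used everywhere in
#' the package: 40 Hz low-pass for kinematic differentiation, 50 Hz high-pass
#' for EMG artifact removal, 100 Hz low-pass for the EMG envelope.
#'
#' @param x numeric vector, uniformly sampled.
#' @param fs sampling frequency in Hz.
#' @param cutoff cutoff frequency in Hz (must lie in (0, fs/2)).
#' @param type `"low"` or `"high"`.
#' @param order filter order (default 4, used throughout the pipeline).
#' @return numeric vector, same length as `x`.
#' @export
butter_zerophase <- function(x, fs, cutoff, type = c("low", "high"), order = 4) {
  type <- match.arg(type)
  n <- length(x)
  if (n < 8L * order) {
    stop("series too short for zero-phase filtering: need at least ",
         8L * order, " samples, got ", n)
  }
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stop("cutoff must lie strictly between 0 and fs/2")
  }
  flt <- butter_cached(order, cutoff / (fs / 2), type)
  # reflective padding: at least 3 filter lengths, and at least 3 periods of
  # the cutoff so that low-frequency transients settle
  npad <- max(3L * (length(flt$b) - 1L), ceiling(3 * fs / cutoff))
  npad <- min(npad, n - 1L)
  head_pad <- 2 * x[1L] - x[seq(npad + 1L, 2L)]
  tail_pad <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  xx <- c(head_pad, x, tail_pad)
  y <- iir_pass(flt, xx)
  y <- rev(iir_pass(flt, rev(y)))
  y[seq.int(npad + 1L, npad + n)]
}

.butter_cache <- new.env(parent = emptyenv())

# Butterworth design plus the steady-state initial filter state (the
# state that makes a constant input produce a constant output from the
# first sample), cached per (order, cutoff, type)
butter_cached <- function(order, w, type) {
  key <- paste(order, w, type, sep = "|")
  hit <- .butter_cache[[key]]
  if (is.null(hit)) {
    flt <- signal::butter(order, w, type = type)
    b <- flt$b / flt$a[1L]
    a <- flt$a / flt$a[1L]
    nf <- max(length(a), length(b))
    b <- c(b, numeric(nf - length(b)))
    a <- c(a, numeric(nf - length(a)))
    # steady-state state vector: solve (I - C^T) zi = b[-1] - a[-1] b[1]
    # with C the companion matrix of a
    comp <- matrix(0, nf - 1L, nf - 1L)
    comp[1L, ] <- -a[-1L]
    if (nf > 2L) comp[cbind(2:(nf - 1L), 1:(nf - 2L))] <- 1
    zi <- solve(diag(nf - 1L) - t(comp), b[-1L] - a[-1L] * b[1L])
    hit <- list(b = b, a = a, zi = zi)
    .butter_cache[[key]] <- hit
  }
  hit
}

# one causal IIR pass with steady-state initialisation at the first sample
iir_pass <- function(flt, x) {
  iir_filter_cpp(flt$b, flt$a, x, flt$zi * x[1L])
}
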