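#' Response-onset detection by successive t-tests
#'
#' At every post-event sample, a one-tailed two-sample (Welch) t-test
#' compares the two aligned ensembles; the response onset is the first time
#' at which the p-values fall below `alpha` for at least `n_consecutive`
#' consecutive samples.  The default run lengths follow the analysis they
#' emulate: 10 consecutive samples for acceleration ensembles, 50 for EMG
#' envelopes.
#'
#' @param a,b trials-by-time matrices on a common event-relative time axis
#'   (e.g. forward- and backward-jump ensembles), at least 2 trials each.
#' @param times event-relative time axis (s), 0 at the event.
#' @param alpha significance threshold per sample.
#' @param n_consecutive required run length of sub-alpha p-values.
#' @param tail `"greater"` tests mean(a) > mean(b), `"less"` the reverse;
#'   the direction is an explicit argument so the expected sign of the
#'   divergence is stated, never inferred.
#' @param search two-element numeric, time range searched (s relative to the
#'   event; default onset to +400 ms, the correction deadline).
#' @return a `latency_result` list: `onset_time` (s, `NA` when the criterion
#'   is never met), `detected`, `n_consecutive`, `alpha`, `tail`, and the
#'   audit series `p_values` with its `p_times`.
#' @export
successive_ttest_latency <- function(a, b, times, alpha = 0.05,
                                     n_consecutive = 10,
                                     tail = c("greater", "less"),
                                     search = c(0, 0.4)) {
  tail <- match.arg(tail)
  if (ncol(a) != length(times) || ncol(b) != length(times)) {
    stop("ensembles and time axis have mismatched lengths")
  }
  if (nrow(a) < 2L || nrow(b) < 2L) {
    stop("need at least 2 trials per ensemble")
  }
  stopifnot(n_consecutive >= 1)
  sel <- which(times >= search[1] & times <= search[2])
  p <- welch_onetailed_p(a[, sel, drop = FALSE], b[, sel, drop = FALSE], tail)
  onset_idx <- first_run_start(p < alpha, n_consecutive)
  structure(list(
    onset_time = if (is.na(onset_idx)) NA_real_ else times[sel[onset_idx]],
    detected = !is.na(onset_idx),
    n_consecutive = n_consecutive, alpha = alpha, tail = tail,
    p_values = p, p_times = times[sel]),
    class = "latency_result")
}

# vectorized per-column one-tailed Welch t-test p-values
welch_onetailed_p <- function(a, b, tail) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2L, stats::var); vb <- apply(b, 2L, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  # degenerate columns: both ensembles constant
  zero <- se2 == 0
  p <- numeric(length(tstat))
  if (tail == "greater") {
    p[!zero] <- stats::pt(tstat[!zero], df[!zero], lower.tail = FALSE)
    p[zero] <- ifelse(ma[zero] > mb[zero], 0, 1)
  } else {
    p[!zero] <- stats::pt(tstat[!zero], df[!zero], lower.tail = TRUE)
    p[zero] <- ifelse(ma[zero] < mb[zero], 0, 1)
  }
  p
}

# index of the first element starting a run of >= k TRUEs, NA if none
first_run_start <- function(x, k) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= k)
  if (length(hit) == 0L) NA_integer_ else starts[hit[1L]]
}

#' Shortest detected response latency across a cohort
#'
#' @param latencies numeric vector of per-participant onset times (s);
#'   `NA` marks participants in whom no onset was detected.
#' @return the minimum detected latency (s).
#' @export
cohort_shortest_latency <- function(latencies) {
  ok <- latencies[!is.na(latencies)]
  if (length(ok) == 0L) stop("no participant has a detected latency")
  min(ok)
}
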