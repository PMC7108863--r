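#' Paired t-test with Cohen's d
#'
#' Classic paired t statistic with two effect-size variants: `dz`
#' (mean difference over SD of differences) and `d_av` (mean difference over
#' the average of the two condition SDs).  Both are computed; `d_variant`
#' selects which one is reported as `cohens_d`.
#'
#' @param a,b paired numeric vectors (same participants, two conditions).
#' @param d_variant `"d_av"` (default) or `"dz"`.
#' @return a `paired_test` list with `t`, `df`, `p` (two-sided), `mean_diff`,
#'   `cohens_d`, `d_variant`, `d_av`, `dz`, `n`.
#' @export
paired_ttest <- function(a, b, d_variant = c("d_av", "dz")) {
  d_variant <- match.arg(d_variant)
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- a - b
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (all(d == 0)) {
      return(structure(list(t = 0, df = n - 1L, p = 1, mean_diff = 0,
                            cohens_d = 0, d_variant = d_variant, d_av = 0,
                            dz = 0, n = n), class = "paired_test"))
    }
    stop("zero variance of a nonzero paired difference; ",
         "t statistic undefined")
  }
  tstat <- mean(d) / (sd_d / sqrt(n))
  dz <- mean(d) / sd_d
  d_av <- mean(d) / mean(c(stats::sd(a), stats::sd(b)))
  structure(list(
    t = tstat, df = n - 1L,
    p = 2 * stats::pt(abs(tstat), n - 1L, lower.tail = FALSE),
    mean_diff = mean(d),
    cohens_d = if (d_variant == "d_av") d_av else dz,
    d_variant = d_variant, d_av = d_av, dz = dz, n = n),
    class = "paired_test")
}

#' Correlation of reflex gain and endpoint variability, with bootstrap CI
#'
#' For each participant, the Pearson correlation between the per-condition
#' long-latency reflex means and endpoint SDs is computed across conditions;
#' the group statistic is the plain arithmetic mean of these correlation
#' coefficients, and its confidence interval is a percentile bootstrap over
#' participants (resampled with replacement).  Participants with zero
#' variance in either variable have an undefined correlation and are dropped
#' with a warning.
#'
#' @param data long data frame with one row per participant and condition.
#' @param x,y column names of the two correlated per-condition quantities
#'   (reflex amplitude and endpoint SD).
#' @param participant,condition column names.
#' @param B number of bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed for the bootstrap (reproducible CIs).
#' @return a `correlation_result` list with `r` (named per-participant
#'   vector), `mean_r`, `ci` (two-element), `level`, `B`, `seed`,
#'   `significant` (CI excludes 0) and `dropped` participants.
#' @export
reflex_variability_correlation <- function(data, x = "ll", y = "endpoint_sd",
                                           participant = "participant",
                                           condition = "condition",
                                           B = 1000L, level = 0.95,
                                           seed = 1L) {
  parts <- split(data, data[[participant]])
  r <- vapply(parts, function(d) {
    if (nrow(d) < 3L) return(NA_real_)
    if (stats::sd(d[[x]]) == 0 || stats::sd(d[[y]]) == 0) return(NA_real_)
    stats::cor(d[[x]], d[[y]])
  }, numeric(1))
  dropped <- names(r)[is.na(r)]
  if (length(dropped) > 0L) {
    warning("correlation undefined for participant(s) ",
            paste(dropped, collapse = ", "), "; dropped from the group mean")
  }
  r <- r[!is.na(r)]
  if (length(r) < 2L) stop("need at least 2 participants with defined r")
  mean_r <- mean(r)
  set.seed(seed)
  boot_means <- vapply(seq_len(B), function(i) {
    mean(r[sample.int(length(r), replace = TRUE)])
  }, numeric(1))
  ci <- unname(stats::quantile(boot_means,
                               c((1 - level) / 2, 1 - (1 - level) / 2),
                               type = 7))
  structure(list(r = r, mean_r = mean_r, ci = ci, level = level, B = B,
                 seed = seed, significant = ci[1] > 0 || ci[2] < 0,
                 dropped = dropped),
            class = "correlation_result")
}
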