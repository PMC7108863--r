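# participant x condition matrix from a long table, with balance check
wide_cell_means <- function(data, value = "value", participant = "participant",
                            condition = "condition") {
  w <- tapply(data[[value]], list(factor(data[[participant]]),
                                  factor(data[[condition]])), mean)
  if (any(is.na(w))) {
    miss <- which(is.na(w), arr.ind = TRUE)
    stop("unbalanced design; missing cells: ",
         paste(rownames(w)[miss[, 1]], colnames(w)[miss[, 2]], sep = ":",
               collapse = ", "))
  }
  w
}

#' One-way repeated-measures ANOVA with partial eta squared
#'
#' Univariate within-subject decomposition: the subject effect is removed,
#' the condition effect is tested against the subject-by-condition residual,
#' `F = MS_cond / MS_error` with `df = (k-1, (k-1)(n-1))`, and partial eta
#' squared is `SS_cond / (SS_cond + SS_error)`.  Both degree-of-freedom
#' labelings in circulation are reported: the conventional error df
#' `(k-1)(n-1)` (used for the p-value) and the subjects-minus-one label
#' `n-1`.
#'
#' @param data long data frame.
#' @param value,participant,condition column names.
#' @return an `rm_anova` list with `effects` (data frame: `effect`, `F`,
#'   `df1`, `df2`, `df2_subjects`, `p`, `partial_eta_sq`), `ms_error`,
#'   `df_error`, `n`, `k`, `condition_means` and `table` (the participant x
#'   condition matrix).
#' @export
rm_anova_oneway <- function(data, value = "value",
                            participant = "participant",
                            condition = "condition") {
  w <- wide_cell_means(data, value, participant, condition)
  n <- nrow(w); k <- ncol(w)
  if (n < 2L || k < 2L) stop("need at least 2 participants and 2 conditions")
  grand <- mean(w)
  cond_means <- colMeans(w)
  subj_means <- rowMeans(w)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_total <- sum((w - grand)^2)
  ss_error <- ss_total - ss_cond - ss_subj
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  ms_error <- ss_error / df2
  f <- if (ss_cond == 0) 0 else (ss_cond / df1) / ms_error
  pes <- if (ss_cond == 0) 0 else ss_cond / (ss_cond + ss_error)
  effects <- data.frame(
    effect = "condition", F = f, df1 = df1, df2 = df2,
    df2_subjects = n - 1L,
    p = stats::pf(f, df1, df2, lower.tail = FALSE),
    partial_eta_sq = pes)
  structure(list(effects = effects, ms_error = ms_error, df_error = df2,
                 n = n, k = k, condition_means = cond_means, table = w),
            class = "rm_anova")
}

#' Tukey-HSD post-hoc test on the repeated-measures error term
#'
#' Pairwise comparisons of the condition means using the studentized-range
#' distribution with the mean square error and error degrees of freedom of
#' the within-subject decomposition.
#'
#' @param anova an `rm_anova` from [rm_anova_oneway()].
#' @return data frame with `cond_a`, `cond_b`, `diff`, `q` and `p_adjusted`.
#' @export
tukey_hsd <- function(anova) {
  stopifnot(inherits(anova, "rm_anova"))
  m <- anova$condition_means
  k <- anova$k
  se <- sqrt(anova$ms_error / anova$n)
  pairs <- utils::combn(names(m), 2L)
  q <- abs(m[pairs[1L, ]] - m[pairs[2L, ]]) / se
  data.frame(
    cond_a = pairs[1L, ], cond_b = pairs[2L, ],
    diff = as.numeric(m[pairs[1L, ]] - m[pairs[2L, ]]),
    q = as.numeric(q),
    p_adjusted = stats::ptukey(as.numeric(q), k, anova$df_error,
                               lower.tail = FALSE),
    row.names = NULL)
}

#' Two-way repeated-measures ANOVA (2 within-subject factors)
#'
#' Each effect (two main effects and the interaction) is tested against its
#' own subject-by-effect interaction error term; partial eta squared is
#' reported per effect.
#'
#' @param data long data frame with one observation (or cell mean) per
#'   participant and factor combination.
#' @param value,participant,factor1,factor2 column names.
#' @return an `rm_anova` list; `effects` has one row per effect named after
#'   the factor columns, plus the interaction `factor1:factor2`.
#' @export
rm_anova_twoway <- function(data, value = "value",
                            participant = "participant",
                            factor1 = "factor1", factor2 = "factor2") {
  s <- factor(data[[participant]])
  f1 <- factor(data[[factor1]])
  f2 <- factor(data[[factor2]])
  y <- tapply(data[[value]], list(s, f1, f2), mean)
  if (any(is.na(y))) stop("unbalanced design: every participant needs every ",
                          "factor combination")
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  grand <- mean(y)
  m_s <- apply(y, 1, mean)
  m_a <- apply(y, 2, mean)
  m_b <- apply(y, 3, mean)
  m_ab <- apply(y, c(2, 3), mean)
  m_sa <- apply(y, c(1, 2), mean)
  m_sb <- apply(y, c(1, 3), mean)

  ss_a <- n * b * sum((m_a - grand)^2)
  ss_b <- n * a * sum((m_b - grand)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + grand)^2)
  ss_sa <- b * sum((sweep(sweep(m_sa, 1, m_s), 2, m_a) + grand)^2)
  ss_sb <- a * sum((sweep(sweep(m_sb, 1, m_s), 2, m_b) + grand)^2)
  resid <- y
  for (i in seq_len(n)) for (j in seq_len(a)) for (l in seq_len(b)) {
    resid[i, j, l] <- y[i, j, l] - m_sa[i, j] - m_sb[i, l] - m_ab[j, l] +
      m_s[i] + m_a[j] + m_b[l] - grand
  }
  ss_sab <- sum(resid^2)

  eff <- function(name, ss_eff, df_eff, ss_err, df_err) {
    f <- if (ss_eff == 0) 0 else (ss_eff / df_eff) / (ss_err / df_err)
    pes <- if (ss_eff == 0) 0 else ss_eff / (ss_eff + ss_err)
    data.frame(effect = name, F = f, df1 = df_eff, df2 = df_err,
               df2_subjects = n - 1L,
               p = stats::pf(f, df_eff, df_err, lower.tail = FALSE),
               partial_eta_sq = pes)
  }
  effects <- rbind(
    eff(factor1, ss_a, a - 1L, ss_sa, (a - 1L) * (n - 1L)),
    eff(factor2, ss_b, b - 1L, ss_sb, (b - 1L) * (n - 1L)),
    eff(paste(factor1, factor2, sep = ":"), ss_ab, (a - 1L) * (b - 1L),
        ss_sab, (a - 1L) * (b - 1L) * (n - 1L)))
  structure(list(effects = effects, n = n, a = a, b = b,
                 cell_means = m_ab), class = "rm_anova")
}
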