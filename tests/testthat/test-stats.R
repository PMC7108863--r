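test_that("one-way RM-ANOVA matches the aov Error-stratum oracle", {
  for (seed in 1:10) {
    tbl <- random_rm_table(n = sample(4:8, 1), k = sample(3:5, 1), seed)
    a <- rm_anova_oneway(tbl)
    o <- oracle_rm_anova_F(tbl)
    expect_equal(a$effects$F, o$F, tolerance = 1e-10)
    expect_equal(a$effects$p, o$p, tolerance = 1e-10)
    expect_equal(a$effects$df1, o$df1)
    expect_equal(a$effects$df2, o$df2)
    expect_true(a$effects$partial_eta_sq >= 0 &&
                  a$effects$partial_eta_sq <= 1)
  }
})

test_that("degenerate and unbalanced RM tables are handled explicitly", {
  tbl <- expand.grid(participant = 1:4, condition = c("a", "b", "c"))
  tbl$value <- 2
  a <- rm_anova_oneway(tbl)
  expect_equal(a$effects$F, 0)
  expect_equal(a$effects$partial_eta_sq, 0)
  expect_error(rm_anova_oneway(tbl[-1, ]), "missing cells")
  # the subjects-minus-one df label is carried alongside the standard df
  tbl2 <- random_rm_table(6, 4, 99)
  a2 <- rm_anova_oneway(tbl2)
  expect_equal(a2$effects$df2_subjects, 5)
  expect_equal(a2$effects$df2, 15)
})

test_that("F equals squared paired t for two conditions", {
  for (seed in 1:10) {
    tbl <- random_rm_table(n = 7, k = 2, seed + 100)
    a <- rm_anova_oneway(tbl)
    w <- tapply(tbl$value, list(tbl$participant, tbl$condition), mean)
    tt <- paired_ttest(w[, 1], w[, 2])
    expect_equal(a$effects$F, tt$t^2, tolerance = 1e-8)
    expect_equal(a$effects$p, tt$p, tolerance = 1e-8)
  }
})

test_that("Tukey-HSD on the RM error term matches stats::TukeyHSD", {
  for (seed in 1:5) {
    tbl <- random_rm_table(n = 6, k = 4, seed + 50)
    a <- rm_anova_oneway(tbl)
    tk <- tukey_hsd(a)
    # oracle: two-way fixed-effects aov (participant + condition) shares the
    # same error stratum; TukeyHSD then uses the identical studentized range
    fit <- aov(value ~ factor(participant) + condition, data = tbl)
    o <- TukeyHSD(fit, "condition")$condition
    key_o <- rownames(o)
    key_g <- paste(tk$cond_b, tk$cond_a, sep = "-")
    reorder <- match(key_o, key_g)
    expect_equal(tk$p_adjusted[reorder], unname(o[, "p adj"]),
                 tolerance = 1e-8)
  }
})

test_that("Tukey separates only truly shifted conditions", {
  set.seed(7)
  n <- 10
  tbl <- expand.grid(participant = seq_len(n), condition = c("a", "b", "c"))
  tbl$value <- rnorm(nrow(tbl), 0, 1) + rep(rnorm(n), 3)
  tbl$value[tbl$condition == "c"] <- tbl$value[tbl$condition == "c"] + 10
  tk <- tukey_hsd(rm_anova_oneway(tbl))
  hot <- tk$cond_a == "c" | tk$cond_b == "c"
  expect_true(all(tk$p_adjusted[hot] < 0.001))
  expect_true(all(tk$p_adjusted[!hot] > 0.1))
})

test_that("two-way RM-ANOVA matches the aov split-plot oracle", {
  for (seed in 1:8) {
    set.seed(seed + 200)
    n <- sample(5:8, 1)
    tbl <- expand.grid(participant = seq_len(n), factor1 = c("A1", "A2"),
                       factor2 = c("B1", "B2"))
    tbl$value <- rnorm(nrow(tbl)) + rep(rnorm(n), 4) +
      2 * (tbl$factor1 == "A2") + 1.5 * (tbl$factor2 == "B2") +
      runif(1, 0, 1.5) * (tbl$factor1 == "A2") * (tbl$factor2 == "B2")
    a <- rm_anova_twoway(tbl)
    s <- factor(tbl$participant)
    fit <- aov(value ~ factor1 * factor2 +
                 Error(s / (factor1 * factor2)), data = tbl)
    sm <- summary(fit)
    oF <- c(sm[["Error: s:factor1"]][[1]]["factor1", "F value"],
            sm[["Error: s:factor2"]][[1]]["factor2", "F value"],
            sm[["Error: s:factor1:factor2"]][[1]]["factor1:factor2",
                                                  "F value"])
    expect_equal(a$effects$F, unname(oF), tolerance = 1e-8)
  }
})

test_that("perfectly additive effects produce a null interaction", {
  tbl <- expand.grid(participant = 1:6, factor1 = c("A1", "A2"),
                     factor2 = c("B1", "B2"))
  tbl$value <- 1 + 2 * (tbl$factor1 == "A2") + 3 * (tbl$factor2 == "B2") +
    0.5 * tbl$participant
  a <- rm_anova_twoway(tbl)
  expect_equal(a$effects$F[a$effects$effect == "factor1:factor2"], 0)
  expect_gt(a$effects$partial_eta_sq[1], 0.99)
})

test_that("paired t and both Cohen's d variants match their formulas", {
  set.seed(31)
  for (r in 1:8) {
    a <- rnorm(9, 1, 1); b <- rnorm(9, 0.5, 1.3)
    got <- paired_ttest(a, b)
    o <- t.test(a, b, paired = TRUE)
    expect_equal(got$t, unname(o$statistic), tolerance = 1e-12)
    expect_equal(got$p, o$p.value, tolerance = 1e-12)
    expect_equal(got$df, unname(o$parameter))
    expect_equal(got$dz, got$t / sqrt(9), tolerance = 1e-12)
    expect_equal(got$d_av, mean(a - b) / mean(c(sd(a), sd(b))),
                 tolerance = 1e-12)
  }
  eq <- paired_ttest(1:5, 1:5)
  expect_equal(eq$t, 0)
  expect_equal(eq$cohens_d, 0)
  expect_error(paired_ttest(1:5, 1:5 + 2), "undefined")
  expect_error(paired_ttest(1, 2), "2 pairs")
})

test_that("per-participant correlations and the bootstrap CI behave as specified", {
  mk <- function(p, x, y) data.frame(participant = p, condition =
                                       paste0("c", seq_along(x)),
                                     ll = x, endpoint_sd = y)
  # perfect positive relation in every participant
  d <- rbind(mk(1, 1:4, 2 * (1:4)), mk(2, 1:4, 3 + (1:4)))
  r <- reflex_variability_correlation(d, B = 200, seed = 4)
  expect_equal(unname(r$r), c(1, 1))
  expect_equal(r$mean_r, 1)
  expect_equal(unname(r$ci), c(1, 1))
  expect_true(r$significant)
  # mirrored relations (r and -r) average to zero
  x <- c(-1, 0, 0, 1)
  d2 <- rbind(mk(1, x, x * 0.5 + c(-1, 1, -1, 1)),
              mk(2, x, -(x * 0.5 + c(-1, 1, -1, 1))))
  r2 <- reflex_variability_correlation(d2, B = 200, seed = 4)
  expect_equal(r2$mean_r, 0, tolerance = 1e-12)
  # reproducibility: identical seeds, identical CI; different seeds differ
  d3 <- do.call(rbind, lapply(1:6, function(p) {
    set.seed(p)
    mk(p, rnorm(5), rnorm(5))
  }))
  a1 <- reflex_variability_correlation(d3, B = 300, seed = 7)
  a2 <- reflex_variability_correlation(d3, B = 300, seed = 7)
  expect_identical(a1$ci, a2$ci)
  # degenerate participants (zero variance) are dropped with a warning
  d4 <- rbind(mk(1, 1:4, 2 * (1:4)), mk(2, rep(1, 4), 1:4),
              mk(3, 1:4, 4:1))
  expect_warning(r4 <- reflex_variability_correlation(d4, B = 100, seed = 1),
                 "dropped")
  expect_equal(length(r4$r), 2)
})
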