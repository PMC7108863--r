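test_that("window means respect the half-open convention and analytic values", {
  fs <- 2000
  t <- seq(0, 0.1 - 1 / fs, by = 1 / fs)
  expect_equal(window_mean(rep(2, length(t)), t, c(0.02, 0.08)), 2.0)
  # ramp r(t) = t over [0, 0.1): mean over [0.05, 0.1) is 0.075 - dt/2
  expect_lt(abs(window_mean(t, t, c(0.05, 0.1)) - 0.075), 1 / fs)
  # half-open: the 50 ms sample belongs to the upper window only
  sl <- t >= 0.030 - 1e-9 & t < 0.050 - 1e-9
  ll <- t >= 0.050 - 1e-9 & t < 0.100 - 1e-9
  expect_equal(sum(sl & ll), 0)
  expect_equal(sum(sl) + sum(ll), sum(t >= 0.030 - 1e-9))
  expect_error(window_mean(t, t, c(0.08, 0.15)), "outside")
})

test_that("window mean of a known burst equals its area over width", {
  fs <- 2000
  t <- seq(-0.1, 0.3, by = 1 / fs)
  center <- 0.075; sdv <- 0.012; peak <- 0.8
  g <- peak * exp(-0.5 * ((t - center) / sdv)^2)
  w <- c(0.05, 0.1)
  got <- window_mean(g, t, w)
  area <- integrate(function(x) peak * exp(-0.5 * ((x - center) / sdv)^2),
                    w[1], w[2])$value
  expect_equal(got, area / diff(w), tolerance = 1e-3)
})

test_that("isometric normalization is exact and scale invariant", {
  fs <- 2000
  expect_equal(isometric_reference(rep(4, 2000), fs), 4.0)
  expect_error(isometric_reference(rep(0, 2000), fs), "not positive")
  set.seed(3)
  ref <- rnorm(2000)
  sig <- abs(rnorm(800)) + 0.2
  t <- seq(0, length.out = length(sig), by = 1 / fs)
  m1 <- window_mean(sig, t, c(0.1, 0.3)) / isometric_reference(ref, fs)
  m2 <- window_mean(5 * sig, t, c(0.1, 0.3)) /
    isometric_reference(5 * ref, fs)
  expect_equal(m1, m2, tolerance = 1e-12)
  # raw 2.0 against reference 4.0 normalizes to 0.5
  expect_equal(2.0 / isometric_reference(rep(4, 100), fs), 0.5)
})

test_that("stretch-reflex quantification selects the stretched muscle and refuses unperturbed trials", {
  fs <- 2000
  n <- 2000
  flex <- rep(1, n); ext <- rep(3, n)
  r <- emg_trace(flex, ext, fs)
  r$stage <- "rectified"
  q <- quantify_stretch_reflex(r, 0.5, "extension", 2)
  expect_equal(q$muscle, "flexor")
  expect_equal(q$bga, 0.5)
  qe <- quantify_stretch_reflex(r, 0.5, "flexion", 2)
  expect_equal(qe$muscle, "extensor")
  expect_equal(qe$ll, 1.5)
  expect_error(quantify_stretch_reflex(r, NA, "extension", 2),
               "no perturbation")
  raw <- emg_trace(flex, ext, fs)
  expect_error(quantify_stretch_reflex(raw, 0.5, "extension", 2),
               "rectified")
})

test_that("background window is blind to post-perturbation bursts", {
  fs <- 2000
  n <- 2000
  t <- seq(0, by = 1 / fs, length.out = n)
  onset <- 0.5
  burst <- exp(-0.5 * ((t - onset - 0.075) / 0.012)^2)
  base <- rep(0.2, n)
  r1 <- emg_trace(base, base, fs); r1$stage <- "rectified"
  r2 <- emg_trace(base + burst, base + burst, fs); r2$stage <- "rectified"
  q1 <- quantify_stretch_reflex(r1, onset, "extension", 1)
  q2 <- quantify_stretch_reflex(r2, onset, "extension", 1)
  expect_equal(q1$bga, q2$bga, tolerance = 1e-6)
  expect_gt(q2$ll, q1$ll)
})

test_that("long-latency amplitude scales exactly with the condition multiplier", {
  cfg <- exact_cfg(1, condition_effects = list(
    conditions = c("full", "half"),
    ll_mult = c(full = 1, half = 0.5),
    endpoint_sd = c(full = 0, half = 0)))
  # isolate the long-latency component: rectification is nonlinear across
  # summed bumps, so exact proportionality holds for the scaled bump alone
  cfg$emg$mv_gain <- 0
  cfg$emg$sl_gain <- 0
  cfg$emg$vol_gain <- 0
  traj <- simulate_trajectory(cfg, "full")
  onset <- 0.65
  rect_of <- function(cond) {
    e <- simulate_emg(traj, cfg, cond, mp_onset_time = onset)
    r <- preprocess_emg(emg_trace(e$flexor, e$extensor, cfg$fs_emg))
    quantify_stretch_reflex(r, onset, "extension", 1)
  }
  qf <- rect_of("full")
  qh <- rect_of("half")
  expect_equal((qh$ll - qh$bga) / (qf$ll - qf$bga), 0.5, tolerance = 1e-9)
})

test_that("delta v-EMG is antisymmetric and signed by the responding muscle", {
  expect_equal(delta_v_emg(0.8, 0.3), 0.5)
  expect_equal(delta_v_emg(0.3, 0.8), -delta_v_emg(0.8, 0.3))
  expect_equal(delta_v_emg(0.4, 0.4), 0)
  fs <- 2000
  n <- 3000
  t <- seq(0, by = 1 / fs, length.out = n)
  onset <- 0.5
  burst <- 0.6 * exp(-0.5 * ((t - onset - 0.145) / 0.015)^2)
  base <- rep(0.1, n)
  fwd <- emg_trace(base + burst, base, fs); fwd$stage <- "rectified"
  bwd <- emg_trace(base, base, fs); bwd$stage <- "rectified"
  v_f <- quantify_v_emg(fwd, onset, "flexor", 1)
  v_b <- quantify_v_emg(bwd, onset, "flexor", 1)
  expect_gt(delta_v_emg(v_f, v_b), 0)
})

test_that("the visuomotor window maps cohort latencies 120/180 ms to 115-175 ms", {
  expect_equal(v_emg_window(0.120, 0.180), c(0.115, 0.175))
  expect_error(v_emg_window(0.180, 0.120))
})
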