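test_that("differentiation passes constants and ramps", {
  fs <- 500
  expect_true(all(abs(derive_kinematics(rep(5, 400), fs)$velocity) < 1e-9))
  ramp <- seq(0, by = 10 / fs, length.out = 500)
  kt <- derive_kinematics(ramp, fs)
  interior <- 100:400
  expect_true(all(abs(kt$velocity[interior] - 10) < 1e-6))
  expect_true(all(abs(kt$acceleration[interior]) < 1e-4))
})

test_that("a 5 Hz sinusoid differentiates to its analytic derivative", {
  fs <- 500
  A <- 3
  t <- seq(0, 2, by = 1 / fs)
  kt <- derive_kinematics(A * sin(2 * pi * 5 * t), fs)
  interior <- 200:800
  v_amp <- max(abs(kt$velocity[interior]))
  expect_equal(v_amp, 2 * pi * 5 * A, tolerance = 0.02)
})

test_that("zero-phase filtering leaves a symmetric pulse's peak in place", {
  fs <- 500
  t <- seq(0, 1, by = 1 / fs)
  pulse <- exp(-0.5 * ((t - 0.5) / 0.02)^2)
  y <- butter_zerophase(pulse, fs, 40, "low")
  expect_equal(which.max(y), which.max(pulse))
})

test_that("series too short for the filters raise a length error", {
  expect_error(derive_kinematics(rnorm(20), 500), "too short")
  expect_error(butter_zerophase(rnorm(10), 500, 40, "low"), "too short")
})

test_that("movement start is the first 5%-of-peak crossing of a half-sine", {
  fs <- 500
  lead <- 0.1
  t <- seq(0, 1.2, by = 1 / fs)
  v <- ifelse(t >= lead & t <= lead + 0.5, sin(pi * (t - lead) / 0.5), 0)
  trace <- data.frame(time = t, angle = cumsum(v) / fs, velocity = v,
                      acceleration = 0)
  attr(trace, "fs") <- fs
  class(trace) <- c("kinematic_trace", "data.frame")
  b <- detect_movement_bounds(trace)
  # analytic crossing: asin(0.05)/(2*pi) = 0.0079609 s after pulse start
  expect_lt(abs(b$start_time - (lead + 0.0079609)), 1 / fs + 1e-9)
  expect_false(b$unterminated)
  expect_lt(abs(b$end_time - (lead + 0.5 - 0.0079609)), 1 / fs + 1e-9)
  expect_true(b$start_time <= b$peak_time && b$peak_time <= b$end_time)
})

test_that("flat velocity is rejected and unterminated movements are flagged", {
  fs <- 500
  mk <- function(v) {
    tr <- data.frame(time = seq_along(v) / fs, angle = cumsum(v) / fs,
                     velocity = v, acceleration = 0)
    attr(tr, "fs") <- fs
    class(tr) <- c("kinematic_trace", "data.frame")
    tr
  }
  expect_error(detect_movement_bounds(mk(rep(0, 500))), "peak")
  # velocity that never settles below threshold for 300 ms
  t <- seq(0, 0.9, by = 1 / fs)
  v <- pmax(sin(pi * t / 0.5), 0.2)
  b <- detect_movement_bounds(mk(v))
  expect_true(b$unterminated)
  expect_true(is.na(b$end_time))
})

test_that("bounds equal a brute-force sample-by-sample scan on noisy profiles", {
  fs <- 500
  oracle_bounds <- function(v, thr_frac = 0.05, settle = 0.3,
                            edge = 0.05) {
    n <- length(v)
    lo <- ceiling(edge * fs) + 1
    hi <- n - ceiling(edge * fs)
    pk <- (lo:hi)[which.max(v[lo:hi])]
    thr <- thr_frac * v[pk]
    start <- NA
    for (j in lo:hi) if (abs(v[j]) > thr) { start <- j; break }
    need <- ceiling(settle * fs)
    end <- NA
    for (j in (pk + 1):hi) {
      if (abs(v[j]) < thr) {
        run <- j
        while (run <= n && abs(v[run]) < thr) run <- run + 1
        if (run - j >= need) { end <- j; break }
      }
    }
    c(start = (start - 1) / fs, end = (end - 1) / fs)
  }
  set.seed(11)
  for (r in 1:10) {
    t <- seq(0, 1.4, by = 1 / fs)
    v <- 100 * exp(-0.5 * ((t - runif(1, 0.4, 0.7)) / 0.12)^2) +
      rnorm(length(t), 0, 1.5)
    tr <- data.frame(time = t, angle = cumsum(v) / fs, velocity = v,
                     acceleration = 0)
    attr(tr, "fs") <- fs
    class(tr) <- c("kinematic_trace", "data.frame")
    b <- detect_movement_bounds(tr)
    o <- oracle_bounds(v)
    expect_equal(b$start_time, unname(o["start"]))
    expect_equal(b$end_time, unname(o["end"]))
  }
})

test_that("metrics of a noiseless minimum-jerk flexion match the closed-form rule", {
  fs <- 500
  t <- seq(0, 1.4, by = 1 / fs)
  angle <- min_jerk_pos(t, -22.5, 45, 0.2, 0.75)
  kt <- derive_kinematics(angle, fs)
  mm <- movement_metrics(kt)
  # 5%-of-peak threshold crossings of 16 s^2 (1-s)^2 = 0.05 sit at
  # s = 0.0594 / 0.9406, clipping the duration to 0.8811 * 0.75 = 0.661 s
  expect_equal(mm$duration, 0.661, tolerance = 0.015)
  expect_equal(mm$endpoint, 22.43, tolerance = 0.15)
  expect_equal(mm$peak_velocity, 112.5, tolerance = 0.02 * 112.5)
  # symmetric profile peaks at the midpoint
  expect_equal(kt$time[which.max(kt$velocity)], 0.2 + 0.375,
               tolerance = 2 / fs)
  expect_true(is.na(mm$velocity_at_mp))
  mm2 <- movement_metrics(kt, mp_onset_time = 0.5)
  expect_equal(mm2$velocity_at_mp, kt$velocity[round(0.5 * fs)])
})

test_that("endpoint SD is the n-1 sample SD and shift-invariant", {
  by <- data.frame(participant = 1, condition = "a")
  expect_equal(endpoint_sd(c(22, 23, 24), by[rep(1, 3), ])$endpoint_sd, 1.0)
  expect_equal(endpoint_sd(rep(5, 4), by[rep(1, 4), ])$endpoint_sd, 0)
  set.seed(2)
  e <- rnorm(12, 20, 2)
  grp <- data.frame(participant = rep(1:2, each = 6),
                    condition = rep(c("a", "b"), 6))
  expect_equal(endpoint_sd(e, grp)$endpoint_sd,
               endpoint_sd(e + 100, grp)$endpoint_sd)
  expect_warning(
    out <- endpoint_sd(c(1, 2, 3), data.frame(participant = c(1, 1, 2),
                                              condition = "a")),
    "fewer than 2")
  expect_true(is.na(out$endpoint_sd[out$participant == 2]))
})
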