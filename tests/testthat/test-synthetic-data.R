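test_that("minimum-jerk trajectory hits the target exactly with zero endpoint noise", {
  cfg <- exact_cfg(1)
  traj <- simulate_trajectory(cfg, "rot0", seed = 5)
  expect_equal(traj$endpoint, 22.5)
  expect_equal(traj$angle[length(traj$angle)], 22.5)
  expect_equal(traj$angle[1], -22.5)
  # closed-form peak speed of a minimum-jerk profile: 1.875 * amplitude / T
  v <- diff(traj$angle) * cfg$fs_kin
  expect_equal(max(v), 1.875 * 45 / 0.75, tolerance = 1e-3)
})

test_that("endpoint scatter matches the configured condition SD (chi-square bounds)", {
  cfg <- generator_config(1, n_participants = 1, block_reps = 1, seed = 1,
                          condition_effects = list(
                            conditions = "rot0", ll_mult = c(rot0 = 1),
                            endpoint_sd = c(rot0 = 2)),
                          endpoint = list(participant_sd_cv = 0))
  n_rep <- 20
  ok <- 0
  set.seed(42)
  for (r in seq_len(n_rep)) {
    e <- replicate(30, simulate_trajectory(cfg, "rot0")$endpoint)
    s <- sd(e)
    if (s >= 1.25 && s <= 2.75) ok <- ok + 1
  }
  # 95% chi-square bounds for the sample SD of 30 draws at sigma = 2
  expect_gte(ok, round(0.9 * n_rep))
})

test_that("unknown condition labels and experiment ids are rejected", {
  cfg <- exact_cfg(1)
  expect_error(simulate_trajectory(cfg, "rot33"), "condition")
  expect_error(generator_config(7), "experiment")
  expect_error(experiment_design(9), "experiment")
})

test_that("perturbation response matches an independent fine-step ODE oracle", {
  skip_if_not_installed("deSolve")
  mp <- mp_params(peak_torque = 2, duration = 0.05, direction = "extension")
  wrist <- list(inertia = 0.005, damping = 0.05)
  fs <- 500
  n <- 150
  defl <- reflexvf:::mp_deflection(mp, wrist, fs, n)
  # independent oracle: lsoda at 10x finer resolution
  tau <- function(t) {
    ifelse(t >= 0 & t <= mp$duration, -2 * sin(pi * t / mp$duration), 0)
  }
  deriv <- function(t, y, parms) {
    list(c(y[2], (tau(t) - wrist$damping * y[2]) / wrist$inertia))
  }
  times <- seq(0, (n - 1) / fs, by = 1 / (10 * fs))
  sol <- deSolve::lsoda(c(0, 0), times, deriv, NULL, rtol = 1e-10,
                        atol = 1e-12)
  oracle <- sol[seq(1, nrow(sol), by = 10), 2] * 180 / pi
  expect_lt(max(abs(defl - oracle)), 1e-3 * max(abs(oracle)))
  # extension perturbation deflects toward extension (negative)
  expect_true(all(defl[2:50] < 0))
})

test_that("zero-torque perturbation leaves the trajectory unchanged", {
  cfg <- exact_cfg(1)
  traj <- simulate_trajectory(cfg, "rot0")
  p <- apply_perturbation(traj$angle, cfg$fs_kin,
                          mp_params(peak_torque = 0, trigger_angle = 3.75),
                          cfg$wrist)
  expect_true(p$triggered)
  expect_equal(p$angle, traj$angle)
})

test_that("a trigger angle never crossed flags the trial instead of perturbing", {
  cfg <- exact_cfg(1)
  traj <- simulate_trajectory(cfg, "rot0")
  p <- apply_perturbation(traj$angle, cfg$fs_kin,
                          mp_params(trigger_angle = 60), cfg$wrist)
  expect_false(p$triggered)
  expect_equal(p$angle, traj$angle)
  expect_true(is.na(p$onset_time))
})

test_that("cursor transform follows x = -alpha*theta with workspace rotation", {
  m0 <- cursor_mapping(alpha = 0.44, rotation = 0)
  expect_equal(cursor_transform(30, m0)$x, -13.2)
  expect_equal(cursor_transform(30, m0)$y, 0)
  # rotation by 180 degrees is the mirror reversal
  m180 <- cursor_mapping(rotation = 180)
  mm <- cursor_mapping(mirror = TRUE)
  th <- c(-20, 0, 15, 30)
  expect_equal(cursor_transform(th, m180)$x, cursor_transform(th, mm)$x,
               tolerance = 1e-12)
  expect_equal(cursor_transform(th, m180)$y, rep(0, 4), tolerance = 1e-12)
  # rotation-matrix oracle for 90 degrees: (-9.9, 0) -> (0, -9.9)
  m90 <- cursor_mapping(rotation = 90)
  p <- cursor_transform(9.9 / 0.44, m90)
  expect_equal(p$x, 0, tolerance = 1e-12)
  expect_equal(p$y, -9.9, tolerance = 1e-12)
  # elimination rule
  mh <- cursor_mapping(visibility = "hide-at-angle", hide_angle = 10)
  expect_equal(cursor_transform(c(5, 15), mh)$visible, c(TRUE, FALSE))
})

test_that("EMG envelopes are exactly linear in the configured gains", {
  cfg <- exact_cfg(1)
  traj <- simulate_trajectory(cfg, "rot0")
  base <- simulate_emg(traj, cfg, "rot0", mp_onset_time = 0.6)
  cfg2 <- cfg
  for (g in c("bga_mean", "mv_gain", "sl_gain", "ll_gain", "vol_gain")) {
    cfg2$emg[[g]] <- 3 * cfg$emg[[g]]
  }
  scaled <- simulate_emg(traj, cfg2, "rot0", mp_onset_time = 0.6)
  expect_equal(scaled$flexor, 3 * base$flexor, tolerance = 1e-12)
  expect_equal(scaled$extensor, 3 * base$extensor, tolerance = 1e-12)
})

test_that("all gains and noise at zero give identically zero EMG", {
  cfg <- exact_cfg(1)
  for (g in c("bga_mean", "mv_gain", "sl_gain", "ll_gain", "vol_gain")) {
    cfg$emg[[g]] <- 0
  }
  traj <- simulate_trajectory(cfg, "rot0")
  emg <- simulate_emg(traj, cfg, "rot0", mp_onset_time = 0.6)
  expect_true(all(emg$flexor == 0))
  expect_true(all(emg$extensor == 0))
})

test_that("per-cell trial counts equal the published designs", {
  d2 <- experiment_design(2)
  expect_equal(sum(d2$n[d2$block == "Normal"]), 40)
  expect_equal(sum(d2$n[d2$block == "Normal" & d2$target == "Std" &
                          d2$trial_type == "MP"]), 8)
  d3 <- experiment_design(3)
  expect_equal(sum(d3$n), 80)
  expect_equal(sum(d3$n[d3$trial_type == "MP"]), 16)
  d4 <- experiment_design(4)
  one_block <- d4[d4$block == "Pro", ]
  expect_equal(sum(one_block$n), 60)
  expect_equal(one_block$n[match(c("N", "MP", "fwd_jump", "bwd_jump"),
                                 one_block$trial_type)],
               c(12L, 12L, 18L, 18L))
  d1 <- experiment_design(1)
  expect_equal(as.integer(tapply(d1$n, d1$block, sum)), rep(20L, 5))

  # generated counts respect the design
  ds <- generate_dataset(2, tiny_cfg(2, seed = 3))
  man <- ds$manifest
  expect_equal(nrow(man), 2 * 80)
  for (p in 1:2) {
    cnt <- table(man$block[man$participant == p],
                 man$trial_type[man$participant == p])
    expect_equal(unname(cnt["Normal", "MP"]), 8)
    expect_equal(unname(cnt["Mirror", "N"]), 32)
  }
})

test_that("identical configurations yield byte-identical datasets", {
  cfg <- tiny_cfg(3, seed = 9)
  ds1 <- generate_dataset(3, cfg)
  ds2 <- generate_dataset(3, cfg)
  expect_identical(ds1$manifest, ds2$manifest)
  expect_identical(ds1$trials[[17]], ds2$trials[[17]])
  expect_identical(ds1$participants[[2]]$reference,
                   ds2$participants[[2]]$reference)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(ds1$manifest, f1, row.names = FALSE)
  write.csv(ds2$manifest, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("cursor elimination durations are graded across hide conditions", {
  ds <- generate_dataset(3, tiny_cfg(3, seed = 2))
  man <- ds$manifest
  mp <- man[man$trial_type == "MP", ]
  med <- tapply(mp$cursor_elim_duration, mp$cursor, median)
  expect_equal(unname(med["Show"]), 0)
  expect_true(med["Long-hide"] > med["Middle-hide"])
  expect_true(med["Middle-hide"] > med["Short-hide"])
  expect_true(med["Short-hide"] > 0)
})

test_that("configured long-latency multipliers are recovered from noisy trials", {
  cfg <- generator_config(1, n_participants = 1, block_reps = 4, seed = 21,
                          emg_for_catch = FALSE)
  ds <- generate_dataset(1, cfg)
  m <- quantify_dataset(ds, kin_metrics = "unperturbed", vel_at_mp = FALSE)
  mp <- m[m$trial_type == "MP", ]
  net <- tapply(mp$ll - mp$bga, mp$condition, mean)
  se <- tapply(mp$ll - mp$bga, mp$condition,
               function(x) sd(x) / sqrt(length(x)))
  for (cond in c("rot90", "rot135", "rot180")) {
    ratio <- net[[cond]] / net[["rot0"]]
    se_ratio <- abs(ratio) *
      sqrt((se[[cond]] / net[[cond]])^2 + (se[["rot0"]] / net[["rot0"]])^2)
    expect_lt(abs(ratio - cfg$condition_effects$ll_mult[[cond]]),
              2 * se_ratio + 0.02)
  }
})
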