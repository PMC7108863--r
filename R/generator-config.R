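#' Mechanical perturbation parameters
#'
#' The perturbation is a half-sine torque pulse delivered by the wrist
#' manipulandum when the hand crosses a trigger angle.  Defaults follow the
#' experimental protocol: 2.0 Nm peak, 50 ms duration.
#'
#' @param peak_torque peak torque in Nm (> 0).
#' @param duration pulse duration in s (> 0).
#' @param direction `"extension"` (stretches the wrist flexor) or
#'   `"flexion"` (stretches the extensor).
#' @param trigger_angle wrist angle in deg at which the pulse is triggered
#'   (flexion positive, 0 = straight wrist).
#' @return an object of class `mp_params`.
#' @export
mp_params <- function(peak_torque = 2.0, duration = 0.05,
                      direction = c("extension", "flexion"),
                      trigger_angle = 3.75) {
  direction <- match.arg(direction)
  stopifnot(peak_torque >= 0, duration > 0)
  structure(list(peak_torque = peak_torque, duration = duration,
                 direction = direction, trigger_angle = trigger_angle),
            class = "mp_params")
}

#' Cursor-to-hand visual mapping
#'
#' The cursor represents the wrist angle theta on screen through
#' `x = -alpha * theta`, optionally rotated about the workspace centre or
#' mirror-reversed, and optionally eliminated during the movement.
#'
#' @param alpha visual feedback gain in cm/deg (> 0).
#' @param rotation rotation of the whole visual workspace in deg; one of
#'   0, 45, 90, 135, 180 in the rotation experiment.
#' @param mirror logical; mirror-reverse the cursor (x negated).
#' @param visibility `"show"`, `"hide-at-onset"` (cursor removed at movement
#'   onset) or `"hide-at-angle"` (removed when theta crosses `hide_angle`).
#' @param hide_angle wrist angle in deg at which the cursor disappears
#'   (required for `"hide-at-angle"`).
#' @return an object of class `cursor_mapping`.
#' @export
cursor_mapping <- function(alpha = 0.44, rotation = 0, mirror = FALSE,
                           visibility = c("show", "hide-at-onset",
                                          "hide-at-angle"),
                           hide_angle = NULL) {
  visibility <- match.arg(visibility)
  stopifnot(alpha > 0)
  if (!rotation %in% c(0, 45, 90, 135, 180)) {
    stop("rotation must be one of 0, 45, 90, 135, 180")
  }
  if (visibility == "hide-at-angle" && is.null(hide_angle)) {
    stop("hide_angle required when visibility = 'hide-at-angle'")
  }
  structure(list(alpha = alpha, rotation = rotation, mirror = mirror,
                 visibility = visibility, hide_angle = hide_angle),
            class = "cursor_mapping")
}

# Per-experiment condition keys, long-latency gain multipliers and task
# geometry.  Endpoint SD per condition is derived from the multiplier through
# a negative linear map unless overridden (see generator_config).
default_condition_effects <- function(experiment_id) {
  switch(as.character(experiment_id),
    "1" = list(
      conditions = c("rot0", "rot45", "rot90", "rot135", "rot180"),
      ll_mult = c(rot0 = 1.0, rot45 = 1.0, rot90 = 0.8, rot135 = 0.7,
                  rot180 = 0.6)),
    "2" = list(
      conditions = c("Normal.Show", "Normal.Hide", "Mirror.Show",
                     "Mirror.Hide"),
      ll_mult = c(Normal.Show = 1.0, Normal.Hide = 0.85, Mirror.Show = 0.8,
                  Mirror.Hide = 0.65)),
    "3" = list(
      conditions = c("Show", "Short-hide", "Middle-hide", "Long-hide"),
      ll_mult = c("Show" = 1.0, "Short-hide" = 0.9, "Middle-hide" = 0.8,
                  "Long-hide" = 0.7)),
    "4" = list(
      conditions = c("Pro", "Anti", "Normal", "Mirror"),
      ll_mult = c(Pro = 1.0, Anti = 1.0, Normal = 1.0, Mirror = 0.7),
      jump_latency = c(Pro = 0.120, Anti = 0.180, Normal = 0.120,
                       Mirror = 0.230)),
    stop("unknown experiment id: ", experiment_id)
  )
}

default_movement <- function(experiment_id) {
  switch(as.character(experiment_id),
    "1" = list(start_angle = -22.5, target_angle = 22.5, duration = 0.75,
               targets = c(Std = 22.5)),
    "2" = list(start_angle = -22.5, target_angle = 22.5, duration = 0.75,
               targets = c(Std = 22.5, Near = 16.5, Far = 28.5)),
    "3" = list(start_angle = -22.5, target_angle = 45, duration = 0.75,
               targets = c(Std = 45, Near = 39, Far = 51)),
    "4" = list(start_angle = -22.5, target_angle = 22.5, duration = 0.75,
               targets = c(Std = 22.5)))
}

default_mp <- function(experiment_id) {
  switch(as.character(experiment_id),
    "1" = mp_params(trigger_angle = 3.75),
    "2" = mp_params(trigger_angle = 0),
    # trigger at +50.6 deg flexion from the -22.5 deg starting point
    "3" = mp_params(trigger_angle = -22.5 + 50.6),
    "4" = mp_params(trigger_angle = 0))
}

default_n_participants <- function(experiment_id, group = "agonist") {
  switch(as.character(experiment_id),
    "1" = if (group == "agonist") 18L else 10L,
    "2" = 10L, "3" = 10L, "4" = 8L)
}

default_block_reps <- function(experiment_id) {
  switch(as.character(experiment_id), "1" = 5L, "2" = 6L, "3" = 6L, "4" = 2L)
}

#' Configuration of the synthetic trial generator
#'
#' Bundles every tunable of the simulated wrist-flexion experiments: cohort
#' size and design repetitions, sampling rates, movement geometry, the wrist
#' plant, the EMG envelope model, per-condition long-latency gain multipliers
#' and endpoint-variability coupling, and the target-jump response model.
#' Identical configurations (including `seed`) always produce identical
#' datasets.
#'
#' @param experiment_id 1 (visual rotation), 2 (mirror/cursor elimination),
#'   3 (graded elimination duration) or 4 (pro/anti and normal/mirror target
#'   jumps).
#' @param n_participants cohort size; defaults to the design of the given
#'   experiment (18, 10, 10, 8).
#' @param group `"agonist"` (extension perturbations, flexor reflex) or
#'   `"antagonist"` (flexion perturbations, extensor reflex); experiment 1
#'   only.
#' @param block_reps number of repetitions of the block set (defaults 5, 6,
#'   6, 2 for experiments 1-4).
#' @param seed integer seed driving all randomness.
#' @param fs_kin,fs_emg sampling rates in Hz (500 and 2000).
#' @param trial_duration,move_onset total simulated trial length and movement
#'   start time, s.
#' @param kin_noise_sd SD (deg) of white measurement noise added to the
#'   recorded angle series (encoder quantization and electrical noise); this
#'   is what gives acceleration ensembles honest trial-to-trial variability
#'   at every sample.
#' @param movement list with `start_angle`, `target_angle`, `duration` (s) and
#'   named `targets` vector (deg).
#' @param wrist list with `inertia` (kg m^2) and `damping` (Nm s/rad) of the
#'   second-order wrist plant that shapes the perturbation response.
#' @param mp an [mp_params()] object.
#' @param emg list of EMG envelope parameters (see Details).
#' @param endpoint list with `base_sd` (deg), `sd_slope` (deg per unit loss of
#'   long-latency gain) and `participant_sd_cv` (between-participant log-SD of
#'   endpoint variability).
#' @param jump list of target-jump response parameters: per-task latencies are
#'   taken from the condition effects; `accel_delay` (s) separates EMG onset
#'   from measurable acceleration divergence; `response_gain` scales the
#'   corrective EMG burst; `width` is the burst SD (s); `latency_jitter_max`
#'   spreads participant latencies above the cohort minimum;
#'   `correction_duration` is the length of the corrective sub-movement (s).
#' @param condition_effects list with `conditions`, `ll_mult` (named gain
#'   multipliers) and optionally `endpoint_sd` and `jump_latency` named
#'   vectors; defaults encode the per-experiment effect pattern.
#' @param isometric list with `ref_mean` (envelope during the 1 Nm reference
#'   contraction, a.u.), `duration` (s) and `noise_sd`.
#' @param stochastic logical; `FALSE` turns off the broadband EMG carrier and
#'   all noise so the envelope itself is returned (deterministic mode used by
#'   exactness tests).
#' @param model_catch_response logical; model kinematic/EMG corrections in
#'   experiment 1 cursor-shift catch trials (off: catch trials carry metadata
#'   only).
#' @param emg_for_catch logical; synthesize EMG for metadata-only catch
#'   trials (they are never analysed; turning this off saves time in large
#'   replicate studies).
#'
#' @details The EMG envelope model: baseline level `bga_mean` plus a
#' movement-related agonist burst (`mv_gain` times the normalized speed
#' profile), plus, on perturbed trials, Gaussian short-latency
#' (centre `sl_latency`, SD `sl_width`, peak `sl_gain`) and long-latency
#' (centre `ll_latency`, SD `ll_width`, peak `ll_gain` times the condition
#' multiplier) bumps in the stretched muscle followed by a voluntary bump at
#' `vol_latency`, plus a corrective burst after target jumps.  `gain_cv` is
#' the trial-to-trial coefficient of variation of the burst gains,
#' `participant_scale_sd` the log-SD of the overall per-participant EMG
#' scale (cancelled by isometric normalization), `ll_between_sd` the log-SD
#' of between-participant long-latency gain.  In stochastic mode the envelope
#' multiplies a unit-variance broadband carrier and `noise_sd` additive sensor
#' noise is appended, so the 50 Hz high-pass + rectification pipeline recovers
#' the envelope up to a constant that normalization cancels.
#'
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(experiment_id,
                             n_participants = NULL,
                             group = c("agonist", "antagonist"),
                             block_reps = NULL,
                             seed = 1L,
                             fs_kin = 500, fs_emg = 2000,
                             trial_duration = 1.4, move_onset = 0.2,
                             kin_noise_sd = 0.01,
                             movement = NULL,
                             wrist = list(inertia = 0.005, damping = 0.05),
                             mp = NULL,
                             emg = list(),
                             endpoint = list(),
                             jump = list(),
                             condition_effects = NULL,
                             isometric = list(ref_mean = 1.0, duration = 1.0,
                                              noise_sd = 0.0),
                             stochastic = TRUE,
                             model_catch_response = FALSE,
                             emg_for_catch = TRUE) {
  group <- match.arg(group)
  experiment_id <- as.integer(experiment_id)
  if (!experiment_id %in% 1:4) stop("unknown experiment id: ", experiment_id)

  emg_defaults <- list(
    bga_mean = 0.05, noise_sd = 0.01,
    mv_gain = 0.25,
    sl_gain = 0.35, sl_latency = 0.040, sl_width = 0.005,
    ll_gain = 0.55, ll_latency = 0.075, ll_width = 0.012,
    vol_gain = 0.30, vol_latency = 0.140, vol_width = 0.025,
    gain_cv = 0.20, participant_scale_sd = 0.20, ll_between_sd = 0.15,
    latency_trial_jitter = 0.002)
  emg <- utils::modifyList(emg_defaults, emg)
  stopifnot(emg$sl_latency < emg$ll_latency, emg$ll_latency < emg$vol_latency)

  endpoint_defaults <- list(base_sd = 1.5, sd_slope = 3.75,
                            participant_sd_cv = 0.15,
                            duration_sd = 0.03)
  endpoint <- utils::modifyList(endpoint_defaults, endpoint)
  stopifnot(endpoint$base_sd > 0)

  jump_defaults <- list(magnitude = 12, trigger_angle = 0,
                        response_gain = 0.6, width = 0.015,
                        accel_delay = 0.080, correction_duration = 0.25,
                        latency_jitter_max = 0.025)
  jump <- utils::modifyList(jump_defaults, jump)

  if (is.null(movement)) movement <- default_movement(experiment_id)
  if (is.null(mp)) {
    mp <- default_mp(experiment_id)
    if (experiment_id == 1L && group == "antagonist") {
      mp$direction <- "flexion"
    }
  }
  if (is.null(condition_effects)) {
    condition_effects <- default_condition_effects(experiment_id)
  }
  if (is.null(condition_effects$endpoint_sd)) {
    mult <- condition_effects$ll_mult
    condition_effects$endpoint_sd <-
      endpoint$base_sd + endpoint$sd_slope * (1 - mult)
  }
  stopifnot(all(condition_effects$ll_mult >= 0),
            all(condition_effects$endpoint_sd >= 0))
  if (is.null(n_participants)) {
    n_participants <- default_n_participants(experiment_id, group)
  }
  if (is.null(block_reps)) block_reps <- default_block_reps(experiment_id)

  structure(list(
    experiment_id = experiment_id, n_participants = as.integer(n_participants),
    group = group, block_reps = as.integer(block_reps), seed = as.integer(seed),
    fs_kin = fs_kin, fs_emg = fs_emg,
    trial_duration = trial_duration, move_onset = move_onset,
    kin_noise_sd = kin_noise_sd,
    movement = movement, wrist = wrist, mp = mp, emg = emg,
    endpoint = endpoint, jump = jump,
    condition_effects = condition_effects, isometric = isometric,
    stochastic = stochastic, model_catch_response = model_catch_response,
    emg_for_catch = emg_for_catch),
    class = "generator_config")
}

#' Per-block trial composition of each experiment design
#'
#' Returns the trial cells of one block of the given experiment, with the
#' per-cell trial counts of the published designs (experiment 1: 5 baseline,
#' 5 perturbed and 5+5 cursor-shift catch trials per rotation block;
#' experiments 2 and 3: the Table-1/Table-2 compositions; experiment 4:
#' 12 baseline, 12 perturbed, 18 forward and 18 backward jumps).
#'
#' @param experiment_id experiment number 1-4.
#' @return data frame with columns `block`, `target`, `cursor`, `trial_type`
#'   and `n` (`trial_type` in `N`, `MP`, `fwd_shift`, `bwd_shift`,
#'   `fwd_jump`, `bwd_jump`).
#' @export
experiment_design <- function(experiment_id) {
  experiment_id <- as.integer(experiment_id)
  d <- switch(as.character(experiment_id),
    "1" = {
      blocks <- c("rot0", "rot45", "rot90", "rot135", "rot180")
      do.call(rbind, lapply(blocks, function(b) {
        data.frame(block = b, target = "Std", cursor = "Show",
                   trial_type = c("N", "MP", "fwd_shift", "bwd_shift"),
                   n = c(5L, 5L, 5L, 5L))
      }))
    },
    "2" = {
      per_block <- function(b) rbind(
        data.frame(block = b, target = "Std", cursor = c("Show", "Show",
                   "Hide", "Hide"), trial_type = c("MP", "N", "MP", "N"),
                   n = c(4L, 6L, 4L, 6L)),
        data.frame(block = b, target = rep(c("Near", "Far"), each = 2),
                   cursor = rep(c("Show", "Hide"), 2),
                   trial_type = "N", n = 5L))
      rbind(per_block("Normal"), per_block("Mirror"))
    },
    "3" = rbind(
      data.frame(block = "Main", target = "Std",
                 cursor = rep(c("Show", "Short-hide", "Middle-hide",
                                "Long-hide"), each = 2),
                 trial_type = rep(c("MP", "N"), 4),
                 n = rep(c(4L, 6L), 4)),
      data.frame(block = "Main", target = rep(c("Near", "Far"), each = 2),
                 cursor = rep(c("Show", "Long-hide"), 2),
                 trial_type = "N", n = 10L)),
    "4" = {
      per_block <- function(session, b) data.frame(
        session = session, block = b, target = "Std", cursor = "Show",
        trial_type = c("N", "MP", "fwd_jump", "bwd_jump"),
        n = c(12L, 12L, 18L, 18L))
      rbind(per_block("ProAnti", "Pro"), per_block("ProAnti", "Anti"),
            per_block("NormalMirror", "Normal"),
            per_block("NormalMirror", "Mirror"))
    },
    stop("unknown experiment id: ", experiment_id))
  if (is.null(d$session)) d$session <- "Main"
  d[, c("session", "block", "target", "cursor", "trial_type", "n")]
}

# condition key used to index condition_effects for a manifest row
condition_key <- function(experiment_id, block, cursor) {
  switch(as.character(experiment_id),
    "1" = block,
    "2" = paste(block, cursor, sep = "."),
    "3" = cursor,
    "4" = block)
}
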