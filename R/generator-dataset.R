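#' Generate a complete multi-participant synthetic dataset
#'
#' Simulates every trial of the requested experiment for a cohort of
#' participants: per-participant EMG scale, reflex gain and endpoint
#' variability heterogeneity, isometric reference recordings, block
#' scheduling with randomized trial order, minimum-jerk flexion trajectories
#' with condition-dependent endpoint scatter, half-sine torque perturbations
#' through the second-order wrist plant, target-jump corrective responses
#' with task-dependent latencies, and two-channel envelope-times-carrier EMG.
#' The whole dataset is a deterministic function of the configuration,
#' including its seed.
#'
#' @param experiment_id experiment number 1-4.
#' @param cfg a [generator_config()]; defaults to the experiment's standard
#'   design.
#' @return an object of class `reflex_dataset`: list with `experiment_id`,
#'   `cfg`, `participants` (per-participant parameters and reference
#'   recordings), `manifest` (one row per trial) and `trials` (parallel list
#'   of `angle`, `emg_flexor`, `emg_extensor` series).
#' @export
generate_dataset <- function(experiment_id, cfg = NULL) {
  experiment_id <- as.integer(experiment_id)
  if (is.null(cfg)) cfg <- generator_config(experiment_id)
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$experiment_id != experiment_id) {
    stop("cfg was built for experiment ", cfg$experiment_id,
         ", not ", experiment_id)
  }
  set.seed(cfg$seed)
  np <- cfg$n_participants

  participants <- vector("list", np)
  for (p in seq_len(np)) {
    participants[[p]] <- list(
      id = p,
      emg_scale = exp(stats::rnorm(1, 0, cfg$emg$participant_scale_sd)),
      ll_scale = exp(stats::rnorm(1, 0, cfg$emg$ll_between_sd)),
      sd_scale = exp(stats::rnorm(1, 0, cfg$endpoint$participant_sd_cv)),
      jump_offset = stats::runif(1, 0, cfg$jump$latency_jitter_max))
  }
  # anchor the cohort minimum jump latency at the configured task latency
  offs <- vapply(participants, `[[`, numeric(1), "jump_offset")
  offs <- offs - min(offs)
  for (p in seq_len(np)) {
    participants[[p]]$jump_offset <- offs[[p]]
    participants[[p]]$reference <- list(
      flexor = simulate_isometric_reference(cfg, participants[[p]]$emg_scale),
      extensor = simulate_isometric_reference(cfg, participants[[p]]$emg_scale))
  }

  design <- experiment_design(experiment_id)
  total <- np * cfg$block_reps * sum(design$n)

  man <- list(
    trial_id = integer(total), participant = integer(total),
    session = character(total), block = character(total),
    rep = integer(total), order_in_block = integer(total),
    condition = character(total), target = character(total),
    cursor = character(total), trial_type = character(total),
    perturbed = logical(total), mp_triggered = logical(total),
    mp_onset_time = rep(NA_real_, total),
    jump_dir = rep(NA_character_, total),
    jump_onset_time = rep(NA_real_, total),
    jump_latency_true = rep(NA_real_, total),
    endpoint_true = numeric(total), duration_true = numeric(total),
    cursor_elim_duration = rep(NA_real_, total),
    ll_mult = numeric(total))
  trials <- vector("list", total)

  i <- 0L
  for (p in seq_len(np)) {
    pp <- participants[[p]]
    sessions <- unique(design$session)
    # counterbalance session order across participants
    if (length(sessions) > 1L && p %% 2L == 0L) sessions <- rev(sessions)
    for (session in sessions) {
      blocks <- unique(design$block[design$session == session])
      block_seq <- sample(rep(blocks, cfg$block_reps))
      reps_seen <- stats::setNames(integer(length(blocks)), blocks)
      for (block in block_seq) {
        reps_seen[[block]] <- reps_seen[[block]] + 1L
        cells <- design[design$session == session & design$block == block, ]
        cell_target <- cells$target
        cell_cursor <- cells$cursor
        cell_type <- cells$trial_type
        cell_idx <- rep(seq_len(nrow(cells)), cells$n)
        cell_idx <- sample(cell_idx)
        for (k in seq_along(cell_idx)) {
          ci <- cell_idx[[k]]
          i <- i + 1L
          tr <- simulate_one_trial(cfg, experiment_id, pp, session, block,
                                   cell_target[[ci]], cell_cursor[[ci]],
                                   cell_type[[ci]])
          trials[[i]] <- tr$signals
          man$trial_id[i] <- i
          man$participant[i] <- p
          man$session[i] <- session
          man$block[i] <- block
          man$rep[i] <- reps_seen[[block]]
          man$order_in_block[i] <- k
          man$condition[i] <- tr$condition
          man$target[i] <- cell_target[[ci]]
          man$cursor[i] <- cell_cursor[[ci]]
          man$trial_type[i] <- cell_type[[ci]]
          man$perturbed[i] <- tr$perturbed
          man$mp_triggered[i] <- tr$mp_triggered
          man$mp_onset_time[i] <- tr$mp_onset_time
          man$jump_dir[i] <- tr$jump_dir
          man$jump_onset_time[i] <- tr$jump_onset_time
          man$jump_latency_true[i] <- tr$jump_latency_true
          man$endpoint_true[i] <- tr$endpoint_true
          man$duration_true[i] <- tr$duration_true
          man$cursor_elim_duration[i] <- tr$cursor_elim_duration
          man$ll_mult[i] <- tr$ll_mult
        }
      }
    }
  }
  manifest <- as.data.frame(man, stringsAsFactors = FALSE)
  structure(list(experiment_id = experiment_id, cfg = cfg,
                 participants = participants, manifest = manifest,
                 trials = trials),
            class = "reflex_dataset")
}

# one trial: trajectory, optional perturbation / jump correction, EMG
simulate_one_trial <- function(cfg, experiment_id, participant, session,
                               block, target, cursor, trial_type) {
  ckey <- condition_key(experiment_id, block, cursor)
  target_angle <- cfg$movement$targets[[target]]
  traj <- simulate_trajectory(cfg, ckey, target_angle, participant$sd_scale)
  angle <- traj$angle
  mp_onset <- NA_real_
  mp_triggered <- NA
  perturbed <- trial_type == "MP"
  jump_dir <- NA_character_
  jump_onset <- NA_real_
  jump_lat <- NA_real_
  jump_emg <- NULL
  elim <- NA_real_

  if (perturbed) {
    pert <- apply_perturbation(traj$angle, cfg$fs_kin, cfg$mp, cfg$wrist)
    angle <- pert$angle
    mp_onset <- pert$onset_time
    mp_triggered <- pert$triggered
  }

  if (trial_type %in% c("fwd_jump", "bwd_jump", "fwd_shift", "bwd_shift")) {
    jump_dir <- if (startsWith(trial_type, "fwd")) "forward" else "backward"
    jidx <- which(traj$angle >= cfg$jump$trigger_angle)[1L]
    jump_onset <- (jidx - 1L) / cfg$fs_kin
    is_jump <- trial_type %in% c("fwd_jump", "bwd_jump")
    if (is_jump || isTRUE(cfg$model_catch_response)) {
      if (is_jump) {
        hand_sign <- if (jump_dir == "forward") 1 else -1
        if (block == "Anti") hand_sign <- -hand_sign
        base_lat <- cfg$condition_effects$jump_latency[[block]]
      } else {
        # catch trials: hand compensates opposite to the cursor shift
        hand_sign <- if (jump_dir == "forward") -1 else 1
        base_lat <- 0.200
      }
      jump_lat <- base_lat + participant$jump_offset +
        stats::rnorm(1, 0, cfg$emg$latency_trial_jitter)
      corr_start <- jump_onset + jump_lat + cfg$jump$accel_delay
      angle <- angle + min_jerk_pos_fast(traj$time, 0,
                                         hand_sign * cfg$jump$magnitude,
                                         corr_start,
                                         cfg$jump$correction_duration)
      jump_emg <- list(onset_time = jump_onset,
                       muscle = if (hand_sign > 0) "flexor" else "extensor",
                       latency = jump_lat)
    }
  }

  if (experiment_id == 3L && perturbed && isTRUE(mp_triggered)) {
    ha <- hide_angle_for(cursor, cfg$movement$start_angle)
    if (is.null(ha)) {
      elim <- 0
    } else {
      eidx <- which(traj$angle >= ha)[1L]
      elim <- mp_onset - (eidx - 1L) / cfg$fs_kin
    }
  }

  if (isTRUE(cfg$stochastic) && cfg$kin_noise_sd > 0) {
    angle <- angle + stats::rnorm(length(angle), 0, cfg$kin_noise_sd)
  }

  is_catch <- trial_type %in% c("fwd_shift", "bwd_shift")
  if (is_catch && !isTRUE(cfg$emg_for_catch)) {
    emg <- list(flexor = NULL, extensor = NULL)
  } else {
    emg <- simulate_emg(traj, cfg, ckey,
                        mp_onset_time = if (isTRUE(mp_triggered)) mp_onset
                          else NA,
                        jump = jump_emg, participant = participant)
  }

  list(signals = list(angle = angle, emg_flexor = emg$flexor,
                      emg_extensor = emg$extensor),
       condition = ckey, perturbed = perturbed, mp_triggered = mp_triggered,
       mp_onset_time = mp_onset, jump_dir = jump_dir,
       jump_onset_time = jump_onset, jump_latency_true = jump_lat,
       endpoint_true = traj$endpoint, duration_true = traj$duration,
       cursor_elim_duration = elim,
       ll_mult = cfg$condition_effects$ll_mult[[ckey]])
}
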