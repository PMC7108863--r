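#' Quantify every trial of a dataset
#'
#' Runs the signal pipeline on each trial: rectified-EMG window measures
#' (background, short- and long-latency components, normalized by the
#' participant's isometric reference) for perturbed trials, visuomotor
#' window means for target-jump trials, and movement metrics (duration,
#' endpoint, peak velocity) for unperturbed trials.
#'
#' @param ds a `reflex_dataset`.
#' @param windows list from [analysis_windows()].
#' @param kin_metrics `"all"` (movement metrics for every analysable trial)
#'   or `"unperturbed"` (only baseline trials; faster when perturbed-trial
#'   kinematics are not analysed).
#' @param vel_at_mp compute the pre-perturbation velocity for perturbed
#'   trials (one extra differentiation per trial).
#' @return data frame, one row per trial, with identification columns and
#'   measures `bga`, `sl`, `ll`, `muscle`, `v_emg_flexor`, `v_emg_extensor`,
#'   `duration_s`, `endpoint_deg`, `peak_vel_dps`, `vel_at_mp_dps`,
#'   `unterminated`.
#' @export
quantify_dataset <- function(ds, windows = analysis_windows(),
                             kin_metrics = c("all", "unperturbed"),
                             vel_at_mp = TRUE) {
  kin_metrics <- match.arg(kin_metrics)
  stopifnot(inherits(ds, "reflex_dataset"))
  cfg <- ds$cfg
  man <- ds$manifest
  refs <- lapply(ds$participants, function(p) list(
    flexor = isometric_reference(p$reference$flexor, cfg$fs_emg),
    extensor = isometric_reference(p$reference$extensor, cfg$fs_emg)))
  names(refs) <- vapply(ds$participants, function(p) as.character(p$id),
                        character(1))
  n <- nrow(man)
  out <- man[, c("trial_id", "participant", "session", "block", "condition",
                 "target", "cursor", "trial_type", "jump_dir",
                 "cursor_elim_duration")]
  out$muscle <- NA_character_
  for (cname in c("bga", "sl", "ll", "v_emg_flexor", "v_emg_extensor",
                  "duration_s", "endpoint_deg", "peak_vel_dps",
                  "vel_at_mp_dps")) {
    out[[cname]] <- NA_real_
  }
  out$unterminated <- NA

  for (i in seq_len(n)) {
    tr <- ds$trials[[i]]
    type <- man$trial_type[i]
    pid <- as.character(man$participant[i])

    if (type == "MP" && isTRUE(man$mp_triggered[i])) {
      # only the stretched muscle enters the reflex windows
      muscle <- if (cfg$mp$direction == "extension") "flexor" else "extensor"
      rect <- rectify_channel(tr[[paste0("emg_", muscle)]], cfg$fs_emg)
      rel <- seq.int(0, length(rect) - 1L) / cfg$fs_emg -
        man$mp_onset_time[i]
      ref <- refs[[pid]][[muscle]]
      out$muscle[i] <- muscle
      out$bga[i] <- window_mean(rect, rel, windows$bga) / ref
      out$sl[i] <- window_mean(rect, rel, windows$short_latency) / ref
      out$ll[i] <- window_mean(rect, rel, windows$long_latency) / ref
      if (vel_at_mp) {
        kt <- derive_kinematics(tr$angle, cfg$fs_kin, acceleration = FALSE)
        j <- max(1L, round(man$mp_onset_time[i] * cfg$fs_kin))
        out$vel_at_mp_dps[i] <- kt$velocity[j]
      }
    } else if (type %in% c("fwd_jump", "bwd_jump")) {
      rel <- seq.int(0, length(tr$emg_flexor) - 1L) / cfg$fs_emg -
        man$jump_onset_time[i]
      out$v_emg_flexor[i] <-
        window_mean(rectify_channel(tr$emg_flexor, cfg$fs_emg), rel,
                    windows$v_emg) / refs[[pid]]$flexor
      out$v_emg_extensor[i] <-
        window_mean(rectify_channel(tr$emg_extensor, cfg$fs_emg), rel,
                    windows$v_emg) / refs[[pid]]$extensor
      if (kin_metrics == "all") {
        kt <- derive_kinematics(tr$angle, cfg$fs_kin, acceleration = FALSE)
        mm <- movement_metrics(kt)
        out$duration_s[i] <- mm$duration
        out$endpoint_deg[i] <- mm$endpoint
        out$peak_vel_dps[i] <- mm$peak_velocity
        out$unterminated[i] <- mm$unterminated
      }
    } else if (type == "N") {
      kt <- derive_kinematics(tr$angle, cfg$fs_kin, acceleration = FALSE)
      mm <- movement_metrics(kt)
      out$duration_s[i] <- mm$duration
      out$endpoint_deg[i] <- mm$endpoint
      out$peak_vel_dps[i] <- mm$peak_velocity
      out$unterminated[i] <- mm$unterminated
    }
    # cursor-shift catch trials carry metadata only
  }
  out
}

# high-pass + rectify one raw EMG channel (the preprocessing stage applied
# channel-wise; preprocess_emg() is the two-channel wrapper)
rectify_channel <- function(x, fs, cutoff = 50) {
  abs(butter_zerophase(x, fs, cutoff, "high"))
}

#' Apply the trial- and participant-screening rules to a measures table
#'
#' Perturbed trials are screened on background activity and the long-latency
#' component, target-jump trials on the visuomotor window means (2-SD rule
#' around the cell median); unperturbed standard-target trials on movement
#' duration and endpoint (3-MAD rule).  Optionally the participant
#' background-stability rule is applied to the screened perturbed trials.
#'
#' @param measures output of [quantify_dataset()].
#' @param participant_rule apply the +/-25% background-activity participant
#'   exclusion (the co-contraction check of the rotation experiment).
#' @return list with `measures` (the input plus logical `included`),
#'   `report` (a `screening_report`) and `excluded_participants`.
#' @export
screen_dataset <- function(measures, participant_rule = FALSE) {
  n <- nrow(measures)
  mask_measures <- rep(NA, n)
  mask_unpert <- rep(NA, n)

  mp <- which(measures$trial_type == "MP" & !is.na(measures$ll))
  if (length(mp) > 0L) {
    mask_measures[mp] <- exclude_measure_outliers(
      measures[mp, c("bga", "ll")],
      measures[mp, c("participant", "condition")])
  }
  jp <- which(measures$trial_type %in% c("fwd_jump", "bwd_jump") &
                !is.na(measures$v_emg_flexor))
  if (length(jp) > 0L) {
    mask_measures[jp] <- exclude_measure_outliers(
      measures[jp, c("v_emg_flexor", "v_emg_extensor")],
      measures[jp, c("participant", "condition", "jump_dir")])
  }
  un <- which(measures$trial_type == "N" & measures$target == "Std" &
                !is.na(measures$duration_s))
  if (length(un) > 0L) {
    mask_unpert[un] <- exclude_unperturbed_outliers(
      measures$duration_s[un], measures$endpoint_deg[un],
      measures[un, c("participant", "condition")])
  }

  excluded_participants <- integer(0)
  part_tab <- NULL
  if (participant_rule && length(mp) > 0L) {
    keep <- mp[!(mask_measures[mp] %in% TRUE)]
    bga_means <- stats::aggregate(
      list(bga = measures$bga[keep]),
      list(participant = measures$participant[keep],
           condition = measures$condition[keep]), mean)
    part_tab <- exclude_participants_bga(bga_means)
    excluded_participants <- part_tab$participant[part_tab$excluded]
  }

  report <- screening_report(
    list(measures = mask_measures, unperturbed = mask_unpert),
    measures$participant, participant_exclusions = part_tab)
  measures$included <- !report$combined &
    !(measures$participant %in% excluded_participants)
  list(measures = measures, report = report,
       excluded_participants = excluded_participants)
}

#' Collapse screened trial measures to participant-by-condition summaries
#'
#' The unit of all statistics: per participant and condition, the mean
#' background/short-/long-latency reflex amplitudes over surviving perturbed
#' trials, the endpoint SD and movement metrics over surviving unperturbed
#' standard-target trials, and (when target jumps are present) the mean
#' visuomotor window responses per jump direction and their
#' forward-minus-backward difference.
#'
#' @param measures screened measures table (with `included`).
#' @return data frame, one row per participant x condition.
#' @export
condition_summaries <- function(measures) {
  m <- measures[measures$included, ]
  key <- c("participant", "condition")
  pieces <- list()

  mp <- m[m$trial_type == "MP" & !is.na(m$ll), ]
  if (nrow(mp) > 0L) {
    pieces$mp <- stats::aggregate(mp[, c("bga", "sl", "ll", "vel_at_mp_dps")],
                                  mp[key], mean, na.rm = TRUE)
    pieces$mp$n_mp <- stats::aggregate(list(n = mp$ll), mp[key], length)$n
  }
  un <- m[m$trial_type == "N" & m$target == "Std" & !is.na(m$endpoint_deg) &
            !(m$unterminated %in% TRUE), ]
  if (nrow(un) > 0L) {
    esd <- endpoint_sd(un$endpoint_deg, un[key])
    mov <- stats::aggregate(un[, c("duration_s", "endpoint_deg",
                                   "peak_vel_dps")], un[key], mean)
    pieces$un <- merge(esd, mov, by = key)
  }
  jp <- m[m$trial_type %in% c("fwd_jump", "bwd_jump") &
            !is.na(m$v_emg_flexor), ]
  if (nrow(jp) > 0L) {
    vag <- stats::aggregate(jp[, c("v_emg_flexor", "v_emg_extensor")],
                            jp[c(key, "jump_dir")], mean)
    fwd <- vag[vag$jump_dir == "forward", ]
    bwd <- vag[vag$jump_dir == "backward", ]
    names(fwd)[names(fwd) == "v_emg_flexor"] <- "v_emg_fwd_flexor"
    names(fwd)[names(fwd) == "v_emg_extensor"] <- "v_emg_fwd_extensor"
    names(bwd)[names(bwd) == "v_emg_flexor"] <- "v_emg_bwd_flexor"
    names(bwd)[names(bwd) == "v_emg_extensor"] <- "v_emg_bwd_extensor"
    vj <- merge(fwd[, c(key, "v_emg_fwd_flexor", "v_emg_fwd_extensor")],
                bwd[, c(key, "v_emg_bwd_flexor", "v_emg_bwd_extensor")],
                by = key, all = TRUE)
    vj$dv_emg_flexor <- delta_v_emg(vj$v_emg_fwd_flexor, vj$v_emg_bwd_flexor)
    vj$dv_emg_extensor <- delta_v_emg(vj$v_emg_fwd_extensor,
                                      vj$v_emg_bwd_extensor)
    pieces$jp <- vj
  }
  if (length(pieces) == 0L) stop("no analysable trials in the measures table")
  out <- Reduce(function(x, y) merge(x, y, by = key, all = TRUE), pieces)
  # carry session/block labels (condition labels are unique within a dataset)
  lab <- unique(measures[, c("participant", "condition", "session")])
  out <- merge(out, lab, by = key, all.x = TRUE)
  out[order(out$participant, out$condition), ]
}

# drop participants missing any condition cell for a given measure
complete_participants <- function(summaries, measure, conditions = NULL) {
  d <- summaries[!is.na(summaries[[measure]]), ]
  if (is.null(conditions)) conditions <- unique(d$condition)
  d <- d[d$condition %in% conditions, ]
  counts <- table(d$participant)
  keep <- names(counts)[counts == length(conditions)]
  if (length(keep) < length(counts)) {
    warning("dropping ", length(counts) - length(keep), " participant(s) ",
            "with incomplete '", measure, "' cells")
  }
  d[d$participant %in% keep, ]
}

#' Detect target-jump response latencies for every participant and block
#'
#' For each participant and block with target jumps, forward- and
#' backward-jump trials are aligned on the jump onset, and the successive
#' t-test procedure is run on the hand-acceleration ensembles (10
#' consecutive sub-alpha samples) and on the flexor and extensor EMG
#' envelopes (50 consecutive samples).  The test direction follows the task:
#' forward corrections accelerate the hand into flexion and recruit the
#' flexor except in the anti-reaction task, where both are reversed.
#'
#' @param ds a `reflex_dataset` containing target-jump trials.
#' @param window alignment window around the jump (s).
#' @return data frame with `participant`, `session`, `block`, `signal`
#'   (`acceleration`, `flexor_emg`, `extensor_emg`, `emg` = earlier of the
#'   two muscles) and `onset_s` (`NA` when not detected).
#' @export
jump_latency_analysis <- function(ds, window = c(-0.1, 0.45)) {
  cfg <- ds$cfg
  man <- ds$manifest
  jm <- man[man$trial_type %in% c("fwd_jump", "bwd_jump"), ]
  if (nrow(jm) == 0L) stop("dataset contains no target-jump trials")
  out <- list()
  for (p in unique(jm$participant)) {
    for (b in unique(jm$block[jm$participant == p])) {
      sel <- jm[jm$participant == p & jm$block == b, ]
      session <- sel$session[1L]
      fwd_ids <- sel$trial_id[sel$jump_dir == "forward"]
      bwd_ids <- sel$trial_id[sel$jump_dir == "backward"]
      anti <- b == "Anti"

      get_accel <- function(ids) lapply(ids, function(tid) {
        derive_kinematics(ds$trials[[tid]]$angle, cfg$fs_kin)$acceleration
      })
      get_env <- function(ids) lapply(ids, function(tid) {
        tr <- ds$trials[[tid]]
        env <- emg_envelope(preprocess_emg(
          emg_trace(tr$emg_flexor, tr$emg_extensor, cfg$fs_emg)))
        list(flexor = env$flexor, extensor = env$extensor)
      })
      ens <- function(series, ids, fs) {
        align_to_event(series, man$jump_onset_time[ids], fs, window)
      }
      acc_f <- ens(get_accel(fwd_ids), fwd_ids, cfg$fs_kin)
      acc_b <- ens(get_accel(bwd_ids), bwd_ids, cfg$fs_kin)
      acc_lat <- successive_ttest_latency(
        acc_f$data, acc_b$data, acc_f$time, n_consecutive = 10,
        tail = if (anti) "less" else "greater")$onset_time

      env_f <- get_env(fwd_ids)
      env_b <- get_env(bwd_ids)
      flex_f <- ens(lapply(env_f, `[[`, "flexor"), fwd_ids, cfg$fs_emg)
      flex_b <- ens(lapply(env_b, `[[`, "flexor"), bwd_ids, cfg$fs_emg)
      ext_f <- ens(lapply(env_f, `[[`, "extensor"), fwd_ids, cfg$fs_emg)
      ext_b <- ens(lapply(env_b, `[[`, "extensor"), bwd_ids, cfg$fs_emg)
      flex_lat <- successive_ttest_latency(
        flex_f$data, flex_b$data, flex_f$time, n_consecutive = 50,
        tail = if (anti) "less" else "greater")$onset_time
      ext_lat <- successive_ttest_latency(
        ext_f$data, ext_b$data, ext_f$time, n_consecutive = 50,
        tail = if (anti) "greater" else "less")$onset_time
      emg_lat <- if (all(is.na(c(flex_lat, ext_lat)))) NA_real_ else {
        min(c(flex_lat, ext_lat), na.rm = TRUE)
      }
      out[[length(out) + 1L]] <- data.frame(
        participant = p, session = session, block = b,
        signal = c("acceleration", "flexor_emg", "extensor_emg", "emg"),
        onset_s = c(acc_lat, flex_lat, ext_lat, emg_lat))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
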