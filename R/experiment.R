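#' Configuration of a full analysis run
#'
#' @param experiment_id experiment number 1-4.
#' @param seed integer seed; propagated to the generator and the bootstrap.
#' @param input `"synthetic"` (generate and analyse a synthetic cohort) or
#'   `"source_tables"` (skip the signal stages and run the statistics on an
#'   external per-participant measures table).
#' @param generator list of [generator_config()] overrides.
#' @param windows analysis windows, see [analysis_windows()].
#' @param v_window `"cohort"` (experiment 4: recompute the visuomotor window
#'   from the cohort's detected response latencies) or `"fixed"`.
#' @param d_variant Cohen's d variant for paired tests.
#' @param bootstrap_B bootstrap resamples for the correlation CI.
#' @param participant_rule apply the background-stability participant
#'   exclusion (defaults to on for experiment 1).
#' @param kin_metrics passed to [quantify_dataset()].
#' @param source_path,source_column_map,measure_map source-table mode inputs,
#'   see [read_source_table()].
#' @param out_dir optional directory; when set, the results bundle is written
#'   there as CSV/JSON.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(experiment_id, seed = 1L,
                              input = c("synthetic", "source_tables"),
                              generator = list(),
                              windows = analysis_windows(),
                              v_window = c("cohort", "fixed"),
                              d_variant = "d_av", bootstrap_B = 1000L,
                              participant_rule = experiment_id == 1,
                              kin_metrics = "all",
                              source_path = NULL, source_column_map = NULL,
                              measure_map = NULL, out_dir = NULL) {
  structure(list(experiment_id = as.integer(experiment_id),
                 seed = as.integer(seed), input = match.arg(input),
                 generator = generator, windows = windows,
                 v_window = match.arg(v_window), d_variant = d_variant,
                 bootstrap_B = as.integer(bootstrap_B),
                 participant_rule = participant_rule,
                 kin_metrics = kin_metrics, source_path = source_path,
                 source_column_map = source_column_map,
                 measure_map = measure_map, out_dir = out_dir),
            class = "experiment_config")
}

stat_row <- function(measure, analysis, effect, statistic, df1 = NA, df2 = NA,
                     p = NA, effect_size = NA, ci_lo = NA, ci_hi = NA) {
  data.frame(measure = measure, analysis = analysis, effect = effect,
             statistic = statistic, df1 = df1, df2 = df2, p = p,
             effect_size = effect_size, ci_lo = ci_lo, ci_hi = ci_hi,
             stringsAsFactors = FALSE)
}

#' Inferential statistics for one experiment's condition summaries
#'
#' Experiments 1 and 3: one-way repeated-measures ANOVA (factor: visual
#' condition) with Tukey-HSD post hocs on background, short- and
#' long-latency amplitudes and endpoint SD, plus the per-participant
#' correlation of long-latency amplitude and endpoint SD with a bootstrap CI
#' on its group mean.  Experiment 2: two-way repeated-measures ANOVA
#' (feedback direction x cursor visibility) on the same measures plus the
#' correlation across the four cells.  Experiment 4: paired t-tests (Pro vs
#' Anti, Normal vs Mirror) on the flexor delta v-EMG and the long-latency
#' reflex.
#'
#' @param summaries output of [condition_summaries()] (or the equivalent
#'   table read from external source data).
#' @param experiment_id experiment number.
#' @param d_variant,B,boot_seed statistics options.
#' @return list with `table` (tidy rows), `anovas`, `tukey`, `ttests`,
#'   `correlation`.
#' @export
experiment_stats <- function(summaries, experiment_id, d_variant = "d_av",
                             B = 1000L, boot_seed = 1L) {
  experiment_id <- as.integer(experiment_id)
  rows <- list()
  anovas <- list()
  tukeys <- list()
  ttests <- list()
  correlation <- NULL
  have <- function(m) m %in% names(summaries) && any(!is.na(summaries[[m]]))

  if (experiment_id %in% c(1L, 3L)) {
    for (m in c("bga", "sl", "ll", "endpoint_sd")) {
      if (!have(m)) next
      d <- complete_participants(summaries, m)
      a <- rm_anova_oneway(d, value = m)
      anovas[[m]] <- a
      rows[[length(rows) + 1L]] <- stat_row(
        m, "rm_anova_oneway", "condition", a$effects$F, a$effects$df1,
        a$effects$df2, a$effects$p, a$effects$partial_eta_sq)
      tk <- tukey_hsd(a)
      tukeys[[m]] <- tk
      for (j in seq_len(nrow(tk))) {
        rows[[length(rows) + 1L]] <- stat_row(
          m, "tukey_hsd", paste(tk$cond_a[j], tk$cond_b[j], sep = " vs "),
          tk$q[j], p = tk$p_adjusted[j])
      }
    }
  } else if (experiment_id == 2L) {
    for (m in c("bga", "sl", "ll", "endpoint_sd", "peak_vel_dps",
                "vel_at_mp_dps")) {
      if (!have(m)) next
      d <- complete_participants(summaries, m)
      fc <- do.call(rbind, strsplit(d$condition, ".", fixed = TRUE))
      d$feedback <- fc[, 1L]
      d$cursor_vis <- fc[, 2L]
      a <- rm_anova_twoway(d, value = m, factor1 = "feedback",
                           factor2 = "cursor_vis")
      anovas[[m]] <- a
      for (j in seq_len(nrow(a$effects))) {
        rows[[length(rows) + 1L]] <- stat_row(
          m, "rm_anova_twoway", a$effects$effect[j], a$effects$F[j],
          a$effects$df1[j], a$effects$df2[j], a$effects$p[j],
          a$effects$partial_eta_sq[j])
      }
    }
  } else if (experiment_id == 4L) {
    pairs <- list(c("Pro", "Anti"), c("Normal", "Mirror"))
    for (m in c("dv_emg_flexor", "dv_emg_extensor", "ll")) {
      if (!have(m)) next
      for (pr in pairs) {
        d <- complete_participants(summaries, m, conditions = pr)
        if (nrow(d) == 0L) next
        w <- wide_cell_means(d, value = m)
        tt <- paired_ttest(w[, pr[1L]], w[, pr[2L]], d_variant = d_variant)
        ttests[[paste(m, pr[1L], pr[2L], sep = "_")]] <- tt
        rows[[length(rows) + 1L]] <- stat_row(
          m, "paired_t", paste(pr, collapse = " vs "), tt$t, df1 = tt$df,
          p = tt$p, effect_size = tt$cohens_d)
      }
    }
  }

  if (experiment_id %in% 1:3 && have("ll") && have("endpoint_sd")) {
    d <- summaries[!is.na(summaries$ll) & !is.na(summaries$endpoint_sd), ]
    correlation <- reflex_variability_correlation(
      d, x = "ll", y = "endpoint_sd", B = B, seed = boot_seed)
    rows[[length(rows) + 1L]] <- stat_row(
      "ll_vs_endpoint_sd", "correlation", "mean_r", correlation$mean_r,
      ci_lo = correlation$ci[1L], ci_hi = correlation$ci[2L])
  }

  list(table = do.call(rbind, rows), anovas = anovas, tukey = tukeys,
       ttests = ttests, correlation = correlation)
}

#' Run a full experiment: generate, process, screen, quantify, test
#'
#' Orchestrates the pipeline for one experiment under a fixed seed; the
#' whole bundle is a deterministic function of the configuration.
#'
#' @param config an [experiment_config()].
#' @return a `results_bundle` list with the generator configuration, trial
#'   `measures`, `screening`, condition `summaries`, `stats`, detected
#'   `latencies` (experiment 4) and the analysis `windows` used.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  id <- config$experiment_id
  windows <- config$windows
  latencies <- NULL

  if (config$input == "synthetic") {
    cfg <- do.call(generator_config,
                   c(list(experiment_id = id, seed = config$seed),
                     config$generator))
    ds <- generate_dataset(id, cfg)
    if (id == 4L && config$v_window == "cohort") {
      latencies <- jump_latency_analysis(ds)
      emg <- latencies[latencies$signal == "emg", ]
      pro_min <- tryCatch(
        cohort_shortest_latency(emg$onset_s[emg$block == "Pro"]),
        error = function(e) NA_real_)
      anti_min <- tryCatch(
        cohort_shortest_latency(emg$onset_s[emg$block == "Anti"]),
        error = function(e) NA_real_)
      if (!is.na(pro_min) && !is.na(anti_min) && pro_min < anti_min) {
        windows$v_emg <- v_emg_window(pro_min, anti_min)
      } else {
        warning("cohort latencies unusable; keeping the fixed ",
                "visuomotor window")
      }
    }
    measures <- quantify_dataset(ds, windows,
                                 kin_metrics = config$kin_metrics)
    scr <- screen_dataset(measures,
                          participant_rule = isTRUE(config$participant_rule))
    summaries <- condition_summaries(scr$measures)
    generator_cfg <- cfg
  } else {
    long <- read_source_table(config$source_path, config$source_column_map,
                              config$measure_map)
    summaries <- stats::reshape(long, idvar = c("participant", "condition"),
                                timevar = "measure", direction = "wide")
    names(summaries) <- sub("^value\\.", "", names(summaries))
    scr <- NULL
    generator_cfg <- NULL
  }

  st <- experiment_stats(summaries, id, d_variant = config$d_variant,
                         B = config$bootstrap_B, boot_seed = config$seed)
  bundle <- structure(list(
    config = config, generator_cfg = generator_cfg,
    measures = if (config$input == "synthetic") scr$measures else NULL,
    screening = if (is.null(scr)) NULL else scr$report,
    excluded_participants = if (is.null(scr)) NULL else {
      scr$excluded_participants
    },
    summaries = summaries, stats = st, latencies = latencies,
    windows = windows), class = "results_bundle")
  if (!is.null(config$out_dir)) write_results_bundle(bundle, config$out_dir)
  bundle
}

#' Write a results bundle to CSV/JSON files
#'
#' @param bundle a `results_bundle` from [run_experiment()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_results_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$measures)) {
    utils::write.csv(bundle$measures, file.path(dir, "measures.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(bundle$summaries, file.path(dir, "summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$stats$table, file.path(dir, "stats.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$latencies)) {
    utils::write.csv(bundle$latencies, file.path(dir, "latencies.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$screening)) {
    s <- bundle$screening
    jsonlite::write_json(
      list(overall_fraction = s$overall_fraction,
           max_participant_fraction = s$max_participant_fraction,
           per_participant_fraction = as.list(s$per_participant_fraction),
           excluded_participants = bundle$excluded_participants),
      file.path(dir, "screening.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(experiment_id = bundle$config$experiment_id,
         seed = bundle$config$seed,
         v_emg_window = bundle$windows$v_emg),
    file.path(dir, "run.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
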