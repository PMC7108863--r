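#' Write a dataset to a plain-text trial store
#'
#' One kinematics CSV (`time_s`, `angle_deg`) and one EMG CSV (`time_s`,
#' `emg_flexor`, `emg_extensor`) per trial, a JSON metadata sidecar per
#' trial, per-participant isometric reference CSVs, and a dataset manifest
#' CSV.
#'
#' @param ds a `reflex_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_store <- function(ds, dir) {
  stopifnot(inherits(ds, "reflex_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fs_kin <- ds$cfg$fs_kin
  fs_emg <- ds$cfg$fs_emg
  for (i in seq_len(nrow(ds$manifest))) {
    tr <- ds$trials[[i]]
    id <- sprintf("trial_%05d", ds$manifest$trial_id[i])
    utils::write.csv(
      data.frame(time_s = seq.int(0, length(tr$angle) - 1L) / fs_kin,
                 angle_deg = tr$angle),
      file.path(dir, paste0(id, "_kin.csv")), row.names = FALSE)
    utils::write.csv(
      data.frame(time_s = seq.int(0, length(tr$emg_flexor) - 1L) / fs_emg,
                 emg_flexor = tr$emg_flexor, emg_extensor = tr$emg_extensor),
      file.path(dir, paste0(id, "_emg.csv")), row.names = FALSE)
    meta <- as.list(ds$manifest[i, ])
    jsonlite::write_json(meta, file.path(dir, paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  for (p in ds$participants) {
    utils::write.csv(
      data.frame(emg_flexor = p$reference$flexor,
                 emg_extensor = p$reference$extensor),
      file.path(dir, sprintf("reference_P%03d.csv", p$id)),
      row.names = FALSE)
  }
  utils::write.csv(ds$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(experiment_id = ds$experiment_id, fs_kin = fs_kin, fs_emg = fs_emg,
         n_participants = ds$cfg$n_participants, seed = ds$cfg$seed),
    file.path(dir, "dataset.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a trial store written by [write_trial_store()]
#'
#' @param dir trial-store directory.
#' @param cfg optional [generator_config()] to attach (the store itself
#'   carries only rates and ids).
#' @return a `reflex_dataset`.
#' @export
read_trial_store <- function(dir, cfg = NULL) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  info <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  trials <- lapply(manifest$trial_id, function(tid) {
    id <- sprintf("trial_%05d", tid)
    kin <- utils::read.csv(file.path(dir, paste0(id, "_kin.csv")))
    emg <- utils::read.csv(file.path(dir, paste0(id, "_emg.csv")))
    list(angle = kin$angle_deg, emg_flexor = emg$emg_flexor,
         emg_extensor = emg$emg_extensor)
  })
  parts <- sort(unique(manifest$participant))
  participants <- lapply(parts, function(p) {
    ref <- utils::read.csv(file.path(dir, sprintf("reference_P%03d.csv", p)))
    list(id = p, reference = list(flexor = ref$emg_flexor,
                                  extensor = ref$emg_extensor))
  })
  if (is.null(cfg)) {
    cfg <- generator_config(info$experiment_id,
                            n_participants = info$n_participants,
                            seed = info$seed)
    cfg$fs_kin <- info$fs_kin
    cfg$fs_emg <- info$fs_emg
  }
  structure(list(experiment_id = info$experiment_id, cfg = cfg,
                 participants = participants, manifest = manifest,
                 trials = trials),
            class = "reflex_dataset")
}

#' Read an external per-participant measures table
#'
#' Ingests a delimited long- or wide-format table of quantified measures
#' (such as the per-participant source tables published with the study) and
#' normalizes it to the package's long format: `participant`, `condition`,
#' `measure`, `value`.
#'
#' @param path CSV/TSV file path (delimiter inferred from the extension).
#' @param column_map named character vector mapping package column names
#'   (`participant`, `condition`, and either `measure` + `value`, or nothing
#'   else for wide tables whose remaining columns are measures) to the file's
#'   column names.
#' @param measure_map optional named character vector renaming measure labels
#'   to the package vocabulary (`bga`, `sl`, `ll`, `endpoint_sd`,
#'   `v_emg_fwd`, `v_emg_bwd`, `dv_emg`, ...).
#' @return long data frame with `participant`, `condition`, `measure`,
#'   `value`.
#' @export
read_source_table <- function(path, column_map = c(participant = "participant",
                                                   condition = "condition"),
                              measure_map = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (need in c("participant", "condition")) {
    if (!need %in% names(column_map) || !column_map[[need]] %in% names(raw)) {
      stop("column_map must map '", need, "' onto one of: ",
           paste(names(raw), collapse = ", "))
    }
  }
  out <- data.frame(participant = raw[[column_map[["participant"]]]],
                    condition = raw[[column_map[["condition"]]]],
                    stringsAsFactors = FALSE)
  if ("measure" %in% names(column_map)) {
    if (!"value" %in% names(column_map)) {
      stop("column_map with 'measure' also needs 'value'")
    }
    out$measure <- raw[[column_map[["measure"]]]]
    out$value <- raw[[column_map[["value"]]]]
  } else {
    mcols <- setdiff(names(raw), unname(column_map))
    if (length(mcols) == 0L) stop("no measure columns found in ", path)
    out <- do.call(rbind, lapply(mcols, function(m) {
      cbind(out, data.frame(measure = m, value = raw[[m]],
                            stringsAsFactors = FALSE))
    }))
  }
  if (!is.null(measure_map)) {
    hit <- out$measure %in% names(measure_map)
    out$measure[hit] <- measure_map[out$measure[hit]]
  }
  if (!is.numeric(out$value)) stop("measure values are not numeric")
  rownames(out) <- NULL
  out
}
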