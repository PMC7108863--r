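#' Screen perturbed/jump trials on their EMG measures
#'
#' A trial is excluded when, for any of the supplied measures (background
#' activity, long-latency reflex, visuomotor response), its value deviates
#' from the condition-cell median by more than two cell standard deviations.
#' The SD is computed over the unmutated cell (n-1 denominator, candidate
#' included); screening is single-pass, so the mask does not depend on trial
#' order.  Cells with fewer than `min_cell` trials are skipped with a
#' warning.
#'
#' @param values data frame (or list) of measure columns, one row per trial.
#' @param by data frame of grouping columns defining the condition cells.
#' @param n_sd exclusion threshold in cell SDs.
#' @param min_cell minimum cell size for the rule to apply.
#' @return logical vector, `TRUE` = excluded.
#' @export
exclude_measure_outliers <- function(values, by, n_sd = 2, min_cell = 3L) {
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  by <- as.data.frame(by, stringsAsFactors = FALSE)
  stopifnot(nrow(values) == nrow(by))
  key <- interaction(by, drop = TRUE, lex.order = TRUE)
  excluded <- logical(nrow(values))
  skipped <- 0L
  for (cell in split(seq_len(nrow(values)), key)) {
    if (length(cell) < min_cell) {
      skipped <- skipped + 1L
      next
    }
    for (m in names(values)) {
      x <- values[[m]][cell]
      s <- stats::sd(x)
      dev <- abs(x - stats::median(x))
      excluded[cell] <- excluded[cell] | (dev > n_sd * s)
    }
  }
  if (skipped > 0L) {
    warning(skipped, " cell(s) smaller than ", min_cell,
            " trials: measure screening skipped there")
  }
  excluded
}

#' Screen unperturbed trials on movement duration and endpoint
#'
#' A trial is excluded when its movement duration or endpoint deviates from
#' the condition-cell median by more than three times the cell's median
#' absolute deviation (raw MAD, no consistency scaling).  When the MAD is
#' zero and any trial deviates, only exact-median trials survive; this is
#' logged loudly.
#'
#' @param duration,endpoint numeric vectors, one value per trial.
#' @param by data frame of grouping columns defining the condition cells.
#' @param n_mad exclusion threshold in MADs.
#' @param min_cell minimum cell size for the rule to apply.
#' @return logical vector, `TRUE` = excluded.
#' @export
exclude_unperturbed_outliers <- function(duration, endpoint, by, n_mad = 3,
                                         min_cell = 3L) {
  by <- as.data.frame(by, stringsAsFactors = FALSE)
  stopifnot(length(duration) == nrow(by), length(endpoint) == nrow(by))
  key <- interaction(by, drop = TRUE, lex.order = TRUE)
  excluded <- logical(length(duration))
  for (cell in split(seq_along(duration), key)) {
    if (length(cell) < min_cell) next
    for (x in list(duration[cell], endpoint[cell])) {
      med <- stats::median(x)
      m <- stats::mad(x, constant = 1)
      dev <- abs(x - med)
      if (m == 0 && any(dev > 0)) {
        warning("zero MAD in a screening cell: only exact-median trials kept")
      }
      excluded[cell] <- excluded[cell] | (dev > n_mad * m)
    }
  }
  excluded
}

#' Exclude participants with unstable background activity
#'
#' A participant is excluded when their mean background activity in any
#' condition falls outside +/-25% of their own average across conditions
#' (co-contraction confounds reflex amplitudes, which scale with background
#' activity).
#'
#' @param bga_means data frame with columns `participant`, `condition`,
#'   `bga` (one row per participant-condition mean).
#' @param tolerance allowed fractional deviation from the across-condition
#'   average.
#' @return data frame with `participant`, `excluded` and the offending
#'   `worst_ratio` (condition mean over grand mean farthest from 1).
#' @export
exclude_participants_bga <- function(bga_means, tolerance = 0.25) {
  stopifnot(all(c("participant", "condition", "bga") %in% names(bga_means)))
  out <- do.call(rbind, lapply(split(bga_means, bga_means$participant),
    function(d) {
      grand <- mean(d$bga)
      ratio <- d$bga / grand
      worst <- ratio[which.max(abs(ratio - 1))]
      data.frame(participant = d$participant[1L],
                 excluded = any(ratio < 1 - tolerance |
                                ratio > 1 + tolerance),
                 worst_ratio = worst)
    }))
  rownames(out) <- NULL
  out
}

#' Assemble a screening report
#'
#' @param masks named list of logical exclusion masks over the same trials
#'   (e.g. `measure`, `unperturbed`); `NA` entries mean the rule did not
#'   apply to that trial and are treated as not excluded.
#' @param participant participant id per trial.
#' @param participant_exclusions optional output of
#'   [exclude_participants_bga()].
#' @param warn_fraction warn when any cell loses more than this fraction.
#' @return a `screening_report` list with the combined mask, overall and
#'   per-participant excluded fractions and the participant exclusion table.
#' @export
screening_report <- function(masks, participant,
                             participant_exclusions = NULL,
                             warn_fraction = 0.5) {
  masks <- lapply(masks, function(m) {
    m[is.na(m)] <- FALSE
    m
  })
  combined <- Reduce(`|`, masks)
  per_part <- tapply(combined, participant, mean)
  if (any(per_part > warn_fraction)) {
    warning("screening excluded more than ", round(100 * warn_fraction),
            "% of trials for participant(s) ",
            paste(names(per_part)[per_part > warn_fraction], collapse = ", "))
  }
  structure(list(
    masks = masks, combined = combined,
    overall_fraction = mean(combined),
    per_participant_fraction = per_part,
    max_participant_fraction = max(per_part),
    participant_exclusions = participant_exclusions),
    class = "screening_report")
}
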