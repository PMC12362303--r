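#' Write a table as TSV
#'
#' Plain tab-separated values with a header, no quoting, no row names; doubles
#' are written with full precision so a write/read round trip reproduces values
#' to better than 1e-12.
#'
#' @param x data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_tsv <- function(x, path) {
  is_num <- vapply(x, is.double, logical(1))
  x[is_num] <- lapply(x[is_num], function(v) sprintf("%.15g", v))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table, checking required columns
#'
#' @param path input file.
#' @param required character vector of column names that must be present.
#' @return data.frame.
#' @export
read_tsv <- function(path, required = NULL) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(x))
    if (length(missing) > 0) {
      stop("malformed table ", basename(path), ": missing column(s) ",
           paste(missing, collapse = ", "))
    }
  }
  x
}

#' Write one run's signal matrix
#'
#' Layout: first column `frame_time_s`, then one column per region label.
#'
#' @param run a `run_series`.
#' @param path output file.
#' @export
write_signals_tsv <- function(run, path) {
  stopifnot(inherits(run, "run_series"))
  df <- data.frame(frame_time_s = run$frame_times, run$values,
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Read a run signal TSV back into a `run_series`
#'
#' @param path input file.
#' @param stage stage tag to attach.
#' @param participant_id,run_index identity.
#' @return `run_series`.
#' @export
read_signals_tsv <- function(path, stage = "raw", participant_id = "sub-001",
                             run_index = 1L) {
  df <- read_tsv(path, required = "frame_time_s")
  tr <- if (nrow(df) > 1) df$frame_time_s[2] - df$frame_time_s[1] else 2
  run_series(as.matrix(df[, -1, drop = FALSE]), tr_seconds = tr,
             participant_id = participant_id, run_index = run_index,
             stage = stage)
}

#' Read a BIDS-style events TSV
#'
#' @param path input file.
#' @return data.frame with onset, duration, trial_type, episode_id, condition.
#' @export
read_events_tsv <- function(path) {
  read_tsv(path, required = c("onset", "duration", "trial_type",
                              "episode_id", "condition"))
}

#' Write the cohort's small tables to a directory
#'
#' Writes participants, episode design, per-episode event streams, per-run
#' event tables, and the ground-truth JSON (generative parameters and coupling
#' weights) in the pipeline's TSV dialects.
#'
#' @param cohort a `navdyn_cohort`.
#' @param dir output directory (created if missing).
#' @param signals if TRUE also writes every participant-run signal and motion
#'   table (large).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, signals = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  design <- cohort$design
  write_tsv(design$participants, file.path(dir, "participants.tsv"))
  write_tsv(design$episodes, file.path(dir, "episodes.tsv"))
  for (r in seq_len(design$n_runs)) {
    write_tsv(run_events(design, r),
              file.path(dir, sprintf("run-%02d_events.tsv", r)))
  }
  streams <- do.call(rbind, lapply(names(cohort$streams), function(e) {
    cbind(episode_id = e, cohort$streams[[e]])
  }))
  write_tsv(streams, file.path(dir, "event_streams.tsv"))
  gt <- cohort$ground_truth
  gt$coupling_w <- as.data.frame(gt$coupling_w)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (signals) {
    for (i in seq_along(cohort$bold$runs)) {
      pid <- names(cohort$bold$runs)[i]
      for (r in seq_len(design$n_runs)) {
        write_signals_tsv(cohort$bold$runs[[i]][[r]],
                          file.path(dir, sprintf("%s_run-%02d_bold.tsv", pid, r)))
        write_tsv(cohort$motion[[i]][[r]],
                  file.path(dir, sprintf("%s_run-%02d_motion.tsv", pid, r)))
      }
    }
  }
  invisible(dir)
}
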