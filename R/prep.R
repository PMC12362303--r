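#' Run-series container
#'
#' Lightweight container for one run's frames x regions signal matrix with its
#' acquisition times and processing stage. Stages advance strictly in the order
#' raw -> psc -> cleaned -> zscored.
#'
#' @param values numeric matrix, frames x regions (column names = region labels).
#' @param tr_seconds repetition time.
#' @param participant_id,run_index identity.
#' @param stage processing stage tag.
#' @return object of class `run_series`.
#' @export
run_series <- function(values, tr_seconds = 2, participant_id = "sub-001",
                       run_index = 1L, stage = "raw") {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), nrow(values) >= 1)
  stage <- match.arg(stage, c("raw", "psc", "cleaned", "zscored"))
  structure(
    list(values = values,
         frame_times = (seq_len(nrow(values)) - 1) * tr_seconds,
         tr_seconds = tr_seconds, participant_id = participant_id,
         run_index = run_index, stage = stage),
    class = "run_series"
  )
}

.assert_stage <- function(run, expected) {
  stopifnot(inherits(run, "run_series"))
  if (run$stage != expected) {
    stop("run is at stage '", run$stage, "', expected '", expected, "'")
  }
}

#' Percent signal change
#'
#' Converts a raw run to percent signal change per region:
#' `y = (x - mean(x)) / mean(x) * 100`, with the mean taken over the whole run.
#'
#' @param run `run_series` at stage "raw".
#' @return `run_series` at stage "psc".
#' @export
percent_signal_change <- function(run) {
  .assert_stage(run, "raw")
  mu <- colMeans(run$values)
  if (any(abs(mu) < .Machine$double.eps * 100)) {
    bad <- colnames(run$values)[abs(mu) < .Machine$double.eps * 100]
    stop("degenerate signal: zero run mean in region(s) ",
         paste(bad, collapse = ", "))
  }
  run$values <- sweep(sweep(run$values, 2, mu, "-"), 2, mu, "/") * 100
  run$stage <- "psc"
  run
}

#' Expand 6 rigid-body motion parameters to the 24-parameter set
#'
#' Columns: the 6 parameters, their backward-difference temporal derivatives
#' (first frame set to 0), their squares, and the squared derivatives.
#'
#' @param params6 numeric matrix/data.frame, frames x 6.
#' @return numeric matrix frames x 24.
#' @export
expand_motion <- function(params6) {
  params6 <- as.matrix(params6)
  if (ncol(params6) != 6) stop("motion table must have 6 columns, got ", ncol(params6))
  if (nrow(params6) < 2) stop("need at least 2 frames")
  d <- rbind(0, diff(params6))
  out <- cbind(params6, d, params6^2, d^2)
  colnames(out) <- c(paste0("m", 1:6), paste0("m", 1:6, "_d"),
                     paste0("m", 1:6, "_sq"), paste0("m", 1:6, "_dsq"))
  out
}

#' Framewise displacement
#'
#' Power-convention FD: the sum of absolute backward differences of the three
#' translations (mm) plus the three rotations (radians) scaled by a 50 mm
#' sphere radius. The first frame is 0 by convention.
#'
#' @param params6 frames x 6 motion table (translations mm, rotations rad).
#' @param radius_mm rotation-to-arc-length scale (50 mm).
#' @return numeric vector of per-frame FD (mm).
#' @export
framewise_displacement <- function(params6, radius_mm = 50) {
  params6 <- as.matrix(params6)
  if (ncol(params6) != 6) stop("motion table must have 6 columns")
  d <- abs(rbind(0, diff(params6)))
  rowSums(d[, 1:3, drop = FALSE]) + radius_mm * rowSums(d[, 4:6, drop = FALSE])
}

#' Participant mean framewise displacement
#'
#' @param motion_runs list of frames x 6 motion tables (one per run).
#' @return scalar mean FD over all frames of all runs.
#' @export
mean_fd <- function(motion_runs) {
  mean(unlist(lapply(motion_runs, framewise_displacement)))
}

#' Discrete cosine drift basis
#'
#' The lowest `k` non-constant DCT-II basis columns
#' `c_j(t) = cos(pi * j * (2t + 1) / (2n))`, `t = 0..n-1`, `j = 1..k`.
#' Columns are zero-mean and mutually orthogonal.
#'
#' @param n_frames number of frames.
#' @param k number of basis functions (default 5).
#' @return numeric matrix n_frames x k.
#' @export
dct_basis <- function(n_frames, k = 5) {
  if (k >= n_frames) stop("invalid config: k must be < n_frames")
  t <- seq_len(n_frames) - 1
  out <- sapply(seq_len(k), function(j) cos(pi * j * (2 * t + 1) / (2 * n_frames)))
  colnames(out) <- paste0("dct_", seq_len(k))
  out
}

#' Build the per-run confound matrix
#'
#' 24 motion expansions + framewise displacement + 5 DCT columns (30 columns;
#' the intercept is added by the regression step).
#'
#' @param params6 frames x 6 motion table for the run.
#' @param k_dct number of DCT columns.
#' @return numeric matrix frames x (24 + 1 + k_dct).
#' @export
confound_matrix <- function(params6, k_dct = 5) {
  cbind(expand_motion(params6),
        framewise_displacement = framewise_displacement(params6),
        dct_basis(nrow(as.matrix(params6)), k_dct))
}

#' Regress confounds out of a percent-signal-change run
#'
#' Per region, replaces the series with the residual of an ordinary
#' least-squares fit on the confound columns plus an intercept. Rank-deficient
#' confound matrices fall back to the pseudo-inverse (minimum-norm) solution
#' with a warning.
#'
#' @param run `run_series` at stage "psc".
#' @param confounds frames x p confound matrix.
#' @return `run_series` at stage "cleaned".
#' @export
regress_confounds <- function(run, confounds) {
  .assert_stage(run, "psc")
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(run$values)) {
    stop("confound rows (", nrow(confounds), ") do not match frames (",
         nrow(run$values), ")")
  }
  X <- cbind(intercept = 1, confounds)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient confound matrix (rank ", qrX$rank, " of ",
            ncol(X), "); using pseudo-inverse")
    sv <- svd(X)
    keep <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
    beta <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% run$values) / sv$d[keep])
    run$values <- run$values - X %*% beta
  } else {
    run$values <- qr.resid(qrX, run$values)
  }
  run$stage <- "cleaned"
  run
}

#' Z-score a cleaned run
#'
#' Per region over the whole run: mean 0, sample SD 1 (denominator n - 1).
#'
#' @param run `run_series` at stage "cleaned".
#' @return `run_series` at stage "zscored".
#' @export
zscore_run <- function(run) {
  .assert_stage(run, "cleaned")
  sds <- apply(run$values, 2, stats::sd)
  if (any(sds <= 0 | !is.finite(sds))) {
    bad <- colnames(run$values)[sds <= 0 | !is.finite(sds)]
    stop("degenerate signal: zero variance in region(s) ",
         paste(bad, collapse = ", "))
  }
  run$values <- scale(run$values)[, , drop = FALSE]
  attr(run$values, "scaled:center") <- NULL
  attr(run$values, "scaled:scale") <- NULL
  run$stage <- "zscored"
  run
}

#' Full run conditioning
#'
#' raw -> percent signal change -> confound regression -> z-scoring, all
#' run-wise.
#'
#' @param run `run_series` at stage "raw".
#' @param params6 the run's frames x 6 motion table.
#' @return `run_series` at stage "zscored".
#' @export
preprocess_run <- function(run, params6) {
  zscore_run(regress_confounds(percent_signal_change(run),
                               confound_matrix(params6)))
}

#' Locate trial windows in a run
#'
#' For every trial: the 30 navigation frames (60 s at TR 2 s), the 26 retained
#' frames (the first 4 excluded for the hemodynamic delay), and the 4 baseline
#' frames (last 2 frames of each of the two fixation phases). Navigation onsets
#' must fall on frame boundaries; misalignment is an error, never silent
#' rounding.
#'
#' @param run a `run_series` (any stage).
#' @param events event table as from [run_events()].
#' @param drop_first number of initial navigation frames excluded (4).
#' @param baseline_frames frames kept at the end of each fixation phase (2).
#' @return named list (by episode_id) of lists with `nav_all`, `nav_frames`
#'   (retained), `baseline_frames` (frame indices into the run).
#' @export
extract_windows <- function(run, events, drop_first = 4L, baseline_frames = 2L) {
  stopifnot(inherits(run, "run_series"))
  tr <- run$tr_seconds
  nf <- nrow(run$values)
  nav <- events[events$trial_type == "navigation", , drop = FALSE]
  fix <- events[events$trial_type %in% c("fixation1", "fixation2"), , drop = FALSE]
  out <- lapply(seq_len(nrow(nav)), function(i) {
    onset <- nav$onset[i]
    if (abs(onset / tr - round(onset / tr)) > 1e-9) {
      stop("navigation onset ", onset, " s is not aligned to the TR grid")
    }
    n_frames <- nav$duration[i] / tr
    if (abs(n_frames - round(n_frames)) > 1e-9) {
      stop("navigation duration not a multiple of TR")
    }
    idx <- onset / tr + seq_len(round(n_frames))
    if (max(idx) > nf) stop("events extend past the end of the run")
    fx <- fix[fix$episode_id == nav$episode_id[i], , drop = FALSE]
    base_idx <- unlist(lapply(seq_len(nrow(fx)), function(j) {
      stopifnot(abs(fx$onset[j] / tr - round(fx$onset[j] / tr)) < 1e-9)
      last <- (fx$onset[j] + fx$duration[j]) / tr
      (last - baseline_frames + 1):last
    }))
    if (max(base_idx) > nf) stop("events extend past the end of the run")
    list(episode_id = nav$episode_id[i],
         nav_all = idx,
         nav_frames = idx[(drop_first + 1):length(idx)],
         baseline_frames = sort(base_idx))
  })
  names(out) <- nav$episode_id
  out
}

#' Baseline-referenced average activation
#'
#' Mean percent signal over the retained navigation frames minus the mean over
#' the 4 baseline frames (last 2 frames of each fixation phase), per episode
#' and region; computed on the percent-signal-change series.
#'
#' @param run `run_series` at stage "psc" or "cleaned".
#' @param windows output of [extract_windows()].
#' @return data.frame with `episode_id`, `region`, `activation`.
#' @export
average_activation <- function(run, windows) {
  stopifnot(inherits(run, "run_series"))
  if (!run$stage %in% c("psc", "cleaned")) {
    stop("activation is computed on the percent-signal series (stage psc/cleaned)")
  }
  out <- do.call(rbind, lapply(windows, function(w) {
    if (length(w$baseline_frames) == 0) stop("missing baseline frames")
    nav_mean <- colMeans(run$values[w$nav_frames, , drop = FALSE])
    base_mean <- colMeans(run$values[w$baseline_frames, , drop = FALSE])
    data.frame(episode_id = w$episode_id,
               region = colnames(run$values),
               activation = nav_mean - base_mean,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Spatial memory performance
#'
#' Proportion of correct responses across scored trials. A missing response
#' (NA) counts as incorrect; episodes listed in `exclude_episodes` are removed
#' from scoring entirely.
#'
#' @param trials data.frame with `participant_id`, `episode_id`, `correct`
#'   (1/0/NA).
#' @param exclude_episodes character vector of episode ids to drop.
#' @return data.frame `participant_id`, `n_scored`, `performance`.
#' @export
spatial_memory_performance <- function(trials, exclude_episodes = character()) {
  keep <- !(trials$episode_id %in% exclude_episodes)
  trials <- trials[keep, , drop = FALSE]
  correct <- ifelse(is.na(trials$correct), 0, trials$correct)
  agg <- stats::aggregate(correct, by = list(participant_id = trials$participant_id),
                          FUN = function(v) c(n = length(v), p = mean(v)))
  out <- data.frame(participant_id = agg$participant_id,
                    n_scored = agg$x[, "n"],
                    performance = agg$x[, "p"],
                    stringsAsFactors = FALSE)
  out[order(out$participant_id), , drop = FALSE]
}
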