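#' Canonical double-gamma HRF
#'
#' SPM-style double-gamma hemodynamic response function sampled on a regular
#' grid: a positive main lobe (gamma shape 6, scale 1) minus an undershoot
#' (shape 16, scale 1) scaled by 1/6, with 32 s support and peak normalized
#' to 1. The peak falls near 5 s.
#'
#' @param dt sample spacing in seconds (default 0.1, matching the 10 Hz event
#'   streams).
#' @param duration kernel support in seconds.
#' @param peak_shape,under_shape,under_ratio gamma shape parameters and
#'   undershoot weight.
#' @return object of class `hrf_kernel`: list with `dt`, `values`, `times`,
#'   `peak_time`.
#' @export
canonical_hrf <- function(dt = 0.1, duration = 32,
                          peak_shape = 6, under_shape = 16, under_ratio = 1 / 6) {
  if (dt <= 0) stop("dt must be positive")
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = peak_shape, scale = 1) -
    under_ratio * stats::dgamma(t, shape = under_shape, scale = 1)
  h <- h / max(h)
  structure(list(dt = dt, values = h, times = t,
                 peak_time = t[which.max(h)]),
            class = "hrf_kernel")
}

#' Aggregate raw gaze flags to a 10 Hz group ratio
#'
#' Per participant, raw on-landmark flags (250 Hz) are averaged within
#' consecutive 100 ms bins; a participant is counted as landmark-viewing in a
#' bin when their bin mean exceeds 0.5. The returned series is the fraction of
#' participants viewing the landmark in each bin.
#'
#' @param flags numeric/logical matrix, samples x participants (0/1).
#' @param bin number of raw samples per bin (25 = 250 Hz -> 10 Hz).
#' @return numeric vector of length `nrow(flags) / bin`, values in [0, 1].
#' @export
aggregate_gaze <- function(flags, bin = 25L) {
  flags <- as.matrix(flags)
  if (ncol(flags) < 1) stop("need at least one gaze participant")
  if (nrow(flags) %% bin != 0) stop("sample count not a multiple of bin size")
  n_bin <- nrow(flags) %/% bin
  grp <- rep(seq_len(n_bin), each = bin)
  binned <- rowsum(flags, grp) / bin
  rowMeans(binned > 0.5)
}

#' Landmark-viewing mask
#'
#' Thresholds a within-trial gaze-ratio series at its 80th percentile
#' (linear-interpolation quantile): samples strictly above the threshold are
#' marked as landmark viewing, so a tie-free series has exactly 20% of its
#' navigation timepoints marked.
#'
#' @param ratio numeric vector, the 10 Hz group gaze ratio for one trial.
#' @return logical vector of the same length.
#' @export
landmark_mask <- function(ratio) {
  if (all(ratio == 0)) {
    warning("all-zero gaze ratio on a landmark trial; empty mask")
    return(rep(FALSE, length(ratio)))
  }
  thr <- stats::quantile(ratio, 0.8, names = FALSE, type = 7)
  ratio > thr
}

#' Convolve an event stream with the HRF and sample at frame times
#'
#' Causal discrete convolution on the stream's own grid (zero-padded before
#' onset), then sampled at the acquisition time of each retained frame.
#'
#' @param stream numeric vector sampled at `hrf$dt` starting at time 0.
#' @param hrf an `hrf_kernel` with matching `dt`.
#' @param frame_times acquisition times (s) of the retained frames, relative to
#'   stream onset; by default the frame onset is used ("onset" sampling), pass
#'   `offset = tr/2` for midpoint sampling.
#' @param offset sampling offset added to each frame time.
#' @return numeric vector, one value per frame time.
#' @export
build_regressor <- function(stream, hrf, frame_times, offset = 0) {
  stopifnot(inherits(hrf, "hrf_kernel"))
  n <- length(stream)
  # causal discrete convolution y[t] = sum_k x[k] h[t-k+1]
  conv <- stats::convolve(stream, rev(hrf$values), type = "open")[seq_len(n)] *
    hrf$dt
  idx <- (frame_times + offset) / hrf$dt
  if (any(abs(idx - round(idx)) > 1e-6)) {
    stop("frame times do not fall on the stream grid")
  }
  idx <- round(idx) + 1L
  if (any(idx < 1 | idx > n)) stop("frame times outside the stream window")
  conv[idx]
}

#' Fit the event regression for canonical dynamics
#'
#' Ordinary least squares of each region's canonical dynamics, concatenated
#' over all episodes' retained navigation frames, on the HRF-convolved
#' angular-velocity regressor (turning) and the HRF-convolved landmark-viewing
#' regressor, plus an intercept. All variables are z-scored before the fit;
#' two-tailed coefficient p-values and R-squared are reported per region.
#'
#' @param Y numeric matrix, frames x regions (canonical dynamics).
#' @param x_turn,x_landmark numeric vectors of length `nrow(Y)`.
#' @return data.frame per region: `region`, `beta_landmark`, `se_landmark`,
#'   `p_landmark`, `beta_turn`, `se_turn`, `p_turn`, `intercept`, `r_squared`.
#' @export
fit_event_regression <- function(Y, x_turn, x_landmark) {
  Y <- as.matrix(Y)
  stopifnot(length(x_turn) == nrow(Y), length(x_landmark) == nrow(Y))
  if (stats::sd(x_turn) == 0 || stats::sd(x_landmark) == 0) {
    stop("constant event regressor")
  }
  if (abs(stats::cor(x_turn, x_landmark)) > 0.999) {
    stop("turn and landmark regressors are collinear")
  }
  z <- function(v) as.numeric(scale(v))
  x1 <- z(x_turn)
  x2 <- z(x_landmark)
  region_names <- if (is.null(colnames(Y))) as.character(seq_len(ncol(Y))) else colnames(Y)
  out <- do.call(rbind, lapply(seq_len(ncol(Y)), function(k) {
    fit <- stats::lm(z(Y[, k]) ~ x1 + x2)
    s <- summary(fit)
    co <- s$coefficients
    data.frame(
      region = region_names[k],
      beta_landmark = co["x2", 1], se_landmark = co["x2", 2],
      p_landmark = co["x2", 4],
      beta_turn = co["x1", 1], se_turn = co["x1", 2], p_turn = co["x1", 4],
      intercept = co["(Intercept)", 1],
      r_squared = s$r.squared,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out$fdr_p_landmark <- fdr_adjust(out$p_landmark)
  out$fdr_p_turn <- fdr_adjust(out$p_turn)
  out
}
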