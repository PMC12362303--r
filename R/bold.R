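#' Construct canonical region signals
#'
#' Builds the ground-truth canonical dynamics g[episode, region] on the
#' 30-frame navigation grid as a standardized mixture of the HRF-convolved
#' angular-velocity stream (weight `beta_turn`), the HRF-convolved
#' landmark-viewing mask (weight `beta_landmark`; the mask is the top-20%
#' threshold of the latent gaze ratio, i.e. the same quantity the analysis
#' regressor encodes), and an episode-specific smooth latent (Gaussian-kernel
#' smoothed white noise, 4 s FWHM) with variance `1 - beta_turn^2 -
#' beta_landmark^2`, partly shared across regions so that cross-region
#' canonical correlations (and hence ISFC) are non-trivial. All components are
#' standardized over the concatenated retained frames (the 26 per episode used
#' by the analysis), so a standardized fit of the canonical dynamics on the two
#' regressors recovers `(beta_turn, beta_landmark)` in expectation.
#'
#' @param design a `navdyn_design`.
#' @param streams output of [generate_event_streams()].
#' @param regions region table with generative couplings.
#' @param params generative parameter list.
#' @param hrf an `hrf_kernel`.
#' @return list with `g` (array 30 x episodes x regions), `frame_times`
#'   (relative to navigation onset), `retained` (indices 5:30), and the
#'   standardized concatenated regressors `x_turn`, `x_landmark` on the
#'   retained grid (for ground-truth recovery checks).
#' @keywords internal
canonical_signals <- function(design, streams, regions, params, hrf) {
  n_ep <- nrow(design$episodes)
  n_reg <- nrow(regions)
  tr <- design$tr_seconds
  nav_frames <- as.integer(60 / tr)
  ft <- (seq_len(nav_frames) - 1) * tr
  retained <- (4 + 1):nav_frames

  x1 <- matrix(0, nav_frames, n_ep)
  x2 <- matrix(0, nav_frames, n_ep)
  for (e in seq_len(n_ep)) {
    st <- streams[[design$episodes$episode_id[e]]]
    x1[, e] <- build_regressor(st$angular_velocity, hrf, ft)
    if (any(st$gaze_ratio > 0)) {
      mask <- landmark_mask(st$gaze_ratio)
      x2[, e] <- build_regressor(as.numeric(mask), hrf, ft)
    }
  }
  zs <- function(m) {
    v <- m[retained, , drop = FALSE]
    (m - mean(v)) / stats::sd(as.numeric(v))
  }
  x1z <- zs(x1)
  x2z <- zs(x2)

  # episode latents: smoothed white noise at 10 Hz sampled at frame times
  smooth_latent <- function() {
    hz <- 10
    pad <- 8 * hz
    n <- 60 * hz + 2 * pad
    w <- stats::rnorm(n)
    sd_s <- (4 / 2.3548) * hz   # 4 s FWHM in samples
    k <- stats::dnorm(seq(-4 * sd_s, 4 * sd_s), sd = sd_s)
    sm <- stats::filter(w, k / sqrt(sum(k^2)), sides = 2)
    sm <- as.numeric(sm)[pad + ft * hz + 1]
    sm
  }
  rho <- params$latent_shared
  g <- array(0, dim = c(nav_frames, n_ep, n_reg),
             dimnames = list(NULL, design$episodes$episode_id, regions$label))
  l_common <- matrix(0, nav_frames, n_ep)
  l_reg <- array(0, dim = c(nav_frames, n_ep, n_reg))
  for (e in seq_len(n_ep)) l_common[, e] <- smooth_latent()
  for (k in seq_len(n_reg)) for (e in seq_len(n_ep)) l_reg[, e, k] <- smooth_latent()
  l_common <- zs(l_common)
  for (k in seq_len(n_reg)) {
    lk <- zs(l_reg[, , k, drop = TRUE])
    b1 <- regions$beta_turn[k]
    b2 <- regions$beta_landmark[k]
    s_lat <- sqrt(1 - b1^2 - b2^2)
    g[, , k] <- b1 * x1z + b2 * x2z +
      s_lat * (sqrt(rho) * l_common + sqrt(1 - rho) * lk)
  }
  list(g = g, frame_times = ft, retained = retained,
       x_turn = as.numeric(x1z[retained, ]),
       x_landmark = as.numeric(x2z[retained, ]))
}

#' Generate raw BOLD run series for the whole cohort
#'
#' Individual navigation-frame signal for participant i, region k, episode e is
#' `w[i,k] * g[,e,k] + sqrt(1 - w[i,k]^2) * noise_sd * eps`, so with unit noise
#' the expected Pearson correlation between an individual segment and the
#' ground-truth canonical signal equals `w[i,k]`. Non-navigation phases carry
#' phase-specific mean offsets plus noise. On top of the neural signal the
#' generator adds a shared motion artifact (`artifact_gain` percent per mm FD,
#' identical across regions), region-idiosyncratic motion-locked noise
#' (`artifact_idio_sd` per mm FD -- the component that survives confound
#' regression and genuinely degrades ICS in high-motion participants), slow
#' cosine drift, and a baseline offset converting percent signal to raw
#' scanner units.
#'
#' @param design a `navdyn_design`.
#' @param streams event streams (see [generate_event_streams()]).
#' @param ground_truth list with at least `coupling_w` (participants x regions
#'   matrix) and region betas embedded in `regions`.
#' @param hrf an `hrf_kernel`.
#' @param seed RNG seed.
#' @param motion motion tables from [generate_motion()]; NULL for zero motion.
#' @param regions region table.
#' @param params generative parameters.
#' @return list with `runs` (per participant, per run `run_series` at stage
#'   "raw") and `canonical` (the [canonical_signals()] output).
#' @export
generate_bold <- function(design, streams, ground_truth, hrf, seed,
                          motion = NULL, regions = design$config$regions,
                          params = design$config$params) {
  stopifnot(inherits(design, "navdyn_design"))
  if (!setequal(names(streams), design$episodes$episode_id)) {
    stop("stream episodes do not match the design")
  }
  set.seed(seed)
  canonical <- canonical_signals(design, streams, regions, params, hrf)
  g <- canonical$g
  tr <- design$tr_seconds
  n <- nrow(design$participants)
  n_reg <- nrow(regions)
  fpr <- design$frames_per_run
  fpt <- as.integer(design$trial_seconds / tr)
  w <- ground_truth$coupling_w
  stopifnot(nrow(w) == n, ncol(w) == n_reg)

  phase_means <- c(fixation1 = 0, map1 = 0.35, navigation = 0.25,
                   fixation2 = 0, map2 = 0.35, question = 0.5, iti = 0)
  lay <- design$layout
  trial_mean <- numeric(fpt)
  for (p in seq_len(nrow(lay))) {
    idx <- lay$onset[p] / tr + seq_len(lay$duration[p] / tr)
    trial_mean[idx] <- phase_means[[lay$phase[p]]]
  }
  run_mean <- rep(trial_mean, design$trials_per_run)
  nav_offset <- lay$onset[lay$phase == "navigation"] / tr

  runs <- lapply(seq_len(n), function(i) {
    per_run <- lapply(seq_len(design$n_runs), function(r) {
      eps <- design$episodes[design$episodes$run == r, , drop = FALSE]
      eps <- eps[order(eps$trial_index), , drop = FALSE]
      sig <- matrix(run_mean, fpr, n_reg)
      colnames(sig) <- regions$label
      noise <- matrix(stats::rnorm(fpr * n_reg, 0, params$noise_sd), fpr, n_reg)
      for (t in seq_len(nrow(eps))) {
        e <- match(eps$episode_id[t], design$episodes$episode_id)
        rows <- (eps$trial_index[t] - 1) * fpt + nav_offset + seq_len(dim(g)[1])
        wi <- w[i, ]
        ge <- matrix(g[, e, ], ncol = n_reg)
        seg <- sweep(ge, 2, wi, "*") +
          sweep(noise[rows, , drop = FALSE], 2, sqrt(1 - wi^2), "*")
        sig[rows, ] <- sig[rows, ] + seg
        noise[rows, ] <- 0
      }
      sig <- sig + noise
      if (!is.null(motion)) {
        fd <- framewise_displacement(motion[[i]][[r]])
        sig <- sig + params$artifact_gain * fd
        if (params$artifact_idio_sd > 0) {
          sig <- sig + matrix(stats::rnorm(fpr * n_reg), fpr, n_reg) *
            (params$artifact_idio_sd * fd)
        }
      }
      if (params$drift_amp > 0) {
        tt <- (seq_len(fpr) - 1) * tr
        period <- stats::runif(1, 200, 400)
        ph <- stats::runif(n_reg, 0, 2 * pi)
        amp <- params$drift_amp * stats::runif(n_reg, 0.5, 1.5)
        drift <- outer(2 * pi * tt / period, ph, "+")
        sig <- sig + sweep(cos(drift), 2, amp, "*")
      }
      raw <- params$baseline_bold * (1 + sig / 100)
      run_series(raw, tr_seconds = tr,
                 participant_id = design$participants$participant_id[i],
                 run_index = r, stage = "raw")
    })
    per_run
  })
  names(runs) <- design$participants$participant_id
  list(runs = runs, canonical = canonical)
}

#' Generate raw eye-tracker gaze flags
#'
#' Simulates a separate eye-tracking cohort (default n = 42) at 250 Hz: per
#' episode and participant, on-landmark flags are Bernoulli draws with
#' probability `gaze_base + gaze_gain * latent ratio` (clipped to [0, 1]).
#' Episodes without local landmarks yield all-zero flags.
#'
#' @param design a `navdyn_design`.
#' @param streams event streams carrying the latent gaze ratio.
#' @param seed RNG seed.
#' @param params generative parameters (`n_gaze`, `gaze_base`, `gaze_gain`).
#' @param hz_raw raw sampling rate (250 Hz).
#' @return named list (by episode) of samples x participants 0/1 matrices.
#' @export
generate_gaze <- function(design, streams, seed,
                          params = design$config$params, hz_raw = 250) {
  set.seed(seed)
  n_gaze <- params$n_gaze
  up <- hz_raw / 10
  lapply(streams, function(st) {
    n_raw <- nrow(st) * up
    if (all(st$gaze_ratio == 0)) {
      return(matrix(0L, n_raw, n_gaze))
    }
    p <- pmin(pmax(params$gaze_base + params$gaze_gain * st$gaze_ratio, 0), 1)
    p_raw <- rep(p, each = up)
    matrix(stats::rbinom(n_raw * n_gaze, 1L, rep(p_raw, n_gaze)),
           n_raw, n_gaze)
  })
}
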