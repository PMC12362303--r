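#' Simulate a full synthetic cohort
#'
#' Runs every generator stage in order -- design, event streams, head motion,
#' alignment weights, BOLD runs, eye-tracking gaze flags, behaviour -- with all
#' randomness drawn from named substreams of the single master seed, so any
#' stage can be regenerated independently and identically.
#'
#' The alignment-weight matrix `w[i, k]` is `w_base[k]` plus a small
#' participant-level general alignment deviation; for the MTL regions it is
#' additionally shifted by `w_med_scale * M_i`, tying the behavioural mediator
#' to measurable MTL coupling. `params$w_override` (scalar) replaces the whole
#' matrix with a constant, which the noise-free and chance-level checks use.
#'
#' @param config a [cohort_config()].
#' @param gaze logical; generate the raw 250 Hz gaze flags (somewhat large).
#' @return object of class `navdyn_cohort`: list with `design`, `streams`,
#'   `motion`, `bold` (runs + canonical), `gaze` (or NULL), `behavior`,
#'   `ground_truth`, `hrf`.
#' @export
simulate_cohort <- function(config = cohort_config(), gaze = TRUE) {
  validate_config(config)
  seed <- config$seed
  design <- generate_design(config)
  streams <- generate_event_streams(design, substream_seed(seed, "streams"))
  motion <- generate_motion(design, config$params,
                            substream_seed(seed, "motion"))
  mediator <- draw_mediator(design, substream_seed(seed, "mediator"),
                            config$params)

  regions <- config$regions
  n <- nrow(design$participants)
  set.seed(substream_seed(seed, "coupling"))
  subj_dev <- stats::rnorm(n, 0, 0.02)
  w <- matrix(rep(regions$w_base, each = n), n, nrow(regions),
              dimnames = list(design$participants$participant_id,
                              regions$label))
  w <- w + subj_dev
  is_mtl <- regions$region %in% mtl_regions()
  w[, is_mtl] <- w[, is_mtl] + config$params$w_med_scale * mediator
  w <- pmin(pmax(w, 0.005), 0.99)
  if (!is.null(config$params$w_override)) {
    w[] <- config$params$w_override
  }

  ground_truth <- list(
    region_betas = regions[, c("label", "beta_turn", "beta_landmark")],
    coupling_w = w,
    mediation_params = config$params[c("med_a", "med_b", "med_cprime")],
    motion_gamma = config$params$motion_gamma,
    noise_sd = config$params$noise_sd,
    mediator = mediator,
    seed = seed
  )

  hrf <- canonical_hrf()
  bold <- generate_bold(design, streams, ground_truth, hrf,
                        substream_seed(seed, "bold"),
                        motion = motion, regions = regions,
                        params = config$params)
  gz <- if (gaze) generate_gaze(design, streams, substream_seed(seed, "gaze"),
                                config$params) else NULL
  behavior <- generate_behavior(design, mediator,
                                substream_seed(seed, "behavior"),
                                config$params)

  structure(list(design = design, streams = streams, motion = motion,
                 bold = bold, gaze = gz, behavior = behavior,
                 ground_truth = ground_truth, hrf = hrf),
            class = "navdyn_cohort")
}

#' Condition every run of a cohort
#'
#' Applies the run-wise pipeline (percent signal change, confound regression on
#' the 30-column motion/FD/DCT set, z-scoring) to every participant and run.
#'
#' @param cohort a `navdyn_cohort`.
#' @return list with `zscored` and `cleaned` run lists (per participant, per
#'   run) and `mean_fd` per participant.
#' @export
preprocess_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "navdyn_cohort"))
  n <- nrow(cohort$design$participants)
  cleaned <- vector("list", n)
  zscored <- vector("list", n)
  fd <- numeric(n)
  for (i in seq_len(n)) {
    cleaned[[i]] <- vector("list", cohort$design$n_runs)
    zscored[[i]] <- vector("list", cohort$design$n_runs)
    for (r in seq_len(cohort$design$n_runs)) {
      m6 <- cohort$motion[[i]][[r]]
      cl <- regress_confounds(percent_signal_change(cohort$bold$runs[[i]][[r]]),
                              confound_matrix(m6))
      cleaned[[i]][[r]] <- cl
      zscored[[i]][[r]] <- zscore_run(cl)
    }
    fd[i] <- mean_fd(cohort$motion[[i]])
  }
  names(cleaned) <- names(zscored) <- cohort$design$participants$participant_id
  list(zscored = zscored, cleaned = cleaned,
       mean_fd = stats::setNames(fd, cohort$design$participants$participant_id))
}

#' Extract the episode-segment array
#'
#' Collects every participant's retained 26-frame navigation segments from the
#' z-scored runs into a 4-d array frames x participants x episodes x regions,
#' ordered as in the design tables.
#'
#' @param cohort a `navdyn_cohort`.
#' @param prep output of [preprocess_cohort()].
#' @return numeric array with dimnames (NULL, participant, episode, region).
#' @export
segment_array <- function(cohort, prep) {
  design <- cohort$design
  n <- nrow(design$participants)
  n_ep <- nrow(design$episodes)
  labels <- colnames(prep$zscored[[1]][[1]]$values)
  n_reg <- length(labels)
  n_keep <- as.integer(60 / design$tr_seconds) - 4L
  seg <- array(NA_real_, dim = c(n_keep, n, n_ep, n_reg),
               dimnames = list(NULL, design$participants$participant_id,
                               design$episodes$episode_id, labels))
  for (r in seq_len(design$n_runs)) {
    ev <- run_events(design, r)
    win <- extract_windows(prep$zscored[[1]][[r]], ev)
    for (i in seq_len(n)) {
      vals <- prep$zscored[[i]][[r]]$values
      for (wnd in win) {
        seg[, i, wnd$episode_id, ] <- vals[wnd$nav_frames, , drop = FALSE]
      }
    }
  }
  seg
}
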