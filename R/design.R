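#' Trial phase layout
#'
#' Fixed within-trial timeline: 8 s fixation, 8 s map, 60 s passive navigation,
#' 8 s fixation, 4 s map, 10 s question, then inter-trial padding to 102 s.
#' All phase boundaries are multiples of the TR (2 s), so windows align to
#' acquisition frames.
#'
#' @return data.frame with columns `phase`, `onset`, `duration` (seconds,
#'   relative to trial start).
#' @export
trial_layout <- function() {
  data.frame(
    phase = c("fixation1", "map1", "navigation", "fixation2", "map2",
              "question", "iti"),
    onset = c(0, 8, 16, 76, 84, 88, 98),
    duration = c(8, 8, 60, 8, 4, 10, 4),
    stringsAsFactors = FALSE
  )
}

#' Generate the study design
#'
#' Draws participant ages (two groups: uniform-ish truncated normals on
#' 20--30 and 50--65), assigns episodes to the four cue conditions (balanced,
#' episodes/4 each) and to runs/trials so that conditions are spread as evenly
#' as possible across runs, and fixes the trial timeline. Deterministic for a
#' given config seed.
#'
#' @param config a [cohort_config()].
#' @return object of class `navdyn_design`: list with `participants`
#'   (participant_id, age, age_group, sex), `episodes` (episode_id, condition,
#'   environment, run, trial_index, question_type), `layout`, `tr_seconds`,
#'   `n_runs`, `trials_per_run`, `trial_seconds`, `frames_per_run`.
#' @export
generate_design <- function(config) {
  validate_config(config)
  set.seed(substream_seed(config$seed, "design"))

  rtrunc <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    bad <- x < lo | x > hi
    while (any(bad)) {
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
      bad <- x < lo | x > hi
    }
    x
  }
  n <- config$n_young + config$n_old
  ages <- c(rtrunc(config$n_young, 23.2, 2.6, 20, 30),
            rtrunc(config$n_old, 55.9, 3.9, 50, 65))
  participants <- data.frame(
    participant_id = sprintf("sub-%03d", seq_len(n)),
    age = round(ages, 1),
    age_group = rep(c("young", "old"), c(config$n_young, config$n_old)),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(42 / 76, 34 / 76)),
    stringsAsFactors = FALSE
  )

  n_ep <- config$n_runs * config$trials_per_run
  conditions <- c("landmark", "distal", "both", "none")
  per_cond <- n_ep %/% 4L
  episodes <- data.frame(
    episode_id = sprintf("ep%02d", seq_len(n_ep)),
    condition = rep(conditions, each = per_cond),
    stringsAsFactors = FALSE
  )
  # deal each condition's episodes round-robin across runs (balanced), then
  # fix any run that exceeded its trial capacity
  run_assign <- integer(n_ep)
  for (cond in conditions) {
    rows <- sample(which(episodes$condition == cond))
    run_assign[rows] <- rep_len(sample(config$n_runs), length(rows))
  }
  episodes$run <- run_assign
  repeat {
    tab <- tabulate(episodes$run, config$n_runs)
    over <- which(tab > config$trials_per_run)
    if (length(over) == 0) break
    under <- which(tab < config$trials_per_run)
    mv <- which(episodes$run == over[1])[1]
    episodes$run[mv] <- under[1]
  }
  episodes$environment <- sample(rep_len(paste0("env", 1:4), n_ep))
  episodes <- episodes[order(episodes$run), , drop = FALSE]
  episodes$trial_index <- unlist(lapply(split(seq_len(n_ep), episodes$run),
                                        seq_along), use.names = FALSE)
  episodes$question_type <- sample(rep_len(c("path", "place"), n_ep))
  rownames(episodes) <- NULL

  layout <- trial_layout()
  trial_seconds <- sum(layout$duration)
  design <- list(
    participants = participants,
    episodes = episodes,
    layout = layout,
    tr_seconds = config$tr_seconds,
    n_runs = config$n_runs,
    trials_per_run = config$trials_per_run,
    trial_seconds = trial_seconds,
    frames_per_run = as.integer(config$trials_per_run * trial_seconds /
                                  config$tr_seconds),
    config = config
  )
  class(design) <- "navdyn_design"
  design
}

#' Per-run BIDS-style event table
#'
#' One row per phase per trial: columns `onset`, `duration`, `trial_type`
#' (phase name), `episode_id`, `condition`. Onsets are relative to run start.
#'
#' @param design a `navdyn_design`.
#' @param run run index.
#' @return data.frame of events for that run.
#' @export
run_events <- function(design, run) {
  eps <- design$episodes[design$episodes$run == run, , drop = FALSE]
  eps <- eps[order(eps$trial_index), , drop = FALSE]
  lay <- design$layout
  out <- do.call(rbind, lapply(seq_len(nrow(eps)), function(i) {
    t0 <- (eps$trial_index[i] - 1) * design$trial_seconds
    data.frame(
      onset = t0 + lay$onset, duration = lay$duration,
      trial_type = lay$phase,
      episode_id = eps$episode_id[i], condition = eps$condition[i],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
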