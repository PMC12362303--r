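#' Generate per-episode event streams
#'
#' For every episode, simulates the 10 Hz angular-velocity trace of the virtual
#' navigator (4--8 half-cosine turn bumps, 1--3 s wide, onsets at least 2 s
#' apart, zero while the navigator is stationary during the first and last 2 s)
#' and, for episodes containing local landmarks (conditions "landmark" and
#' "both"), a latent group gaze-on-landmark ratio built from 2--4 smooth gaze
#' bumps. Episodes without local landmarks have an identically-zero gaze ratio.
#'
#' @param design a `navdyn_design`.
#' @param seed RNG seed (a substream of the master seed when called from
#'   [simulate_cohort()]).
#' @param nav_seconds navigation duration (60 s).
#' @param hz sampling rate of the streams (10 Hz).
#' @return named list (by episode_id) of data.frames with columns `time_s`,
#'   `angular_velocity` (deg/s, >= 0), `gaze_ratio` (in [0, 1]); each carries a
#'   `condition` attribute.
#' @export
generate_event_streams <- function(design, seed, nav_seconds = 60, hz = 10) {
  stopifnot(inherits(design, "navdyn_design"))
  set.seed(seed)
  n_samp <- as.integer(nav_seconds * hz)
  tgrid <- (seq_len(n_samp) - 1) / hz

  bump <- function(t, onset, width, amp) {
    # half-cosine bump supported on [onset, onset + width]
    inside <- t >= onset & t <= onset + width
    out <- numeric(length(t))
    out[inside] <- amp * 0.5 * (1 - cos(2 * pi * (t[inside] - onset) / width))
    out
  }

  draw_onsets <- function(k, lo, hi, min_gap = 2) {
    # rejection-sample k onsets in [lo, hi] pairwise >= min_gap apart
    for (try in 1:200) {
      on <- sort(stats::runif(k, lo, hi))
      if (k == 1 || all(diff(on) >= min_gap)) return(on)
    }
    seq(lo, hi, length.out = k)
  }

  streams <- lapply(seq_len(nrow(design$episodes)), function(i) {
    cond <- design$episodes$condition[i]
    n_turn <- sample(4:8, 1)
    widths <- stats::runif(n_turn, 1, 3)
    onsets <- draw_onsets(n_turn, 2, nav_seconds - 2 - max(widths))
    av <- numeric(n_samp)
    for (j in seq_len(n_turn)) {
      av <- av + bump(tgrid, onsets[j], widths[j], stats::runif(1, 20, 60))
    }
    av[tgrid < 2 | tgrid >= nav_seconds - 2] <- 0

    gr <- numeric(n_samp)
    if (cond %in% c("landmark", "both")) {
      n_lm <- sample(2:4, 1)
      lm_on <- draw_onsets(n_lm, 4, nav_seconds - 10, min_gap = 6)
      gr <- rep(0.04, n_samp)
      for (j in seq_len(n_lm)) {
        gr <- gr + bump(tgrid, lm_on[j], stats::runif(1, 3, 6),
                        stats::runif(1, 0.5, 0.9))
      }
      gr <- pmin(pmax(gr, 0), 1)
    }
    out <- data.frame(time_s = tgrid, angular_velocity = av, gaze_ratio = gr)
    attr(out, "condition") <- cond
    attr(out, "n_turns") <- n_turn
    out
  })
  names(streams) <- design$episodes$episode_id
  streams
}
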