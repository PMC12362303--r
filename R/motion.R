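#' Generate rigid-body head-motion traces
#'
#' Simulates 6-parameter motion (3 translations in mm, 3 rotations in radians)
#' per participant and run as mean-reverting AR(1) walks with occasional
#' spikes. Each participant's innovation scale is
#' `fd_base * max(0.2, 1 + motion_gamma * z(age) + motion_noise * eps)`,
#' so expected mean framewise displacement rises linearly with standardized
#' age; with the defaults (gamma 0.285, noise SD 0.5) the cohort-level
#' age--mean-FD Pearson correlation is approximately
#' `gamma / sqrt(gamma^2 + noise^2) ~ 0.49`. Setting `motion_gamma = 0` removes
#' the age confound; setting `motion_scale = 0` yields identically-zero motion
#' (FD = 0 at all frames).
#'
#' @param design a `navdyn_design`.
#' @param params generative parameter list (see [default_params()]).
#' @param seed RNG seed.
#' @return list (by participant) of lists (by run) of data.frames with columns
#'   `trans_x_mm`, `trans_y_mm`, `trans_z_mm`, `rot_x_rad`, `rot_y_rad`,
#'   `rot_z_rad`; the top-level list carries a `motion_scale` attribute with
#'   each participant's scale multiplier.
#' @export
generate_motion <- function(design, params = default_params(), seed = 1L) {
  stopifnot(inherits(design, "navdyn_design"))
  set.seed(seed)
  n <- nrow(design$participants)
  nf <- design$frames_per_run
  age_z <- as.numeric(scale(design$participants$age))
  m <- pmax(0.2, 1 + params$motion_gamma * age_z +
              params$motion_noise * stats::rnorm(n))
  m <- m * params$motion_scale

  # innovation SDs chosen so the per-frame expected FD at scale 1 is ~ fd_base:
  # E[FD] ~ (3*st + 150*sr) * sqrt(2/pi) * sqrt(2*(1-phi)) -- phi near 1 makes
  # consecutive differences ~ the innovations themselves, so use the direct form
  phi <- 0.95
  st0 <- params$fd_base / (2 * 3 * sqrt(2 / pi))        # translations take half
  sr0 <- params$fd_base / (2 * 150 * sqrt(2 / pi))      # rotations take half

  cols <- c("trans_x_mm", "trans_y_mm", "trans_z_mm",
            "rot_x_rad", "rot_y_rad", "rot_z_rad")
  out <- lapply(seq_len(n), function(i) {
    lapply(seq_len(design$n_runs), function(r) {
      sds <- c(rep(st0, 3), rep(sr0, 3)) * m[i]
      x <- sapply(sds, function(s) {
        innov <- stats::rnorm(nf, 0, s)
        spikes <- stats::rbinom(nf, 1, params$spike_prob) *
          stats::rnorm(nf, 0, 5 * s)
        as.numeric(stats::filter(innov + spikes, phi, method = "recursive"))
      })
      x <- as.data.frame(x)
      names(x) <- cols
      x
    })
  })
  names(out) <- design$participants$participant_id
  attr(out, "motion_scale") <- m
  out
}
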