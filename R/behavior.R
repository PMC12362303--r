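#' Generate trial responses from the mediation chain
#'
#' Latent performance per participant is
#' `perf = c' * z(age) + b * M + resid`, where `M = a * z(age) + resid` is the
#' standardized latent mediator (the same quantity that shifts the alignment
#' weight of the MTL regions in the BOLD generator). Residual variances are
#' chosen so M and perf are unit-variance, making (a, b, c') directly the
#' standardized path coefficients a mediation fit should recover. Trial
#' correctness is Bernoulli with probability
#' `plogis(perf_base_logit + perf_slope * perf)`, and a small configurable
#' fraction of responses is missing (NA = no response).
#'
#' @param design a `navdyn_design`.
#' @param mediator standardized latent mediator per participant (typically from
#'   [draw_mediator()]).
#' @param seed RNG seed.
#' @param params generative parameters.
#' @return list with `trials` (participant_id, episode_id, correct in
#'   \{1, 0, NA\}) and `latent` (participant_id, mediator, perf_latent).
#' @export
generate_behavior <- function(design, mediator, seed,
                              params = design$config$params) {
  set.seed(seed)
  n <- nrow(design$participants)
  stopifnot(length(mediator) == n)
  age_z <- as.numeric(scale(design$participants$age))
  a <- params$med_a; b <- params$med_b; cp <- params$med_cprime
  resid_var <- 1 - (cp^2 + b^2 + 2 * a * b * cp)
  if (resid_var < 0) stop("invalid mediation parameters: implied residual variance < 0")
  perf <- cp * age_z + b * mediator + sqrt(resid_var) * stats::rnorm(n)

  n_ep <- nrow(design$episodes)
  p_correct <- stats::plogis(params$perf_base_logit + params$perf_slope * perf)
  trials <- data.frame(
    participant_id = rep(design$participants$participant_id, each = n_ep),
    episode_id = rep(design$episodes$episode_id, n),
    correct = stats::rbinom(n * n_ep, 1L, rep(p_correct, each = n_ep)),
    stringsAsFactors = FALSE
  )
  miss <- stats::runif(nrow(trials)) < params$missing_frac
  trials$correct[miss] <- NA_integer_
  list(trials = trials,
       latent = data.frame(participant_id = design$participants$participant_id,
                           mediator = mediator, perf_latent = perf,
                           stringsAsFactors = FALSE))
}

#' Draw the latent mediator
#'
#' `M = a * z(age) + sqrt(1 - a^2) * eps`, unit variance in expectation.
#'
#' @param design a `navdyn_design`.
#' @param seed RNG seed.
#' @param params generative parameters (uses `med_a`).
#' @return numeric vector, one value per participant.
#' @export
draw_mediator <- function(design, seed, params = design$config$params) {
  set.seed(seed)
  age_z <- as.numeric(scale(design$participants$age))
  params$med_a * age_z + sqrt(1 - params$med_a^2) *
    stats::rnorm(nrow(design$participants))
}
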