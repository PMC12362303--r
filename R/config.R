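#' Build a cohort/pipeline configuration
#'
#' Collects every tunable of the synthetic cohort and the analysis pipeline in
#' one validated list. Defaults reproduce the study conditions: 76 participants
#' (45 aged 20--30, 31 aged 50--65), 24 one-minute episodes in 4 runs of 6
#' trials at TR 2 s with 102-s trials, age-correlated head motion targeting
#' r(age, mean FD) around 0.49, and a mediation chain with standardized paths
#' a = -0.318 (age to MTL coupling), b = 0.313 (coupling to performance) and
#' direct effect c' = -0.598, i.e. indirect effect a*b = -0.0995 and total
#' effect c = -0.697.
#'
#' @param n_young,n_old group sizes (must each be >= 2).
#' @param n_runs,trials_per_run scan layout; episodes = n_runs * trials_per_run
#'   and must be divisible by 4 (the number of cue conditions).
#' @param tr_seconds repetition time in seconds.
#' @param regions region table as from [region_table()].
#' @param seed master RNG seed; all generator stages draw from named substreams
#'   derived from it.
#' @param params named list overriding generative parameters, see
#'   [default_params()].
#' @return object of class `navdyn_config`.
#' @export
cohort_config <- function(n_young = 45L, n_old = 31L,
                          n_runs = 4L, trials_per_run = 6L,
                          tr_seconds = 2, regions = region_table(),
                          seed = 1L, params = list()) {
  p <- default_params()
  unknown <- setdiff(names(params), names(p))
  if (length(unknown) > 0) {
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "))
  }
  p[names(params)] <- params
  cfg <- list(
    n_young = as.integer(n_young), n_old = as.integer(n_old),
    n_runs = as.integer(n_runs), trials_per_run = as.integer(trials_per_run),
    tr_seconds = tr_seconds, regions = regions, seed = as.integer(seed),
    params = p
  )
  class(cfg) <- "navdyn_config"
  validate_config(cfg)
  cfg
}

#' Default generative parameters
#'
#' @return named list of generator tunables:
#' \describe{
#'   \item{motion_gamma}{slope of mean framewise displacement on standardized
#'     age (0.285 with motion_noise 0.5 targets a cohort age--FD correlation of
#'     about 0.49).}
#'   \item{motion_noise}{SD of the participant-level motion scale noise.}
#'   \item{fd_base}{baseline per-frame expected FD scale, mm.}
#'   \item{spike_prob}{per-frame probability of a motion spike.}
#'   \item{noise_sd}{SD of the idiosyncratic navigation-frame noise; 1 keeps
#'     the alignment weight w interpretable as the expected individual-to-truth
#'     correlation.}
#'   \item{artifact_gain}{shared motion artifact: percent-signal units added to
#'     every region per mm of framewise displacement.}
#'   \item{artifact_idio_sd}{SD of region-idiosyncratic motion-locked noise per
#'     mm FD (this is what makes motion degrade ICS even after confound
#'     regression).}
#'   \item{drift_amp}{amplitude of slow cosine drift, percent signal.}
#'   \item{baseline_bold}{raw scanner units at 0 percent signal change.}
#'   \item{latent_shared}{fraction of episode-latent variance shared across
#'     regions (gives canonical dynamics a cross-region component so ISFC is
#'     non-trivial).}
#'   \item{med_a, med_b, med_cprime}{true standardized mediation paths.}
#'   \item{w_med_scale}{how strongly the latent mediator shifts the alignment
#'     weight of MTL regions.}
#'   \item{perf_base_logit, perf_slope}{map from latent performance to the
#'     per-trial correctness probability.}
#'   \item{missing_frac}{fraction of trials with no response.}
#'   \item{n_gaze}{size of the separate eye-tracking cohort.}
#'   \item{gaze_base, gaze_gain}{Bernoulli gaze-flag probability is
#'     gaze_base + gaze_gain * latent ratio.}
#' }
#' @export
default_params <- function() {
  list(
    motion_gamma = 0.285, motion_noise = 0.5, fd_base = 0.15,
    spike_prob = 0.01, motion_scale = 1,
    noise_sd = 1, artifact_gain = 0.6, artifact_idio_sd = 0.8,
    drift_amp = 0.4, baseline_bold = 800,
    latent_shared = 0.3,
    med_a = -0.318, med_b = 0.313, med_cprime = -0.598,
    w_med_scale = 0.035,
    perf_base_logit = 0.85, perf_slope = 1.0, missing_frac = 0.02,
    n_gaze = 42L, gaze_base = 0.03, gaze_gain = 0.9,
    w_override = NULL
  )
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "navdyn_config"))
  if (cfg$n_young < 2L || cfg$n_old < 2L) {
    stop("invalid config: need at least 2 participants per age group")
  }
  n_ep <- cfg$n_runs * cfg$trials_per_run
  if (n_ep %% 4L != 0L) {
    stop("invalid config: episodes (n_runs * trials_per_run) must be divisible by 4 conditions")
  }
  if (cfg$tr_seconds <= 0) stop("invalid config: tr_seconds must be positive")
  if (!all(c("region", "hemisphere", "label", "beta_turn", "beta_landmark", "w_base")
           %in% names(cfg$regions))) {
    stop("invalid config: region table missing required columns")
  }
  if (any(cfg$regions$beta_turn^2 + cfg$regions$beta_landmark^2 >= 1)) {
    stop("invalid config: beta_turn^2 + beta_landmark^2 must be < 1 per region")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Accepts a file with any of the [cohort_config()] arguments
#' (`n_young`, `n_old`, `n_runs`, `trials_per_run`, `tr_seconds`, `seed`,
#' `regions` as a vector of base region names, and a nested `params` list).
#' Unknown keys are an error before anything runs.
#'
#' @param path path to a `.json`, `.yaml`, or `.yml` file.
#' @return a validated `navdyn_config`.
#' @export
read_config <- function(path) {
  spec <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- c("n_young", "n_old", "n_runs", "trials_per_run", "tr_seconds",
               "regions", "seed", "params")
  unknown <- setdiff(names(spec), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(spec$regions)) spec$regions <- region_table(spec$regions)
  if (!is.null(spec$params)) spec$params <- as.list(spec$params)
  do.call(cohort_config, spec)
}

# Deterministic substream seed derivation: every generator stage seeds its own
# RNG stream from the master seed and a stage name, so stages can be
# regenerated independently and identically.
substream_seed <- function(master, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483629)
}
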