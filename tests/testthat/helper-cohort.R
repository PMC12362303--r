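# Shared fixtures: all synthetic, built in code.

# small region subset for fast cohort tests
small_regions <- function(names = c("dorsal_visual_area",
                                    "parahippocampal_region",
                                    "hippocampal_formation")) {
  region_table(names)
}

# a miniature but structurally complete cohort configuration
tiny_config <- function(seed = 1L, n_young = 4L, n_old = 4L,
                        regions = small_regions(), params = list()) {
  cohort_config(n_young = n_young, n_old = n_old, seed = seed,
                regions = regions,
                params = utils::modifyList(list(n_gaze = 8L), params))
}

# deterministic cohort with every stochastic nuisance switched off
noise_free_config <- function(seed = 1L, regions = small_regions()) {
  tiny_config(seed = seed, regions = regions,
              params = list(w_override = 1, noise_sd = 0, drift_amp = 0,
                            artifact_gain = 0, artifact_idio_sd = 0,
                            motion_scale = 0, spike_prob = 0))
}

# white-noise segment array (what a coupling-free cohort looks like after
# conditioning): frames x participants x episodes x regions
null_segments <- function(n = 8, n_ep = 24, n_reg = 1, n_frames = 26) {
  array(stats::rnorm(n_frames * n * n_ep * n_reg),
        dim = c(n_frames, n, n_ep, n_reg),
        dimnames = list(NULL, sprintf("sub-%03d", seq_len(n)),
                        sprintf("ep%02d", seq_len(n_ep)),
                        paste0("region_", seq_len(n_reg))))
}

# construct a vector with an exact Pearson correlation r to x
with_exact_cor <- function(x, r, seed = 1L) {
  set.seed(seed)
  e <- stats::rnorm(length(x))
  e <- stats::lm.fit(cbind(1, x), e)$residuals
  xz <- (x - mean(x)) / stats::sd(x)
  r * xz + sqrt(1 - r^2) * e / stats::sd(e)
}

# brute-force OLS residual via the normal equations (independent oracle)
normal_eq_residual <- function(y, X) {
  X <- cbind(1, X)
  y - X %*% solve(t(X) %*% X, t(X) %*% y)
}

# brute-force direct-sum causal convolution (independent oracle)
direct_convolution <- function(x, h, dt) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    k <- seq_len(min(t, length(h)))
    out[t] <- sum(h[k] * x[t - k + 1])
  }
  out * dt
}
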