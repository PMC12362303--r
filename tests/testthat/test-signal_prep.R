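test_that("percent signal change matches the two-pass definition", {
  r <- run_series(cbind(a = c(100, 100, 100, 100)))
  expect_equal(unname(percent_signal_change(r)$values[, 1]), c(0, 0, 0, 0))

  r <- run_series(cbind(a = c(90, 110)))
  expect_equal(unname(percent_signal_change(r)$values[, 1]), c(-10, 10))

  set.seed(1)
  x <- matrix(800 + stats::rnorm(300 * 2, sd = 10), 300, 2,
              dimnames = list(NULL, c("a", "b")))
  got <- percent_signal_change(run_series(x))$values
  oracle <- apply(x, 2, function(v) (v - mean(v)) / mean(v) * 100)
  expect_equal(unname(got), unname(oracle), tolerance = 1e-12)

  expect_error(percent_signal_change(run_series(cbind(z = c(-1, 1)))),
               "degenerate")
})

test_that("motion expansion builds the 24-parameter set", {
  const <- matrix(2, 5, 6)
  out <- expand_motion(const)
  expect_equal(dim(out), c(5L, 24L))
  expect_true(all(out[, 7:12] == 0))   # derivatives
  expect_true(all(out[, 19:24] == 0))  # squared derivatives

  p <- cbind(c(0, 1, 3), matrix(0, 3, 5))
  out <- expand_motion(p)
  expect_equal(unname(out[, 7]), c(0, 1, 2))
  expect_equal(unname(out[, 13]), c(0, 1, 9))
  expect_equal(unname(out[, 19]), c(0, 1, 4))

  set.seed(2)
  m <- matrix(stats::rnorm(60), 10, 6)
  out <- expand_motion(m)
  d <- rbind(0, diff(m))
  expect_equal(unname(out), unname(cbind(m, d, m^2, d^2)))
  expect_error(expand_motion(m[, 1:5]), "6 columns")
})

test_that("framewise displacement follows the 50 mm sphere convention", {
  expect_true(all(framewise_displacement(matrix(0.3, 10, 6)) == 0))

  m <- matrix(0, 5, 6); m[3:5, 1] <- 1   # single 1 mm translation step
  expect_equal(framewise_displacement(m), c(0, 0, 1, 0, 0))

  m <- matrix(0, 4, 6); m[2:4, 5] <- 0.01  # 0.01 rad rotation step
  expect_equal(framewise_displacement(m), c(0, 0.5, 0, 0))
})

test_that("the DCT drift basis is zero-mean, orthogonal, and matches closed form", {
  b <- dct_basis(306, 5)
  expect_equal(dim(b), c(306L, 5L))
  expect_true(all(abs(colMeans(b)) < 1e-12))
  cp <- crossprod(b)
  expect_true(all(abs(cp[upper.tri(cp)] / sqrt(diag(cp)[1]^2)) < 1e-9))

  t <- 0:7
  expect_equal(unname(dct_basis(8, 2)[, 1]), cos(pi * (2 * t + 1) / 16))
  expect_error(dct_basis(4, 5), "invalid config")
})

test_that("confound regression residualizes exactly and handles rank deficiency", {
  n <- 60
  set.seed(3)
  conf <- cbind(stats::rnorm(n), stats::rnorm(n), dct_basis(n, 3))
  # signal inside the confound span vanishes
  r <- run_series(cbind(a = 3 * conf[, 3] + 5), stage = "raw")
  r$stage <- "psc"
  out <- regress_confounds(r, conf)
  expect_true(all(abs(out$values) < 1e-9))

  # random signal: residual matches normal-equations oracle, orthogonal to confounds
  y <- cbind(a = stats::rnorm(n), b = stats::rnorm(n))
  r <- run_series(y, stage = "raw"); r$stage <- "psc"
  out <- regress_confounds(r, conf)
  oracle <- sapply(seq_len(ncol(y)), function(j) normal_eq_residual(y[, j], conf))
  expect_equal(unname(out$values), unname(oracle), tolerance = 1e-8)
  expect_true(max(abs(crossprod(conf, out$values))) < 1e-6 * n)

  # duplicated column triggers the pseudo-inverse fallback with a warning
  expect_warning(regress_confounds({
    rr <- run_series(y, stage = "raw"); rr$stage <- "psc"; rr
  }, cbind(conf, conf[, 1])), "rank-deficient")
})

test_that("z-scoring normalizes per run and is affine invariant", {
  r <- run_series(cbind(a = c(-1, 0, 1)), stage = "raw"); r$stage <- "cleaned"
  expect_equal(unname(zscore_run(r)$values[, 1]), c(-1, 0, 1))

  set.seed(4)
  v <- stats::rnorm(50)
  r1 <- run_series(cbind(a = v), stage = "raw"); r1$stage <- "cleaned"
  r2 <- run_series(cbind(a = 3.7 * v - 11), stage = "raw"); r2$stage <- "cleaned"
  z1 <- zscore_run(r1)$values; z2 <- zscore_run(r2)$values
  expect_equal(z1, z2, tolerance = 1e-10)
  expect_lt(abs(mean(z1)), 1e-12)
  expect_lt(abs(stats::sd(z1) - 1), 1e-12)

  rc <- run_series(cbind(a = rep(2, 5)), stage = "raw"); rc$stage <- "cleaned"
  expect_error(zscore_run(rc), "degenerate")
})

test_that("stage order is enforced and scale invariance holds end to end", {
  r <- run_series(cbind(a = c(1, 2, 3)))
  expect_error(zscore_run(r), "stage")
  expect_error(regress_confounds(r, dct_basis(3, 1)), "stage")

  set.seed(5)
  raw <- matrix(800 + stats::rnorm(306 * 2, sd = 8), 306, 2,
                dimnames = list(NULL, c("a", "b")))
  m6 <- matrix(stats::rnorm(306 * 6, sd = 0.01), 306, 6)
  z1 <- preprocess_run(run_series(raw), m6)$values
  z2 <- preprocess_run(run_series(raw * 4.2), m6)$values
  expect_equal(z1, z2, tolerance = 1e-8)
})

test_that("trial windows give 30 navigation frames, 26 retained, 4 baseline", {
  design <- generate_design(tiny_config(seed = 8))
  ev <- run_events(design, 1)
  run <- run_series(matrix(stats::rnorm(306 * 2), 306, 2,
                           dimnames = list(NULL, c("a", "b"))))
  win <- extract_windows(run, ev)
  expect_equal(length(win), design$trials_per_run)
  for (w in win) {
    expect_equal(length(w$nav_all), 30L)
    expect_equal(length(w$nav_frames), 26L)
    expect_equal(length(w$baseline_frames), 4L)
    expect_equal(w$nav_frames, w$nav_all[5:30])
  }
  ev_bad <- ev
  ev_bad$onset[ev_bad$trial_type == "navigation"][1] <- 17  # off the TR grid
  expect_error(extract_windows(run, ev_bad), "not aligned")
})

test_that("baseline-referenced activation is the two-mean difference", {
  design <- generate_design(tiny_config(seed = 9))
  ev <- run_events(design, 1)
  vals <- matrix(0.5, 306, 1, dimnames = list(NULL, "a"))
  r <- run_series(vals, stage = "raw"); r$stage <- "psc"
  win <- extract_windows(r, ev)
  act <- average_activation(r, win)
  expect_true(all(abs(act$activation) < 1e-12))

  set.seed(10)
  vals <- matrix(stats::rnorm(306), 306, 1, dimnames = list(NULL, "a"))
  r <- run_series(vals, stage = "raw"); r$stage <- "psc"
  act <- average_activation(r, win)
  w1 <- win[[1]]
  expect_equal(act$activation[1],
               mean(vals[w1$nav_frames, 1]) - mean(vals[w1$baseline_frames, 1]))
})

test_that("performance scoring counts non-responses as incorrect", {
  trials <- data.frame(
    participant_id = "sub-001",
    episode_id = sprintf("ep%02d", 1:24),
    correct = c(rep(1L, 12), rep(0L, 6), rep(NA, 6))
  )
  perf <- spatial_memory_performance(trials)
  expect_equal(perf$performance, 0.5)

  # one flagged episode excluded, all remaining correct
  trials$correct <- c(rep(1L, 23), 0L)
  perf <- spatial_memory_performance(trials, exclude_episodes = "ep24")
  expect_equal(perf$n_scored, 23)
  expect_equal(perf$performance, 1.0)

  trials$correct <- NA
  expect_equal(spatial_memory_performance(trials)$performance, 0.0)
})
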