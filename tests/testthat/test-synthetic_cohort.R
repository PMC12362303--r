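test_that("default design reproduces the study layout and scales down", {
  design <- generate_design(cohort_config(seed = 5))
  expect_equal(nrow(design$participants), 76)
  expect_equal(sum(design$participants$age_group == "young"), 45)
  expect_true(all(design$participants$age[design$participants$age_group == "young"]
                  >= 20 - 1e-9))
  expect_true(all(design$participants$age[design$participants$age_group == "young"]
                  <= 30 + 1e-9))
  expect_true(all(design$participants$age[design$participants$age_group == "old"]
                  >= 50 & design$participants$age[design$participants$age_group == "old"] <= 65))
  expect_equal(nrow(design$episodes), 24)
  expect_equal(as.vector(table(design$episodes$condition)), rep(6L, 4))
  expect_equal(as.vector(table(design$episodes$run)), rep(6L, 4))
  expect_equal(sum(design$layout$duration), 102)
  expect_equal(design$frames_per_run, 306)

  mini <- generate_design(cohort_config(n_young = 2, n_old = 2, seed = 5))
  expect_equal(nrow(mini$participants), 4)
  expect_equal(mini$layout, design$layout)

  expect_error(cohort_config(n_young = 1, n_old = 5), "invalid config")
})

test_that("the design is deterministic field for field under a fixed seed", {
  d1 <- generate_design(cohort_config(seed = 42))
  d2 <- generate_design(cohort_config(seed = 42))
  expect_identical(d1$participants, d2$participants)
  expect_identical(d1$episodes, d2$episodes)
})

test_that("event streams respect turn counts, stationarity, and landmark gating", {
  design <- generate_design(tiny_config(seed = 2))
  streams <- generate_event_streams(design, seed = 9)
  for (e in seq_along(streams)) {
    st <- streams[[e]]
    expect_equal(nrow(st), 600)
    expect_true(all(st$angular_velocity >= 0))
    expect_true(all(st$angular_velocity[st$time_s < 2] == 0))
    expect_true(all(st$angular_velocity[st$time_s >= 58] == 0))
    expect_true(attr(st, "n_turns") >= 4 && attr(st, "n_turns") <= 8)
    expect_true(all(st$gaze_ratio >= 0 & st$gaze_ratio <= 1))
    if (!(attr(st, "condition") %in% c("landmark", "both"))) {
      expect_true(all(st$gaze_ratio == 0))
    } else {
      expect_true(any(st$gaze_ratio > 0))
    }
  }
})

test_that("motion tables carry a tunable age confound and clean overrides", {
  cfg0 <- cohort_config(seed = 1, params = list(motion_gamma = 0))
  rs <- vapply(1:10, function(s) {
    d <- generate_design(cohort_config(seed = s, params = list(motion_gamma = 0)))
    m <- generate_motion(d, cfg0$params, seed = s + 500)
    fd <- vapply(seq_along(m), function(i) mean_fd(m[[i]]), numeric(1))
    stats::cor(d$participants$age, fd)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)

  cfg <- cohort_config(seed = 1)
  rs <- vapply(1:25, function(s) {
    d <- generate_design(cohort_config(seed = s))
    m <- generate_motion(d, cfg$params, seed = s)
    fd <- vapply(seq_along(m), function(i) mean_fd(m[[i]]), numeric(1))
    stats::cor(d$participants$age, fd)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.493), 0.1)

  d <- generate_design(tiny_config())
  m0 <- generate_motion(d, utils::modifyList(cfg$params, list(motion_scale = 0)), 3)
  expect_true(all(framewise_displacement(m0[[1]][[1]]) == 0))
})

test_that("noise-free coupling makes every navigation segment the canonical signal", {
  coh <- simulate_cohort(noise_free_config(seed = 3), gaze = FALSE)
  can <- coh$bold$canonical
  r1 <- percent_signal_change(coh$bold$runs[[1]][[1]])
  ev <- run_events(coh$design, 1)
  win <- extract_windows(r1, ev)
  for (wnd in win) {
    e <- match(wnd$episode_id, coh$design$episodes$episode_id)
    seg <- r1$values[wnd$nav_frames, ]
    g <- can$g[can$retained, e, ]
    # percent-signal segments equal the canonical signal up to the positive
    # affine transform the run-mean normalization introduces
    expect_equal(apply(seg, 2, scale), apply(g, 2, scale),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # and a second participant is bit-identical to the first
  expect_equal(coh$bold$runs[[1]][[1]]$values, coh$bold$runs[[2]][[1]]$values,
               tolerance = 1e-12)
})

test_that("individual-to-canonical correlation tracks the coupling weight w", {
  for (w in c(0, 0.6)) {
    cfg <- tiny_config(seed = 11, n_young = 10, n_old = 10,
                       regions = small_regions("dorsal_visual_area"),
                       params = list(w_override = w, drift_amp = 0,
                                     artifact_gain = 0, artifact_idio_sd = 0,
                                     motion_scale = 0))
    coh <- simulate_cohort(cfg, gaze = FALSE)
    can <- coh$bold$canonical
    rs <- c()
    for (i in 1:20) {
      r1 <- percent_signal_change(coh$bold$runs[[i]][[1]])
      win <- extract_windows(r1, run_events(coh$design, 1))
      for (wnd in win) {
        e <- match(wnd$episode_id, coh$design$episodes$episode_id)
        rs <- c(rs, stats::cor(r1$values[wnd$nav_frames, 1],
                               can$g[can$retained, e, 1]))
      }
    }
    expect_lt(abs(mean(rs) - w), 0.05)
  }
})

test_that("gaze flags follow the latent ratio and its gating", {
  design <- generate_design(tiny_config(seed = 4))
  streams <- generate_event_streams(design, seed = 14)
  flags <- generate_gaze(design, streams, seed = 15,
                         params = utils::modifyList(default_params(),
                                                    list(n_gaze = 12L)))
  none_ep <- design$episodes$episode_id[design$episodes$condition == "none"][1]
  expect_true(all(flags[[none_ep]] == 0))

  # probability pinned at 1 -> aggregated ratio identically 1
  p1 <- utils::modifyList(default_params(),
                          list(n_gaze = 5L, gaze_base = 1, gaze_gain = 0))
  f1 <- generate_gaze(design, streams, seed = 16, params = p1)
  lm_ep <- design$episodes$episode_id[design$episodes$condition == "landmark"][1]
  expect_true(all(aggregate_gaze(f1[[lm_ep]]) == 1))

  # default SNR: aggregated ratio tracks the latent ratio
  agg <- aggregate_gaze(flags[[lm_ep]])
  expect_gt(stats::cor(agg, streams[[lm_ep]]$gaze_ratio), 0.5)
})

test_that("behaviour encodes the mediation chain and missingness", {
  design <- generate_design(cohort_config(seed = 6))
  p_null <- utils::modifyList(default_params(),
                              list(med_b = 0, med_cprime = 0, missing_frac = 0.1))
  rs <- vapply(1:10, function(s) {
    m <- draw_mediator(design, seed = s, params = p_null)
    beh <- generate_behavior(design, m, seed = s + 100, params = p_null)
    stats::cor(design$participants$age, beh$latent$perf_latent)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)

  m <- draw_mediator(design, seed = 1, params = p_null)
  beh <- generate_behavior(design, m, seed = 2, params = p_null)
  expect_lt(abs(mean(is.na(beh$trials$correct)) - 0.1), 0.03)

  # negative total effect appears with the default paths
  beh_def <- generate_behavior(design, draw_mediator(design, 3), seed = 4)
  expect_lt(stats::cor(design$participants$age, beh_def$latent$perf_latent), 0)
})

test_that("identical seed and config give byte-identical cohorts", {
  c1 <- simulate_cohort(tiny_config(seed = 77), gaze = FALSE)
  c2 <- simulate_cohort(tiny_config(seed = 77), gaze = FALSE)
  expect_identical(c1$bold$runs[[2]][[3]]$values, c2$bold$runs[[2]][[3]]$values)
  expect_identical(c1$motion[[1]][[1]], c2$motion[[1]][[1]])
  expect_identical(c1$behavior$trials, c2$behavior$trials)
  expect_identical(c1$ground_truth$coupling_w, c2$ground_truth$coupling_w)
})
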