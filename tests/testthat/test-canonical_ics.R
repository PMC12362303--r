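test_that("leave-one-out canonical dynamics are the mean of the others", {
  seg <- cbind(s1 = c(1, 0), s2 = c(2, 0), s3 = c(3, 0))
  expect_equal(canonical_dynamics(seg, 1)[1], 2.5)

  same <- cbind(a = 1:5, b = 1:5, c = 1:5)
  expect_equal(canonical_dynamics(same, "b"), as.numeric(1:5))

  set.seed(1)
  m <- matrix(stats::rnorm(26 * 10), 26, 10)
  got <- canonical_dynamics(m, 4)
  oracle <- apply(m[, -4], 1, mean)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(canonical_dynamics(m[, 1, drop = FALSE], 1), "at least 2")
})

test_that("ICS is the Fisher-Z Pearson correlation with clipping", {
  x <- stats::rnorm(26)
  self <- ics(x, x)
  expect_equal(self$r, 1)
  expect_equal(self$z, atanh(1 - 1e-7))

  t26 <- seq_len(26)
  s <- sin(2 * pi * t26 / 13); cs <- cos(2 * pi * t26 / 13)
  expect_lt(abs(ics(s, cs)$z), 0.05)

  set.seed(2)
  tmpl <- stats::rnorm(26)
  ind <- with_exact_cor(tmpl, 0.5)
  got <- ics(ind, tmpl)
  expect_equal(got$r, 0.5, tolerance = 1e-12)
  expect_equal(got$z, 0.5493, tolerance = 1e-4)

  expect_error(ics(rep(1, 26), tmpl), "degenerate")
})

test_that("ICS is invariant to positive affine transforms of either input", {
  set.seed(3)
  a <- stats::rnorm(26); b <- stats::rnorm(26)
  base <- ics(a, b)$z
  expect_equal(ics(2.5 * a + 3, b)$z, base, tolerance = 1e-12)
  expect_equal(ics(a, 0.1 * b - 7)$z, base, tolerance = 1e-12)
})

test_that("the decoder picks the argmax and flags ties deterministically", {
  sims <- c(ep01 = 0.2, ep02 = 0.9, ep03 = 0.9)
  out <- decode_episode(sims, "ep02")
  expect_equal(out$predicted, "ep02")
  expect_true(out$correct)
  expect_true(out$tie_flag)
  expect_error(decode_episode(c(a = 0.1, b = NA), "a"), "missing")
})

test_that("a noise-free cohort decodes perfectly with ICS at the clip bound", {
  coh <- simulate_cohort(noise_free_config(seed = 21), gaze = FALSE)
  suppressWarnings(prep <- preprocess_cohort(coh))
  seg <- segment_array(coh, prep)
  cross <- cross_episode_similarity(seg)
  res <- compute_ics(seg, cross)
  expect_true(all(abs(res$table$r - 1) < 1e-9))
  expect_true(all(res$table$z == atanh(1 - 1e-7)))
  dec <- decode_cohort(cross)
  expect_true(all(dec$accuracy == 1))
  # perfect decoder: permutation p at its floor
  dp <- decoding_permutation_test(cross[, , , 1], n_perm = 99, seed = 1)
  expect_equal(dp$p, 1 / 100)
})

test_that("a coupling-free cohort decodes at the 1/24 chance level", {
  cfg <- tiny_config(seed = 31, n_young = 6, n_old = 6,
                     regions = small_regions(c("dorsal_visual_area",
                                               "parahippocampal_region")),
                     params = list(w_override = 0))
  coh <- simulate_cohort(cfg, gaze = FALSE)
  prep <- preprocess_cohort(coh)
  seg <- segment_array(coh, prep)
  dec <- decode_cohort(cross_episode_similarity(seg))
  expect_lt(abs(mean(dec$accuracy) - 1 / 24), 0.03)
})

test_that("permutation p-values respect the add-one floor and direction", {
  set.seed(5)
  seg <- null_segments(n = 6, n_ep = 8)
  pt <- ics_permutation_test(seg[, , , 1], n_perm = 50, seed = 2)
  expect_gte(pt$p, 1 / 51)
  expect_lte(pt$p, 1)

  # shift the observed statistic below the null by depressing matched pairs:
  # anti-aligned segments against their own template
  seg2 <- seg
  seg2[, 1, , 1] <- -3 * apply(seg[, -1, , 1], c(1, 3), mean)
  # observed below the null median implies p > 0.5 for a clearly negative case
  pt2 <- ics_permutation_test(seg2[, , , 1], n_perm = 100, seed = 3)
  if (pt2$observed < stats::median(pt2$null)) expect_gt(pt2$p, 0.5)
})

test_that("the template-fixed null strategies remain available", {
  set.seed(6)
  seg <- null_segments(n = 6, n_ep = 8)
  p1 <- ics_permutation_test(seg[, , , 1], n_perm = 50, seed = 4,
                             strategy = "same_participant")
  p2 <- ics_permutation_test(seg[, , , 1], n_perm = 50, seed = 4,
                             strategy = "any_participant")
  expect_true(p1$p >= 1 / 51 && p1$p <= 1)
  expect_true(p2$p >= 1 / 51 && p2$p <= 1)
})

test_that("decoding label permutations have a 1/n_ep null mean", {
  set.seed(7)
  seg <- null_segments(n = 12, n_ep = 24)
  cr <- cross_episode_similarity(seg)
  dp <- decoding_permutation_test(cr[, , , 1], n_perm = 3000, seed = 8)
  expect_lt(abs(mean(dp$null) - 1 / 24), 0.005)
})

test_that("the condition contrast is a pooled two-sample t over episodes", {
  cc <- condition_contrast(c(1, 2, 3, 4, 5, 6),
                           rep(c("landmark", "none"), each = 3))
  expect_equal(cc$df, 4)
  expect_equal(cc$t, (2 - 5) / sqrt(1 * (1 / 3 + 1 / 3)), tolerance = 1e-12)

  acc <- stats::runif(12)
  cc <- condition_contrast(acc, rep(c("landmark", "none"), each = 6))
  expect_equal(cc$df, 10)

  cc0 <- condition_contrast(rep(0.3, 12), rep(c("landmark", "none"), each = 6))
  expect_equal(cc0$t, 0)
  expect_equal(cc0$p, 1)
  expect_error(condition_contrast(c(1, 2), c("landmark", "none")), "at least 2")
})
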