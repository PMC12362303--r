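test_that("residualization matches the normal-equations oracle", {
  set.seed(1)
  cov <- stats::rnorm(40)
  x_orth <- as.numeric(normal_eq_residual(stats::rnorm(40), cov))
  expect_equal(residualize(x_orth, cov), x_orth - mean(x_orth), tolerance = 1e-10)

  expect_true(all(abs(residualize(cov, cov)) < 1e-10))

  x <- stats::rnorm(40)
  expect_equal(residualize(x, cov), as.numeric(normal_eq_residual(x, cov)),
               tolerance = 1e-10)
  expect_lt(abs(sum(residualize(x, cov) * cov)), 1e-8)

  expect_warning(r0 <- residualize(x, rep(2, 40)), "constant covariate")
  expect_equal(r0, x - mean(x))
  expect_error(residualize(1:4, 1:3), "length mismatch")
})

test_that("pearson_p has exact endpoints and matches both oracles", {
  expect_equal(pearson_p(0, 10), 1)
  expect_equal(pearson_p(1, 10), 0)
  expect_equal(pearson_p(-1, 10), 0)
  expect_error(pearson_p(0.5, 4), "n >= 5")

  # oracle 1: numeric integration of the null density of r
  density_p <- function(r, n) {
    f <- function(v) (1 - v^2)^((n - 4) / 2) / beta(1 / 2, (n - 2) / 2)
    2 * stats::integrate(f, abs(r), 1, rel.tol = 1e-10)$value
  }
  for (n in c(5, 10, 30, 76)) {
    for (r in c(0.1, 0.3, 0.632, 0.9)) {
      expect_equal(pearson_p(r, n), density_p(r, n), tolerance = 1e-6)
      # oracle 2: the t-transform
      tt <- r * sqrt((n - 2) / (1 - r^2))
      expect_equal(pearson_p(r, n), 2 * stats::pt(-tt, n - 2),
                   tolerance = 1e-12)
    }
  }
})

test_that("BH adjustment reproduces hand-computed values and stays monotone", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_adjust(numeric(0)), numeric(0))

  set.seed(2)
  p <- stats::runif(50)
  adj <- fdr_adjust(p)
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-12))
  expect_true(all(adj <= 1))
})

test_that("motion-partialled correlation isolates the shared signal", {
  set.seed(3)
  n <- 76
  motion <- stats::rnorm(n)
  perf <- as.numeric(normal_eq_residual(stats::rnorm(n), motion))
  out <- correlate_with_performance(cbind(m = perf), perf, motion)
  expect_gt(out$r, 0.999)
  expect_equal(out$n, n)

  # both variables purely motion-driven: partial r collapses to noise level
  rs <- vapply(1:15, function(s) {
    set.seed(s)
    motion <- stats::rnorm(n)
    measure <- 2 * motion + stats::rnorm(n, sd = 0.05)
    perf <- -3 * motion + stats::rnorm(n, sd = 0.05)
    correlate_with_performance(cbind(m = measure), perf, motion)$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)
  expect_error(correlate_with_performance(cbind(1:10), 1:10, 1:9),
               "length mismatch")
})

test_that("the null rejection rate of the partial correlation is near alpha", {
  set.seed(4)
  n <- 76
  p <- vapply(1:800, function(i) {
    motion <- stats::rnorm(n)
    correlate_with_performance(cbind(stats::rnorm(n)), stats::rnorm(n),
                               motion)$p
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 0.025)
})

test_that("age regression z-scores inputs and reports the collinearity-consistent VIF", {
  set.seed(5)
  age <- c(stats::runif(45, 20, 30), stats::runif(31, 50, 65))
  motion_orth <- as.numeric(normal_eq_residual(stats::rnorm(76), age))
  out <- age_regression(cbind(m = stats::rnorm(76)), age, motion_orth)
  expect_equal(out$vif_age, 1, tolerance = 1e-6)

  motion_493 <- with_exact_cor(age, 0.493)
  out <- age_regression(cbind(m = stats::rnorm(76)), age, motion_493)
  expect_equal(round(out$vif_age, 2), 1.32)

  # exact standardized age effect recovered when the measure is noise-free
  a_true <- -0.5
  age_z <- as.numeric(scale(age))
  noise <- as.numeric(normal_eq_residual(stats::rnorm(76), cbind(age_z, motion_493)))
  measure <- a_true * age_z + sqrt(1 - a_true^2) * noise / stats::sd(noise)
  out <- age_regression(cbind(m = measure), age, motion_493)
  expect_equal(out$a, a_true, tolerance = 1e-8)
  expect_equal(out$b, 0, tolerance = 1e-8)
  expect_error(age_regression(cbind(1:5), rep(1, 5), 1:5), "constant")
})

test_that("mediation obeys the OLS decomposition identity and Sobel arithmetic", {
  set.seed(6)
  n <- 76
  age <- stats::rnorm(n); med <- stats::rnorm(n)
  perf <- 0.3 * age + 0.5 * med + stats::rnorm(n)
  motion <- stats::rnorm(n)
  m <- mediation(age, med, perf, motion)
  expect_equal(m$total_c, m$direct_c_prime + m$indirect, tolerance = 1e-8)

  s <- sobel_test(0.5, 0.1, 0.4, 0.1)
  expect_equal(round(s$z, 3), 3.123)
  expect_equal(s$z, 0.2 / sqrt(0.0041), tolerance = 1e-12)
  expect_equal(sobel_test(0.5, 0.1, 0, 0.1)$z, 0)

  # mediator unrelated to outcome: indirect effect collapses
  med2 <- stats::rnorm(n)
  perf2 <- 0.4 * age + stats::rnorm(n, sd = 0.1)
  m2 <- mediation(age, med2, perf2, motion)
  expect_lt(abs(m2$indirect), 0.1)
  expect_error(mediation(1:5, 1:5, 1:5, 1:5), "n > 5")
})

test_that("the Sobel test stays conservative under a null indirect path", {
  set.seed(7)
  n <- 76
  rej <- vapply(1:500, function(i) {
    age <- stats::rnorm(n)
    med <- stats::rnorm(n)                         # a = 0
    perf <- 0.5 * med + stats::rnorm(n)
    motion <- stats::rnorm(n)
    mediation(age, med, perf, motion)$sobel_p < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.07)
})

test_that("the ICS vs activation comparison pairs regions faithfully", {
  set.seed(8)
  n <- 40
  perf <- stats::rnorm(n); motion <- stats::rnorm(n)
  m <- cbind(r1 = stats::rnorm(n), r2 = stats::rnorm(n))
  cmp <- activation_vs_ics_comparison(m, m, perf, motion)
  expect_equal(cmp$r_ics, cmp$r_activation)

  # dynamics-loaded performance: the ICS column dominates
  wins <- vapply(1:40, function(s) {
    set.seed(s + 100)
    ics_m <- matrix(stats::rnorm(n * 3), n, 3,
                    dimnames = list(NULL, paste0("r", 1:3)))
    act_m <- matrix(stats::rnorm(n * 3), n, 3,
                    dimnames = list(NULL, paste0("r", 1:3)))
    perf <- rowMeans(ics_m) + stats::rnorm(n, sd = 0.5)
    cmp <- activation_vs_ics_comparison(ics_m, act_m, perf, stats::rnorm(n))
    mean(cmp$r_ics) > mean(cmp$r_activation)
  }, logical(1))
  expect_gt(mean(wins), 0.9)
})
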