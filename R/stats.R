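#' Residualize one variable on a covariate
#'
#' OLS residual of `x` on `covariate` plus an intercept. A constant covariate
#' degenerates to simple centering, with a warning.
#'
#' @param x numeric vector.
#' @param covariate numeric vector, same length.
#' @return residual vector (zero-mean, orthogonal to the covariate).
#' @export
residualize <- function(x, covariate) {
  if (length(x) != length(covariate)) stop("length mismatch")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(covariate) == 0) {
    warning("constant covariate; returning centered x")
    return(x - mean(x))
  }
  stats::lm.fit(cbind(1, covariate), x)$residuals
}

#' Two-tailed p-value for a Pearson correlation
#'
#' Exact null tail mass for the sample correlation under independence, i.e. the
#' tail of the density `f(r) = (1 - r^2)^((n-4)/2) / B(1/2, (n-2)/2)`, computed
#' through the equivalent t-statistic `t = r * sqrt((n-2) / (1-r^2))` with
#' `n - 2` degrees of freedom.
#'
#' @param r observed correlation, |r| <= 1.
#' @param n sample size (>= 5; below that the density exponent degenerates).
#' @return two-tailed p-value.
#' @export
pearson_p <- function(r, n) {
  if (any(n < 5)) stop("need n >= 5")
  if (any(abs(r) > 1)) stop("|r| must be <= 1")
  p <- ifelse(abs(r) == 1, 0,
              2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2))
  pmin(p, 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1).
#'
#' @param p vector of raw p-values.
#' @return adjusted p-values, same order.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Motion-partialled correlation with performance
#'
#' Residualizes both the per-participant measure and performance on mean head
#' motion, correlates the residuals, and assigns the two-tailed p-value with
#' `n` = participant count; BH-FDR across regions.
#'
#' @param measure participants x regions matrix (or vector).
#' @param performance per-participant performance.
#' @param motion per-participant mean framewise displacement.
#' @return data.frame `region`, `r`, `n`, `p`, `fdr_p`.
#' @export
correlate_with_performance <- function(measure, performance, motion) {
  measure <- as.matrix(measure)
  if (nrow(measure) != length(performance) ||
      length(performance) != length(motion)) {
    stop("length mismatch between measure, performance, and motion")
  }
  if (nrow(measure) < 5) stop("need at least 5 participants")
  perf_res <- residualize(performance, motion)
  rs <- vapply(seq_len(ncol(measure)), function(k) {
    stats::cor(residualize(measure[, k], motion), perf_res)
  }, numeric(1))
  out <- data.frame(
    region = if (is.null(colnames(measure))) as.character(seq_along(rs))
             else colnames(measure),
    r = rs, n = nrow(measure), p = pearson_p(rs, nrow(measure)),
    stringsAsFactors = FALSE
  )
  out$fdr_p <- fdr_adjust(out$p)
  out
}

#' Age regression with motion covariate
#'
#' Fits `measure = a * Age + b * Motion + c + e` with all three variables
#' z-scored across participants, and reports the variance inflation factor for
#' age, `1 / (1 - R^2)` of age regressed on motion.
#'
#' @param measure per-participant measure (vector, or matrix for many regions).
#' @param age,motion per-participant covariates.
#' @return data.frame `region`, `a` (age coefficient), `b` (motion
#'   coefficient), `se_a`, `se_b`, `p_a`, `p_b`, `intercept`, `vif_age`.
#' @export
age_regression <- function(measure, age, motion) {
  measure <- as.matrix(measure)
  if (stats::sd(age) == 0) stop("age is constant")
  if (nrow(measure) < 4) stop("need n >= 4")
  z <- function(v) as.numeric(scale(v))
  age_z <- z(age)
  mot_z <- if (stats::sd(motion) > 0) z(motion) else motion * 0
  vif <- if (stats::sd(motion) > 0) 1 / (1 - stats::cor(age_z, mot_z)^2) else 1
  out <- do.call(rbind, lapply(seq_len(ncol(measure)), function(k) {
    fit <- summary(stats::lm(z(measure[, k]) ~ age_z + mot_z))$coefficients
    data.frame(
      region = if (is.null(colnames(measure))) as.character(k)
               else colnames(measure)[k],
      a = fit["age_z", 1], b = fit["mot_z", 1],
      se_a = fit["age_z", 2], se_b = fit["mot_z", 2],
      p_a = fit["age_z", 4], p_b = fit["mot_z", 4],
      intercept = fit["(Intercept)", 1], vif_age = vif,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Three-equation mediation analysis with Sobel test
#'
#' Standardizes X (age), M (mediator), Y (performance), and Z (motion), then
#' fits `Y ~ X + Z` (total effect c), `M ~ X + Z` (path a), and
#' `Y ~ X + M + Z` (direct effect c', path b). The indirect effect is `a * b`
#' with classic Sobel standard error `sqrt(a^2 SE_b^2 + b^2 SE_a^2)` and a
#' two-tailed normal p-value. On any single dataset the OLS decomposition
#' identity `c = c' + a * b` holds to numerical precision.
#'
#' @param age,mediator,performance,motion per-participant vectors.
#' @return list with `total_c`, `se_c`, `p_c`, `path_a`, `se_a`, `p_a`,
#'   `path_b`, `se_b`, `p_b`, `direct_c_prime`, `se_c_prime`, `p_c_prime`,
#'   `indirect`, `sobel_z`, `sobel_p`, `candidate` (path a < 0 with p < 0.05).
#' @export
mediation <- function(age, mediator, performance, motion) {
  n <- length(age)
  if (n <= 5) stop("need n > 5")
  z <- function(v) as.numeric(scale(v))
  X <- z(age); M <- z(mediator); Y <- z(performance)
  Z <- if (stats::sd(motion) > 0) z(motion) else motion * 0
  f1 <- summary(stats::lm(Y ~ X + Z))$coefficients
  f2 <- summary(stats::lm(M ~ X + Z))$coefficients
  f3 <- summary(stats::lm(Y ~ X + M + Z))$coefficients
  a <- f2["X", 1]; se_a <- f2["X", 2]
  b <- f3["M", 1]; se_b <- f3["M", 2]
  indirect <- a * b
  sobel_se <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  sobel_z <- if (sobel_se == 0) 0 else indirect / sobel_se
  list(
    total_c = f1["X", 1], se_c = f1["X", 2], p_c = f1["X", 4],
    path_a = a, se_a = se_a, p_a = f2["X", 4],
    path_b = b, se_b = se_b, p_b = f3["M", 4],
    direct_c_prime = f3["X", 1], se_c_prime = f3["X", 2],
    p_c_prime = f3["X", 4],
    indirect = indirect, sobel_z = sobel_z,
    sobel_p = 2 * stats::pnorm(-abs(sobel_z)),
    candidate = a < 0 && f2["X", 4] < 0.05
  )
}

#' Sobel z from injected coefficients
#'
#' Classic Sobel arithmetic for a known (a, SE_a, b, SE_b).
#'
#' @param a,se_a,b,se_b path coefficients and standard errors.
#' @return list with `z` and two-tailed `p`.
#' @export
sobel_test <- function(a, se_a, b, se_b) {
  se <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  z <- if (se == 0) 0 else (a * b) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Region-wise mediation table
#'
#' Applies [mediation()] per region (column of the mediator matrix), with the
#' candidate filter of the second model (a < 0, p < 0.05) recorded per region.
#'
#' @param age,performance,motion per-participant vectors.
#' @param mediators participants x regions matrix (ICS or ISFC).
#' @param candidates_only if TRUE, rows failing the candidate filter carry NA
#'   mediation columns (the age path is always reported).
#' @return data.frame in the age-regression + mediation layout.
#' @export
mediation_table <- function(age, mediators, performance, motion,
                            candidates_only = TRUE) {
  mediators <- as.matrix(mediators)
  out <- do.call(rbind, lapply(seq_len(ncol(mediators)), function(k) {
    m <- mediation(age, mediators[, k], performance, motion)
    d <- data.frame(
      region = if (is.null(colnames(mediators))) as.character(k)
               else colnames(mediators)[k],
      a = m$path_a, p_a = m$p_a, b = m$path_b,
      total_c = m$total_c, direct_c_prime = m$direct_c_prime,
      indirect = m$indirect, sobel_z = m$sobel_z, sobel_p = m$sobel_p,
      candidate = m$candidate, stringsAsFactors = FALSE
    )
    if (candidates_only && !m$candidate) {
      d[c("indirect", "sobel_z", "sobel_p")] <- NA_real_
    }
    d
  }))
  rownames(out) <- NULL
  out
}

#' Side-by-side ICS vs activation correlations with performance
#'
#' Motion-partialled correlation of performance with episode-averaged ICS and
#' with baseline-referenced average activation, per region.
#'
#' @param ics_pr participants x regions ICS matrix.
#' @param activation_pr participants x regions activation matrix.
#' @param performance,motion per-participant vectors.
#' @return data.frame `region`, `r_ics`, `p_ics`, `r_activation`,
#'   `p_activation`.
#' @export
activation_vs_ics_comparison <- function(ics_pr, activation_pr, performance,
                                         motion) {
  a <- correlate_with_performance(ics_pr, performance, motion)
  b <- correlate_with_performance(activation_pr, performance, motion)
  data.frame(region = a$region, r_ics = a$r, p_ics = a$p,
             r_activation = b$r[match(a$region, b$region)],
             p_activation = b$p[match(a$region, b$region)],
             stringsAsFactors = FALSE)
}
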