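#' Fisher Z-transform with clipping
#'
#' `atanh(r)` after clipping `|r|` at `1 - 1e-7` so perfect correlations stay
#' finite.
#'
#' @param r correlation(s).
#' @param clip clip bound on |r|.
#' @return Fisher-Z value(s).
#' @export
fisher_z <- function(r, clip = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clip), clip))
}

#' Leave-one-subject-out canonical dynamics
#'
#' Frame-wise mean of one region x episode's segments over all participants
#' except the excluded one.
#'
#' @param segments frames x participants matrix.
#' @param exclude participant column index (or name) to leave out.
#' @return numeric vector of frame-wise means.
#' @export
canonical_dynamics <- function(segments, exclude) {
  segments <- as.matrix(segments)
  if (ncol(segments) < 2) stop("need at least 2 participants")
  if (is.character(exclude)) exclude <- match(exclude, colnames(segments))
  rowMeans(segments[, -exclude, drop = FALSE])
}

#' Individual-to-canonical similarity
#'
#' Pearson correlation between one participant's segment and the leave-one-out
#' canonical template, Fisher Z-transformed.
#'
#' @param individual numeric vector (the participant's 26-frame segment).
#' @param template numeric vector (the canonical template excluding them).
#' @return list with `r` and `z`.
#' @export
ics <- function(individual, template) {
  if (stats::sd(individual) == 0 || stats::sd(template) == 0) {
    stop("degenerate signal: zero-variance segment")
  }
  r <- stats::cor(individual, template)
  list(r = r, z = fisher_z(r))
}

#' All segment-template correlations per region
#'
#' For every participant i, region k, and ordered episode pair (e, e'),
#' computes the Pearson correlation between participant i's segment of episode
#' e and the leave-i-out canonical template of episode e'. The diagonal
#' (e == e') holds the matched ICS correlations; off-diagonal entries feed the
#' episode decoder and the permutation null.
#'
#' @param seg segment array from [segment_array()]
#'   (frames x participants x episodes x regions).
#' @return array participants x episodes(segment) x episodes(template) x
#'   regions of correlations.
#' @export
cross_episode_similarity <- function(seg) {
  d <- dim(seg)
  n <- d[2]; n_ep <- d[3]; n_reg <- d[4]
  if (n < 2) stop("need at least 2 participants")
  out <- array(NA_real_, dim = c(n, n_ep, n_ep, n_reg),
               dimnames = list(dimnames(seg)[[2]], dimnames(seg)[[3]],
                               dimnames(seg)[[3]], dimnames(seg)[[4]]))
  for (k in seq_len(n_reg)) {
    sk <- seg[, , , k, drop = FALSE]
    dim(sk) <- d[1:3]
    tot <- apply(sk, c(1, 3), sum)          # frames x episodes, sum over subj
    for (i in seq_len(n)) {
      si <- sk[, i, ]                        # frames x episodes
      ti <- (tot - si) / (n - 1)             # leave-i-out templates
      out[i, , , k] <- stats::cor(si, ti)
    }
  }
  out
}

#' Cohort-level ICS
#'
#' @param seg segment array from [segment_array()].
#' @param cross optional precomputed [cross_episode_similarity()] array.
#' @return list with `table` (long data.frame participant_id, region,
#'   episode_id, r, z), `participant_region` (participants x regions matrix of
#'   episode-averaged z), and `cross` (the similarity array, reused downstream).
#' @export
compute_ics <- function(seg, cross = cross_episode_similarity(seg)) {
  d <- dim(cross)
  n <- d[1]; n_ep <- d[2]; n_reg <- d[4]
  diag_idx <- cbind(rep(seq_len(n), n_ep * n_reg),
                    rep(rep(seq_len(n_ep), each = n), n_reg),
                    rep(rep(seq_len(n_ep), each = n), n_reg),
                    rep(seq_len(n_reg), each = n * n_ep))
  r <- cross[diag_idx]
  tab <- data.frame(
    participant_id = dimnames(cross)[[1]][diag_idx[, 1]],
    episode_id = dimnames(cross)[[2]][diag_idx[, 2]],
    region = dimnames(cross)[[4]][diag_idx[, 4]],
    r = r, z = fisher_z(r), stringsAsFactors = FALSE
  )
  pr <- apply(array(tab$z, dim = c(n, n_ep, n_reg)), c(1, 3), mean)
  dimnames(pr) <- list(dimnames(cross)[[1]], dimnames(cross)[[4]])
  list(table = tab, participant_region = pr, cross = cross)
}

#' Region-level ICS summary
#'
#' Mean ICS (Fisher-Z), standard error over participants, and optionally the
#' episode-relabelling permutation p-value per region.
#'
#' @param ics_result output of [compute_ics()].
#' @param seg segment array (needed when `n_perm > 0`).
#' @param n_perm permutations for the mean-ICS test (0 to skip).
#' @param seed RNG seed for the permutation draws.
#' @param strategy null strategy, see [ics_permutation_test()].
#' @return data.frame region, mean_ics, se, p_perm, fdr_p.
#' @export
ics_region_summary <- function(ics_result, seg = NULL, n_perm = 10000,
                               seed = 1L, strategy = "relabel") {
  pr <- ics_result$participant_region
  out <- data.frame(region = colnames(pr),
                    mean_ics = colMeans(pr),
                    se = apply(pr, 2, stats::sd) / sqrt(nrow(pr)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (n_perm > 0) {
    if (is.null(seg)) stop("segment array required for the permutation test")
    out$p_perm <- vapply(seq_len(ncol(pr)), function(k) {
      ics_permutation_test(seg[, , , k], n_perm = n_perm,
                           seed = seed + k, strategy = strategy)$p
    }, numeric(1))
    out$fdr_p <- fdr_adjust(out$p_perm)
  }
  out
}

#' Decode an episode from one segment
#'
#' Predicts the episode whose canonical template has the highest similarity to
#' the individual segment; ties are broken deterministically in favour of the
#' lowest episode index and flagged.
#'
#' @param similarities named numeric vector of correlations against all
#'   templates for one segment.
#' @param true_episode name (or index) of the actual episode.
#' @return list with `predicted`, `correct`, `tie_flag`.
#' @export
decode_episode <- function(similarities, true_episode) {
  if (any(is.na(similarities))) stop("missing template similarity")
  best <- which(similarities == max(similarities))
  predicted <- best[1]
  nm <- names(similarities)
  pred_id <- if (is.null(nm)) predicted else nm[predicted]
  list(predicted = pred_id,
       correct = identical(pred_id, true_episode) ||
         (is.numeric(true_episode) && predicted == true_episode),
       tie_flag = length(best) > 1)
}

#' Cohort-level episode decoding
#'
#' @param cross similarity array from [cross_episode_similarity()].
#' @return list with `accuracy` (participants x regions), `by_episode`
#'   (episodes x regions, participant-averaged accuracy), `summary`
#'   (region, accuracy_pct, se_pct), `argmax` (participants x episodes x
#'   regions predicted indices), `ties` (count of tied decisions).
#' @export
decode_cohort <- function(cross) {
  d <- dim(cross)
  n <- d[1]; n_ep <- d[2]; n_reg <- d[4]
  amax <- array(0L, dim = c(n, n_ep, n_reg))
  ties <- 0L
  for (k in seq_len(n_reg)) for (i in seq_len(n)) {
    m <- cross[i, , , k]
    idx <- max.col(m, ties.method = "first")
    amax[i, , k] <- idx
    ties <- ties + sum(rowSums(m == m[cbind(seq_len(n_ep), idx)]) > 1)
  }
  correct <- sweep(amax, 2, seq_len(n_ep), "==")
  acc <- apply(correct, c(1, 3), mean)
  dimnames(acc) <- list(dimnames(cross)[[1]], dimnames(cross)[[4]])
  by_ep <- apply(correct, c(2, 3), mean)
  dimnames(by_ep) <- list(dimnames(cross)[[2]], dimnames(cross)[[4]])
  summary <- data.frame(region = colnames(acc),
                        accuracy_pct = 100 * colMeans(acc),
                        se_pct = 100 * apply(acc, 2, stats::sd) / sqrt(nrow(acc)),
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(accuracy = acc, by_episode = by_ep, summary = summary,
       argmax = amax, ties = ties)
}

#' Mean matched leave-one-out similarity for one region
#'
#' Mean over participants and episodes of the Pearson correlation between each
#' individual segment and its leave-one-out canonical template, fully
#' vectorised (used by the permutation machinery).
#'
#' @param seg_k frames x participants x episodes array for one region.
#' @return scalar mean correlation.
#' @keywords internal
matched_mean_similarity <- function(seg_k) {
  d <- dim(seg_k)
  nf <- d[1]; n <- d[2]; n_ep <- d[3]
  pc <- seg_k - rep(colMeans(seg_k), each = nf)       # center every segment
  tot <- apply(pc, c(1, 3), sum)                      # frames x episodes
  tot_e <- tot[, rep(seq_len(n_ep), each = n), drop = FALSE]
  pm <- matrix(pc, nf, n * n_ep)
  num <- colSums(pm * tot_e) - colSums(pm^2)          # pc . (tot - pc)
  ti_ss <- colSums(tot_e^2) - 2 * colSums(pm * tot_e) + colSums(pm^2)
  ti_mean <- rep(colMeans(tot), each = n)             # pc columns are centered
  den2 <- ti_ss - nf * ti_mean^2
  mean(num / sqrt(colSums(pm^2) * den2))
}

#' Permutation test for mean ICS
#'
#' Tests whether a region's mean matched ICS exceeds what mismatched
#' episode-template pairings produce. Three null strategies:
#' \describe{
#'   \item{"relabel" (default)}{each permutation re-labels every participant's
#'     episodes independently and recomputes the leave-one-out canonical
#'     templates from the re-labelled data before taking the matched mean.
#'     Under the global null the observed labelling is exchangeable with the
#'     permuted ones, so the test is calibrated.}
#'   \item{"same_participant"}{pairs the fixed canonical template of episode j
#'     with an individual segment of a randomly chosen different episode
#'     j' != j of the same participant (templates not recomputed). Cheap, but
#'     anticonservative under the null: the matched statistic retains the
#'     mutual segment-template containment that mismatched pairs lack, roughly
#'     doubling its variance relative to this null.}
#'   \item{"any_participant"}{as above but drawing the segment from a random
#'     participant.}
#' }
#' One-sided add-one estimator `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param seg_k frames x participants x episodes segment array for one region
#'   (`seg[, , , k]`).
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed.
#' @param strategy null strategy, see above.
#' @return list with `observed` (mean matched ICS correlation), `null`
#'   (numeric vector), `p`.
#' @export
ics_permutation_test <- function(seg_k, n_perm = 10000, seed = 1L,
                                 strategy = c("relabel", "same_participant",
                                              "any_participant")) {
  strategy <- match.arg(strategy)
  if (n_perm < 1) stop("invalid config: n_perm must be >= 1")
  d <- dim(seg_k)
  nf <- d[1]; n <- d[2]; n_ep <- d[3]
  if (n_ep < 2) stop("need at least 2 episodes")
  set.seed(seed)
  observed <- matched_mean_similarity(seg_k)

  if (strategy == "relabel") {
    null <- vapply(seq_len(n_perm), function(b) {
      p <- seg_k
      for (i in seq_len(n)) p[, i, ] <- seg_k[, i, sample.int(n_ep)]
      matched_mean_similarity(p)
    }, numeric(1))
  } else {
    cross_k <- .cross_one_region(seg_k)
    n_cell <- n * n_ep
    tmpl <- rep(seq_len(n_ep), each = n)
    subj <- rep(seq_len(n), n_ep)
    null <- vapply(seq_len(n_perm), function(b) {
      off <- sample.int(n_ep - 1L, n_cell, replace = TRUE)
      seg_ep <- (tmpl + off - 1L) %% n_ep + 1L
      sub <- if (strategy == "same_participant") subj
             else sample.int(n, n_cell, replace = TRUE)
      mean(cross_k[cbind(sub, seg_ep, tmpl)])
    }, numeric(1))
  }
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  list(observed = observed, null = null, p = p, strategy = strategy)
}

.cross_one_region <- function(seg_k) {
  d <- dim(seg_k)
  n <- d[2]
  tot <- apply(seg_k, c(1, 3), sum)
  out <- array(NA_real_, dim = c(n, d[3], d[3]))
  for (i in seq_len(n)) {
    si <- seg_k[, i, ]
    out[i, , ] <- stats::cor(si, (tot - si) / (n - 1))
  }
  out
}

#' Permutation test for decoding accuracy
#'
#' Permutes the episode labels of the canonical templates and re-applies the
#' decoder; because the argmax template of each segment is unchanged, each
#' permuted decision is correct exactly when the permutation maps the true
#' episode onto the argmax index, giving a null accuracy distribution with
#' mean 1/(number of episodes). One-sided add-one p-value.
#'
#' @param cross_k participants x episodes x episodes slice for one region.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `observed` (accuracy), `null` (vector of null
#'   accuracies), `p`.
#' @export
decoding_permutation_test <- function(cross_k, n_perm = 10000, seed = 1L) {
  if (n_perm < 1) stop("invalid config: n_perm must be >= 1")
  d <- dim(cross_k)
  n <- d[1]; n_ep <- d[2]
  set.seed(seed)
  amax <- t(vapply(seq_len(n),
                   function(i) max.col(cross_k[i, , ], ties.method = "first"),
                   integer(n_ep)))
  observed <- mean(sweep(amax, 2, seq_len(n_ep), "==") )
  ep_idx <- rep(seq_len(n_ep), each = n)
  amax_v <- as.numeric(amax)
  null <- vapply(seq_len(n_perm), function(j) {
    perm <- sample.int(n_ep)
    mean(amax_v == perm[ep_idx])
  }, numeric(1))
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  list(observed = observed, null = null, p = p)
}

#' Condition contrast on episode-wise decoding accuracy
#'
#' Pooled-variance two-sample t-test across episodes (the episode, not the
#' participant, is the unit: accuracies are first averaged over participants
#' per episode), comparing two sets of conditions.
#'
#' @param acc_by_episode named numeric vector of participant-averaged accuracy
#'   per episode.
#' @param condition condition label per episode (same order).
#' @param group1,group2 condition labels defining the two groups.
#' @return list with `t`, `df`, `p`, `mean1`, `mean2`.
#' @export
condition_contrast <- function(acc_by_episode, condition,
                               group1 = "landmark", group2 = "none") {
  x <- acc_by_episode[condition %in% group1]
  y <- acc_by_episode[condition %in% group2]
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 episodes per group")
  if (stats::sd(c(x, y)) == 0) {
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                mean1 = mean(x), mean2 = mean(y)))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean1 = mean(x), mean2 = mean(y))
}
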