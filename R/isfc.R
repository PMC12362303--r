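#' Intersubject functional connectivity for one segment pair
#'
#' Fisher-Z Pearson correlation between an individual's seed-region segment and
#' the leave-one-out canonical template of a target region for the same
#' episode. With seed == target this is exactly the ICS of that region.
#'
#' @param seed_segment individual seed-region segment (26 frames).
#' @param target_template leave-one-out canonical template of the target
#'   region, same episode.
#' @return list with `r`, `z`.
#' @export
isfc <- function(seed_segment, target_template) {
  ics(seed_segment, target_template)
}

#' All seed x target intersubject correlations
#'
#' For every participant and episode, correlates the individual segment of each
#' seed region with the leave-one-out canonical template of each target region,
#' then averages the Fisher-Z values over episodes (the average is taken on the
#' Z scale, not on r).
#'
#' @param seg segment array (frames x participants x episodes x regions).
#' @return participants x seed-regions x target-regions array of
#'   episode-averaged Fisher-Z connectivity.
#' @export
isfc_matrix <- function(seg) {
  d <- dim(seg)
  nf <- d[1]; n <- d[2]; n_ep <- d[3]; n_reg <- d[4]
  if (n < 2) stop("need at least 2 participants")
  labels <- dimnames(seg)[[4]]
  tot <- apply(seg, c(1, 3, 4), sum)  # frames x episodes x regions
  acc <- array(0, dim = c(n, n_reg, n_reg),
               dimnames = list(dimnames(seg)[[2]], labels, labels))
  for (i in seq_len(n)) {
    zi <- array(0, dim = c(n_reg, n_reg))
    for (e in seq_len(n_ep)) {
      si <- matrix(seg[, i, e, ], nf, n_reg)          # individual, all regions
      ti <- (matrix(tot[, e, ], nf, n_reg) - si) / (n - 1)  # LOSO templates
      zi <- zi + fisher_z(stats::cor(si, ti))
    }
    acc[i, , ] <- zi / n_ep
  }
  acc
}

#' Seed-based ISFC profile
#'
#' Episode-averaged Fisher-Z connectivity between one seed region's individual
#' dynamics and the canonical dynamics of every target region, excluding both
#' hemispheres of the seed's own bilateral region (46 - 2 = 44 targets for a
#' hippocampal-formation seed).
#'
#' @param isfc_all array from [isfc_matrix()] (or a segment array, which is
#'   converted).
#' @param seed seed region label (e.g. "hippocampal_formation_L"), or both
#'   hemisphere labels to average jointly.
#' @return participants x targets matrix of episode-averaged Fisher-Z values.
#' @export
isfc_profile <- function(isfc_all, seed) {
  if (length(dim(isfc_all)) == 4) isfc_all <- isfc_matrix(isfc_all)
  labels <- dimnames(isfc_all)[[2]]
  if (!all(seed %in% labels)) stop("unknown seed region: ",
                                   paste(setdiff(seed, labels), collapse = ", "))
  base <- sub("_[LR]$", "", seed)
  targets <- labels[!(sub("_[LR]$", "", labels) %in% base)]
  prof <- isfc_all[, seed, targets, drop = FALSE]
  if (length(seed) > 1) {
    prof <- apply(prof, c(1, 3), mean)
  } else {
    dim(prof) <- dim(prof)[c(1, 3)]
    dimnames(prof) <- list(dimnames(isfc_all)[[1]], targets)
  }
  prof
}

#' Seed-wise summary of connectivity--performance coupling
#'
#' For every seed region: computes the motion-partialled Pearson correlation
#' between each target's episode-averaged ISFC and spatial memory performance,
#' and averages r over targets.
#'
#' @param isfc_all array from [isfc_matrix()].
#' @param performance per-participant performance vector (design order).
#' @param motion per-participant mean framewise displacement.
#' @return data.frame `seed`, `mean_r`, `n_targets`, sorted by `mean_r`
#'   descending.
#' @export
seedwise_summary <- function(isfc_all, performance, motion) {
  labels <- dimnames(isfc_all)[[2]]
  out <- do.call(rbind, lapply(labels, function(s) {
    prof <- isfc_profile(isfc_all, s)
    rs <- vapply(seq_len(ncol(prof)), function(j) {
      stats::cor(residualize(prof[, j], motion), residualize(performance, motion))
    }, numeric(1))
    data.frame(seed = s, mean_r = mean(rs), n_targets = ncol(prof),
               stringsAsFactors = FALSE)
  }))
  out[order(-out$mean_r), , drop = FALSE]
}
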