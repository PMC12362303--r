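#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> condition -> ICS/decoding (+ permutation tests) ->
#' event regression -> hippocampal ISFC -> brain-behaviour statistics and
#' mediation, end to end, and optionally writes every result table plus a
#' provenance manifest. All randomness descends from `config$seed`;
#' deterministic stages are bit-identical across reruns of the same config.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional output directory for TSV results and the manifest.
#' @param n_perm permutations for the region-wise ICS and decoding tests
#'   (0 skips them).
#' @param seed_region base name of the ISFC seed region.
#' @param use_empirical_gaze build the landmark regressor from the simulated
#'   eye-tracker flags (the full observational route) rather than the latent
#'   gaze ratio.
#' @return list of result tables: `performance`, `mean_fd`, `ics_summary`,
#'   `decoding_summary`, `condition_contrast`, `event_regression`,
#'   `isfc_performance`, `seedwise`, `ics_performance`,
#'   `activation_comparison`, `age_regression`, `mediation_ics`,
#'   `mediation_isfc`, plus `cohort`, `ics`, `decoding` intermediates.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL,
                         n_perm = 2000, seed_region = "hippocampal_formation",
                         use_empirical_gaze = TRUE) {
  validate_config(config)
  cohort <- simulate_cohort(config, gaze = use_empirical_gaze)
  design <- cohort$design
  prep <- preprocess_cohort(cohort)
  seg <- segment_array(cohort, prep)

  # --- ICS and decoding ----------------------------------------------------
  cross <- cross_episode_similarity(seg)
  ics_res <- compute_ics(seg, cross)
  ics_summary <- ics_region_summary(ics_res, seg, n_perm = n_perm,
                                    seed = config$seed + 101L)
  decoding <- decode_cohort(cross)
  if (n_perm > 0) {
    decoding$summary$p_perm <- vapply(seq_len(dim(cross)[4]), function(k) {
      decoding_permutation_test(cross[, , , k], n_perm = n_perm,
                                seed = config$seed + 202L + k)$p
    }, numeric(1))
    decoding$summary$fdr_p <- fdr_adjust(decoding$summary$p_perm)
  }

  # condition contrast on a landmark-sensitive region (ventral visual area,
  # falling back to the first region when it is not in the region set)
  cc_region <- grep("ventral_visual_area", colnames(decoding$by_episode),
                    value = TRUE)[1]
  if (is.na(cc_region)) cc_region <- colnames(decoding$by_episode)[1]
  contrast <- condition_contrast(
    decoding$by_episode[, cc_region],
    design$episodes$condition, group1 = "landmark", group2 = "none"
  )

  # --- event regression on canonical dynamics ------------------------------
  hrf <- cohort$hrf
  tr <- design$tr_seconds
  retained_times <- (4:(60 / tr - 1)) * tr
  n_ep <- nrow(design$episodes)
  x1 <- x2 <- numeric(0)
  for (e in seq_len(n_ep)) {
    st <- cohort$streams[[design$episodes$episode_id[e]]]
    x1 <- c(x1, build_regressor(st$angular_velocity, hrf, retained_times))
    ratio <- if (use_empirical_gaze && !is.null(cohort$gaze)) {
      aggregate_gaze(cohort$gaze[[design$episodes$episode_id[e]]])
    } else {
      st$gaze_ratio
    }
    mask <- if (any(ratio > 0)) landmark_mask(ratio) else rep(FALSE, length(ratio))
    x2 <- c(x2, build_regressor(as.numeric(mask), hrf, retained_times))
  }
  Y <- apply(seg, c(1, 3, 4), mean)            # frames x episodes x regions
  Yc <- matrix(Y, prod(dim(Y)[1:2]), dim(Y)[3],
               dimnames = list(NULL, dimnames(Y)[[3]]))
  event_reg <- fit_event_regression(Yc, x1, x2)

  # --- behaviour and motion covariates -------------------------------------
  perf <- spatial_memory_performance(cohort$behavior$trials)
  perf <- perf[match(design$participants$participant_id, perf$participant_id), ]
  performance <- perf$performance
  motion_fd <- prep$mean_fd

  # --- ISFC (needs at least two distinct bilateral regions) ----------------
  isfc_all <- isfc_matrix(seg)
  labels <- dimnames(isfc_all)[[2]]
  seeds <- grep(paste0("^", seed_region, "_[LR]$"), labels, value = TRUE)
  if (length(seeds) == 0) {
    seeds <- grep(paste0("^", sub("_[LR]$", "", labels[1]), "_[LR]$"),
                  labels, value = TRUE)
  }
  have_targets <- length(unique(sub("_[LR]$", "", labels))) > 1
  if (have_targets) {
    prof <- isfc_profile(isfc_all, seeds)
    isfc_perf <- correlate_with_performance(prof, performance, motion_fd)
    seedwise <- seedwise_summary(isfc_all, performance, motion_fd)
  } else {
    prof <- NULL
    isfc_perf <- NULL
    seedwise <- NULL
  }

  # --- brain-behaviour statistics ------------------------------------------
  ics_pr <- ics_res$participant_region
  activation <- activation_matrix(cohort, prep)
  ics_perf <- correlate_with_performance(ics_pr, performance, motion_fd)
  comparison <- activation_vs_ics_comparison(ics_pr, activation, performance,
                                             motion_fd)
  age <- design$participants$age
  age_reg <- age_regression(ics_pr, age, motion_fd)
  med_ics <- mediation_table(age, ics_pr, performance, motion_fd)
  med_isfc <- if (is.null(prof)) NULL
              else mediation_table(age, prof, performance, motion_fd)

  results <- list(
    cohort = cohort, prep_mean_fd = motion_fd, ics = ics_res,
    decoding = decoding,
    performance = perf,
    ics_summary = ics_summary,
    decoding_summary = decoding$summary,
    condition_contrast = contrast,
    event_regression = event_reg,
    isfc_performance = isfc_perf,
    seedwise = seedwise,
    ics_performance = ics_perf,
    activation_comparison = comparison,
    age_regression = age_reg,
    mediation_ics = med_ics,
    mediation_isfc = med_isfc
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(ics_res$table, file.path(out_dir, "ics_long.tsv"))
    write_tsv(ics_summary, file.path(out_dir, "ics_region_summary.tsv"))
    write_tsv(decoding$summary, file.path(out_dir, "decoding_summary.tsv"))
    write_tsv(event_reg, file.path(out_dir, "event_regression.tsv"))
    if (!is.null(isfc_perf)) {
      write_tsv(isfc_perf, file.path(out_dir, "isfc_performance.tsv"))
      write_tsv(seedwise, file.path(out_dir, "seedwise_summary.tsv"))
      write_tsv(med_isfc, file.path(out_dir, "mediation_isfc.tsv"))
    }
    write_tsv(ics_perf, file.path(out_dir, "ics_performance.tsv"))
    write_tsv(comparison, file.path(out_dir, "activation_comparison.tsv"))
    write_tsv(age_reg, file.path(out_dir, "age_regression.tsv"))
    write_tsv(med_ics, file.path(out_dir, "mediation_ics.tsv"))
    write_tsv(perf, file.path(out_dir, "performance.tsv"))
    manifest <- list(
      seed = config$seed, n_participants = nrow(design$participants),
      n_episodes = nrow(design$episodes), n_regions = nrow(config$regions),
      n_perm = n_perm, seed_region = seed_region,
      r_version = as.character(getRversion()),
      config_hash = config_hash(config)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  results
}

#' Episode-averaged activation per participant and region
#'
#' Baseline-referenced average activation computed on the cleaned
#' percent-signal runs, averaged over episodes.
#'
#' @param cohort a `navdyn_cohort`.
#' @param prep output of [preprocess_cohort()].
#' @return participants x regions matrix.
#' @export
activation_matrix <- function(cohort, prep) {
  design <- cohort$design
  n <- nrow(design$participants)
  labels <- colnames(prep$cleaned[[1]][[1]]$values)
  acc <- matrix(0, n, length(labels),
                dimnames = list(design$participants$participant_id, labels))
  n_ep <- nrow(design$episodes)
  for (r in seq_len(design$n_runs)) {
    ev <- run_events(design, r)
    win <- extract_windows(prep$cleaned[[1]][[r]], ev)
    for (i in seq_len(n)) {
      act <- average_activation(prep$cleaned[[i]][[r]], win)
      agg <- rowsum(act$activation, act$region)
      acc[i, rownames(agg)] <- acc[i, rownames(agg)] + agg[, 1]
    }
  }
  acc / n_ep
}

#' Stable hash of a configuration
#'
#' Small order-independent checksum of the serialized config, recorded in the
#' provenance manifest so reruns can assert they used the same settings.
#'
#' @param config a `navdyn_config`.
#' @return character scalar.
#' @export
config_hash <- function(config) {
  s <- jsonlite::serializeJSON(config[setdiff(names(config), "regions")])
  v <- utf8ToInt(paste0(s, collapse = ""))
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}
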