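#!/usr/bin/env Rscript

# Stage 5: intersubject functional connectivity with the hippocampal seed.
#
# Fisher-Z Pearson correlation between each individual's hippocampal-formation
# dynamics and the leave-one-out canonical dynamics of the 44 cortical targets
# (both hippocampal hemispheres excluded), averaged over the 24 episodes on the
# Z scale; motion-partialled correlation of each target's connectivity with
# spatial memory performance, and the seed-wise summary over all 46 seeds.

suppressPackageStartupMessages(library(navdyn))

seed <- 20260923L
cohort <- simulate_cohort(cohort_config(seed = seed), gaze = FALSE)
prep <- preprocess_cohort(cohort)
seg <- segment_array(cohort, prep)

perf <- spatial_memory_performance(cohort$behavior$trials)$performance
isfc_all <- isfc_matrix(seg)
seeds <- grep("^hippocampal_formation_", dimnames(isfc_all)[[2]], value = TRUE)
prof <- isfc_profile(isfc_all, seeds)
isfc_perf <- correlate_with_performance(prof, perf, prep$mean_fd)
sw <- seedwise_summary(isfc_all, perf, prep$mean_fd)

dir.create("results", showWarnings = FALSE)
write_tsv(isfc_perf[order(-isfc_perf$r), ], "results/isfc_performance.tsv")
write_tsv(sw, "results/seedwise_summary.tsv")

cat(sprintf("Hippocampal-seed profile: %d targets per participant\n",
            ncol(prof)))
top <- isfc_perf[order(-isfc_perf$r), ][1, ]
cat(sprintf("Strongest connectivity-performance coupling: %s (r = %.3f, p = %.2g)\n",
            top$region, top$r, top$p))
cat(sprintf("Seed ranked first by mean r with performance: %s (mean r = %.3f)\n",
            sw$seed[1], sw$mean_r[1]))
cat("Wrote results/isfc_performance.tsv, results/seedwise_summary.tsv\n")
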