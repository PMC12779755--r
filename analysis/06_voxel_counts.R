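#!/usr/bin/env Rscript
## Stage 6 — suprathreshold voxel counts and the zero-inflated count model.
##
## Subject MVPA maps are thresholded at 10 points above chance and counted
## inside ROIs; feature differences in counts are then modelled with a
## zero-inflated Poisson mixed model (feature fixed effect, subject random
## intercept), with Tukey-adjusted pairwise contrasts. A seeded recovery
## study checks that known feature offsets are estimated faithfully.

library(kinedecode)

st <- readRDS("scratch/analysis/datasets.rds")
maps <- readRDS("scratch/analysis/accuracy_maps.rds")
spec <- st$spec
aff <- grid_affine(spec)
rois <- data.frame(label = c("effect region", "adjacent region"),
                   x = c(0, 6), y = c(0, 6), z = c(0, -6), radius_mm = 5)

rows <- list()
for (nm in names(maps)) {
  for (s in seq_along(maps[[nm]])) {
    bm <- threshold_mvpa_subject(maps[[nm]][[s]], margin = 10)
    ct <- count_in_rois(bm, rois, aff, spec$grid_dims)
    ct$subject <- s; ct$dataset <- nm
    rows[[length(rows) + 1L]] <- ct
  }
}
counts <- do.call(rbind, rows)
write.csv(counts, "results/voxel_counts.csv", row.names = FALSE)
agg <- aggregate(count ~ dataset + roi, counts, function(x)
  sprintf("%.1f +/- %.1f", mean(x), sd(x)))
print(agg, row.names = FALSE)

## count-model recovery at the study scale (20 subjects, offsets -0.7/-1.4)
message("zero-inflated Poisson recovery study (100 seeds) ...")
zip <- zip_recovery_experiment(n_seeds = 100, seed = 20260926)
zt <- data.frame(parameter = c("direction - amplitude", "velocity - amplitude"),
                 true = zip$true_offsets,
                 mean_estimate = round(zip$mean_estimates, 3))
write.csv(zt, "results/zip_recovery.csv", row.names = FALSE)
print(zt, row.names = FALSE)
message(sprintf("max |bias| = %.3f across %d converged fits", zip$max_abs_error,
                zip$n_fit))

## qualitative ordering: amplitude > direction > velocity in fitted means
ok <- vapply(1:20, function(s) {
  d <- simulate_zip_counts(20, c(amplitude = log(20), direction = log(10),
                                 velocity = log(4)), zi_prob = 0.2,
                           subject_sd = 0.5, seed = 300 + s)
  f <- fit_zip_mixed(d)
  co <- f$coefficients
  co[2] < 0 && co[3] < co[2]
}, logical(1))
message(sprintf("fitted amplitude > direction > velocity ordering in %d/20 seeds",
                sum(ok)))
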