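#!/usr/bin/env Rscript
## Stage 4 — ROI decoding, bootstrap confusion-cell inference, univariate
## ROI ANOVA and leave-one-subject-out stability.
##
## The literature ROI set (S1, SMA, bilateral S2, thalamus, cerebellum) is
## defined in MNI mm; on this desk-scale grid centred at the origin only a
## central synthetic ROI falls inside the volume, so the ROI machinery is
## demonstrated with a 5-mm sphere at the effect-region centre, plus the
## Table-style fixture written as a config for full-scale grids.

library(kinedecode)

st <- readRDS("scratch/analysis/datasets.rds")
stacks <- readRDS("scratch/analysis/beta_stacks.rds")
spec <- st$spec
aff <- grid_affine(spec)

write_roi_config(roi_table(5), "results/roi_table.tsv")
vox <- roi_voxels(c(0, 0, 0), aff, spec$grid_dims, radius_mm = 5)
message("central 5-mm ROI: ", length(vox), " voxels")

rows <- list(); boots <- list()
for (nm in names(stacks)) {
  cvs <- lapply(stacks[[nm]], function(s) {
    sub <- stack_subset(s, vox)
    loro_cv_accuracy(sub$samples, feature_labels(sub, "amplitude"), sub$run)
  })
  confs <- array(0, c(length(cvs), 2, 2))
  for (i in seq_along(cvs)) confs[i, , ] <- cvs[[i]]$confusion
  bs <- bootstrap_cell_significance(confs, n_boot = 1e5, seed = 20260923)
  boots[[nm]] <- bs
  rows[[nm]] <- data.frame(
    dataset = nm,
    mean_accuracy = round(mean(vapply(cvs, `[[`, 1, "accuracy")), 1),
    chance = 50, any_cell_significant = bs$any_significant)
}
roi_mvpa <- do.call(rbind, rows)
write.csv(roi_mvpa, "results/roi_mvpa.csv", row.names = FALSE)
print(roi_mvpa, row.names = FALSE)

## univariate ROI ANOVA: mean beta per amplitude level per subject
anova_rows <- lapply(names(stacks), function(nm) {
  b <- t(vapply(stacks[[nm]], function(s) {
    sub <- stack_subset(s, vox)
    amp <- feature_labels(sub, "amplitude")
    c(A10 = mean(sub$samples[amp == "A10", ]),
      A40 = mean(sub$samples[amp == "A40", ]))
  }, numeric(2)))
  r <- roi_univariate_anova(b)
  data.frame(dataset = nm, F = round(r$F, 2), p = signif(r$p, 3),
             extreme_pair_p_sidak = signif(r$pairwise$p_adj[1], 3))
})
roi_uni <- do.call(rbind, anova_rows)
write.csv(roi_uni, "results/roi_univariate.csv", row.names = FALSE)
print(roi_uni, row.names = FALSE)

## stability across subjects (subject-unique patterns should not transfer)
loso <- lapply(names(stacks), function(nm) {
  subs <- lapply(stacks[[nm]], stack_subset, voxels = vox)
  r <- loso_stability(subs, "amplitude")
  data.frame(dataset = nm, loso_accuracy = round(r$accuracy, 1),
             stable = r$stable)
})
loso <- do.call(rbind, loso)
write.csv(loso, "results/loso_stability.csv", row.names = FALSE)
print(loso, row.names = FALSE)
message("Pattern decoding is strong within subjects but does not transfer ",
        "across them (unique pattern orientations); the uniform gain ",
        "transfers, mirroring the amplitude-stability contrast.")
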