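#' Threshold a subject accuracy map at a fixed margin above chance
#'
#' A voxel is flagged iff its accuracy-minus-chance value is at least
#' `margin` percentage points (inclusive `>=`, so a map sitting exactly at
#' the margin is entirely flagged).
#'
#' @param acc_map an `accuracy_map` or a 3-D array in accuracy-minus-chance
#'   percent units.
#' @param margin percentage points above chance (default 10).
#' @return Logical 3-D array (`NA` treated as not flagged).
#' @export
threshold_mvpa_subject <- function(acc_map, margin = 10) {
  v <- if (inherits(acc_map, "accuracy_map")) acc_map$values else acc_map
  out <- !is.na(v) & v >= margin
  out
}

#' Subject-level univariate thresholding with cluster-extent FDR
#'
#' The subject's run-wise condition betas provide the replicate structure:
#' per voxel, a one-way ANOVA across condition levels (runs as replicates)
#' gives an F map; voxels at uncorrected `p < cluster_forming_p` form
#' 26-connectivity clusters; each cluster's extent receives a p-value from a
#' permutation null (level labels permuted within run, distribution of the
#' maximum cluster extent); Benjamini-Hochberg across clusters at
#' `cluster_fdr` keeps the surviving clusters, which are binarised.
#'
#' @param stack a [beta_stack()] for the subject (smoothed betas upstream
#'   for the univariate route).
#' @param feature decoding feature whose levels are compared.
#' @param cluster_forming_p voxelwise uncorrected threshold (default 0.001).
#' @param cluster_fdr cluster-level FDR (default 0.05; 0 empties the map).
#' @param n_perm label permutations (default 200).
#' @param seed integer seed.
#' @return A list of class `uni_threshold`: `binary` (logical 3-D array),
#'   `F`, `p_voxel` (3-D arrays), `clusters` (extent + p + q per cluster).
#' @export
threshold_univariate_subject <- function(stack, feature = "amplitude",
                                         cluster_forming_p = 0.001,
                                         cluster_fdr = 0.05,
                                         n_perm = 200, seed = 1L) {
  labels <- feature_labels(stack, feature)
  runs <- stack$run
  k <- length(unique(labels))
  n_distinct <- factorial(k)^length(unique(runs))
  if (n_distinct < 10)
    stop("fewer than 10 distinct label permutations (", n_distinct,
         "); simulate more runs or levels")
  dims <- stack$grid_dims
  fmap_of <- function(lab) {
    anova_f_rows(stack$samples, lab)
  }
  obs <- fmap_of(labels)
  pvox <- stats::pf(obs$F, obs$df1, obs$df2, lower.tail = FALSE)
  Fcrit <- stats::qf(cluster_forming_p, obs$df1, obs$df2, lower.tail = FALSE)

  to_vol <- function(vals, fill = 0) {
    a <- array(fill, dims); a[stack$voxel_index] <- vals; a
  }
  supra <- to_vol(obs$F > Fcrit, FALSE)
  lab3 <- label_components(supra)
  n_cl <- max(lab3)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed_chain(seed, 909L))
  clusters <- data.frame(cluster = integer(0), extent = integer(0),
                         p = numeric(0), q = numeric(0))
  binary <- array(FALSE, dims)
  if (n_cl > 0 && cluster_fdr > 0) {
    ext <- tabulate(lab3[lab3 > 0], nbins = n_cl)
    null_max <- replicate(n_perm, {
      pl <- labels
      for (r in unique(runs)) {
        i <- which(runs == r)
        pl[i] <- labels[i][sample.int(length(i))]
      }
      pf <- fmap_of(pl)
      ps <- to_vol(pf$F > Fcrit, FALSE)
      pl3 <- label_components(ps)
      if (max(pl3) > 0) max(tabulate(pl3[pl3 > 0])) else 0L
    })
    pcl <- vapply(ext, function(e) (1 + sum(null_max >= e)) / (n_perm + 1),
                  numeric(1))
    qcl <- stats::p.adjust(pcl, method = "BH")
    clusters <- data.frame(cluster = seq_len(n_cl), extent = ext,
                           p = pcl, q = qcl)
    for (cl in which(qcl <= cluster_fdr)) binary[lab3 == cl] <- TRUE
  }
  structure(list(binary = binary, F = to_vol(obs$F, NA_real_),
                 p_voxel = to_vol(pvox, NA_real_), clusters = clusters),
            class = "uni_threshold")
}

# Vectorised one-way ANOVA across rows grouped by lab (balanced or not):
# samples is n x v, one F per column (voxel).
anova_f_rows <- function(samples, lab) {
  lab <- factor(lab)
  k <- nlevels(lab); n <- nrow(samples)
  G <- stats::model.matrix(~ 0 + lab)
  ns <- colSums(G)
  gm <- (t(G) %*% samples) / ns
  grand <- colMeans(samples)
  ssb <- colSums(ns * sweep(gm, 2, grand)^2)
  ssw <- colSums(samples^2) - colSums(ns * gm^2)
  df1 <- k - 1; df2 <- n - k
  list(F = (ssb / df1) / (ssw / df2), df1 = df1, df2 = df2)
}

#' Count suprathreshold voxels within ROIs
#'
#' @param binary logical 3-D map.
#' @param rois data.frame of ROI definitions ([roi_table()] columns).
#' @param affine,grid_dims grid geometry.
#' @param mask optional logical array restricting the ROIs.
#' @return data.frame with `roi` and integer `count` (counts are bounded by
#'   ROI size and invariant to voxel enumeration order).
#' @export
count_in_rois <- function(binary, rois, affine, grid_dims, mask = NULL) {
  counts <- vapply(seq_len(nrow(rois)), function(i) {
    vox <- roi_voxels(rois[i, ], affine, grid_dims, mask)
    sum(binary[vox])
  }, integer(1))
  data.frame(roi = rois$label, count = counts, stringsAsFactors = FALSE)
}

#' Simulate a zero-inflated Poisson count table
#'
#' One count per subject x feature: a structural zero with probability
#' `zi_prob`, otherwise Poisson with log mean
#' `log_mean[feature] + subject_intercept`, subject intercepts normal with
#' SD `subject_sd`. Used for parameter-recovery checks of [fit_zip_mixed()].
#'
#' @param n_subjects number of subjects.
#' @param log_means named numeric log means per feature.
#' @param zi_prob structural-zero probability.
#' @param subject_sd random-intercept SD.
#' @param seed integer seed.
#' @return data.frame `subject`, `feature`, `count`.
#' @export
simulate_zip_counts <- function(n_subjects, log_means, zi_prob = 0.2,
                                subject_sd = 0.5, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed_chain(seed, 1010L))
  feats <- names(log_means)
  b <- stats::rnorm(n_subjects, 0, subject_sd)
  df <- expand.grid(subject = seq_len(n_subjects), feature = feats,
                    stringsAsFactors = FALSE)
  mu <- exp(log_means[df$feature] + b[df$subject])
  y <- stats::rpois(nrow(df), mu)
  y[stats::runif(nrow(df)) < zi_prob] <- 0L
  data.frame(subject = factor(df$subject), feature = factor(df$feature, levels = feats),
             count = y)
}

#' Zero-inflated Poisson mixed model for ROI voxel counts
#'
#' Fits `count ~ feature + (1 | subject)` with a constant zero-inflation
#' term (`glmmTMB`, ZIP family by default, negative binomial as an option).
#' The omnibus feature effect is a likelihood-ratio test against the
#' feature-free model, with Bonferroni adjustment over the analysis family
#' (7 ROIs x 2 analysis types = 14 tests at study scale); pairwise feature
#' contrasts are estimated marginal means with Tukey-adjusted p-values.
#'
#' @param counts data.frame with `subject`, `feature`, `count` (e.g. rows of
#'   [count_in_rois()] bound over subjects/features).
#' @param family `"poisson"` or `"nbinom2"`.
#' @param n_family_tests size of the Bonferroni family for the omnibus
#'   (default 14).
#' @return A list of class `zip_fit`: `model`, `coefficients` (conditional
#'   fixed effects), `zi_logit`, `subject_sd`, `omnibus` (`chisq`, `df`,
#'   `p`, `p_bonferroni`), `pairwise` (emmeans contrast data.frame),
#'   `converged`.
#' @export
fit_zip_mixed <- function(counts, family = c("poisson", "nbinom2"),
                          n_family_tests = 14) {
  family <- match.arg(family)
  counts$feature <- factor(counts$feature)
  counts$subject <- factor(counts$subject)
  if (nlevels(counts$feature) < 2)
    stop("need at least 2 features with variation to compare")
  fam <- if (family == "poisson") stats::poisson() else glmmTMB::nbinom2()
  fit <- glmmTMB::glmmTMB(count ~ feature + (1 | subject), data = counts,
                          ziformula = ~1, family = fam)
  if (!is.null(fit$fit$convergence) && fit$fit$convergence != 0)
    stop("zero-inflated model did not converge; gradient norm ",
         format(max(abs(fit$fit$gradient))))
  fit0 <- glmmTMB::glmmTMB(count ~ 1 + (1 | subject), data = counts,
                           ziformula = ~1, family = fam)
  lrt <- stats::anova(fit0, fit)
  chisq <- lrt$Chisq[2]; dfd <- lrt[["Chi Df"]][2]; pom <- lrt[["Pr(>Chisq)"]][2]
  em <- emmeans::emmeans(fit, ~feature)
  pw <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "tukey"))
  co <- glmmTMB::fixef(fit)
  structure(list(model = fit,
                 coefficients = co$cond,
                 zi_logit = unname(co$zi[1]),
                 subject_sd = sqrt(unlist(glmmTMB::VarCorr(fit)$cond)[1]),
                 omnibus = list(chisq = chisq, df = dfd, p = pom,
                                p_bonferroni = min(1, pom * n_family_tests)),
                 pairwise = pw,
                 converged = TRUE),
            class = "zip_fit")
}
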