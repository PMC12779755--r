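#' Literature-based regions of interest for passive finger movement
#'
#' Six spherical ROI centres (MNI mm) over the passive-movement network:
#' contralateral primary somatosensory cortex (L S1), supplementary motor
#' area (SMA), bilateral secondary somatosensory cortex (L/R S2), the
#' contralateral thalamus (ventral posterolateral nucleus) and the
#' ipsilateral cerebellum (lobule VI).
#'
#' @param radius_mm sphere radius (5 mm default; 8 mm variant supported).
#' @return A data.frame with columns `label`, `x`, `y`, `z`, `radius_mm`.
#' @export
roi_table <- function(radius_mm = 5) {
  data.frame(
    label = c("L S1", "SMA", "L S2", "R S2", "L Thalamus", "R Cerebellum"),
    x = c(-41, -8, -54, 54, -17, 25),
    y = c(-28, -14, -25, -27, -20, -49),
    z = c(61, 62, 20, 27, 8, -26),
    radius_mm = radius_mm,
    stringsAsFactors = FALSE
  )
}

#' Write / read ROI definitions as a plain-text config
#'
#' Tab-separated `label, x, y, z, radius_mm`; coordinates round-trip
#' unchanged.
#'
#' @param rois data.frame as returned by [roi_table()].
#' @param path file path.
#' @export
write_roi_config <- function(rois, path) {
  utils::write.table(rois, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_config
#' @export
read_roi_config <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' In-mask voxels of a spherical ROI
#'
#' @param roi one-row data.frame (`x`, `y`, `z`, `radius_mm`) or a numeric
#'   centre `c(x, y, z)` with `radius_mm` given separately.
#' @param affine grid affine ([grid_affine()]).
#' @param grid_dims 3-vector of grid dimensions.
#' @param mask optional logical array; default all voxels.
#' @param radius_mm radius when `roi` is a bare centre vector.
#' @return Integer vector of linear voxel indices; error if empty.
#' @export
roi_voxels <- function(roi, affine, grid_dims, mask = NULL, radius_mm = NULL) {
  if (is.data.frame(roi)) {
    centre <- as.numeric(roi[1, c("x", "y", "z")])
    radius_mm <- roi$radius_mm[1]
  } else centre <- as.numeric(roi)
  stopifnot(length(centre) == 3, !is.null(radius_mm))
  nv <- prod(grid_dims)
  ijk <- arrayInd(seq_len(nv), grid_dims)
  mm <- vox_to_mm(ijk, affine)
  d2 <- (mm[, 1] - centre[1])^2 + (mm[, 2] - centre[2])^2 + (mm[, 3] - centre[3])^2
  keep <- d2 <= radius_mm^2
  if (!is.null(mask)) keep <- keep & as.vector(mask)
  idx <- which(keep)
  if (!length(idx))
    stop("ROI at (", paste(centre, collapse = ", "), ") mm, radius ",
         radius_mm, " mm contains no in-mask voxel")
  idx
}

#' Bootstrap significance of confusion-matrix cells across subjects
#'
#' Per cell, subjects are resampled with replacement `n_boot` times and the
#' resampled group means form a percentile confidence interval at level
#' `1 - alpha / n_cells` (the per-cell alpha divides the nominal level by
#' the number of matrix elements: 4 for two classes, 9 for three). A cell is
#' significant iff the chance level falls outside its interval; the matrix
#' is flagged significant iff at least one cell is.
#'
#' @param confusions 3-D array `n_subjects x k x k` of per-subject confusion
#'   matrices in percent (rows sum to 100).
#' @param n_boot bootstrap resamples (the study-scale default is 1e5).
#' @param alpha nominal significance level before the cell adjustment.
#' @param chance chance level in percent; default `100 / k`.
#' @param seed integer seed (results are bit-reproducible given the seed).
#' @return A list of class `confusion_summary`: `mean` (group mean matrix),
#'   `ci_lo`, `ci_hi`, `significant` (logical k x k), `any_significant`,
#'   `ci_level`.
#' @export
bootstrap_cell_significance <- function(confusions, n_boot = 1e5, alpha = 0.05,
                                        chance = NULL, seed = 1L) {
  stopifnot(length(dim(confusions)) == 3)
  n <- dim(confusions)[1]; k <- dim(confusions)[2]
  if (n < 2) stop("need at least 2 subjects to bootstrap")
  if (is.null(chance)) chance <- 100 / k
  n_cells <- k * k
  lev <- 1 - alpha / n_cells
  X <- matrix(confusions, nrow = n)  # subjects x cells (column-major cells)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed_chain(seed, 707L))
  qlo <- (1 - lev) / 2; qhi <- 1 - qlo
  chunk <- 10000L
  boots <- matrix(NA_real_, n_boot, n_cells)
  done <- 0L
  while (done < n_boot) {
    b <- min(chunk, n_boot - done)
    idx <- matrix(sample.int(n, b * n, replace = TRUE), b, n)
    for (j in seq_len(n_cells)) {
      xj <- X[, j]
      boots[done + seq_len(b), j] <- rowMeans(matrix(xj[idx], b, n))
    }
    done <- done + b
  }
  lo <- apply(boots, 2, stats::quantile, probs = qlo, names = FALSE)
  hi <- apply(boots, 2, stats::quantile, probs = qhi, names = FALSE)
  sig <- chance < lo | chance > hi
  dn <- dimnames(confusions)[2:3]
  structure(list(mean = matrix(colMeans(X), k, k, dimnames = dn),
                 ci_lo = matrix(lo, k, k, dimnames = dn),
                 ci_hi = matrix(hi, k, k, dimnames = dn),
                 significant = matrix(sig, k, k, dimnames = dn),
                 any_significant = any(sig), ci_level = lev, chance = chance),
            class = "confusion_summary")
}

#' Sidak multiplicity adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for `m` tests; always `>= p`, with equality iff
#' `m = 1`.
#'
#' @param p raw p-value(s).
#' @param m number of tests.
#' @return Adjusted p-value(s), capped at 1.
#' @export
sidak_adjust <- function(p, m) pmin(1, 1 - (1 - p)^m)

#' Repeated-measures one-way ANOVA on ROI activation estimates
#'
#' Betas averaged over ROI voxels (and over runs and the non-target factors)
#' give one value per subject and condition level. The omnibus test is a
#' subject-blocked ANOVA (subject as a random block, the within-subject
#' design); pairwise level differences are paired t-tests with Sidak
#' adjustment over the `k (k - 1) / 2` comparisons.
#'
#' @param betas numeric matrix `n_subjects x k_levels`, columns named by
#'   level.
#' @return A list of class `roi_anova`: `F`, `p` (omnibus), `df1`, `df2`,
#'   `pairwise` (data.frame: `level1`, `level2`, `estimate`, `t`, `p`,
#'   `p_adj`), `means`.
#' @export
roi_univariate_anova <- function(betas) {
  betas <- as.matrix(betas)
  n <- nrow(betas); k <- ncol(betas)
  if (n < 3) stop("need at least 3 subjects for the repeated-measures ANOVA")
  if (k < 2) stop("need at least 2 condition levels")
  if (is.null(colnames(betas))) colnames(betas) <- paste0("L", seq_len(k))
  df <- data.frame(y = as.vector(betas),
                   level = factor(rep(colnames(betas), each = n),
                                  levels = colnames(betas)),
                   subject = factor(rep(seq_len(n), k)))
  a <- stats::aov(y ~ level + subject, data = df)
  s <- summary(a)[[1]]
  Fv <- s["level", "F value"]; pv <- s["level", "Pr(>F)"]
  m <- k * (k - 1) / 2
  pairs <- utils::combn(colnames(betas), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    l1 <- pairs[1, j]; l2 <- pairs[2, j]
    tt <- stats::t.test(betas[, l1], betas[, l2], paired = TRUE)
    data.frame(level1 = l1, level2 = l2,
               estimate = unname(tt$estimate), t = unname(tt$statistic),
               p = tt$p.value, p_adj = sidak_adjust(tt$p.value, m),
               stringsAsFactors = FALSE)
  }))
  structure(list(F = Fv, p = pv, df1 = s["level", "Df"],
                 df2 = s["Residuals", "Df"], pairwise = pw,
                 means = colMeans(betas)),
            class = "roi_anova")
}

#' Leave-one-subject-out decoding stability
#'
#' Trains the linear SVM on the run-wise condition betas of all subjects but
#' one and tests on the held-out subject, one fold per subject. Returns the
#' mean confusion matrix across folds; no statistical test is attached --
#' the analysis is summarised by a stability flag, true iff the smallest
#' diagonal cell exceeds the largest off-diagonal cell.
#'
#' @param stacks list of per-subject [beta_stack()]s restricted to a common
#'   ROI (identical voxel sets).
#' @param feature decoding target, see [feature_labels()].
#' @param config a [classifier_config()].
#' @return A list of class `loso_result`: `confusion` (%), `accuracy`,
#'   `stable`, `n_subjects`.
#' @export
loso_stability <- function(stacks, feature = "amplitude",
                           config = classifier_config()) {
  ns <- length(stacks)
  if (ns < 3) stop("need at least 3 subjects for leave-one-subject-out")
  X <- do.call(rbind, lapply(stacks, `[[`, "samples"))
  labels <- unlist(lapply(stacks, feature_labels, feature = feature))
  subj <- rep(seq_len(ns), vapply(stacks, function(s) nrow(s$samples), 1L))
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("only one condition level present; stability needs >= 2")
  conf <- matrix(0, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  accs <- numeric(ns)
  for (s in seq_len(ns)) {
    te <- subj == s
    fit <- e1071::svm(x = X[!te, , drop = FALSE],
                      y = factor(labels[!te], levels = classes),
                      kernel = "linear", cost = config$C, scale = FALSE)
    pred <- as.character(stats::predict(fit, X[te, , drop = FALSE]))
    truth <- labels[te]
    accs[s] <- 100 * mean(pred == truth)
    cf <- matrix(0, length(classes), length(classes),
                 dimnames = dimnames(conf))
    for (i in seq_along(pred)) cf[truth[i], pred[i]] <- cf[truth[i], pred[i]] + 1
    conf <- conf + 100 * cf / rowSums(cf)
  }
  conf <- conf / ns
  stable <- min(diag(conf)) > max(conf[row(conf) != col(conf)])
  structure(list(confusion = conf, accuracy = mean(accs), stable = stable,
                 n_subjects = ns),
            class = "loso_result")
}

#' Restrict a beta stack to a voxel subset
#'
#' @param stack a [beta_stack()].
#' @param voxels linear grid indices (e.g. from [roi_voxels()]).
#' @return A `beta_stack` over the intersection of `voxels` with the stack's
#'   voxels.
#' @export
stack_subset <- function(stack, voxels) {
  cols <- match(intersect(voxels, stack$voxel_index), stack$voxel_index)
  if (!length(cols)) stop("no stack voxels inside the requested subset")
  out <- stack
  out$samples <- stack$samples[, cols, drop = FALSE]
  out$voxel_index <- stack$voxel_index[cols]
  out
}
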