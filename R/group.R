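#' Separable Gaussian smoothing of a 3-D map
#'
#' Separable 1-D Gaussian kernels along each axis with
#' `sigma = fwhm_mm / (sqrt(8 log 2) * voxel_mm)` voxels, truncated at
#' 3 sigma and normalised to unit sum (values beyond the array are treated
#' as zero -- zero padding). `fwhm_mm = 0` is the identity. `NA` voxels
#' (outside a mask) are treated as zero and restored to `NA` afterwards.
#'
#' @param map 3-D numeric array.
#' @param fwhm_mm full width at half maximum in millimetres (default 6).
#' @param voxel_mm isotropic voxel edge (default 3).
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_smooth <- function(map, fwhm_mm = 6, voxel_mm = 3) {
  stopifnot(fwhm_mm >= 0, voxel_mm > 0)
  if (fwhm_mm == 0) return(map)
  dims <- dim(map)
  stopifnot(length(dims) == 3)
  na <- is.na(map)
  map[na] <- 0
  sigma <- fwhm_mm / (sqrt(8 * log(2)) * voxel_mm)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    n <- dims[axis]
    K <- matrix(0, n, n)
    for (o in -r:r) {
      i <- seq_len(n); j <- i + o
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- K[cbind(i[ok], j[ok])] + k[o + r + 1]
    }
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- K %*% matrix(ap, nrow = n)
    aperm(array(m, dims[perm]), order(perm))
  }
  out <- smooth_axis(smooth_axis(smooth_axis(map, 1), 2), 3)
  out[na] <- NA_real_
  out
}

#' Voxelwise one-sample t-map across subjects
#'
#' `t = mean / (sd / sqrt(n))` against zero with `n - 1` degrees of freedom.
#' Voxels with zero across-subject variance get a `+/-Inf` sentinel and are
#' flagged.
#'
#' @param subject_maps numeric matrix `n_subjects x n_voxels` (or a list of
#'   3-D arrays, flattened).
#' @param alternative `"greater"` (accuracy above chance) or `"two.sided"`.
#' @return A list of class `group_stat_map`: `stat`, `p`, `df`, `degenerate`
#'   (logical), `n`.
#' @export
one_sample_t_map <- function(subject_maps, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  M <- maps_to_matrix(subject_maps)
  n <- nrow(M)
  if (n < 3) stop("need at least 3 subjects")
  mu <- colMeans(M)
  sd <- sqrt(colSums(sweep(M, 2, mu)^2) / (n - 1))
  degenerate <- sd == 0
  tv <- mu / (sd / sqrt(n))
  tv[degenerate] <- sign(mu[degenerate]) * Inf
  p <- if (alternative == "greater") stats::pt(tv, n - 1, lower.tail = FALSE)
       else 2 * stats::pt(abs(tv), n - 1, lower.tail = FALSE)
  structure(list(stat = tv, p = p, df = n - 1, degenerate = degenerate, n = n),
            class = "group_stat_map")
}

maps_to_matrix <- function(x) {
  if (is.list(x)) x <- do.call(rbind, lapply(x, as.vector))
  as.matrix(x)
}

#' Voxelwise Welch (unequal-variance) one-way ANOVA map
#'
#' Welch's F with Welch-Satterthwaite denominator degrees of freedom,
#' computed per voxel across groups of subject maps. For two groups, Welch F
#' equals the squared Welch t.
#'
#' @param group_maps list (one element per level) of matrices
#'   `n_subjects x n_voxels`.
#' @return A list of class `group_stat_map`: `stat` (F), `p`, `df1`, `df2`
#'   (vector), `degenerate`, `n`.
#' @export
welch_anova_map <- function(group_maps) {
  stopifnot(length(group_maps) >= 2)
  Ms <- lapply(group_maps, maps_to_matrix)
  ns <- vapply(Ms, nrow, 1L)
  if (any(ns < 3)) stop("need at least 3 subjects per level")
  k <- length(Ms)
  means <- vapply(Ms, colMeans, numeric(ncol(Ms[[1]])))
  vars <- vapply(seq_len(k), function(i)
    colSums(sweep(Ms[[i]], 2, means[, i])^2) / (ns[i] - 1),
    numeric(ncol(Ms[[1]])))
  w <- sweep(1 / vars, 2, ns, "*")           # n_i / s_i^2, voxels x k
  sw <- rowSums(w)
  mw <- rowSums(w * means) / sw
  A <- rowSums(w * (means - mw)^2) / (k - 1)
  lam <- sweep(w, 1, sw, "/")
  B <- 1 + 2 * (k - 2) / (k^2 - 1) *
    rowSums(sweep((1 - lam)^2, 2, ns - 1, "/"))
  Fv <- A / B
  df2 <- (k^2 - 1) / (3 * rowSums(sweep((1 - lam)^2, 2, ns - 1, "/")))
  degenerate <- !is.finite(Fv)
  p <- stats::pf(Fv, k - 1, df2, lower.tail = FALSE)
  structure(list(stat = Fv, p = p, df1 = k - 1, df2 = df2,
                 degenerate = degenerate, n = sum(ns)),
            class = "group_stat_map")
}

#' Max-statistic permutation family-wise-error correction
#'
#' Exact FWE control under exchangeability: for a one-sample test the
#' subject maps are sign-flipped; for the ANOVA the level labels are
#' permuted within subject. Each permutation records the volume-maximum
#' statistic and `p_fwe(v)` is the proportion of permutation maxima (the
#' observed statistic included) at or above `stat(v)`. Permutation p-values
#' are invariant to monotone transforms of the statistic.
#'
#' @param subject_maps matrix `n_subjects x n_voxels` (one-sample) or a list
#'   of such matrices by level (ANOVA), subjects row-aligned across levels.
#' @param type `"one_sample"` or `"anova"`.
#' @param alpha FWE threshold recorded in the output (0.05 default; 5e-5 is
#'   the strict preset).
#' @param n_perm number of permutations (>= 100, or a warning-level failure).
#' @param seed integer seed.
#' @return A list of class `fwe_result`: `stat`, `p_fwe`, `threshold_mask`
#'   (stat with `p_fwe < alpha`), `alpha`, `n_perm`, `max_dist`.
#' @export
fwe_threshold <- function(subject_maps, type = c("one_sample", "anova"),
                          alpha = 0.05, n_perm = 1000, seed = 1L) {
  type <- match.arg(type)
  if (n_perm < 100) stop("n_perm < 100 gives unusable FWE resolution")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed_chain(seed, 808L))
  if (type == "one_sample") {
    M <- maps_to_matrix(subject_maps)
    n <- nrow(M)
    obs <- one_sample_t_map(M)$stat
    maxes <- replicate(n_perm, {
      s <- sample(c(-1, 1), n, replace = TRUE)
      max(one_sample_t_map(M * s)$stat, na.rm = TRUE)
    })
  } else {
    Ms <- lapply(subject_maps, maps_to_matrix)
    k <- length(Ms); n <- nrow(Ms[[1]])
    obs <- welch_anova_map(Ms)$stat
    big <- array(unlist(Ms), dim = c(n, ncol(Ms[[1]]), k))
    maxes <- replicate(n_perm, {
      perm <- big
      for (s in seq_len(n)) perm[s, , ] <- big[s, , sample.int(k)]
      max(welch_anova_map(lapply(seq_len(k), function(i)
        perm[, , i, drop = FALSE][, , 1]))$stat, na.rm = TRUE)
    })
  }
  p_fwe <- vapply(obs, function(x)
    (1 + sum(maxes >= x)) / (n_perm + 1), numeric(1))
  p_fwe[!is.finite(obs)] <- ifelse(obs[!is.finite(obs)] > 0, 1 / (n_perm + 1), 1)
  structure(list(stat = obs, p_fwe = p_fwe,
                 threshold_mask = p_fwe < alpha, alpha = alpha,
                 n_perm = n_perm, max_dist = maxes,
                 method = "max-statistic permutation (not random-field theory)"),
            class = "fwe_result")
}

# 26-connectivity connected components of a logical 3-D array.
label_components <- function(mask3d) {
  dims <- dim(mask3d)
  lab <- array(0L, dims)
  idx <- which(mask3d)
  if (!length(idx)) return(lab)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  cur <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start; lab[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      ijk <- arrayInd(v, dims)
      nb <- sweep(off, 2, as.integer(ijk), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      lin <- (nb[ok, 3] - 1L) * dims[1] * dims[2] +
             (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
      new <- lin[mask3d[lin] & lab[lin] == 0L]
      if (length(new)) { lab[new] <- cur; queue <- c(queue, new) }
    }
  }
  lab
}

#' Cluster and peak report for a thresholded map
#'
#' Suprathreshold voxels are grouped into 26-connectivity components;
#' clusters below `min_extent` voxels are dropped. Within a cluster, peaks
#' are selected greedily by descending statistic subject to a pairwise
#' separation greater than `peak_sep_mm`.
#'
#' @param mask3d logical 3-D suprathreshold map.
#' @param stat3d numeric 3-D statistic map (for peak values).
#' @param affine grid affine for mm coordinates.
#' @param min_extent minimum cluster extent in voxels (default 10).
#' @param peak_sep_mm minimum peak separation in mm (default 20).
#' @return A data.frame (class `cluster_report`): one row per peak with
#'   `cluster`, `extent`, `peak_stat`, `x`, `y`, `z`, `is_subpeak`.
#' @export
report_clusters <- function(mask3d, stat3d, affine, min_extent = 10,
                            peak_sep_mm = 20) {
  lab <- label_components(mask3d)
  out <- list()
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_extent)
    keep <- keep[order(-vapply(keep, function(cl) max(stat3d[lab == cl]), 1))]
    for (ci in seq_along(keep)) {
      cl <- keep[ci]
      vox <- which(lab == cl)
      o <- order(-stat3d[vox])
      vox <- vox[o]
      mm <- vox_to_mm(arrayInd(vox, dim(mask3d)), affine)
      sel <- integer(0)
      for (i in seq_along(vox)) {
        if (!length(sel)) { sel <- i; next }
        d <- sqrt(rowSums((mm[sel, , drop = FALSE] -
                           matrix(mm[i, ], length(sel), 3, byrow = TRUE))^2))
        if (all(d > peak_sep_mm)) sel <- c(sel, i)
      }
      out[[length(out) + 1L]] <- data.frame(
        cluster = ci, extent = length(vox),
        peak_stat = stat3d[vox[sel]],
        x = mm[sel, 1], y = mm[sel, 2], z = mm[sel, 3],
        is_subpeak = seq_along(sel) > 1)
    }
  }
  rep <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster = integer(0), extent = integer(0),
               peak_stat = numeric(0), x = numeric(0), y = numeric(0),
               z = numeric(0), is_subpeak = logical(0))
  class(rep) <- c("cluster_report", "data.frame")
  rep
}
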