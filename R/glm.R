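#' Fit a voxelwise GLM with AR(1) prewhitening
#'
#' Two-pass estimation: ordinary least squares residuals give a lag-1
#' autocorrelation estimate pooled across in-mask voxels (a single rho per
#' run, which stabilises small grids); data and design are then whitened by
#' the AR(1) transform (first observation scaled by `sqrt(1 - rho^2)`,
#' subsequent rows `y_t - rho * y_{t-1}`) and refit by OLS.
#'
#' @param bold a `bold_run`, or a numeric matrix `n_scans x n_voxels`.
#' @param design a `design_matrix` from [build_design_matrix()] (or a plain
#'   numeric matrix).
#' @param mask optional logical array over the grid (see [implicit_mask()]);
#'   default uses every voxel.
#' @param prewhiten set `FALSE` to skip the AR(1) step (plain OLS).
#' @return A list of class `glm_fit`: `betas` (p x n_voxels, rows named),
#'   `sigma2`, `ar1_rho`, `dof`, `xtx_inv` (of the whitened design), `mask`,
#'   `grid_dims`, `affine`, plus the design's column bookkeeping.
#' @export
fit_glm_ar1 <- function(bold, design, mask = NULL, prewhiten = TRUE) {
  X <- if (inherits(design, "design_matrix")) design$values else as.matrix(design)
  grid_dims <- NULL; affine <- NULL
  if (inherits(bold, "bold_run")) {
    d <- dim(bold$data)
    grid_dims <- d[1:3]; affine <- bold$affine
    Y <- t(matrix(bold$data, ncol = d[4]))
    if (!is.null(mask)) Y <- Y[, as.vector(mask), drop = FALSE]
  } else {
    Y <- as.matrix(bold)
  }
  n <- nrow(Y); p <- ncol(X)
  stopifnot(nrow(X) == n)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[setdiff(seq_len(p), qx$pivot[seq_len(qx$rank)])]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  res <- qr.resid(qx, Y)
  rho <- 0
  if (prewhiten) {
    num <- sum(res[-1, ] * res[-n, ])
    den <- sum(res^2)
    r_obs <- if (den > 0) num / den else 0
    rho <- ar1_debias(r_obs, qx, n)
    if (rho > 0) {
      Yw <- rbind(sqrt(1 - rho^2) * Y[1, ], Y[-1, ] - rho * Y[-n, , drop = FALSE])
      Xw <- rbind(sqrt(1 - rho^2) * X[1, ], X[-1, ] - rho * X[-n, , drop = FALSE])
      qx <- qr(Xw)
      Y <- Yw; X <- Xw
      res <- qr.resid(qx, Y)
    }
  }
  betas <- qr.coef(qx, Y)
  dof <- n - qx$rank
  sigma2 <- colSums(res^2) / dof
  xtx_inv <- if (all(qx$pivot == seq_len(p))) chol2inv(qr.R(qx))
             else solve(crossprod(X))
  rownames(betas) <- colnames(X)
  out <- list(betas = betas, sigma2 = sigma2, ar1_rho = rho, dof = dof,
              xtx_inv = xtx_inv, mask = mask, grid_dims = grid_dims,
              affine = affine)
  if (inherits(design, "design_matrix")) {
    out$column_names <- design$column_names
    out$task_columns <- design$task_columns
    out$modulator_columns <- design$modulator_columns
  }
  structure(out, class = "glm_fit")
}

# Bias-corrected pooled AR(1) estimate. The lag-1 autocorrelation of OLS
# residuals is biased (the hat matrix removes low-frequency noise), so the
# raw ratio r_obs = e'Le / e'e is matched against its expectation under
# AR(1) noise with coefficient rho: tr(MLMV(rho)) / tr(MV(rho)), M the
# residual-forming matrix, L the symmetrised lag-1 operator, V the AR(1)
# correlation matrix. Solved by 1-D root finding over rho.
ar1_debias <- function(r_obs, qx, n) {
  Q <- qr.Q(qx)
  M <- -tcrossprod(Q)
  diag(M) <- diag(M) + 1
  ML <- 0.5 * (cbind(M[, -1], 0) + cbind(0, M[, -n]))  # M %*% L
  MLM <- ML %*% M
  lag <- abs(outer(seq_len(n), seq_len(n), "-"))
  expected_r <- function(rho) {
    V <- rho^lag
    sum(MLM * V) / sum(M * V)
  }
  g <- function(rho) expected_r(rho) - r_obs
  lo <- -0.3; hi <- 0.97
  glo <- g(lo); ghi <- g(hi)
  rho <- if (glo * ghi <= 0)
    stats::uniroot(g, c(lo, hi), tol = 1e-4)$root
  else r_obs
  max(min(rho, 0.97), 0)
}

#' F-test of a contrast on a fitted GLM
#'
#' `F = (C b)' [C (X'X)^-1 C']^-1 (C b) / (q * sigma2)` per voxel, with
#' `(q, dof)` degrees of freedom, on the whitened system.
#'
#' @param fit a `glm_fit`.
#' @param C contrast matrix, `q` rows. Columns either span the full design
#'   (`ncol(C) == nrow(betas)`) or just the task columns, in which case the
#'   matrix is zero-padded onto the task block.
#' @return List with vectors `F`, `p`, and scalars `df1`, `df2`.
#' @export
glm_contrast_f <- function(fit, C) {
  C <- as.matrix(C)
  p <- nrow(fit$betas)
  if (ncol(C) != p) {
    stopifnot(!is.null(fit$task_columns), ncol(C) == length(fit$task_columns))
    Cfull <- matrix(0, nrow(C), p)
    Cfull[, fit$task_columns] <- C
    C <- Cfull
  }
  q <- nrow(C)
  CB <- C %*% fit$betas
  M <- C %*% fit$xtx_inv %*% t(C)
  quad <- colSums(CB * solve(M, CB))
  Fv <- quad / (q * fit$sigma2)
  list(F = Fv, p = stats::pf(Fv, q, fit$dof, lower.tail = FALSE),
       df1 = q, df2 = fit$dof)
}

#' Main-effect contrast matrices by Kronecker product
#'
#' For a factorial design with `levels = c(a, v, d)` (amplitude, velocity,
#' direction) and conditions ordered amplitude-slowest (the
#' [spec_conditions()] order), the main effect of factor i is the Kronecker
#' product with a successive-difference matrix (`(levels_i - 1) x levels_i`)
#' in position i and averaging row vectors (entries `1/levels_j`) elsewhere.
#' Every row sums to zero.
#'
#' @param levels integer vector of factor level counts (each >= 2).
#' @return Named list (`amplitude`, `velocity`, `direction` for 3 factors;
#'   `factor1...` otherwise) of contrast matrices over the
#'   `prod(levels)` conditions.
#' @examples
#' dim(kron_main_effect_contrasts(c(3, 3, 2))$amplitude)  # 2 x 18
#' @export
kron_main_effect_contrasts <- function(levels = c(3, 3, 2)) {
  stopifnot(all(levels >= 2))
  diffm <- function(k) {
    D <- matrix(0, k - 1, k)
    D[cbind(seq_len(k - 1), seq_len(k - 1))] <- 1
    D[cbind(seq_len(k - 1), seq_len(k - 1) + 1)] <- -1
    D
  }
  avgm <- function(k) matrix(1 / k, 1, k)
  nf <- length(levels)
  out <- lapply(seq_len(nf), function(i) {
    parts <- lapply(seq_len(nf), function(j)
      if (i == j) diffm(levels[j]) else avgm(levels[j]))
    Reduce(kronecker, parts)
  })
  names(out) <- if (nf == 3) c("amplitude", "velocity", "direction")
                else paste0("factor", seq_len(nf))
  out
}

#' Stack per-run condition betas into an MVPA sample matrix
#'
#' One sample (row) per run x condition: the beta map of that condition's
#' constant regressor over the in-mask voxels. This run-wise beta stack is
#' the unit of both searchlight and ROI decoding.
#'
#' @param fits list of `glm_fit`s, one per run, fitted on a common mask with
#'   identical task columns.
#' @return A list of class `beta_stack`: `samples`
#'   (`n_runs*n_conditions x n_voxels`), `trial_type`, `run`, `voxel_index`
#'   (linear indices into the grid), `grid_dims`, `affine`, `mask`.
#' @export
beta_stack <- function(fits) {
  stopifnot(length(fits) >= 1)
  f1 <- fits[[1]]
  types <- f1$column_names[f1$task_columns]
  mats <- lapply(fits, function(f) {
    stopifnot(identical(f$column_names[f$task_columns], types))
    f$betas[f$task_columns, , drop = FALSE]
  })
  samples <- do.call(rbind, mats)
  if (anyNA(samples)) stop("beta stack contains missing values")
  vox <- if (!is.null(f1$mask)) which(as.vector(f1$mask)) else
    seq_len(ncol(samples))
  structure(list(samples = samples,
                 trial_type = rep(types, times = length(fits)),
                 run = rep(seq_along(fits), each = length(types)),
                 voxel_index = vox,
                 grid_dims = f1$grid_dims, affine = f1$affine,
                 mask = f1$mask),
            class = "beta_stack")
}

#' Kinematic-feature labels of beta-stack samples
#'
#' Parses `"A{..}_V{..}_{ext|flex}"` trial types into the level of one
#' kinematic feature, the decoding target.
#'
#' @param stack a `beta_stack` (or character vector of trial types).
#' @param feature `"amplitude"`, `"velocity"` or `"direction"`.
#' @return Character vector of level labels per sample.
#' @export
feature_labels <- function(stack, feature = c("amplitude", "velocity", "direction")) {
  feature <- match.arg(feature)
  tt <- if (inherits(stack, "beta_stack")) stack$trial_type else stack
  parts <- strsplit(tt, "_", fixed = TRUE)
  i <- switch(feature, amplitude = 1L, velocity = 2L, direction = 3L)
  vapply(parts, `[[`, character(1), i)
}
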