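test_that("canonical HRF has the expected shape", {
  k <- canonical_hrf(hrf_params(), tr_s = 2)
  expect_equal(k[1], 0)
  expect_gt(sum(k), 0)
  # dense numerical evaluation: peak near 5 s for default parameters
  kd <- canonical_hrf(hrf_params(), tr_s = 2, dt = 0.01)
  expect_equal((which.max(kd) - 1) * 0.01, 5.0, tolerance = 0.05)
  # doubling the peak:undershoot ratio halves the undershoot depth
  und <- function(ratio) {
    kk <- canonical_hrf(hrf_params(peak_to_undershoot_ratio = ratio), 2, dt = 0.01)
    kk <- kk / max(kk)
    min(kk)
  }
  expect_equal(und(12) / und(6), 0.5, tolerance = 0.1)
})

test_that("design matrices carry the documented task+modulator column counts", {
  ev1 <- sample_events(experiment_spec("exp1"), 1, seed = 1)
  ev2 <- sample_events(experiment_spec("exp2"), 1, seed = 1)
  n_task_mod <- function(X) length(c(X$task_columns, X$modulator_columns))
  X1f <- build_design_matrix(ev1, 400, 2, model = "full_interaction")
  X2f <- build_design_matrix(ev2, 306, 2, model = "full_interaction")
  X1n <- build_design_matrix(ev1, 400, 2, model = "non_interaction")
  X2n <- build_design_matrix(ev2, 306, 2, model = "non_interaction")
  expect_equal(n_task_mod(X1f), 36)
  expect_equal(n_task_mod(X2f), 16)
  expect_equal(n_task_mod(X1n), 19)
  expect_equal(n_task_mod(X2n), 9)
  expect_length(X1f$task_columns, 18)   # base condition regressors, Exp 1
  # column-count identity for an arbitrary factorial spec
  sp <- tiny_spec()
  ev <- sample_events(sp, 1, seed = 2)
  expect_equal(n_task_mod(build_design_matrix(ev, 120, 2)), 2 * 8)
  expect_equal(n_task_mod(build_design_matrix(ev, 120, 2, model = "non_interaction")),
               8 + 1)
  # variable-epoch carries duration in the boxcars: no modulators
  Xv <- build_design_matrix(ev, 120, 2, epoch_mode = "variable_epoch")
  expect_length(Xv$modulator_columns, 0)
  expect_true(all(is.finite(X1f$values)))
  expect_false(anyDuplicated(X1f$column_names) > 0)
})

test_that("equal trial durations give identically zero modulators", {
  sp <- tiny_spec()
  sp$duration_jitter_frac <- 0
  sp$amplitude_levels <- c(A20 = 0.2, A40 = 0.4)
  sp$velocity_levels <- c(V20 = 0.2, V40 = 0.4)
  ev <- sample_events(sp, 1, seed = 1)
  ev$duration <- rep(1, nrow(ev))  # force equal durations
  X <- build_design_matrix(ev, 120, 2, model = "full_interaction")
  expect_equal(max(abs(X$values[, X$modulator_columns])), 0)
  Xn <- build_design_matrix(ev, 120, 2, model = "non_interaction")
  expect_equal(max(abs(Xn$values[, Xn$modulator_columns])), 0)
})

test_that("design construction fails loudly on bad inputs", {
  sp <- tiny_spec()
  ev <- sample_events(sp, 1, seed = 1)
  expect_error(build_design_matrix(ev, 20, 2), "beyond the run")
  ev2 <- ev[ev$trial_type != "A10_V20_ext", ]
  expect_error(build_design_matrix(ev2, 120, 2, conditions = spec_conditions(sp)),
               "empty condition cell.*A10_V20_ext")
})

test_that("DCT high-pass basis has the documented size and orthogonality", {
  B <- dct_highpass_basis(400, 2, 128)
  expect_equal(ncol(B), 13)
  expect_true(all(abs(colSums(B)) < 1e-8))            # orthogonal to constant
  expect_equal(crossprod(B), diag(13), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(ncol(dct_highpass_basis(400, 2, Inf)), 0)
  expect_error(dct_highpass_basis(100, 2, 3), "cutoff")
})

test_that("implicit mask follows the global-signal fraction rule", {
  sp <- tiny_spec(grid = c(3L, 3L, 3L))
  mk_bold <- function(arr4) structure(list(data = arr4, tr_s = 2,
                                           affine = grid_affine(sp),
                                           events = NULL), class = "bold_run")
  homog <- mk_bold(array(7, c(3, 3, 3, 5)))
  expect_true(all(implicit_mask(homog)))
  # one voxel at 5% of the global signal is excluded, the rest at 100% stay
  a <- array(1, c(3, 3, 3, 5)); a[2, 2, 2, ] <- 0.05
  m <- implicit_mask(mk_bold(a), 0.1)
  expect_false(m[2, 2, 2])
  expect_equal(sum(m), 26)
  # monotonicity in the fraction
  set.seed(1)
  b <- array(runif(27 * 5, 0.5, 2), c(3, 3, 3, 5))
  m1 <- implicit_mask(mk_bold(b), 0.1)
  m2 <- implicit_mask(mk_bold(b), 0.999)
  expect_true(all(m1[m2]))
  expect_error(implicit_mask(mk_bold(array(1, c(3, 3, 3, 2))), 0.9999999),
               NA)  # all equal: strict > keeps none? grand mean equals values
})

test_that("GLM estimation matches explicit least-squares oracles", {
  set.seed(42)
  n <- 80
  X <- cbind(intercept = 1, a = rnorm(n), b = rnorm(n))
  Y <- matrix(rnorm(n * 6), n)
  f <- fit_glm_ar1(Y, X, prewhiten = FALSE)
  oracle <- solve(crossprod(X)) %*% crossprod(X, Y)   # normal equations
  expect_lt(max(abs(f$betas - oracle)), 1e-8)
  expect_equal(f$dof, n - 3)
  # rho = 0 data: prewhitened fit equals plain OLS
  f0 <- fit_glm_ar1(Y, X, prewhiten = TRUE)
  expect_lt(f0$ar1_rho, 0.15)
  # noise-free recovery through the full simulate->design path
  sp <- tiny_spec(grid = c(2L, 2L, 1L))
  ev <- sample_events(sp, 1, seed = 3)
  eff <- effect_spec(univariate_gain = 2.5, noise_sd = 0, drift_amp = 0,
                     baseline = 0)
  bold <- simulate_run(ev, eff, sp, seed = 1)
  Xd <- build_design_matrix(ev, sp$n_volumes, sp$tr_s,
                            epoch_mode = "variable_epoch",
                            conditions = spec_conditions(sp))
  fr <- fit_glm_ar1(bold, Xd, prewhiten = FALSE)
  expect_lt(max(abs(fr$betas[fr$task_columns, ] - 2.5)), 1e-6)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  set.seed(1)
  X <- cbind(a = rnorm(30), b = rnorm(30))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  expect_error(fit_glm_ar1(matrix(rnorm(30), 30), X), "rank deficient")
})

test_that("pooled AR(1) estimate recovers the simulated coefficient", {
  sp <- calibration_spec()
  conds <- spec_conditions(sp)
  rhos <- vapply(1:25, function(s) {
    ev <- sample_events(sp, 1, s)
    eff <- effect_spec(univariate_gain = 0, noise_ar1 = 0.3, noise_sd = 1)
    bold <- simulate_run(ev, eff, sp, seed = s)
    X <- build_design_matrix(ev, sp$n_volumes, sp$tr_s, conditions = conds)
    fit_glm_ar1(bold, X)$ar1_rho
  }, numeric(1))
  expect_gt(mean(rhos), 0.2)
  expect_lt(mean(rhos), 0.4)
})

test_that("Kronecker main-effect contrasts have the factorial structure", {
  C <- kron_main_effect_contrasts(c(3, 3, 2))
  expect_equal(dim(C$amplitude), c(2, 18))
  expect_equal(dim(C$velocity), c(2, 18))
  expect_equal(dim(C$direction), c(1, 18))
  expect_true(all(abs(rowSums(C$amplitude)) < 1e-12))
  C2 <- kron_main_effect_contrasts(c(2, 2, 2))
  expect_true(all(vapply(C2, nrow, 1L) == 1))
  expect_true(all(vapply(C2, ncol, 1L) == 8))
  # a beta vector constant across amplitude levels is annihilated
  conds <- spec_conditions(experiment_spec("exp1"))
  beta <- as.numeric(factor(conds$velocity)) * 2 +
          (conds$direction == "ext") * 0.5
  expect_equal(max(abs(C$amplitude %*% beta)), 0, tolerance = 1e-12)
  expect_gt(max(abs(C$velocity %*% beta)), 0.1)
})

test_that("unbiased beta recovery over seeded noise replicates", {
  sp <- tiny_spec(grid = c(2L, 2L, 1L))
  conds <- spec_conditions(sp)
  gains <- stats::setNames(rep(2, 8), conds$trial_type)
  gains["A40_V20_ext"] <- 5
  ests <- vapply(1:40, function(s) {
    ev <- sample_events(sp, 1, s)
    eff <- effect_spec(univariate_gain = gains, noise_sd = 1,
                       duration_scaling = FALSE)
    bold <- simulate_run(ev, eff, sp, seed = s + 500)
    X <- build_design_matrix(ev, sp$n_volumes, sp$tr_s, conditions = conds)
    f <- fit_glm_ar1(bold, X)
    f$betas["A40_V20_ext", 1] - f$betas["A40_V20_flex", 1]
  }, numeric(1))
  # injected difference of 3 units, recovered within Monte-Carlo error
  expect_lt(abs(mean(ests) - 3), 3 * stats::sd(ests) / sqrt(length(ests)) + 0.15)
})
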