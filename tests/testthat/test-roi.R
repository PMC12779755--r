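test_that("ROI fixture table matches the literature coordinates exactly", {
  tb <- roi_table()
  expect_equal(tb$label, c("L S1", "SMA", "L S2", "R S2", "L Thalamus",
                           "R Cerebellum"))
  expect_equal(tb$x, c(-41, -8, -54, 54, -17, 25))
  expect_equal(tb$y, c(-28, -14, -25, -27, -20, -49))
  expect_equal(tb$z, c(61, 62, 20, 27, 8, -26))
  expect_true(all(tb$radius_mm == 5))
  # round-trip through the plain-text config
  tmp <- tempfile(fileext = ".tsv")
  write_roi_config(tb, tmp)
  expect_equal(read_roi_config(tmp), tb)
})

test_that("spherical ROIs select the documented voxel counts", {
  spec <- experiment_spec("exp1", grid_dims = c(15L, 15L, 15L))
  aff <- grid_affine(spec)
  v5 <- roi_voxels(c(0, 0, 0), aff, spec$grid_dims, radius_mm = 5)
  v8 <- roi_voxels(c(0, 0, 0), aff, spec$grid_dims, radius_mm = 8)
  expect_length(v5, 19)
  expect_length(v8, 81)
  # mask restriction is monotone
  mask <- array(TRUE, spec$grid_dims)
  mask[8, 8, 8] <- FALSE
  v5m <- roi_voxels(c(0, 0, 0), aff, spec$grid_dims, mask, radius_mm = 5)
  expect_length(v5m, 18)
  expect_true(all(v5m %in% v5))
  # empty ROI is an explicit failure
  empty_mask <- array(FALSE, spec$grid_dims)
  expect_error(roi_voxels(c(0, 0, 0), aff, spec$grid_dims, empty_mask,
                          radius_mm = 5), "no in-mask voxel")
})

test_that("bootstrap cell significance is deterministic and flags degenerate cells", {
  # all subjects classify perfectly: every diagonal cell significant
  k <- 2; n <- 6
  confs <- array(0, c(n, k, k))
  confs[, 1, 1] <- 100; confs[, 2, 2] <- 100
  bs <- bootstrap_cell_significance(confs, n_boot = 500, seed = 4)
  expect_true(all(diag(bs$significant)))
  expect_true(bs$any_significant)
  expect_equal(bs$ci_level, 1 - 0.05 / 4)

  set.seed(10)
  confs2 <- array(runif(n * 4, 20, 80), c(n, k, k))
  b1 <- bootstrap_cell_significance(confs2, n_boot = 1e5, seed = 99)
  b2 <- bootstrap_cell_significance(confs2, n_boot = 1e5, seed = 99)
  expect_identical(b1$ci_lo, b2$ci_lo)
  expect_identical(b1$ci_hi, b2$ci_hi)
  expect_error(bootstrap_cell_significance(confs2[1, , , drop = FALSE]),
               "at least 2 subjects")
})

test_that("bootstrap CI width shrinks like 1/sqrt(n) on i.i.d. accuracies", {
  width_at <- function(n, seed) {
    set.seed(seed)
    confs <- array(rnorm(n * 4, mean = 50, sd = 10), c(n, 2, 2))
    bs <- bootstrap_cell_significance(confs, n_boot = 4000, seed = seed)
    mean(bs$ci_hi - bs$ci_lo)
  }
  w10 <- mean(vapply(1:6, function(s) width_at(10, s), numeric(1)))
  w40 <- mean(vapply(1:6, function(s) width_at(40, s), numeric(1)))
  expect_equal(w10 / w40, 2, tolerance = 0.3)
})

test_that("Sidak adjustment has the closed form and its order properties", {
  expect_equal(sidak_adjust(0.01, 3), 1 - 0.99^3)
  expect_equal(sidak_adjust(0.01, 3), 0.029701)
  expect_equal(sidak_adjust(0.2, 1), 0.2)
  p <- runif(20)
  expect_true(all(sidak_adjust(p, 5) >= p))
  expect_true(all(sidak_adjust(p, 7) <= 1))
})

test_that("repeated-measures ROI ANOVA separates null and monotone effects", {
  set.seed(2)
  n <- 12
  # equal level means: omnibus and all pairwise tests stay quiet
  base <- rnorm(n)
  betas0 <- cbind(L1 = base + rnorm(n, sd = 0.3),
                  L2 = base + rnorm(n, sd = 0.3),
                  L3 = base + rnorm(n, sd = 0.3))
  r0 <- roi_univariate_anova(betas0)
  expect_gt(r0$p, 0.1)
  expect_true(all(r0$pairwise$p_adj > 0.1))
  expect_equal(nrow(r0$pairwise), 3)   # k(k-1)/2
  expect_true(all(r0$pairwise$p_adj >= r0$pairwise$p))

  expect_error(roi_univariate_anova(betas0[1:2, ]), "at least 3 subjects")

  # monotone amplitude gain, extreme-pair difference of 1 paired-SD, n = 20
  hits <- vapply(1:30, function(s) {
    set.seed(s)
    subj <- rnorm(20, sd = 0.5)
    b <- sapply(c(0, 0.5, 1), function(mu) mu + subj + rnorm(20, sd = 1 / sqrt(2)))
    colnames(b) <- c("A10", "A20", "A40")
    r <- roi_univariate_anova(b)
    ext <- r$pairwise[r$pairwise$level1 == "A10" & r$pairwise$level2 == "A40", ]
    r$p < 0.05 && ext$p_adj < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("leave-one-subject-out stability distinguishes shared from unique patterns", {
  types <- c("A10_V20_ext", "A10_V20_flex", "A40_V20_ext", "A40_V20_flex")
  n_vox <- 40
  make_subject <- function(pat, seed) {
    synthetic_stack(n_runs = 4, trial_types = types, n_vox = n_vox,
                    noise_sd = 1, patterns = pat, pattern_scale = 4,
                    seed = seed)
  }
  flags <- vapply(1:8, function(rep) {
    shared <- condition_patterns(types, seq_len(n_vox), seed = 1000 + rep)
    unique_flags <- loso_stability(lapply(1:5, function(s)
      make_subject(condition_patterns(types, seq_len(n_vox),
                                      seed = rep * 50 + s), seed = rep * 90 + s)))
    shared_flags <- loso_stability(lapply(1:5, function(s)
      make_subject(shared, seed = rep * 90 + s)))
    c(unique_flags$stable, shared_flags$stable)
  }, logical(2))
  expect_lte(mean(flags[1, ]), 0.25)   # subject-unique patterns do not generalise
  expect_gte(mean(flags[2, ]), 0.9)    # shared patterns do

  one_level <- synthetic_stack(trial_types = c("A10_V20_ext", "A10_V40_ext"))
  expect_error(loso_stability(list(one_level, one_level, one_level),
                              feature = "amplitude"),
               "only one condition level")
})

test_that("stack_subset restricts samples to the requested voxels", {
  st <- synthetic_stack(n_vox = 50)
  sub <- stack_subset(st, c(3L, 7L, 20L))
  expect_equal(ncol(sub$samples), 3)
  expect_equal(sub$voxel_index, c(3L, 7L, 20L))
  expect_error(stack_subset(st, 1000L), "no stack voxels")
})
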