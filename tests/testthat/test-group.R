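test_that("Gaussian smoothing preserves mass and has the nominal width", {
  a <- array(0, c(9, 9, 9)); a[5, 5, 5] <- 1
  sm <- gaussian_smooth(a, 6, 3)
  expect_equal(sum(sm), 1, tolerance = 1e-6)      # interior support
  # impulse response: half maximum one voxel away => FWHM ~ 2 voxels (6 mm)
  expect_equal(sm[6, 5, 5] / sm[5, 5, 5], 0.5, tolerance = 0.05)
  expect_identical(gaussian_smooth(a, 0, 3), a)   # fwhm -> 0 is the identity
  # NA handling: mask restored
  a[1, 1, 1] <- NA
  sm2 <- gaussian_smooth(a, 6, 3)
  expect_true(is.na(sm2[1, 1, 1]))
  expect_false(anyNA(sm2[2:9, 2:9, 2:9]))
})

test_that("one-sample t map matches the closed-form oracle exactly", {
  set.seed(6)
  M <- matrix(rnorm(15 * 40), 15)
  g <- one_sample_t_map(M)
  v <- 17
  expect_lt(abs(g$stat[v] - mean(M[, v]) / (sd(M[, v]) / sqrt(15))), 1e-10)
  expect_equal(g$df, 14)
  # identical positive maps: degenerate-significant sentinel
  Mc <- matrix(2, 5, 10)
  gc <- one_sample_t_map(Mc)
  expect_true(all(gc$degenerate))
  expect_true(all(gc$stat == Inf))
  expect_error(one_sample_t_map(M[1:2, ]), "at least 3 subjects")
})

test_that("Welch ANOVA map agrees with oneway.test and the t^2 identity", {
  set.seed(7)
  g2 <- list(matrix(rnorm(10 * 5), 10), matrix(rnorm(12 * 5, sd = 2), 12))
  w2 <- welch_anova_map(g2)
  tt <- t.test(g2[[1]][, 3], g2[[2]][, 3], var.equal = FALSE)
  expect_lt(abs(w2$stat[3] - unname(tt$statistic)^2), 1e-10)
  expect_lt(abs(w2$df2[3] - unname(tt$parameter)), 1e-8)

  g3 <- list(matrix(rnorm(8 * 4), 8), matrix(rnorm(9 * 4, 1), 9),
             matrix(rnorm(10 * 4, 0.5, 2), 10))
  w3 <- welch_anova_map(g3)
  ot <- oneway.test(y ~ gr, data.frame(
    y = c(g3[[1]][, 2], g3[[2]][, 2], g3[[3]][, 2]),
    gr = factor(rep(1:3, times = c(8, 9, 10)))))
  expect_lt(abs(w3$stat[2] - unname(ot$statistic)), 1e-10)
  expect_lt(abs(w3$df2[2] - unname(ot$parameter[2])), 1e-8)
})

test_that("Welch ANOVA keeps nominal size under heteroskedastic nulls", {
  # the small group carries the larger variance: the classical-ANOVA
  # failure mode, which Welch is designed to resist
  rates <- vapply(1:400, function(s) {
    set.seed(s)
    g <- list(matrix(rnorm(8 * 2, sd = 2), 8), matrix(rnorm(24 * 2, sd = 1), 24))
    w <- welch_anova_map(g)
    cls <- anova_classic <- {
      y <- c(g[[1]][, 1], g[[2]][, 1]); gr <- factor(rep(1:2, c(8, 24)))
      summary(aov(y ~ gr))[[1]][["Pr(>F)"]][1]
    }
    c(w$p[1] < 0.05, cls < 0.05)
  }, logical(2))
  welch_rate <- mean(rates[1, ]); classic_rate <- mean(rates[2, ])
  expect_lt(abs(welch_rate - 0.05), 0.035)
  expect_gt(classic_rate, welch_rate)   # classical ANOVA drifts, Welch holds
})

test_that("sign-flip FWE control localises signal and nests across thresholds", {
  set.seed(12)
  n <- 14; n_vox <- 120
  M <- matrix(rnorm(n * n_vox), n)
  M[, 5:8] <- M[, 5:8] + 2.5        # strong focal signal
  f05 <- fwe_threshold(M, "one_sample", alpha = 0.05, n_perm = 300, seed = 2)
  expect_true(all(f05$threshold_mask[5:8]))
  expect_lt(mean(f05$threshold_mask[-(5:8)]), 0.05)
  # stricter threshold strictly nested inside the looser one
  f55 <- fwe_threshold(M, "one_sample", alpha = 5e-5, n_perm = 300, seed = 2)
  expect_true(all(which(f55$threshold_mask) %in% which(f05$threshold_mask)))
  expect_error(fwe_threshold(M, "one_sample", n_perm = 50), "n_perm")
})

test_that("family-wise error rate is controlled on pure-noise maps", {
  any_sig <- vapply(1:120, function(s) {
    set.seed(s + 3000)
    M <- matrix(rnorm(12 * 40), 12)
    f <- fwe_threshold(M, "one_sample", alpha = 0.05, n_perm = 150,
                       seed = s)
    any(f$threshold_mask)
  }, logical(1))
  # binomial(120, 0.05) 99% envelope
  expect_lt(mean(any_sig), 0.115)
})

test_that("cluster reports honour extent and peak-separation rules", {
  dims <- c(20L, 20L, 5L)
  aff <- diag(c(3, 3, 3, 1)); aff[1:3, 4] <- -3 * (dims - 1) / 2
  stat <- array(0, dims); mask <- array(FALSE, dims)
  # 9-voxel blob: below the extent threshold
  mask[1:3, 1:3, 1] <- TRUE; stat[1:3, 1:3, 1] <- 5
  expect_equal(nrow(report_clusters(mask, stat, aff)), 0)
  # two 3x3x2=18-voxel blobs joined by a bridge, peaks ~33 mm apart
  mask <- array(FALSE, dims); stat <- array(0, dims)
  mask[2:4, 2:4, 2:3] <- TRUE;  stat[2:4, 2:4, 2:3] <- 4; stat[3, 3, 2] <- 10
  mask[13:15, 2:4, 2:3] <- TRUE; stat[13:15, 2:4, 2:3] <- 4; stat[14, 3, 2] <- 8
  mask[5:12, 3, 2] <- TRUE; stat[5:12, 3, 2] <- 1       # bridge
  rep1 <- report_clusters(mask, stat, aff, min_extent = 10, peak_sep_mm = 20)
  expect_equal(length(unique(rep1$cluster)), 1)          # one joined cluster
  expect_equal(nrow(rep1), 2)                            # two separated peaks
  expect_equal(sort(rep1$peak_stat, decreasing = TRUE), c(10, 8))
  d <- sqrt(sum((as.numeric(rep1[1, c("x", "y", "z")]) -
                 as.numeric(rep1[2, c("x", "y", "z")]))^2))
  expect_gt(d, 20)
  # empty map: empty report
  expect_equal(nrow(report_clusters(array(FALSE, dims), stat, aff)), 0)
})

test_that("permutation p-values are invariant to monotone stat transforms", {
  set.seed(5)
  M <- matrix(rnorm(10 * 30), 10)
  f1 <- fwe_threshold(M, "one_sample", n_perm = 200, seed = 9)
  f2 <- fwe_threshold(3 * M, "one_sample", n_perm = 200, seed = 9)  # t invariant
  expect_equal(f1$p_fwe, f2$p_fwe)
})
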