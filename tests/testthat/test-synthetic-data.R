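test_that("event sampling yields exact balanced factorial schedules", {
  ev1 <- sample_events(experiment_spec("exp1"), run_index = 1, seed = 7)
  expect_equal(nrow(ev1), 144)              # 18 combinations x 8 repetitions
  expect_true(all(table(ev1$trial_type) == 8))
  expect_equal(length(unique(ev1$trial_type)), 18)

  ev2 <- sample_events(experiment_spec("exp2"), run_index = 1, seed = 7)
  expect_equal(nrow(ev2), 40)
  expect_true(all(table(ev2$trial_type) == 5))

  # onsets strictly increasing, all events inside the run
  expect_true(all(diff(ev1$onset) > 0))
  expect_lt(max(ev2$onset + ev2$duration), 306 * 2)

  # determinism
  expect_identical(ev1, sample_events(experiment_spec("exp1"), 1, seed = 7))
  expect_false(identical(ev1$onset,
                         sample_events(experiment_spec("exp1"), 2, seed = 7)$onset))
})

test_that("ITIs stay inside the configured half-range", {
  spec <- experiment_spec("exp1")
  ev <- sample_events(spec, 1, seed = 3)
  gaps <- ev$onset[-1] - (ev$onset[-nrow(ev)] + ev$duration[-nrow(ev)])
  expect_true(all(gaps >= spec$iti_mean_s - spec$iti_halfrange_s - 1e-9))
  expect_true(all(gaps <= spec$iti_mean_s + spec$iti_halfrange_s + 1e-9))
})

test_that("infeasible schedules fail with an explicit overflow message", {
  spec <- tiny_spec(n_volumes = 30L)  # 60 s for ~158 s of schedule
  expect_error(sample_events(spec, 1, seed = 1), "overflow|cannot fit")
})

test_that("trial durations are coupled to amplitude and velocity levels", {
  ev <- sample_events(experiment_spec("exp1"), 1, seed = 11)
  by_amp <- tapply(ev$duration, ev$amplitude, mean)
  by_vel <- tapply(ev$duration, ev$velocity, mean)
  expect_gt(diff(range(by_amp)), 0.2)
  expect_gt(diff(range(by_vel)), 0.2)
  # duration ~ amplitude / velocity up to the configured jitter
  ratio <- ev$duration / (ev$amplitude_frac / ev$velocity_frac)
  expect_true(all(abs(ratio - 1) <= 0.1 + 1e-9))
})

test_that("noise-free effect-free runs are constant volumes", {
  spec <- tiny_spec(grid = c(2L, 2L, 2L))
  ev <- sample_events(spec, 1, seed = 1)
  eff <- effect_spec(univariate_gain = 0, noise_sd = 0, drift_amp = 0,
                     baseline = 5)
  bold <- simulate_run(ev, eff, spec, seed = 1)
  expect_true(all(bold$data == 5))
  expect_equal(dim(bold$data), c(2, 2, 2, spec$n_volumes))
})

test_that("doubling the gain doubles noise-free GLM betas (forward linearity)", {
  spec <- tiny_spec(grid = c(2L, 2L, 1L))
  ev <- sample_events(spec, 1, seed = 2)
  X <- build_design_matrix(ev, spec$n_volumes, spec$tr_s,
                           epoch_mode = "variable_epoch",
                           conditions = spec_conditions(spec))
  fit_for_gain <- function(g) {
    eff <- effect_spec(univariate_gain = g, noise_sd = 0, drift_amp = 0,
                       baseline = 0)
    f <- fit_glm_ar1(simulate_run(ev, eff, spec, seed = 1), X, prewhiten = FALSE)
    f$betas[f$task_columns, 1]
  }
  b1 <- fit_for_gain(1); b2 <- fit_for_gain(2)
  expect_equal(b2, 2 * b1, tolerance = 1e-8)
  expect_equal(unname(b1), rep(1, 8), tolerance = 1e-6)
})

test_that("simulated AR(1) noise has the requested lag-1 autocorrelation", {
  spec <- tiny_spec(grid = c(4L, 4L, 2L), n_volumes = 300L, reps = 4L)
  spec$n_volumes <- 300L
  eff <- effect_spec(univariate_gain = 0, noise_ar1 = 0.3, noise_sd = 1,
                     drift_amp = 0)
  acs <- vapply(1:6, function(s) {
    ev <- sample_events(spec, 1, s)
    b <- simulate_run(ev, eff, spec, seed = s)
    m <- matrix(b$data, ncol = spec$n_volumes)
    mean(apply(m[1:10, ], 1, function(x)
      stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]))
  }, numeric(1))
  expect_lt(abs(mean(acs) - 0.3), 0.05)
})

test_that("zero-mean patterns leave the region mean unchanged while voxels differ", {
  types <- paste0("c", 1:4)
  p <- condition_patterns(types, 1:80, seed = 5)
  expect_equal(unname(rowMeans(p)), rep(0, 4), tolerance = 1e-12)
  # independent rows: small expected pairwise correlation
  cors <- cor(t(p))[lower.tri(diag(4))]
  expect_true(all(abs(cors) < 0.5))
  # zero-mean patterns leave the region-mean betas exactly as they are
  # without patterns, while voxelwise betas change
  spec <- tiny_spec(grid = c(4L, 4L, 4L))
  region <- 1:32
  ev <- sample_events(spec, 1, seed = 4)
  X <- build_design_matrix(ev, spec$n_volumes, spec$tr_s,
                           conditions = spec_conditions(spec))
  beta_of <- function(strength) {
    eff <- effect_spec(univariate_gain = 5, pattern_strength = strength,
                       pattern_region = region, noise_sd = 0, drift_amp = 0,
                       baseline = 0, duration_scaling = FALSE)
    f <- fit_glm_ar1(simulate_run(ev, eff, spec, seed = 4), X,
                     prewhiten = FALSE)
    f$betas[f$task_columns, ]
  }
  with_pat <- beta_of(10); without_pat <- beta_of(0)
  expect_equal(rowMeans(with_pat[, region]), rowMeans(without_pat[, region]),
               tolerance = 1e-8)
  expect_gt(mean(abs(with_pat[, region] - without_pat[, region])), 0.5)
})

test_that("make_dataset is deterministic and respects the run/subject layout", {
  spec <- tiny_spec(grid = c(2L, 2L, 2L))
  eff <- effect_spec(noise_sd = 0.5)
  ds <- make_dataset(spec, eff, n_subjects = 2, seed = 42)
  expect_length(ds$subjects, 2)
  expect_length(ds$subjects[[1]]$runs, 4)
  ds2 <- make_dataset(spec, eff, n_subjects = 2, seed = 42)
  expect_identical(ds$subjects[[1]]$runs[[1]]$events,
                   ds2$subjects[[1]]$runs[[1]]$events)
  expect_identical(ds$subjects[[2]]$runs[[3]]$data,
                   ds2$subjects[[2]]$runs[[3]]$data)
  # different subjects get different schedules
  expect_false(identical(ds$subjects[[1]]$runs[[1]]$events$onset,
                         ds$subjects[[2]]$runs[[1]]$events$onset))
})

test_that("events and BOLD round-trip through TSV and NIfTI", {
  spec <- tiny_spec(grid = c(3L, 3L, 3L))
  ev <- sample_events(spec, 1, seed = 9)
  tmp <- tempfile(fileext = ".tsv")
  write_events(ev, tmp)
  ev2 <- read_events(tmp)
  expect_equal(ev2$onset, ev$onset, tolerance = 1e-9)
  expect_identical(ev2$trial_type, ev$trial_type)
  expect_identical(names(ev2)[1:3], c("onset", "duration", "trial_type"))

  eff <- effect_spec(noise_sd = 0.5)
  bold <- simulate_run(ev, eff, spec, seed = 1)
  nii <- tempfile(fileext = ".nii.gz")
  write_bold(bold, nii)
  back <- read_bold(nii)
  expect_equal(back$data, bold$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$tr_s, spec$tr_s)
  expect_equal(unclass(back$affine)[1:3, 4], bold$affine[1:3, 4],
               tolerance = 1e-5, ignore_attr = TRUE)
})
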