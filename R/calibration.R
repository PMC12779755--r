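#' Reduced factorial specification used by the calibration studies
#'
#' A 2 x 2 x 2 design (amplitudes 10/40%, velocities 20/40%/s, both
#' directions) whose trial durations span 0.25-2 s -- the short-event regime
#' in which a first-order duration modulator is the appropriate model. The
#' default grid and run length are deliberately small; they keep the seeded
#' replicate studies below desk-scale compute while preserving the
#' statistical structure of the full designs.
#'
#' @param reps repetitions per combination per run.
#' @param n_volumes volumes per run.
#' @param grid_dims simulation grid.
#' @param slow if `TRUE`, use the slow event-related variant (ITI 12 +/- 2 s
#'   as in the 2 x 2 x 2 experiment); the long intervals decouple
#'   neighbouring trials, which matters for unbiased condition-beta
#'   estimation when the neural epoch and the modelled epoch differ in
#'   shape.
#' @return An [experiment_spec()].
#' @export
calibration_spec <- function(reps = 4L, n_volumes = 135L,
                             grid_dims = c(3L, 3L, 3L), slow = FALSE) {
  experiment_spec("custom",
                  amplitude_levels = c(A10 = 0.10, A40 = 0.40),
                  velocity_levels = c(V20 = 0.20, V40 = 0.40),
                  reps_per_combo_per_run = as.integer(reps),
                  iti_mean_s = if (slow) 12 else 4,
                  iti_halfrange_s = 2,
                  n_volumes = as.integer(n_volumes),
                  grid_dims = as.integer(grid_dims))
}

# Study-condition neural gain: a 2-s event peaks at ~4 noise SD and a 0.5-s
# event at ~1 SD under the sum-normalised HRF kernel -- the strong
# somatosensory-response regime.
.calib_gain <- 10

#' False-positive control of the duration-modulated GLM
#'
#' The core methodological property of the duration-as-covariate model:
#' trial duration is confounded with condition (duration = amplitude /
#' velocity) but there is NO condition effect beyond it (equal gain for all
#' conditions). For each simulated run, the amplitude main effect is
#' F-tested under three first-level models -- constant epochs plus a single
#' run-centred duration modulator (the canonical duration-covariate model),
#' the full-interaction variant with condition-specific modulators, and the
#' variable-epoch model -- in two ground-truth scenarios: neural activity
#' duration scaling with time-on-task or fixed. The duration-covariate
#' model keeps the empirical type-I error at the nominal level in both
#' scenarios; the variable-epoch model fails when activity does not scale;
#' the full-interaction variant (whose condition-specific modulators are
#' centred within condition) is reported alongside -- under the scaling
#' scenario its condition betas retain between-condition duration
#' responses, which is the residual time-on-task confound discussed in the
#' methods vignette.
#'
#' @param n_sims simulated runs per scenario.
#' @param alpha nominal level of the main-effect test.
#' @param seed integer seed.
#' @return data.frame with columns `scenario` (`scaling` / `non_scaling`),
#'   `model` (`constant_modulator` / `full_interaction` /
#'   `variable_epoch`), `type_i` (empirical rate), `n_sims`.
#' @export
fp_control_experiment <- function(n_sims = 500, alpha = 0.05, seed = 1L) {
  spec <- calibration_spec()
  conds <- spec_conditions(spec)
  Camp <- kron_main_effect_contrasts(c(2, 2, 2))$amplitude
  one <- function(s, scaling) {
    ev <- sample_events(spec, 1, seed_chain(seed, s, scaling))
    eff <- effect_spec(univariate_gain = .calib_gain,
                       duration_scaling = scaling)
    bold <- simulate_run(ev, eff, spec, seed = seed_chain(seed, s, scaling, 2L))
    Y <- t(matrix(bold$data, ncol = spec$n_volumes))
    Xn <- build_design_matrix(ev, spec$n_volumes, spec$tr_s,
                              model = "non_interaction", conditions = conds)
    Xf <- build_design_matrix(ev, spec$n_volumes, spec$tr_s,
                              model = "full_interaction", conditions = conds)
    Xv <- build_design_matrix(ev, spec$n_volumes, spec$tr_s,
                              epoch_mode = "variable_epoch", conditions = conds)
    c(glm_contrast_f(fit_glm_ar1(Y, Xn), Camp)$p[1],
      glm_contrast_f(fit_glm_ar1(Y, Xf), Camp)$p[1],
      glm_contrast_f(fit_glm_ar1(Y, Xv), Camp)$p[1])
  }
  out <- list()
  for (scaling in c(TRUE, FALSE)) {
    ps <- vapply(seq_len(n_sims), one, numeric(3), scaling = scaling)
    out[[length(out) + 1L]] <- data.frame(
      scenario = if (scaling) "scaling" else "non_scaling",
      model = c("constant_modulator", "full_interaction", "variable_epoch"),
      type_i = rowMeans(ps < alpha), n_sims = n_sims)
  }
  do.call(rbind, out)
}

# Shared first-level route of the group-level studies: implicit mask from
# run 1, duration-modulated GLM per run, run-wise condition beta stack.
subject_stack <- function(subject, spec, conds) {
  mask <- implicit_mask(subject$runs[[1]])
  fits <- lapply(subject$runs, function(run) {
    X <- build_design_matrix(run$events, spec$n_volumes, spec$tr_s,
                             model = "full_interaction", conditions = conds)
    fit_glm_ar1(run, X, mask)
  })
  beta_stack(fits)
}

#' Null calibration of searchlight and ROI decoding
#'
#' No-signal datasets (zero task gain: AR(1) noise, drift and baseline
#' only) are decoded with the full searchlight and an ROI classifier;
#' accuracy minus chance should sit at zero within Monte-Carlo error.
#' Returns per-subject map means and ROI accuracies, plus their group means
#' and standard errors.
#'
#' @param n_subjects subjects simulated for the searchlight calibration.
#' @param n_roi_subjects subjects simulated for the ROI calibration (on a
#'   smaller grid; the ROI accuracy of a single sphere is a noisy,
#'   quantised per-subject quantity, so its calibration check uses a
#'   larger group than the searchlight's).
#' @param seed integer seed.
#' @param grid_dims simulation grid for the searchlight.
#' @return list: `map_means` (per-subject searchlight map means, acc-chance
#'   %), `roi_acc` (per-subject ROI accuracy minus chance), `mean_map`,
#'   `se_map`, `mean_roi`, `se_roi`, `chance`.
#' @export
decoder_null_experiment <- function(n_subjects = 6, n_roi_subjects = 16,
                                    seed = 1L, grid_dims = c(6L, 6L, 6L)) {
  spec <- calibration_spec(reps = 3L, n_volumes = 72L, grid_dims = grid_dims)
  conds <- spec_conditions(spec)
  eff <- effect_spec(univariate_gain = 0)  # no task response at all
  ds <- make_dataset(spec, eff, n_subjects, seed = seed_chain(seed, 11L))
  off <- sphere_offsets(8, spec$voxel_mm)
  map_means <- numeric(n_subjects)
  for (s in seq_len(n_subjects)) {
    st <- subject_stack(ds$subjects[[s]], spec, conds)
    labels <- feature_labels(st, "amplitude")
    m <- searchlight_map(st, labels, off)
    map_means[s] <- mean(m$values, na.rm = TRUE)
  }
  spec_roi <- calibration_spec(reps = 3L, n_volumes = 72L,
                               grid_dims = c(4L, 4L, 4L))
  ds_roi <- make_dataset(spec_roi, eff, n_roi_subjects,
                         seed = seed_chain(seed, 22L))
  centre_vox <- roi_voxels(c(0, 0, 0), grid_affine(spec_roi),
                           spec_roi$grid_dims, radius_mm = 5)
  roi_acc <- vapply(seq_len(n_roi_subjects), function(s) {
    st <- subject_stack(ds_roi$subjects[[s]], spec_roi, conds)
    sub <- stack_subset(st, centre_vox)
    cv <- loro_cv_accuracy(sub$samples, feature_labels(sub, "amplitude"), sub$run)
    cv$accuracy - cv$chance
  }, numeric(1))
  list(map_means = map_means, roi_acc = roi_acc,
       mean_map = mean(map_means), se_map = stats::sd(map_means) / sqrt(n_subjects),
       mean_roi = mean(roi_acc),
       se_roi = stats::sd(roi_acc) / sqrt(n_roi_subjects),
       chance = 50)
}

#' Bootstrap confusion-cell false-positive calibration
#'
#' Simulates ROIs whose per-subject confusion matrices are i.i.d. with every
#' cell centred exactly on chance (multinomial predictions with uniform
#' class probabilities), runs [bootstrap_cell_significance()] on each, and
#' reports the proportion of cells declared significant -- which should not
#' exceed the nominal alpha.
#'
#' @param n_rois simulated ROIs.
#' @param n_subjects subjects per ROI.
#' @param k classes (2 -> 4 cells, adjusted CI level 1 - alpha/4).
#' @param trials_per_class test trials behind each confusion row.
#' @param n_boot bootstrap resamples per ROI (analysis-scale default; the
#'   study-scale default of [bootstrap_cell_significance()] is 1e5).
#' @param alpha nominal level.
#' @param seed integer seed.
#' @return list: `fp_rate` (proportion of significant cells), `n_cells`,
#'   `alpha`.
#' @export
bootstrap_fp_experiment <- function(n_rois = 200, n_subjects = 50, k = 2,
                                    trials_per_class = 8, n_boot = 2000,
                                    alpha = 0.05, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed_chain(seed, 33L))
  sig <- 0L; tot <- 0L
  for (r in seq_len(n_rois)) {
    confs <- array(0, c(n_subjects, k, k))
    for (s in seq_len(n_subjects)) {
      for (i in seq_len(k)) {
        confs[s, i, ] <- 100 * stats::rmultinom(1, trials_per_class,
                                                rep(1 / k, k)) / trials_per_class
      }
    }
    bs <- bootstrap_cell_significance(confs, n_boot = n_boot, alpha = alpha,
                                      seed = seed_chain(seed, 44L, r))
    sig <- sig + sum(bs$significant)
    tot <- tot + k * k
  }
  list(fp_rate = sig / tot, n_cells = tot, alpha = alpha)
}

#' Multivariate / univariate dissociation study
#'
#' For each seed, a group dataset is simulated with one of two ground-truth
#' effects confined to a central region: `"pattern"` injects zero-mean
#' multivoxel condition patterns (information in the spatial configuration,
#' region-mean response identical across conditions); `"gain"` injects a
#' spatially uniform response difference between amplitude levels. Both
#' routes of the pipeline are then run -- searchlight decoding of amplitude
#' with smoothed accuracy maps, one-sample group t and sign-flip
#' max-statistic FWE; and the univariate route with smoothed subject-level
#' amplitude contrast maps, Welch ANOVA and label-permutation FWE -- and a
#' detection ("hit") is any FWE-significant voxel. Pattern effects should be
#' detected by the multivariate route only; gain effects by both.
#'
#' The datasets use the fixed-epoch (non-scaling) neural scenario and the
#' slow event-related schedule, under which the duration-modulated model's
#' condition betas are unbiased (fast schedules couple a trial's duration
#' to its successor's onset, which interacts with response-shape misfit;
#' long intervals remove the overlap); this isolates the pattern-vs-gain
#' contrast from residual time-on-task effects (see the methods vignette).
#'
#' @param n_seeds independent group datasets per effect type.
#' @param n_subjects subjects per dataset.
#' @param effect_types subset of `c("pattern", "gain")`.
#' @param alpha FWE level.
#' @param n_perm permutations for the FWE null.
#' @param seed integer seed.
#' @return data.frame: `effect`, `mvpa_hit_rate`, `univariate_hit_rate`,
#'   `n_seeds`.
#' @export
dissociation_experiment <- function(n_seeds = 20, n_subjects = 6,
                                    effect_types = c("pattern", "gain"),
                                    alpha = 0.05, n_perm = 200, seed = 1L) {
  spec <- calibration_spec(reps = 3L, n_volumes = 165L,
                           grid_dims = c(6L, 6L, 6L), slow = TRUE)
  conds <- spec_conditions(spec)
  dims <- spec$grid_dims
  centre <- as.matrix(expand.grid(2:4, 2:4, 2:4))
  region <- (centre[, 3] - 1) * dims[1] * dims[2] +
            (centre[, 2] - 1) * dims[1] + centre[, 1]
  off <- sphere_offsets(8, spec$voxel_mm)
  amp_gain <- .calib_gain
  res <- list()
  for (et in effect_types) {
    eff <- if (et == "pattern")
      effect_spec(univariate_gain = amp_gain, pattern_strength = amp_gain,
                  pattern_region = region, duration_scaling = FALSE)
    else {
      rg <- stats::setNames(ifelse(conds$amplitude == "A40", amp_gain, 0),
                            conds$trial_type)
      effect_spec(univariate_gain = amp_gain, pattern_region = region,
                  region_gain = rg, duration_scaling = FALSE)
    }
    hits_m <- hits_u <- logical(n_seeds)
    for (sd_i in seq_len(n_seeds)) {
      ds <- make_dataset(spec, eff, n_subjects,
                         seed = seed_chain(seed, et == "gain", sd_i))
      acc_maps <- vector("list", n_subjects)
      lvl_maps <- list(A10 = matrix(0, n_subjects, prod(dims)),
                       A40 = matrix(0, n_subjects, prod(dims)))
      for (s in seq_len(n_subjects)) {
        st <- subject_stack(ds$subjects[[s]], spec, conds)
        m <- searchlight_map(st, feature_labels(st, "amplitude"), off)
        acc_maps[[s]] <- gaussian_smooth(m$values, 6, spec$voxel_mm)
        amp <- feature_labels(st, "amplitude")
        for (lv in c("A10", "A40")) {
          bmean <- colMeans(st$samples[amp == lv, , drop = FALSE])
          vol <- array(0, dims); vol[st$voxel_index] <- bmean
          lvl_maps[[lv]][s, ] <- as.vector(gaussian_smooth(vol, 6, spec$voxel_mm))
        }
      }
      M <- do.call(rbind, lapply(acc_maps, function(a) {
        v <- as.vector(a); v[is.na(v)] <- 0; v
      }))
      fwe_m <- fwe_threshold(M, "one_sample", alpha = alpha, n_perm = n_perm,
                             seed = seed_chain(seed, sd_i, 1L))
      fwe_u <- fwe_threshold(lvl_maps, "anova", alpha = alpha, n_perm = n_perm,
                             seed = seed_chain(seed, sd_i, 2L))
      hits_m[sd_i] <- any(fwe_m$threshold_mask)
      hits_u[sd_i] <- any(fwe_u$threshold_mask)
    }
    res[[et]] <- data.frame(effect = et, mvpa_hit_rate = mean(hits_m),
                            univariate_hit_rate = mean(hits_u),
                            n_seeds = n_seeds)
  }
  do.call(rbind, res)
}

#' Parameter recovery for the zero-inflated count model
#'
#' Simulates counts from a known zero-inflated Poisson mixed model and
#' refits it, reporting the mean estimated feature offsets across seeds.
#'
#' @param n_seeds replicate datasets.
#' @param n_subjects subjects per dataset.
#' @param log_means true log means per feature.
#' @param zi_prob,subject_sd true zero-inflation probability and
#'   random-intercept SD.
#' @param seed integer seed.
#' @return list: `true_offsets` (relative to the first feature),
#'   `mean_estimates`, `max_abs_error`, `n_fit` (converged fits).
#' @export
zip_recovery_experiment <- function(n_seeds = 100, n_subjects = 20,
                                    log_means = c(amplitude = log(8),
                                                  direction = log(8) - 0.7,
                                                  velocity = log(8) - 1.4),
                                    zi_prob = 0.2, subject_sd = 0.5,
                                    seed = 1L) {
  true_off <- log_means[-1] - log_means[1]
  ests <- matrix(NA_real_, n_seeds, length(true_off))
  for (i in seq_len(n_seeds)) {
    d <- simulate_zip_counts(n_subjects, log_means, zi_prob, subject_sd,
                             seed = seed_chain(seed, i))
    fit <- tryCatch(fit_zip_mixed(d), error = function(e) NULL)
    if (!is.null(fit)) ests[i, ] <- fit$coefficients[-1]
  }
  ok <- stats::complete.cases(ests)
  mean_est <- colMeans(ests[ok, , drop = FALSE])
  list(true_offsets = unname(true_off), mean_estimates = unname(mean_est),
       max_abs_error = max(abs(mean_est - true_off)), n_fit = sum(ok))
}
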