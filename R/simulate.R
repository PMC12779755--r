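#' Voxel-grid affine for a design specification
#'
#' The simulated grid is isotropic (`voxel_mm` edge) and centred on the MNI
#' origin, so literature MNI coordinates can index it directly once the grid
#' is large enough. The affine maps 1-based voxel indices `(i,j,k)` to mm via
#' `mm = origin + (ijk - 1) * voxel_mm`.
#'
#' @param spec an [experiment_spec()].
#' @return A 4 x 4 affine matrix.
#' @export
grid_affine <- function(spec) {
  v <- spec$voxel_mm
  origin <- -v * (spec$grid_dims - 1) / 2
  a <- diag(c(v, v, v, 1))
  a[1:3, 4] <- origin
  a
}

#' Convert voxel indices to millimetre coordinates (and back)
#'
#' @param ijk integer matrix (n x 3) of 1-based voxel indices.
#' @param affine 4 x 4 affine from [grid_affine()].
#' @return `vox_to_mm`: n x 3 matrix of mm coordinates. `mm_to_vox`: n x 3
#'   matrix of fractional 1-based voxel indices.
#' @export
vox_to_mm <- function(ijk, affine) {
  ijk <- rbind_matrix(ijk)
  t(affine %*% t(cbind(ijk - 1, 1)))[, 1:3, drop = FALSE]
}

#' @rdname vox_to_mm
#' @param mm numeric matrix (n x 3) of mm coordinates.
#' @export
mm_to_vox <- function(mm, affine) {
  mm <- rbind_matrix(mm)
  t(solve(affine) %*% t(cbind(mm, 1)))[, 1:3, drop = FALSE] + 1
}

rbind_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
}

# Microtime boxcar train: heights placed over [onset, onset + duration)
# at resolution res bins per TR.
microtime_train <- function(onsets, durations, heights, n_scans, tr_s, res) {
  nb <- n_scans * res
  dt <- tr_s / res
  u <- numeric(nb)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1
    b <- min(nb, ceiling((onsets[i] + durations[i]) / dt))
    if (a <= nb && b >= a) u[a:b] <- u[a:b] + heights[i]
  }
  u
}

# FFT convolution of each column of U with kernel k, truncated to nrow(U).
conv_cols <- function(U, k) {
  U <- as.matrix(U)
  n <- nrow(U); m <- length(k)
  L <- stats::nextn(n + m - 1)
  fk <- stats::fft(c(k, rep(0, L - m)))
  FU <- stats::mvfft(rbind(U, matrix(0, L - n, ncol(U))))
  out <- Re(stats::mvfft(FU * fk, inverse = TRUE)) / L
  out[seq_len(n), , drop = FALSE]
}

# HRF-convolved scan-resolution regressors, one column per column of the
# microtime matrix; sampled at the first microtime bin of each TR.
convolve_regressors <- function(U, n_scans, tr_s, hrf = hrf_params()) {
  res <- hrf$microtime_resolution
  k <- canonical_hrf(hrf, tr_s = tr_s)
  C <- conv_cols(U, as.numeric(k))
  C[(seq_len(n_scans) - 1L) * res + 1L, , drop = FALSE]
}

#' Simulate one BOLD run from an event table
#'
#' Forward model: for every condition, a neural boxcar train (trial-specific
#' duration when `effects$duration_scaling`, otherwise a fixed
#' `fixed_neural_duration_s` epoch) is convolved with the canonical HRF; the
#' voxelwise response amplitude is `univariate_gain[condition] +
#' pattern_strength * pattern[condition, voxel]` inside `pattern_region`.
#' AR(1) noise with marginal SD `noise_sd`, two slow cosine drifts (periods
#' 256 s and 384 s, random per-voxel phases) and a constant baseline complete
#' the signal.
#'
#' @param events an `event_table` from [sample_events()].
#' @param effects an [effect_spec()].
#' @param spec the [experiment_spec()] (grid, TR, volumes).
#' @param seed integer seed; the run is a pure function of
#'   `(events, effects, spec, seed)`.
#' @param patterns optional pre-generated condition-pattern matrix from
#'   [condition_patterns()] (rows = `trial_type`); generated from the seed
#'   when `NULL` and `pattern_strength > 0`.
#' @param hrf [hrf_params()].
#' @return A list of class `bold_run`: `data` (4-D array x,y,z,t), `tr_s`,
#'   `affine`, `events`.
#' @export
simulate_run <- function(events, effects, spec, seed = 1L, patterns = NULL,
                         hrf = hrf_params()) {
  n_scans <- spec$n_volumes
  n_vox <- prod(spec$grid_dims)
  region <- effects$pattern_region
  if (length(region) && (min(region) < 1 || max(region) > n_vox))
    stop("pattern_region indices outside the voxel grid")
  types <- unique(events$trial_type)
  res <- hrf$microtime_resolution

  neural_dur <- if (effects$duration_scaling) events$duration else
    rep(effects$fixed_neural_duration_s, nrow(events))
  U <- sapply(types, function(tt) {
    i <- events$trial_type == tt
    microtime_train(events$onset[i], neural_dur[i], rep(1, sum(i)),
                    n_scans, spec$tr_s, res)
  })
  R <- convolve_regressors(U, n_scans, spec$tr_s, hrf)

  gain <- effects$univariate_gain
  g <- if (is.null(names(gain))) rep(gain[1], length(types)) else {
    gi <- gain[types]; gi[is.na(gi)] <- 1; unname(gi)
  }
  G <- matrix(g, nrow = length(types), ncol = n_vox)
  if (effects$pattern_strength > 0 && length(region)) {
    if (is.null(patterns)) patterns <- condition_patterns(types, region, seed)
    G[, region] <- G[, region] +
      effects$pattern_strength * patterns[types, , drop = FALSE]
  }
  if (!is.null(effects$region_gain) && length(region)) {
    rg <- effects$region_gain[types]
    rg[is.na(rg)] <- 0
    G[, region] <- G[, region] + rg
  }
  signal <- R %*% G

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed_chain(seed, 303L))
  rho <- effects$noise_ar1
  if (effects$noise_sd > 0) {
    E <- matrix(stats::rnorm(n_scans * n_vox), n_scans, n_vox)
    E[1, ] <- E[1, ] / sqrt(1 - rho^2)  # stationary start
    E <- E * (effects$noise_sd * sqrt(1 - rho^2))
    noise <- if (rho > 0)
      apply(E, 2, function(e) stats::filter(e, rho, method = "recursive"))
    else E
  } else noise <- 0
  tsec <- (seq_len(n_scans) - 1) * spec$tr_s
  drift <- 0
  if (effects$drift_amp > 0) {
    ph <- matrix(stats::runif(2 * n_vox, 0, 2 * pi), 2, n_vox)
    drift <- effects$drift_amp *
      (cos(outer(tsec, ph[1, ], function(t, p) 2 * pi * t / 256 + p)) +
       cos(outer(tsec, ph[2, ], function(t, p) 2 * pi * t / 384 + p)))
  }
  y <- effects$baseline + signal + noise + drift
  data <- array(t(y), dim = c(spec$grid_dims, n_scans))
  structure(list(data = data, tr_s = spec$tr_s, affine = grid_affine(spec),
                 events = events),
            class = "bold_run")
}

#' Simulate a complete multi-subject dataset
#'
#' `n_runs` runs per subject with subject- and run-specific seeds derived
#' deterministically from the master seed. Each subject receives a unique
#' random pattern orientation unless `effects$shared_pattern` is set --
#' subject-unique patterns emulate multivoxel codes that do not generalise
#' across individuals. A per-subject maximum aperture (mm, normal draw) turns
#' the fractional amplitudes into recorded millimetre displacements in the
#' event tables.
#'
#' @param spec an [experiment_spec()].
#' @param effects an [effect_spec()].
#' @param n_subjects number of subjects (>= 1).
#' @param seed master integer seed.
#' @param hrf [hrf_params()].
#' @return A list of class `kin_dataset`: `spec`, `effects`, `subjects` --
#'   each with `aperture_mm`, `patterns` and a list `runs` of `bold_run`s.
#' @export
make_dataset <- function(spec, effects, n_subjects, seed = 1L,
                         hrf = hrf_params()) {
  stopifnot(n_subjects >= 1)
  types <- spec_conditions(spec)$trial_type
  subjects <- lapply(seq_len(n_subjects), function(s) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed_chain(seed, s, 404L))
    aperture <- stats::rnorm(1, spec$aperture_mean_mm, spec$aperture_sd_mm)
    pat_seed <- if (effects$shared_pattern) seed_chain(seed, 505L)
                else seed_chain(seed, s, 505L)
    patterns <- if (effects$pattern_strength > 0 && length(effects$pattern_region))
      condition_patterns(types, effects$pattern_region, pat_seed) else NULL
    runs <- lapply(seq_len(spec$n_runs), function(r) {
      ev <- sample_events(spec, run_index = r, seed = seed_chain(seed, s))
      ev$amplitude_mm <- ev$amplitude_frac * aperture
      simulate_run(ev, effects, spec, seed = seed_chain(seed, s, r, 606L),
                   patterns = patterns, hrf = hrf)
    })
    list(aperture_mm = aperture, patterns = patterns, runs = runs)
  })
  structure(list(spec = spec, effects = effects, subjects = subjects,
                 seed = seed),
            class = "kin_dataset")
}

#' Write / read a 4-D BOLD run as NIfTI-1
#'
#' The grid affine is stored as the sform; TR is stored in the fourth pixdim.
#'
#' @param bold a `bold_run`.
#' @param path output path (`.nii.gz`).
#' @return `write_bold` returns `path` invisibly; `read_bold` returns a
#'   `bold_run` (without events).
#' @export
write_bold <- function(bold, path) {
  img <- RNifti::asNifti(bold$data)
  aff <- structure(bold$affine, code = 2L)
  RNifti::sform(img) <- aff
  pd <- RNifti::pixdim(img)
  if (length(pd) >= 4) {
    pd[4] <- bold$tr_s
    RNifti::pixdim(img) <- pd
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold
#' @export
read_bold <- function(path) {
  img <- RNifti::readNifti(path)
  structure(list(data = array(as.numeric(img), dim = dim(img)),
                 tr_s = RNifti::pixdim(img)[4],
                 affine = unclass(RNifti::xform(img)),
                 events = NULL),
            class = "bold_run")
}
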