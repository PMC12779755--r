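# Shared miniature objects; everything is generated in code under fixed
# seeds so the suite needs no stored data.

tiny_spec <- function(grid = c(4L, 4L, 4L), n_volumes = 120L, reps = 4L) {
  experiment_spec("custom",
                  amplitude_levels = c(A10 = 0.10, A40 = 0.40),
                  velocity_levels = c(V20 = 0.20, V40 = 0.40),
                  reps_per_combo_per_run = reps,
                  n_volumes = n_volumes, grid_dims = grid)
}

# Synthetic beta stack built directly (no simulation): per run x condition
# rows of N(0, noise_sd) voxel noise plus optional condition patterns.
synthetic_stack <- function(n_runs = 4, trial_types = c("A10_V20_ext", "A10_V20_flex",
                                                        "A40_V20_ext", "A40_V20_flex"),
                            n_vox = 60, noise_sd = 1, patterns = NULL,
                            pattern_scale = 0, grid_dims = NULL, seed = 1) {
  set.seed(seed)
  k <- length(trial_types)
  samples <- matrix(rnorm(n_runs * k * n_vox, sd = noise_sd), n_runs * k, n_vox)
  if (!is.null(patterns) && pattern_scale > 0) {
    for (r in seq_len(n_runs)) {
      rows <- (r - 1) * k + seq_len(k)
      samples[rows, ] <- samples[rows, ] + pattern_scale * patterns
    }
  }
  if (is.null(grid_dims)) {
    n1 <- ceiling(n_vox^(1 / 3))
    grid_dims <- c(n1, n1, ceiling(n_vox / n1^2))
  }
  structure(list(samples = samples,
                 trial_type = rep(trial_types, n_runs),
                 run = rep(seq_len(n_runs), each = k),
                 voxel_index = seq_len(n_vox),
                 grid_dims = grid_dims,
                 affine = {
                   a <- diag(c(3, 3, 3, 1)); a[1:3, 4] <- -3 * (grid_dims - 1) / 2; a
                 },
                 mask = NULL),
            class = "beta_stack")
}
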