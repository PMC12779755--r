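#' Experimental design specification for a robotic passive-movement study
#'
#' Describes a factorial event-related fMRI design in which each trial is a
#' single robotic displacement of the fingers defined by three kinematic
#' features: amplitude (fraction of the subject's maximum thumb-index
#' aperture), velocity (fraction of maximum aperture per second) and direction
#' (extension or flexion). Trial duration is mechanically determined as
#' amplitude / velocity, so duration is confounded with condition by design --
#' the confound the duration-modulated GLM has to control.
#'
#' Two presets reproduce the study conditions:
#' * `"exp1"`: fast event-related 3 x 3 x 2 design -- amplitudes 10/20/40%,
#'   velocities 20/40/80%/s, 8 repetitions per combination per run,
#'   inter-trial interval 4 +/- 2 s, 400 volumes per run.
#' * `"exp2"`: slow event-related 2 x 2 x 2 design -- amplitudes 10/40%,
#'   velocities 5/20%/s, 5 repetitions, ITI 12 +/- 2 s, 306 volumes per run.
#'
#' @param preset `"exp1"`, `"exp2"` or `"custom"`.
#' @param ... named overrides of any field (e.g. `grid_dims`, `n_volumes`,
#'   `reps_per_combo_per_run`, `amplitude_levels`).
#' @return An object of class `experiment_spec`: a list with fields `name`,
#'   `amplitude_levels`, `velocity_levels`, `directions`,
#'   `reps_per_combo_per_run`, `iti_mean_s`, `iti_halfrange_s`, `n_volumes`,
#'   `tr_s`, `n_runs`, `voxel_mm`, `grid_dims`, `duration_jitter_frac`,
#'   `aperture_mean_mm`, `aperture_sd_mm`.
#' @examples
#' spec <- experiment_spec("exp1")
#' nrow(spec_conditions(spec))  # 18 unique combinations
#' @export
experiment_spec <- function(preset = c("exp1", "exp2", "custom"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    exp1 = list(
      name = "exp1",
      amplitude_levels = c(A10 = 0.10, A20 = 0.20, A40 = 0.40),
      velocity_levels  = c(V20 = 0.20, V40 = 0.40, V80 = 0.80),
      reps_per_combo_per_run = 8L,
      iti_mean_s = 4, iti_halfrange_s = 2,
      n_volumes = 400L
    ),
    exp2 = list(
      name = "exp2",
      amplitude_levels = c(A10 = 0.10, A40 = 0.40),
      velocity_levels  = c(V5 = 0.05, V20 = 0.20),
      reps_per_combo_per_run = 5L,
      iti_mean_s = 12, iti_halfrange_s = 2,
      n_volumes = 306L
    ),
    custom = list(
      name = "custom",
      amplitude_levels = c(A10 = 0.10, A40 = 0.40),
      velocity_levels  = c(V20 = 0.20, V40 = 0.40),
      reps_per_combo_per_run = 4L,
      iti_mean_s = 4, iti_halfrange_s = 2,
      n_volumes = 120L
    )
  )
  common <- list(
    directions = c("ext", "flex"),
    tr_s = 2,
    n_runs = 4L,
    voxel_mm = 3,
    grid_dims = c(20L, 20L, 20L),
    duration_jitter_frac = 0.1,
    aperture_mean_mm = 96,
    aperture_sd_mm = 13
  )
  spec <- utils::modifyList(c(base, common), list(...))
  stopifnot(
    length(spec$amplitude_levels) >= 1, length(spec$velocity_levels) >= 1,
    all(spec$amplitude_levels > 0), all(spec$velocity_levels > 0),
    spec$reps_per_combo_per_run >= 1, spec$n_volumes >= 1, spec$tr_s > 0,
    spec$iti_halfrange_s >= 0, spec$iti_mean_s >= spec$iti_halfrange_s,
    length(spec$grid_dims) == 3, all(spec$grid_dims >= 1),
    spec$duration_jitter_frac >= 0, spec$duration_jitter_frac < 1
  )
  if (is.null(names(spec$amplitude_levels))) {
    names(spec$amplitude_levels) <- paste0("A", round(100 * spec$amplitude_levels))
  }
  if (is.null(names(spec$velocity_levels))) {
    names(spec$velocity_levels) <- paste0("V", round(100 * spec$velocity_levels))
  }
  structure(spec, class = "experiment_spec")
}

#' Unique factorial condition table for a design
#'
#' Conditions are ordered with amplitude varying slowest, then velocity, then
#' direction; this canonical order is what the Kronecker-product main-effect
#' contrasts assume. `trial_type` labels follow the BIDS convention
#' `"A{level}_V{level}_{ext|flex}"`.
#'
#' @param spec an [experiment_spec()].
#' @return A data.frame with columns `trial_type`, `amplitude`, `velocity`,
#'   `direction` and the numeric fractions `amplitude_frac`, `velocity_frac`.
#' @export
spec_conditions <- function(spec) {
  amps <- names(spec$amplitude_levels)
  vels <- names(spec$velocity_levels)
  dirs <- spec$directions
  g <- expand.grid(direction = dirs, velocity = vels, amplitude = amps,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("amplitude", "velocity", "direction")]
  g$trial_type <- paste(g$amplitude, g$velocity, g$direction, sep = "_")
  g$amplitude_frac <- unname(spec$amplitude_levels[g$amplitude])
  g$velocity_frac <- unname(spec$velocity_levels[g$velocity])
  rownames(g) <- NULL
  g[, c("trial_type", "amplitude", "velocity", "direction",
        "amplitude_frac", "velocity_frac")]
}

#' Deterministically combine seed components into one 32-bit seed
#'
#' Linear-congruential fold of an arbitrary integer vector; keeps every
#' derived seed inside the positive 32-bit range.
#'
#' @param ... integers (master seed, subject index, run index, stage tag ...).
#' @return A single integer seed.
#' @export
seed_chain <- function(...) {
  v <- as.numeric(c(...))
  s <- 0
  for (x in v) s <- (s * 69069 + abs(x) + 1) %% 2147483629
  as.integer(s)
}

#' Sample a pseudorandomised event schedule for one run
#'
#' Every factorial combination appears exactly `reps_per_combo_per_run` times
#' in a seeded random order. Trial durations are `amplitude / velocity`
#' seconds, jittered by a uniform multiplicative factor; inter-trial intervals
#' are uniform on `iti_mean_s +/- iti_halfrange_s`. The schedule is redrawn
#' (up to 100 seeded attempts) until the last trial ends before the run does,
#' which mirrors how an infeasible randomisation would be rejected before
#' scanning; if no draw fits, an error reports required vs available seconds.
#'
#' @param spec an [experiment_spec()].
#' @param run_index run number (enters the derived seed).
#' @param seed integer master seed.
#' @return A data.frame of class `event_table`: columns `onset`, `duration`,
#'   `trial_type`, `amplitude`, `velocity`, `direction`, `amplitude_frac`,
#'   `velocity_frac`.
#' @examples
#' ev <- sample_events(experiment_spec("exp2"), run_index = 1, seed = 1)
#' table(ev$trial_type)  # each of the 8 combinations exactly 5 times
#' @export
sample_events <- function(spec, run_index = 1L, seed = 1L) {
  conds <- spec_conditions(spec)
  trials0 <- conds[rep(seq_len(nrow(conds)), each = spec$reps_per_combo_per_run), ]
  n <- nrow(trials0)
  run_len <- spec$n_volumes * spec$tr_s
  base_dur <- trials0$amplitude_frac / trials0$velocity_frac
  if (sum(base_dur) >= run_len) {
    stop(sprintf(
      "event schedule cannot fit: %.1f s of movement alone vs %.1f s available",
      sum(base_dur), run_len))
  }
  rs <- seed_chain(seed, run_index, 101L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rs)
  for (attempt in seq_len(100L)) {
    ord <- sample.int(n)
    trials <- trials0[ord, ]
    jit <- stats::runif(n, -spec$duration_jitter_frac, spec$duration_jitter_frac)
    duration <- (trials$amplitude_frac / trials$velocity_frac) * (1 + jit)
    iti <- stats::runif(n, spec$iti_mean_s - spec$iti_halfrange_s,
                        spec$iti_mean_s + spec$iti_halfrange_s)
    # first ITI is the lead-in before the first trial
    onset <- cumsum(iti) + cumsum(c(0, duration[-n]))
    if (onset[n] + duration[n] < run_len) {
      ev <- data.frame(onset = onset, duration = duration,
                       trial_type = trials$trial_type,
                       amplitude = trials$amplitude, velocity = trials$velocity,
                       direction = trials$direction,
                       amplitude_frac = trials$amplitude_frac,
                       velocity_frac = trials$velocity_frac,
                       stringsAsFactors = FALSE)
      rownames(ev) <- NULL
      class(ev) <- c("event_table", "data.frame")
      return(ev)
    }
  }
  stop(sprintf(
    "event schedule overflow: ~%.1f s required (events + intervals) vs %.1f s available",
    sum(base_dur) + n * spec$iti_mean_s, run_len))
}

# save/restore the global RNG state so generators are pure in (spec, seed)
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write / read a BIDS-style events table
#'
#' Tab-separated with `onset`, `duration`, `trial_type` first, extra kinematic
#' columns preserved.
#'
#' @param events an `event_table` data.frame.
#' @param path file path (`*_events.tsv`).
#' @return `write_events` returns `path` invisibly; `read_events` returns the
#'   `event_table`.
#' @export
write_events <- function(events, path) {
  first <- c("onset", "duration", "trial_type")
  rest <- setdiff(names(events), first)
  utils::write.table(events[, c(first, rest)], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Ground-truth effect specification for the BOLD simulator
#'
#' Controls the condition effects injected into simulated runs:
#' * `univariate_gain`: named multiplier of the mean BOLD response per
#'   condition (`trial_type` label); unnamed scalar recycles to all
#'   conditions. A mean shift every voxel in `pattern_region` shares.
#' * `pattern_strength`: scale of zero-mean, condition-specific multivoxel
#'   patterns confined to `pattern_region`. Patterns carry condition
#'   information in the spatial configuration while leaving the region-mean
#'   response unchanged -- the multivariate-only signal.
#' * `duration_scaling`: if `TRUE`, the neural epoch lasts as long as the
#'   trial (activity scales with time-on-task); if `FALSE` it is a fixed
#'   `fixed_neural_duration_s` epoch regardless of trial duration.
#' * AR(1) noise (`noise_ar1`, `noise_sd`, marginal SD), slow cosine drift
#'   (`drift_amp`, periods 256 s and 384 s, beyond the 128 s high-pass
#'   cutoff), and a constant `baseline` that makes implicit masking by
#'   global-signal fraction meaningful.
#'
#' @param univariate_gain scalar or named numeric by `trial_type`.
#' @param pattern_strength scalar (0 disables patterns).
#' @param pattern_region integer vector of linear voxel indices into the grid.
#' @param duration_scaling logical.
#' @param fixed_neural_duration_s epoch length in the non-scaling scenario;
#'   shorter than the shortest trial so the two scenarios are distinguishable.
#' @param noise_ar1,noise_sd AR(1) coefficient and marginal noise SD.
#' @param drift_amp amplitude of each of the two cosine drift components.
#' @param baseline constant signal offset.
#' @param shared_pattern if `TRUE`, [make_dataset()] gives every subject the
#'   same pattern (patterns generalise across subjects); default `FALSE`
#'   gives each subject a unique random pattern orientation.
#' @param region_gain optional named numeric (by `trial_type`): an additive
#'   response amplitude applied uniformly to every voxel of
#'   `pattern_region` -- a spatially consistent (univariate) condition
#'   effect confined to the region, as opposed to the zero-mean patterns.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(univariate_gain = 1, pattern_strength = 0,
                        pattern_region = integer(0), duration_scaling = TRUE,
                        fixed_neural_duration_s = 0.5,
                        noise_ar1 = 0.3, noise_sd = 1, drift_amp = 1,
                        baseline = 100, shared_pattern = FALSE,
                        region_gain = NULL) {
  stopifnot(noise_ar1 >= 0, noise_ar1 < 1, noise_sd >= 0,
            pattern_strength >= 0, fixed_neural_duration_s > 0)
  structure(list(univariate_gain = univariate_gain,
                 pattern_strength = pattern_strength,
                 pattern_region = as.integer(pattern_region),
                 duration_scaling = isTRUE(duration_scaling),
                 fixed_neural_duration_s = fixed_neural_duration_s,
                 noise_ar1 = noise_ar1, noise_sd = noise_sd,
                 drift_amp = drift_amp, baseline = baseline,
                 shared_pattern = isTRUE(shared_pattern),
                 region_gain = region_gain),
            class = "effect_spec")
}

#' Zero-mean condition patterns over a voxel region
#'
#' One independent standard-normal pattern vector per condition, centred to
#' mean zero across the region (so the region-average signal carries no
#' condition information; expected pairwise correlation between conditions is
#' zero).
#'
#' @param trial_types character vector of condition labels.
#' @param region integer voxel indices.
#' @param seed integer seed.
#' @return Matrix `length(trial_types) x length(region)` with row names.
#' @export
condition_patterns <- function(trial_types, region, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed_chain(seed, 202L))
  p <- matrix(stats::rnorm(length(trial_types) * length(region)),
              nrow = length(trial_types))
  p <- p - rowMeans(p)
  rownames(p) <- trial_types
  p
}
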