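#' Discrete-cosine high-pass basis
#'
#' Non-constant discrete cosine transform functions used as nuisance
#' regressors to remove slow drifts with periods longer than `cutoff_s`.
#' `K = ceiling(2 * n_scans * tr_s / cutoff_s)` cosines of orders `1..K` are
#' returned (the order-0 constant is left to the model intercept); the
#' highest-order cosine may sit marginally past the nominal cutoff
#' frequency, so the filter never under-covers the band it is asked to
#' remove. An infinite cutoff disables filtering (zero columns).
#'
#' @param n_scans number of volumes.
#' @param tr_s repetition time (s).
#' @param cutoff_s high-pass cutoff period (default 128 s); `Inf` disables
#'   filtering (zero columns).
#' @return Matrix `n_scans x K`, columns named `dct_1 ... dct_K`, orthonormal
#'   and orthogonal to the constant.
#' @examples
#' ncol(dct_highpass_basis(400, 2))  # 13
#' @export
dct_highpass_basis <- function(n_scans, tr_s, cutoff_s = 128) {
  stopifnot(cutoff_s > 2 * tr_s)
  K <- if (is.finite(cutoff_s)) ceiling(2 * n_scans * tr_s / cutoff_s) else 0L
  K <- max(0L, min(K, n_scans - 1L))
  if (K == 0L) {
    m <- matrix(numeric(0), nrow = n_scans, ncol = 0)
    return(m)
  }
  t <- seq_len(n_scans) - 0.5
  B <- sapply(seq_len(K), function(k) {
    sqrt(2 / n_scans) * cos(pi * k * t / n_scans)
  })
  colnames(B) <- paste0("dct_", seq_len(K))
  B
}

#' Implicit analysis mask from the global signal
#'
#' A voxel enters the mask iff its temporal mean exceeds `fraction` of the
#' global signal, defined here as the grand mean over all voxels and time
#' points of the run. This liberal threshold keeps low-signal edge voxels
#' available to the model; spurious inclusions are expected to be removed at
#' the group level by explicit masking.
#'
#' @param bold a `bold_run`.
#' @param fraction fraction of the global signal (default 0.1).
#' @return Logical 3-D array over the grid.
#' @export
implicit_mask <- function(bold, fraction = 0.1) {
  stopifnot(fraction > 0, fraction < 1)
  d <- dim(bold$data)
  n_scans <- d[4]
  m <- array(rowMeans(matrix(bold$data, ncol = n_scans)), dim = d[1:3])
  global <- mean(m)
  mask <- m > fraction * global
  if (!any(mask)) stop("implicit mask is empty: no voxel exceeds ",
                       fraction, " of the global signal")
  mask
}

#' Build a run-wise first-level design matrix
#'
#' One constant regressor per factorial combination plus duration parametric
#' modulators, HRF-convolved at microtime resolution and sampled at scan
#' times:
#' * `epoch_mode = "constant_mean_duration"` (the duration-controlled model):
#'   every condition's boxcars use the mean stimulus duration across all
#'   trials of the run. `model = "full_interaction"` adds one duration
#'   modulator per condition, heights the trial durations centred within
#'   that condition and run (centring applied before convolution), allowing
#'   the duration response to differ across conditions while keeping each
#'   (constant, modulator) pair well conditioned; `model =
#'   "non_interaction"` adds a single modulator over all trials, centred on
#'   the run grand mean, so between-condition duration differences are
#'   credited to the modulator rather than to the condition betas.
#' * `epoch_mode = "variable_epoch"`: each trial's boxcar carries its own
#'   duration and no modulators are added (duration lives in the epochs).
#'
#' Motion nuisance columns, the discrete-cosine high-pass set and an
#' intercept are appended unconvolved.
#'
#' @param events `event_table` for the run.
#' @param n_scans,tr_s scan count and repetition time.
#' @param model `"full_interaction"` or `"non_interaction"`.
#' @param epoch_mode `"constant_mean_duration"` or `"variable_epoch"`.
#' @param nuisance optional matrix of nuisance time courses (e.g. 6 motion
#'   parameters), `n_scans` rows.
#' @param highpass_cutoff_s DCT cutoff; `NULL` or `Inf` to omit.
#' @param hrf [hrf_params()].
#' @param conditions optional `spec_conditions()` table fixing the expected
#'   set and order of combinations; defaults to the conditions present in
#'   `events` (canonical label sort). An empty condition cell is an error.
#' @return A list of class `design_matrix`: `values` (n_scans x p),
#'   `column_names`, `task_columns`, `modulator_columns`, `nuisance_columns`
#'   (DCT + motion + intercept).
#' @examples
#' ev <- sample_events(experiment_spec("exp2"), 1, seed = 1)
#' X <- build_design_matrix(ev, 306, 2)
#' length(c(X$task_columns, X$modulator_columns))  # 16
#' @export
build_design_matrix <- function(events, n_scans, tr_s,
                                model = c("full_interaction", "non_interaction"),
                                epoch_mode = c("constant_mean_duration", "variable_epoch"),
                                nuisance = NULL, highpass_cutoff_s = 128,
                                hrf = hrf_params(), conditions = NULL) {
  model <- match.arg(model)
  epoch_mode <- match.arg(epoch_mode)
  if (max(events$onset + events$duration) > n_scans * tr_s)
    stop("events extend beyond the run: last event ends at ",
         round(max(events$onset + events$duration), 1), " s vs ",
         n_scans * tr_s, " s scanned")
  types <- if (!is.null(conditions)) conditions$trial_type
           else sort(unique(events$trial_type))
  missing <- setdiff(types, unique(events$trial_type))
  if (length(missing))
    stop("empty condition cell(s): ", paste(missing, collapse = ", "))

  res <- hrf$microtime_resolution
  dbar <- mean(events$duration)
  cols <- list(); names_task <- character(0)
  for (tt in types) {
    i <- events$trial_type == tt
    dur <- if (epoch_mode == "variable_epoch") events$duration[i]
           else rep(dbar, sum(i))
    cols[[length(cols) + 1L]] <-
      microtime_train(events$onset[i], dur, rep(1, sum(i)), n_scans, tr_s, res)
    names_task <- c(names_task, tt)
  }
  n_task <- length(cols)
  names_mod <- character(0)
  if (epoch_mode == "constant_mean_duration") {
    if (model == "full_interaction") {
      for (tt in types) {
        i <- events$trial_type == tt
        centred <- events$duration[i] - mean(events$duration[i])
        cols[[length(cols) + 1L]] <-
          microtime_train(events$onset[i], rep(dbar, sum(i)), centred,
                          n_scans, tr_s, res)
        names_mod <- c(names_mod, paste0(tt, "_xdur"))
      }
    } else {
      cols[[length(cols) + 1L]] <-
        microtime_train(events$onset, rep(dbar, nrow(events)),
                        events$duration - dbar, n_scans, tr_s, res)
      names_mod <- "all_xdur"
    }
  }
  U <- do.call(cbind, cols)
  Xtask <- convolve_regressors(U, n_scans, tr_s, hrf)

  extra <- list(); names_nuis <- character(0)
  if (!is.null(highpass_cutoff_s) && is.finite(highpass_cutoff_s)) {
    B <- dct_highpass_basis(n_scans, tr_s, highpass_cutoff_s)
    if (ncol(B) > 0) { extra$dct <- B; names_nuis <- c(names_nuis, colnames(B)) }
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == n_scans)
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuis_", seq_len(ncol(nuisance)))
    extra$nuis <- nuisance
    names_nuis <- c(names_nuis, colnames(nuisance))
  }
  extra$icpt <- matrix(1, n_scans, 1)
  names_nuis <- c(names_nuis, "intercept")

  X <- cbind(Xtask, do.call(cbind, extra))
  cn <- c(names_task, names_mod, names_nuis)
  if (anyDuplicated(cn)) stop("duplicate design-matrix column names")
  colnames(X) <- cn
  structure(list(values = X, column_names = cn,
                 task_columns = seq_len(n_task),
                 modulator_columns = n_task + seq_along(names_mod),
                 nuisance_columns = n_task + length(names_mod) + seq_along(names_nuis)),
            class = "design_matrix")
}

#' Export a design matrix as TSV
#'
#' @param design a `design_matrix`.
#' @param path output path.
#' @export
write_design_matrix <- function(design, path) {
  utils::write.table(design$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
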