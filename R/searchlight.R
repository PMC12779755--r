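#' Integer voxel offsets of a searchlight sphere
#'
#' All integer grid offsets whose centre-to-centre Euclidean distance is at
#' most `radius_mm` (inclusive comparison -- this convention yields 81 voxels
#' for an 8 mm radius and 19 voxels for 5 mm on a 3 mm grid). The set always
#' contains the origin and is symmetric under sign flips of any axis.
#'
#' @param radius_mm sphere radius in millimetres.
#' @param voxel_mm isotropic voxel edge in millimetres.
#' @return A list of class `sphere_offsets`: `offsets` (n x 3 integer
#'   matrix), `radius_mm`, `voxel_mm`.
#' @examples
#' nrow(sphere_offsets(8, 3)$offsets)  # 81
#' @export
sphere_offsets <- function(radius_mm, voxel_mm) {
  stopifnot(radius_mm > 0, voxel_mm > 0)
  r <- floor(radius_mm / voxel_mm)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  keep <- sqrt(rowSums(g^2)) * voxel_mm <= radius_mm
  structure(list(offsets = g[keep, , drop = FALSE],
                 radius_mm = radius_mm, voxel_mm = voxel_mm),
            class = "sphere_offsets")
}

#' Linear-SVM classifier configuration
#'
#' @param C regularisation parameter (default 1).
#' @param scaling `"none"` or `"minmax01"` -- per-feature min-max scaling to
#'   `[0, 1]` estimated on the training folds only and applied to the test
#'   fold, preserving train/test independence.
#' @return A list of class `classifier_config` (`kernel` fixed to linear,
#'   `cv` to leave-one-run-out).
#' @export
classifier_config <- function(C = 1, scaling = c("none", "minmax01")) {
  stopifnot(C > 0)
  structure(list(kernel = "linear", C = C, scaling = match.arg(scaling),
                 cv = "leave_one_run_out"),
            class = "classifier_config")
}

minmax_train_apply <- function(train, test) {
  lo <- apply(train, 2, min); hi <- apply(train, 2, max)
  rg <- hi - lo; rg[rg == 0] <- 1
  list(train = sweep(sweep(train, 2, lo), 2, rg, "/"),
       test = sweep(sweep(test, 2, lo), 2, rg, "/"))
}

#' Leave-one-run-out cross-validated SVM accuracy
#'
#' Per fold, a linear support-vector machine (one-vs-one voting for more
#' than two classes) is trained on all runs but one and tested on the
#' held-out run. Fold accuracies are averaged; the confusion matrix pools
#' test predictions across folds and is row-normalised to percent (rows =
#' true labels).
#'
#' @param samples numeric matrix, samples x features.
#' @param labels class label per sample.
#' @param run_ids run (fold) id per sample; every label must appear in every
#'   run.
#' @param config a [classifier_config()].
#' @return A list of class `cv_result`: `accuracy` (mean fold accuracy, %),
#'   `confusion` (k x k, rows sum to 100), `chance` (%), `n_folds`.
#' @export
loro_cv_accuracy <- function(samples, labels, run_ids, config = classifier_config()) {
  samples <- as.matrix(samples)
  labels <- as.character(labels)
  runs <- sort(unique(run_ids))
  if (length(runs) < 2) stop("leave-one-run-out needs at least 2 runs")
  classes <- sort(unique(labels))
  tab <- table(run_ids, labels)
  if (any(tab == 0))
    stop("label(s) missing from a run: every class must appear in every fold")
  conf <- matrix(0, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  acc <- numeric(length(runs))
  for (f in seq_along(runs)) {
    te <- run_ids == runs[f]
    xtr <- samples[!te, , drop = FALSE]; xte <- samples[te, , drop = FALSE]
    if (config$scaling == "minmax01") {
      sc <- minmax_train_apply(xtr, xte)
      xtr <- sc$train; xte <- sc$test
    }
    fit <- e1071::svm(x = xtr, y = factor(labels[!te], levels = classes),
                      kernel = "linear", cost = config$C, scale = FALSE)
    pred <- as.character(stats::predict(fit, xte))
    truth <- labels[te]
    acc[f] <- 100 * mean(pred == truth)
    for (i in seq_along(pred)) conf[truth[i], pred[i]] <- conf[truth[i], pred[i]] + 1
  }
  conf <- 100 * conf / rowSums(conf)
  structure(list(accuracy = mean(acc), confusion = conf,
                 chance = 100 / length(classes), n_folds = length(runs)),
            class = "cv_result")
}

#' Searchlight map of cross-validated accuracy minus chance
#'
#' For every in-mask centre voxel, [loro_cv_accuracy()] is run on the
#' in-mask voxels inside the sphere (spheres are clipped at the mask
#' boundary) and `accuracy - chance` is assigned to the centre.
#'
#' @param stack a [beta_stack()].
#' @param labels class label per stack sample (see [feature_labels()]).
#' @param offsets a [sphere_offsets()].
#' @param config a [classifier_config()].
#' @return A list of class `accuracy_map`: `values` (3-D array of accuracy
#'   minus chance in percent, `NA` outside the mask), `chance` (%),
#'   `n_folds`, `affine`.
#' @export
searchlight_map <- function(stack, labels, offsets = sphere_offsets(8, 3),
                            config = classifier_config()) {
  dims <- stack$grid_dims
  if (is.null(dims)) stop("beta stack carries no grid geometry")
  nv <- prod(dims)
  in_mask <- logical(nv); in_mask[stack$voxel_index] <- TRUE
  col_of <- integer(nv); col_of[stack$voxel_index] <- seq_along(stack$voxel_index)
  ijk <- arrayInd(stack$voxel_index, dims)
  off <- offsets$offsets
  values <- array(NA_real_, dims)
  chance <- 100 / length(unique(labels))
  nf <- length(unique(stack$run))
  for (v in seq_along(stack$voxel_index)) {
    nb <- sweep(off, 2, ijk[v, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- (nb[ok, 3] - 1L) * dims[1] * dims[2] + (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    lin <- lin[in_mask[lin]]
    cols <- col_of[lin]
    cv <- loro_cv_accuracy(stack$samples[, cols, drop = FALSE], labels,
                           stack$run, config)
    values[stack$voxel_index[v]] <- cv$accuracy - chance
  }
  structure(list(values = values, chance = chance, n_folds = nf,
                 affine = stack$affine),
            class = "accuracy_map")
}
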