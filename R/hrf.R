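#' Canonical haemodynamic response function parameters
#'
#' The canonical double-gamma HRF: a gamma-density peak minus a scaled
#' gamma-density undershoot. Defaults are the standard canonical settings
#' (peak delay 6 s, undershoot delay 16 s, unit dispersions, peak:undershoot
#' ratio 6, 32 s kernel) used throughout event-related fMRI modelling.
#'
#' @param peak_delay_s,undershoot_delay_s gamma delays (shape = delay /
#'   dispersion).
#' @param peak_dispersion,undershoot_dispersion gamma scales in seconds.
#' @param peak_to_undershoot_ratio relative weight of the undershoot.
#' @param kernel_length_s truncation of the sampled kernel.
#' @param microtime_resolution time bins per TR used for convolution.
#' @return A list of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       peak_to_undershoot_ratio = 6,
                       kernel_length_s = 32, microtime_resolution = 16L) {
  p <- list(peak_delay_s = peak_delay_s,
            undershoot_delay_s = undershoot_delay_s,
            peak_dispersion = peak_dispersion,
            undershoot_dispersion = undershoot_dispersion,
            peak_to_undershoot_ratio = peak_to_undershoot_ratio,
            kernel_length_s = kernel_length_s,
            microtime_resolution = as.integer(microtime_resolution))
  stopifnot(all(unlist(p) > 0))
  structure(p, class = "hrf_params")
}

#' Sample the canonical double-gamma HRF kernel
#'
#' Difference of two gamma densities sampled on the microtime grid
#' `dt = tr_s / microtime_resolution` and truncated at `kernel_length_s`.
#' The kernel is normalised to unit sum so convolution preserves the scale of
#' a sustained input; it is exactly zero at t = 0 (both gamma shapes exceed
#' one).
#'
#' @param params an [hrf_params()].
#' @param tr_s repetition time in seconds.
#' @param dt optional explicit sampling step (overrides `tr_s /
#'   microtime_resolution`), used for dense numerical checks.
#' @return Numeric kernel sampled at `t = 0, dt, 2 dt, ...`, with attribute
#'   `dt`.
#' @examples
#' k <- canonical_hrf(hrf_params(), tr_s = 2)
#' k[1] == 0
#' @export
canonical_hrf <- function(params = hrf_params(), tr_s = 2, dt = NULL) {
  if (is.null(dt)) dt <- tr_s / params$microtime_resolution
  t <- seq(0, params$kernel_length_s, by = dt)
  peak <- stats::dgamma(t, shape = params$peak_delay_s / params$peak_dispersion,
                        scale = params$peak_dispersion)
  under <- stats::dgamma(t, shape = params$undershoot_delay_s / params$undershoot_dispersion,
                         scale = params$undershoot_dispersion)
  k <- peak - under / params$peak_to_undershoot_ratio
  k <- k / sum(k)
  attr(k, "dt") <- dt
  k
}
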