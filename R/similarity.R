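#' Signal correlation between two response traces
#'
#' Responses sampled at `sampling_rate_hz` are averaged within
#' non-overlapping bins of `bin_ms` milliseconds per trial, the binned
#' trials are concatenated, and the Pearson correlation is returned. For
#' single-trial (deterministic model) responses pass one trial.
#'
#' @param a,b Numeric matrices (trials x timepoints) or vectors (one
#'   trial) on a common time base.
#' @param sampling_rate_hz Sampling rate of the traces.
#' @param bin_ms Bin width in milliseconds (default 500).
#' @return Pearson correlation in `[-1, 1]`, or `NA` if either binned
#'   trace has zero variance.
#' @export
signal_correlation <- function(a, b, sampling_rate_hz, bin_ms = 500) {
  ba <- bin_trace(a, sampling_rate_hz, bin_ms)
  bb <- bin_trace(b, sampling_rate_hz, bin_ms)
  if (length(ba) != length(bb)) stop("traces are not on the same time base",
                                     call. = FALSE)
  if (length(ba) < 2L) stop("need at least 2 bins", call. = FALSE)
  if (stats::sd(ba) == 0 || stats::sd(bb) == 0) return(NA_real_)
  stats::cor(ba, bb)
}

#' Bin a response trace into fixed-width time bins
#'
#' @inheritParams signal_correlation
#' @param x Vector (one trial) or matrix (trials x timepoints).
#' @return Vector of per-bin means, trials concatenated. A trailing
#'   partial bin is dropped.
#' @export
bin_trace <- function(x, sampling_rate_hz, bin_ms = 500) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  per_bin <- max(1L, round(sampling_rate_hz * bin_ms / 1000))
  n_bins <- floor(ncol(x) / per_bin)
  if (n_bins < 1L) stop("trace shorter than one bin", call. = FALSE)
  idx <- rep(seq_len(n_bins), each = per_bin)
  out <- apply(x[, seq_len(n_bins * per_bin), drop = FALSE], 1L,
               function(row) as.numeric(tapply(row, idx, mean)))
  as.numeric(out)  # column-major: trial after trial
}

#' Trial-to-trial reliability ceiling (CCmax)
#'
#' The upper bound of the correlation achievable between a neuron's
#' responses and any deterministic prediction, estimated from N repeated
#' trials as `sqrt((N * Var(ybar) - mean(Var(y))) / ((N - 1) * Var(ybar)))`
#' where `Var(ybar)` is the variance over time of the trial-averaged
#' response and `mean(Var(y))` the mean over time of the across-trial
#' variance. A negative radicand (noise-dominated neuron) is clipped to
#' 0; sampling fluctuation can push the radicand slightly above one
#' (the finite-N estimator carries an `N/(N-1)` factor), so the result
#' is also capped at 1.
#'
#' @param trials Numeric matrix, trials x timepoints (N >= 2 rows).
#' @return CCmax in `[0, 1]`, or `NA` if the trial mean has zero variance.
#' @export
cc_max <- function(trials) {
  trials <- as.matrix(trials)
  n <- nrow(trials)
  if (n < 2L) stop("need at least 2 trials", call. = FALSE)
  var_mean <- stats::var(colMeans(trials))
  if (!is.finite(var_mean) || var_mean == 0) return(NA_real_)
  mean_var <- mean(apply(trials, 2L, stats::var))
  rad <- (n * var_mean - mean_var) / ((n - 1) * var_mean)
  sqrt(min(1, max(0, rad)))
}

#' Prediction performance (CCabs)
#'
#' Pearson correlation between a model prediction and the trial-averaged
#' observed response: `Cov(x, y) / sqrt(Var(x) Var(y))`.
#'
#' @param pred Predicted trace.
#' @param obs Observed trace, either a vector (already trial-averaged) or
#'   a trials x timepoints matrix (averaged here).
#' @return Correlation in `[-1, 1]`, or `NA` for zero-variance input.
#' @export
cc_abs <- function(pred, obs) {
  if (!is.null(dim(obs))) obs <- colMeans(as.matrix(obs))
  if (length(pred) != length(obs) || length(pred) < 2L) {
    stop("`pred` and `obs` must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(NA_real_)
  stats::cor(pred, obs)
}

#' Feature-weight similarity (cosine)
#'
#' Cosine similarity between two readout feature-weight vectors -- the
#' "what" component of a neuron's tuning.
#'
#' @param w_a,w_b Numeric vectors of equal dimension with nonzero norm.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
feature_similarity <- function(w_a, w_b) {
  if (length(w_a) != length(w_b)) stop("dimension mismatch", call. = FALSE)
  na <- sqrt(sum(w_a^2)); nb <- sqrt(sum(w_b^2))
  if (na == 0 || nb == 0) stop("zero feature vector", call. = FALSE)
  sum(w_a * w_b) / (na * nb)
}

#' Receptive-field center distance in visual degrees
#'
#' Given two readout locations on the monitor (cm, monitor coordinates
#' with origin at the monitor center), returns the angle between the two
#' eye-to-point rays, with the eye on the monitor normal through its
#' center at `distance_cm` (default 15 cm).
#'
#' @param p_a,p_b Length-2 numeric vectors, monitor coordinates in cm.
#' @param distance_cm Eye-to-monitor distance (default 15).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rf_center_distance <- function(p_a, p_b, distance_cm = 15) {
  stopifnot(length(p_a) == 2L, length(p_b) == 2L, distance_cm > 0)
  ra <- c(p_a, distance_cm); rb <- c(p_b, distance_cm)
  cosang <- sum(ra * rb) / (sqrt(sum(ra^2)) * sqrt(sum(rb^2)))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Difference in preferred orientation
#'
#' Circular distance between two orientations on the 180-degree-periodic
#' orientation circle.
#'
#' @param o_a,o_b Orientations in degrees, `[0, 180)`.
#' @return Difference in degrees, `[0, 90]`.
#' @export
delta_orientation <- function(o_a, o_b) {
  d <- abs(o_a - o_b) %% 180
  pmin(d, 180 - d)
}
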