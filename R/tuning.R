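#' Direction tuning curve
#'
#' Mean responses to a set of equally spaced motion directions, averaged
#' across stimulus blocks.
#'
#' @param directions_deg Directions in degrees, typically 16 values
#'   equally spaced over `[0, 360)`.
#' @param responses Mean response per direction (same length).
#' @return Object of class `tuning_curve`.
#' @export
tuning_curve <- function(directions_deg, responses) {
  if (length(directions_deg) != length(responses)) {
    stop("directions and responses must have equal length", call. = FALSE)
  }
  if (any(!is.finite(responses))) stop("non-finite responses", call. = FALSE)
  structure(list(directions_deg = directions_deg, responses = responses),
            class = "tuning_curve")
}

#' Global orientation selectivity index (gOSI)
#'
#' Vector-sum selectivity: `|sum R_theta * exp(2i*theta)| / sum R_theta`
#' with theta in radians. Zero for flat curves, one when a single
#' direction carries all the response; invariant to uniform rescaling.
#'
#' @param curve A [tuning_curve()].
#' @return gOSI in `[0, 1]`, or `NA` if the summed response is not
#'   positive.
#' @export
gosi <- function(curve) {
  stopifnot(inherits(curve, "tuning_curve"))
  r <- curve$responses
  s <- sum(r)
  if (s <= 0) return(NA_real_)
  th <- curve$directions_deg * pi / 180
  Mod(sum(r * exp(2i * th))) / s
}

#' Orientation selectivity index (OSI)
#'
#' `(R_po - R_ortho) / (R_po + R_ortho)` where `R_po` is the mean response
#' at the preferred orientation and `R_ortho` at the orthogonal
#' orientation; each orientation pools its two opposite directions. The
#' preferred orientation is taken from a fitted tuning curve when
#' supplied, else from the orientation with the largest pooled response.
#'
#' @param curve A [tuning_curve()].
#' @param preferred_deg Optional preferred orientation in `[0, 180)`
#'   (e.g. from [fit_von_mises()]); directions are matched to the nearest
#'   orientation on the grid.
#' @return OSI in `[-1, 1]`.
#' @export
osi <- function(curve, preferred_deg = NULL) {
  stopifnot(inherits(curve, "tuning_curve"))
  ori <- curve$directions_deg %% 180
  levels <- sort(unique(ori))
  pooled <- vapply(levels, function(o) mean(curve$responses[ori == o]),
                   numeric(1))
  if (is.null(preferred_deg)) {
    po <- levels[which.max(pooled)]
  } else {
    d <- delta_orientation(levels, preferred_deg)
    po <- levels[which.min(d)]
  }
  ortho <- levels[which.min(delta_orientation(levels, (po + 90) %% 180))]
  r_po <- pooled[match(po, levels)]
  r_or <- pooled[match(ortho, levels)]
  if (r_po + r_or == 0) return(NA_real_)
  (r_po - r_or) / (r_po + r_or)
}

#' Bimodal von Mises tuning function with offset
#'
#' `f(theta) = (1 / (2*pi*I0(kappa))) * (p * exp(kappa*cos(theta - mu)) +
#' (1 - p) * exp(-kappa*cos(theta - mu))) + b`: two peaks 180 degrees
#' apart with relative height `p` (0.5 = symmetric), concentration
#' `kappa`, preferred direction `mu` and offset `b`.
#'
#' @param theta_deg Directions in degrees.
#' @param mu Preferred direction (deg).
#' @param kappa Concentration (>= 0).
#' @param p Peak balance in `[0, 1]`.
#' @param b Offset.
#' @param amplitude Optional multiplicative response gain (default 1).
#' @return Function values.
#' @export
von_mises_curve <- function(theta_deg, mu, kappa, p, b, amplitude = 1) {
  th <- (theta_deg - mu) * pi / 180
  # exponentially scaled Bessel keeps large kappa finite:
  # exp(k cos)/(2 pi I0(k)) = exp(k (cos - 1)) / (2 pi I0(k) exp(-k))
  i0s <- besselI(kappa, 0, expon.scaled = TRUE)
  amplitude * (p * exp(kappa * (cos(th) - 1)) +
                 (1 - p) * exp(-kappa * (cos(th) + 1))) /
    (2 * pi * i0s) + b
}

#' Fit the bimodal von Mises tuning function by least squares
#'
#' Minimizes squared error over `(mu, kappa, p, b, amplitude)` with
#' multi-start: 8 equally spaced starting values of `mu`, box constraints
#' `kappa` in `[0, 20]`, `p` in `[0, 1]`. The preferred orientation is
#' `mu mod 180`. Near-flat curves (no concentration) are flagged
#' degenerate since `mu` is unidentifiable there.
#'
#' @param curve A [tuning_curve()].
#' @param n_starts Number of equally spaced `mu` starting points.
#' @return Object of class `von_mises_fit` with fields `mu`, `kappa`,
#'   `p`, `b`, `amplitude`, `preferred_orientation`, `sse`, `r_squared`,
#'   `degenerate`, `converged`.
#' @export
fit_von_mises <- function(curve, n_starts = 8L) {
  stopifnot(inherits(curve, "tuning_curve"))
  th <- curve$directions_deg
  r <- curve$responses
  obj <- function(par) {
    sum((r - von_mises_curve(th, par[1], par[2], par[3], par[4], par[5]))^2)
  }
  amp0 <- max(stats::sd(r) * 2 * pi, 1e-6)
  best <- NULL
  for (mu0 in seq(0, 360 - 360 / n_starts, length.out = n_starts)) {
    fit <- tryCatch(
      stats::optim(c(mu0, 2, 0.7, min(r), amp0), obj, method = "L-BFGS-B",
                   lower = c(-360, 0, 0, -Inf, 1e-8),
                   upper = c(720, 20, 1, Inf, Inf)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE, degenerate = TRUE),
                     class = "von_mises_fit"))
  }
  par <- best$par
  sst <- sum((r - mean(r))^2)
  fitted <- von_mises_curve(th, par[1], par[2], par[3], par[4], par[5])
  r2 <- if (sst > 0) 1 - best$value / sst else NA_real_
  # kappa ~ 0 leaves mu unidentifiable; modulation below noise floor too
  degenerate <- par[2] < 1e-3 || (max(fitted) - min(fitted)) <
    1e-6 * max(1, abs(mean(r)))
  structure(list(mu = par[1] %% 360, kappa = par[2], p = par[3],
                 b = par[4], amplitude = par[5],
                 preferred_orientation = par[1] %% 180,
                 sse = best$value, r_squared = r2,
                 degenerate = degenerate,
                 converged = best$convergence == 0),
            class = "von_mises_fit")
}

#' @export
print.von_mises_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<von_mises_fit> failed to converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<von_mises_fit> mu = %.1f deg, kappa = %.2f, p = %.2f, b = %.3f; pref. orientation %.1f deg%s\n",
    x$mu, x$kappa, x$p, x$b, x$preferred_orientation,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
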