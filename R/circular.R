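#' Signed circular error between two orientations
#'
#' Minimal signed angular difference `reported - reference` on the full
#' 360-degree orientation circle, mapped to the half-open interval
#' (-180, 180]. The response space is the full circle (stimuli take one of
#' 360 possible orientations), so all wrapping uses period 360.
#'
#' @param reported,reference numeric vectors of orientations in degrees,
#'   each in `[0, 360)`. Recycled to a common length.
#' @return numeric vector of signed errors in degrees, in `(-180, 180]`.
#' @examples
#' circ_error(10, 350)   # 20
#' circ_error(0, 180)    # 180 (antipode maps to +180)
#' @export
circ_error <- function(reported, reference) {
  if (any(!is.finite(reported)) || any(!is.finite(reference)))
    stop("orientations must be finite", call. = FALSE)
  if (any(reported < 0 | reported >= 360) || any(reference < 0 | reference >= 360))
    stop("orientations must lie in [0, 360)", call. = FALSE)
  d <- (reported - reference) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Wrap arbitrary angles in degrees to (-180, 180]
#' @param x numeric vector of angles in degrees.
#' @return wrapped angles in `(-180, 180]`.
#' @export
wrap180 <- function(x) {
  d <- x %% 360
  ifelse(d > 180, d - 360, d)
}

#' von Mises density on the orientation circle
#'
#' Density (per radian) of the von Mises distribution, the circular analog
#' of the Gaussian, with mean direction `mu` and concentration `kappa`.
#' Angles are supplied in degrees and converted to radians internally;
#' the density integrates to 1 over one full cycle.
#'
#' @param error numeric vector, angles in degrees (typically signed errors
#'   in `(-180, 180]`).
#' @param mu mean direction in degrees (default 0).
#' @param kappa concentration parameter, `kappa >= 0`; `kappa = 0` gives
#'   the circular uniform density `1/(2*pi)`.
#' @return numeric vector of densities per radian.
#' @export
vonmises_density <- function(error, mu = 0, kappa) {
  if (length(kappa) != 1L || !is.finite(kappa) || kappa < 0)
    stop("kappa must be a single nonnegative number", call. = FALSE)
  x <- (error - mu) * pi / 180
  # exponentially-scaled Bessel avoids overflow at large kappa
  exp(kappa * (cos(x) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' @rdname sd_to_kappa
#' @export
kappa_to_sd <- function(kappa, sd_max = 100) {
  if (any(!is.finite(kappa)) || any(kappa < 0))
    stop("kappa must be nonnegative", call. = FALSE)
  r <- besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
  sd_deg <- ifelse(r <= 0, Inf, sqrt(-2 * log(r)) * 180 / pi)
  pmin(sd_deg, sd_max)
}

#' Convert between circular standard deviation and von Mises concentration
#'
#' The circular sd of a von Mises distribution with concentration
#' \eqn{\kappa} is \eqn{\sqrt{-2\ln(I_1(\kappa)/I_0(\kappa))}} radians;
#' `kappa_to_sd` evaluates it (in degrees), `sd_to_kappa` inverts it by
#' monotone bisection on \eqn{\log\kappa} over a fixed bracket
#' `[1e-6, 1e4]`. The map is strictly decreasing, so the inverse is unique.
#' `kappa = 0` corresponds to the circular uniform, whose sd is unbounded;
#' `kappa_to_sd` caps its output at `sd_max` so that bounded optimisation
#' has a finite box.
#'
#' @param sd circular standard deviation in degrees, `> 0`.
#' @param kappa concentration, `>= 0`.
#' @param sd_max cap (degrees) applied to the returned sd (default 100).
#' @return `sd_to_kappa`: concentration; `kappa_to_sd`: sd in degrees.
#' @export
sd_to_kappa <- function(sd) {
  if (any(!is.finite(sd)) || any(sd <= 0))
    stop("sd must be positive", call. = FALSE)
  vapply(sd, function(s) {
    s_rad <- s * pi / 180
    f <- function(logk) {
      k <- exp(logk)
      r <- besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
      sqrt(-2 * log(r)) - s_rad
    }
    lo <- log(1e-6); hi <- log(1e4)
    if (f(hi) > 0) return(1e4)   # sd smaller than achievable at kappa = 1e4
    if (f(lo) < 0) return(1e-6)  # sd larger than achievable at kappa = 1e-6
    uniroot(f, c(lo, hi), tol = 1e-12)$root |> exp()
  }, numeric(1))
}
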