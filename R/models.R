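#' Candidate mixture model specifications
#'
#' Six candidate models for the signed-error distribution of a
#' continuous-report trial with two temporally flanking distractors:
#' * `standard` — target von Mises component plus a uniform guessing
#'   component (free: `g`, `sd`).
#' * `swap` — adds a single substitution rate `beta` shared equally by
#'   the `m = 2` distractors (free: `g`, `beta`, `sd`).
#' * `two_misreport` — separate substitution rates `beta1` (preceding
#'   distractor) and `beta2` (succeeding distractor)
#'   (free: `g`, `beta1`, `beta2`, `sd`).
#' * `*_bias` — same, with the mean `mu` of the target von Mises
#'   component as an additional free parameter (the distractor
#'   components stay centred on the distractor orientations).
#'
#' All von Mises components share a single `sd`.
#'
#' @param name one of `"standard"`, `"swap"`, `"two_misreport"`,
#'   `"standard_bias"`, `"swap_bias"`, `"two_misreport_bias"`.
#' @return list with `name`, `n_free_params`, `m` (distractor count) and
#'   `bias` flag.
#' @export
model_spec <- function(name = c("standard", "swap", "two_misreport",
                                "standard_bias", "swap_bias",
                                "two_misreport_bias")) {
  name <- match.arg(name)
  base <- sub("_bias$", "", name)
  bias <- grepl("_bias$", name)
  k <- c(standard = 2L, swap = 3L, two_misreport = 4L)[[base]] + bias
  list(name = name, base = base, bias = bias, n_free_params = k, m = 2L)
}

#' @rdname mixture_density
#' @export
mixture_params <- function(g = 0, beta1 = 0, beta2 = 0, sd, mu = 0) {
  p <- list(g = g, beta1 = beta1, beta2 = beta2, sd = sd, mu = mu)
  validate_params(p)
  p
}

validate_params <- function(p) {
  with(p, {
    if (g < 0 || beta1 < 0 || beta2 < 0 || g + beta1 + beta2 > 1 + 1e-12)
      stop("mixture weights must be nonnegative with g + beta1 + beta2 <= 1",
           call. = FALSE)
    if (!is.finite(sd) || sd <= 0)
      stop("sd must be positive and finite", call. = FALSE)
  })
  invisible(p)
}

DENSITY_FLOOR <- 1e-300

#' Mixture-model densities over error triples
#'
#' Per-trial densities (per radian) of the candidate models, evaluated at
#' signed errors relative to the target (`theta`) and to the two
#' distractors (`theta1`, `theta2`), all in degrees.
#'
#' `two_misreport_density` implements
#' \deqn{(1-g-\beta_1-\beta_2)\,\varphi_\sigma(\theta-\mu) + g/2\pi
#'   + \beta_1\,\varphi_\sigma(\theta_1^*) + \beta_2\,\varphi_\sigma(\theta_2^*)}
#' `swap_density` pools the distractors with a single rate:
#' \deqn{(1-g-\beta)\,\varphi_\sigma(\theta-\mu) + g/2\pi
#'   + (\beta/m)\sum_i \varphi_\sigma(\theta_i^*)}
#' and `standard_density` keeps only the target and guess components.
#' The bias parameter `mu` shifts the target component only.
#'
#' @param theta,theta1,theta2 signed errors in degrees.
#' @param p parameter list from [mixture_params()]; `beta1 = beta2 =
#'   beta/2` expresses the swap model's shared rate.
#' @return numeric vector of densities (per radian).
#' @name mixture_density
NULL

#' @rdname mixture_density
#' @export
two_misreport_density <- function(theta, theta1, theta2, p) {
  validate_params(p)
  kappa <- sd_to_kappa(p$sd)
  w <- 1 - p$g - p$beta1 - p$beta2
  w * vonmises_density(theta, p$mu, kappa) +
    p$g / (2 * pi) +
    p$beta1 * vonmises_density(theta1, 0, kappa) +
    p$beta2 * vonmises_density(theta2, 0, kappa)
}

#' @rdname mixture_density
#' @export
standard_density <- function(theta, p) {
  validate_params(p)
  kappa <- sd_to_kappa(p$sd)
  (1 - p$g) * vonmises_density(theta, p$mu, kappa) + p$g / (2 * pi)
}

#' @rdname mixture_density
#' @param beta shared substitution rate, split equally across the `m = 2`
#'   distractors.
#' @export
swap_density <- function(theta, theta1, theta2, beta, p) {
  p2 <- p
  p2$beta1 <- p2$beta2 <- beta / 2
  two_misreport_density(theta, theta1, theta2, p2)
}

#' Log-likelihood of a mixture model on a set of trials
#'
#' Sum of log per-trial densities. Densities are floored at a tiny
#' positive constant so the log-likelihood is always finite.
#'
#' @param spec model specification from [model_spec()].
#' @param errors data frame with columns `theta` and (for models with
#'   distractor components) `theta1`, `theta2`.
#' @param p parameter list from [mixture_params()]; for swap models
#'   `beta1 = beta2 = beta/2`.
#' @return scalar log-likelihood.
#' @export
loglik <- function(spec, errors, p) {
  if (!nrow(errors)) stop("no trials supplied", call. = FALSE)
  dens <- switch(spec$base,
    standard = standard_density(errors$theta, p),
    swap = ,
    two_misreport = two_misreport_density(errors$theta, errors$theta1,
                                          errors$theta2, p))
  sum(log(pmax(dens, DENSITY_FLOOR)))
}

#' Target report rate implied by mixture weights
#'
#' The weight of the target-centred component, `1 - g - beta1 - beta2`.
#'
#' @param p parameter list from [mixture_params()].
#' @return scalar probability.
#' @export
target_report_rate <- function(p) {
  1 - p$g - p$beta1 - p$beta2
}
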