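# Run code under a temporary RNG state so seeded fits don't disturb the
# caller's random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

SD_MIN <- 0.25

# Transformed (unconstrained) coordinates: mixture weights through a
# multinomial logit anchored on the target component, sd through a scaled
# logit into [SD_MIN, sd_max], mu through a scaled logit into (-180, 180).
theta_to_params <- function(u, spec, sd_max) {
  nw <- switch(spec$base, standard = 1L, swap = 2L, two_misreport = 3L)
  a <- c(0, u[seq_len(nw)])
  w <- exp(a - max(a)); w <- w / sum(w)
  u_sd <- u[nw + 1L]
  sd <- SD_MIN + (sd_max - SD_MIN) * stats::plogis(u_sd)
  mu <- if (spec$bias) 360 * (stats::plogis(u[nw + 2L]) - 0.5) else 0
  p <- switch(spec$base,
    standard = mixture_params(g = w[2], sd = sd, mu = mu),
    swap = mixture_params(g = w[2], beta1 = w[3] / 2, beta2 = w[3] / 2,
                          sd = sd, mu = mu),
    two_misreport = mixture_params(g = w[2], beta1 = w[3], beta2 = w[4],
                                   sd = sd, mu = mu))
  if (spec$base == "swap") p$beta <- w[3]
  p
}

n_transformed <- function(spec) {
  switch(spec$base, standard = 1L, swap = 2L, two_misreport = 3L) +
    1L + as.integer(spec$bias)
}

# log prior: uniform over the weight simplex, Jeffreys 1/sigma on sd
# truncated to [SD_MIN, sd_max] (truncation enforced by the box), uniform mu.
log_prior <- function(p) -log(p$sd)

#' MAP fit of a mixture model to one cell of trials
#'
#' Maximises log-likelihood plus log-prior over the bounded parameter
#' space by multi-start quasi-Newton optimisation on unconstrained
#' coordinates (multinomial-logit weights, scaled-logit sd and bias).
#' Priors: uniform over the weight simplex, Jeffreys-type \eqn{1/\sigma}
#' on sd truncated to `[0.25, sd_max]` degrees, uniform bias. These are
#' weak enough that the MAP estimate is close to the MLE at typical cell
#' sizes.
#'
#' @param spec model specification from [model_spec()], or a model name.
#' @param errors data frame of signed errors (`theta`, `theta1`,
#'   `theta2`) in degrees for one participant-by-condition cell.
#' @param n_starts number of seeded random starts (default 20).
#' @param seed optional integer seed for the starts.
#' @param sd_max upper bound on sd in degrees (default 100).
#' @return list of class `maskmix_fit`: `model`, `params`, `loglik`,
#'   `logposterior`, `aicc`, `n_trials`, `n_starts`, `converged`.
#' @export
map_fit <- function(spec, errors, n_starts = 20, seed = NULL, sd_max = 100) {
  if (is.character(spec)) spec <- model_spec(spec)
  errors <- errors[!is.na(errors$theta), , drop = FALSE]
  n <- nrow(errors)
  if (n < 10) stop("need at least 10 trials to fit", call. = FALSE)
  if (spec$base != "standard" &&
      (any(is.na(errors$theta1)) || any(is.na(errors$theta2))))
    stop("distractor errors required for this model", call. = FALSE)

  negpost <- function(u) {
    p <- theta_to_params(u, spec, sd_max)
    -(loglik(spec, errors, p) + log_prior(p))
  }
  nw <- switch(spec$base, standard = 1L, swap = 2L, two_misreport = 3L)
  d <- n_transformed(spec)
  # start 1 is deterministic (small weights, sd 15 deg, zero bias); the
  # rest draw weights uniformly over the simplex (so boundary optima such
  # as pure guessing are reachable), sd log-uniform, bias near zero
  starts <- with_seed(seed, {
    s <- matrix(0, n_starts, d)
    s[1, ] <- c(rep(-2, nw), stats::qlogis((15 - SD_MIN) / (sd_max - SD_MIN)),
                if (spec$bias) 0)
    for (i in seq_len(n_starts)[-1]) {
      w <- stats::rexp(nw + 1L)          # Dirichlet(1) weights
      w <- w / sum(w)
      sd_i <- exp(stats::runif(1, log(2), log(80)))
      s[i, ] <- c(log(w[-1] / w[1]),
                  stats::qlogis((sd_i - SD_MIN) / (sd_max - SD_MIN)),
                  if (spec$bias) stats::rnorm(1, 0, 1))
    }
    s
  })
  best <- NULL
  n_ok <- 0L
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[i, ], negpost, method = "BFGS",
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("all optimisation starts failed (model ", spec$name, ", n = ", n, ")",
         call. = FALSE)
  p <- theta_to_params(best$par, spec, sd_max)
  ll <- loglik(spec, errors, p)
  structure(list(model = spec, params = p, loglik = ll,
                 logposterior = -best$value, aicc = aicc(ll, spec$n_free_params, n),
                 n_trials = n, n_starts = n_starts, converged = n_ok > 0L),
            class = "maskmix_fit")
}

#' @export
print.maskmix_fit <- function(x, ...) {
  cat("MAP fit:", x$model$name, " (n =", x$n_trials, "trials)\n")
  p <- x$params
  cat(sprintf("  g = %.3f  beta1 = %.3f  beta2 = %.3f  sd = %.1f deg",
              p$g, p$beta1, p$beta2, p$sd))
  if (x$model$bias) cat(sprintf("  mu = %.1f deg", p$mu))
  cat(sprintf("\n  logLik = %.2f  AICc = %.2f\n", x$loglik, x$aicc))
  invisible(x)
}

#' Small-sample-corrected Akaike information criterion
#'
#' \eqn{-2\ln L + 2k + 2k(k+1)/(n-k-1)}; penalises each additional model
#' parameter, with the correction term vanishing as \eqn{n} grows.
#'
#' @param loglik maximised log-likelihood.
#' @param k number of free parameters.
#' @param n number of observations; must exceed `k + 1`.
#' @return scalar AICc.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined for n <= k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit and compare candidate models by AICc
#'
#' Fits each candidate model to the same cell of trials and tabulates
#' AICc and the AICc difference relative to the two-misreport model
#' (positive differences favour two-misreport).
#'
#' @param errors data frame of signed errors for one cell.
#' @param models character vector of model names; must include
#'   `"two_misreport"`.
#' @param n_starts,seed,sd_max passed to [map_fit()]; each model gets a
#'   distinct deterministic sub-seed derived from `seed`.
#' @return data frame with one row per model: `model`, `k`, `loglik`,
#'   `aicc`, `delta_aicc`, `winner`; fits attached as attribute `fits`.
#' @export
compare_models <- function(errors,
                           models = c("two_misreport", "swap",
                                      "swap_bias", "two_misreport_bias"),
                           n_starts = 20, seed = NULL, sd_max = 100) {
  if (length(models) < 2) stop("need at least two models", call. = FALSE)
  if (!"two_misreport" %in% models)
    stop("comparison is anchored on the two_misreport model", call. = FALSE)
  fits <- lapply(seq_along(models), function(i) {
    s <- if (is.null(seed)) NULL else (seed + 1000L * i) %% .Machine$integer.max
    map_fit(models[i], errors, n_starts = n_starts, seed = s, sd_max = sd_max)
  })
  names(fits) <- models
  tab <- data.frame(model = models,
                    k = vapply(fits, function(f) f$model$n_free_params, integer(1)),
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    aicc = vapply(fits, `[[`, numeric(1), "aicc"))
  tab$delta_aicc <- tab$aicc - tab$aicc[tab$model == "two_misreport"]
  tab$winner <- tab$aicc == min(tab$aicc)
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}
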