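#' Draw von Mises random deviates
#'
#' Best–Fisher rejection sampler (wrapped-Cauchy envelope). For
#' `kappa < 1e-8` the distribution is indistinguishable from circular
#' uniform and is sampled as such.
#'
#' @param n number of deviates.
#' @param mu mean direction in degrees.
#' @param kappa concentration (`>= 0`).
#' @return angles in degrees, wrapped to `(-180, 180]` around `mu`'s frame
#'   (i.e. raw values `mu + noise`, not reduced to `[0, 360)`).
#' @export
rvonmises <- function(n, mu = 0, kappa) {
  stopifnot(kappa >= 0)
  if (kappa < 1e-8) return(mu + stats::runif(n, -180, 180))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    acc <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    th <- sign(u3[acc] - 0.5) * acos(pmax(pmin(f[acc], 1), -1))
    k <- length(th)
    out[got + seq_len(k)] <- th
    got <- got + k
  }
  mu + out * 180 / pi
}

#' Draw three pairwise-distinct stimulus orientations
#'
#' Integer orientations uniform on 0..359 for the first distractor, the
#' target and the second distractor, with the design constraint that all
#' three differ within a trial.
#'
#' @param n number of trials.
#' @return data frame with columns `d1_ori`, `target_ori`, `d2_ori`.
#' @export
draw_orientations <- function(n = 1) {
  out <- matrix(sample.int(360, 3 * n, replace = TRUE) - 1L, ncol = 3)
  bad <- which(out[, 1] == out[, 2] | out[, 1] == out[, 3] | out[, 2] == out[, 3])
  while (length(bad)) {
    out[bad, ] <- matrix(sample.int(360, 3 * length(bad), replace = TRUE) - 1L,
                         ncol = 3)
    bad <- bad[out[bad, 1] == out[bad, 2] | out[bad, 1] == out[bad, 3] |
                 out[bad, 2] == out[bad, 3]]
  }
  data.frame(d1_ori = out[, 1], target_ori = out[, 2], d2_ori = out[, 3])
}

#' Simulate continuous-report responses from the generative mixture
#'
#' Each trial's response comes from one of four components drawn with
#' probabilities `(1 - g - beta1 - beta2, g, beta1, beta2)`: a von Mises
#' centred on the target (shifted by `mu` for bias variants), a uniform
#' guess, or a von Mises centred on the first or second distractor. All
#' von Mises components share `sd`.
#'
#' @param oris data frame from [draw_orientations()] (columns `d1_ori`,
#'   `target_ori`, `d2_ori`; distractors may be `NA` when `beta1 = beta2
#'   = 0`, as on baseline trials).
#' @param p parameter list from [mixture_params()].
#' @return numeric vector of reported orientations in `[0, 360)`.
#' @export
generate_trial <- function(oris, p) {
  validate_params(p)
  n <- nrow(oris)
  kappa <- sd_to_kappa(p$sd)
  comp <- sample(4L, n, replace = TRUE,
                 prob = c(target_report_rate(p), p$g, p$beta1, p$beta2))
  centre <- rep(NA_real_, n)
  centre[comp == 1L] <- oris$target_ori[comp == 1L] + p$mu
  centre[comp == 3L] <- oris$d1_ori[comp == 3L]
  centre[comp == 4L] <- oris$d2_ori[comp == 4L]
  resp <- numeric(n)
  vm <- comp != 2L
  resp[vm] <- centre[vm] + rvonmises(sum(vm), 0, kappa)
  resp[!vm] <- stats::runif(sum(!vm), 0, 360)
  resp %% 360
}

#' Built-in true-parameter profiles over SOA
#'
#' Named SOA-to-parameter maps emulating the qualitative patterns of the
#' three experimental regimes:
#' * `crowding` — temporal crowding (SOAs 175–475 ms): precision and
#'   both substitution rates fall as SOA grows; guessing flat.
#' * `masking_similar` — masking with target and masks of equal
#'   strength (SOAs 40–120 ms): guessing non-monotonic with a dip at the
#'   shortest SOA, substitution of the preceding distractor rising and of
#'   the succeeding distractor falling steeply with SOA; precision flat.
#' * `masking_dissimilar` — masking with target and masks of different
#'   luminance: precision degrades with SOA, guessing flat, substitution
#'   rates as in the similar case.
#'
#' Values are package defaults shaped to these qualitative patterns; all
#' satisfy the mixture simplex constraint at every SOA.
#'
#' @param name profile name.
#' @return data frame with columns `soa`, `g`, `beta1`, `beta2`, `sd`.
#' @export
builtin_profiles <- function(name = c("crowding", "masking_similar",
                                      "masking_dissimilar")) {
  name <- match.arg(name)
  switch(name,
    crowding = data.frame(
      soa = c(175, 225, 275, 375, 475),
      g = 0.08,
      beta1 = c(0.10, 0.08, 0.06, 0.05, 0.04),
      beta2 = c(0.10, 0.08, 0.07, 0.05, 0.04),
      sd = c(24, 22, 20, 18, 16)),
    masking_similar = data.frame(
      soa = c(40, 60, 80, 100, 120),
      g = c(0.05, 0.15, 0.16, 0.15, 0.13),
      beta1 = c(0.02, 0.04, 0.06, 0.08, 0.10),
      beta2 = c(0.25, 0.18, 0.12, 0.08, 0.05),
      sd = 17),
    masking_dissimilar = data.frame(
      soa = c(40, 60, 80, 100, 120),
      g = 0.08,
      beta1 = c(0.02, 0.04, 0.06, 0.08, 0.10),
      beta2 = c(0.22, 0.16, 0.11, 0.07, 0.05),
      sd = c(13, 14.5, 16, 17.5, 19)))
}

#' Configuration for a synthetic experiment
#'
#' Bundles the design (SOAs, trial counts, sample size), the true
#' SOA-dependent mixture parameters, between-participant heterogeneity
#' and the trial-exclusion rate.
#'
#' @param profile data frame mapping SOA to true parameters (columns
#'   `soa`, `g`, `beta1`, `beta2`, `sd`), e.g. from [builtin_profiles()].
#' @param n_participants number of simulated participants.
#' @param trials_per_soa experimental trials at each SOA (default 100).
#' @param baseline_trials unmasked single-target trials (default 100).
#' @param baseline_params 2-parameter truth for the baseline condition.
#' @param between_participant_sd sd of Gaussian jitter applied to each
#'   participant's true parameters on transformed scales (logit for
#'   weights, log for sd); 0 disables heterogeneity.
#' @param trial_exclusion_rate probability a trial is flagged for
#'   exclusion (saccade or missing response).
#' @param similarity label attached to all trials (`"similar"`,
#'   `"dissimilar"` or `NA`).
#' @param seed integer seed for the generator.
#' @return list of class `maskmix_config`.
#' @export
generator_config <- function(profile = builtin_profiles("masking_similar"),
                             n_participants = 16,
                             trials_per_soa = 100,
                             baseline_trials = 100,
                             baseline_params = list(g = 0.03, sd = 12),
                             between_participant_sd = 0.15,
                             trial_exclusion_rate = 0.04,
                             similarity = NA_character_,
                             seed = 1L) {
  stopifnot(all(c("soa", "g", "beta1", "beta2", "sd") %in% names(profile)),
            all(profile$g + profile$beta1 + profile$beta2 <= 1),
            all(profile$sd > 0),
            trial_exclusion_rate >= 0, trial_exclusion_rate < 1)
  structure(list(profile = profile, n_participants = n_participants,
                 trials_per_soa = trials_per_soa,
                 baseline_trials = baseline_trials,
                 baseline_params = baseline_params,
                 between_participant_sd = between_participant_sd,
                 trial_exclusion_rate = trial_exclusion_rate,
                 similarity = similarity, seed = as.integer(seed)),
            class = "maskmix_config")
}

# Participant-level jitter on transformed scales, kept inside the simplex.
jitter_params <- function(g, beta1, beta2, sd, tau) {
  if (tau > 0) {
    g <- stats::plogis(stats::qlogis(pmin(pmax(g, 1e-4), 0.999)) + stats::rnorm(1, 0, tau))
    beta1 <- stats::plogis(stats::qlogis(pmin(pmax(beta1, 1e-4), 0.999)) + stats::rnorm(1, 0, tau))
    beta2 <- stats::plogis(stats::qlogis(pmin(pmax(beta2, 1e-4), 0.999)) + stats::rnorm(1, 0, tau))
    sd <- exp(log(sd) + stats::rnorm(1, 0, tau / 2))
  }
  tot <- g + beta1 + beta2
  if (tot > 0.95) { sc <- 0.95 / tot; g <- g * sc; beta1 <- beta1 * sc; beta2 <- beta2 * sc }
  list(g = g, beta1 = beta1, beta2 = beta2, sd = min(max(sd, 1), 100))
}

#' Generate a full synthetic experiment
#'
#' Simulates every participant of the configured design: `trials_per_soa`
#' trials at each SOA with that participant's SOA-specific true
#' parameters, plus unmasked baseline trials from the 2-parameter
#' baseline truth. Trial order is shuffled within participant; exclusion
#' flags are set at the configured rate (split between saccades and
#' missing responses, the latter with no recorded click). The realised
#' per-participant true parameters are returned alongside the trials.
#'
#' @param config a `maskmix_config` from [generator_config()].
#' @return list with `trials` (trial table in the [read_trials()] schema)
#'   and `truth` (one row per participant-by-condition with the true
#'   parameters).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "maskmix_config"))
  with_seed(config$seed, {
    all_trials <- list(); all_truth <- list()
    for (pid in seq_len(config$n_participants)) {
      pt <- list(); tt <- list()
      for (i in seq_len(nrow(config$profile))) {
        row <- config$profile[i, ]
        pp <- jitter_params(row$g, row$beta1, row$beta2, row$sd,
                            config$between_participant_sd)
        p <- mixture_params(g = pp$g, beta1 = pp$beta1, beta2 = pp$beta2,
                            sd = pp$sd)
        oris <- draw_orientations(config$trials_per_soa)
        resp <- generate_trial(oris, p)
        pt[[i]] <- data.frame(participant_id = sprintf("P%02d", pid),
                              condition = as.character(row$soa),
                              similarity = config$similarity,
                              oris, response_ori = resp)
        tt[[i]] <- data.frame(participant_id = sprintf("P%02d", pid),
                              condition = as.character(row$soa),
                              g = pp$g, beta1 = pp$beta1, beta2 = pp$beta2,
                              sd = pp$sd)
      }
      if (config$baseline_trials > 0) {
        bp <- jitter_params(config$baseline_params$g, 0, 0,
                            config$baseline_params$sd,
                            config$between_participant_sd)
        p <- mixture_params(g = bp$g, sd = bp$sd)
        oris <- data.frame(d1_ori = NA_real_,
                           target_ori = sample.int(360, config$baseline_trials,
                                                   replace = TRUE) - 1,
                           d2_ori = NA_real_)
        resp <- generate_trial(oris, p)
        pt[[length(pt) + 1L]] <-
          data.frame(participant_id = sprintf("P%02d", pid),
                     condition = "baseline", similarity = config$similarity,
                     oris, response_ori = resp)
        tt[[length(tt) + 1L]] <-
          data.frame(participant_id = sprintf("P%02d", pid),
                     condition = "baseline",
                     g = bp$g, beta1 = 0, beta2 = 0, sd = bp$sd)
      }
      d <- do.call(rbind, pt)
      d <- d[sample.int(nrow(d)), , drop = FALSE]
      flagged <- stats::runif(nrow(d)) < config$trial_exclusion_rate
      saccade <- flagged & stats::runif(nrow(d)) < 0.5
      d$saccade_excluded <- saccade
      d$no_response <- flagged & !saccade
      d$response_ori[d$no_response] <- NA_real_
      all_trials[[pid]] <- d
      all_truth[[pid]] <- do.call(rbind, tt)
    }
    trials <- do.call(rbind, all_trials)
    rownames(trials) <- NULL
    truth <- do.call(rbind, all_truth)
    rownames(truth) <- NULL
    list(trials = trials, truth = truth)
  })
}
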