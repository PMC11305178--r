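# Simulate one cell of masked trials and return its signed error triples.
sim_errors <- function(n, g = 0, beta1 = 0, beta2 = 0, sd = 15, mu = 0,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  oris <- draw_orientations(n)
  p <- mixture_params(g = g, beta1 = beta1, beta2 = beta2, sd = sd, mu = mu)
  resp <- generate_trial(oris, p)
  data.frame(theta = circ_error(resp, oris$target_ori),
             theta1 = circ_error(resp, oris$d1_ori),
             theta2 = circ_error(resp, oris$d2_ori))
}

# Minimal well-formed trial table for preprocessing tests.
make_trials <- function(n = 20, participant = "P01", condition = "60",
                        saccade = rep(FALSE, n), no_resp = rep(FALSE, n),
                        seed = 1) {
  set.seed(seed)
  oris <- draw_orientations(n)
  resp <- (oris$target_ori + round(rnorm(n, 0, 10))) %% 360
  resp[no_resp] <- NA_real_
  data.frame(participant_id = participant, condition = condition,
             similarity = NA_character_, oris, response_ori = resp,
             saccade_excluded = saccade, no_response = no_resp)
}

# Numeric integral of a per-radian density over one response cycle.
integrate_over_circle <- function(dens_fun) {
  stats::integrate(function(deg) dens_fun(deg) * pi / 180,
                   lower = 0, upper = 360, rel.tol = 1e-10,
                   subdivisions = 2000L)$value
}
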