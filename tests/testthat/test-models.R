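test_that("two-misreport density matches a term-by-term scalar evaluation", {
  set.seed(31)
  for (i in 1:20) {
    th <- runif(1, -180, 180); t1 <- runif(1, -180, 180); t2 <- runif(1, -180, 180)
    w <- diff(c(0, sort(runif(3)), 1))  # random point on the 4-simplex
    p <- mixture_params(g = w[2], beta1 = w[3], beta2 = w[4],
                        sd = runif(1, 5, 60))
    kappa <- sd_to_kappa(p$sd)
    expected <- (1 - p$g - p$beta1 - p$beta2) * vonmises_density(th, 0, kappa) +
      p$g / (2 * pi) +
      p$beta1 * vonmises_density(t1, 0, kappa) +
      p$beta2 * vonmises_density(t2, 0, kappa)
    expect_equal(two_misreport_density(th, t1, t2, p), expected)
  }
})

test_that("model reductions hold to machine precision", {
  set.seed(32)
  th <- runif(50, -180, 180); t1 <- runif(50, -180, 180); t2 <- runif(50, -180, 180)

  # beta1 = beta2 = 0 reduces to the standard model
  p0 <- mixture_params(g = 0.2, sd = 20)
  expect_equal(two_misreport_density(th, t1, t2, p0), standard_density(th, p0))

  # swap with rate beta equals two-misreport with beta1 = beta2 = beta/2
  ps <- mixture_params(g = 0.1, beta1 = 0.15, beta2 = 0.15, sd = 18)
  expect_equal(swap_density(th, t1, t2, beta = 0.3, mixture_params(g = 0.1, sd = 18)),
               two_misreport_density(th, t1, t2, ps))

  # pure guessing is uniform
  pg <- mixture_params(g = 1, sd = 10)
  expect_equal(two_misreport_density(th, t1, t2, pg), rep(1 / (2 * pi), 50))
  expect_equal(standard_density(th, pg), rep(1 / (2 * pi), 50))
})

test_that("mixture density normalises over the response circle", {
  oris <- data.frame(d1_ori = 40, target_ori = 170, d2_ori = 310)
  p <- mixture_params(g = 0.15, beta1 = 0.1, beta2 = 0.2, sd = 22)
  z <- integrate_over_circle(function(r) {
    two_misreport_density(circ_error(r %% 360, oris$target_ori),
                          circ_error(r %% 360, oris$d1_ori),
                          circ_error(r %% 360, oris$d2_ori), p)
  })
  expect_equal(z, 1, tolerance = 1e-8)
})

test_that("log-likelihood sums per-trial logs, order-invariantly and finitely", {
  spec <- model_spec("two_misreport")
  err <- sim_errors(100, g = 0.1, beta1 = 0.1, beta2 = 0.1, sd = 15, seed = 33)
  p <- mixture_params(g = 0.1, beta1 = 0.1, beta2 = 0.1, sd = 15)
  naive <- sum(vapply(seq_len(100), function(i)
    log(two_misreport_density(err$theta[i], err$theta1[i], err$theta2[i], p)),
    numeric(1)))
  expect_equal(loglik(spec, err, p), naive)
  expect_equal(loglik(spec, err[sample(100), ], p), loglik(spec, err, p))

  one <- data.frame(theta = 10, theta1 = 20, theta2 = 30)
  expect_equal(loglik(spec, one, mixture_params(g = 1, sd = 10)),
               log(1 / (2 * pi)))
  # extreme parameters stay finite through the density floor
  far <- data.frame(theta = 180, theta1 = 170, theta2 = -170)
  expect_true(is.finite(loglik(model_spec("standard"), far,
                               mixture_params(g = 0, sd = 0.3))))
})

test_that("parameter invariants are enforced and weights conserve mass", {
  expect_error(mixture_params(g = 0.6, beta1 = 0.3, beta2 = 0.2, sd = 10),
               "<= 1")
  expect_error(mixture_params(g = -0.1, sd = 10), "nonnegative")
  expect_error(mixture_params(g = 0.1, sd = 0), "positive")

  p <- mixture_params(g = 0.1, beta1 = 0.05, beta2 = 0.05, sd = 12)
  expect_equal(target_report_rate(p), 0.8)
  expect_equal(target_report_rate(p) + p$g + p$beta1 + p$beta2, 1)
  expect_equal(target_report_rate(mixture_params(g = 1, sd = 10)), 0)
})

test_that("maximised log-likelihood increases weakly along the model nesting", {
  err <- sim_errors(400, g = 0.1, beta1 = 0.05, beta2 = 0.2, sd = 15, seed = 34)
  f_std <- map_fit("standard", err, n_starts = 8, seed = 1)
  f_swap <- map_fit("swap", err, n_starts = 8, seed = 1)
  f_two <- map_fit("two_misreport", err, n_starts = 8, seed = 1)
  expect_gte(f_swap$loglik, f_std$loglik - 1e-6)
  expect_gte(f_two$loglik, f_swap$loglik - 1e-6)
})
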