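test_that("orientation triples are distinct, uniform and reproducible", {
  set.seed(71)
  oris <- draw_orientations(10000)
  expect_true(all(oris$d1_ori != oris$target_ori &
                    oris$d1_ori != oris$d2_ori &
                    oris$target_ori != oris$d2_ori))
  expect_true(all(as.matrix(oris) %in% 0:359))
  chi <- chisq.test(table(factor(oris$target_ori, levels = 0:359)))
  expect_gt(chi$p.value, 0.001)

  set.seed(99); a <- draw_orientations(50)
  set.seed(99); b <- draw_orientations(50)
  expect_identical(a, b)
})

test_that("responses follow the generative mixture", {
  # pure guessing: responses uniform on the circle
  set.seed(72)
  oris <- draw_orientations(10000)
  resp <- generate_trial(oris, mixture_params(g = 1, sd = 15))
  ks <- suppressWarnings(ks.test(resp / 360, "punif"))
  expect_gt(ks$p.value, 0.001)

  # near-zero noise, no guessing: response pinned to the target
  resp0 <- generate_trial(oris[1:200, ], mixture_params(g = 0, sd = 0.3))
  expect_lt(max(abs(circ_error(resp0, oris$target_ori[1:200]))), 3)

  # component frequencies follow the mixture weights; classify each
  # response by its nearest stimulus (well-separated errors at sd = 5)
  set.seed(73)
  n <- 50000
  o <- data.frame(d1_ori = 60, target_ori = 180, d2_ori = 300)[rep(1, n), ]
  p <- mixture_params(g = 0.2, beta1 = 0.15, beta2 = 0.25, sd = 5)
  r <- generate_trial(o, p)
  near <- function(ref) abs(circ_error(r, ref)) < 25
  expect_equal(mean(near(180)), target_report_rate(p) + p$g * 50 / 360,
               tolerance = 0.02)
  expect_equal(mean(near(60)), p$beta1 + p$g * 50 / 360, tolerance = 0.02)
  expect_equal(mean(near(300)), p$beta2 + p$g * 50 / 360, tolerance = 0.02)
})

test_that("generated experiments have the designed trial counts and schema", {
  cfg <- generator_config(n_participants = 2, seed = 5)
  sim <- generate_experiment(cfg)
  tr <- sim$trials
  for (pid in unique(tr$participant_id)) {
    d <- tr[tr$participant_id == pid, ]
    # 600 experimental trials: 100 at each of 5 SOAs plus 100 unmasked
    expect_equal(nrow(d), 600)
    expect_equal(sum(!is_baseline(d$condition)), 500)
    expect_equal(sum(is_baseline(d$condition)), 100)
    expect_equal(sort(unique(as.numeric(d$condition[!is_baseline(d$condition)]))),
                 c(40, 60, 80, 100, 120))
  }
  masked <- tr[!is_baseline(tr$condition), ]
  expect_true(all(masked$d1_ori != masked$target_ori))
  resp <- tr$response_ori[!tr$no_response]
  expect_true(all(resp >= 0 & resp < 360))
  expect_true(all(is.na(tr$response_ori[tr$no_response])))
  expect_true(all(c("participant_id", "condition", "similarity", "d1_ori",
                    "target_ori", "d2_ori", "response_ori", "saccade_excluded",
                    "no_response") %in% names(tr)))
  # truth table covers every participant x condition cell
  expect_equal(nrow(sim$truth), 2 * 6)

  sim2 <- generate_experiment(cfg)
  expect_identical(sim, sim2)  # same seed, same experiment
})

test_that("built-in profiles encode the qualitative SOA patterns and stay valid", {
  for (nm in c("crowding", "masking_similar", "masking_dissimilar")) {
    pr <- builtin_profiles(nm)
    expect_true(all(pr$g + pr$beta1 + pr$beta2 <= 1))
    expect_true(all(pr$sd > 0))
  }
  cr <- builtin_profiles("crowding")
  expect_gt(cr$sd[cr$soa == 175], cr$sd[cr$soa == 475])
  expect_gt(cr$beta1[1], cr$beta1[5])
  ms <- builtin_profiles("masking_similar")
  expect_gt(ms$beta2[ms$soa == 40], ms$beta2[ms$soa == 120])
  expect_lt(ms$g[1], ms$g[2])  # guessing dips at the shortest SOA
  expect_true(all(diff(ms$beta1) > 0))
  md <- builtin_profiles("masking_dissimilar")
  expect_true(all(diff(md$sd) > 0))
  expect_error(builtin_profiles("nope"))
})

test_that("generated data round-trip through fitting (pipeline recovery)", {
  # one participant, no heterogeneity, big cells: recovered parameters
  # should match the generating profile within fitting tolerances
  pr <- builtin_profiles("masking_similar")[c(1, 5), ]
  cfg <- generator_config(profile = pr, n_participants = 1,
                          trials_per_soa = 1000, baseline_trials = 0,
                          between_participant_sd = 0,
                          trial_exclusion_rate = 0, seed = 8)
  sim <- generate_experiment(cfg)
  err <- compute_errors(sim$trials)
  for (i in seq_len(nrow(pr))) {
    cell <- err[err$condition == as.character(pr$soa[i]), ]
    f <- map_fit("two_misreport", cell, n_starts = 10, seed = 80 + i)
    expect_lt(abs(f$params$g - pr$g[i]), 0.05)
    expect_lt(abs(f$params$beta1 - pr$beta1[i]), 0.05)
    expect_lt(abs(f$params$beta2 - pr$beta2[i]), 0.05)
    expect_lt(abs(f$params$sd - pr$sd[i]), 2.5)
  }
})
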