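test_that("one-way RM ANOVA matches a sums-of-squares oracle and its df structure", {
  set.seed(51)
  d <- expand.grid(participant = 1:16, level = c(40, 60, 80, 100, 120))
  d$value <- rnorm(nrow(d)) + 0.2 * as.numeric(factor(d$level))
  out <- rm_anova_oneway(d)
  expect_equal(out$df1, 4)
  expect_equal(out$df2, 60)  # (5-1)*(16-1)

  # oracle: partition SS by hand on the participant x level matrix
  m <- tapply(d$value, list(d$participant, d$level), mean)
  gm <- mean(m)
  ss_cond <- nrow(m) * sum((colMeans(m) - gm)^2)
  ss_subj <- ncol(m) * sum((rowMeans(m) - gm)^2)
  ss_err <- sum((m - gm)^2) - ss_cond - ss_subj
  expect_equal(out$F, (ss_cond / 4) / (ss_err / 60))
  expect_equal(out$p, pf(out$F, 4, 60, lower.tail = FALSE))
  expect_equal(out$eta_p2, partial_eta_sq(out$F, 4, 60))

  # constant response gives a zero F
  d$value <- 7
  expect_equal(rm_anova_oneway(d)$F, 0)
  expect_error(rm_anova_oneway(d[-1, ]), "balanced")
})

test_that("RM ANOVA F is invariant to permuting participant labels", {
  set.seed(52)
  d <- expand.grid(participant = 1:12, level = 1:5)
  d$value <- rnorm(nrow(d))
  f0 <- rm_anova_oneway(d)$F
  perm <- sample(12)
  d2 <- d; d2$participant <- perm[d$participant]
  expect_equal(rm_anova_oneway(d2)$F, f0)
})

test_that("mixed ANOVA reproduces textbook sums of squares and mixed-design dfs", {
  set.seed(53)
  d <- expand.grid(participant = 1:30, within = c(175, 225, 275, 375, 475))
  d$between <- ifelse(d$participant <= 15, "similar", "dissimilar")
  d$value <- rnorm(nrow(d)) + 0.1 * as.numeric(factor(d$within)) +
    0.4 * (d$between == "similar")
  out <- mixed_anova(d)
  expect_equal(out$df1, c(1, 4, 4))
  expect_equal(out$df2, c(28, 112, 112))  # paper-style (1,28) and (4,112)

  # oracle: classic split-plot SS decomposition (balanced groups)
  m <- tapply(d$value, list(d$participant, d$within), mean)
  grp <- ifelse(seq_len(30) <= 15, "similar", "dissimilar")
  gm <- mean(m)
  a <- ncol(m); n_per <- 15
  subj_means <- rowMeans(m)
  grp_means <- tapply(subj_means, grp, mean)
  ss_between <- a * n_per * sum((grp_means - gm)^2)
  ss_subj_within_grp <- a * sum((subj_means - grp_means[grp])^2)
  cell <- matrix(0, 2, a, dimnames = list(names(grp_means), colnames(m)))
  for (g in names(grp_means)) cell[g, ] <- colMeans(m[grp == g, ])
  ss_within <- 2 * n_per * sum((colMeans(m) - gm)^2)
  ss_inter <- n_per * sum((cell - outer(grp_means, rep(1, a)) -
                             rep(1, 2) %o% colMeans(m) + gm)^2)
  ss_err <- sum((m - gm)^2) - ss_between - ss_subj_within_grp -
    ss_within - ss_inter
  expect_equal(out$F[out$effect == "between"],
               (ss_between / 1) / (ss_subj_within_grp / 28))
  expect_equal(out$F[out$effect == "within"], (ss_within / 4) / (ss_err / 112))
  expect_equal(out$F[out$effect == "between:within"],
               (ss_inter / 4) / (ss_err / 112))

  # mirrored groups (participant i in each group has identical data):
  # the between-group sum of squares is exactly zero
  base_vals <- matrix(rnorm(15 * 5), 15, 5)
  d$value <- base_vals[cbind(((d$participant - 1) %% 15) + 1,
                             as.integer(factor(d$within)))]
  expect_lt(mixed_anova(d)$F[1], 1e-20)
})

test_that("partial eta squared reproduces printed effect sizes and is monotone", {
  expect_equal(round(partial_eta_sq(6.05, 4, 56), 2), 0.30)
  expect_equal(round(partial_eta_sq(23.01, 4, 60), 3), 0.605)
  expect_equal(partial_eta_sq(0, 4, 60), 0)
  F <- seq(0, 50, by = 0.5)
  v <- partial_eta_sq(F, 4, 60)
  expect_true(all(diff(v) > 0) && all(v >= 0 & v < 1))
})

test_that("paired t test and Cohen's d on differences match hand computation", {
  set.seed(54)
  x <- rnorm(15, 20, 4); y <- rnorm(15, 18, 4)
  out <- paired_t_cohens_d(x, y)
  expect_equal(out$df, 14)
  dd <- x - y
  expect_equal(out$t, mean(dd) / (sd(dd) / sqrt(15)))
  expect_equal(out$d, mean(dd) / sd(dd))
  expect_equal(out$p, 2 * pt(-abs(out$t), 14))

  same <- paired_t_cohens_d(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$d, 0)
  expect_error(paired_t_cohens_d(x, y[1:10]), "paired")
})

test_that("minimum sample size search is self-consistent and reproduces N = 12", {
  eta <- partial_eta_sq(6.05, 4, 56)
  n_min <- min_sample_size(df1 = 4, eta_p2 = eta)
  expect_equal(n_min, 12)
  expect_gte(rm_anova_power(n_min, 4, eta), 0.95)
  expect_lt(rm_anova_power(n_min - 1, 4, eta), 0.95)

  # power is nondecreasing in N at fixed effect size
  pw <- vapply(2:30, rm_anova_power, numeric(1), df1 = 4, eta_p2 = eta)
  expect_true(all(diff(pw) >= -1e-12))
})
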