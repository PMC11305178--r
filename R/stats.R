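# Pull F, dfs and p for a named effect out of a summary.aovlist object.
extract_effect <- function(sav, effect) {
  for (stratum in sav) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    i <- match(effect, rn)
    if (!is.na(i) && !is.na(tab[i, "F value"])) {
      resid <- match("Residuals", rn)
      return(data.frame(effect = effect,
                        F = tab[i, "F value"],
                        df1 = tab[i, "Df"],
                        df2 = tab[resid, "Df"],
                        p = tab[i, "Pr(>F)"]))
    }
  }
  stop("effect not found: ", effect, call. = FALSE)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject F test for a single factor measured at every level on
#' every participant (complete, balanced table), with uncorrected degrees
#' of freedom `df1 = levels - 1`, `df2 = (levels - 1)(participants - 1)`
#' and partial eta squared attached. No sphericity correction is applied.
#'
#' @param data data frame with columns `participant`, `level`, `value`
#'   (one row per participant-by-level cell).
#' @return data frame: `effect`, `F`, `df1`, `df2`, `p`, `eta_p2`.
#' @export
rm_anova_oneway <- function(data) {
  stopifnot(all(c("participant", "level", "value") %in% names(data)))
  tab <- table(data$participant, data$level)
  if (any(tab != 1))
    stop("design must be complete and balanced (one value per cell)",
         call. = FALSE)
  d <- data.frame(participant = factor(data$participant),
                  level = factor(data$level), value = data$value)
  if (stats::var(d$value) == 0) {
    # constant response: no effect and no error variance; define F = 0
    return(data.frame(effect = "SOA", F = 0, df1 = nlevels(d$level) - 1,
                      df2 = (nlevels(d$level) - 1) * (nlevels(d$participant) - 1),
                      p = 1, eta_p2 = 0))
  }
  fit <- stats::aov(value ~ level + Error(participant / level), data = d)
  out <- extract_effect(summary(fit), "level")
  out$effect <- "SOA"
  out$eta_p2 <- partial_eta_sq(out$F, out$df1, out$df2)
  out
}

#' Two-way mixed-design ANOVA
#'
#' Main effects and interaction for a design with one within-subject
#' factor (e.g. SOA) and one between-subject factor (e.g.
#' target-distractor similarity), using the conventional mixed-design
#' error terms: the between effect is tested against participants within
#' groups; the within effect and the interaction against the
#' participant-by-within residual.
#'
#' @param data data frame with columns `participant`, `within`,
#'   `between`, `value`; each participant belongs to one `between` group
#'   and contributes one value at every `within` level.
#' @return data frame with one row per effect (`within`, `between`,
#'   `within:between`): `F`, `df1`, `df2`, `p`, `eta_p2`.
#' @export
mixed_anova <- function(data) {
  stopifnot(all(c("participant", "within", "between", "value") %in% names(data)))
  d <- data.frame(participant = factor(data$participant),
                  within = factor(data$within),
                  between = factor(data$between), value = data$value)
  if (nlevels(d$between) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(d$participant, d$within) != 1))
    stop("within factor must be complete and balanced", call. = FALSE)
  fit <- stats::aov(value ~ between * within + Error(participant / within),
                    data = d)
  sav <- summary(fit)
  out <- rbind(extract_effect(sav, "between"),
               extract_effect(sav, "within"),
               extract_effect(sav, "between:within"))
  out$eta_p2 <- partial_eta_sq(out$F, out$df1, out$df2)
  out
}

#' Partial eta squared from an F statistic
#'
#' \eqn{\eta_p^2 = F \cdot df_1 / (F \cdot df_1 + df_2)}; strictly
#' increasing in F and bounded in `[0, 1)`.
#'
#' @param F F statistic (`>= 0`).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return effect size in `[0, 1)`.
#' @export
partial_eta_sq <- function(F, df1, df2) {
  stopifnot(all(F >= 0))
  F * df1 / (F * df1 + df2)
}

#' Paired t test with Cohen's d
#'
#' Two-sided paired t test (`df = n - 1`) with the effect size computed
#' on the paired differences: `d = mean(x - y) / sd(x - y)`.
#'
#' @param x,y equal-length paired samples.
#' @return data frame: `t`, `df`, `p`, `d`, `mean_diff`.
#' @export
paired_t_cohens_d <- function(x, y) {
  if (length(x) != length(y)) stop("samples must be paired", call. = FALSE)
  if (length(x) < 2) stop("need at least two pairs", call. = FALSE)
  diff <- x - y
  n <- length(diff)
  if (stats::sd(diff) == 0) {
    # identical pairs: no effect and no spread; define t = d = 0
    return(data.frame(t = 0, df = n - 1, p = 1, d = 0, mean_diff = mean(diff)))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value,
             d = mean(diff) / stats::sd(diff), mean_diff = mean(diff))
}

#' Noncentral-F power for a repeated-measures design
#'
#' Power of the F test with numerator df `u = df1`, denominator df
#' `v = df1 * (N - 1)` (the within-error df of a one-way
#' repeated-measures design) and noncentrality
#' \eqn{\lambda = f^2 (u + v + 1)}, where \eqn{f^2 = \eta_p^2 /
#' (1 - \eta_p^2)}.
#'
#' @param N number of participants.
#' @param df1 numerator degrees of freedom (levels - 1).
#' @param eta_p2 assumed partial eta squared.
#' @param alpha significance level.
#' @return scalar power.
#' @export
rm_anova_power <- function(N, df1, eta_p2, alpha = 0.05) {
  f2 <- eta_p2 / (1 - eta_p2)
  u <- df1
  v <- df1 * (N - 1)
  lambda <- f2 * (u + v + 1)
  1 - stats::pf(stats::qf(1 - alpha, u, v), u, v, ncp = lambda)
}

#' Minimum sample size for a target power
#'
#' Smallest `N` at which [rm_anova_power()] reaches `power_target`;
#' power is nondecreasing in `N` at fixed effect size, so an upward
#' search suffices.
#'
#' @param df1 numerator degrees of freedom.
#' @param eta_p2 assumed partial eta squared.
#' @param alpha significance level (default 0.05).
#' @param power_target required power (default 0.95).
#' @param n_max search limit (default 10000).
#' @return integer minimum N.
#' @export
min_sample_size <- function(df1, eta_p2, alpha = 0.05, power_target = 0.95,
                            n_max = 10000) {
  stopifnot(alpha > 0, alpha < 1, power_target > 0, power_target < 1,
            eta_p2 > 0, eta_p2 < 1)
  for (N in 2:n_max) {
    if (rm_anova_power(N, df1, eta_p2, alpha) >= power_target) return(N)
  }
  stop("power target unreachable within N <= ", n_max, call. = FALSE)
}
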