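hinge_design <- function(x, breaks) {
  X <- cbind(1, x)
  for (b in breaks) X <- cbind(X, pmax(x - b, 0))
  X
}

rss_at <- function(x, y, breaks) {
  fit <- stats::.lm.fit(hinge_design(x, breaks), y)
  sum(fit$residuals^2)
}

#' Segmented (piecewise linear) regression against SOA
#'
#' Fits a continuous piecewise-linear model of `y` on `x` with 1 or 2
#' breakpoints. Breakpoints are estimated by profiling the residual sum
#' of squares over a 1-ms grid strictly inside the observed `x` range;
#' slope estimates come from the conditional linear fit at the selected
#' breakpoints, while their standard errors and 95% confidence intervals
#' use the full nonlinear-least-squares Jacobian (which treats each
#' breakpoint as an estimated parameter), since purely conditional SEs
#' understate the sampling variability of the short-segment slopes. The
#' residual degrees of freedom likewise count each breakpoint: `n - 4`
#' for one breakpoint, `n - 6` for two.
#'
#' @param x numeric vector of SOAs in ms.
#' @param y numeric vector of parameter estimates (one per observation;
#'   typically participant-by-SOA values pooled across experiments).
#' @param n_break number of breakpoints, 1 or 2.
#' @param min_gap minimum separation between two breakpoints, ms.
#' @return list of class `maskmix_segfit`: `breakpoints`, `slopes` (data
#'   frame with `slope`, `se`, `t`, `ci_lo`, `ci_hi` per segment),
#'   `coef`, `rss`, `tss`, `df_resid`, `n`, `x`, `y`.
#' @export
fit_piecewise <- function(x, y, n_break = 1, min_gap = 10) {
  stopifnot(length(x) == length(y), n_break %in% c(1, 2))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 3) stop("degenerate x: need at least 3 distinct SOAs",
                                  call. = FALSE)
  n <- length(x)
  n_par <- 2 + 2 * n_break
  if (n < n_par + 2) stop("too few points for a ", n_break, "-breakpoint fit",
                          call. = FALSE)
  grid <- seq(ceiling(min(x)) + 1, floor(max(x)) - 1, by = 1)
  if (n_break == 1) {
    rss <- vapply(grid, function(b) rss_at(x, y, b), numeric(1))
    breaks <- grid[which.min(rss)]
  } else {
    best <- Inf; breaks <- NULL
    for (b1 in grid) {
      g2 <- grid[grid >= b1 + min_gap]
      if (!length(g2)) next
      r <- vapply(g2, function(b2) rss_at(x, y, c(b1, b2)), numeric(1))
      j <- which.min(r)
      if (r[j] < best) { best <- r[j]; breaks <- c(b1, g2[j]) }
    }
  }
  X <- hinge_design(x, breaks)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  df_resid <- n - n_par
  sigma2 <- rss / df_resid
  # slope uncertainty via the full nonlinear-least-squares Jacobian,
  # which includes the breakpoint columns d mean/d c_j = -coef_j 1[x > c_j];
  # conditioning on the estimated breakpoints alone understates slope SEs
  J <- X
  for (j in seq_along(breaks))
    J <- cbind(J, -fit$coefficients[2 + j] * (x > breaks[j]))
  # pseudo-inverse: when a hinge coefficient is ~0 its breakpoint column
  # vanishes (the breakpoint is unidentified) and the SE falls back to the
  # conditional one
  JtJ <- crossprod(J)
  sv <- svd(JtJ)
  pos <- sv$d > max(sv$d) * ncol(J) * .Machine$double.eps
  JtJinv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  # segment slopes are cumulative sums of the hinge coefficients
  nseg <- n_break + 1
  A <- matrix(0, nseg, ncol(J))
  for (s in seq_len(nseg)) A[s, 2:(1 + s)] <- 1
  slope <- drop(A[, seq_len(ncol(X)), drop = FALSE] %*% fit$coefficients)
  se <- sqrt(diag(A %*% JtJinv %*% t(A)) * sigma2)
  tcrit <- stats::qt(0.975, df_resid)
  slopes <- data.frame(segment = seq_len(nseg), slope = slope, se = se,
                       t = slope / se,
                       ci_lo = slope - tcrit * se, ci_hi = slope + tcrit * se)
  structure(list(breakpoints = breaks, slopes = slopes,
                 coef = fit$coefficients, rss = rss,
                 tss = sum((y - mean(y))^2), df_resid = df_resid,
                 n = n, x = x, y = y),
            class = "maskmix_segfit")
}

#' @export
print.maskmix_segfit <- function(x, ...) {
  cat("Segmented fit:", length(x$breakpoints), "breakpoint(s) at",
      paste(x$breakpoints, collapse = ", "), "ms\n")
  print(x$slopes, row.names = FALSE, digits = 4)
  ov <- overall_model_test(x)
  cat(sprintf("Overall F(%d,%d) = %.3f, p = %.4g\n", ov$df1, ov$df2, ov$F, ov$p))
  invisible(x)
}

#' Predicted values of a segmented fit
#' @param object a `maskmix_segfit`.
#' @param newdata optional numeric vector of SOAs; defaults to the fitted x.
#' @param ... unused.
#' @export
predict.maskmix_segfit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  drop(hinge_design(x, object$breakpoints) %*% object$coef)
}

#' Test whether segment slopes differ
#'
#' F test of the segmented model against the nested equal-slope model at
#' the same breakpoints (with continuity, equal slopes collapse to a
#' single straight line). `df1` equals the number of slope constraints
#' (one per breakpoint); `df2` is the segmented model's residual df.
#'
#' @param fit a `maskmix_segfit` from [fit_piecewise()].
#' @return data frame: `F`, `df1`, `df2`, `p`.
#' @export
slope_difference_test <- function(fit) {
  nb <- length(fit$breakpoints)
  rss0 <- sum(stats::lm.fit(cbind(1, fit$x), fit$y)$residuals^2)
  F <- ((rss0 - fit$rss) / nb) / (fit$rss / fit$df_resid)
  data.frame(F = F, df1 = nb, df2 = fit$df_resid,
             p = stats::pf(F, nb, fit$df_resid, lower.tail = FALSE))
}

#' Overall model F test of a segmented fit
#'
#' F of the full segmented model against the intercept-only model;
#' `df1 = 3` for one breakpoint and `df1 = 5` for two (slopes and
#' breakpoints all counted as estimated parameters).
#'
#' @param fit a `maskmix_segfit` from [fit_piecewise()].
#' @return data frame: `F`, `df1`, `df2`, `p`.
#' @export
overall_model_test <- function(fit) {
  df1 <- 2 * length(fit$breakpoints) + 1
  F <- ((fit$tss - fit$rss) / df1) / (fit$rss / fit$df_resid)
  data.frame(F = F, df1 = df1, df2 = fit$df_resid,
             p = stats::pf(F, df1, fit$df_resid, lower.tail = FALSE))
}
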