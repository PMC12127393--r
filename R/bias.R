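# Publication-bias diagnostics for a pooled meta-analysis of correlations:
# funnel-plot coordinates, Egger's regression test, Rosenthal's fail-safe N
# with the 5k+10 robustness criterion, and Duval-Tweedie trim-and-fill.

#' Funnel-plot coordinates
#'
#' Returns the per-study plotting coordinates (Fisher-z effect against its
#' standard error; by convention the SE axis is drawn inverted so precise
#' studies sit at the top) together with the pooled random-effects center.
#' When a [trim_and_fill()] result is supplied, its imputed studies are
#' appended and flagged in the `source` column.
#'
#' @param x A `meta_pool` fit.
#' @param trimfill Optional `trim_fill` result for the same fit.
#' @return A list with `points` (data frame `study_id`, `z`, `r`, `sei`,
#'   `source`), `center` (pooled Fisher-z) and `center_r`.
#' @export
funnel_coordinates <- function(x, trimfill = NULL) {
  stopifnot(inherits(x, "meta_pool"))
  pts <- data.frame(study_id = x$data$study_id, z = x$data$z, r = x$data$r,
                    sei = x$data$sei, source = "observed",
                    stringsAsFactors = FALSE)
  if (!is.null(trimfill)) {
    stopifnot(inherits(trimfill, "trim_fill"))
    if (nrow(trimfill$imputed) > 0L)
      pts <- rbind(pts, data.frame(study_id = trimfill$imputed$study_id,
                                   z = trimfill$imputed$z,
                                   r = tanh(trimfill$imputed$z),
                                   sei = sqrt(trimfill$imputed$vi),
                                   source = "imputed",
                                   stringsAsFactors = FALSE))
  }
  list(points = pts, center = x$b, center_r = x$r)
}

#' Funnel plot of a pooled meta-analysis
#'
#' Basic funnel plot (Fisher-z effect vs. standard error, SE axis inverted)
#' with the pooled center as a vertical reference line. Imputed studies from
#' a [trim_and_fill()] result are drawn as filled points.
#'
#' @param x A `meta_pool` fit.
#' @param trimfill Optional `trim_fill` result to overlay.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return The [funnel_coordinates()] list, invisibly.
#' @export
plot.meta_pool <- function(x, trimfill = NULL, ...) {
  fc <- funnel_coordinates(x, trimfill)
  obs <- fc$points$source == "observed"
  graphics::plot(fc$points$z[obs], fc$points$sei[obs],
                 ylim = rev(range(c(0, fc$points$sei))),
                 xlim = range(fc$points$z),
                 xlab = "Fisher's z", ylab = "Standard error",
                 pch = 1, ...)
  if (any(!obs))
    graphics::points(fc$points$z[!obs], fc$points$sei[!obs], pch = 16)
  graphics::abline(v = fc$center, lty = 2)
  invisible(fc)
}

#' Egger's regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effect \eqn{z_i/SE_i} on the
#' precision \eqn{1/SE_i}. Under a symmetric funnel the intercept is zero;
#' the test is a two-tailed t test of the intercept on k - 2 degrees of
#' freedom.
#'
#' @param x A `meta_pool` fit with k >= 3 and non-identical standard errors.
#' @return Object of class `egger_test`: list with `intercept`, `slope`,
#'   `se_intercept`, `t_stat`, `df`, `pval`.
#' @export
egger_test <- function(x) {
  stopifnot(inherits(x, "meta_pool"))
  k <- x$k
  if (k < 3L)
    stop("Egger's test needs at least 3 studies")
  sei <- x$data$sei
  if (diff(range(sei)) < 1e-12)
    stop("Egger's test is undefined when all standard errors are identical: the precision design is singular")
  prec <- 1 / sei
  score <- x$data$z / sei
  fit <- stats::lm(score ~ prec)
  sm <- summary(fit)$coefficients
  out <- list(intercept = unname(sm["(Intercept)", "Estimate"]),
              slope = unname(sm["prec", "Estimate"]),
              se_intercept = unname(sm["(Intercept)", "Std. Error"]),
              t_stat = unname(sm["(Intercept)", "t value"]),
              df = k - 2L,
              pval = unname(sm["(Intercept)", "Pr(>|t|)"]))
  class(out) <- "egger_test"
  out
}

#' @export
print.egger_test <- function(x, digits = 4, ...) {
  cat("Egger's regression test for funnel-plot asymmetry\n")
  cat(sprintf("intercept = %.*f (SE = %.*f), t = %.*f (df = %d), p = %s\n",
              digits, x$intercept, digits, x$se_intercept, digits, x$t_stat,
              x$df, format.pval(x$pval, digits = digits)))
  invisible(x)
}

#' Rosenthal's fail-safe N
#'
#' The number of unpublished null-result studies that would have to exist to
#' bring the Stouffer-combined significance of the meta-analysis below the
#' critical value: the smallest non-negative integer N with
#' \eqn{|\sum Z_i| / \sqrt{k + N} < z_{crit}}, where \eqn{Z_i = z_i/SE_i}
#' are the per-study standard-normal scores. If the combined effect is not
#' significant to begin with, N is 0 by definition. The result is flagged
#' robust when N exceeds Rosenthal's 5k + 10 criterion.
#'
#' @param x A `meta_pool` fit with k >= 2.
#' @param alpha Significance level, default 0.05.
#' @param sides 2 (default; \eqn{z_{crit} = 1.96} at alpha 0.05) or 1
#'   (\eqn{z_{crit} = 1.645}).
#' @return Object of class `fail_safe`: list with `n_fs`,
#'   `criterion_5k_10 = 5k + 10`, `robust`, `z_crit`, `combined_z`, `k`.
#' @export
fail_safe_n <- function(x, alpha = 0.05, sides = 2) {
  stopifnot(inherits(x, "meta_pool"))
  k <- x$k
  if (k < 2L)
    stop("fail-safe N needs at least 2 studies")
  if (!(sides %in% c(1, 2)))
    stop("'sides' must be 1 or 2")
  if (!(alpha > 0 && alpha < 1))
    stop("'alpha' must be in (0, 1)")
  z_crit <- stats::qnorm(1 - alpha / sides)
  S <- sum(x$data$z / x$data$sei)
  val <- S^2 / z_crit^2 - k
  n_fs <- if (val < 0) 0L else as.integer(floor(val) + 1)
  criterion <- as.integer(5 * k + 10)
  out <- list(n_fs = n_fs, criterion_5k_10 = criterion,
              robust = n_fs > criterion, z_crit = z_crit,
              combined_z = S / sqrt(k), k = k)
  class(out) <- "fail_safe"
  out
}

#' @export
print.fail_safe <- function(x, ...) {
  cat("Rosenthal fail-safe N\n")
  cat(sprintf("N = %d; 5k + 10 criterion = %d; robust: %s\n",
              x$n_fs, x$criterion_5k_10, if (x$robust) "yes" else "no"))
  invisible(x)
}

#' Duval-Tweedie trim-and-fill
#'
#' Rank-based estimation and imputation of funnel-plot-suppressed studies
#' using the L0 estimator. Iteratively: (1) the funnel center is estimated by
#' fixed-effect pooling of the non-trimmed studies; (2) absolute deviations
#' of all observed studies from that center are ranked (midranks on ties)
#' and \eqn{L_0 = \max(0, \mathrm{round}((4T - n(n+1))/(2n-1)))} is computed
#' from the rank sum T of the heavy-side studies; (3) the L0 most extreme
#' heavy-side studies are trimmed. Iteration stops when L0 repeats (or
#' errors after `maxiter`). The trimmed studies are then mirrored about the
#' final center (same variances) and the adjusted summary is the
#' random-effects pooling of observed + imputed studies.
#'
#' `side` names the HEAVY side of the funnel, i.e. the side that is trimmed;
#' imputation happens on the opposite side. `"auto"` picks the side with the
#' larger one-sided rank sum of deviations from the fixed-effect center.
#'
#' @param x A `meta_pool` fit with k >= 3.
#' @param side `"auto"` (default), `"left"` or `"right"`.
#' @param maxiter Maximum trimming iterations before aborting, default 20.
#' @return Object of class `trim_fill`: list with `side`, `l0`, `imputed`
#'   (data frame `study_id`, `z`, `vi`), `adjusted` (a `meta_pool` fit on
#'   observed + imputed), `iterations`, `center_z` (final trimmed center on
#'   the Fisher-z scale) and `observed` (the input fit).
#' @export
trim_and_fill <- function(x, side = c("auto", "left", "right"), maxiter = 20L) {
  stopifnot(inherits(x, "meta_pool"))
  side <- match.arg(side)
  k <- x$k
  if (k < 3L)
    stop("trim-and-fill needs at least 3 studies")
  zi <- x$data$z
  vi <- x$data$vi
  w <- 1 / vi
  # near-ties in |deviation| are genuine ties up to floating noise; rank on
  # rounded values so midranks apply to them (keeps L0 exact on symmetric
  # fixtures)
  tie_rank <- function(dev) rank(signif(abs(dev), 8), ties.method = "average")
  dev_sign <- function(dev) {
    tol <- 1e-10 * max(abs(dev), 1e-300)
    sign(dev) * (abs(dev) > tol)
  }
  if (side == "auto") {
    ctr <- sum(w * zi) / sum(w)
    s <- dev_sign(zi - ctr)
    rk <- tie_rank(zi - ctr)
    side <- if (sum(rk[s > 0]) >= sum(rk[s < 0])) "right" else "left"
  }
  sgn <- if (side == "left") -1 else 1
  z <- sgn * zi
  l0 <- 0L
  iter <- 0L
  center <- NA_real_
  repeat {
    iter <- iter + 1L
    if (iter > maxiter)
      stop(sprintf(paste0("trim-and-fill did not converge after %d iterations ",
                          "(last L0 = %d, center = %.6f); the funnel may be ",
                          "degenerate"), maxiter, l0, sgn * center))
    keep <- seq_len(k)
    if (l0 > 0L)
      keep <- keep[-order(z, decreasing = TRUE)[seq_len(l0)]]
    center <- sum(w[keep] * z[keep]) / sum(w[keep])
    dev <- z - center
    rk <- tie_rank(dev)
    Tn <- sum(rk[dev_sign(dev) > 0])
    l0_new <- max(0L, as.integer(round((4 * Tn - k * (k + 1)) / (2 * k - 1))))
    if (l0_new == l0) break
    l0 <- l0_new
  }
  if (l0 > 0L) {
    trim_idx <- order(z, decreasing = TRUE)[seq_len(l0)]
    imp_z <- sgn * (2 * center - z[trim_idx])
    imputed <- data.frame(study_id = paste0("filled_", seq_len(l0)),
                          z = imp_z, vi = vi[trim_idx],
                          stringsAsFactors = FALSE)
  } else {
    imputed <- data.frame(study_id = character(0), z = numeric(0),
                          vi = numeric(0), stringsAsFactors = FALSE)
  }
  all_z <- c(zi, imputed$z)
  all_vi <- c(vi, imputed$vi)
  # vi = 1/(n-3) so the equivalent sample size n = 3 + 1/vi is exact
  adjusted <- meta_pool(tanh(all_z), 3 + 1 / all_vi,
                        slab = c(x$data$study_id, imputed$study_id),
                        method = if (x$method == "FE") "FE" else "DL",
                        level = x$level)
  out <- list(side = side, l0 = l0, imputed = imputed, adjusted = adjusted,
              iterations = iter, center_z = sgn * center, observed = x)
  class(out) <- "trim_fill"
  out
}

#' @export
print.trim_fill <- function(x, digits = 4, ...) {
  cat(sprintf("Trim-and-fill (L0 estimator, heavy side = %s)\n", x$side))
  cat(sprintf("Imputed studies: %d (after %d iteration%s)\n", x$l0,
              x$iterations, if (x$iterations == 1L) "" else "s"))
  cat(sprintf("Observed pooled r = %.*f; adjusted pooled r = %.*f [%.*f, %.*f]\n",
              digits, x$observed$r, digits, x$adjusted$r,
              digits, x$adjusted$ci.lb, digits, x$adjusted$ci.ub))
  invisible(x)
}
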