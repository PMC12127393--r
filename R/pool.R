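# Fixed- and random-effects pooling of Fisher-z effects.
#
# All pooling is carried out on the Fisher-z scale; point estimates and CI
# endpoints (not variances) are back-transformed to the correlation scale.
# Inference for the pooled effect uses the normal distribution (no
# Knapp-Hartung adjustment), and the between-study variance is estimated by
# DerSimonian-Laird; both choices match the defaults of the mainstream
# commercial meta-analysis software this pipeline mirrors.

#' DerSimonian-Laird estimate of the between-study variance
#'
#' \eqn{\tau^2 = \max(0, (Q - df)/C)} with \eqn{C = \sum w - \sum w^2/\sum w}
#' and fixed-effect weights \eqn{w = 1/v}.
#'
#' @param zi Numeric vector of Fisher-z effects (k >= 2).
#' @param vi Numeric vector of their sampling variances.
#' @return Non-negative between-study variance on the Fisher-z scale.
#' @export
tau2_dl <- function(zi, vi) {
  k <- length(zi)
  if (k < 2L)
    stop("tau-squared is undefined for fewer than 2 effects")
  if (length(vi) != k || any(vi <= 0))
    stop("'vi' must be positive and the same length as 'zi'")
  w <- 1 / vi
  zbar <- sum(w * zi) / sum(w)
  Q <- sum(w * (zi - zbar)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  max(0, (Q - (k - 1)) / C)
}

#' Higgins' I-squared from Q and its degrees of freedom
#'
#' The proportion of total effect-size variance attributable to true
#' between-study variation: \eqn{\max(0, (Q - df)/Q)}. Values above 0.75 are
#' conventionally read as high heterogeneity.
#'
#' @param Q Cochran heterogeneity statistic (non-negative).
#' @param df Degrees of freedom, k - 1 (at least 1).
#' @return Proportion in [0, 1).
#' @export
i_squared <- function(Q, df) {
  if (!is.numeric(Q) || Q < 0)
    stop("'Q' must be non-negative")
  if (!is.numeric(df) || df < 1)
    stop("'df' must be at least 1")
  if (Q <= 0) return(0)
  max(0, (Q - df) / Q)
}

# Core inverse-variance pooling on the z scale. tau2 = NULL means estimate by
# DL (method "DL"); a supplied tau2 is used as-is (common-tau2 subgroup
# pooling). Returns the bare statistics; meta_pool() wraps them.
.pool_z <- function(zi, vi, method, level, tau2 = NULL) {
  k <- length(zi)
  w_fe <- 1 / vi
  zbar_fe <- sum(w_fe * zi) / sum(w_fe)
  Q <- if (k > 1L) sum(w_fe * (zi - zbar_fe)^2) else 0
  df <- k - 1L
  I2 <- if (df >= 1L) i_squared(Q, df) else 0
  Qp <- if (df >= 1L) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_
  if (method == "FE") {
    tau2 <- 0
  } else if (is.null(tau2)) {
    tau2 <- tau2_dl(zi, vi)
  }
  w <- 1 / (vi + tau2)
  b <- sum(w * zi) / sum(w)
  se <- sqrt(1 / sum(w))
  zval <- b / se
  pval <- 2 * stats::pnorm(-abs(zval))
  crit <- stats::qnorm(1 - (1 - level) / 2)
  list(k = k, b = b, se = se, zval = zval, pval = pval,
       ci.lb.z = b - crit * se, ci.ub.z = b + crit * se,
       Q = Q, df = df, Qp = Qp, tau2 = tau2, I2 = I2)
}

#' Pool correlation coefficients across studies
#'
#' Inverse-variance pooling of correlations on the Fisher-z scale. The
#' default (`method = "DL"`) is the random-effects model with
#' DerSimonian-Laird between-study variance and weights
#' \eqn{1/(v_i + \tau^2)}; `method = "FE"` gives the fixed-effect model with
#' weights \eqn{1/v_i}. The heterogeneity statistics Q, I-squared and the
#' Q-test p-value are always computed at the fixed-effect stage.
#'
#' @param ri Correlations, one per study, each strictly inside (-1, 1).
#' @param ni Sample sizes (>= 4), same length as `ri`.
#' @param data Optional data frame in which to evaluate `ri`, `ni`, `slab`.
#' @param slab Optional study labels; defaults to `study_1`, `study_2`, ...
#' @param method `"DL"` (random effects, needs k >= 2) or `"FE"` (fixed
#'   effect, k >= 1).
#' @param level Confidence level for the pooled correlation, default 0.95.
#' @return An object of class `meta_pool`: a list with the pooled Fisher-z
#'   estimate `b`, its `se`, the back-transformed pooled correlation `r`,
#'   `ci.lb`/`ci.ub` on the r scale, test statistic `zval` and two-tailed
#'   `pval`, heterogeneity `Q`, `df`, `Qp`, `tau2`, `I2`, and the per-study
#'   effect table in `$data`.
#' @seealso [leave_one_out()], [egger_test()], [fail_safe_n()],
#'   [trim_and_fill()], [subgroup_analysis()]
#' @examples
#' fit <- meta_pool(c(0.2, 0.3, 0.4), c(103, 103, 103))
#' fit
#' coef(fit)
#' @export
meta_pool <- function(ri, ni, data = NULL, slab = NULL,
                      method = c("DL", "FE"), level = 0.95) {
  method <- match.arg(method)
  mf <- match.call()
  ri <- eval(mf$ri, data, parent.frame())
  ni <- eval(mf$ni, data, parent.frame())
  slab <- eval(mf$slab, data, parent.frame())
  if (!is.numeric(ri) || length(ri) == 0L)
    stop("'ri' must be a non-empty numeric vector")
  if (length(ni) != length(ri))
    stop("'ri' and 'ni' must have the same length")
  if (!(is.numeric(level) && length(level) == 1L && level > 0 && level < 1))
    stop("'level' must be a single number in (0, 1)")
  k <- length(ri)
  if (method == "DL" && k < 2L)
    stop("random-effects pooling needs at least 2 effects; use method = \"FE\" for a single study")
  if (is.null(slab)) slab <- paste0("study_", seq_len(k))
  slab <- as.character(slab)
  zi <- r_to_z(ri)
  vi <- z_variance(ni)
  res <- .pool_z(zi, vi, method, level)
  out <- c(res, list(
    r = tanh(res$b),
    ci.lb = tanh(res$ci.lb.z),
    ci.ub = tanh(res$ci.ub.z),
    method = method,
    level = level,
    data = data.frame(study_id = slab, r = ri, n = ni, z = zi, vi = vi,
                      sei = sqrt(vi), stringsAsFactors = FALSE),
    call = match.call()))
  class(out) <- "meta_pool"
  out
}

#' Pool one variable pair from a study table
#'
#' Convenience wrapper: [study_effects()] followed by [meta_pool()].
#'
#' @inheritParams study_effects
#' @inheritParams meta_pool
#' @return A `meta_pool` fit for the requested pair.
#' @export
pool_pair <- function(studies, pair = c("pa_mpa", "pa_sc", "sc_mpa"),
                      method = c("DL", "FE"), level = 0.95) {
  eff <- study_effects(studies, pair)
  fit <- meta_pool(eff$r, eff$n, slab = eff$study_id,
                   method = match.arg(method), level = level)
  fit$pair <- match.arg(pair)
  fit
}

#' @export
print.meta_pool <- function(x, digits = 4, ...) {
  lab <- if (x$method == "DL") "Random-effects model (DerSimonian-Laird)"
         else "Fixed-effect model"
  cat(lab, sprintf("(k = %d)", x$k), "\n\n")
  cat(sprintf("Pooled r: %.*f  %d%% CI [%.*f, %.*f]  (z = %.*f on Fisher scale)\n",
              digits, x$r, round(100 * x$level), digits, x$ci.lb, digits,
              x$ci.ub, digits, x$b))
  cat(sprintf("Test of the pooled effect: z = %.*f, p = %s\n",
              digits, x$zval, format.pval(x$pval, digits = digits)))
  if (x$df >= 1L)
    cat(sprintf("Heterogeneity: Q = %.*f (df = %d, p = %s), tau^2 = %.*f, I^2 = %.1f%%\n",
                digits, x$Q, x$df, format.pval(x$Qp, digits = digits),
                digits, x$tau2, 100 * x$I2))
  invisible(x)
}

#' @export
summary.meta_pool <- function(object, ...) {
  object$per_study <- transform(object$data, score = object$data$z / object$data$sei)
  class(object) <- c("summary.meta_pool", class(object))
  object
}

#' @export
print.summary.meta_pool <- function(x, digits = 4, ...) {
  NextMethod()
  cat("\nPer-study effects:\n")
  print(format(x$per_study, digits = digits), ...)
  invisible(x)
}

#' Pooled effect on the Fisher-z and correlation scales
#' @param object A `meta_pool` fit.
#' @param ... Ignored.
#' @return Named vector `c(z = ..., r = ...)`.
#' @export
coef.meta_pool <- function(object, ...) {
  c(z = object$b, r = object$r)
}

#' @export
confint.meta_pool <- function(object, parm, level, ...) {
  out <- matrix(c(object$ci.lb, object$ci.ub), nrow = 1,
                dimnames = list("r", c("lower", "upper")))
  out
}

#' Residuals of a pooled meta-analysis
#'
#' Deviations of the per-study Fisher-z effects from the pooled estimate,
#' raw (`type = "z"`) or standardized by \eqn{\sqrt{v_i + \tau^2}}
#' (`type = "standardized"`).
#'
#' @param object A `meta_pool` fit.
#' @param type `"z"` or `"standardized"`.
#' @param ... Ignored.
#' @export
residuals.meta_pool <- function(object, type = c("z", "standardized"), ...) {
  type <- match.arg(type)
  res <- object$data$z - object$b
  if (type == "standardized")
    res <- res / sqrt(object$data$vi + object$tau2)
  stats::setNames(res, object$data$study_id)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the meta-analysis k times, each time omitting one study and
#' re-estimating everything including tau-squared. The attribute `range`
#' holds the min/max of the leave-one-out pooled correlations; by
#' construction this interval contains the full-sample pooled r.
#'
#' @param x A `meta_pool` fit with k >= 3.
#' @return Data frame of class `meta_loo` with one row per omitted study
#'   (`omitted`, `r`, `ci.lb`, `ci.ub`, `pval`, `tau2`, `Q`) and an attribute
#'   `range = c(min, max)` of the pooled correlations.
#' @export
leave_one_out <- function(x) {
  stopifnot(inherits(x, "meta_pool"))
  k <- x$k
  if (k < 3L)
    stop("leave-one-out sensitivity needs at least 3 studies")
  rows <- lapply(seq_len(k), function(i) {
    fit <- meta_pool(x$data$r[-i], x$data$n[-i], slab = x$data$study_id[-i],
                     method = x$method, level = x$level)
    data.frame(omitted = x$data$study_id[i], r = fit$r, ci.lb = fit$ci.lb,
               ci.ub = fit$ci.ub, pval = fit$pval, tau2 = fit$tau2,
               Q = fit$Q, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "range") <- range(out$r)
  attr(out, "full_r") <- x$r
  class(out) <- c("meta_loo", "data.frame")
  out
}

#' @export
print.meta_loo <- function(x, digits = 4, ...) {
  cat("Leave-one-out sensitivity analysis\n")
  cat(sprintf("Full-sample pooled r = %.*f; leave-one-out range [%.*f, %.*f]\n\n",
              digits, attr(x, "full_r"), digits, attr(x, "range")[1],
              digits, attr(x, "range")[2]))
  print.data.frame(x, digits = digits, row.names = FALSE, ...)
  invisible(x)
}
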