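# Two-stage meta-analytic structural equation modelling (MASEM) for the
# PA -> SC -> MPA mediation system. Stage 1 pools each cell of the 3x3
# correlation matrix by univariate random-effects meta-analysis on the
# Fisher-z scale over the studies reporting it; stage 2 fits the saturated
# standardized path model
#   SC  = a * PA + e1
#   MPA = c * PA + b * SC + e2
# by closed-form least squares on the pooled correlation matrix and
# decomposes the total effect d = c + a*b.

.VARS <- c("PA", "SC", "MPA")

# model-implied correlations of the saturated path system (also used by the
# synthetic-data generator to invert the model)
.implied_matrix <- function(a, b, c) {
  R <- diag(3)
  dimnames(R) <- list(.VARS, .VARS)
  R["PA", "SC"] <- R["SC", "PA"] <- a
  R["PA", "MPA"] <- R["MPA", "PA"] <- c + a * b
  R["SC", "MPA"] <- R["MPA", "SC"] <- b + a * c
  R
}

#' Construct a pooled correlation matrix object
#'
#' Container for the stage-1 MASEM output (or for an externally reported
#' pooled matrix used as a worked-example input): the 3x3 PA/SC/MPA
#' correlation matrix, the per-cell study counts, and the effective sample
#' size carried into the stage-2 path model.
#'
#' @param r Either a symmetric 3x3 correlation matrix in (PA, SC, MPA) order,
#'   or a named length-3 vector `c(pa_mpa = , pa_sc = , sc_mpa = )`.
#' @param n_effective Positive integer effective sample size.
#' @param cell_k Optional named integer vector of per-cell study counts
#'   (`pa_mpa`, `pa_sc`, `sc_mpa`).
#' @param cell_ci Optional named list of per-cell confidence intervals.
#' @return Object of class `pooled_matrix`: list with `variables`, `r`
#'   (3x3 matrix), `cell_k`, `cell_ci`, `n_effective`.
#' @details The matrix must be exactly symmetric with a unit diagonal,
#'   off-diagonal entries strictly inside (-1, 1), and positive definite;
#'   a non-positive-definite matrix is rejected with the offending
#'   eigenvalue rather than silently bent.
#' @examples
#' m <- pooled_matrix(c(pa_mpa = -0.184, pa_sc = 0.213, sc_mpa = -0.449),
#'                    n_effective = 11386)
#' stage2_fit_mediation(m)
#' @export
pooled_matrix <- function(r, n_effective, cell_k = NULL, cell_ci = NULL) {
  if (is.numeric(r) && is.null(dim(r)) && length(r) == 3L) {
    if (is.null(names(r)) || !setequal(names(r), .PAIRS))
      stop("a length-3 'r' must be named: pa_mpa, pa_sc, sc_mpa")
    R <- .implied_matrix(0, 0, 0)
    R["PA", "MPA"] <- R["MPA", "PA"] <- r[["pa_mpa"]]
    R["PA", "SC"] <- R["SC", "PA"] <- r[["pa_sc"]]
    R["SC", "MPA"] <- R["MPA", "SC"] <- r[["sc_mpa"]]
  } else if (is.matrix(r) && all(dim(r) == c(3L, 3L))) {
    R <- r
    dimnames(R) <- list(.VARS, .VARS)
  } else {
    stop("'r' must be a 3x3 matrix or a named length-3 vector")
  }
  if (max(abs(R - t(R))) > 1e-8)
    stop("correlation matrix is not symmetric")
  R <- (R + t(R)) / 2
  if (any(abs(diag(R) - 1) > 1e-8))
    stop("correlation matrix must have a unit diagonal")
  diag(R) <- 1
  off <- R[upper.tri(R)]
  if (any(abs(off) >= 1 - 1e-12))
    stop("off-diagonal correlations must lie strictly inside (-1, 1)")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("pooled correlation matrix is not positive definite (smallest eigenvalue %.3e)",
                 min(ev)))
  if (!(is.numeric(n_effective) && length(n_effective) == 1L && n_effective >= 4))
    stop("'n_effective' must be a single number >= 4")
  out <- list(variables = .VARS, r = R, cell_k = cell_k, cell_ci = cell_ci,
              n_effective = n_effective)
  class(out) <- "pooled_matrix"
  out
}

#' @export
print.pooled_matrix <- function(x, digits = 3, ...) {
  cat("Pooled correlation matrix (effective n =", x$n_effective, ")\n")
  print(round(x$r, digits))
  if (!is.null(x$cell_k)) {
    cat("Studies per cell:\n")
    print(x$cell_k)
  }
  invisible(x)
}

#' Read / write a pooled correlation matrix as JSON
#'
#' The JSON schema is `{"variables": [...], "r": 3x3, "n_effective": int,
#' "cell_k": {...}}`.
#'
#' @param path File path.
#' @return `read_pooled_matrix()` returns a `pooled_matrix`;
#'   `write_pooled_matrix()` returns `path` invisibly.
#' @export
read_pooled_matrix <- function(path) {
  obj <- jsonlite::fromJSON(path)
  R <- matrix(unlist(obj$r), 3, 3)
  cell_k <- if (!is.null(obj$cell_k)) unlist(obj$cell_k) else NULL
  pooled_matrix(R, n_effective = obj$n_effective, cell_k = cell_k)
}

#' @rdname read_pooled_matrix
#' @param m A `pooled_matrix`.
#' @export
write_pooled_matrix <- function(m, path) {
  stopifnot(inherits(m, "pooled_matrix"))
  jsonlite::write_json(list(variables = m$variables, r = m$r,
                            n_effective = m$n_effective,
                            cell_k = as.list(m$cell_k)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Stage 1: pool the per-study correlation matrices
#'
#' Each of the three correlation cells is pooled by univariate random-effects
#' meta-analysis on the Fisher-z scale over the studies reporting it (missing
#' cells are simply omitted), then back-transformed and assembled into a
#' symmetric matrix whose positive definiteness is verified. This univariate
#' approximation to multivariate TSSEM is transparent and oracle-testable;
#' the interface isolates it so a multivariate estimator could be slotted in.
#'
#' The effective sample size for stage 2 is computed from the studies that
#' report the complete matrix: `n_rule = "sum"` (default) takes the sum of
#' their sample sizes; `"harmonic"` takes their harmonic mean times their
#' count. An explicit `n_effective` overrides either rule (used when
#' reproducing a published analysis whose effective n is reported).
#'
#' @param studies A `study_table` data frame.
#' @param level Confidence level for the per-cell CIs.
#' @param n_rule `"sum"` or `"harmonic"`.
#' @param n_effective Optional explicit effective sample size.
#' @return A [pooled_matrix()] with per-cell `cell_k` and `cell_ci`.
#' @export
stage1_pool_matrix <- function(studies, level = 0.95,
                               n_rule = c("sum", "harmonic"),
                               n_effective = NULL) {
  n_rule <- match.arg(n_rule)
  studies <- as_study_table(as.data.frame(studies))
  fits <- lapply(.PAIRS, function(p) {
    eff <- study_effects(studies, p)
    if (nrow(eff) < 2L)
      stop(sprintf("cell %s has %d contributing study/ies; at least 2 are required",
                   p, nrow(eff)))
    meta_pool(eff$r, eff$n, slab = eff$study_id, method = "DL", level = level)
  })
  names(fits) <- .PAIRS
  rs <- vapply(fits, `[[`, numeric(1), "r")
  cell_k <- vapply(fits, `[[`, integer(1), "k")
  cell_ci <- lapply(fits, function(f) c(lower = f$ci.lb, upper = f$ci.ub))
  if (is.null(n_effective)) {
    complete <- stats::complete.cases(studies[, .R_COLS])
    if (!any(complete))
      stop("no study reports the complete 3x3 matrix; supply 'n_effective' explicitly")
    n_c <- studies$n[complete]
    # "harmonic" = harmonic mean of the complete studies' n times their count
    n_effective <- switch(n_rule,
      sum = sum(n_c),
      harmonic = round(length(n_c)^2 / sum(1 / n_c)))
  }
  m <- pooled_matrix(c(pa_mpa = rs[["pa_mpa"]], pa_sc = rs[["pa_sc"]],
                       sc_mpa = rs[["sc_mpa"]]),
                     n_effective = n_effective, cell_k = cell_k,
                     cell_ci = cell_ci)
  m$cell_fits <- fits
  m
}

#' Stage 2: fit the saturated mediation path model
#'
#' Solves the standardized path system `SC = a*PA + e1`,
#' `MPA = c*PA + b*SC + e2` in closed form on a pooled correlation matrix:
#' `a = r(PA,SC)` and `(c, b)` solve the 2x2 normal equations of the
#' two-predictor regression of MPA on PA and SC. The indirect effect is
#' `ab = a*b`, the total effect `d = c + ab` (which equals `r(PA,MPA)`
#' identically), and the proportion mediated is `ab/d` when the mediation is
#' consistent. Wald standard errors use OLS asymptotics with the effective
#' sample size. The model is saturated (df = 0), so the reported fit indices
#' are trivially perfect and the model-implied matrix reproduces the input.
#'
#' @param m A [pooled_matrix()], or a bare symmetric 3x3 matrix in
#'   (PA, SC, MPA) order (then `n_effective` is required).
#' @param n_effective Effective sample size when `m` is a bare matrix.
#' @param level Confidence level for the Wald intervals, default 0.95.
#' @return Object of class `masem_fit`: list with `coefficients`
#'   (`a`, `b`, `c`, `ab`, `d`), `se`, `ci` (Wald), `prop_mediated`
#'   (see [proportion_mediated()]), `fit` (`chi2`, `df`, `cfi`, `tli`,
#'   `rmsea`), `implied` (model-implied matrix), `R` (input matrix),
#'   `n_effective`.
#' @examples
#' fit <- stage2_fit_mediation(
#'   pooled_matrix(c(pa_mpa = -0.184, pa_sc = 0.213, sc_mpa = -0.449), 11386))
#' summary(fit)
#' @export
stage2_fit_mediation <- function(m, n_effective = NULL, level = 0.95) {
  if (inherits(m, "pooled_matrix")) {
    R <- m$r
    n <- m$n_effective
  } else {
    if (is.null(n_effective))
      stop("'n_effective' is required when 'm' is a bare matrix")
    m <- pooled_matrix(m, n_effective)
    R <- m$r
    n <- m$n_effective
  }
  a <- R["PA", "SC"]
  if (abs(a) >= 1 - 1e-12)
    stop("PA and SC are collinear (|r| = 1); the path model is not identified")
  S <- R[c("PA", "SC"), c("PA", "SC")]
  rv <- R[c("PA", "SC"), "MPA"]
  beta <- solve(S, rv)
  cc <- unname(beta["PA"])
  b <- unname(beta["SC"])
  ab <- a * b
  d <- cc + ab
  # Wald SEs: standardized-OLS asymptotics at the effective sample size
  se_a <- sqrt((1 - a^2) / (n - 2))
  R2_m <- sum(beta * rv)
  sigma2_m <- (1 - R2_m) / (n - 3)
  V_cb <- sigma2_m * solve(S)
  se_c <- sqrt(V_cb["PA", "PA"])
  se_b <- sqrt(V_cb["SC", "SC"])
  se_ab <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)    # Sobel
  se_d <- sqrt((1 - d^2) / (n - 2))
  coefs <- c(a = a, b = b, c = cc, ab = ab, d = d)
  se <- c(a = se_a, b = se_b, c = se_c, ab = se_ab, d = se_d)
  crit <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(lower = coefs - crit * se, upper = coefs + crit * se)
  implied <- .implied_matrix(a, b, cc)
  # ML discrepancy of the saturated model: identically zero up to rounding
  F_ml <- log(det(implied)) - log(det(R)) +
    sum(diag(R %*% solve(implied))) - 3
  chi2 <- max(0, (n - 1) * F_ml)
  vc <- matrix(0, 3, 3, dimnames = list(c("a", "c", "b"), c("a", "c", "b")))
  vc["a", "a"] <- se_a^2
  vc[c("c", "b"), c("c", "b")] <- V_cb
  out <- list(coefficients = coefs, se = se, ci = ci, vcov = vc,
              prop_mediated = proportion_mediated(ab, d),
              fit = list(chi2 = chi2, df = 0L, cfi = 1, tli = 1, rmsea = 0),
              implied = implied, R = R, n_effective = n, level = level)
  class(out) <- "masem_fit"
  out
}

#' Proportion of the total effect that is mediated
#'
#' `ab / d`. Defined only for consistent mediation (indirect and total
#' effects of the same sign, non-zero total); for inconsistent mediation the
#' proportion is reported as undefined with an explanatory code instead of a
#' misleading number. A zero indirect effect gives 0; `c = 0` (full
#' mediation) gives 1.
#'
#' @param ab Indirect effect, or a `masem_fit` (then `d` is ignored).
#' @param d Total effect.
#' @return List with `value` (number, or `NA` when undefined), `defined`
#'   (logical) and `code` (`NULL` or `"inconsistent_mediation"`).
#' @export
proportion_mediated <- function(ab, d = NULL) {
  if (inherits(ab, "masem_fit")) {
    d <- ab$coefficients[["d"]]
    ab <- ab$coefficients[["ab"]]
  }
  if (ab == 0)
    return(list(value = 0, defined = TRUE, code = NULL))
  if (d == 0 || sign(ab) != sign(d))
    return(list(value = NA_real_, defined = FALSE,
                code = "inconsistent_mediation"))
  list(value = ab / d, defined = TRUE, code = NULL)
}

#' Monte-Carlo confidence interval for the indirect effect
#'
#' Draws `(a*, b*)` from independent normal distributions centered at the
#' estimated paths with their Wald standard errors and returns the
#' equal-tail quantiles of the product `a* b*`. This is the standard
#' Monte-Carlo method for the sampling distribution of a product of normal
#' coefficients, which is skewed even when both factors are normal.
#'
#' @param fit A `masem_fit`.
#' @param draws Number of Monte-Carlo draws, at least 1000 (default 10000).
#' @param level Confidence level, default 0.95.
#' @param seed Optional integer seed for reproducibility.
#' @return Named numeric `c(lower, upper)`.
#' @export
indirect_ci_montecarlo <- function(fit, draws = 10000L, level = 0.95,
                                   seed = NULL) {
  stopifnot(inherits(fit, "masem_fit"))
  if (draws < 1000L)
    stop("Monte-Carlo intervals need at least 1000 draws")
  if (anyNA(fit$se[c("a", "b")]))
    stop("path standard errors are missing")
  if (!is.null(seed)) set.seed(seed)
  a_star <- stats::rnorm(draws, fit$coefficients[["a"]], fit$se[["a"]])
  b_star <- stats::rnorm(draws, fit$coefficients[["b"]], fit$se[["b"]])
  q <- stats::quantile(a_star * b_star,
                       c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' @export
coef.masem_fit <- function(object, ...) object$coefficients

#' @export
vcov.masem_fit <- function(object, ...) object$vcov

#' @export
confint.masem_fit <- function(object, parm, level, ...) {
  ci <- object$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.masem_fit <- function(x, digits = 3, ...) {
  cat("Saturated mediation path model (PA -> SC -> MPA)\n")
  cat(sprintf("Effective n = %d\n\n", as.integer(x$n_effective)))
  tab <- cbind(estimate = x$coefficients, se = x$se, x$ci)
  print(round(tab, digits))
  pm <- x$prop_mediated
  if (pm$defined) {
    cat(sprintf("\nProportion mediated: %.1f%%\n", 100 * pm$value))
  } else {
    cat(sprintf("\nProportion mediated: undefined (%s)\n", pm$code))
  }
  invisible(x)
}

#' @export
summary.masem_fit <- function(object, ...) {
  class(object) <- c("summary.masem_fit", class(object))
  object
}

#' @export
print.summary.masem_fit <- function(x, digits = 3, ...) {
  NextMethod()
  cat(sprintf("Model fit: chi2 = %.2e (df = %d), CFI = %g, TLI = %g, RMSEA = %g (saturated)\n",
              x$fit$chi2, x$fit$df, x$fit$cfi, x$fit$tli, x$fit$rmsea))
  invisible(x)
}
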