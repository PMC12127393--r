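#' Fisher's z transformation of a correlation coefficient
#'
#' Maps a Pearson correlation \eqn{r} to the variance-stabilizing scale
#' \eqn{z = 0.5 \log((1+r)/(1-r)) = \mathrm{atanh}(r)}, on which sample
#' correlations are approximately normal with variance \eqn{1/(n-3)}.
#'
#' Correlations within `1e-12` of \eqn{\pm 1} are rejected rather than
#' clamped: a correlation that close to unity is almost always a data error,
#' and silent clamping would hide it.
#'
#' @param r Numeric vector of correlations, each strictly inside (-1, 1).
#' @return Numeric vector of Fisher-z values.
#' @seealso [z_to_r()], [z_variance()]
#' @examples
#' r_to_z(0.5)        # 0.5 * log(3)
#' z_to_r(r_to_z(0.31))
#' @export
r_to_z <- function(r) {
  if (!is.numeric(r) || length(r) == 0L)
    stop("'r' must be a non-empty numeric vector")
  if (anyNA(r))
    stop("'r' contains missing values")
  if (any(abs(r) >= 1 - 1e-12))
    stop("correlations must lie strictly inside (-1, 1); Fisher's z is undefined at |r| = 1")
  atanh(r)
}

#' Back-transform a Fisher-z value to a correlation
#'
#' The exact inverse of [r_to_z()]: \eqn{r = (e^{2z}-1)/(e^{2z}+1) = \tanh(z)}.
#'
#' @param z Numeric vector of finite Fisher-z values.
#' @return Numeric vector of correlations in (-1, 1).
#' @export
z_to_r <- function(z) {
  if (!is.numeric(z) || length(z) == 0L)
    stop("'z' must be a non-empty numeric vector")
  if (anyNA(z) || any(!is.finite(z)))
    stop("'z' must be finite")
  tanh(z)
}

#' Sampling variance of a Fisher-z transformed correlation
#'
#' Returns \eqn{V_z = 1/(n-3)}, the large-sample variance of the Fisher-z
#' transform of a sample correlation based on `n` observations.
#'
#' @param n Numeric vector of sample sizes, each at least 4.
#' @return Numeric vector of variances.
#' @examples
#' z_variance(103)   # 0.01
#' @export
z_variance <- function(n) {
  if (!is.numeric(n) || length(n) == 0L || anyNA(n))
    stop("'n' must be a non-empty numeric vector without missing values")
  if (any(n < 4))
    stop("sample sizes must be at least 4 so that 1/(n-3) is finite and positive")
  1 / (n - 3)
}

#' Standard-normal score of a Fisher-z effect
#'
#' The per-study test statistic \eqn{z/SE_z}, used e.g. as input to the
#' fail-safe N computation and to the publication-censoring rule of the
#' synthetic-data generator.
#'
#' @param z Fisher-z effect value(s).
#' @param se Standard error(s), \eqn{\sqrt{1/(n-3)}}; must be positive.
#' @return Numeric vector of standard-normal scores.
#' @export
study_z_score <- function(z, se) {
  if (!is.numeric(z) || !is.numeric(se))
    stop("'z' and 'se' must be numeric")
  if (any(se <= 0))
    stop("'se' must be positive")
  z / se
}
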