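# Independent brute-force oracles, written as plain summations so they stay
# independent of the package's implementation paths.

# fixed-effect pooling by direct summation
oracle_pool_fixed <- function(zi, vi) {
  w <- numeric(length(zi))
  for (i in seq_along(zi)) w[i] <- 1 / vi[i]
  zbar <- 0
  for (i in seq_along(zi)) zbar <- zbar + w[i] * zi[i]
  zbar <- zbar / sum(w)
  Q <- 0
  for (i in seq_along(zi)) Q <- Q + w[i] * (zi[i] - zbar)^2
  list(b = zbar, se = sqrt(1 / sum(w)), Q = Q, df = length(zi) - 1)
}

oracle_tau2_dl <- function(zi, vi) {
  fe <- oracle_pool_fixed(zi, vi)
  w <- 1 / vi
  C <- sum(w) - sum(w * w) / sum(w)
  max(0, (fe$Q - fe$df) / C)
}

oracle_pool_random <- function(zi, vi) {
  t2 <- oracle_tau2_dl(zi, vi)
  w <- 1 / (vi + t2)
  b <- sum(w * zi) / sum(w)
  list(b = b, se = sqrt(1 / sum(w)), tau2 = t2)
}

# two-parameter OLS of standardized effect on precision, closed form
oracle_egger <- function(zi, sei) {
  x <- 1 / sei
  y <- zi / sei
  k <- length(x)
  xbar <- mean(x); ybar <- mean(y)
  Sxx <- sum((x - xbar)^2)
  slope <- sum((x - xbar) * (y - ybar)) / Sxx
  intercept <- ybar - slope * xbar
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (k - 2)
  se_int <- sqrt(s2 * (1 / k + xbar^2 / Sxx))
  t <- intercept / se_int
  list(intercept = intercept, slope = slope, se_intercept = se_int,
       t = t, p = 2 * stats::pt(-abs(t), k - 2))
}

# between-group fixed-effect heterogeneity from group estimates and variances
oracle_q_between <- function(theta, v) {
  w <- 1 / v
  tbar <- sum(w * theta) / sum(w)
  sum(w * (theta - tbar)^2)
}

# brute-force stage-2 fit: numerical least squares on the discrepancy
# between model-implied and observed correlations
oracle_stage2 <- function(R) {
  obj <- function(p) {
    a <- p[1]; b <- p[2]; cc <- p[3]
    (R[1, 2] - a)^2 + (R[1, 3] - (cc + a * b))^2 + (R[2, 3] - (b + a * cc))^2
  }
  fit <- stats::optim(c(0, 0, 0), obj, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 1000))
  stats::setNames(fit$par, c("a", "b", "c"))
}

# random positive-definite 3x3 correlation matrix via random loadings
random_pd_corr3 <- function() {
  repeat {
    L <- matrix(stats::rnorm(9), 3, 3)
    S <- L %*% t(L) + diag(3) * 0.5
    R <- stats::cov2cor(S)
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > 1e-3 &&
        max(abs(R[upper.tri(R)])) < 0.95)
      return(R)
  }
}

# direct simulation of Fisher-z effects for pooling recovery checks
sim_z_effects <- function(k, mu_z, tau, ni) {
  vi <- 1 / (ni - 3)
  zi <- stats::rnorm(k, mu_z, tau) + stats::rnorm(k, 0, sqrt(vi))
  list(ri = tanh(zi), ni = ni, zi = zi, vi = vi)
}
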