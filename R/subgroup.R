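# Mixed-effects subgroup moderation: random-effects pooling within each
# moderator level, fixed-effect contrast between the level estimates.

#' Subgroup (moderator) analysis of pooled correlations
#'
#' Within each moderator level the correlations are pooled by the
#' random-effects model of [meta_pool()]; by default each level gets its own
#' DerSimonian-Laird tau-squared (`tau2 = "separate"`), with
#' `tau2 = "common"` pooling a single tau-squared from the full data set and
#' using it in every level. Between levels, the fixed-effect heterogeneity
#' statistic
#' \eqn{Q_B = \sum_j w_j (\hat\theta_j - \bar\theta)^2}, with
#' \eqn{w_j = 1/SE(\hat\theta_j)^2} and \eqn{\bar\theta} the weighted mean
#' of the level estimates, is referred to a chi-square distribution on
#' (number of levels - 1) degrees of freedom.
#'
#' Levels with a single study cannot support a random-effects fit; they are
#' dropped with a warning rather than aborting the analysis.
#'
#' @param ri Correlations, one per study.
#' @param ni Sample sizes, same length.
#' @param group Moderator level for each study (character or factor).
#' @param data Optional data frame in which to evaluate `ri`, `ni`, `group`,
#'   `slab`.
#' @param slab Optional study labels.
#' @param level Confidence level for the within-level summaries.
#' @param tau2 `"separate"` (default) or `"common"`.
#' @return Object of class `meta_subgroup`: list with `groups` (named list
#'   of `meta_pool` fits), `table` (per-level k, r, CI, z, p, tau2, I2),
#'   `Q_between`, `df_between`, `p_between`, `dropped` (labels of excluded
#'   single-study levels).
#' @examples
#' set.seed(1)
#' g <- rep(c("college", "secondary"), each = 5)
#' r <- tanh(rnorm(10, ifelse(g == "college", -0.2, -0.1), 0.05))
#' subgroup_analysis(r, rep(400, 10), g)
#' @export
subgroup_analysis <- function(ri, ni, group, data = NULL, slab = NULL,
                              level = 0.95, tau2 = c("separate", "common")) {
  tau2 <- match.arg(tau2)
  mf <- match.call()
  ri <- eval(mf$ri, data, parent.frame())
  ni <- eval(mf$ni, data, parent.frame())
  group <- eval(mf$group, data, parent.frame())
  slab <- eval(mf$slab, data, parent.frame())
  if (length(group) != length(ri) || length(ni) != length(ri))
    stop("'ri', 'ni' and 'group' must have the same length")
  if (anyNA(group))
    stop("'group' contains missing labels")
  group <- as.character(group)
  if (is.null(slab)) slab <- paste0("study_", seq_along(ri))
  tab <- table(group)
  dropped <- names(tab)[tab < 2L]
  if (length(dropped) > 0L) {
    warning("excluding moderator level(s) with a single study: ",
            paste(dropped, collapse = ", "))
    keep <- !(group %in% dropped)
    ri <- ri[keep]; ni <- ni[keep]; group <- group[keep]; slab <- slab[keep]
  }
  labels <- sort(unique(group))
  if (length(labels) < 2L)
    stop("subgroup analysis needs at least 2 moderator levels with k >= 2 each")
  common_tau2 <- if (tau2 == "common") tau2_dl(r_to_z(ri), z_variance(ni)) else NULL
  fits <- lapply(labels, function(lab) {
    idx <- group == lab
    zi <- r_to_z(ri[idx]); vi <- z_variance(ni[idx])
    res <- .pool_z(zi, vi, method = "DL", level = level, tau2 = common_tau2)
    out <- c(res, list(r = tanh(res$b), ci.lb = tanh(res$ci.lb.z),
                       ci.ub = tanh(res$ci.ub.z), method = "DL",
                       level = level,
                       data = data.frame(study_id = slab[idx], r = ri[idx],
                                         n = ni[idx], z = zi, vi = vi,
                                         sei = sqrt(vi),
                                         stringsAsFactors = FALSE)))
    class(out) <- "meta_pool"
    out
  })
  names(fits) <- labels
  theta <- vapply(fits, `[[`, numeric(1), "b")
  wj <- 1 / vapply(fits, `[[`, numeric(1), "se")^2
  theta_bar <- sum(wj * theta) / sum(wj)
  Q_between <- sum(wj * (theta - theta_bar)^2)
  df_between <- length(labels) - 1L
  p_between <- stats::pchisq(Q_between, df_between, lower.tail = FALSE)
  table_out <- data.frame(
    group = labels,
    k = vapply(fits, `[[`, integer(1), "k"),
    r = vapply(fits, `[[`, numeric(1), "r"),
    ci.lb = vapply(fits, `[[`, numeric(1), "ci.lb"),
    ci.ub = vapply(fits, `[[`, numeric(1), "ci.ub"),
    zval = vapply(fits, `[[`, numeric(1), "zval"),
    pval = vapply(fits, `[[`, numeric(1), "pval"),
    tau2 = vapply(fits, `[[`, numeric(1), "tau2"),
    I2 = vapply(fits, `[[`, numeric(1), "I2"),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(groups = fits, table = table_out, Q_between = Q_between,
              df_between = df_between, p_between = p_between,
              tau2_rule = tau2, dropped = dropped)
  class(out) <- "meta_subgroup"
  out
}

#' @export
print.meta_subgroup <- function(x, digits = 4, ...) {
  cat("Mixed-effects subgroup analysis\n")
  cat(sprintf("Between-group: Q = %.*f (df = %d), p = %s\n\n", digits,
              x$Q_between, x$df_between,
              format.pval(x$p_between, digits = digits)))
  print(format(x$table, digits = digits), row.names = FALSE, ...)
  if (length(x$dropped) > 0L)
    cat("\nExcluded single-study level(s):",
        paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
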