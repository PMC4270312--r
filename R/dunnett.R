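# Dunnett many-to-one comparisons after one-way ANOVA.
#
# The joint distribution of the treatment-vs-control t statistics is a
# central multivariate t with product correlation rho_ij = lambda_i*lambda_j,
# lambda_i = sqrt(n_i/(n_i + n0)). Conditioning on the shared control-mean
# normal Z0 and the pooled-scale chi variable W = sqrt(chisq_df/df) makes the
# comparisons independent, leaving a 2-D numerical integral.

# P(max_j |T_j| <= t) for the Dunnett statistic vector
dunnett_cdf <- function(t, lambdas, df) {
  if (t <= 0) return(0)
  s <- sqrt(1 - lambdas^2)
  inner <- function(u) {
    # u: scalar scale value W; integrate the control normal out
    f <- function(z) {
      acc <- rep(1, length(z))
      for (j in seq_along(lambdas)) {
        acc <- acc * (stats::pnorm((t * u + lambdas[j] * z) / s[j]) -
                      stats::pnorm((-t * u + lambdas[j] * z) / s[j]))
      }
      acc * stats::dnorm(z)
    }
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
  }
  if (is.infinite(df)) return(inner(1))
  dens <- function(u) {
    exp((1 - df / 2) * log(2) + (df / 2) * log(df) + (df - 1) * log(u) -
          df * u^2 / 2 - lgamma(df / 2))
  }
  outer_f <- function(u) vapply(u, function(ui) dens(ui) * inner(ui), 1.0)
  stats::integrate(outer_f, 0, Inf, rel.tol = 1e-9, abs.tol = 1e-12)$value
}

#' Two-sided Dunnett-adjusted p-values
#'
#' @param tstats observed t statistics, one per treatment-vs-control
#'   comparison.
#' @param lambdas per-comparison `sqrt(n_i/(n_i+n0))` correlation loadings.
#' @param df pooled error degrees of freedom.
#' @param method `"integration"` (numerical, default) or `"mc"`
#'   (seeded Monte-Carlo fallback).
#' @param n_draws,seed Monte-Carlo settings.
#' @return adjusted p-values in `[raw p, 1]`.
#' @export
dunnett_p_adjust <- function(tstats, lambdas, df,
                             method = c("integration", "mc"),
                             n_draws = 1e5, seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(tstats) == length(lambdas))
  if (method == "integration") {
    vapply(abs(tstats), function(t) {
      min(max(1 - dunnett_cdf(t, lambdas, df), 0), 1)
    }, 1.0)
  } else {
    s <- sqrt(1 - lambdas^2)
    with_seed(seed, {
      z0 <- stats::rnorm(n_draws)
      w <- sqrt(stats::rchisq(n_draws, df) / df)
      tmax <- rep(0, n_draws)
      for (j in seq_along(lambdas)) {
        tj <- (lambdas[j] * z0 + s[j] * stats::rnorm(n_draws)) / w
        tmax <- pmax(tmax, abs(tj))
      }
      vapply(abs(tstats), function(t) mean(tmax >= t), 1.0)
    })
  }
}

#' One-way ANOVA with Dunnett's many-to-one post hoc test
#'
#' Equal-variance pooled-error ANOVA across all groups, followed by two-sided
#' Dunnett comparisons of every non-control group against the control.
#'
#' @param groups named list of numeric vectors (one per group), each `n >= 2`.
#' @param control index or name of the control group.
#' @param method,n_draws,seed see [dunnett_p_adjust()].
#' @return list of class `dunnett_result`: `f_statistic`, `f_pvalue`,
#'   `df_error`, and `comparisons` data.frame (`group, estimate, t, p_raw,
#'   p_adjusted, star`).
#' @export
anova_dunnett <- function(groups, control = 1L,
                          method = c("integration", "mc"),
                          n_draws = 1e5, seed = 1L) {
  method <- match.arg(method)
  if (length(groups) < 2L) stop_fs("need >= 2 groups")
  ns <- vapply(groups, length, 1L)
  if (any(ns < 2L)) stop_fs("every group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  ci <- if (is.character(control)) match(control, names(groups)) else as.integer(control)
  if (is.na(ci) || ci < 1L || ci > length(groups)) stop_fs("bad control group")

  k <- length(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, 1.0)
  sse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1.0))
  df_err <- N - k
  if (df_err < 1L || sse <= 0) stop_fs("no residual variance to pool")
  ms_err <- sse / df_err
  grand <- sum(ns * means) / N
  ms_grp <- sum(ns * (means - grand)^2) / (k - 1)
  f_stat <- ms_grp / ms_err
  f_p <- stats::pf(f_stat, k - 1, df_err, lower.tail = FALSE)

  trt <- setdiff(seq_len(k), ci)
  est <- means[trt] - means[ci]
  se <- sqrt(ms_err * (1 / ns[trt] + 1 / ns[ci]))
  tstat <- est / se
  lambdas <- sqrt(ns[trt] / (ns[trt] + ns[ci]))
  p_raw <- 2 * stats::pt(-abs(tstat), df_err)
  p_adj <- pmax(dunnett_p_adjust(tstat, lambdas, df_err, method = method,
                                 n_draws = n_draws, seed = seed),
                p_raw)
  structure(list(
    f_statistic = f_stat, f_pvalue = f_p, df_error = df_err,
    control = names(groups)[ci],
    comparisons = data.frame(
      group = names(groups)[trt], estimate = unname(est), t = unname(tstat),
      p_raw = unname(p_raw), p_adjusted = unname(p_adj),
      star = star_annotation(unname(p_adj)), stringsAsFactors = FALSE)),
    class = "dunnett_result")
}

#' @export
print.dunnett_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.4g (error df = %d); Dunnett vs %s\n",
              x$f_statistic, x$f_pvalue, x$df_error, x$control))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Significance star annotation
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, otherwise `n.s.`.
#' @param p p-value vector in `[0, 1]`.
#' @return character vector.
#' @export
star_annotation <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop_fs("p must lie in [0, 1]")
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s.")))
}
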