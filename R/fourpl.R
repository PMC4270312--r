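# Four-parameter logistic (4PL) curves: construction, evaluation, inversion,
# least-squares fitting. Used for dose-response EC50/IC50 and ELISA calibration.

#' Construct a four-parameter logistic curve
#'
#' The curve is `response(c) = bottom + (top - bottom) / (1 + (ec50/c)^hill)`.
#' With `hill > 0` the response rises from `bottom` (c -> 0) to `top`
#' (c -> Inf); flipping the sign of `hill` mirrors the direction. At
#' `c = ec50` the response is the midpoint `(top + bottom)/2` for any `hill`.
#'
#' @param bottom,top asymptotic responses; must differ.
#' @param ec50 half-maximal concentration (> 0), in whatever concentration
#'   unit the curve is used with (package presets use molar).
#' @param hill Hill slope, nonzero.
#' @return object of class `four_pl`.
#' @export
four_pl <- function(bottom, top, ec50, hill) {
  if (!is.finite(bottom) || !is.finite(top) || bottom == top) {
    stop_fs("4PL requires finite bottom != top")
  }
  if (!is.finite(ec50) || ec50 <= 0) stop_fs("4PL requires ec50 > 0")
  if (!is.finite(hill) || hill == 0) stop_fs("4PL requires a nonzero hill slope")
  structure(list(bottom = bottom, top = top, ec50 = ec50, hill = hill),
            class = "four_pl")
}

#' @export
print.four_pl <- function(x, ...) {
  cat(sprintf("<four_pl> bottom=%g top=%g ec50=%g hill=%g\n",
              x$bottom, x$top, x$ec50, x$hill))
  invisible(x)
}

#' Evaluate a 4PL curve
#'
#' @param params a [four_pl()].
#' @param conc concentration vector (>= 0; `0` returns the appropriate
#'   asymptote as a limit).
#' @return numeric response vector.
#' @export
predict_4pl <- function(params, conc) {
  stopifnot(inherits(params, "four_pl"))
  if (any(conc < 0)) stop_fs("concentrations must be nonnegative")
  out <- numeric(length(conc))
  pos <- conc > 0
  x <- exp(params$hill * (log(params$ec50) - log(conc[pos])))
  out[pos] <- params$bottom + (params$top - params$bottom) / (1 + x)
  # c -> 0 limit: bottom when hill > 0 else top
  out[!pos] <- if (params$hill > 0) params$bottom else params$top
  out
}

#' Invert a 4PL curve (signal -> concentration)
#'
#' Closed-form inverse; only signals strictly between the two asymptotes are
#' invertible.
#'
#' @param params a [four_pl()].
#' @param signal response value(s) strictly between `bottom` and `top`.
#' @return concentration(s) in the curve's concentration unit.
#' @export
invert_4pl <- function(params, signal) {
  stopifnot(inherits(params, "four_pl"))
  lo <- min(params$bottom, params$top)
  hi <- max(params$bottom, params$top)
  if (any(signal <= lo)) {
    stop_fs("signal %g at or below the lower asymptote (%g): not invertible",
            min(signal), lo)
  }
  if (any(signal >= hi)) {
    stop_fs("signal %g at or above the upper asymptote (%g): not invertible",
            max(signal), hi)
  }
  x <- (params$top - params$bottom) / (signal - params$bottom) - 1
  params$ec50 * exp(-log(x) / params$hill)
}

#' Fit a 4PL curve by least squares
#'
#' Profiles the two nonlinear parameters (log EC50 and Hill slope) with a
#' Nelder-Mead search; for fixed (EC50, hill) the asymptotes enter linearly
#' and are solved exactly, which makes the fit robust and lets noiseless data
#' be recovered essentially to machine precision. Concentrations are handled
#' on the log scale internally; the loss is unweighted least squares on the
#' linear response scale.
#'
#' @param concentrations positive concentration vector (any consistent unit).
#' @param responses response vector, same length.
#' @param direction `"auto"` (default), `"up"` or `"down"`: sign constraint
#'   used only for initialization.
#' @return object of class `four_pl_fit`: the fitted [four_pl()] under
#'   `$params`, plus `$rss`, `$sigma`, `$se` (approximate standard errors for
#'   bottom/top/log_ec50/hill), `$converged`, `$degenerate`.
#' @export
fit_4pl <- function(concentrations, responses, direction = c("auto", "up", "down")) {
  direction <- match.arg(direction)
  if (length(concentrations) != length(responses)) {
    stop_fs("concentrations and responses must have equal length")
  }
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stop_fs("concentrations must be positive and finite")
  }
  if (length(unique(concentrations)) < 4L) {
    stop_fs("need >= 4 distinct concentrations to fit a 4PL")
  }
  lc <- log(concentrations)
  y <- responses

  # noise estimate: pooled within-concentration SD (0 when no replicates)
  groups <- split(y, concentrations)
  nrep <- vapply(groups, length, 1L)
  if (any(nrep > 1L)) {
    ss <- sum(vapply(groups[nrep > 1L], function(g) sum((g - mean(g))^2), 1.0))
    noise_sd <- sqrt(ss / sum(nrep[nrep > 1L] - 1L))
  } else {
    noise_sd <- 0
  }
  means <- vapply(groups, mean, 1.0)
  if (diff(range(y)) == 0 || diff(range(means)) < 3 * noise_sd) {
    return(structure(list(params = NULL, degenerate = TRUE, converged = FALSE,
                          rss = sum((y - mean(y))^2), sigma = stats::sd(y),
                          se = NULL),
                     class = "four_pl_fit"))
  }

  le_lo <- min(lc) - 5; le_hi <- max(lc) + 5
  sse <- function(theta) {
    # soft box on log-EC50 and hill keeps Nelder-Mead out of degenerate flats
    if (theta[1] < le_lo || theta[1] > le_hi || abs(theta[2]) > 50) {
      return(1e12 * (1 + abs(theta[1]) + abs(theta[2])))
    }
    g <- 1 / (1 + exp(theta[2] * (theta[1] - lc)))
    fit <- stats::lm.fit(cbind(1, g), y)
    sum(fit$residuals^2)
  }
  hill0 <- switch(direction,
    up = 1, down = -1,
    auto = if (stats::cor(lc, y) >= 0) 1 else -1)
  # midpoint crossing as EC50 start
  mid <- (max(means) + min(means)) / 2
  ord <- order(as.numeric(names(means)))
  cm <- as.numeric(names(means))[ord]
  le0 <- log(cm[which.min(abs(means[ord] - mid))])

  best <- NULL
  for (start in list(c(le0, hill0), c(le0, 2 * hill0), c(median(lc), hill0))) {
    opt <- stats::optim(start, sse, method = "Nelder-Mead",
                        control = list(reltol = 1e-15, maxit = 5000))
    opt <- stats::optim(opt$par, sse, method = "Nelder-Mead",
                        control = list(reltol = 1e-15, maxit = 5000))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (!is.finite(best$value)) stop_fs("4PL fit failed to converge (non-finite loss)")
  theta <- best$par
  g <- 1 / (1 + exp(theta[2] * (theta[1] - lc)))
  lin <- stats::lm.fit(cbind(1, g), y)
  bottom <- unname(lin$coefficients[1])
  top <- unname(bottom + lin$coefficients[2])
  if (bottom > top) {
    # mirrored parameterization is the same curve: canonicalize to top > bottom
    tmp <- bottom; bottom <- top; top <- tmp
    theta[2] <- -theta[2]
  }
  params <- four_pl(bottom, top, exp(theta[1]), theta[2])

  rss <- sum(lin$residuals^2)
  dof <- max(length(y) - 4L, 1L)
  sigma <- sqrt(rss / dof)
  se <- tryCatch({
    pv <- c(bottom, top, theta[1], theta[2])
    f <- function(p) p[1] + (p[2] - p[1]) / (1 + exp(p[4] * (p[3] - lc)))
    J <- vapply(seq_along(pv), function(j) {
      h <- max(1e-6, abs(pv[j]) * 1e-6)
      pp <- pm <- pv; pp[j] <- pv[j] + h; pm[j] <- pv[j] - h
      (f(pp) - f(pm)) / (2 * h)
    }, numeric(length(y)))
    sqrt(diag(sigma^2 * solve(crossprod(J))))
  }, error = function(e) rep(NA_real_, 4L))
  names(se) <- c("bottom", "top", "log_ec50", "hill")

  structure(list(params = params, degenerate = FALSE,
                 converged = best$convergence == 0L,
                 rss = rss, sigma = sigma, se = se),
            class = "four_pl_fit")
}

#' @export
print.four_pl_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<four_pl_fit> degenerate (flat data), no EC50\n")
  } else {
    cat(sprintf("<four_pl_fit> ec50=%g hill=%.3f bottom=%g top=%g rss=%.3g\n",
                x$params$ec50, x$params$hill, x$params$bottom, x$params$top, x$rss))
  }
  invisible(x)
}
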