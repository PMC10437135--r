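#' @export
print.ubm <- function(x, ...) {
  cat("Bayesian Gaussian regression (ubm)\n")
  cat("  formula:", deparse(x$formula), "\n")
  if (!is.null(x$group)) cat("  random intercept:", x$group, "(",
                             nlevels(x$g), "levels )\n")
  cat("  n =", length(x$y), "rows;", x$chains, "chains x",
      x$iter - x$warmup, "post-warmup iterations\n")
  if (x$n_dropped > 0) cat("  listwise-deleted rows:", x$n_dropped, "\n")
  print(round(x$summary, 3))
  if (!x$converged) cat("  WARNING: not converged (some R-hat > 1.05)\n")
  invisible(x)
}

#' Posterior summary of a fitted model
#'
#' @param object a [ubm()] fit.
#' @param ... unused.
#' @return The fit's coefficient summary augmented with the R-squared
#'   partition, printed with interval level and diagnostics.
#' @export
summary.ubm <- function(object, ...) {
  r2 <- r2_partition(object)
  structure(list(summary = object$summary, r2 = r2,
                 ci_level = object$ci_level, converged = object$converged,
                 n = length(object$y), group = object$group),
            class = "summary.ubm")
}

#' @export
print.summary.ubm <- function(x, ...) {
  cat(sprintf("Posterior summary (%d%% %s intervals), n = %d\n",
              round(100 * x$ci_level), "equal-tailed", x$n))
  print(round(x$summary, 3))
  cat(sprintf("marginal R2 = %.3f, conditional R2 = %.3f\n",
              x$r2[["marginal_r2"]], x$r2[["conditional_r2"]]))
  if (!x$converged) cat("WARNING: some R-hat > 1.05\n")
  invisible(x)
}

#' @export
coef.ubm <- function(object, ...) {
  stats::setNames(colMeans(ubm_beta(object)), object$coef_names)
}

#' @export
nobs.ubm <- function(object, ...) length(object$y)

#' @export
fitted.ubm <- function(object, ...) {
  mu <- as.numeric(object$X %*% coef(object))
  if (!is.null(object$g))
    mu <- mu + unname(colMeans(ubm_u(object))[as.integer(object$g)])
  mu
}

#' @export
residuals.ubm <- function(object, ...) object$y - fitted(object)

#' Posterior predictions for new data
#'
#' @param object a [ubm()] fit.
#' @param newdata data.frame with the model's covariates (default: the
#'   fitted data). Group levels unseen in the fit have their random
#'   intercept integrated out.
#' @param interval add equal-tailed credible bounds at the fit's `ci_level`?
#' @param ... unused.
#' @return A data.frame with `fit` (posterior mean of the linear predictor)
#'   and optionally `lwr`, `upr`.
#' @export
predict.ubm <- function(object, newdata = NULL, interval = FALSE, ...) {
  if (is.null(newdata)) newdata <- object$data
  X <- stats::model.matrix(stats::delete.response(stats::terms(object$formula)),
                           newdata)
  beta <- ubm_beta(object)
  mu <- beta %*% t(X)
  if (!is.null(object$group) && object$group %in% names(newdata)) {
    lev <- as.character(newdata[[object$group]])
    known <- lev %in% levels(object$g)
    if (any(known)) {
      u <- ubm_u(object)
      mu[, known] <- mu[, known] +
        u[, match(lev[known], levels(object$g)), drop = FALSE]
    }
  }
  out <- data.frame(fit = colMeans(mu))
  if (interval) {
    a <- (1 - object$ci_level) / 2
    out$lwr <- apply(mu, 2, stats::quantile, probs = a)
    out$upr <- apply(mu, 2, stats::quantile, probs = 1 - a)
  }
  out
}

#' Posterior predictive simulation
#'
#' Draws `nsim` replicated response vectors from the posterior predictive
#' distribution of the fitted rows.
#'
#' @param object a [ubm()] fit.
#' @param nsim number of replicated datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return A matrix with `length(object$y)` rows and `nsim` columns.
#' @export
simulate.ubm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  beta <- ubm_beta(object)
  s_idx <- sample(nrow(beta), nsim, replace = nsim > nrow(beta))
  mu <- beta[s_idx, , drop = FALSE] %*% t(object$X)
  if (!is.null(object$g))
    mu <- mu + ubm_u(object)[s_idx, as.integer(object$g), drop = FALSE]
  sigma <- object$draws[s_idx, "sigma"]
  out <- vapply(seq_len(nsim), function(j)
    stats::rnorm(ncol(mu), mu[j, ], sigma[j]), numeric(ncol(mu)))
  matrix(out, ncol = nsim)
}

#' Coefficient interval plot
#'
#' Dot-and-whisker plot of the fixed-effect posteriors (mean and credible
#' interval), intercept omitted by default.
#'
#' @param x a [ubm()] fit.
#' @param intercept include the intercept row?
#' @param ... passed to [graphics::plot()].
#' @export
plot.ubm <- function(x, intercept = FALSE, ...) {
  s <- x$summary[seq_along(x$coef_names), , drop = FALSE]
  if (!intercept) s <- s[rownames(s) != "(Intercept)", , drop = FALSE]
  k <- nrow(s)
  graphics::plot(s$mean, seq_len(k), xlim = range(s$lower, s$upper, 0),
                 ylim = c(0.5, k + 0.5), yaxt = "n", pch = 16,
                 xlab = "posterior coefficient", ylab = "", ...)
  graphics::segments(s$lower, seq_len(k), s$upper, seq_len(k))
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(k), labels = rownames(s), las = 1)
  invisible(x)
}

#' @export
print.elpd_comparison <- function(x, ...) {
  cat("LOO-ELPD model comparison (best first):\n")
  print.data.frame(cbind(x[1], round(x[-1], 2)), row.names = FALSE)
  invisible(x)
}
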