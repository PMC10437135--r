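#' Bayesian Gaussian regression with an optional society random intercept
#'
#' Fits, by MCMC through JAGS, the multilevel linear model used to explain
#' song unusualness: a Gaussian likelihood with a linear predictor over the
#' standardized covariates and, optionally, a random intercept per group
#' (society). Priors are weakly informative: Normal(0, `prior_scale_beta`) on
#' coefficients, half-Student-t(`prior_df_sd`, 0, `prior_scale_sd`) on the
#' residual and group standard deviations.
#'
#' @param formula model formula for the fixed effects, e.g.
#'   `response ~ neighbours_radius + phylo_nn + kinship_u + economic_u`.
#'   Use `response ~ 1` for an intercept-only model.
#' @param data a data.frame (e.g. from [assemble_predictors()]); rows with
#'   missing values in any used variable are dropped (listwise deletion,
#'   reported).
#' @param group name of a grouping column for a random intercept (e.g.
#'   `"society_id"`), or `NULL` for fixed effects only.
#' @param chains,iter,warmup MCMC settings: number of chains, total
#'   iterations per chain, and burn-in iterations discarded from each chain
#'   (defaults 4, 4000, 2000).
#' @param ci_level equal-tailed credible interval level (default 0.89).
#' @param seed integer seed; every chain's RNG is derived from it.
#' @param prior_scale_beta,prior_scale_sd,prior_df_sd prior hyperparameters.
#' @param hpd use highest-posterior-density intervals instead of equal-tailed?
#' @param quiet suppress JAGS progress output.
#' @return An object of class `ubm` with posterior draws, a coefficient
#'   summary (mean, sd, interval bounds), R-hat and effective sample size per
#'   parameter, and a `converged` flag (all R-hat < 1.05). Methods:
#'   [print.ubm()], [summary.ubm()], `coef`, `fitted`, `residuals`,
#'   `predict`, `plot`, `simulate`, `nobs`.
#' @seealso [r2_partition()], [loo_elpd()], [compare_elpd()], [kfold_cv()],
#'   [select_radius()]
#' @export
ubm <- function(formula, data, group = NULL, chains = 4, iter = 4000,
                warmup = 2000, ci_level = 0.89, seed = 1,
                prior_scale_beta = 2.5, prior_scale_sd = 2.5, prior_df_sd = 3,
                hpd = FALSE, quiet = TRUE) {
  stopifnot(warmup < iter, ci_level > 0, ci_level < 1, chains >= 1)
  mf_vars <- all.vars(formula)
  used <- c(mf_vars, group)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols))
    stop("columns not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  keep <- stats::complete.cases(data[used])
  n_dropped <- sum(!keep)
  d <- data[keep, , drop = FALSE]
  mf <- stats::model.frame(formula, d)
  y <- unname(stats::model.response(mf))
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X))
    stop("singular design: fixed-effect columns are linearly dependent",
         call. = FALSE)
  if (nrow(X) < 10 * ncol(X))
    warning("fewer than 10 rows per fixed effect (n = ", nrow(X), ", p = ",
            ncol(X), ")", call. = FALSE)
  g <- if (!is.null(group)) factor(d[[group]]) else NULL

  draws <- run_jags_gaussian(X, y, g, chains = chains, iter = iter,
                             warmup = warmup, seed = seed,
                             prior_scale_beta = prior_scale_beta,
                             prior_scale_sd = prior_scale_sd,
                             prior_df_sd = prior_df_sd, quiet = quiet)

  diag <- mcmc_diagnostics(draws$samples)
  mat <- normalize_par_names(
    as.matrix(do.call(rbind, lapply(draws$samples, as.matrix))))
  chain_id <- rep(seq_along(draws$samples), each = nrow(draws$samples[[1]]))

  par_names <- colnames(mat)
  core <- c(paste0("beta[", seq_len(ncol(X)), "]"), "sigma",
            if (!is.null(g)) "sigma_u")
  summ <- posterior_summary(mat[, core, drop = FALSE], ci_level, hpd)
  rownames(summ) <- c(colnames(X), "sigma", if (!is.null(g)) "sigma_u")
  summ$rhat <- diag$rhat[core]
  summ$ess <- diag$ess[core]

  fit <- structure(list(
    call = match.call(), formula = formula, group = group,
    X = X, y = y, g = g, data = d, n_dropped = n_dropped,
    draws = mat, chain_id = chain_id,
    coef_names = colnames(X),
    summary = summ, rhat = diag$rhat, ess = diag$ess,
    converged = all(diag$rhat[core] < 1.05, na.rm = TRUE),
    chains = chains, iter = iter, warmup = warmup, seed = seed,
    ci_level = ci_level, hpd = hpd,
    priors = list(scale_beta = prior_scale_beta, scale_sd = prior_scale_sd,
                  df_sd = prior_df_sd)),
    class = "ubm")
  fit
}

jags_model_string <- function(has_group) {
  paste0("
model {
  for (i in 1:N) {
    mu[i] <- inprod(X[i,], beta[])", if (has_group) " + u[g[i]]", "
    y[i] ~ dnorm(mu[i], tau)
  }
  for (p in 1:P) { beta[p] ~ dnorm(0, prec_beta) }
  sigma ~ dt(0, prec_sd, df_sd) T(0,)
  tau <- pow(sigma, -2)",
  if (has_group) "
  for (j in 1:J) { u[j] ~ dnorm(0, tau_u) }
  sigma_u ~ dt(0, prec_sd, df_sd) T(0,)
  tau_u <- pow(sigma_u, -2)", "
}")
}

run_jags_gaussian <- function(X, y, g, chains, iter, warmup, seed,
                              prior_scale_beta, prior_scale_sd, prior_df_sd,
                              quiet = TRUE) {
  has_group <- !is.null(g)
  dat <- list(N = nrow(X), P = ncol(X), X = X, y = as.numeric(y),
              prec_beta = 1 / prior_scale_beta^2,
              prec_sd = 1 / prior_scale_sd^2, df_sd = prior_df_sd)
  if (has_group) {
    dat$g <- as.integer(g)
    dat$J <- nlevels(g)
  }
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (abs(seed) * 1009L + ch * 7919L) %% 2147483629L + 1L)
  })
  monitor <- c("beta", "sigma", if (has_group) c("sigma_u", "u"))
  run <- function() {
    jm <- rjags::jags.model(textConnection(jags_model_string(has_group)),
                            data = dat, inits = inits, n.chains = chains,
                            n.adapt = max(100L, warmup %/% 4L), quiet = TRUE)
    stats::update(jm, n.iter = warmup, progress.bar = "none")
    rjags::coda.samples(jm, variable.names = monitor,
                        n.iter = iter - warmup, progress.bar = "none")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()
  list(samples = samples)
}

# JAGS drops the index on length-1 parameter vectors ("beta" not "beta[1]").
normalize_par_names <- function(mat) {
  cn <- colnames(mat)
  cn[cn == "beta"] <- "beta[1]"
  cn[cn == "u"] <- "u[1]"
  colnames(mat) <- cn
  mat
}

mcmc_diagnostics <- function(samples) {
  nm <- colnames(samples[[1]])
  ess <- tryCatch(coda::effectiveSize(samples),
                  error = function(e) stats::setNames(rep(NA_real_, length(nm)), nm))
  rhat <- if (length(samples) >= 2) {
    gd <- tryCatch(coda::gelman.diag(samples, autoburnin = FALSE,
                                     multivariate = FALSE)$psrf[, 1],
                   error = function(e) stats::setNames(rep(NA_real_, length(nm)), nm))
    gd
  } else stats::setNames(rep(NA_real_, length(nm)), nm)
  fix <- function(v) { names(v)[names(v) == "beta"] <- "beta[1]"
    names(v)[names(v) == "u"] <- "u[1]"; v }
  list(rhat = fix(rhat[nm]), ess = fix(ess[nm]))
}

posterior_summary <- function(mat, ci_level, hpd = FALSE) {
  a <- (1 - ci_level) / 2
  if (hpd) {
    hp <- coda::HPDinterval(coda::as.mcmc(mat), prob = ci_level)
    lo <- hp[, 1]; hi <- hp[, 2]
  } else {
    lo <- apply(mat, 2, stats::quantile, probs = a)
    hi <- apply(mat, 2, stats::quantile, probs = 1 - a)
  }
  data.frame(mean = colMeans(mat), sd = apply(mat, 2, stats::sd),
             lower = lo, upper = hi)
}

ubm_beta <- function(fit) {
  fit$draws[, paste0("beta[", seq_along(fit$coef_names), "]"), drop = FALSE]
}

ubm_u <- function(fit) {
  if (is.null(fit$g)) return(NULL)
  fit$draws[, paste0("u[", seq_len(nlevels(fit$g)), "]"), drop = FALSE]
}

# S x N pointwise log-likelihood matrix of the fitted rows.
loglik_matrix <- function(fit) {
  beta <- ubm_beta(fit)
  mu <- beta %*% t(fit$X)
  if (!is.null(fit$g)) mu <- mu + ubm_u(fit)[, as.integer(fit$g), drop = FALSE]
  sigma <- fit$draws[, "sigma"]
  t(vapply(seq_len(nrow(mu)), function(s)
    stats::dnorm(fit$y, mu[s, ], sigma[s], log = TRUE),
    numeric(ncol(mu))))
}

#' Marginal and conditional R-squared of a fitted model
#'
#' Variance-partitioned R-squared computed per posterior draw and summarised
#' by the posterior mean: marginal = var(fixed-effect predictions) /
#' (var_fixed + var_group + var_residual); conditional adds the group
#' variance to the numerator. Models without a group effect have var_group =
#' 0, so the two coincide.
#'
#' @param fit a [ubm()] fit.
#' @return A named numeric vector `c(marginal_r2, conditional_r2)`, with the
#'   per-draw values in attribute `"draws"`.
#' @export
r2_partition <- function(fit) {
  beta <- ubm_beta(fit)
  mu_f <- beta %*% t(fit$X)
  var_f <- apply(mu_f, 1, stats::var)
  var_g <- if (!is.null(fit$g)) fit$draws[, "sigma_u"]^2 else 0
  var_e <- fit$draws[, "sigma"]^2
  denom <- var_f + var_g + var_e
  marg <- var_f / denom
  cond <- (var_f + var_g) / denom
  structure(c(marginal_r2 = mean(marg), conditional_r2 = mean(cond)),
            draws = cbind(marginal = marg, conditional = cond),
            class = "r2_partition")
}

#' @export
print.r2_partition <- function(x, ...) {
  cat(sprintf("marginal R2 = %.3f, conditional R2 = %.3f\n",
              x[["marginal_r2"]], x[["conditional_r2"]]))
  invisible(x)
}

#' PSIS leave-one-out expected log pointwise predictive density
#'
#' Estimates LOO-ELPD from the posterior draws by Pareto-smoothed importance
#' sampling; higher is better. `pareto_k` values above 0.7 flag observations
#' whose importance weights are unreliable (use [exact_loo()] to verify).
#'
#' @param fit a [ubm()] fit.
#' @return A list with `elpd`, `se`, `pointwise` (per-row values) and
#'   `pareto_k` diagnostics.
#' @export
loo_elpd <- function(fit) {
  res <- psis_loo_from_loglik(loglik_matrix(fit))
  res$n <- length(res$pointwise)
  res
}

#' Exact leave-one-out ELPD by refitting
#'
#' Refits the model once per observation, each time holding that observation
#' out, and evaluates its log predictive density under the refit posterior.
#' For a held-out row whose group is absent from the training rows the group
#' intercept is integrated out (predictive sd \eqn{\sqrt{\sigma^2+\sigma_u^2}}).
#' Intended for small instances as the importance-sampling oracle.
#'
#' @param fit a [ubm()] fit.
#' @param chains,iter,warmup MCMC settings for each refit (defaults: the
#'   original fit's).
#' @return A list with `elpd`, `se` and `pointwise`.
#' @export
exact_loo <- function(fit, chains = fit$chains, iter = fit$iter,
                      warmup = fit$warmup) {
  n <- length(fit$y)
  pw <- numeric(n)
  for (i in seq_len(n)) {
    pw[i] <- refit_lpd(fit, train = setdiff(seq_len(n), i), test = i,
                       chains = chains, iter = iter, warmup = warmup,
                       seed = fit$seed + i)
  }
  list(elpd = sum(pw), se = stats::sd(pw) * sqrt(n), pointwise = pw)
}

# Refit on `train` rows and return summed log predictive density of `test`
# rows (vector of per-row lpd contributions summed per call site as needed).
refit_lpd <- function(fit, train, test, chains, iter, warmup, seed) {
  g_tr <- if (!is.null(fit$g)) droplevels(fit$g[train]) else NULL
  draws <- run_jags_gaussian(fit$X[train, , drop = FALSE], fit$y[train], g_tr,
                             chains = chains, iter = iter, warmup = warmup,
                             seed = seed,
                             prior_scale_beta = fit$priors$scale_beta,
                             prior_scale_sd = fit$priors$scale_sd,
                             prior_df_sd = fit$priors$df_sd)
  mat <- normalize_par_names(
    as.matrix(do.call(rbind, lapply(draws$samples, as.matrix))))
  beta <- mat[, paste0("beta[", seq_along(fit$coef_names), "]"), drop = FALSE]
  sigma <- mat[, "sigma"]
  out <- 0
  for (i in test) {
    mu <- as.numeric(beta %*% fit$X[i, ])
    sd_i <- sigma
    if (!is.null(fit$g)) {
      lev <- as.character(fit$g[i])
      if (lev %in% levels(g_tr)) {
        mu <- mu + mat[, paste0("u[", match(lev, levels(g_tr)), "]")]
      } else {
        sd_i <- sqrt(sigma^2 + mat[, "sigma_u"]^2)
      }
    }
    ll <- stats::dnorm(fit$y[i], mu, sd_i, log = TRUE)
    out <- out + (log_sum_exp(ll) - log(length(ll)))
  }
  out
}

#' Compare models by LOO-ELPD
#'
#' Ranks fits on the same rows by PSIS-LOO ELPD and reports, for each model,
#' the ELPD difference to the best model with its standard error (from the
#' pointwise differences).
#'
#' @param ... named [ubm()] fits, or a single named list of fits.
#' @return A data.frame (class `elpd_comparison`) sorted best first with
#'   columns `model`, `elpd`, `se`, `delta_elpd`, `delta_se`, `max_pareto_k`.
#' @export
compare_elpd <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) && !inherits(fits[[1]], "ubm"))
    fits <- fits[[1]]
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  ys <- lapply(fits, function(f) unname(f$y))
  if (length(unique(vapply(ys, length, 1L))) != 1L ||
      !all(vapply(ys[-1], function(y) isTRUE(all.equal(y, ys[[1]])), TRUE)))
    stop("models were not fitted on identical rows", call. = FALSE)
  loos <- lapply(fits, loo_elpd)
  elpd <- vapply(loos, `[[`, numeric(1), "elpd")
  best <- which.max(elpd)
  n <- length(ys[[1]])
  delta <- numeric(length(fits)); dse <- numeric(length(fits))
  for (i in seq_along(fits)) {
    d <- loos[[i]]$pointwise - loos[[best]]$pointwise
    delta[i] <- sum(d)
    dse[i] <- stats::sd(d) * sqrt(n)
  }
  out <- data.frame(model = names(fits), elpd = elpd,
                    se = vapply(loos, `[[`, numeric(1), "se"),
                    delta_elpd = delta, delta_se = dse,
                    max_pareto_k = vapply(loos, function(l)
                      max(l$pareto_k, na.rm = TRUE), numeric(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$elpd), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("elpd_comparison", "data.frame")
  out
}

#' Choose the neighbour-count radius by bivariate model comparison
#'
#' Fits, for each candidate radius, the bivariate model
#' `response ~ neighbour count` with a society random intercept, and ranks
#' the fits by LOO-ELPD. Radii whose ELPD is within `tie_margin` of the best
#' are reported as practically equivalent; the best-ranked is chosen.
#'
#' @param scores song scores from [unusualness()].
#' @param societies society table with coordinates.
#' @param radii candidate radii in km (default 250, 500, 1000).
#' @param tie_margin ELPD difference below which models count as tied
#'   (default 4).
#' @param chains,iter,warmup,seed MCMC settings passed to [ubm()].
#' @return A list with `chosen` (radius in km), `comparison` (the
#'   [compare_elpd()] table with a `radius` column) and `tied` (radii within
#'   `tie_margin` of the best).
#' @export
select_radius <- function(scores, societies, radii = c(250, 500, 1000),
                          tie_margin = 4, chains = 4, iter = 4000,
                          warmup = 2000, seed = 1) {
  fits <- list()
  for (r in radii) {
    nb <- neighbour_counts(societies, r)
    d <- data.frame(response = scores$unusualness,
                    society_id = scores$society_id,
                    n_neighbours = nb$n_neighbours[
                      match(scores$society_id, nb$society_id)],
                    stringsAsFactors = FALSE)
    d <- d[stats::complete.cases(d), , drop = FALSE]
    d <- standardize(d, c("response", "n_neighbours"))
    fits[[paste0("radius_", r)]] <-
      ubm(response ~ n_neighbours, d, group = "society_id",
          chains = chains, iter = iter, warmup = warmup, seed = seed)
  }
  if (length(radii) == 1L) {
    return(list(chosen = radii, comparison = NULL, tied = radii))
  }
  comp <- compare_elpd(fits)
  comp$radius <- as.numeric(sub("radius_", "", comp$model))
  tied <- comp$radius[abs(comp$delta_elpd) < tie_margin]
  list(chosen = comp$radius[1], comparison = comp, tied = tied)
}

#' k-fold cross-validation of a fitted model
#'
#' Splits the fitted rows into `k` disjoint folds by a seeded shuffle, refits
#' the model `k` times leaving one fold out each time, and reports the
#' held-out log predictive density per observation together with the
#' stability of the fixed-effect posterior means across folds.
#'
#' @param fit a [ubm()] fit.
#' @param k number of folds (default 10); `k = n` gives exact leave-one-out.
#' @param seed seed for the fold shuffle and the refits.
#' @param chains,iter,warmup MCMC settings for each refit.
#' @return A list with `elpd_kfold`, `se`, `pointwise`, `folds` (fold id per
#'   row) and `coef_stability` (per-fold fixed-effect posterior means and
#'   their across-fold sd).
#' @export
kfold_cv <- function(fit, k = 10, seed = fit$seed, chains = fit$chains,
                     iter = fit$iter, warmup = fit$warmup) {
  n <- length(fit$y)
  if (k > n) stop("k cannot exceed the number of rows", call. = FALSE)
  old <- .Random.seed_safe()
  set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n))
  .Random.seed_restore(old)
  pw <- numeric(n)
  coefs <- matrix(NA_real_, k, length(fit$coef_names),
                  dimnames = list(NULL, fit$coef_names))
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- setdiff(seq_len(n), test)
    g_tr <- if (!is.null(fit$g)) droplevels(fit$g[train]) else NULL
    draws <- run_jags_gaussian(fit$X[train, , drop = FALSE], fit$y[train],
                               g_tr, chains = chains, iter = iter,
                               warmup = warmup, seed = seed + f,
                               prior_scale_beta = fit$priors$scale_beta,
                               prior_scale_sd = fit$priors$scale_sd,
                               prior_df_sd = fit$priors$df_sd)
    mat <- normalize_par_names(
      as.matrix(do.call(rbind, lapply(draws$samples, as.matrix))))
    beta <- mat[, paste0("beta[", seq_along(fit$coef_names), "]"),
                drop = FALSE]
    coefs[f, ] <- colMeans(beta)
    sigma <- mat[, "sigma"]
    for (i in test) {
      mu <- as.numeric(beta %*% fit$X[i, ])
      sd_i <- sigma
      if (!is.null(fit$g)) {
        lev <- as.character(fit$g[i])
        if (lev %in% levels(g_tr))
          mu <- mu + mat[, paste0("u[", match(lev, levels(g_tr)), "]")]
        else sd_i <- sqrt(sigma^2 + mat[, "sigma_u"]^2)
      }
      ll <- stats::dnorm(fit$y[i], mu, sd_i, log = TRUE)
      pw[i] <- log_sum_exp(ll) - log(length(ll))
    }
  }
  list(elpd_kfold = sum(pw), se = stats::sd(pw) * sqrt(n), pointwise = pw,
       folds = folds,
       coef_stability = list(per_fold = coefs, sd = apply(coefs, 2, stats::sd)))
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
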