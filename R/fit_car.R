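#' MCMC settings
#'
#' @param n_chains number of chains (run sequentially from one seeded RNG
#'   stream, so results are bit-reproducible).
#' @param n_iter iterations per chain (including burn-in).
#' @param n_burnin burn-in iterations discarded per chain; proposal step
#'   sizes adapt only during burn-in.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed for the whole run.
#' @return list of class `mcmc_control`.
#' @export
mcmc_control <- function(n_chains = 4, n_iter = 5000, n_burnin = 2000,
                         thin = 1, seed = 1) {
  stopifnot(n_chains >= 1, n_iter > n_burnin, n_burnin >= 0, thin >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed)), class = "mcmc_control")
}

#' Prior settings for the spatial models
#'
#' Defaults follow common practice for these models: gamma(1, 0.0005) on the
#' precisions, a vague normal(0, 1000) intercept, uniform(0,1) on the Leroux
#' mixing parameter, and a log-normal (median 1, sdlog 0.5) prior on the
#' shared-component scaling parameter.
#'
#' @param tau_shape,tau_rate gamma hyperprior on every precision.
#' @param alpha_var variance of the normal intercept prior.
#' @param sdlog_kappa sdlog of the log-normal prior on the sharing parameter
#'   (joint model only).
#' @return list of class `car_prior`.
#' @export
car_prior <- function(tau_shape = 1, tau_rate = 0.0005, alpha_var = 1000,
                      sdlog_kappa = 0.5) {
  stopifnot(tau_shape > 0, tau_rate > 0, alpha_var > 0, sdlog_kappa > 0)
  structure(list(tau_shape = tau_shape, tau_rate = tau_rate,
                 alpha_var = alpha_var, sdlog_kappa = sdlog_kappa),
            class = "car_prior")
}

# align a (possibly named) per-tract vector with graph$tract_ids
.align <- function(x, graph, what) {
  if (!is.null(names(x))) {
    m <- match(graph$tract_ids, names(x))
    if (anyNA(m)) stop(what, " missing for some tracts", call. = FALSE)
    x <- x[m]
  }
  if (length(x) != graph$n) stop(what, " must have one value per tract", call. = FALSE)
  unname(as.numeric(x))
}

# split-chain R-hat (Gelman-Rubin, split halves)
.split_rhat <- function(x, chain) {
  halves <- lapply(split(x, chain), function(v) {
    h <- length(v) %/% 2
    list(v[seq_len(h)], v[(h + 1):(2 * h)])
  })
  segs <- unlist(halves, recursive = FALSE)
  m <- length(segs); n <- length(segs[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(segs, mean, numeric(1))
  vars <- vapply(segs, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size via Geyer initial positive sequence, pooled chains
.ess <- function(x, chain) {
  per <- vapply(split(x, chain), function(v) {
    n <- length(v)
    if (stats::var(v) == 0) return(n)
    r <- stats::acf(v, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
    s <- 0
    for (k in seq(1, length(r) - 1, by = 2)) {
      pair <- r[k] + r[k + 1]
      if (is.na(pair) || pair <= 0) break
      s <- s + pair
    }
    n / (1 + 2 * s)
  }, numeric(1))
  sum(per)
}

#' Fit a Bayesian spatial Poisson disease-mapping model
#'
#' Fits `O_i ~ Poisson(E_i * theta_i)` with a log-linear relative risk by
#' Metropolis-within-Gibbs MCMC:
#' \describe{
#'   \item{`bym`}{`log theta = alpha + u + v`, intrinsic CAR spatial effect
#'     `u ~ ICAR(tau_u)` plus exchangeable `v_i ~ N(0, 1/tau_v)` (the classic
#'     convolution model).}
#'   \item{`icar`}{spatial effect only.}
#'   \item{`iid`}{exchangeable effect only (no spatial term).}
#'   \item{`leroux`}{single effect with precision
#'     `tau * ((1-lambda) I + lambda Q)`, interpolating between independence
#'     (`lambda = 0`) and the intrinsic CAR (`lambda = 1`).}
#' }
#' Intrinsic fields are kept sum-to-zero per connected component (the
#' intercept carries the level). Precisions get conjugate gamma updates; the
#' fields, intercept and `logit(lambda)` get adaptive random-walk updates.
#' Tracts with `E_i = 0` are excluded from the likelihood (with a warning)
#' and reported with `NA` summaries.
#'
#' @param O observed counts per tract (named vector or in graph order).
#' @param E expected counts per tract.
#' @param graph an `adjacency_graph` covering all tracts.
#' @param model one of `"bym"`, `"icar"`, `"leroux"`, `"iid"`.
#' @param prior a [car_prior()].
#' @param mcmc an [mcmc_control()].
#' @param fix_lambda optionally fix the Leroux mixing parameter (0..1);
#'   `NULL` leaves it free with a uniform prior.
#' @return An object of class `car_fit`. Key pieces: `$summary` (per-tract
#'   `O, E, SRR, SRR_median, ci_low, ci_high, PP, exceeds` on the percent
#'   scale), `$hyper` (posterior summaries of the hyperparameters), `$dic`,
#'   `$waic`, `$rhat`, `$ess`, `$converged`, and the raw `$draws`.
#' @seealso [posterior_probability()], [dic()], [waic()], [compare_models()]
#' @export
fit_car <- function(O, E, graph, model = c("bym", "icar", "leroux", "iid"),
                    prior = car_prior(), mcmc = mcmc_control(),
                    fix_lambda = NULL) {
  model <- match.arg(model)
  O <- .align(O, graph, "O"); E <- .align(E, graph, "E")
  if (any(O < 0) || any(E < 0)) stop("O and E must be non-negative", call. = FALSE)
  in_lik <- as.integer(E > 0)
  if (!any(in_lik == 1L)) stop("E <= 0 on all tracts", call. = FALSE)
  if (any(in_lik == 0L))
    warning(sum(in_lik == 0L), " tract(s) with E = 0 excluded from the likelihood")
  if (model %in% c("bym", "icar", "leroux")) {
    d <- lengths(graph$nbr)
    if (model != "leroux" && any(d == 0))
      warning("isolated tract(s) carry no spatial effect (treated as unstructured)")
  }
  n <- graph$n
  comp <- graph_components(graph) - 1L
  nbr0 <- lapply(graph$nbr, function(v) as.integer(v - 1L))
  eigQ <- numeric(n)
  if (model == "leroux")
    eigQ <- eigen(as.matrix(build_icar_precision(graph, allow_islands = TRUE)),
                  symmetric = TRUE, only.values = TRUE)$values
  fl <- if (is.null(fix_lambda)) NA_real_ else {
    stopifnot(fix_lambda >= 0, fix_lambda <= 1)
    as.numeric(fix_lambda)
  }
  alpha0 <- log((sum(O[in_lik == 1]) + 0.5) / sum(E[in_lik == 1]))
  # start the latent field at the residual log-SMR so the precision updates
  # do not lock it at zero (the usual ICAR initialization trap)
  res0 <- log((O + 0.5) / pmax(E, 0.5)) - alpha0
  res0 <- res0 - stats::ave(res0, graph_components(graph))
  tau0 <- 1 / max(stats::var(res0), 0.05)

  set.seed(mcmc$seed)
  theta <- NULL; hyper_draws <- list(); chain_id <- integer(0)
  nkeep <- (mcmc$n_iter - mcmc$n_burnin) %/% mcmc$thin
  for (ch in seq_len(mcmc$n_chains)) {
    jit <- stats::rnorm(n, 0, 0.05)
    inits <- list(alpha = alpha0 + stats::rnorm(1, 0, 0.1),
                  u = as.numeric(scale(res0 + jit, scale = FALSE)),
                  v = stats::rnorm(n, 0, 0.05),
                  tau_u = tau0 * exp(stats::rnorm(1, 0, 0.3)),
                  tau_v = 2 * tau0 * exp(stats::rnorm(1, 0, 0.3)),
                  lambda = stats::runif(1, 0.2, 0.8))
    res <- car_mcmc_cpp(O, E, in_lik, nbr0, comp, model,
                        prior$tau_shape, prior$tau_rate, prior$alpha_var,
                        mcmc$n_iter, mcmc$n_burnin, mcmc$thin, fl, eigQ, inits)
    theta <- cbind(theta, res$theta)
    hyper_draws$alpha <- c(hyper_draws$alpha, res$alpha)
    hyper_draws$tau_u <- c(hyper_draws$tau_u, res$tau_u)
    hyper_draws$tau_v <- c(hyper_draws$tau_v, res$tau_v)
    hyper_draws$lambda <- c(hyper_draws$lambda, res$lambda)
    chain_id <- c(chain_id, rep(ch, nkeep))
  }
  rownames(theta) <- graph$tract_ids

  active <- switch(model,
                   bym = c("alpha", "tau_u", "tau_v"),
                   icar = c("alpha", "tau_u"),
                   iid = c("alpha", "tau_v"),
                   leroux = if (is.na(fl)) c("alpha", "tau_u", "lambda")
                            else c("alpha", "tau_u"))
  qfun <- function(x) c(mean = mean(x), sd = stats::sd(x),
                        q2.5 = unname(stats::quantile(x, 0.025)),
                        median = stats::median(x),
                        q97.5 = unname(stats::quantile(x, 0.975)))
  hyper <- t(vapply(hyper_draws[active], qfun, numeric(5)))
  if (model == "leroux")
    rownames(hyper)[rownames(hyper) == "tau_u"] <- "tau"
  rhat <- vapply(hyper_draws[active], .split_rhat, numeric(1), chain = chain_id)
  ess <- vapply(hyper_draws[active], .ess, numeric(1), chain = chain_id)
  converged <- all(is.na(rhat) | rhat < 1.1)
  if (!converged)
    warning("possible non-convergence: max split R-hat = ",
            round(max(rhat, na.rm = TRUE), 3))

  pp <- posterior_probability(theta)
  smry <- data.frame(tract_id = graph$tract_ids, O = O, E = E,
                     SRR = 100 * rowMeans(theta),
                     SRR_median = 100 * apply(theta, 1, stats::median),
                     ci_low = 100 * apply(theta, 1, stats::quantile, 0.025),
                     ci_high = 100 * apply(theta, 1, stats::quantile, 0.975),
                     PP = pp$PP, exceeds = pp$exceeds,
                     stringsAsFactors = FALSE)
  na_cols <- c("SRR", "SRR_median", "ci_low", "ci_high", "PP")
  smry[in_lik == 0L, na_cols] <- NA_real_
  smry$exceeds[in_lik == 0L] <- NA
  rownames(smry) <- NULL

  keep <- in_lik == 1L
  fit_dic <- dic(theta[keep, , drop = FALSE], O[keep], E[keep])
  fit_waic <- waic(theta[keep, , drop = FALSE], O[keep], E[keep])

  structure(list(model = model, summary = smry, hyper = hyper,
                 dic = fit_dic$DIC, p_D = fit_dic$p_D,
                 waic = fit_waic$WAIC, p_waic = fit_waic$p_WAIC,
                 rhat = rhat, ess = ess, converged = converged,
                 draws = list(theta = theta, hyper = hyper_draws,
                              chain = chain_id),
                 O = O, E = E, in_lik = in_lik, tract_ids = graph$tract_ids,
                 graph = graph, prior = prior, mcmc = mcmc,
                 fix_lambda = fix_lambda),
            class = "car_fit")
}

#' Posterior exceedance probability
#'
#' `PP_i` is the fraction of retained posterior draws with relative risk
#' above 1 (SRR above 100); `PP >= 0.8` flags a statistically meaningful
#' admissions excess.
#'
#' @param theta_draws matrix of posterior relative-risk draws (tracts x
#'   draws), or a `car_fit`.
#' @param cutoff flagging threshold on PP (default 0.8).
#' @return data.frame `PP`, `exceeds` per tract.
#' @export
posterior_probability <- function(theta_draws, cutoff = 0.8) {
  if (inherits(theta_draws, "car_fit")) theta_draws <- theta_draws$draws$theta
  theta_draws <- as.matrix(theta_draws)
  if (ncol(theta_draws) < 1) stop("no posterior draws", call. = FALSE)
  PP <- rowMeans(theta_draws > 1)
  data.frame(PP = PP, exceeds = PP >= cutoff)
}

.pois_deviance <- function(theta, O, E) {
  -2 * sum(stats::dpois(O, E * theta, log = TRUE))
}

#' Deviance information criterion
#'
#' `DIC = Dbar + p_D` with `Dbar` the posterior mean deviance and
#' `p_D = Dbar - D(theta_bar)` the effective number of parameters; deviance
#' is the Poisson log-likelihood with offsets `E_i`.
#'
#' @param theta_draws matrix of relative-risk draws (tracts x draws; >= 2
#'   draws).
#' @param O,E observed and expected counts per tract.
#' @return list `DIC`, `p_D`, `Dbar`.
#' @export
dic <- function(theta_draws, O, E) {
  theta_draws <- as.matrix(theta_draws)
  if (ncol(theta_draws) < 2) stop("need at least 2 draws", call. = FALSE)
  devs <- apply(theta_draws, 2, .pois_deviance, O = O, E = E)
  Dbar <- mean(devs)
  Dhat <- .pois_deviance(rowMeans(theta_draws), O, E)
  p_D <- Dbar - Dhat
  list(DIC = Dbar + p_D, p_D = p_D, Dbar = Dbar)
}

#' Watanabe-Akaike information criterion
#'
#' `WAIC = -2 (lppd - p_WAIC)`, with the log pointwise predictive density
#' computed by log-sum-exp over draws and the variance-form penalty
#' `p_WAIC = sum_i var_draws(log p(O_i | theta_i))`.
#'
#' @inheritParams dic
#' @return list `WAIC`, `p_WAIC`, `lppd`.
#' @export
waic <- function(theta_draws, O, E) {
  theta_draws <- as.matrix(theta_draws)
  S <- ncol(theta_draws)
  if (S < 2) stop("need at least 2 draws", call. = FALSE)
  ll <- matrix(stats::dpois(rep(O, S), rep(E, S) * as.numeric(theta_draws),
                            log = TRUE), nrow = length(O))
  lppd_i <- apply(ll, 1, function(r) {
    m <- max(r)
    m + log(mean(exp(r - m)))
  })
  p_i <- apply(ll, 1, stats::var)
  list(WAIC = -2 * (sum(lppd_i) - sum(p_i)), p_WAIC = sum(p_i),
       lppd = sum(lppd_i))
}

#' Compare fitted models by DIC and WAIC
#'
#' @param ... two or more `car_fit` objects on identical data, or a single
#'   list of them.
#' @return data.frame with one row per model: `DIC`, `p_D`, `WAIC`,
#'   `p_WAIC`, differences to the best model (`dDIC`, `dWAIC`), ranks, and
#'   best-by-criterion flags.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "car_fit"))
    fits <- fits[[1]]
  if (length(fits) < 2) stop("need at least 2 fits", call. = FALSE)
  ref <- fits[[1]]
  for (f in fits[-1])
    if (!identical(f$O, ref$O) || !identical(f$E, ref$E))
      stop("fits are not on identical data", call. = FALSE)
  nm <- names(fits)
  if (is.null(nm) || any(nm == ""))
    nm <- make.unique(vapply(fits, `[[`, character(1), "model"))
  out <- data.frame(model = nm,
                    DIC = vapply(fits, `[[`, numeric(1), "dic"),
                    p_D = vapply(fits, `[[`, numeric(1), "p_D"),
                    WAIC = vapply(fits, `[[`, numeric(1), "waic"),
                    p_WAIC = vapply(fits, `[[`, numeric(1), "p_waic"),
                    stringsAsFactors = FALSE)
  out$dDIC <- out$DIC - min(out$DIC)
  out$dWAIC <- out$WAIC - min(out$WAIC)
  out$rank_DIC <- rank(out$DIC, ties.method = "min")
  out$rank_WAIC <- rank(out$WAIC, ties.method = "min")
  out$best_DIC <- out$rank_DIC == 1
  out$best_WAIC <- out$rank_WAIC == 1
  out[order(out$DIC), ]
}
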