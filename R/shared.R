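#' Fit a shared-component joint model for two sexes
#'
#' Knorr-Held/Best-style joint smoothing of male and female admission risks:
#' \deqn{\log\theta_{i,m} = \alpha_m + \kappa\,\delta_i + v_{i,m}, \qquad
#'       \log\theta_{i,f} = \alpha_f + \delta_i/\kappa + v_{i,f},}
#' with a shared intrinsic CAR field `delta ~ ICAR(tau_delta)` (sum-to-zero
#' per component), sex-specific exchangeable effects, and a log-normal
#' (median 1) prior on the sharing parameter `kappa`. Pooling the sexes
#' through one spatial field borrows strength across them when their spatial
#' patterns agree.
#'
#' @param O_male,E_male,O_female,E_female observed/expected counts per tract
#'   (named vectors or in graph order); both sexes must share the tract set.
#' @param graph an `adjacency_graph`.
#' @param prior a [car_prior()] (`sdlog_kappa` controls the kappa prior).
#' @param mcmc an [mcmc_control()].
#' @param fix_kappa optionally fix kappa (e.g. 1); `NULL` leaves it free.
#' @param unstructured include the sex-specific exchangeable effects
#'   (default `TRUE`).
#' @return An object of class `shared_car_fit`: per-sex `$summary` tables
#'   (as in [fit_car()]), `$kappa` posterior summary, `$delta` (posterior
#'   mean shared field), `$cross_correlation` (posterior mean over draws of
#'   the Pearson correlation between male and female log-risks across
#'   tracts, with a 95% interval), `$dic`, `$waic`, diagnostics and raw
#'   draws.
#' @export
fit_shared_component <- function(O_male, E_male, O_female, E_female, graph,
                                 prior = car_prior(), mcmc = mcmc_control(),
                                 fix_kappa = NULL, unstructured = TRUE) {
  Om <- .align(O_male, graph, "O_male"); Em <- .align(E_male, graph, "E_male")
  Of <- .align(O_female, graph, "O_female"); Ef <- .align(E_female, graph, "E_female")
  if (any(c(Om, Of) < 0) || any(c(Em, Ef) < 0))
    stop("counts must be non-negative", call. = FALSE)
  in_m <- as.integer(Em > 0); in_f <- as.integer(Ef > 0)
  if (!any(in_m == 1L) || !any(in_f == 1L))
    stop("E <= 0 on all tracts for one sex", call. = FALSE)
  n <- graph$n
  comp <- graph_components(graph) - 1L
  nbr0 <- lapply(graph$nbr, function(v) as.integer(v - 1L))
  fk <- if (is.null(fix_kappa)) NA_real_ else {
    stopifnot(fix_kappa > 0)
    as.numeric(fix_kappa)
  }

  # start the shared field at the centred average residual log-SMR of the
  # two sexes (avoids the zero-field precision trap)
  am0 <- log((sum(Om[in_m == 1]) + 0.5) / sum(Em[in_m == 1]))
  af0 <- log((sum(Of[in_f == 1]) + 0.5) / sum(Ef[in_f == 1]))
  res0 <- 0.5 * (log((Om + 0.5) / pmax(Em, 0.5)) - am0 +
                 log((Of + 0.5) / pmax(Ef, 0.5)) - af0)
  res0 <- res0 - stats::ave(res0, comp)

  set.seed(mcmc$seed)
  nkeep <- (mcmc$n_iter - mcmc$n_burnin) %/% mcmc$thin
  th_m <- th_f <- del <- NULL
  hy <- list(); chain_id <- integer(0)
  for (ch in seq_len(mcmc$n_chains)) {
    inits <- list(
      alpha_m = am0 + stats::rnorm(1, 0, 0.1),
      alpha_f = af0 + stats::rnorm(1, 0, 0.1),
      delta = as.numeric(scale(res0 + stats::rnorm(n, 0, 0.05), scale = FALSE)),
      v_m = stats::rnorm(n, 0, 0.1), v_f = stats::rnorm(n, 0, 0.1),
      tau_d = exp(stats::rnorm(1, 0, 0.5)),
      tau_vm = exp(stats::rnorm(1, 0, 0.5)),
      tau_vf = exp(stats::rnorm(1, 0, 0.5)),
      kappa = exp(stats::rnorm(1, 0, 0.2)))
    res <- shared_mcmc_cpp(Om, Em, Of, Ef, in_m, in_f, nbr0, comp,
                           prior$tau_shape, prior$tau_rate, prior$alpha_var,
                           prior$sdlog_kappa, mcmc$n_iter, mcmc$n_burnin,
                           mcmc$thin, fk, unstructured, inits)
    th_m <- cbind(th_m, res$theta_m); th_f <- cbind(th_f, res$theta_f)
    del <- cbind(del, res$delta)
    for (nm in c("kappa", "tau_d", "tau_vm", "tau_vf", "alpha_m", "alpha_f"))
      hy[[nm]] <- c(hy[[nm]], res[[nm]])
    chain_id <- c(chain_id, rep(ch, nkeep))
  }
  rownames(th_m) <- rownames(th_f) <- rownames(del) <- graph$tract_ids

  sex_summary <- function(theta, O, E, in_lik) {
    pp <- posterior_probability(theta)
    s <- data.frame(tract_id = graph$tract_ids, O = O, E = E,
                    SRR = 100 * rowMeans(theta),
                    SRR_median = 100 * apply(theta, 1, stats::median),
                    ci_low = 100 * apply(theta, 1, stats::quantile, 0.025),
                    ci_high = 100 * apply(theta, 1, stats::quantile, 0.975),
                    PP = pp$PP, exceeds = pp$exceeds, stringsAsFactors = FALSE)
    s[in_lik == 0L, c("SRR", "SRR_median", "ci_low", "ci_high", "PP")] <- NA_real_
    s$exceeds[in_lik == 0L] <- NA
    rownames(s) <- NULL
    s
  }
  smry <- list(male = sex_summary(th_m, Om, Em, in_m),
               female = sex_summary(th_f, Of, Ef, in_f))

  # posterior cross-sex correlation of log-risks over tracts, per draw
  both <- in_m == 1L & in_f == 1L
  cc_draws <- vapply(seq_len(ncol(th_m)), function(s)
    stats::cor(log(th_m[both, s]), log(th_f[both, s])), numeric(1))
  cross <- c(mean = mean(cc_draws),
             q2.5 = unname(stats::quantile(cc_draws, 0.025)),
             q97.5 = unname(stats::quantile(cc_draws, 0.975)))

  active <- c("alpha_m", "alpha_f", "tau_d",
              if (unstructured) c("tau_vm", "tau_vf"),
              if (is.na(fk)) "kappa")
  qfun <- function(x) c(mean = mean(x), sd = stats::sd(x),
                        q2.5 = unname(stats::quantile(x, 0.025)),
                        median = stats::median(x),
                        q97.5 = unname(stats::quantile(x, 0.975)))
  hyper <- t(vapply(hy[active], qfun, numeric(5)))
  rhat <- vapply(hy[active], .split_rhat, numeric(1), chain = chain_id)
  converged <- all(is.na(rhat) | rhat < 1.1)
  if (!converged)
    warning("possible non-convergence: max split R-hat = ",
            round(max(rhat, na.rm = TRUE), 3))

  # joint fit indices: pooled Poisson likelihood over both sexes
  keep_theta <- rbind(th_m[in_m == 1L, , drop = FALSE],
                      th_f[in_f == 1L, , drop = FALSE])
  keep_O <- c(Om[in_m == 1L], Of[in_f == 1L])
  keep_E <- c(Em[in_m == 1L], Ef[in_f == 1L])
  fit_dic <- dic(keep_theta, keep_O, keep_E)
  fit_waic <- waic(keep_theta, keep_O, keep_E)

  structure(list(summary = smry, hyper = hyper,
                 kappa = if (is.na(fk)) qfun(hy$kappa) else
                   c(mean = fk, sd = 0, q2.5 = fk, median = fk, q97.5 = fk),
                 delta = stats::setNames(rowMeans(del), graph$tract_ids),
                 cross_correlation = cross,
                 dic = fit_dic$DIC, p_D = fit_dic$p_D,
                 waic = fit_waic$WAIC, p_waic = fit_waic$p_WAIC,
                 rhat = rhat, converged = converged,
                 draws = list(theta_male = th_m, theta_female = th_f,
                              delta = del, hyper = hy, chain = chain_id,
                              cross_correlation = cc_draws),
                 tract_ids = graph$tract_ids, graph = graph,
                 prior = prior, mcmc = mcmc, fix_kappa = fix_kappa,
                 unstructured = unstructured),
            class = "shared_car_fit")
}

#' @export
print.shared_car_fit <- function(x, ...) {
  cat("Shared-component joint fit (", length(x$tract_ids), " tracts)\n", sep = "")
  cat(sprintf("  kappa: %.3f [%.3f, %.3f]\n",
              x$kappa["mean"], x$kappa["q2.5"], x$kappa["q97.5"]))
  cat(sprintf("  cross-sex log-risk correlation: %.3f [%.3f, %.3f]\n",
              x$cross_correlation["mean"], x$cross_correlation["q2.5"],
              x$cross_correlation["q97.5"]))
  cat(sprintf("  DIC = %.1f | WAIC = %.1f | max split R-hat = %.3f\n",
              x$dic, x$waic, max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.shared_car_fit <- function(object, ...) {
  print(object)
  cat("\nHyperparameter posterior:\n")
  print(round(cbind(object$hyper, rhat = object$rhat), 4))
  invisible(object)
}

#' Pearson correlation between male and female SAR values
#'
#' @param sar_male,sar_female `standardized_result` objects (their `SAR`
#'   column is used) or plain numeric vectors, matched by tract id when
#'   names/ids are available. Tracts with undefined SAR in either sex are
#'   dropped pairwise.
#' @return the Pearson correlation coefficient.
#' @export
sar_cross_correlation <- function(sar_male, sar_female) {
  get <- function(x) {
    if (inherits(x, "standardized_result") || is.data.frame(x))
      stats::setNames(x$SAR, x$tract_id)
    else x
  }
  xm <- get(sar_male); xf <- get(sar_female)
  if (!is.null(names(xm)) && !is.null(names(xf))) {
    common <- intersect(names(xm), names(xf))
    xm <- xm[common]; xf <- xf[common]
  }
  if (length(xm) != length(xf)) stop("mismatched tract sets", call. = FALSE)
  ok <- !is.na(xm) & !is.na(xf)
  if (sum(ok) < 3) stop("fewer than 3 tracts with defined SAR in both sexes",
                        call. = FALSE)
  if (stats::var(xm[ok]) == 0 || stats::var(xf[ok]) == 0)
    stop("zero variance", call. = FALSE)
  stats::cor(xm[ok], xf[ok])
}
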