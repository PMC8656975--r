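#' @export
print.car_fit <- function(x, ...) {
  cat("Bayesian spatial Poisson fit (", x$model, " prior)\n", sep = "")
  cat("  tracts:", length(x$tract_ids),
      " | chains:", x$mcmc$n_chains,
      "x", x$mcmc$n_iter, sprintf("(burn-in %d, thin %d)\n",
                                  x$mcmc$n_burnin, x$mcmc$thin))
  cat(sprintf("  DIC = %.1f (p_D = %.1f) | WAIC = %.1f (p_WAIC = %.1f)\n",
              x$dic, x$p_D, x$waic, x$p_waic))
  cat(sprintf("  max split R-hat = %.3f%s\n", max(x$rhat, na.rm = TRUE),
              if (x$converged) "" else "  ** possible non-convergence **"))
  invisible(x)
}

#' @export
summary.car_fit <- function(object, ...) {
  s <- object$summary
  out <- list(model = object$model, hyper = object$hyper,
              rhat = object$rhat, ess = object$ess,
              dic = object$dic, p_D = object$p_D,
              waic = object$waic, p_waic = object$p_waic,
              srr_quantiles = stats::quantile(s$SRR, c(0, .25, .5, .75, 1),
                                              na.rm = TRUE),
              n_tracts = nrow(s),
              n_exceed = sum(s$exceeds, na.rm = TRUE),
              n_undefined = sum(is.na(s$SRR)),
              converged = object$converged)
  class(out) <- "summary.car_fit"
  out
}

#' @export
print.summary.car_fit <- function(x, ...) {
  cat("Model:", x$model, "\n\nHyperparameter posterior:\n")
  print(round(cbind(x$hyper, rhat = x$rhat, ess = round(x$ess)), 4))
  cat(sprintf("\nDIC = %.1f (p_D = %.1f) | WAIC = %.1f (p_WAIC = %.1f)\n",
              x$dic, x$p_D, x$waic, x$p_waic))
  cat("\nSmoothed relative risk (SRR, % scale):\n")
  print(round(x$srr_quantiles, 1))
  cat(sprintf("\n%d of %d tracts flagged PP >= 0.8", x$n_exceed, x$n_tracts))
  if (x$n_undefined) cat(sprintf(" (%d undefined, E = 0)", x$n_undefined))
  cat("\n")
  invisible(x)
}

#' @export
coef.car_fit <- function(object, ...) {
  object$hyper[, "mean"]
}

#' @export
fitted.car_fit <- function(object, ...) {
  stats::setNames(object$summary$SRR / 100, object$summary$tract_id)
}

#' @param type `"pearson"` (default), `"response"` or `"deviance"` residuals
#'   of the observed counts against the posterior-mean fitted means
#'   `E_i * theta_i`.
#' @rdname fit_car
#' @export
residuals.car_fit <- function(object, type = c("pearson", "response", "deviance"),
                              ...) {
  type <- match.arg(type)
  mu <- object$E * fitted(object)
  r <- object$O - mu
  out <- switch(type,
                response = r,
                pearson = r / sqrt(pmax(mu, .Machine$double.eps)),
                deviance = sign(r) * sqrt(2 * (ifelse(object$O > 0,
                  object$O * log(object$O / mu), 0) - r)))
  stats::setNames(out, object$tract_ids)
}

#' Plot a fitted disease-mapping model
#'
#' If the graph carries lattice coordinates, draws a choropleth-style image
#' of the chosen per-tract statistic; otherwise a caterpillar plot of SRR
#' with 95% credible intervals, ordered by SRR.
#'
#' @param x a `car_fit`.
#' @param what per-tract statistic to map: `"SRR"` (default) or `"PP"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.car_fit <- function(x, what = c("SRR", "PP"), ...) {
  what <- match.arg(what)
  s <- x$summary
  co <- x$graph$coords
  if (!is.null(co)) {
    co <- co[match(s$tract_id, co$tract_id), ]
    z <- matrix(NA_real_, max(co$row), max(co$col))
    z[cbind(co$row, co$col)] <- s[[what]]
    graphics::image(t(z[rev(seq_len(nrow(z))), , drop = FALSE]),
                    axes = FALSE, main = paste(what, "-", x$model), ...)
  } else {
    o <- order(s$SRR)
    graphics::plot(seq_along(o), s$SRR[o], pch = 16, cex = 0.5,
                   ylim = range(c(s$ci_low, s$ci_high), na.rm = TRUE),
                   xlab = "tract (ordered)", ylab = "SRR (%)",
                   main = paste("SRR -", x$model))
    graphics::segments(seq_along(o), s$ci_low[o], seq_along(o), s$ci_high[o],
                       col = "grey")
    graphics::abline(h = 100, lty = 2)
  }
  invisible(x)
}

#' @export
as.data.frame.car_fit <- function(x, ...) x$summary
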