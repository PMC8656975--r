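test_that("posterior exceedance probability is the draw fraction above 1", {
  draws <- rbind(c(0.9, 1.1, 1.2, 1.3, 0.8),   # direct count: 3/5
                 c(1.5, 1.2, 1.1, 1.4, 1.3),   # all above
                 c(0.9, 1.1, 0.95, 1.05, 1.0)) # symmetric-ish
  pp <- posterior_probability(draws)
  expect_equal(pp$PP, c(0.6, 1, 0.4))
  expect_equal(pp$exceeds, c(FALSE, TRUE, FALSE))
  expect_error(posterior_probability(matrix(nrow = 2, ncol = 0)), "draws")
})

test_that("WAIC matches a brute-force log-sum-exp oracle", {
  # single tract, O = 3, E = 2, draws theta in {1, 2}
  O <- 3; E <- 2
  th <- matrix(c(1, 2), nrow = 1)
  ll <- dpois(O, E * c(1, 2), log = TRUE)
  lppd <- log(mean(exp(ll)))                 # brute force
  p_w <- stats::var(ll)
  w <- waic(th, O, E)
  expect_lt(abs(w$WAIC - (-2 * (lppd - p_w))), 1e-10)
  expect_lt(abs(w$p_WAIC - p_w), 1e-10)
})

test_that("identical draws give zero effective-parameter penalties", {
  th <- matrix(1.3, nrow = 4, ncol = 50)
  O <- c(2, 5, 1, 0); E <- c(2, 3, 1, 1)
  expect_equal(dic(th, O, E)$p_D, 0)
  expect_equal(waic(th, O, E)$p_WAIC, 0)
  expect_error(dic(th[, 1, drop = FALSE], O, E), "2 draws")
  expect_error(waic(th[, 1, drop = FALSE], O, E), "2 draws")
})

test_that("DIC matches its definition on a tiny posterior", {
  O <- c(4, 1); E <- c(3, 2)
  th <- rbind(c(1, 1.5, 0.8), c(0.5, 1, 1.2))
  devs <- apply(th, 2, function(t) -2 * sum(dpois(O, E * t, log = TRUE)))
  Dhat <- -2 * sum(dpois(O, E * rowMeans(th), log = TRUE))
  d <- dic(th, O, E)
  expect_equal(d$DIC, mean(devs) + (mean(devs) - Dhat))
})

test_that("model comparison ranks by DIC and flags the best model", {
  g <- make_lattice(4, 4, "rook")
  dat <- sim_dataset(g, seed = 1)
  mc <- mcmc_control(n_chains = 2, n_iter = 800, n_burnin = 300, seed = 3)
  f1 <- quiet_fit(dat$O, dat$E, g, "bym", mcmc = mc)
  f2 <- quiet_fit(dat$O, dat$E, g, "iid", mcmc = mc)
  tab <- compare_models(bym = f1, iid = f2)
  expect_equal(tab$dDIC[1], 0)
  expect_equal(sort(tab$rank_DIC), 1:2)
  expect_equal(sum(tab$best_DIC), 1)
  dat2 <- sim_dataset(g, seed = 2)
  f3 <- quiet_fit(dat2$O, dat2$E, g, "iid", mcmc = mc)
  expect_error(compare_models(f1, f3), "identical data")
  expect_error(compare_models(f1), "at least 2")

  # the three spatial priors land in the same DIC envelope on one dataset
  f_ic <- quiet_fit(dat$O, dat$E, g, "icar", mcmc = mc)
  f_le <- quiet_fit(dat$O, dat$E, g, "leroux", mcmc = mc)
  tab3 <- compare_models(bym = f1, icar = f_ic, leroux = f_le)
  expect_true(all(is.finite(tab3$DIC)) && all(is.finite(tab3$WAIC)))
  expect_lt(max(tab3$DIC) - min(tab3$DIC), 50)
})

test_that("the null-risk large-E limit smooths to the global level", {
  g <- make_lattice(5, 5, "queen")
  set.seed(10)
  E <- rep(600, 25)
  O <- rpois(25, E)
  f <- quiet_fit(O, E, g, "bym",
                 mcmc = mcmc_control(n_chains = 2, n_iter = 2000,
                                     n_burnin = 800, seed = 5))
  expect_true(all(f$summary$SRR > 95 & f$summary$SRR < 105))
  expect_gt(mean(f$summary$PP), 0.2)
  expect_lt(mean(f$summary$PP), 0.8)
})

test_that("smoothing contracts the SAR map and contracts harder at small E", {
  g <- make_lattice(8, 8, "queen")
  dat <- sim_dataset(g, seed = 21, mean_E = 10)
  mc <- mcmc_control(n_chains = 2, n_iter = 1500, n_burnin = 600, seed = 7)
  f <- quiet_fit(dat$O, dat$E, g, "bym", mcmc = mc)
  sar_v <- 100 * dat$O / dat$E
  expect_lte(stats::var(f$summary$SRR), stats::var(sar_v))

  dats <- list(O = rpois(64, dat$E / 5 * dat$theta), E = dat$E / 5)
  fs <- quiet_fit(dats$O, dats$E, g, "bym", mcmc = mc)
  ratio_big <- stats::var(f$summary$SRR) / stats::var(sar_v)
  ratio_small <- stats::var(fs$summary$SRR) /
    stats::var(100 * dats$O / dats$E)
  expect_lt(ratio_small, ratio_big)
})

test_that("fits are bit-reproducible and zero-E tracts are excluded", {
  g <- make_lattice(4, 4, "rook")
  dat <- sim_dataset(g, seed = 31)
  mc <- mcmc_control(n_chains = 2, n_iter = 600, n_burnin = 200, seed = 13)
  f1 <- quiet_fit(dat$O, dat$E, g, "bym", mcmc = mc)
  f2 <- quiet_fit(dat$O, dat$E, g, "bym", mcmc = mc)
  expect_identical(f1$draws$theta, f2$draws$theta)
  expect_identical(f1$summary, f2$summary)

  E0 <- dat$E; E0[3] <- 0; O0 <- dat$O; O0[3] <- 0
  # short chains may also warn about convergence; the E = 0 warning is the
  # one under test
  ws <- capture_warnings(f3 <- fit_car(O0, E0, g, "bym", mcmc = mc))
  expect_true(any(grepl("E = 0", ws)))
  expect_true(is.na(f3$summary$SRR[3]))
  expect_true(all(!is.na(f3$summary$SRR[-3])))
  expect_error(fit_car(rep(0, 16), rep(0, 16), g, "bym", mcmc = mc), "all tracts")
})

test_that("credible intervals bracket the posterior median", {
  g <- make_lattice(5, 5, "rook")
  dat <- sim_dataset(g, seed = 41)
  f <- quiet_fit(dat$O, dat$E, g, "leroux",
                 mcmc = mcmc_control(n_chains = 2, n_iter = 1000,
                                     n_burnin = 400, seed = 17))
  s <- f$summary
  expect_true(all(s$ci_low <= s$SRR_median & s$SRR_median <= s$ci_high))
  expect_true(all(s$PP >= 0 & s$PP <= 1))
  expect_true(is.finite(f$dic) && is.finite(f$waic))
})

test_that("prior Gibbs on the ICAR-precision pair recovers the prior moments", {
  # Geweke-style check of the conjugate precision update: alternate exact
  # field draws u | tau (the generator) with the gamma update tau | u; the
  # stationary tau margin must be the gamma(1, 0.0005) prior
  g <- make_lattice(5, 5, "rook")
  Q <- as.matrix(build_icar_precision(g))
  quad <- function(u) as.numeric(t(u) %*% Q %*% u)
  a <- 1; b <- 5e-4
  set.seed(99)
  n_it <- 30000   # log tau mixes like a slow random walk; long chain needed
  tau <- 1; taus <- numeric(n_it)
  for (k in seq_len(n_it)) {
    u <- simulate_icar_field(g, tau_u = tau, seed = sample.int(1e6, 1))
    tau <- rgamma(1, a + (25 - 1) / 2, rate = b + quad(u) / 2)
    taus[k] <- tau
  }
  expect_lt(abs(mean(taus) / (a / b) - 1), 0.1)
})

test_that("hyperparameter tables expose the parameters active per model", {
  g <- make_lattice(4, 4, "rook")
  dat <- sim_dataset(g, seed = 51)
  mc <- mcmc_control(n_chains = 2, n_iter = 600, n_burnin = 200, seed = 19)
  expect_setequal(rownames(quiet_fit(dat$O, dat$E, g, "bym", mcmc = mc)$hyper),
                  c("alpha", "tau_u", "tau_v"))
  expect_setequal(rownames(quiet_fit(dat$O, dat$E, g, "icar", mcmc = mc)$hyper),
                  c("alpha", "tau_u"))
  expect_setequal(rownames(quiet_fit(dat$O, dat$E, g, "leroux", mcmc = mc)$hyper),
                  c("alpha", "tau", "lambda"))
  f <- quiet_fit(dat$O, dat$E, g, "iid", mcmc = mc)
  expect_setequal(rownames(f$hyper), c("alpha", "tau_v"))
  # S3 surface
  expect_named(coef(f), rownames(f$hyper))
  expect_length(fitted(f), 16)
  expect_length(residuals(f), 16)
  expect_s3_class(as.data.frame(f), "data.frame")
  expect_output(print(f), "iid")
  expect_output(print(summary(f)), "Hyperparameter")
})
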