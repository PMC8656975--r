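test_that("checkerboard values on a 2x2 rook lattice give I = -1", {
  g <- make_lattice(2, 2, "rook")
  W <- make_weights(g, "row")
  x <- ifelse((g$coords$row + g$coords$col) %% 2 == 0, 1, -1)
  expect_equal(morans_i(x, W), -1)
  # and every local statistic is negative (all neighbour products negative)
  expect_true(all(local_moran(x, W) < 0))
})

test_that("sum of local Moran statistics equals n times the global I", {
  for (s in 1:5) {
    g <- make_lattice(6, 7, sample(c("rook", "queen"), 1))
    W <- make_weights(g, "row")
    set.seed(s)
    x <- rnorm(g$n)
    expect_lt(abs(sum(local_moran(x, W)) - g$n * morans_i(x, W)), 1e-10)
  }
})

test_that("a tract at the mean has a zero local statistic", {
  gp <- path_graph(5)
  W <- make_weights(gp)
  x <- c(1, 3, 2, 0, 4)        # mean 2, site 3 at the mean
  expect_equal(unname(local_moran(x, W)["c"]), 0)
})

test_that("degenerate inputs are rejected", {
  g <- make_lattice(3, 3, "rook")
  W <- make_weights(g)
  expect_error(morans_i(rep(2, 9), W), "variance")
  expect_error(morans_i(rnorm(5), W), "per tract")
  expect_error(morans_i_test(rnorm(9), W, n_perm = 10), "99")
  expect_error(lisa(rnorm(9), W, alpha = 1.5), "alpha")
})

test_that("permutation pseudo p matches exhaustive enumeration at n = 5", {
  gp <- path_graph(5)
  W <- make_weights(gp)
  x <- c(2.3, -1.1, 0.4, 5.0, -2.2)
  allI <- vapply(all_perms(x), function(p) morans_i(p, W), numeric(1))
  Iobs <- morans_i(x, W)
  p_exact <- mean(abs(allI) >= abs(Iobs) - 1e-12)
  mt <- morans_i_test(x, W, n_perm = 999, seed = 4)
  expect_lt(abs(mt$p_value - p_exact), 0.02)
  expect_equal(mt$expectation, -1 / 4)
})

test_that("randomization expectation of I is -1/(n-1)", {
  g <- make_lattice(5, 5, "rook")
  W <- make_weights(g)
  set.seed(77)
  Is <- vapply(1:200, function(k) morans_i(rnorm(25), W), numeric(1))
  se <- stats::sd(Is) / sqrt(200)
  expect_lt(abs(mean(Is) - (-1 / 24)), 3 * se)
})

test_that("the permutation test has power on ICAR surfaces and correct size", {
  g <- make_lattice(15, 15, "rook")
  W <- make_weights(g)
  # power: strongly autocorrelated surfaces rejected at 0.01
  rej <- vapply(1:20, function(s) {
    u <- simulate_icar_field(g, tau_u = 1, seed = s)
    morans_i_test(u, W, n_perm = 199, seed = s)$p_value <= 0.01
  }, logical(1))
  expect_gte(mean(rej), 0.95)

  # size: iid surfaces rejected at about the nominal 5% rate
  g2 <- make_lattice(7, 7, "rook")
  W2 <- make_weights(g2)
  set.seed(123)
  p <- vapply(1:200, function(k)
    morans_i_test(rnorm(49), W2, n_perm = 199)$p_value, numeric(1))
  expect_gte(mean(p <= 0.05), 0.02)
  expect_lte(mean(p <= 0.05), 0.08)
})

test_that("the analytic normal test agrees with permutation on sign and scale", {
  g <- make_lattice(10, 10, "rook")
  W <- make_weights(g)
  u <- simulate_icar_field(g, tau_u = 1, seed = 31)
  mp <- morans_i_test(u, W, n_perm = 999, seed = 1)
  mn <- morans_i_test(u, W, method = "normal")
  expect_equal(mp$I, mn$I)
  expect_lt(abs(mp$z - mn$z) / mn$z, 0.25)
})

test_that("LISA classifies a constructed plateau correctly", {
  g <- make_lattice(9, 9, "rook")
  W <- make_weights(g)
  co <- g$coords
  x <- ifelse(co$row %in% 4:6 & co$col %in% 4:6, 10, 0)
  set.seed(9)
  x <- x + rnorm(81, 0, 0.01)
  L <- lisa(x, W, n_perm = 999, alpha = 0.05, seed = 2)
  core <- co$row == 5 & co$col == 5
  inside <- co$row %in% 4:6 & co$col %in% 4:6
  far <- co$row %in% c(1, 9) | co$col %in% c(1, 9)
  expect_equal(L$class[core], "high-high")
  expect_false(any(L$class[inside] == "high-low"))
  expect_true(all(L$class[far] %in% c("low-low", "not-significant")))
})

test_that("a single extreme tract amid zeros is a high-low spatial outlier", {
  g <- make_lattice(5, 5, "rook")
  W <- make_weights(g)
  set.seed(3)
  x <- rnorm(25, 0, 0.01)
  x[13] <- 100
  L <- lisa(x, W, n_perm = 999, seed = 5)
  if (L$pseudo_p[13] <= 0.05) expect_equal(L$class[13], "high-low")
  expect_true(L$I_local[13] < 0)
})

test_that("LISA significance fraction under the null is near alpha", {
  g <- make_lattice(9, 9, "rook")
  W <- make_weights(g)
  set.seed(55)
  frac <- vapply(1:40, function(k) {
    L <- lisa(rnorm(81), W, n_perm = 199, alpha = 0.05)
    mean(L$class != "not-significant")
  }, numeric(1))
  expect_gte(mean(frac), 0.025)
  expect_lte(mean(frac), 0.10)
})

test_that("cluster classes respect the sign of the local statistic", {
  g <- make_lattice(8, 8, "queen")
  W <- make_weights(g)
  u <- simulate_icar_field(g, 0.5, seed = 14)
  L <- lisa(u, W, n_perm = 199, seed = 3)
  hh_ll <- L$class %in% c("high-high", "low-low")
  hl_lh <- L$class %in% c("high-low", "low-high")
  expect_true(all(L$I_local[hh_ll] > 0))
  expect_true(all(L$I_local[hl_lh] < 0))
})

test_that("randomized procedures are reproducible under a fixed seed", {
  g <- make_lattice(6, 6, "rook")
  W <- make_weights(g)
  set.seed(8); x <- rnorm(36)
  expect_identical(morans_i_test(x, W, n_perm = 199, seed = 10),
                   morans_i_test(x, W, n_perm = 199, seed = 10))
  expect_identical(lisa(x, W, n_perm = 199, seed = 10),
                   lisa(x, W, n_perm = 199, seed = 10))
})
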