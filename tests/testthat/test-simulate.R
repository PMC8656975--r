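test_that("simulated populations hit the study-area scale and are reproducible", {
  g <- make_lattice(18, 31, "queen")     # 558 tracts
  pop <- simulate_population(g, mean_pop = 1265, seed = 42)
  expect_equal(nrow(pop), 558 * 10)
  expect_true(all(pop$value >= 0))
  # grand total around 558 * 1265 = 705,870 (study area ~705,968): the mean
  # over seeds within 5%, each seed within 10% (per-tract CV is 0.5)
  totals <- vapply(1:5, function(s)
    sum(simulate_population(g, 1265, seed = s)$value), numeric(1))
  expect_lt(abs(mean(totals) / 705968 - 1), 0.05)
  expect_true(all(abs(totals / 705968 - 1) < 0.10))
  # per-tract heterogeneity: coefficient of variation near 0.5 by default
  tr <- tapply(pop$value, pop$tract_id, sum)
  expect_gt(stats::sd(tr) / mean(tr), 0.3)
  expect_lt(stats::sd(tr) / mean(tr), 0.7)

  expect_identical(simulate_population(g, 1265, seed = 7),
                   simulate_population(g, 1265, seed = 7))
})

test_that("a degenerate profile puts every person in one stratum", {
  g <- make_lattice(3, 3, "rook")
  prof <- default_age_sex_profile()
  prof$prop <- c(1, rep(0, 9))
  pop <- simulate_population(g, 100, profile = prof, dispersion = 1e9, seed = 1)
  filled <- pop[pop$sex == prof$sex[1] & pop$age_group == prof$age_group[1], ]
  expect_equal(sum(filled$value), sum(pop$value))
  bad <- prof; bad$prop[1] <- 0.5
  expect_error(simulate_population(g, 100, profile = bad), "summing to 1|sum")
})

test_that("ICAR field draws satisfy the sum-to-zero constraint per component", {
  g <- make_lattice(6, 6, "queen")
  u <- simulate_icar_field(g, tau_u = 1, seed = 3)
  expect_lt(abs(sum(u)), 1e-10)

  g2 <- adjacency_graph(c("a", "b", "c", "d"),
                        rbind(c("a", "b"), c("c", "d")))
  u2 <- simulate_icar_field(g2, tau_u = 2, seed = 5)
  expect_lt(abs(u2["a"] + u2["b"]), 1e-10)
  expect_lt(abs(u2["c"] + u2["d"]), 1e-10)

  # precision -> infinity shrinks the field
  ub <- simulate_icar_field(g, tau_u = 1e6, seed = 9)
  expect_true(all(abs(ub) < 0.01))

  gi <- adjacency_graph(c("a", "b", "c"), rbind(c("a", "b")))
  expect_error(simulate_icar_field(gi, 1, seed = 1), "island")
  ui <- simulate_icar_field(gi, 1, seed = 1, allow_islands = TRUE)
  expect_identical(unname(ui["c"]), 0)
})

test_that("ICAR draws are spatially positively autocorrelated", {
  g <- make_lattice(15, 15, "rook")
  W <- make_weights(g)
  Is <- vapply(1:100, function(s)
    morans_i(simulate_icar_field(g, tau_u = 1, seed = s), W), numeric(1))
  expect_gt(mean(Is > 0), 0.95)
})

test_that("admission simulation follows the Poisson intensity", {
  g <- make_lattice(5, 5, "rook")
  pop <- simulate_population(g, 2000, seed = 2)
  rates <- rbind(calibrate_rates(pop, "male", 500),
                 calibrate_rates(pop, "female", 300))
  surf <- make_risk_surface(g, seed = 4)
  cnt <- simulate_admissions(pop, rates, surf, seed = 6)
  expect_identical(cnt[c("tract_id", "sex", "age_group")],
                   pop[c("tract_id", "sex", "age_group")])
  expect_identical(cnt, simulate_admissions(pop, rates, surf, seed = 6))

  # null intensity
  r0 <- rates; r0$rate <- 0
  expect_true(all(simulate_admissions(pop, r0, surf, seed = 1)$value == 0))
  rneg <- rates; rneg$rate[1] <- -1
  expect_error(simulate_admissions(pop, rneg, surf), "non-negative")

  # doubling theta doubles the expected total (checked in expectation)
  one <- stats::setNames(rep(1, g$n), g$tract_ids)
  tot1 <- mean(vapply(1:20, function(s)
    sum(simulate_admissions(pop, rates, one, seed = s)$value), numeric(1)))
  tot2 <- mean(vapply(1:20, function(s)
    sum(simulate_admissions(pop, rates, 2 * one, seed = 100 + s)$value),
    numeric(1)))
  expect_lt(abs(tot2 / tot1 - 2), 0.1)
})

test_that("calibrated rates reproduce the target event total in expectation", {
  g <- make_lattice(18, 31, "queen")
  pop <- simulate_population(g, 1265, seed = 11)
  rates <- rbind(calibrate_rates(pop, "male", 3218 * 0.6442),
                 calibrate_rates(pop, "female", 3218 * 0.3558))
  one <- stats::setNames(rep(1, g$n), g$tract_ids)
  # with theta == 1 the total is Poisson with mean 3218: 99% of seeds within
  # 3 * sqrt(3218)
  tot <- vapply(1:10, function(s)
    sum(simulate_admissions(pop, rates, one, seed = s)$value), numeric(1))
  expect_true(all(abs(tot - 3218) < 3 * sqrt(3218)))
})

test_that("the full synthetic study assembles and is deterministic", {
  st <- simulate_study(seed = 1, n_rows = 6, n_cols = 6, total_events = 400)
  expect_equal(st$graph$n, 36)
  expect_setequal(unique(st$counts$sex), sexes)
  expect_true(any(is.na(st$events$tract_id)))
  st2 <- simulate_study(seed = 1, n_rows = 6, n_cols = 6, total_events = 400)
  expect_identical(st$counts, st2$counts)
  expect_identical(st$surface$male$u, st$surface$female$u)  # shared field
  null <- simulate_study(seed = 2, n_rows = 6, n_cols = 6, total_events = 400,
                         null_risk = TRUE)
  expect_true(all(null$surface$male$theta == 1))
})
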