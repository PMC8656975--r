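test_that("reference rates match hand arithmetic", {
  # two-tract toy: tract A n=1000 O=2, tract B n=3000 O=6, one stratum
  tb <- one_stratum_tables(c("A", "B"), n_pop = c(1000, 3000), n_obs = c(2, 6))
  r <- reference_rates(tb$counts, tb$pop)
  expect_equal(r$rate[r$sex == "male" & r$age_group == "40-64"], 8 / 4000)
  expect_true(all(r$rate[!(r$sex == "male" & r$age_group == "40-64")] == 0))

  # single stratum, O=50 over n=100,000
  tb2 <- one_stratum_tables("A", 100000, 50)
  r2 <- reference_rates(tb2$counts, tb2$pop)
  expect_equal(r2$rate[r2$sex == "male" & r2$age_group == "40-64"], 5e-4)

  # zero events everywhere -> all rates 0
  tb3 <- one_stratum_tables(c("A", "B"), c(10, 20), c(0, 0))
  expect_true(all(reference_rates(tb3$counts, tb3$pop)$rate == 0))

  # events in an empty stratum is inconsistent input
  bad <- tb$counts
  bad$value[bad$sex == "female" & bad$age_group == "85+" &
              bad$tract_id == "A"] <- 3
  expect_error(reference_rates(bad, tb$pop), "zero population")
})

test_that("expected counts apply rates to the stratified population", {
  tb <- one_stratum_tables(c("A", "B"), c(1000, 3000), c(2, 6))
  r <- reference_rates(tb$counts, tb$pop)
  E <- expected_counts(tb$pop, r)
  expect_equal(E$E[E$tract_id == "A" & E$sex == "male"], 2)
  expect_equal(E$E[E$tract_id == "B" & E$sex == "male"], 6)
  r0 <- r; r0$rate <- 0
  expect_true(all(expected_counts(tb$pop, r0)$E == 0))
  expect_error(expected_counts(tb$pop, r[1:3, ]), "cover")
})

test_that("SAR is O/E on the percent scale with an E=0 guard", {
  obs <- data.frame(tract_id = c("A", "B", "C"), sex = "male",
                    O = c(5, 3, 0), stringsAsFactors = FALSE)
  exp_ <- data.frame(tract_id = c("A", "B", "C"), sex = "male",
                     E = c(5, 0, 2), stringsAsFactors = FALSE)
  expect_message(s <- sar(obs, exp_), "undefined")
  expect_equal(s$SAR[s$tract_id == "A"], 100)
  expect_true(is.na(s$SAR[s$tract_id == "B"]))
  expect_false(s$defined[s$tract_id == "B"])
  expect_equal(s$SAR[s$tract_id == "C"], 0)
  obs$O[1] <- -1
  expect_error(sar(obs, exp_), "negative")
})

test_that("internally derived rates force area-wide SAR balance", {
  tb <- one_stratum_tables(c("A", "B"), c(1000, 3000), c(2, 6))
  s <- standardize(tb$counts, tb$pop)
  sm <- s[s$sex == "male", ]
  expect_equal(sm$SAR[sm$tract_id == "A"], 100)
  expect_equal(sm$SAR[sm$tract_id == "B"], 100)
})

test_that("conservation holds on simulated data (sum E = sum O per sex)", {
  st <- simulate_study(seed = 5, n_rows = 8, n_cols = 8, total_events = 800)
  s <- standardize(st$counts, st$pop)
  for (sx in sexes) {
    ss <- s[s$sex == sx, ]
    expect_lt(abs(sum(ss$E) - sum(ss$O)) / max(sum(ss$O), 1), 1e-8)
  }
})

test_that("SAR is invariant to population scaling and period scaling", {
  st <- simulate_study(seed = 6, n_rows = 5, n_cols = 5, total_events = 300)
  s1 <- standardize(st$counts, st$pop)
  popc <- st$pop; popc$value <- popc$value * 7L
  s2 <- standardize(st$counts, popc)
  expect_equal(s1$SAR, s2$SAR)

  # scaling rates by k scales E by k and leaves O/E ratios' SAR unchanged
  r <- reference_rates(st$counts, st$pop)
  rk <- r; rk$rate <- r$rate * 3
  E1 <- expected_counts(st$pop, r); E2 <- expected_counts(st$pop, rk)
  expect_equal(E2$E, 3 * E1$E)
})

test_that("SAR means approach 100 under the null as population grows", {
  # law-of-large-numbers check: theta == 1, huge strata
  g <- make_lattice(4, 4, "rook")
  tb <- one_stratum_tables(g$tract_ids, rep(1e6, 16), rep(0, 16))
  r <- data.frame(sex = rep(sexes, each = 5), age_group = rep(age_groups, 2),
                  rate = rep(c(0.002, 0), c(3, 7)), stringsAsFactors = FALSE)
  one <- stats::setNames(rep(1, 16), g$tract_ids)
  cnt <- simulate_admissions(tb$pop, r, one, seed = 8)
  s <- standardize(cnt, tb$pop)
  expect_lt(abs(mean(s$SAR[s$sex == "male"]) - 100), 1)
})
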