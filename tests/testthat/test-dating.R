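test_that("correction coefficients rescale onto the reference lineage", {
  rc <- correction_coefficient(c(ref = 0.8, slow = 0.5, fast = 1.0),
                               reference = "ref")
  expect_equal(rc$rho[rc$species == "ref"], 1)
  expect_equal(rc$rho[rc$species == "fast"], 0.8)
  expect_equal(rc$rho[rc$species == "slow"], 1.6)

  # idempotence: correcting the corrected peaks changes nothing
  corrected <- stats::setNames(rc$ks_out * rc$rho, rc$species)
  rc2 <- correction_coefficient(corrected, reference = "ref")
  expect_true(all(abs(rc2$rho - 1) < 1e-12))

  expect_error(correction_coefficient(c(a = 1), reference = "b"),
               "not present")
  expect_error(correction_coefficient(c(ref = 0, b = 1), reference = "ref"),
               "positive")
})

test_that("rate calibration inverts the molecular clock", {
  r <- calibrate_rate(0.944, 112.1)
  expect_equal(r$r, 0.944 / (2 * 112.1e6))
  expect_lt(abs(r$r - 4.21e-9), 0.01e-9)
  expect_equal(calibrate_rate(2 * 0.944, 112.1)$r, 2 * r$r)
  expect_lt(calibrate_rate(0.944, 1e9)$r, 5e-13)
  expect_error(calibrate_rate(0, 10), "positive")
})

test_that("WGD dating is the exact inverse of the Ks law", {
  ages <- date_wgd(c(0.655, 0.944), rate = 4.21e-9)
  expect_equal(ages$age_ma, c(77.79, 112.11), tolerance = 1e-4)
  # round trip for arbitrary (T, r)
  for (t_ma in c(5, 77.8, 250)) {
    ks <- 2 * 3e-9 * t_ma * 1e6
    expect_equal(date_wgd(ks, 3e-9)$age_ma, t_ma)
  }
  expect_error(date_wgd(0, 4.21e-9), "positive")
})

test_that("LTR divergence counts mismatches over aligned columns", {
  a <- strrep("ACGT", 25)
  expect_equal(ltr_divergence(a, a)$lambda, 0)

  b <- a
  substr(b, 1, 1) <- "G"; substr(b, 50, 50) <- "A"; substr(b, 99, 99) <- "T"
  d <- ltr_divergence(a, b)
  expect_equal(d$lambda, 0.03)
  expect_equal(d$n_columns, 100)
  expect_error(ltr_divergence("", a), "nonempty")
})

test_that("LTR divergence matches the Jukes-Cantor forward oracle", {
  k_true <- 0.2
  co <- simulate_ltr_cohort(40, age_mode_ma = k_true / (2 * 1.51e-9) / 1e6,
                            age_sd_ma = 0, rate = 1.51e-9,
                            ltr_length = 1000, seed = 8)
  lam <- purrr::map2_dbl(co$ltr5, co$ltr3,
                         function(a, b) ltr_divergence(a, b)$lambda)
  p_expected <- jc_lambda(k_true)
  # binomial oracle around the JC-expected mismatch proportion
  se <- sqrt(p_expected * (1 - p_expected) / 1000)
  expect_lt(abs(mean(lam) - p_expected), 3 * se / sqrt(40) + 3 * se)
})

test_that("insertion times follow T = K / 2r", {
  expect_equal(ltr_insertion_time(0)$T_ma, 0)
  k <- ltr_insertion_time(jc_lambda(0.03), rate = 1.51e-9)
  expect_equal(k$K, 0.03)
  expect_lt(abs(k$T_ma - 9.9), 0.05)
  # monotone in lambda right up to saturation
  ks <- ltr_insertion_time(c(0.74, 0.7499))$K
  expect_gt(ks[2], ks[1])
  sat <- ltr_insertion_time(0.75)
  expect_true(sat$saturated)
  expect_true(is.na(sat$K))
})

test_that("a burst cohort's K density peaks at 2 r T", {
  co <- simulate_ltr_cohort(400, age_mode_ma = 9.9, age_sd_ma = 2,
                            rate = 1.51e-9, ltr_length = 1000, seed = 3)
  dated <- date_ltr_cohort(co, rate = 1.51e-9)
  burst <- ltr_burst_profile(dated)
  expect_lt(abs(burst$peak_k - 0.03) / 0.03, 0.15)

  # degenerate cohort: identical K values still yield the mode
  flat <- ltr_burst_profile(rep(0.05, 20))
  expect_lt(abs(flat$peak_k - 0.05), 0.001)

  expect_error(ltr_burst_profile(numeric(0)), "at least 10")
})

test_that("JC dating recovers simulated insertion ages within 10%", {
  for (t_ma in c(30, 99)) {  # 2rT of 0.09 and 0.3
    co <- simulate_ltr_cohort(500, age_mode_ma = t_ma, age_sd_ma = 0,
                              rate = 1.51e-9, ltr_length = 500,
                              seed = 60 + t_ma)
    dated <- date_ltr_cohort(co, rate = 1.51e-9)
    expect_lt(abs(mean(dated$T_ma) - t_ma) / t_ma, 0.1)
  }
})

test_that("saturating LTR simulations are refused", {
  expect_error(simulate_ltr_cohort(5, age_mode_ma = 300, age_sd_ma = 0,
                                   rate = 1.51e-9, ltr_length = 200,
                                   seed = 1),
               "undefined")
  expect_equal(nrow(simulate_ltr_cohort(0, 9.9, seed = 1)), 0)
  # zero rate leaves the two copies identical
  co <- simulate_ltr_cohort(3, 9.9, 0, rate = 1e-22, ltr_length = 200,
                            seed = 2)
  expect_identical(co$ltr5, co$ltr3)
})
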