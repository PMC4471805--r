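test_that("melting_model obeys its limiting behaviors", {
  flat <- list(bf = c(-20000, 0), bu = c(-2000, 0), tm = 50, dh = 300)
  # at Tm the signal is the midpoint of the (flat) baselines
  expect_equal(melting_model(flat, 50), -11000, tolerance = 1e-6)
  # huge dH: step function around Tm
  steep <- list(bf = c(-20000, 0), bu = c(-2000, 0), tm = 50, dh = 5000)
  expect_equal(melting_model(steep, 45), -20000, tolerance = 1e-3)
  expect_equal(melting_model(steep, 55), -2000, tolerance = 1e-3)
  # dH -> 0: constant blend of the baselines (f = 1/2 everywhere)
  soft <- list(bf = c(-20000, 0), bu = c(-2000, 0), tm = 50, dh = 1e-9)
  expect_equal(melting_model(soft, c(10, 50, 80)), rep(-11000, 3),
               tolerance = 1e-5)
  # zero amplitude reduces to the folded baseline line
  none <- list(bf = c(-20000, 10), bu = c(-20000, 10), tm = 50, dh = 300)
  expect_equal(melting_model(none, c(4, 40, 90)),
               -20000 + 10 * c(4, 40, 90))
})

test_that("noiseless fits recover generative parameters near-exactly", {
  f1 <- fit_melting(simulate_melting(melt_pars_1tr(37, 200), noise = 0), 1)
  expect_true(f1$converged)
  expect_equal(f1$transitions$tm, 37, tolerance = 1e-4)
  expect_equal(f1$transitions$dh_vh, 200, tolerance = 1e-3)

  f2 <- fit_melting(simulate_melting(melt_pars_2tr(c(50, 70)), noise = 0), 2)
  expect_equal(f2$transitions$tm, c(50, 70), tolerance = 1e-3)
  expect_equal(f2$transitions$dh_vh, c(250, 250), tolerance = 1e-2)
  expect_true(all(f2$transitions$cooperative))
})

test_that("noiseless recovery holds across random parameter draws", {
  set.seed(55)
  for (i in 1:12) {
    tm <- stats::runif(1, 25, 75)
    dh <- stats::runif(1, 120, 400)
    fit <- fit_melting(simulate_melting(melt_pars_1tr(tm, dh), noise = 0), 1)
    expect_equal(fit$transitions$tm, tm, tolerance = 1e-3)
    expect_equal(fit$transitions$dh_vh, dh, tolerance = 1e-2)
  }
  for (i in 1:4) {
    tm1 <- stats::runif(1, 25, 50)
    tm2 <- tm1 + stats::runif(1, 15, 30)
    fit <- fit_melting(simulate_melting(melt_pars_2tr(c(tm1, tm2)),
                                        noise = 0), 2)
    expect_equal(fit$transitions$tm, c(tm1, tm2), tolerance = 1e-2)
  }
})

test_that("2% noise leaves recovered Tm within 1 degree (median)", {
  err1 <- vapply(1:11, function(s) {
    f <- fit_melting(simulate_melting(melt_pars_1tr(37, 200), noise = 0.02,
                                      seed = s), 1)
    abs(f$transitions$tm - 37)
  }, numeric(1))
  expect_lt(stats::median(err1), 1)

  err2 <- t(vapply(1:11, function(s) {
    f <- fit_melting(simulate_melting(melt_pars_2tr(c(50, 70)), noise = 0.02,
                                      seed = s), 2)
    abs(f$transitions$tm - c(50, 70))
  }, numeric(2)))
  expect_lt(stats::median(err2[, 1]), 1)
  expect_lt(stats::median(err2[, 2]), 1)
})

test_that("transition-free input is flagged non-cooperative", {
  lin <- melting_curve(4:90, -20000 + 50 * (4:90))
  fit <- fit_melting(lin, 1)
  expect_false(fit$transitions$cooperative)

  # one real transition fitted with two: the spurious one is non-cooperative
  one <- simulate_melting(melt_pars_1tr(50, 250), noise = 0.01, seed = 3)
  fit2 <- fit_melting(one, 2)
  expect_true(any(fit2$transitions$cooperative))
})

test_that("delta_tm is antisymmetric and validates inputs", {
  fa <- fit_melting(simulate_melting(melt_pars_2tr(c(50, 70)), noise = 0), 2)
  fb <- fit_melting(simulate_melting(melt_pars_2tr(c(25, 70)), noise = 0), 2)
  expect_equal(delta_tm(fa, fa, 1), 0)
  expect_equal(delta_tm(fa, fb, 1), 25, tolerance = 1e-3)
  expect_equal(delta_tm(fb, fa, 1), -delta_tm(fa, fb, 1))
  # the shared transition is unaffected
  expect_equal(delta_tm(fa, fb, 2), 0, tolerance = 0.05)

  f1 <- fit_melting(simulate_melting(melt_pars_1tr(37), noise = 0), 1)
  expect_error(delta_tm(fa, f1), "different numbers")
  expect_error(delta_tm(fa, fb, 3), "not present")
})

test_that("derivative-based Tm agrees with the fit for a sharp transition", {
  mc <- simulate_melting(melt_pars_1tr(55, 400), noise = 0.005, seed = 9)
  expect_equal(tm_from_derivative(mc), 55, tolerance = 0.05)
})

test_that("melting fit methods and file round-trip", {
  mc <- simulate_melting(melt_pars_1tr(37, 200), noise = 0.02, seed = 2)
  fit <- fit_melting(mc, 1)
  expect_named(coef(fit), c("tm1", "dh_vh1"))
  expect_length(residuals(fit), length(mc$temperature))
  expect_equal(predict(fit), predict(fit, mc$temperature))
  sims <- simulate(fit, nsim = 2, seed = 8, noise = 0.02)
  expect_s3_class(sims[[1]], "melting_curve")
  expect_output(print(fit), "Tm1")

  dir <- withr::local_tempdir()
  p <- file.path(dir, "melt.csv")
  write_melting_curve(mc, p)
  back <- read_melting_curve(p)
  expect_equal(back$theta222, mc$theta222, tolerance = 1e-6)
})
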