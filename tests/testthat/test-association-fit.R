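test_that("noiseless fits recover the generative kd near-exactly", {
  truth <- scheme_monomer_trimer(12.5, kd = 6.75)
  curve <- predict_binding_curve(truth, 152 / 2^(0:10))
  fit <- fit_association(curve, scheme_monomer_trimer(12.5, kd = 100))
  expect_true(fit$converged)
  expect_equal(fit$scheme$steps$kd, 6.75, tolerance = 1e-6)
  expect_equal(fit$apparent_kd, apparent_kd(truth), tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)

  # two-step ladder, both constants free
  hx <- scheme_dimer_tetramer_hexamer(46, kd1 = 3, kd2 = 3)
  c2 <- predict_binding_curve(hx, 41 / 2^(0:10))
  fit2 <- fit_association(c2, scheme_dimer_tetramer_hexamer(46, 20, 20))
  expect_equal(fit2$scheme$steps$kd, c(3, 3), tolerance = 1e-4)
})

test_that("noisy dilution-series fits recover the apparent Kd", {
  # 11-point 1:1 series from 152 uM, 3 replicates, 3% MW noise
  truth <- scheme_monomer_trimer(12.5, kd = 6.75)  # apparent Kd = 3 uM
  recovered <- vapply(1:15, function(s) {
    des <- series_design(152, 11, replicates = 3, noise_mw = 0.03, seed = s)
    data <- simulate_binding_series(truth, des)
    fit_association(data, scheme_monomer_trimer(12.5, kd = 50))$apparent_kd
  }, numeric(1))
  # median recovery within +/-20% of the generative apparent Kd
  expect_lt(abs(stats::median(recovered) - 3) / 3, 0.20)
})

test_that("tag mass shifts the curve but not the fitted kd", {
  des <- series_design(41, 11, noise_mw = 0, seed = 1)
  plain <- scheme_dimer_tetramer_hexamer(46, kd1 = 3, kd2 = 3, tag_mass = 0)
  tagged <- scheme_dimer_tetramer_hexamer(46, kd1 = 3, kd2 = 3, tag_mass = 16)
  d_plain <- simulate_binding_series(plain, des)
  d_tag <- simulate_binding_series(tagged, des)
  # tagged curve is the plain curve scaled by the mass ratio
  expect_equal(d_tag$mw / d_plain$mw, rep(62 / 46, 11))
  f_plain <- fit_association(d_plain,
                             scheme_dimer_tetramer_hexamer(46, 10, 10))
  f_tag <- fit_association(d_tag,
                           scheme_dimer_tetramer_hexamer(46, 10, 10,
                                                         tag_mass = 16))
  expect_equal(f_plain$scheme$steps$kd, f_tag$scheme$steps$kd,
               tolerance = 1e-4)
})

test_that("degenerate flat data drive the kd to the bound, flagged", {
  flat <- binding_curve(152 / 2^(0:10), rep(12.5, 11))
  fit <- fit_association(flat, scheme_monomer_trimer(12.5, kd = 10))
  expect_true(fit$at_boundary || !fit$converged)
  expect_false(fit$converged)
})

test_that("fit input validation and overload handling", {
  sc <- scheme_monomer_trimer(12.5, kd = 5)
  tiny <- binding_curve(c(1, 2), c(13, 14))
  expect_error(fit_association(tiny, sc), "at least 3")
  curve <- predict_binding_curve(sc, 152 / 2^(0:10))
  expect_error(fit_association(curve, sc, free = 5), "index")
  # overloaded points are excluded from the fit
  flagged <- binding_curve(curve$c_total, curve$mw,
                           overloaded = c(rep(FALSE, 9), TRUE, TRUE))
  fit <- fit_association(flagged, scheme_monomer_trimer(12.5, kd = 50))
  expect_equal(fit$n_points, 9)
  expect_equal(fit$scheme$steps$kd, 5, tolerance = 1e-5)
})

test_that("bootstrap CI brackets the estimate and methods are consistent", {
  truth <- scheme_monomer_trimer(12.5, kd = 6.75)
  des <- series_design(152, 11, replicates = 2, noise_mw = 0.03, seed = 7)
  data <- simulate_binding_series(truth, des)
  fit <- fit_association(data, scheme_monomer_trimer(12.5, kd = 50),
                         bootstrap = 100, seed = 1729)
  expect_true(fit$apparent_kd_ci[1] <= fit$apparent_kd + 1e-9)
  expect_true(fit$apparent_kd_ci[2] >= fit$apparent_kd - 1e-9)

  expect_named(coef(fit), c("kd_3mer", "apparent_kd"))
  expect_equal(predict(fit, 1e-6), 12.5, tolerance = 1e-4)
  expect_length(residuals(fit), fit$n_points)
  sims <- simulate(fit, nsim = 2, seed = 3, noise_mw = 0.03)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "binding_curve")
  expect_output(print(fit), "apparent Kd")
})
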