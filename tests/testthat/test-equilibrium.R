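test_that("solve_equilibrium reproduces hand-solved cases", {
  # monomer-trimer, overall K = [M]^3/[T] = 1, c_total = 4: [M] = [T] = 1
  sc <- scheme_monomer_trimer(12.5, kd = 1)
  d <- solve_equilibrium(sc, 4)
  expect_equal(unname(d$concentrations), c(1, 1), tolerance = 1e-9)

  # dimer->tetramer->hexamer with k1 = k2 = 3, c_total = 36:
  # t = d^2/k1 = 3, h = t*d/k2 = 3, and 2*3 + 4*3 + 6*3 = 36
  hx <- scheme_dimer_tetramer_hexamer(46, kd1 = 3, kd2 = 3)
  dh <- solve_equilibrium(hx, 36)
  expect_equal(unname(dh$concentrations), c(3, 3, 3), tolerance = 1e-9)

  # zero concentration: all species zero
  expect_equal(unname(solve_equilibrium(sc, 0)$concentrations), c(0, 0))
})

test_that("mass conservation and oracle agreement hold for random schemes", {
  set.seed(101)
  for (i in 1:100) {
    sch <- random_scheme()
    ct <- 10^stats::runif(1, -2, 3)
    d <- solve_equilibrium(sch, ct)
    expect_true(all(d$concentrations >= 0))
    # protomer conservation to 1e-9 relative
    tot <- sum(sch$species$order * d$concentrations)
    expect_equal(tot, ct, tolerance = 1e-9)
    # independent bisection oracle to 1e-8 relative
    oc <- oracle_equilibrium(sch, ct)
    expect_equal(unname(d$concentrations), oc, tolerance = 1e-8)
  }
})

test_that("weight-average MW matches its definition and bounds", {
  sc <- scheme_monomer_trimer(12.5, kd = 1)
  # [M] = [T] = 1: (12.5^2 + 37.5^2) / (12.5 + 37.5) = 31.25
  expect_equal(weight_average_mw(solve_equilibrium(sc, 4)), 31.25)
  expect_error(weight_average_mw(solve_equilibrium(sc, 0)), "undefined")

  # equal mass fractions of the two species: midpoint 25 kDa
  dist <- solve_equilibrium(sc, 4)
  dist$concentrations <- c(n1 = 3, n3 = 1)  # mass 37.5 each
  expect_equal(weight_average_mw(dist), 25)

  # monotone and bounded for random schemes
  set.seed(202)
  for (i in 1:20) {
    sch <- random_scheme()
    grid <- 10^seq(-2, 3, length.out = 12)
    curve <- predict_binding_curve(sch, grid)
    expect_true(all(diff(curve$mw) > 0))
    expect_true(all(curve$mw > min(sch$species$mass)))
    expect_true(all(curve$mw < max(sch$species$mass)))
  }
})

test_that("predict_binding_curve approaches monomer and saturation limits", {
  sc <- scheme_monomer_trimer(12.5, kd = 6.75)
  low <- predict_binding_curve(sc, 1e-7)
  expect_equal(low$mw, 12.5, tolerance = 1e-4)
  high <- predict_binding_curve(sc, 1e8)
  expect_equal(high$mw, 37.5, tolerance = 1e-3)
  expect_error(predict_binding_curve(sc, numeric(0)), "empty")
  expect_error(predict_binding_curve(sc, c(1, -1)), "positive")
})

test_that("species_molar_ratio behaves at its edges", {
  hx <- scheme_dimer_tetramer_hexamer(46, kd1 = 3, kd2 = 3)
  d <- solve_equilibrium(hx, 36)
  expect_equal(species_molar_ratio(d, 6, 4), 1)
  expect_equal(species_molar_ratio(d, 4, 4), 1)
  # higher orders vanish faster on dilution
  dil <- solve_equilibrium(hx, 0.001)
  expect_lt(species_molar_ratio(dil, 6, 4), 1e-3)
  expect_error(species_molar_ratio(d, 5, 4), "not in scheme")
})

test_that("apparent Kd matches the monomer-trimer closed form", {
  # midpoint at [M]^2 = K/3: for K = 1, c_mid = 2/sqrt(3)
  sc <- scheme_monomer_trimer(12.5, kd = 1)
  expect_equal(apparent_kd(sc), 2 / sqrt(3), tolerance = 1e-6)

  # scale invariance: rescaling the kd rescales the apparent Kd as sqrt
  # (kd3 has uM^2 units), i.e. K -> f K gives c_mid -> sqrt(f) c_mid
  sc4 <- scheme_monomer_trimer(12.5, kd = 4)
  expect_equal(apparent_kd(sc4), 2 * 2 / sqrt(3), tolerance = 1e-6)

  # single-step uM-scale scheme: apparent Kd scales linearly with kd
  d1 <- build_scheme("d", 10, 0, "monomer", list(c(2, 1)))
  d5 <- build_scheme("d", 10, 0, "monomer", list(c(2, 5)))
  expect_equal(apparent_kd(d5) / apparent_kd(d1), 5, tolerance = 1e-6)

  # curve that stays in the monomer limit: no midpoint crossing
  expect_error(apparent_kd(sc, c_range = c(1e-9, 1e-7)), "midpoint")

  # the inflection-point estimator is a distinct summary: it sits below the
  # midpoint for this scheme but scales the same way with the kd
  infl <- apparent_kd(sc, method = "inflection")
  expect_gt(infl, 0)
  expect_lt(infl, apparent_kd(sc))
  infl4 <- apparent_kd(sc4, method = "inflection")
  expect_equal(infl4 / infl, 2, tolerance = 1e-3)

  # binding_curve input: interpolated midpoint close to the scheme value
  # (finite span biases the observed extremes slightly)
  curve <- predict_binding_curve(sc, 10^seq(-4, 4, by = 0.05))
  expect_equal(apparent_kd(curve), apparent_kd(sc), tolerance = 0.01)
})
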