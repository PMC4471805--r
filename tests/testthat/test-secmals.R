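test_that("dRI to concentration conversion and baseline handling", {
  n <- 101
  dri <- numeric(n); dri[45:55] <- 1.85e-5
  ch <- chromatogram(seq(10, 14, length.out = n), ls = numeric(n), dri = dri)
  c_mass <- concentration_from_ri(ch)
  # delta-n 1.85e-5 over dn/dc 0.1850 ml/g = 1e-4 g/ml = 0.1 mg/ml
  expect_equal(max(c_mass), 0.1, tolerance = 1e-9)

  # linearity
  ch2 <- chromatogram(ch$volume, ch$ls, 2 * dri)
  expect_equal(max(concentration_from_ri(ch2)), 0.2, tolerance = 1e-9)

  # constant offsets are removed by the outer-slice baseline
  ch3 <- chromatogram(ch$volume, ch$ls, dri + 3e-4)
  expect_equal(concentration_from_ri(ch3), c_mass, tolerance = 1e-9)

  # all-zero trace warns
  ch0 <- chromatogram(1:10, numeric(10), numeric(10))
  expect_warning(concentration_from_ri(ch0), "all zero")
})

test_that("molar conversion arithmetic", {
  expect_equal(molar_from_mass(0.1, 12.5), 8)
  expect_equal(molar_from_mass(1, 46), 1000 / 46, tolerance = 1e-9)
  expect_equal(molar_from_mass(0, 12.5), 0)
  expect_error(molar_from_mass(0.1, 0), "positive")
})

test_that("light scattering to MW: arithmetic, linearity, masking", {
  n <- 101
  vol <- seq(10, 14, length.out = n)
  c_mass <- 0.1 * exp(-0.5 * ((vol - 12) / 0.4)^2)
  ls <- 0.01 * c_mass * 12.5
  ch <- chromatogram(vol, ls, dri = c_mass / 1000 * 0.185, ls_calib = 0.01)
  mw <- mw_from_light_scattering(ch, c_mass)
  # robust baseline subtraction perturbs the Gaussian tails by ~1e-5 relative
  expect_equal(mw[vol == 12], 12.5, tolerance = 1e-4)
  # tripled LS at fixed concentration triples the MW
  ch3 <- chromatogram(vol, 3 * ls, ch$dri, ls_calib = 0.01)
  expect_equal(mw_from_light_scattering(ch3, c_mass)[vol == 12], 37.5,
               tolerance = 1e-4)
  # below-threshold slices are masked, not errors
  expect_true(any(is.na(mw)))
  expect_false(is.na(mw[vol == 12]))
})

test_that("noiseless chromatogram round-trip recovers the injection", {
  sc <- scheme_monomer_trimer(12.5, kd = 6.75)
  ch <- simulate_chromatogram(sc, load_c = 20, noise = 0)
  prof <- slice_profile(ch, 12.5)
  ip <- extract_injection_point(prof)
  # apex concentration within 1%
  expect_equal(ip$c_peak, 20, tolerance = 0.01)
  # the summary MW equals the concentration-weighted model MW over the same
  # half-height window (the statistic the generator encoded slice by slice)
  half <- max(prof$c_molar) / 2
  win <- prof$valid & prof$c_molar >= half
  model_mw <- vapply(prof$c_molar[win], function(ct)
    weight_average_mw(solve_equilibrium(sc, ct)), numeric(1))
  expected <- sum(prof$c_molar[win] * model_mw) / sum(prof$c_molar[win])
  expect_equal(ip$mw_mean, expected, tolerance = 0.01)
  # and lies within the model MW bounds across the window
  expect_gt(ip$mw_mean, min(model_mw) * 0.999)
  expect_lt(ip$mw_mean, weight_average_mw(solve_equilibrium(sc, 20)) * 1.001)

  # a saturated (uniform-MW) peak recovers the generative MW within 1%
  sat <- scheme_monomer_trimer(12.5, kd = 1e-6)
  ip_sat <- extract_injection_point(slice_profile(
    simulate_chromatogram(sat, load_c = 50, noise = 0), 12.5))
  expect_equal(ip_sat$mw_mean, 37.5, tolerance = 0.01)

  # dilution limit: recovered MW tends to the monomer mass
  ip_dil <- extract_injection_point(slice_profile(
    simulate_chromatogram(sc, load_c = 0.005, noise = 0), 12.5))
  expect_equal(ip_dil$mw_mean, 12.5, tolerance = 0.02)
})

test_that("noisy round-trip stays within the injected noise", {
  sc <- scheme_monomer_trimer(12.5, kd = 6.75)
  errs <- vapply(1:20, function(s) {
    ch <- simulate_chromatogram(sc, load_c = 20, noise = 0.01, seed = s)
    ip <- extract_injection_point(slice_profile(ch, 12.5))
    abs(ip$c_peak - 20) / 20
  }, numeric(1))
  expect_lt(stats::median(errs), 0.03)
})

test_that("halving the load lowers both concentration and MW", {
  sc <- scheme_monomer_trimer(12.5, kd = 6.75)
  hi <- extract_injection_point(slice_profile(
    simulate_chromatogram(sc, load_c = 20, noise = 0), 12.5))
  lo <- extract_injection_point(slice_profile(
    simulate_chromatogram(sc, load_c = 10, noise = 0), 12.5))
  expect_equal(lo$c_peak / hi$c_peak, 0.5, tolerance = 0.01)
  expect_lt(lo$mw_mean, hi$mw_mean)
})

test_that("overload flag responds to peak asymmetry", {
  vol <- seq(10, 14, length.out = 201)
  # symmetric peak: not overloaded
  c_sym <- 10 * exp(-0.5 * ((vol - 12) / 0.3)^2)
  prof_sym <- structure(list(volume = vol, c_mass = c_sym * 12.5 / 1000,
                             c_molar = c_sym, mw = rep(37.5, 201),
                             valid = rep(TRUE, 201)),
                        class = "sliced_profile")
  expect_false(extract_injection_point(prof_sym)$overloaded)
  # strongly tailing peak: flagged
  width <- ifelse(vol < 12, 0.05, 0.8)
  c_asym <- 10 * exp(-0.5 * ((vol - 12) / width)^2)
  prof_asym <- structure(list(volume = vol, c_mass = c_asym * 12.5 / 1000,
                              c_molar = c_asym, mw = rep(37.5, 201),
                              valid = rep(TRUE, 201)),
                         class = "sliced_profile")
  expect_true(extract_injection_point(prof_asym)$overloaded)
})

test_that("assemble_binding_curve sorts, flags and warns", {
  sc <- scheme_monomer_trimer(12.5, kd = 6.75)
  loads <- c(20, 5, 10)
  pts <- lapply(loads, function(l)
    extract_injection_point(slice_profile(
      simulate_chromatogram(sc, load_c = l, noise = 0), 12.5)))
  curve <- assemble_binding_curve(pts)
  expect_equal(nrow(curve), 3)
  expect_true(all(diff(curve$c_total) > 0))

  all_over <- lapply(pts, function(p) { p$overloaded <- TRUE; p })
  expect_warning(assemble_binding_curve(all_over), "overloaded")
})

test_that("chromatogram and binding-curve files round-trip", {
  dir <- withr::local_tempdir()
  sc <- scheme_monomer_trimer(12.5, kd = 6.75)
  ch <- simulate_chromatogram(sc, load_c = 20, noise = 0.01, seed = 2)
  p <- file.path(dir, "trace.csv")
  write_chromatogram(ch, p)
  back <- read_chromatogram(p)
  expect_equal(back$dri, ch$dri, tolerance = 1e-6)
  expect_equal(back$dn_dc, 0.1850)

  bc <- binding_curve(c(1, 2, 4), c(15, 20, 28),
                      overloaded = c(FALSE, FALSE, TRUE))
  bp <- file.path(dir, "points.csv")
  write_binding_curve(bc, bp)
  bc2 <- read_binding_curve(bp)
  expect_equal(bc2$mw, bc$mw)
  expect_equal(bc2$overloaded, bc$overloaded)

  expect_error(read_chromatogram(file.path(dir, "nope.csv")), "not found")
  bad <- file.path(dir, "bad.csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_chromatogram(bad), "volume_ml")
})
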