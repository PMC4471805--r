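#' Design of a SEC-MALS dilution-series experiment
#'
#' A 1:1 (twofold) dilution series from a top concentration, the design used
#' to map weight-average MW across ~3 orders of magnitude of concentration.
#'
#' @param top_concentration highest protomer-equivalent concentration, uM.
#' @param n_dilutions number of 1:1 dilution steps including the top
#'   (default 11, spanning about three decades).
#' @param replicates independent injections per concentration (default 1).
#' @param noise_mw relative (multiplicative lognormal) MW noise, default 0.03.
#' @param seed RNG seed.
#' @return A list of class `series_design`.
#' @export
series_design <- function(top_concentration, n_dilutions = 11,
                          replicates = 1, noise_mw = 0.03, seed = 1L) {
  if (top_concentration <= 0) stop("'top_concentration' must be positive")
  if (n_dilutions < 1) stop("'n_dilutions' must be at least 1")
  if (replicates < 1) stop("'replicates' must be at least 1")
  if (noise_mw < 0) stop("'noise_mw' must be nonnegative")
  structure(list(top_concentration = top_concentration,
                 n_dilutions = as.integer(n_dilutions),
                 replicates = as.integer(replicates),
                 noise_mw = noise_mw, seed = as.integer(seed)),
            class = "series_design")
}

#' Simulate a SEC-MALS dilution-series binding curve
#'
#' Concentrations follow `top x 2^-(i-1)`, i = 1..n_dilutions, each with the
#' design's number of replicate injections. The model MW from
#' [predict_binding_curve()] receives multiplicative lognormal noise
#' (MALS noise grows with signal), reproducibly from the design seed.
#'
#' @param scheme an [assembly_scheme][build_scheme].
#' @param design a [series_design].
#' @return A [binding_curve] with `provenance = "simulated"`.
#' @examples
#' sc <- scheme_monomer_trimer(12.5, kd = 6.75)
#' simulate_binding_series(sc, series_design(152, 11, noise_mw = 0))
#' @export
simulate_binding_series <- function(scheme, design) {
  stopifnot(inherits(scheme, "assembly_scheme"),
            inherits(design, "series_design"))
  conc <- design$top_concentration * 2^-(seq_len(design$n_dilutions) - 1L)
  conc <- rep(conc, each = design$replicates)
  model <- predict_binding_curve(scheme, conc)  # sorted ascending
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(design$seed)
  noisy <- model$mw * exp(stats::rnorm(length(model$mw), 0, design$noise_mw))
  binding_curve(model$c_total, noisy, provenance = "simulated")
}

#' Simulate a SEC-MALS chromatogram
#'
#' A Gaussian elution peak whose apex reaches `load_c` protomer-equivalent
#' uM; each slice's oligomer composition (hence MW) comes from
#' [solve_equilibrium()] at the slice concentration (fast exchange on the
#' chromatographic timescale). Detector traces follow the forward model of
#' the processing module — dRI = (c/1000) x dn/dc, LS = k x c x MW — with
#' additive Gaussian noise scaled to the apex signal of each trace.
#'
#' @param scheme an [assembly_scheme][build_scheme].
#' @param load_c apex protomer-equivalent concentration, uM.
#' @param peak_center elution volume of the apex, ml.
#' @param peak_width Gaussian sigma of the peak, ml.
#' @param noise relative additive detector noise (fraction of apex signal).
#' @param seed RNG seed.
#' @param dn_dc,ls_calib instrument constants.
#' @param volume elution grid, ml (default `peak_center` +/- 5 sigma at 4
#'   sigma/50 spacing plus flat baseline flanks).
#' @return A [chromatogram].
#' @export
simulate_chromatogram <- function(scheme, load_c, peak_center = 12,
                                  peak_width = 0.4, noise = 0, seed = 1L,
                                  dn_dc = 0.1850, ls_calib = 0.01,
                                  volume = NULL) {
  stopifnot(inherits(scheme, "assembly_scheme"))
  if (load_c <= 0) stop("'load_c' must be positive (uM)")
  if (is.null(volume))
    volume <- seq(peak_center - 5 * peak_width, peak_center + 5 * peak_width,
                  length.out = 121)
  c_molar <- load_c * exp(-0.5 * ((volume - peak_center) / peak_width)^2)
  mass <- unit_mass(scheme)
  mw <- vapply(c_molar, function(ct) {
    if (ct < load_c * 1e-6) return(min(scheme$species$mass))
    weight_average_mw(solve_equilibrium(scheme, ct))
  }, numeric(1))
  c_mass <- c_molar * mass / 1000          # mg/ml
  dri <- (c_mass / 1000) * dn_dc           # dimensionless delta-n
  ls <- ls_calib * c_mass * mw
  if (noise > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    dri <- dri + stats::rnorm(length(dri), 0, noise * max(dri))
    ls <- ls + stats::rnorm(length(ls), 0, noise * max(ls))
  }
  chromatogram(volume, ls, dri, dn_dc = dn_dc, ls_calib = ls_calib)
}

#' Simulate a thermal melting curve
#'
#' Evaluates [melting_model()] on a temperature grid and applies
#' multiplicative lognormal noise.
#'
#' @param pars melting-model parameter list (see [melting_model()]).
#' @param grid temperatures, degrees C (default 4-90 in 1-degree steps, the
#'   standard ramp).
#' @param noise relative noise (default 0).
#' @param seed RNG seed.
#' @param ramp_rate metadata, degrees C/min.
#' @return A [melting_curve].
#' @examples
#' pars <- list(bf = c(-30000, 30), bu = c(-5000, -10), tm = 37, dh = 200)
#' mc <- simulate_melting(pars, noise = 0.02, seed = 7)
#' @export
simulate_melting <- function(pars, grid = seq(4, 90, by = 1), noise = 0,
                             seed = 1L, ramp_rate = 1) {
  theta <- melting_model(pars, grid)
  if (noise > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    theta <- theta * exp(stats::rnorm(length(theta), 0, noise))
  }
  melting_curve(grid, theta, ramp_rate = ramp_rate)
}

#' Simulate a CD spectrum from secondary-structure fractions
#'
#' Linear blend of the basis spectra plus multiplicative noise; the exact
#' inverse of [deconvolute_secondary_structure()] at zero noise.
#'
#' @param fractions named numeric vector or `ss_fractions` object with
#'   helix/strand/coil fractions (nonnegative, summing to ~1).
#' @param basis basis matrix from [cd_basis_spectra()].
#' @param noise relative noise (default 0).
#' @param seed RNG seed.
#' @return A [cd_spectrum].
#' @export
simulate_cd_spectrum <- function(fractions, basis = cd_basis_spectra(),
                                 noise = 0, seed = 1L) {
  if (inherits(fractions, "ss_fractions")) fractions <- fractions$fractions
  fractions <- fractions[colnames(basis)]
  if (any(is.na(fractions)) || any(fractions < 0))
    stop("'fractions' must supply nonnegative helix, strand and coil values")
  mre <- drop(basis %*% fractions)
  if (noise > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    scale <- max(abs(mre))
    mre <- mre + stats::rnorm(length(mre), 0, noise * scale)
  }
  cd_spectrum(attr(basis, "wavelength"), mre)
}

PROTON_MASS_DA <- 1.00728

#' Predict native mass-spectrometry charge-state series
#'
#' Forward m/z prediction for intact oligomers observed by native
#' electrospray MS: m/z = (order x protomer mass in Da + z x 1.00728) / z
#' for each requested oligomer order and charge.
#'
#' @param scheme an [assembly_scheme][build_scheme]; protomer + tag mass is
#'   used.
#' @param orders oligomer orders to predict; must be species of the scheme.
#' @param z_range integer charge range `c(zmin, zmax)`, zmin >= 1.
#' @return Data frame of class `native_ms_peaks` with columns `order`, `z`,
#'   `mz`.
#' @examples
#' sc <- scheme_dimer_tetramer_hexamer(46, kd1 = 3, kd2 = 3)
#' predict_native_ms_peaks(sc, orders = c(2, 4, 6), z_range = c(10, 25))
#' @export
predict_native_ms_peaks <- function(scheme, orders = scheme$species$order,
                                    z_range = c(5, 30)) {
  stopifnot(inherits(scheme, "assembly_scheme"))
  if (any(!(orders %in% scheme$species$order)))
    stop("orders not in scheme: ",
         paste(setdiff(orders, scheme$species$order), collapse = ", "))
  if (z_range[1] < 1) stop("minimum charge must be >= 1")
  zz <- seq.int(z_range[1], z_range[2])
  mass_da <- unit_mass(scheme) * 1000
  out <- expand.grid(order = orders, z = zz)
  out$mz <- (out$order * mass_da + out$z * PROTON_MASS_DA) / out$z
  out <- out[order(out$order, out$z), ]
  rownames(out) <- NULL
  class(out) <- c("native_ms_peaks", "data.frame")
  out
}

#' SEC-MALS experimental-design fixture table
#'
#' The per-construct design parameters of the dilution-series experiments:
#' construct label, monomeric MW (kDa), size-exclusion column, and the
#' minimum and maximum on-column concentrations reached (uM,
#' protomer-equivalent). Used to parameterize realistic synthetic series.
#'
#' @return Data frame with columns `construct`, `monomer_kda`, `column`,
#'   `c_min_um`, `c_max_um`.
#' @export
secmals_design_table <- function() {
  data.frame(
    construct = c("SAS-5_FL", "SAS-5_FLEX-MsyB", "SAS-5_2-265-MsyB",
                  "SAS-5_2-265-MsyB (b)", "SAS-5_2-265 L141E",
                  "SAS-5_2-265 L141E/M167E", "SAS-5_2-265 I247E",
                  "SAS-5_2-265 L141E/I247E", "SAS-5_Imp", "SAS-5_CC-L",
                  "C.briggsae SAS-5 (96-199)", "C.brenneri SAS-5 (1-82)",
                  "C.remanei SAS-5 (98-206)", "C.sinica SAS-5 (94-204)",
                  "C.tropicalis SAS-5 (94-199)"),
    monomer_kda = c(46, 62, 46, 46, 46, 46, 46, 46, 6.5, 12.5,
                    12.7, 10.2, 13, 13, 12.5),
    column = c("Superose6", "Superose6", "Superose6", "Superdex200",
               "Superdex200", "Superdex200", "Superdex200", "Superdex200",
               "Superdex75", "Superdex75", "Superdex75", "Superdex75",
               "Superdex75", "Superdex75", "Superdex75"),
    c_min_um = c(0.10, 0.03, 0.02, 0.05, 1.32, 1.16, 0.05, 0.82, 2.92,
                 0.18, 0.10, 0.21, 0.21, 0.16, 0.12),
    c_max_um = c(0.57, 9.5, 41, 41, 63, 63, 63, 63, 92, 152,
                 149, 186, 146, 145, 152),
    stringsAsFactors = FALSE
  )
}
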