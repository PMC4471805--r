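#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing: each point is replaced by the
#' value at its position of a degree-`order` polynomial fitted to the
#' surrounding `window` points. Edges use the polynomial fitted to the
#' truncated window, so series length is preserved and polynomials of degree
#' <= `order` pass through unchanged.
#'
#' @param values numeric series to smooth.
#' @param window odd window length (points), must exceed `order` and not the
#'   series length.
#' @param order polynomial degree (default 3).
#' @return Smoothed series of the same length.
#' @examples
#' x <- seq(0, 2 * pi, length.out = 101)
#' noisy <- sin(x) + rnorm(101, 0, 0.1)
#' smooth <- smooth_signal(noisy, window = 11, order = 3)
#' @export
smooth_signal <- function(values, window = 11, order = 3) {
  n <- length(values)
  if (window %% 2 != 1) stop("'window' must be odd")
  if (order >= window) stop("'order' must be smaller than 'window'")
  if (window > n) stop("'window' (", window, ") exceeds series length (", n, ")")
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  # interior: fixed convolution weights from the pseudo-inverse row at 0
  off <- -h:h
  A <- outer(off, 0:order, `^`)
  w <- solve(crossprod(A), t(A))[1L, ]   # row selecting the constant term
  for (i in seq_len(n)) {
    if (i > h && i <= n - h) {
      out[i] <- sum(w * values[(i - h):(i + h)])
    } else {
      idx <- max(1L, i - h):min(n, i + h)
      o <- idx - i
      Ai <- outer(o, 0:min(order, length(idx) - 1L), `^`)
      beta <- qr.solve(Ai, values[idx])
      out[i] <- beta[1L]
    }
  }
  out
}

#' Mean-residue molar ellipticity
#'
#' Converts the raw CD signal (machine millidegrees) to mean-residue molar
#' ellipticity: \eqn{[\theta]_{MRE} = \theta_{mdeg} / (10 \, c_M \, l \, N)}
#' with molar protein concentration \eqn{c_M}, path length \eqn{l} (cm) and
#' residue count \eqn{N}.
#'
#' @param raw_mdeg raw ellipticity, millidegrees.
#' @param conc protein concentration, uM.
#' @param path cuvette path length, cm.
#' @param n_res number of residues.
#' @return Mean-residue ellipticity, deg cm^2 dmol^-1.
#' @examples
#' mean_residue_ellipticity(100, conc = 20, path = 0.1, n_res = 100)  # 5e4
#' @export
mean_residue_ellipticity <- function(raw_mdeg, conc, path, n_res) {
  if (conc <= 0 || path <= 0 || n_res <= 0)
    stop("'conc', 'path' and 'n_res' must all be positive")
  raw_mdeg / (10 * (conc * 1e-6) * path * n_res)
}

#' Construct a CD spectrum
#'
#' @param wavelength strictly monotone wavelength grid, nm (far-UV,
#'   typically 180-260).
#' @param mre mean-residue molar ellipticity, deg cm^2 dmol^-1.
#' @param ht_voltage optional per-wavelength photomultiplier high-tension
#'   voltage (V); points above `ht_max` are dropped, mirroring the standard
#'   practice of truncating data where the detector saturates.
#' @param conc,path,n_res optional sample metadata (uM, cm, residue count).
#' @param ht_max high-tension cutoff in volts (default 800).
#' @return An object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelength, mre, ht_voltage = NULL,
                        conc = NA, path = NA, n_res = NA, ht_max = 800) {
  wavelength <- as.numeric(wavelength); mre <- as.numeric(mre)
  if (length(wavelength) != length(mre))
    stop("'wavelength' and 'mre' must have equal length")
  d <- diff(wavelength)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("'wavelength' must be strictly monotone")
  if (!is.null(ht_voltage)) {
    if (length(ht_voltage) != length(mre))
      stop("'ht_voltage' must match the spectrum length")
    keep <- ht_voltage <= ht_max
    wavelength <- wavelength[keep]; mre <- mre[keep]
    ht_voltage <- ht_voltage[keep]
  }
  structure(list(wavelength = wavelength, mre = mre,
                 ht_voltage = ht_voltage,
                 meta = list(conc = conc, path = path, n_res = n_res)),
            class = "cd_spectrum")
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat("CD spectrum: ", length(x$wavelength), " points, ",
      format(min(x$wavelength)), "-", format(max(x$wavelength)), " nm\n",
      sep = "")
  invisible(x)
}

#' Idealized secondary-structure basis spectra
#'
#' Synthetic reference spectra for pure alpha-helix, beta-strand and random
#' coil on a far-UV grid, built from Gaussian bands at the canonical
#' positions: helix with the pi-pi* maximum near 192 nm and the double
#' minimum at 208/222 nm; strand with a maximum near 196 nm and a single
#' minimum near 218 nm; coil dominated by a deep minimum near 198 nm with a
#' weak positive band near 220 nm. Magnitudes follow textbook mean-residue
#' ellipticities. These are idealized stand-ins for non-redistributable
#' experimental reference sets, adequate for the semi-quantitative fractions
#' this analysis reports.
#'
#' @param wavelength wavelength grid, nm (default 190-250).
#' @return Matrix with columns `helix`, `strand`, `coil` (deg cm^2 dmol^-1)
#'   and `wavelength` attribute.
#' @export
cd_basis_spectra <- function(wavelength = seq(190, 250, by = 1)) {
  g <- function(center, width, amp) amp * exp(-((wavelength - center) / width)^2)
  helix <- g(192, 6, 70000) + g(208, 7, -33000) + g(222, 9, -35000)
  strand <- g(196, 7, 30000) + g(218, 11, -13000)
  coil <- g(198, 8, -40000) + g(222, 14, 3000)
  m <- cbind(helix = helix, strand = strand, coil = coil)
  attr(m, "wavelength") <- wavelength
  m
}

# exact nonnegative least squares for a small number of columns:
# enumerate active sets, keep the feasible solution with minimal RSS
nnls_small <- function(A, b) {
  p <- ncol(A)
  best <- NULL; best_rss <- Inf
  for (mask in seq_len(2^p - 1)) {
    cols <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    As <- A[, cols, drop = FALSE]
    beta <- tryCatch(qr.solve(crossprod(As), crossprod(As, b)),
                     error = function(e) NULL)
    if (is.null(beta) || any(!is.finite(beta)) || any(beta < -1e-12)) next
    r <- b - As %*% beta
    rss <- sum(r^2)
    if (rss < best_rss - 1e-9) {
      best_rss <- rss
      full <- numeric(p); full[cols] <- pmax(beta, 0)
      best <- full
    }
  }
  zero_rss <- sum(b^2)
  if (is.null(best) || zero_rss < best_rss) {
    best <- numeric(p); best_rss <- zero_rss
  }
  list(coef = best, rss = best_rss)
}

#' Deconvolute a CD spectrum into secondary-structure fractions
#'
#' Nonnegative least squares of the mean-residue ellipticity against
#' helix/strand/coil basis spectra; the nonnegative coefficients are
#' renormalized to fractions summing to 1. The result is semi-quantitative:
#' it depends on the basis set and is best read as relative composition.
#'
#' @param spec a [cd_spectrum].
#' @param basis basis matrix from [cd_basis_spectra()] (or any matrix with a
#'   `wavelength` attribute and columns helix/strand/coil) on a grid covering
#'   the spectrum's wavelengths.
#' @return An object of class `ss_fractions`: list with `fractions` (named
#'   helix/strand/coil, in [0,1], summing to 1), `coef` (raw nonnegative
#'   coefficients), `rss`, `residual_rms`.
#' @examples
#' basis <- cd_basis_spectra()
#' spec <- cd_spectrum(attr(basis, "wavelength"),
#'                     0.6 * basis[, "helix"] + 0.4 * basis[, "coil"])
#' deconvolute_secondary_structure(spec, basis)$fractions
#' @export
deconvolute_secondary_structure <- function(spec, basis = cd_basis_spectra()) {
  stopifnot(inherits(spec, "cd_spectrum"))
  wl_basis <- attr(basis, "wavelength")
  if (is.null(wl_basis)) stop("'basis' lacks a wavelength attribute")
  idx <- match(round(spec$wavelength, 6), round(wl_basis, 6))
  if (any(is.na(idx)))
    stop("basis does not cover the spectrum's wavelength grid (",
         sum(is.na(idx)), " unmatched wavelengths)")
  A <- basis[idx, , drop = FALSE]
  fit <- nnls_small(A, spec$mre)
  coefs <- fit$coef
  names(coefs) <- colnames(basis)
  total <- sum(coefs)
  fractions <- if (total > 0) coefs / total else coefs
  structure(list(fractions = fractions, coef = coefs, rss = fit$rss,
                 residual_rms = sqrt(fit$rss / length(spec$mre))),
            class = "ss_fractions")
}

#' @export
print.ss_fractions <- function(x, ...) {
  cat("Secondary-structure fractions (semi-quantitative):\n")
  print(round(x$fractions, 3))
  cat("residual RMS:", format(signif(x$residual_rms, 3)), "\n")
  invisible(x)
}

#' Read / write CD spectra
#'
#' Delimited text with header `wavelength_nm, signal[, ht_volts]`; `signal`
#' is taken as mean-residue ellipticity unless `conc`, `path` and `n_res`
#' are given, in which case it is treated as raw millidegrees and converted.
#'
#' @param path file path.
#' @param conc,path_cm,n_res optional conversion metadata (uM, cm, count).
#' @param ht_max high-tension truncation voltage (default 800 V).
#' @return A [cd_spectrum].
#' @export
read_cd_spectrum <- function(path, conc = NULL, path_cm = NULL, n_res = NULL,
                             ht_max = 800) {
  df <- read_delimited(path, c("wavelength_nm", "signal"))
  sig <- df$signal
  if (!is.null(conc) && !is.null(path_cm) && !is.null(n_res))
    sig <- mean_residue_ellipticity(sig, conc, path_cm, n_res)
  cd_spectrum(df$wavelength_nm, sig, ht_voltage = df[["ht_volts"]],
              ht_max = ht_max)
}

#' @rdname read_cd_spectrum
#' @param spec a [cd_spectrum] to write (MRE written as `signal`).
#' @export
write_cd_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "cd_spectrum"))
  out <- data.frame(wavelength_nm = spec$wavelength, signal = spec$mre)
  if (!is.null(spec$ht_voltage)) out$ht_volts <- spec$ht_voltage
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
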