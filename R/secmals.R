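#' Construct a SEC-MALS chromatogram
#'
#' Holds the elution-volume-indexed detector traces of one injection:
#' light scattering (LS), differential refractive index (dRI, a dimensionless
#' refractive-index difference), and optionally UV absorbance, together with
#' the instrument constants needed to turn them into concentrations and
#' molecular weights.
#'
#' @param volume strictly increasing elution volumes (ml).
#' @param ls light-scattering trace (instrument units).
#' @param dri differential refractive index trace (dimensionless delta-n).
#' @param uv optional absorbance trace.
#' @param dn_dc refractive-index increment of the protein, ml/g (default
#'   0.1850, the standard value applied to all constructs).
#' @param ls_calib lumped light-scattering calibration constant k such that
#'   MW (kDa) = LS / (k x c) with c in mg/ml. A single constant replaces the
#'   full multi-angle Zimm formalism, valid for proteins far below the
#'   Rayleigh size limit.
#' @return An object of class `chromatogram`.
#' @export
chromatogram <- function(volume, ls, dri, uv = NULL,
                         dn_dc = 0.1850, ls_calib = 0.01) {
  volume <- as.numeric(volume); ls <- as.numeric(ls); dri <- as.numeric(dri)
  n <- length(volume)
  if (length(ls) != n || length(dri) != n)
    stop("'volume', 'ls' and 'dri' must have equal length")
  if (!is.null(uv) && length(uv) != n)
    stop("'uv' must match the trace length")
  if (n < 2L || any(diff(volume) <= 0))
    stop("'volume' must be strictly increasing with at least 2 slices")
  if (!is.numeric(dn_dc) || dn_dc <= 0) stop("'dn_dc' must be positive (ml/g)")
  if (!is.numeric(ls_calib) || ls_calib <= 0) stop("'ls_calib' must be positive")
  structure(list(volume = volume, ls = ls, dri = dri, uv = uv,
                 dn_dc = dn_dc, ls_calib = ls_calib),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat("SEC-MALS chromatogram: ", length(x$volume), " slices, ",
      format(min(x$volume)), "-", format(max(x$volume)), " ml, dn/dc = ",
      format(x$dn_dc), " ml/g\n", sep = "")
  invisible(x)
}

# robust baseline: median of the outer 5% of slices at each end
trace_baseline <- function(y) {
  n <- length(y)
  k <- max(1L, floor(0.05 * n))
  stats::median(c(y[seq_len(k)], y[seq.int(n - k + 1L, n)]))
}

#' Mass concentration per slice from the differential refractive index
#'
#' The on-column protein concentration is computed from the dRI trace as
#' c (g/ml) = delta-n / (dn/dc), reported in mg/ml. A robust baseline (median
#' of the outer 5% of slices) is subtracted first.
#'
#' @param chrom a [chromatogram].
#' @return Numeric vector of per-slice mass concentrations (mg/ml); negative
#'   baseline-noise values are left as-is (masking is applied downstream).
#' @examples
#' # delta-n of 1.85e-5 at dn/dc 0.1850 ml/g is 0.1 mg/ml
#' ch <- chromatogram(1:10, rep(0, 10), c(rep(0, 4), 1.85e-5, rep(0, 5)))
#' max(concentration_from_ri(ch))
#' @export
concentration_from_ri <- function(chrom) {
  stopifnot(inherits(chrom, "chromatogram"))
  dri <- chrom$dri - trace_baseline(chrom$dri)
  if (all(dri == 0)) warning("dRI trace is all zero; no valid slices")
  1000 * dri / chrom$dn_dc   # (g/ml) * 1000 = mg/ml
}

#' Convert mass concentration to protomer-equivalent molarity
#'
#' @param c_mass mass concentration(s), mg/ml.
#' @param mass_kda protomer (plus tag) mass in kDa.
#' @return Concentration(s) in uM: 1000 x (mg/ml) / kDa.
#' @examples
#' molar_from_mass(0.1, 12.5)  # 8 uM
#' @export
molar_from_mass <- function(c_mass, mass_kda) {
  if (!is.numeric(mass_kda) || length(mass_kda) != 1L || mass_kda <= 0)
    stop("'mass_kda' must be a single positive mass (kDa)")
  1000 * c_mass / mass_kda
}

#' Per-slice molecular weight from light scattering
#'
#' Under the single-constant Rayleigh approximation the weight-average MW of
#' each elution slice is MW = LS / (k x c) with c the slice mass
#' concentration. Slices below the concentration threshold are masked (NA)
#' rather than producing unstable ratios. The LS trace is baseline-subtracted
#' the same way as the dRI trace.
#'
#' @param chrom a [chromatogram].
#' @param c_mass per-slice mass concentration, mg/ml (from
#'   [concentration_from_ri()]).
#' @param threshold_frac slices with concentration below this fraction of the
#'   apex are masked (default 0.05).
#' @return Numeric vector of per-slice MW (kDa), NA on masked slices.
#' @export
mw_from_light_scattering <- function(chrom, c_mass, threshold_frac = 0.05) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (length(c_mass) != length(chrom$ls))
    stop("'c_mass' must match the trace length")
  ls <- chrom$ls - trace_baseline(chrom$ls)
  apex <- max(c_mass)
  valid <- c_mass > max(0, apex * threshold_frac)
  mw <- rep(NA_real_, length(c_mass))
  mw[valid] <- ls[valid] / (chrom$ls_calib * c_mass[valid])
  mw
}

#' Slice a chromatogram into concentration and molecular-weight profiles
#'
#' Runs the full per-slice conversion: dRI to mass concentration, mass to
#' protomer-equivalent molarity, LS to MW, with a shared validity mask.
#'
#' @param chrom a [chromatogram].
#' @param mass_kda protomer (plus tag) mass in kDa, for the molar conversion.
#' @param threshold_frac apex fraction below which slices are masked.
#' @return An object of class `sliced_profile`: list with `volume`, `c_mass`
#'   (mg/ml), `c_molar` (uM), `mw` (kDa), `valid` (logical mask).
#' @export
slice_profile <- function(chrom, mass_kda, threshold_frac = 0.05) {
  c_mass <- concentration_from_ri(chrom)
  mw <- mw_from_light_scattering(chrom, c_mass, threshold_frac)
  structure(list(volume = chrom$volume,
                 c_mass = c_mass,
                 c_molar = molar_from_mass(c_mass, mass_kda),
                 mw = mw,
                 valid = !is.na(mw)),
            class = "sliced_profile")
}

#' Reduce a sliced profile to one binding point
#'
#' The injection is summarized by the apex: the reported on-column
#' concentration is the protomer-equivalent molarity of the maximal slice,
#' and the reported MW is the concentration-weighted mean over the half-height
#' window around the apex. Peak overloading is flagged when the leading and
#' trailing half-height widths differ by more than `asymmetry_max`.
#'
#' @param profile a [sliced_profile][slice_profile].
#' @param asymmetry_max maximal tolerated ratio between the wider and
#'   narrower half-height flank (default 3).
#' @return An object of class `injection_point`: list with `c_peak` (uM),
#'   `mw_mean` (kDa), `overloaded` (logical), `apex_volume` (ml).
#' @export
extract_injection_point <- function(profile, asymmetry_max = 3) {
  stopifnot(inherits(profile, "sliced_profile"))
  if (!any(profile$valid))
    stop("profile has no valid slices; nothing to extract")
  apex <- which.max(ifelse(profile$valid, profile$c_molar, -Inf))
  c_apex <- profile$c_molar[apex]
  half <- c_apex / 2
  # contiguous half-height window around the apex
  left <- apex
  while (left > 1L && !is.na(profile$c_molar[left - 1L]) &&
         profile$c_molar[left - 1L] >= half && profile$valid[left - 1L])
    left <- left - 1L
  right <- apex
  n <- length(profile$c_molar)
  while (right < n && !is.na(profile$c_molar[right + 1L]) &&
         profile$c_molar[right + 1L] >= half && profile$valid[right + 1L])
    right <- right + 1L
  win <- left:right
  w <- profile$c_molar[win]
  mw_mean <- sum(w * profile$mw[win]) / sum(w)

  lead_width <- profile$volume[apex] - profile$volume[left]
  trail_width <- profile$volume[right] - profile$volume[apex]
  widths <- sort(c(lead_width, trail_width))
  overloaded <- widths[1] > 0 && widths[2] / widths[1] > asymmetry_max

  structure(list(c_peak = c_apex, mw_mean = mw_mean,
                 overloaded = overloaded,
                 apex_volume = profile$volume[apex]),
            class = "injection_point")
}

#' @export
print.injection_point <- function(x, ...) {
  cat("Injection point: c_peak = ", format(signif(x$c_peak, 4)),
      " uM, MW = ", format(signif(x$mw_mean, 4)), " kDa",
      if (x$overloaded) "  [overloaded]", "\n", sep = "")
  invisible(x)
}

#' Assemble injection points into a binding curve
#'
#' @param points list of [injection_point][extract_injection_point] objects.
#' @return A [binding_curve] sorted by concentration, with overloaded points
#'   retained but flagged (the association fit excludes them by default).
#' @export
assemble_binding_curve <- function(points) {
  if (length(points) < 1L) stop("no injection points supplied")
  ok <- vapply(points, inherits, logical(1), what = "injection_point")
  if (!all(ok)) stop("all elements must be injection_point objects")
  cc <- vapply(points, `[[`, numeric(1), "c_peak")
  mw <- vapply(points, `[[`, numeric(1), "mw_mean")
  ov <- vapply(points, `[[`, logical(1), "overloaded")
  if (all(ov))
    warning("all injections flagged as overloaded; ",
            "fitting will refuse this curve by default")
  binding_curve(cc, mw, overloaded = ov, provenance = "measured")
}

#' Read / write chromatogram trace files
#'
#' Delimited text with header `volume_ml, ls, dri[, uv]` (comma or tab).
#' Instrument constants (`dn_dc`, `ls_calib`) travel in an optional sidecar
#' key-value file `<path>.meta` with lines `key = value`, or can be given
#' directly.
#'
#' @param path trace file path.
#' @param dn_dc,ls_calib instrument constants; override any sidecar values.
#' @return `read_chromatogram` returns a [chromatogram];
#'   `write_chromatogram` returns `path` invisibly.
#' @export
read_chromatogram <- function(path, dn_dc = NULL, ls_calib = NULL) {
  df <- read_delimited(path, c("volume_ml", "ls", "dri"))
  meta_path <- paste0(path, ".meta")
  meta <- if (file.exists(meta_path)) read_keyvalue(meta_path) else list()
  chromatogram(df$volume_ml, df$ls, df$dri, uv = df[["uv"]],
               dn_dc = dn_dc %||% meta$dn_dc %||% 0.1850,
               ls_calib = ls_calib %||% meta$ls_calib %||% 0.01)
}

#' @rdname read_chromatogram
#' @param chrom a [chromatogram] to write.
#' @param write_meta also write the `<path>.meta` sidecar with the instrument
#'   constants (default TRUE).
#' @export
write_chromatogram <- function(chrom, path, write_meta = TRUE) {
  stopifnot(inherits(chrom, "chromatogram"))
  out <- data.frame(volume_ml = chrom$volume, ls = chrom$ls, dri = chrom$dri)
  if (!is.null(chrom$uv)) out$uv <- chrom$uv
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (write_meta)
    write_keyvalue(list(dn_dc = chrom$dn_dc, ls_calib = chrom$ls_calib),
                   paste0(path, ".meta"))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal key-value (ini-like) config: lines of "key = value", '#' comments
read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed key-value line in '", path, "': ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

write_keyvalue <- function(x, path) {
  lines <- vapply(names(x), function(k)
    paste(k, "=", format(x[[k]], digits = 15)), character(1))
  writeLines(lines, path)
  invisible(path)
}
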