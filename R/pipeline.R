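#' SEC-MALS analysis pipeline
#'
#' Runs the full chain chromatograms -> injection points -> binding curve ->
#' association fit, and writes a structured text report plus a
#' machine-readable binding-point table. All randomness (the bootstrap) flows
#' from the single `seed` entry of the configuration.
#'
#' @param config a named list, or path to a key-value config file
#'   (`key = value` lines), with entries:
#'   \describe{
#'     \item{inputs}{character vector of chromatogram trace files (for a
#'       file-based config, a comma-separated list).}
#'     \item{scheme}{preset name: `"monomer_trimer"`,
#'       `"monomer_dimer_trimer"` or `"dimer_tetramer_hexamer"`.}
#'     \item{protomer_mass, tag_mass}{masses in kDa (tag defaults to 0).}
#'     \item{kd_start}{starting stepwise Kd (recycled across steps;
#'       default 10).}
#'     \item{dn_dc, ls_calib}{instrument constants (defaults 0.1850, 0.01).}
#'     \item{overload_max}{peak asymmetry threshold (default 3).}
#'     \item{bootstrap}{bootstrap replicates for the apparent-Kd CI
#'       (default 0).}
#'     \item{seed}{RNG seed (default 1729).}
#'     \item{out_dir}{output directory (created if absent).}
#'   }
#' @return Invisibly, a list with the `fit` (an
#'   [association_fit][fit_association]), the assembled `curve`, and the
#'   paths written.
#' @export
run_secmals_pipeline <- function(config) {
  cfg <- load_config(config)
  inputs <- cfg$inputs
  if (is.character(inputs) && length(inputs) == 1L && grepl(",", inputs))
    inputs <- trimws(strsplit(inputs, ",")[[1]])
  if (is.null(inputs) || !length(inputs))
    stop("config entry 'inputs' must list at least one chromatogram file")
  missing_files <- inputs[!file.exists(inputs)]
  if (length(missing_files))
    stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  if (is.null(cfg$protomer_mass))
    stop("config entry 'protomer_mass' (kDa) is required")

  scheme <- make_preset_scheme(cfg$scheme %||% "monomer_trimer",
                               cfg$protomer_mass, cfg$tag_mass %||% 0,
                               cfg$kd_start %||% 10)
  mass <- unit_mass(scheme)

  points <- lapply(inputs, function(f) {
    ch <- read_chromatogram(f, dn_dc = cfg$dn_dc, ls_calib = cfg$ls_calib)
    extract_injection_point(slice_profile(ch, mass),
                            asymmetry_max = cfg$overload_max %||% 3)
  })
  curve <- assemble_binding_curve(points)
  fit <- fit_association(curve, scheme,
                         bootstrap = cfg$bootstrap %||% 0,
                         seed = cfg$seed %||% 1729)

  out_dir <- cfg$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  curve_path <- file.path(out_dir, "binding_points.csv")
  write_binding_curve(curve, curve_path)
  report_path <- file.path(out_dir, "secmals_report.txt")
  kds <- fit$scheme$steps$kd
  report <- c(
    list(package_version = as.character(utils::packageVersion("oligofit")),
         seed = cfg$seed %||% 1729,
         scheme = scheme$name,
         n_points = fit$n_points,
         converged = fit$converged,
         apparent_kd_uM = fit$apparent_kd,
         apparent_kd_ci_low = fit$apparent_kd_ci[1],
         apparent_kd_ci_high = fit$apparent_kd_ci[2],
         rss_kda2 = fit$rss),
    stats::setNames(as.list(kds),
                    paste0("kd_", fit$scheme$steps$order, "mer_uM"))
  )
  write_keyvalue(report, report_path)
  invisible(list(fit = fit, curve = curve,
                 paths = c(report = report_path, curve = curve_path)))
}

#' Thermal-melting analysis pipeline
#'
#' Fits one or two melting curves with the two-state van't Hoff model and
#' writes a per-transition report; when two inputs are given (e.g. wild type
#' and mutant) the report includes their per-transition Tm differences.
#'
#' @param config named list or key-value file path with entries `inputs`
#'   (one or two `temp_C, theta222` files), `n_transitions` (1 or 2,
#'   default 1), `out_dir`.
#' @return Invisibly, a list with `fits` (list of
#'   [melting_fit][fit_melting]) and the report path.
#' @export
run_melting_pipeline <- function(config) {
  cfg <- load_config(config)
  inputs <- cfg$inputs
  if (is.character(inputs) && length(inputs) == 1L && grepl(",", inputs))
    inputs <- trimws(strsplit(inputs, ",")[[1]])
  if (is.null(inputs) || !length(inputs))
    stop("config entry 'inputs' must list one or two melting-curve files")
  missing_files <- inputs[!file.exists(inputs)]
  if (length(missing_files))
    stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  n_tr <- cfg$n_transitions %||% 1

  fits <- lapply(inputs, function(f) fit_melting(read_melting_curve(f), n_tr))

  out_dir <- cfg$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  report_path <- file.path(out_dir, "melting_report.txt")
  report <- list(package_version =
                   as.character(utils::packageVersion("oligofit")),
                 n_transitions = n_tr,
                 n_inputs = length(inputs))
  for (i in seq_along(fits)) {
    tr <- fits[[i]]$transitions
    for (j in seq_len(nrow(tr))) {
      pre <- paste0("input", i, "_transition", j, "_")
      report[[paste0(pre, "tm_C")]] <- tr$tm[j]
      report[[paste0(pre, "dh_vh_kJmol")]] <- tr$dh_vh[j]
      report[[paste0(pre, "cooperative")]] <- tr$cooperative[j]
    }
    report[[paste0("input", i, "_converged")]] <- fits[[i]]$converged
  }
  if (length(fits) == 2L && fits[[1]]$converged && fits[[2]]$converged) {
    for (j in seq_len(n_tr))
      report[[paste0("delta_tm_transition", j, "_C")]] <-
        delta_tm(fits[[1]], fits[[2]], j)
  }
  write_keyvalue(report, report_path)
  invisible(list(fits = fits, paths = c(report = report_path)))
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    read_keyvalue(config)
  } else if (is.list(config)) {
    config
  } else stop("'config' must be a named list or a config file path")
}

make_preset_scheme <- function(name, protomer_mass, tag_mass, kd_start) {
  switch(name,
    monomer_trimer = scheme_monomer_trimer(protomer_mass, kd = kd_start,
                                           tag_mass = tag_mass),
    monomer_dimer_trimer = scheme_monomer_dimer_trimer(
      protomer_mass, kd1 = kd_start, kd2 = kd_start, tag_mass = tag_mass),
    dimer_tetramer_hexamer = scheme_dimer_tetramer_hexamer(
      protomer_mass, kd1 = kd_start, kd2 = kd_start, tag_mass = tag_mass),
    stop("unknown scheme preset '", name, "'; use monomer_trimer, ",
         "monomer_dimer_trimer or dimer_tetramer_hexamer")
  )
}
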