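#' Construct a SEC-MALS binding curve
#'
#' A binding curve pairs on-column protomer-equivalent concentrations with the
#' weight-average molecular weights observed (or predicted) at those
#' concentrations — the fit surface of a SEC-MALS dilution-series experiment.
#'
#' @param c_total positive concentrations in uM (protomer-equivalent).
#' @param mw positive weight-average molecular weights in kDa.
#' @param mw_sigma optional per-point MW uncertainties in kDa.
#' @param overloaded optional logical flags marking injections that overloaded
#'   the size-exclusion column (retained but excluded from fitting by
#'   default).
#' @param provenance one of `"measured"`, `"simulated"`, `"model"`.
#' @return A data frame of class `binding_curve` with columns `c_total`, `mw`,
#'   optionally `mw_sigma`, and `overloaded`; rows sorted by concentration.
#' @examples
#' binding_curve(c(1, 2, 4), c(15, 20, 28), provenance = "measured")
#' @export
binding_curve <- function(c_total, mw, mw_sigma = NULL, overloaded = NULL,
                          provenance = c("measured", "simulated", "model")) {
  provenance <- match.arg(provenance)
  c_total <- as.numeric(c_total); mw <- as.numeric(mw)
  if (length(c_total) != length(mw))
    stop("'c_total' and 'mw' must have equal length")
  if (any(!is.finite(c_total)) || any(c_total <= 0))
    stop("all 'c_total' must be positive and finite (uM)")
  if (any(!is.finite(mw)) || any(mw <= 0))
    stop("all 'mw' must be positive and finite (kDa)")
  if (!is.null(mw_sigma) && length(mw_sigma) != length(mw))
    stop("'mw_sigma' must match the length of 'mw'")
  if (is.null(overloaded)) overloaded <- rep(FALSE, length(mw))
  df <- data.frame(c_total = c_total, mw = mw)
  if (!is.null(mw_sigma)) df$mw_sigma <- as.numeric(mw_sigma)
  df$overloaded <- as.logical(overloaded)
  o <- order(df$c_total)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "provenance") <- provenance
  class(df) <- c("binding_curve", "data.frame")
  df
}

#' @export
print.binding_curve <- function(x, ...) {
  cat("SEC-MALS binding curve (", attr(x, "provenance"), "), ",
      nrow(x), " points, c = ", format(min(x$c_total)), "-",
      format(max(x$c_total)), " uM\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Read / write binding-curve tables
#'
#' Delimited text with header columns `conc_uM`, `mw_kDa`, optional
#' `mw_sigma_kDa` and `overloaded`; comma or tab separation is auto-detected
#' on reading.
#'
#' @param path file path.
#' @param provenance provenance label to attach on reading.
#' @return `read_binding_curve` returns a [binding_curve];
#'   `write_binding_curve` returns `path` invisibly.
#' @export
read_binding_curve <- function(path, provenance = "measured") {
  df <- read_delimited(path, c("conc_uM", "mw_kDa"))
  binding_curve(df$conc_uM, df$mw_kDa,
                mw_sigma = df[["mw_sigma_kDa"]],
                overloaded = df[["overloaded"]],
                provenance = provenance)
}

#' @rdname read_binding_curve
#' @param curve a [binding_curve] to write.
#' @export
write_binding_curve <- function(curve, path) {
  stopifnot(inherits(curve, "binding_curve"))
  out <- data.frame(conc_uM = curve$c_total, mw_kDa = curve$mw)
  if (!is.null(curve$mw_sigma)) out$mw_sigma_kDa <- curve$mw_sigma
  out$overloaded <- curve$overloaded
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# delimited reader with separator auto-detection (comma vs tab)
read_delimited <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          strip.white = TRUE, check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("file '", path, "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "),
         " (found: ", paste(names(df), collapse = ", "), ")")
  df
}
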