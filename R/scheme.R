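#' Define a homo-oligomer assembly scheme
#'
#' An assembly scheme describes how copies of a protomer (optionally carrying a
#' fusion tag) self-associate through an ordered ladder of mass-action steps.
#' The base unit of assembly is either the monomer or an obligate (infinitely
#' tight) dimer; each association step adds base units to the previous product
#' and is governed by a stepwise dissociation constant.
#'
#' The first step consumes as many base units as needed to reach its product
#' order, so its dissociation constant carries units of
#' \eqn{\mu M^{(n_1/b - 1)}} where \eqn{n_1} is the first product order and
#' \eqn{b} the base-unit order. Subsequent steps add base units one (or more)
#' at a time; for the common case of one base unit per step their constants are
#' plain micromolar.
#'
#' @param name character label for the scheme.
#' @param protomer_mass monomeric molecular weight in kDa (per protomer,
#'   excluding any tag).
#' @param tag_mass fusion-tag mass in kDa per protomer (0 for untagged
#'   constructs).
#' @param base_unit `"monomer"` or `"obligate_dimer"`. An obligate dimer is a
#'   dimer so tight that it is treated as the indivisible unit of higher
#'   assembly; its internal dissociation is not modelled.
#' @param steps list of association steps, each a numeric vector or list
#'   `c(order = <protomer count of product>, kd = <stepwise Kd in uM scale>)`.
#'   Orders must be strictly increasing multiples of the base-unit order.
#'
#' @return An object of class `assembly_scheme`: a list with elements `name`,
#'   `protomer_mass`, `tag_mass`, `base_unit`, `base_order` (1 or 2), `steps`
#'   (data frame of `order`, `kd`), and `species` (data frame of `order`,
#'   `mass` with mass = order x (protomer_mass + tag_mass) in kDa; the first
#'   row is the free base unit).
#'
#' @examples
#' # a 12.5 kDa coiled-coil protomer forming a trimer
#' cc <- build_scheme("cc", protomer_mass = 12.5, steps = list(c(3, 6.75)))
#' cc$species
#'
#' # obligate dimer assembling to tetramer then hexamer
#' hex <- build_scheme("flex", 46, tag_mass = 16, base_unit = "obligate_dimer",
#'                     steps = list(c(4, 3), c(6, 3)))
#' @seealso [solve_equilibrium()], [predict_binding_curve()],
#'   [scheme_monomer_trimer()] and the other presets.
#' @export
build_scheme <- function(name, protomer_mass, tag_mass = 0,
                         base_unit = c("monomer", "obligate_dimer"),
                         steps = list()) {
  base_unit <- match.arg(base_unit)
  if (!is.numeric(protomer_mass) || length(protomer_mass) != 1L ||
      !is.finite(protomer_mass) || protomer_mass <= 0)
    stop("'protomer_mass' must be a single positive number (kDa)")
  if (!is.numeric(tag_mass) || length(tag_mass) != 1L ||
      !is.finite(tag_mass) || tag_mass < 0)
    stop("'tag_mass' must be a single nonnegative number (kDa)")
  base_order <- if (base_unit == "monomer") 1L else 2L

  if (length(steps) < 1L)
    stop("scheme '", name, "' has fewer than two species: ",
         "at least one association step is required")
  step_mat <- t(vapply(steps, function(s) {
    s <- unlist(s)
    if (length(s) != 2L) stop("each step must be (order, kd)")
    as.numeric(s)
  }, numeric(2)))
  orders <- step_mat[, 1L]
  kds <- step_mat[, 2L]
  if (any(orders != round(orders)) || any(orders <= base_order))
    stop("step product 'order' values must be integers greater than the ",
         "base-unit order (", base_order, ")")
  if (any(diff(c(base_order, orders)) <= 0))
    stop("step product orders must be strictly increasing")
  if (any(orders %% base_order != 0))
    stop("step product orders must be multiples of the base-unit order for ",
         "base_unit = '", base_unit, "'")
  if (any(!is.finite(kds)) || any(kds <= 0))
    stop("every step 'kd' must be positive and finite")

  unit_mass <- protomer_mass + tag_mass
  species_orders <- c(base_order, as.integer(orders))
  scheme <- structure(list(
    name = as.character(name),
    protomer_mass = protomer_mass,
    tag_mass = tag_mass,
    base_unit = base_unit,
    base_order = base_order,
    steps = data.frame(order = as.integer(orders), kd = kds),
    species = data.frame(order = species_orders,
                         mass = species_orders * unit_mass)
  ), class = "assembly_scheme")
  scheme
}

#' @export
print.assembly_scheme <- function(x, ...) {
  cat("Assembly scheme '", x$name, "'\n", sep = "")
  cat("  protomer ", format(x$protomer_mass), " kDa",
      if (x$tag_mass > 0) paste0(" + tag ", format(x$tag_mass), " kDa"),
      ", base unit: ", x$base_unit, "\n", sep = "")
  lab <- function(o) paste0(o, "-mer")
  prev <- x$base_order
  for (i in seq_len(nrow(x$steps))) {
    cat("  ", lab(prev), " -> ", lab(x$steps$order[i]),
        "  Kd = ", format(x$steps$kd[i]), "\n", sep = "")
    prev <- x$steps$order[i]
  }
  cat("  species masses (kDa): ",
      paste(format(x$species$mass), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Preset assembly schemes
#'
#' Convenience constructors for the schemes used throughout the package:
#' direct monomer-trimer association (the coiled-coil default), monomer
#' through dimer to trimer, and an obligate dimer assembling to tetramer and
#' hexamer (the two-domain full-length architecture).
#'
#' @param protomer_mass protomer mass in kDa; defaults are the coiled-coil
#'   construct mass (12.5 kDa) for the trimer schemes and 46 kDa for the
#'   hexamer scheme.
#' @param tag_mass fusion-tag mass in kDa per protomer.
#' @param kd,kd1,kd2 stepwise dissociation constants. For
#'   `scheme_monomer_trimer`, `kd` is the overall trimerization constant
#'   \eqn{K = [M]^3/[T]} in \eqn{\mu M^2}. For the two-step schemes the
#'   constants are per-step in uM.
#' @return An `assembly_scheme`.
#' @examples
#' scheme_monomer_trimer(12.5, kd = 6.75)
#' scheme_dimer_tetramer_hexamer(46, tag_mass = 16, kd1 = 3, kd2 = 3)
#' @export
scheme_monomer_trimer <- function(protomer_mass = 12.5, kd = 6.75,
                                  tag_mass = 0) {
  build_scheme("monomer-trimer", protomer_mass, tag_mass, "monomer",
               steps = list(c(3, kd)))
}

#' @rdname scheme_monomer_trimer
#' @export
scheme_monomer_dimer_trimer <- function(protomer_mass = 12.5, kd1 = 10,
                                        kd2 = 10, tag_mass = 0) {
  build_scheme("monomer-dimer-trimer", protomer_mass, tag_mass, "monomer",
               steps = list(c(2, kd1), c(3, kd2)))
}

#' @rdname scheme_monomer_trimer
#' @export
scheme_dimer_tetramer_hexamer <- function(protomer_mass = 46, kd1 = 3,
                                          kd2 = 3, tag_mass = 0) {
  build_scheme("dimer-tetramer-hexamer", protomer_mass, tag_mass,
               "obligate_dimer", steps = list(c(4, kd1), c(6, kd2)))
}

# mass of one protomer-equivalent including tag, kDa
unit_mass <- function(scheme) scheme$protomer_mass + scheme$tag_mass

# base units consumed by each step: the first step assembles its product from
# free base units directly (n1/b of them); later steps add to the previous
# product ((n_j - n_{j-1})/b each)
step_increments <- function(scheme) {
  orders <- scheme$steps$order
  b <- scheme$base_order
  c(orders[1L] / b, diff(orders) / b)
}
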