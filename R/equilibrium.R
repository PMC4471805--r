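#' Solve the mass-action equilibrium of an assembly scheme
#'
#' Computes the molar concentration of every oligomeric species at a given
#' total protomer-equivalent concentration. Writing \eqn{x} for the free
#' base-unit concentration, each step product obeys
#' \deqn{[P_j] = [P_{j-1}] \, x^{m_j} / K_j}
#' where \eqn{m_j} is the number of base units the step consumes (the first
#' step starts from \eqn{[P_0] = 1}, i.e. consumes all \eqn{n_1/b} base units
#' at once). Protomer conservation
#' \eqn{\sum_i order_i [S_i] = c_{total}} is a strictly increasing function of
#' \eqn{x}, so the solution is unique and is found by bracketed bisection on
#' \eqn{[0, c_{total}/b]} followed by Newton polishing to relative tolerance
#' 1e-12.
#'
#' @param scheme an [assembly_scheme][build_scheme].
#' @param c_total total protomer-equivalent concentration in uM (>= 0).
#' @return An object of class `species_distribution`: list with `scheme`,
#'   `c_total`, and `concentrations` (named numeric vector of molar species
#'   concentrations in uM, ordered as `scheme$species`).
#' @examples
#' sc <- scheme_monomer_trimer(12.5, kd = 1)
#' d <- solve_equilibrium(sc, 4)   # [M] = 1 uM, [T] = 1 uM
#' d$concentrations
#' @export
solve_equilibrium <- function(scheme, c_total) {
  stopifnot(inherits(scheme, "assembly_scheme"))
  if (!is.numeric(c_total) || length(c_total) != 1L || !is.finite(c_total) ||
      c_total < 0)
    stop("'c_total' must be a single nonnegative concentration (uM)")

  orders <- scheme$species$order
  if (c_total == 0) {
    conc <- numeric(length(orders))
    names(conc) <- species_names(scheme)
    return(structure(list(scheme = scheme, c_total = 0,
                          concentrations = conc),
                     class = "species_distribution"))
  }

  b <- scheme$base_order
  incr <- step_increments(scheme)
  kds <- scheme$steps$kd

  # species concentrations for free base-unit concentration x
  species_conc <- function(x) {
    conc <- numeric(length(orders))
    conc[1L] <- x
    prev <- 1
    for (j in seq_along(kds)) {
      prev <- prev * x^incr[j] / kds[j]
      conc[j + 1L] <- prev
    }
    conc
  }
  protomer_total <- function(x) sum(orders * species_conc(x))

  # bisection on [0, c_total/b]: f is strictly increasing
  lo <- 0
  hi <- c_total / b
  f_hi <- protomer_total(hi) - c_total
  if (f_hi < 0) hi <- hi * (1 + 1e-12)  # guard against rounding
  for (it in 1:200) {
    mid <- 0.5 * (lo + hi)
    if (protomer_total(mid) - c_total > 0) hi <- mid else lo <- mid
    if ((hi - lo) < 1e-14 * c_total) break
  }
  x <- 0.5 * (lo + hi)

  # Newton polish; [P_j] is proportional to x^expo_j so the derivative of the
  # protomer total wrt x is analytic
  expo <- cumsum(incr)  # cumulative base units consumed up to product j
  for (it in 1:50) {
    conc <- species_conc(x)
    f <- sum(orders * conc) - c_total
    dconc <- c(1, expo * conc[-1L] / x)
    df <- sum(orders * dconc)
    step <- f / df
    x_new <- x - step
    if (x_new <= 0) x_new <- x / 2
    x <- x_new
    if (abs(step) < 1e-15 * x) break
  }

  conc <- species_conc(x)
  names(conc) <- species_names(scheme)
  resid <- abs(sum(orders * conc) - c_total) / c_total
  if (resid > 1e-9)
    stop("equilibrium solver failed to conserve mass (relative residual ",
         format(resid), ") for scheme '", scheme$name, "' at c_total = ",
         format(c_total), " uM")
  structure(list(scheme = scheme, c_total = c_total, concentrations = conc),
            class = "species_distribution")
}

species_names <- function(scheme) {
  paste0("n", scheme$species$order)
}

#' @export
print.species_distribution <- function(x, ...) {
  cat("Species distribution at c_total =", format(x$c_total),
      "uM (protomer-equivalent)\n")
  df <- data.frame(order = x$scheme$species$order,
                   mass_kDa = x$scheme$species$mass,
                   conc_uM = unname(x$concentrations))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Weight-average molecular weight of a species distribution
#'
#' The observable reported by multi-angle light scattering:
#' \deqn{M_w = \sum_i c_i M_i^2 / \sum_i c_i M_i}
#' with molar species concentrations \eqn{c_i} and species masses \eqn{M_i}.
#' Equivalently, the mass-concentration-weighted mean of species masses.
#'
#' @param dist a [species_distribution][solve_equilibrium] with positive total
#'   concentration.
#' @return Weight-average MW in kDa.
#' @examples
#' sc <- scheme_monomer_trimer(12.5, kd = 1)
#' weight_average_mw(solve_equilibrium(sc, 4))  # 31.25 kDa
#' @export
weight_average_mw <- function(dist) {
  stopifnot(inherits(dist, "species_distribution"))
  if (dist$c_total <= 0)
    stop("weight-average MW is undefined at zero total concentration")
  m <- dist$scheme$species$mass
  c <- dist$concentrations
  sum(c * m^2) / sum(c * m)
}

#' Predict the SEC-MALS binding curve of a scheme
#'
#' Evaluates the model weight-average MW on a grid of total
#' protomer-equivalent concentrations. The curve is strictly increasing in
#' concentration and bounded by the smallest and largest species masses.
#'
#' @param scheme an [assembly_scheme][build_scheme].
#' @param c_grid numeric vector of positive total concentrations (uM).
#' @return A [binding_curve] with `provenance = "model"`.
#' @examples
#' sc <- scheme_monomer_trimer(12.5, kd = 6.75)
#' predict_binding_curve(sc, c(0.1, 1, 10, 100))
#' @export
predict_binding_curve <- function(scheme, c_grid) {
  stopifnot(inherits(scheme, "assembly_scheme"))
  if (length(c_grid) == 0L) stop("'c_grid' is empty")
  if (any(!is.finite(c_grid)) || any(c_grid <= 0))
    stop("'c_grid' must contain positive finite concentrations (uM)")
  mw <- vapply(c_grid, function(ct)
    weight_average_mw(solve_equilibrium(scheme, ct)), numeric(1))
  binding_curve(c_total = c_grid, mw = mw, provenance = "model")
}

#' Molar ratio between two oligomeric species
#'
#' @param dist a [species_distribution][solve_equilibrium].
#' @param order_a,order_b protomer counts of the numerator and denominator
#'   species (e.g. 6 and 4 for the hexamer:tetramer ratio).
#' @return Dimensionless molar ratio `[order_a]/[order_b]`.
#' @examples
#' sc <- scheme_dimer_tetramer_hexamer(46, kd1 = 3, kd2 = 3)
#' species_molar_ratio(solve_equilibrium(sc, 36), 6, 4)  # 1
#' @export
species_molar_ratio <- function(dist, order_a, order_b) {
  stopifnot(inherits(dist, "species_distribution"))
  orders <- dist$scheme$species$order
  ia <- match(order_a, orders)
  ib <- match(order_b, orders)
  if (is.na(ia)) stop("species of order ", order_a, " not in scheme")
  if (is.na(ib)) stop("species of order ", order_b, " not in scheme")
  denom <- dist$concentrations[ib]
  if (denom <= 0)
    stop("denominator species (order ", order_b, ") has zero concentration ",
         "at c_total = ", format(dist$c_total), " uM")
  unname(dist$concentrations[ia] / denom)
}

#' Apparent dissociation constant from the binding-curve inflection
#'
#' The apparent Kd is the model-free summary practitioners read off a
#' MW-vs-concentration plot: the total concentration at which the curve is
#' halfway between its monomer (or obligate-dimer) limit and its saturated
#' largest-oligomer limit. An alternative estimator locates the inflection of
#' MW against log10 concentration (zero of the second derivative).
#'
#' For direct monomer-trimer association with overall constant
#' \eqn{K = [M]^3/[T]}, the midpoint condition is \eqn{[M]^2 = K/3}, giving a
#' closed-form apparent Kd of \eqn{2\sqrt{K/3}}.
#'
#' @param x an [assembly_scheme][build_scheme] (the model curve is used), or a
#'   [binding_curve] of model predictions (log-linear interpolation is used).
#' @param method `"midpoint"` (default) or `"inflection"` (second derivative
#'   of MW vs log10 c).
#' @param c_range search range in uM when `x` is a scheme.
#' @return Apparent Kd in protomer-equivalent uM.
#' @examples
#' sc <- scheme_monomer_trimer(12.5, kd = 1)
#' apparent_kd(sc)            # 2/sqrt(3) = 1.1547 uM
#' @export
apparent_kd <- function(x, method = c("midpoint", "inflection"),
                        c_range = c(1e-6, 1e6)) {
  method <- match.arg(method)
  if (inherits(x, "assembly_scheme")) {
    masses <- x$species$mass
    m_min <- min(masses); m_max <- max(masses)
    mw_at <- function(lc) vapply(lc, function(l)
      weight_average_mw(solve_equilibrium(x, 10^l)), numeric(1))
    if (method == "midpoint") {
      target <- (m_min + m_max) / 2
      f <- function(l) mw_at(l) - target
      lo <- log10(c_range[1]); hi <- log10(c_range[2])
      if (f(lo) > 0 || f(hi) < 0)
        stop("binding curve does not cross the midpoint within c_range; ",
             "widen the concentration range")
      r <- stats::uniroot(f, c(lo, hi), tol = 1e-12)
      return(10^r$root)
    }
    # inflection: maximize d MW / d log10 c (zero of second derivative)
    h <- 1e-4
    d1 <- function(l) (mw_at(l + h) - mw_at(l - h)) / (2 * h)
    opt <- stats::optimize(d1, c(log10(c_range[1]), log10(c_range[2])),
                           maximum = TRUE, tol = 1e-10)
    return(10^opt$maximum)
  }
  if (inherits(x, "binding_curve")) {
    o <- order(x$c_total)
    lc <- log10(x$c_total[o]); mw <- x$mw[o]
    m_min <- min(mw); m_max <- max(mw)
    if (method == "midpoint") {
      target <- (m_min + m_max) / 2
      above <- mw >= target
      if (!any(above) || all(above))
        stop("binding curve does not cross its own midpoint; provide a curve ",
             "spanning the transition")
      i <- which(above)[1L]
      l <- lc[i - 1L] + (target - mw[i - 1L]) * (lc[i] - lc[i - 1L]) /
        (mw[i] - mw[i - 1L])
      return(10^l)
    }
    d1 <- diff(mw) / diff(lc)
    lm_ <- (lc[-1] + lc[-length(lc)]) / 2
    return(10^lm_[which.max(d1)])
  }
  stop("'x' must be an assembly_scheme or a binding_curve")
}
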