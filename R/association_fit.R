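#' Fit an assembly scheme to SEC-MALS binding data
#'
#' Least-squares fit of the mass-action model to observed (concentration,
#' weight-average MW) points. Dissociation constants are optimized on a
#' log10 scale within bounds [1e-4, 1e4] uM to preserve positivity; the fit
#' minimizes \eqn{\sum (M_{w,obs} - M_{w,model})^2}. For multi-step schemes
#' all free constants start equal (at their template values), reflecting the
#' observation that stepwise constants of the assembly ladder are typically
#' comparable.
#'
#' The model-free apparent Kd (midpoint of the fitted curve, see
#' [apparent_kd()]) is reported alongside the stepwise constants; an optional
#' nonparametric bootstrap (resampling points with replacement) yields a
#' percentile confidence interval for it.
#'
#' Points flagged `overloaded` in the data are excluded from the fit.
#'
#' @param data a [binding_curve] with at least 3 usable points.
#' @param scheme_template an [assembly_scheme][build_scheme] supplying masses,
#'   base unit, step structure, and starting kd values.
#' @param free integer indices of the steps whose kds are optimized (default
#'   all).
#' @param bootstrap number of bootstrap replicates for the apparent-Kd
#'   confidence interval; 0 (default) skips the bootstrap. The documented
#'   default when requested is 200.
#' @param seed RNG seed for the bootstrap (default 1729).
#' @param kd_bounds lower/upper bounds for each kd, uM.
#' @return An object of class `association_fit`; see Details. Elements
#'   include `scheme` (with fitted kds), `apparent_kd` (uM),
#'   `apparent_kd_ci`, `rss` (kDa^2), `converged`, `at_boundary`,
#'   `n_points`, `data`, `fitted`.
#' @details Convergence is reported `FALSE` when the optimizer fails or any
#'   fitted constant sits at a bound (e.g. data with no association drive the
#'   kd to the upper bound).
#' @examples
#' sc <- scheme_monomer_trimer(12.5, kd = 6.75)
#' curve <- predict_binding_curve(sc, 152 / 2^(0:10))
#' fit <- fit_association(curve, scheme_monomer_trimer(12.5, kd = 50))
#' coef(fit)
#' @export
fit_association <- function(data, scheme_template, free = NULL,
                            bootstrap = 0, seed = 1729,
                            kd_bounds = c(1e-4, 1e4)) {
  stopifnot(inherits(data, "binding_curve"),
            inherits(scheme_template, "assembly_scheme"))
  usable <- !data$overloaded
  if (sum(usable) < 3L)
    stop("need at least 3 non-overloaded binding points to fit (have ",
         sum(usable), ")")
  if (is.null(free)) free <- seq_len(nrow(scheme_template$steps))
  free <- as.integer(free)
  if (length(free) < 1L || any(free < 1L) ||
      any(free > nrow(scheme_template$steps)))
    stop("'free' must index steps of the scheme template")
  if (sum(usable) < length(free))
    stop("fewer usable points (", sum(usable), ") than free parameters (",
         length(free), ")")

  cc <- data$c_total[usable]
  mw <- data$mw[usable]

  set_kds <- function(scheme, log_kd) {
    scheme$steps$kd[free] <- 10^log_kd
    scheme
  }
  objective <- function(log_kd, c_obs, mw_obs) {
    sch <- set_kds(scheme_template, log_kd)
    pred <- vapply(c_obs, function(ct)
      weight_average_mw(solve_equilibrium(sch, ct)), numeric(1))
    sum((mw_obs - pred)^2)
  }

  lb <- rep(log10(kd_bounds[1]), length(free))
  ub <- rep(log10(kd_bounds[2]), length(free))
  start <- pmin(pmax(log10(scheme_template$steps$kd[free]), lb), ub)

  run_fit <- function(c_obs, mw_obs) {
    res <- try(stats::optim(start, objective, c_obs = c_obs, mw_obs = mw_obs,
                            method = "L-BFGS-B", lower = lb, upper = ub,
                            control = list(factr = 1e4, maxit = 500)),
               silent = TRUE)
    if (inherits(res, "try-error"))
      return(list(par = start, value = objective(start, c_obs, mw_obs),
                  ok = FALSE, boundary = FALSE))
    eps <- 1e-6
    boundary <- any(res$par <= lb + eps) || any(res$par >= ub - eps)
    list(par = res$par, value = res$value,
         ok = res$convergence == 0, boundary = boundary)
  }

  main <- run_fit(cc, mw)
  fitted_scheme <- set_kds(scheme_template, main$par)
  app_kd <- tryCatch(apparent_kd(fitted_scheme), error = function(e) NA_real_)

  ci <- c(NA_real_, NA_real_)
  if (bootstrap > 0) {
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed), add = TRUE)
    set.seed(seed)
    boot_kd <- vapply(seq_len(bootstrap), function(b) {
      idx <- sample.int(length(cc), replace = TRUE)
      r <- run_fit(cc[idx], mw[idx])
      sch <- set_kds(scheme_template, r$par)
      tryCatch(apparent_kd(sch), error = function(e) NA_real_)
    }, numeric(1))
    ci <- unname(stats::quantile(boot_kd, c(0.025, 0.975), na.rm = TRUE))
  }

  pred <- vapply(data$c_total, function(ct)
    weight_average_mw(solve_equilibrium(fitted_scheme, ct)), numeric(1))

  structure(list(
    scheme = fitted_scheme,
    apparent_kd = app_kd,
    apparent_kd_ci = ci,
    rss = main$value,
    converged = main$ok && !main$boundary,
    at_boundary = main$boundary,
    n_points = sum(usable),
    free = free,
    data = data,
    fitted = pred,
    bootstrap = bootstrap,
    seed = seed
  ), class = "association_fit")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' @export
print.association_fit <- function(x, ...) {
  cat("Mass-action association fit: scheme '", x$scheme$name, "'\n", sep = "")
  cat("  fitted stepwise Kd (uM scale): ",
      paste(format(signif(x$scheme$steps$kd, 4)), collapse = ", "), "\n",
      sep = "")
  cat("  apparent Kd (midpoint): ", format(signif(x$apparent_kd, 4)), " uM",
      if (!any(is.na(x$apparent_kd_ci)))
        paste0("  [95% CI ", format(signif(x$apparent_kd_ci[1], 4)), ", ",
               format(signif(x$apparent_kd_ci[2], 4)), "]"),
      "\n", sep = "")
  cat("  RSS = ", format(signif(x$rss, 4)), " kDa^2 over ", x$n_points,
      " points; converged: ", x$converged,
      if (x$at_boundary) " (parameter at bound)", "\n", sep = "")
  invisible(x)
}

#' @export
summary.association_fit <- function(object, ...) {
  print(object)
  resid <- residuals(object)
  cat("  residual SD = ", format(signif(stats::sd(resid), 4)), " kDa\n",
      sep = "")
  invisible(object)
}

#' @export
coef.association_fit <- function(object, ...) {
  kds <- object$scheme$steps$kd
  names(kds) <- paste0("kd_", object$scheme$steps$order, "mer")
  c(kds, apparent_kd = object$apparent_kd)
}

#' Predicted weight-average MW from a fitted association model
#'
#' @param object an `association_fit`.
#' @param newdata optional numeric vector of concentrations (uM); defaults to
#'   the fitted data's concentrations.
#' @param ... unused.
#' @return Numeric vector of predicted MW (kDa).
#' @export
predict.association_fit <- function(object, newdata = NULL, ...) {
  cc <- if (is.null(newdata)) object$data$c_total else as.numeric(newdata)
  vapply(cc, function(ct)
    weight_average_mw(solve_equilibrium(object$scheme, ct)), numeric(1))
}

#' @export
residuals.association_fit <- function(object, ...) {
  keep <- !object$data$overloaded
  (object$data$mw - object$fitted)[keep]
}

#' Simulate binding curves from a fitted association model
#'
#' Draws `nsim` noisy replicates of the fitted model curve at the data's
#' concentrations, using the multiplicative lognormal MW noise model of
#' [simulate_binding_series()].
#'
#' @param object an `association_fit`.
#' @param nsim number of replicate curves.
#' @param seed RNG seed.
#' @param noise_mw relative MW noise (default 0.03).
#' @param ... unused.
#' @return A list of [binding_curve] objects.
#' @export
simulate.association_fit <- function(object, nsim = 1, seed = NULL,
                                     noise_mw = 0.03, ...) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  mu <- predict(object)
  lapply(seq_len(nsim), function(i)
    binding_curve(object$data$c_total,
                  mu * exp(stats::rnorm(length(mu), 0, noise_mw)),
                  provenance = "simulated"))
}

#' Plot a fitted SEC-MALS binding curve
#'
#' Observed points (overloaded injections open) and the fitted model curve on
#' a log concentration axis, with species masses as horizontal guides.
#'
#' @param x an `association_fit`.
#' @param n_grid number of grid points for the model curve.
#' @param ... passed to [graphics::plot()].
#' @export
plot.association_fit <- function(x, n_grid = 100, ...) {
  d <- x$data
  grid <- 10^seq(log10(min(d$c_total)), log10(max(d$c_total)),
                 length.out = n_grid)
  curve_mw <- predict(x, grid)
  graphics::plot(d$c_total, d$mw, log = "x",
                 pch = ifelse(d$overloaded, 1, 16),
                 xlab = "on-column concentration (uM)",
                 ylab = "weight-average MW (kDa)", ...)
  graphics::lines(grid, curve_mw, col = "firebrick", lwd = 2)
  graphics::abline(h = x$scheme$species$mass, lty = 3, col = "grey60")
  if (is.finite(x$apparent_kd))
    graphics::abline(v = x$apparent_kd, lty = 2, col = "steelblue")
  invisible(x)
}
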