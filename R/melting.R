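GAS_CONSTANT_KJ <- 8.31446e-3  # kJ mol^-1 K^-1

#' Construct a thermal melting curve
#'
#' The CD signal at 222 nm recorded while ramping temperature, the standard
#' probe of alpha-helix unfolding.
#'
#' @param temperature strictly increasing temperatures, degrees C.
#' @param theta222 ellipticity at 222 nm (any consistent units; mean-residue
#'   ellipticity recommended).
#' @param ramp_rate heating rate metadata, degrees C per minute (default 1).
#' @return An object of class `melting_curve`.
#' @export
melting_curve <- function(temperature, theta222, ramp_rate = 1) {
  temperature <- as.numeric(temperature); theta222 <- as.numeric(theta222)
  if (length(temperature) != length(theta222))
    stop("'temperature' and 'theta222' must have equal length")
  if (any(diff(temperature) <= 0))
    stop("'temperature' must be strictly increasing")
  structure(list(temperature = temperature, theta222 = theta222,
                 ramp_rate = ramp_rate),
            class = "melting_curve")
}

#' @export
print.melting_curve <- function(x, ...) {
  cat("Melting curve: ", length(x$temperature), " points, ",
      format(min(x$temperature)), "-", format(max(x$temperature)),
      " C at ", format(x$ramp_rate), " C/min\n", sep = "")
  invisible(x)
}

#' Read / write melting curves
#'
#' Delimited text with header `temp_C, theta222` (comma or tab).
#' @param path file path.
#' @return `read_melting_curve` returns a [melting_curve].
#' @export
read_melting_curve <- function(path) {
  df <- read_delimited(path, c("temp_C", "theta222"))
  melting_curve(df$temp_C, df$theta222)
}

#' @rdname read_melting_curve
#' @param curve a [melting_curve] to write.
#' @export
write_melting_curve <- function(curve, path) {
  stopifnot(inherits(curve, "melting_curve"))
  utils::write.csv(data.frame(temp_C = curve$temperature,
                              theta222 = curve$theta222),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Two-state van't Hoff melting model
#'
#' Signal model for one or two independent two-state unfolding transitions
#' with linear folded and unfolded baselines:
#' \deqn{\theta(T) = y_F(T) + [y_U(T) - y_F(T)] \sum_j \phi_j f_j(T)}
#' where \eqn{f_j = K_j/(1+K_j)},
#' \eqn{K_j = \exp[-(\Delta H_j/R)(1/T - 1/T_{m,j})]} (temperatures in
#' Kelvin), and the fractional amplitudes \eqn{\phi_j > 0} partition the
#' total folded-to-unfolded signal change (\eqn{\sum_j \phi_j = 1}).
#' \eqn{\Delta C_p} is taken as zero. At \eqn{T = T_m} each \eqn{f_j} is 1/2;
#' \eqn{\Delta H \to \infty} gives a step, \eqn{\Delta H \to 0} a constant
#' baseline blend.
#'
#' @param pars list with `bf = c(intercept, slope)` (folded baseline),
#'   `bu = c(intercept, slope)` (unfolded baseline), `tm` (degrees C, one per
#'   transition), `dh` (van't Hoff enthalpy, kJ/mol, one per transition),
#'   `phi` (fractional amplitudes, summing to 1; defaults to equal).
#' @param temperature temperatures at which to evaluate, degrees C.
#' @return Numeric vector of model ellipticities.
#' @examples
#' pars <- list(bf = c(-30000, 30), bu = c(-5000, -10), tm = 37, dh = 200)
#' theta <- melting_model(pars, 4:90)
#' @export
melting_model <- function(pars, temperature) {
  tm <- pars$tm; dh <- pars$dh
  stopifnot(length(tm) == length(dh), length(tm) >= 1)
  phi <- pars$phi %||% rep(1 / length(tm), length(tm))
  if (length(phi) != length(tm)) stop("'phi' must match the number of transitions")
  tK <- temperature + 273.15
  f_total <- 0
  for (j in seq_along(tm)) {
    K <- exp(-(dh[j] / GAS_CONSTANT_KJ) * (1 / tK - 1 / (tm[j] + 273.15)))
    f_total <- f_total + phi[j] * K / (1 + K)
  }
  yF <- pars$bf[1] + pars$bf[2] * temperature
  yU <- pars$bu[1] + pars$bu[2] * temperature
  yF + (yU - yF) * f_total
}

# pack/unpack the optimizer parameter vector
melt_pack <- function(pars, n_tr) {
  v <- c(pars$bf, pars$bu, pars$tm, log(pars$dh))
  if (n_tr == 2) v <- c(v, stats::qlogis(pars$phi[1]))
  v
}
melt_unpack <- function(v, n_tr) {
  pars <- list(bf = v[1:2], bu = v[3:4],
               tm = v[5:(4 + n_tr)],
               dh = exp(v[(5 + n_tr):(4 + 2 * n_tr)]))
  pars$phi <- if (n_tr == 2) {
    p <- stats::plogis(v[5 + 2 * n_tr]); c(p, 1 - p)
  } else 1
  pars
}

#' Fit a one- or two-transition two-state model to a melting curve
#'
#' Nonlinear least squares of [melting_model()] against the observed
#' theta-222 trace. To avoid local minima, optimization is multi-started
#' from a grid of candidate melting temperatures every 10 degrees C across
#' the data range (all ordered pairs for two transitions); the best
#' residual-sum-of-squares solution is kept and transitions are reported
#' with tm1 < tm2. A transition whose fitted signal amplitude is smaller
#' than 3x the residual noise is flagged non-cooperative, capturing melts
#' that degenerate to a near-linear trace.
#'
#' @param curve a [melting_curve] with at least 20 points spanning both
#'   baselines.
#' @param n_transitions 1 or 2.
#' @return An object of class `melting_fit`: list with `transitions` (data
#'   frame of `tm` degrees C, `dh_vh` kJ/mol, `amplitude` in signal units,
#'   `cooperative` flag), `baselines` (folded/unfolded intercept and slope),
#'   `pars` (the model parameter list), `rss`, `sigma`, `converged`,
#'   `n_points`, `curve`.
#' @examples
#' pars <- list(bf = c(-30000, 30), bu = c(-5000, -10), tm = 37, dh = 200)
#' mc <- melting_curve(4:90, melting_model(pars, 4:90))
#' fit <- fit_melting(mc, 1)
#' coef(fit)
#' @export
fit_melting <- function(curve, n_transitions = 1) {
  stopifnot(inherits(curve, "melting_curve"))
  n_tr <- as.integer(n_transitions)
  if (!n_tr %in% 1:2) stop("'n_transitions' must be 1 or 2")
  tt <- curve$temperature
  yy <- curve$theta222
  n <- length(tt)
  if (n < 20L) stop("need at least 20 points spanning both baselines")

  # standardize the signal so baseline parameters are O(1); ellipticities are
  # O(1e4) and would otherwise swamp the finite-difference gradients in Tm
  y_center <- mean(yy)
  y_scale <- stats::sd(yy)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  ys <- (yy - y_center) / y_scale

  # baseline guesses from the outer 15% of the trace
  k <- max(2L, floor(0.15 * n))
  lo_fit <- stats::lm.fit(cbind(1, tt[1:k]), ys[1:k])$coefficients
  hi_idx <- (n - k + 1L):n
  hi_fit <- stats::lm.fit(cbind(1, tt[hi_idx]), ys[hi_idx])$coefficients

  t_range <- range(tt)
  tm_grid <- seq(t_range[1] + 5, t_range[2] - 5, by = 10)
  if (!length(tm_grid)) tm_grid <- mean(t_range)
  starts <- if (n_tr == 1) {
    lapply(tm_grid, function(tm) list(tm = tm, dh = 200, phi = 1))
  } else {
    pairs <- expand.grid(tm1 = tm_grid, tm2 = tm_grid)
    pairs <- pairs[pairs$tm1 < pairs$tm2, , drop = FALSE]
    lapply(seq_len(nrow(pairs)), function(i)
      list(tm = c(pairs$tm1[i], pairs$tm2[i]), dh = c(200, 200),
           phi = c(0.5, 0.5)))
  }

  obj <- function(v) {
    pars <- melt_unpack(v, n_tr)
    r <- ys - melting_model(pars, tt)
    sum(r^2)
  }
  npar <- 4 + 2 * n_tr + (n_tr == 2)
  lb <- rep(-Inf, npar); ub <- rep(Inf, npar)
  lb[5:(4 + n_tr)] <- t_range[1]; ub[5:(4 + n_tr)] <- t_range[2]
  lb[(5 + n_tr):(4 + 2 * n_tr)] <- log(5)
  ub[(5 + n_tr):(4 + 2 * n_tr)] <- log(5000)
  if (n_tr == 2) { lb[npar] <- stats::qlogis(0.02); ub[npar] <- stats::qlogis(0.98) }

  # --- stage 1: variable projection over the nonlinear (Tm, log dH) only.
  # Conditional on the transition shapes f_j(T), the signal is linear in
  # {1, T, f_j, T f_j}; solving that least-squares problem exactly at every
  # step reduces the search to 2 (or 4) well-scaled nonlinear parameters.
  frac_unf <- function(tm, dh) {
    tK <- tt + 273.15
    K <- exp(-(dh / GAS_CONSTANT_KJ) * (1 / tK - 1 / (tm + 273.15)))
    K / (1 + K)
  }
  vp_solve <- function(w, slopes) {  # w = c(tm_j..., log dh_j...)
    tms <- w[seq_len(n_tr)]; dhs <- exp(w[n_tr + seq_len(n_tr)])
    X <- cbind(1, tt)
    for (j in seq_len(n_tr)) {
      f <- frac_unf(tms[j], dhs[j])
      X <- if (slopes) cbind(X, f, tt * f) else cbind(X, f)
    }
    fit <- stats::lm.fit(X, ys)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    list(rss = sum(fit$residuals^2), beta = beta, tm = tms, dh = dhs,
         slopes = slopes)
  }
  w_lb <- c(rep(t_range[1], n_tr), rep(log(5), n_tr))
  w_ub <- c(rep(t_range[2], n_tr), rep(log(5000), n_tr))
  w0s <- lapply(starts, function(s)
    pmin(pmax(c(s$tm, log(s$dh)), w_lb + 1e-8), w_ub - 1e-8))
  # each projected optimization is cheap (2 or 4 nonlinear parameters), so
  # refine from every grid start and keep the distinct local solutions. The
  # multistart sweep runs on the reduced family (constant step amplitudes):
  # adding T*f columns makes the family flexible enough that noise can
  # displace its global optimum away from the true Tm. The full family is
  # evaluated once from each survivor as an extra candidate.
  vp_sweep <- function(slopes) {
    vp_obj <- function(w) vp_solve(w, slopes)$rss
    sols <- list()
    for (w0 in w0s[order(vapply(w0s, vp_obj, numeric(1)))]) {
      res <- try(stats::optim(w0, vp_obj, method = "L-BFGS-B", lower = w_lb,
                              upper = w_ub,
                              control = list(factr = 1e2, maxit = 1000,
                                             ndeps = rep(1e-7, 2 * n_tr))),
                 silent = TRUE)
      if (inherits(res, "try-error")) next
      res$slopes <- slopes
      dup <- any(vapply(sols, function(s)
        max(abs(s$par - res$par)) < 0.5, logical(1)))
      if (!dup) sols[[length(sols) + 1L]] <- res
    }
    sols
  }
  vp_sols <- vp_sweep(FALSE)
  fit_failed <- length(vp_sols) == 0L
  if (fit_failed)
    vp_sols <- list(list(par = w0s[[1]],
                         value = vp_solve(w0s[[1]], FALSE)$rss,
                         convergence = 99, slopes = FALSE))
  vp_sols <- vp_sols[order(vapply(vp_sols, `[[`, numeric(1), "value"))]
  vp_sols <- utils::head(vp_sols, 3L)
  # refine the best reduced-family solutions under the full family too
  vp_full <- lapply(vp_sols, function(s) {
    res <- try(stats::optim(s$par, function(w) vp_solve(w, TRUE)$rss,
                            method = "L-BFGS-B", lower = w_lb, upper = w_ub,
                            control = list(factr = 1e2, maxit = 1000,
                                           ndeps = rep(1e-7, 2 * n_tr))),
               silent = TRUE)
    if (inherits(res, "try-error")) return(NULL)
    res$slopes <- TRUE
    res
  })
  vp_sols <- c(vp_sols, Filter(Negate(is.null), vp_full))

  # --- stage 2: map each projected solution onto the constrained
  # parameterization (shared baselines, fractional amplitudes phi)
  constrained_start <- function(w, slopes) {
    sol <- vp_solve(w, slopes)
    beta <- sol$beta
    bf_hat <- beta[1:2]
    if (slopes) {
      step0 <- beta[seq(3, length(beta), by = 2)] # per-transition intercepts
      step1 <- beta[seq(4, length(beta), by = 2)] # per-transition slopes
    } else {
      step0 <- beta[-(1:2)]
      step1 <- rep(0, n_tr)
    }
    d0 <- sum(step0); d1 <- sum(step1)           # total unfolded - folded
    bu_hat <- bf_hat + c(d0, d1)
    t_mid <- mean(tt)
    denom <- d0 + d1 * t_mid
    phi_hat <- if (n_tr == 2) {
      p <- if (abs(denom) > 0) (step0[1] + step1[1] * t_mid) / denom else 0.5
      p <- min(max(p, 0.02), 0.98)
      c(p, 1 - p)
    } else 1
    v0 <- melt_pack(list(bf = bf_hat, bu = bu_hat, tm = sol$tm, dh = sol$dh,
                         phi = phi_hat), n_tr)
    pmin(pmax(v0, lb + 1e-8), ub - 1e-8)
  }

  # --- stage 3: polish each candidate under the constrained model, keep the
  # lowest constrained RSS
  obj_box <- function(v) if (any(v < lb) || any(v > ub)) Inf else obj(v)
  best <- NULL
  for (s in vp_sols) {
    v0 <- constrained_start(s$par, s$slopes)
    cand <- list(par = v0, value = obj(v0), convergence = s$convergence)
    res <- try(stats::optim(v0, obj, method = "L-BFGS-B", lower = lb,
                            upper = ub,
                            control = list(factr = 1e2, maxit = 2000,
                                           ndeps = rep(1e-7, npar))),
               silent = TRUE)
    if (!inherits(res, "try-error") && res$value <= cand$value) cand <- res
    pol <- try(stats::optim(cand$par, obj_box, method = "Nelder-Mead",
                            control = list(maxit = 5000, reltol = 1e-15)),
               silent = TRUE)
    if (!inherits(pol, "try-error") && pol$value < cand$value)
      cand <- list(par = pol$par, value = pol$value,
                   convergence = cand$convergence)
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  converged <- !fit_failed && best$convergence %in% c(0, 1)

  pars <- melt_unpack(best$par, n_tr)
  # back-transform baselines to the original signal units
  pars$bf <- c(pars$bf[1] * y_scale + y_center, pars$bf[2] * y_scale)
  pars$bu <- c(pars$bu[1] * y_scale + y_center, pars$bu[2] * y_scale)
  # order transitions by tm
  o <- order(pars$tm)
  pars$tm <- pars$tm[o]; pars$dh <- pars$dh[o]
  if (n_tr == 2) pars$phi <- pars$phi[o]

  fitted <- melting_model(pars, tt)
  resid <- yy - fitted
  dof <- max(1, n - npar)
  sigma <- sqrt(sum(resid^2) / dof)

  delta_at <- function(tm)
    (pars$bu[1] + pars$bu[2] * tm) - (pars$bf[1] + pars$bf[2] * tm)
  phi <- if (n_tr == 2) pars$phi else 1
  amplitude <- phi * vapply(pars$tm, delta_at, numeric(1))
  # a transition must rise above the noise AND carry a non-trivial share of
  # the signal range; a near-linear trace fits with amplitude ~ 0 and
  # sigma ~ 0, which must not count as cooperative
  signal_span <- diff(range(yy))
  cooperative <- abs(amplitude) >= pmax(3 * sigma, 0.01 * signal_span)

  structure(list(
    transitions = data.frame(tm = pars$tm, dh_vh = pars$dh,
                             amplitude = amplitude,
                             cooperative = cooperative),
    baselines = data.frame(state = c("folded", "unfolded"),
                           intercept = c(pars$bf[1], pars$bu[1]),
                           slope = c(pars$bf[2], pars$bu[2])),
    pars = pars,
    rss = sum(resid^2),
    sigma = sigma,
    converged = converged,
    n_points = n,
    curve = curve
  ), class = "melting_fit")
}

#' @export
print.melting_fit <- function(x, ...) {
  cat("Two-state thermal unfolding fit (", nrow(x$transitions),
      " transition", if (nrow(x$transitions) > 1) "s", ")\n", sep = "")
  tr <- x$transitions
  for (j in seq_len(nrow(tr))) {
    cat(sprintf("  Tm%d = %.2f C, dH_vH = %.0f kJ/mol, amplitude = %.3g%s\n",
                j, tr$tm[j], tr$dh_vh[j], tr$amplitude[j],
                if (!tr$cooperative[j]) "  [non-cooperative]" else ""))
  }
  cat("  residual SD = ", format(signif(x$sigma, 3)),
      "; converged: ", x$converged, "\n", sep = "")
  invisible(x)
}

#' @export
summary.melting_fit <- function(object, ...) {
  print(object)
  cat("  baselines:\n")
  print(object$baselines, row.names = FALSE)
  invisible(object)
}

#' @export
coef.melting_fit <- function(object, ...) {
  tr <- object$transitions
  out <- c(rbind(tr$tm, tr$dh_vh))
  names(out) <- as.vector(rbind(paste0("tm", seq_len(nrow(tr))),
                                paste0("dh_vh", seq_len(nrow(tr)))))
  out
}

#' @export
predict.melting_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$curve$temperature else as.numeric(newdata)
  melting_model(object$pars, tt)
}

#' @export
residuals.melting_fit <- function(object, ...) {
  object$curve$theta222 - predict(object)
}

#' Simulate noisy melting curves from a fitted model
#'
#' @param object a `melting_fit`.
#' @param nsim number of replicates.
#' @param seed RNG seed.
#' @param noise relative multiplicative noise (default 0.02).
#' @param ... unused.
#' @return A list of [melting_curve] objects.
#' @export
simulate.melting_fit <- function(object, nsim = 1, seed = NULL,
                                 noise = 0.02, ...) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  lapply(seq_len(nsim), function(i)
    simulate_melting(object$pars, object$curve$temperature, noise = noise))
}

#' @export
plot.melting_fit <- function(x, ...) {
  graphics::plot(x$curve$temperature, x$curve$theta222, pch = 16,
                 cex = 0.6, col = "grey40",
                 xlab = "temperature (C)",
                 ylab = expression(theta[222]), ...)
  tt <- seq(min(x$curve$temperature), max(x$curve$temperature),
            length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
  graphics::abline(v = x$transitions$tm, lty = 2, col = "steelblue")
  invisible(x)
}

#' Melting-temperature difference between two fits
#'
#' Computes `tm_a - tm_b` for a matched transition — the standard way to
#' express mutational (de)stabilization of one domain while the other is
#' unchanged.
#'
#' @param fit_a,fit_b converged [melting_fit][fit_melting] objects with the
#'   same number of transitions.
#' @param transition transition index to compare (default 1, the lower-Tm
#'   transition).
#' @return Temperature difference in degrees C.
#' @export
delta_tm <- function(fit_a, fit_b, transition = 1) {
  stopifnot(inherits(fit_a, "melting_fit"), inherits(fit_b, "melting_fit"))
  if (nrow(fit_a$transitions) != nrow(fit_b$transitions))
    stop("fits have different numbers of transitions (",
         nrow(fit_a$transitions), " vs ", nrow(fit_b$transitions), ")")
  if (transition < 1 || transition > nrow(fit_a$transitions))
    stop("transition index ", transition, " not present in both fits")
  if (!fit_a$converged || !fit_b$converged)
    stop("both fits must have converged")
  fit_a$transitions$tm[transition] - fit_b$transitions$tm[transition]
}

#' Apparent Tm from the derivative of the raw trace
#'
#' Model-free alternative estimator: the temperature of the extremum of the
#' first derivative of the (Savitzky-Golay smoothed) signal.
#'
#' @param curve a [melting_curve].
#' @param window,order smoothing window and polynomial order passed to
#'   [smooth_signal()].
#' @return Temperature (degrees C) of maximal signal change.
#' @export
tm_from_derivative <- function(curve, window = 11, order = 3) {
  stopifnot(inherits(curve, "melting_curve"))
  y <- smooth_signal(curve$theta222, window, order)
  tt <- curve$temperature
  d1 <- diff(y) / diff(tt)
  tm_mid <- (tt[-1] + tt[-length(tt)]) / 2
  tm_mid[which.max(abs(d1))]
}
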