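#' Default box bounds for parameter identification
#'
#' Spans the physically sensible range for alginate/polyacrylamide gels
#' while keeping the model valid: segment caps, contour lengths and
#' cross-link densities of order 1-100, chain densities and moduli from
#' fractions of a kPa to MPa scale, sliding ratio close to (but above) 1.
#'
#' @return list with numeric vectors `lower` and `upper` named by the eight
#'   parameters.
#' @export
dnh_default_bounds <- function() {
  lower <- c(n_max = 5, r_bar = 0.5, kappa = 1e-3, N_P = 1e-3,
             nu = 1.0, E = 1e-3, mu = 1e-3, alpha = 1e-3)
  upper <- c(n_max = 500, r_bar = 20, kappa = 100, N_P = 1e3,
             nu = 1.5, E = 1e4, mu = 1e3, alpha = 10)
  list(lower = lower, upper = upper)
}

# geometric-midpoint initial guess inside the default bounds
.default_init <- function(bounds = dnh_default_bounds()) {
  sqrt(bounds$lower * bounds$upper)
}

.stack_residuals <- function(theta, free, fixed, curves, control,
                             fail_value = 1e6) {
  p <- fixed
  p[names(theta)] <- theta
  res <- tryCatch({
    params <- dnh_params(p[["n_max"]], p[["r_bar"]], p[["kappa"]], p[["N_P"]],
                         p[["nu"]], p[["E"]], p[["mu"]], p[["alpha"]])
    unlist(lapply(curves, function(cv) {
      prog <- attr(cv, "program")
      sim <- dnh_simulate(params, prog, control)
      sim$stress - cv$stress
    }))
  }, error = function(e) NULL)
  if (is.null(res) || any(!is.finite(res))) {
    n <- sum(vapply(curves, nrow, integer(1L)))
    return(rep(fail_value, n))
  }
  res
}

#' Fit the double-network hydrogel model to tensile data
#'
#' Identifies the material parameters by damped (Levenberg-Marquardt) least
#' squares on the stacked stress residuals of one or more stress-stretch
#' curves, with box bounds. By convention the enthalpic modulus `E` is
#' frozen (taken from experiment, see [estimate_modulus()]); any other
#' subset may be frozen too. The optimization is deterministic: identical
#' data, initial values and bounds give identical results.
#'
#' @param curves a `"stress_stretch_curve"` or list of them; each must carry
#'   its generating `"loading_program"` (as curves from [dnh_simulate()],
#'   [dnh_synthesize()] and [read_curve()] do).
#' @param init named numeric vector or `"dnh_params"` with starting values;
#'   missing entries default to geometric midpoints of the bounds. `E`
#'   defaults to [estimate_modulus()] of the first curve when frozen and not
#'   supplied.
#' @param bounds list with named `lower`/`upper` vectors; defaults from
#'   [dnh_default_bounds()].
#' @param frozen character vector of parameter names held fixed (default
#'   `"E"`).
#' @param control a `"dnh_control"` object (model options).
#' @param lm_control passed to [minpack.lm::nls.lm.control()].
#' @return an object of class `"dnh_fit"` with methods `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `plot` and `simulate`.
#' @examples
#' \donttest{
#' truth <- dnh_default_params()
#' data <- dnh_synthesize(truth, loading_program(c(4, 1, 8)), noise_sd = 1,
#'                        seed = 1)
#' fit <- dnh_fit(data, init = coef_perturb(truth, 0.1, seed = 2))
#' summary(fit)
#' }
#' @export
dnh_fit <- function(curves, init = NULL, bounds = dnh_default_bounds(),
                    frozen = "E", control = dnh_control(),
                    lm_control = minpack.lm::nls.lm.control(maxiter = 200)) {
  if (inherits(curves, "stress_stretch_curve")) curves <- list(curves)
  if (length(curves) < 1L) stop("at least one curve is required")
  for (cv in curves) {
    if (!inherits(cv, "stress_stretch_curve") || is.null(attr(cv, "program"))) {
      stop("each curve must be a `stress_stretch_curve` carrying its loading program")
    }
  }
  pn <- dnh_param_names()
  if (!all(frozen %in% pn)) {
    stop("`frozen` must be a subset of: ", paste(pn, collapse = ", "))
  }
  lower <- dnh_default_bounds()$lower
  upper <- dnh_default_bounds()$upper
  lower[names(bounds$lower)] <- bounds$lower
  upper[names(bounds$upper)] <- bounds$upper

  start <- .default_init(list(lower = lower, upper = upper))
  if (inherits(init, "dnh_params")) init <- as.numeric(init)
  if (!is.null(init)) {
    if (is.null(names(init)) || !all(names(init) %in% pn)) {
      stop("`init` must be named by parameter")
    }
    start[names(init)] <- init
  }
  if ("E" %in% frozen && (is.null(init) || !("E" %in% names(init)))) {
    start[["E"]] <- estimate_modulus(curves[[1L]])
  }
  if (any(start < lower - 1e-12) || any(start > upper + 1e-12)) {
    bad <- pn[start < lower - 1e-12 | start > upper + 1e-12]
    stop("initial values outside bounds for: ", paste(bad, collapse = ", "))
  }

  free <- setdiff(pn, frozen)
  theta0 <- start[free]
  fixed <- start

  n_eval <- 0L
  fn <- function(theta) {
    n_eval <<- n_eval + 1L
    names(theta) <- free
    .stack_residuals(theta, free, fixed, curves, control)
  }

  if (length(free) == 0L) {
    r <- fn(numeric(0))
    est <- start
    result <- list(converged = TRUE, message = "all parameters frozen",
                   niter = 0L, deviance = sum(r^2), info = 0L)
  } else {
    lm <- minpack.lm::nls.lm(par = theta0, fn = fn,
                             lower = lower[free], upper = upper[free],
                             control = lm_control)
    est <- start
    est[free] <- lm$par
    if (lm$info == 0L || !all(is.finite(unlist(lm$par)))) {
      stop("singular Jacobian or invalid inputs in Levenberg-Marquardt: ",
           lm$message)
    }
    result <- list(converged = lm$info %in% c(1L, 2L, 3L, 4L),
                   message = lm$message, niter = lm$niter,
                   deviance = lm$deviance, info = lm$info)
  }

  params <- dnh_params(est[["n_max"]], est[["r_bar"]], est[["kappa"]],
                       est[["N_P"]], est[["nu"]], est[["E"]], est[["mu"]],
                       est[["alpha"]],
                       stress_unit = attr(curves[[1L]], "stress_unit") %||% "kPa")
  fitted_curves <- lapply(curves, function(cv) {
    dnh_simulate(params, attr(cv, "program"), control)
  })
  resid <- unlist(lapply(seq_along(curves), function(i) {
    fitted_curves[[i]]$stress - curves[[i]]$stress
  }))
  tol <- 1e-8 * max(1, abs(c(lower, upper)))
  on_bound <- free[abs(est[free] - lower[free]) < tol |
                     abs(est[free] - upper[free]) < tol]

  structure(
    list(params = params, frozen = frozen, free = free,
         init = start, lower = lower, upper = upper,
         residual_norm = sum(resid^2), residuals = resid,
         n_evaluations = n_eval, n_iterations = result$niter,
         converged = result$converged, message = result$message,
         info = result$info, bounds_active = on_bound,
         curves = curves, fitted_curves = fitted_curves,
         control = control),
    class = "dnh_fit"
  )
}

#' Perturb a parameter set multiplicatively
#'
#' Convenience for recovery experiments: each parameter is multiplied by
#' `1 + u`, `u ~ Uniform(-rel, rel)` (with `nu` kept >= 1), reproducibly
#' under the seed.
#'
#' @param params a `"dnh_params"` or named numeric vector.
#' @param rel relative perturbation half-width (e.g. 0.2 for +/-20\%).
#' @param seed integer seed.
#' @return named numeric vector.
#' @export
coef_perturb <- function(params, rel = 0.2, seed = 1) {
  v <- if (inherits(params, "dnh_params")) as.numeric(params) else params
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  out <- v * (1 + stats::runif(length(v), -rel, rel))
  names(out) <- names(v)
  if ("nu" %in% names(out)) out[["nu"]] <- max(out[["nu"]], 1 + 0.25 * (v[["nu"]] - 1))
  out
}

#' @export
coef.dnh_fit <- function(object, ...) {
  as.numeric(object$params)
}

#' @export
print.dnh_fit <- function(x, ...) {
  cat("Double-network hydrogel constitutive fit\n")
  cat(sprintf("  %d curve(s), %d samples; frozen: %s\n",
              length(x$curves), length(x$residuals),
              if (length(x$frozen)) paste(x$frozen, collapse = ", ") else "none"))
  cat(sprintf("  converged: %s (%d iterations, %d evaluations)\n",
              x$converged, x$n_iterations, x$n_evaluations))
  cat(sprintf("  residual sum of squares: %.6g\n", x$residual_norm))
  print(x$params)
  invisible(x)
}

#' @export
summary.dnh_fit <- function(object, ...) {
  est <- coef(object)
  out <- list(
    coefficients = data.frame(
      estimate = est,
      frozen = names(est) %in% object$frozen,
      lower = object$lower[names(est)],
      upper = object$upper[names(est)],
      on_bound = names(est) %in% object$bounds_active,
      row.names = names(est)
    ),
    residual_norm = object$residual_norm,
    sigma = sqrt(object$residual_norm / max(1, length(object$residuals) -
                                              length(object$free))),
    n_samples = length(object$residuals),
    converged = object$converged,
    message = object$message,
    stress_unit = object$params$stress_unit
  )
  class(out) <- "summary.dnh_fit"
  out
}

#' @export
print.summary.dnh_fit <- function(x, ...) {
  cat("Double-network hydrogel constitutive fit\n\nParameters:\n")
  print(format(x$coefficients, digits = 5))
  cat(sprintf("\nResidual sum of squares: %.6g (%s^2), sigma = %.4g %s on %d samples\n",
              x$residual_norm, x$stress_unit, x$sigma, x$stress_unit,
              x$n_samples))
  cat(sprintf("Convergence: %s (%s)\n", x$converged, x$message))
  invisible(x)
}

#' Predict stress for a new loading program
#'
#' @param object a `"dnh_fit"`.
#' @param newdata a `"loading_program"`, a numeric vector of virgin-path
#'   stretches, or `NULL` (the programs of the fitted curves).
#' @param ... unused.
#' @return a `"stress_stretch_curve"` (or list of them for `NULL`
#'   `newdata`).
#' @export
predict.dnh_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    out <- object$fitted_curves
    if (length(out) == 1L) out[[1L]] else out
  } else if (inherits(newdata, "loading_program")) {
    dnh_simulate(object$params, newdata, object$control)
  } else if (is.numeric(newdata)) {
    Lam <- sort(newdata)
    dmg <- damage_state(1)
    stress <- numeric(length(Lam))
    for (i in seq_along(Lam)) {
      st <- uniaxial_kinematics(Lam[i], object$control$chain_stretch)
      dmg <- update_damage(dmg, st)
      stress[i] <- nominal_stress(Lam[i], dmg, object$params, object$control)
    }
    stress_stretch_curve(Lam, stress,
                         stress_unit = object$params$stress_unit)
  } else {
    stop("`newdata` must be a loading_program, numeric stretches, or NULL")
  }
}

#' @export
fitted.dnh_fit <- function(object, ...) {
  unlist(lapply(object$fitted_curves, function(cv) cv$stress))
}

#' @export
residuals.dnh_fit <- function(object, ...) {
  object$residuals
}

#' Plot a fitted model against its data
#'
#' Base-graphics stress-stretch plot: data as points, fitted model as
#' lines, one panel per curve.
#'
#' @param x a `"dnh_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dnh_fit <- function(x, ...) {
  k <- length(x$curves)
  if (k > 1L) {
    old <- graphics::par(mfrow = grDevices::n2mfrow(k))
    on.exit(graphics::par(old), add = TRUE)
  }
  for (i in seq_len(k)) {
    cv <- x$curves[[i]]
    ft <- x$fitted_curves[[i]]
    graphics::plot(cv$stretch, cv$stress, pch = 1, cex = 0.6,
                   xlab = expression(Lambda),
                   ylab = sprintf("nominal stress [%s]", x$params$stress_unit),
                   main = attr(cv, "label") %||% "", ...)
    graphics::lines(ft$stretch, ft$stress, col = 2, lwd = 1.5)
  }
  invisible(x)
}

#' Simulate replicate noisy curves from a fitted model
#'
#' @param object a `"dnh_fit"`.
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param noise_sd noise level; defaults to the fit's residual sigma.
#' @param program program to simulate; defaults to the first fitted curve's.
#' @param ... unused.
#' @return list of `"stress_stretch_curve"` objects (length `nsim`).
#' @export
simulate.dnh_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = NULL, program = NULL, ...) {
  if (is.null(noise_sd)) noise_sd <- summary(object)$sigma
  if (is.null(program)) program <- attr(object$curves[[1L]], "program")
  if (is.null(seed)) seed <- 1L
  lapply(seq_len(nsim), function(i) {
    dnh_synthesize(object$params, program, noise_sd = noise_sd,
                   seed = as.integer(seed) + i - 1L, control = object$control)
  })
}
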