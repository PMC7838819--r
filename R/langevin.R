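#' Inverse Langevin function
#'
#' The Langevin function \eqn{L(\beta) = \coth\beta - 1/\beta} maps the
#' dimensionless chain force \eqn{\beta} to the relative end-to-end extension
#' \eqn{x = r/(n l)} of a freely jointed chain. Its inverse has no closed
#' form; the default is the Puso approximant
#' \deqn{\beta(x) = \frac{3x}{1 - x^3},}
#' which is exact to first order at small \eqn{x} and diverges correctly as
#' \eqn{x \to 1^-}. `method = "exact"` solves \eqn{L(\beta) = x} by
#' safeguarded Newton iteration to near machine precision and is intended as
#' a high-precision reference.
#'
#' @param x numeric vector of relative extensions, `0 <= x < 1`.
#' @param method `"puso"` (default) or `"exact"`.
#' @param tol convergence tolerance for the Newton solver (exact method).
#' @return numeric vector \eqn{\beta \ge 0}, same length as `x`.
#' @examples
#' inverse_langevin(c(0, 0.5, 0.9))
#' langevin(inverse_langevin(0.5, method = "exact"))  # 0.5
#' @seealso [langevin()], [entropic_chain_energy()]
#' @export
inverse_langevin <- function(x, method = c("puso", "exact"), tol = 1e-14) {
  method <- match.arg(method)
  if (!is.numeric(x)) stop("`x` must be numeric")
  bad <- !is.finite(x) | x < 0 | x >= 1
  if (any(bad)) {
    stop(sprintf(
      "inverse Langevin is defined on [0, 1); got x = %s",
      paste(format(x[bad][seq_len(min(3L, sum(bad)))]), collapse = ", ")
    ))
  }
  if (method == "puso") {
    return(3 * x / (1 - x^3))
  }
  vapply(x, .inv_langevin_newton, numeric(1L), tol = tol)
}

#' Langevin function
#'
#' \eqn{L(\beta) = \coth\beta - 1/\beta}, evaluated with a series expansion
#' near zero to avoid cancellation.
#'
#' @param beta numeric vector, `beta >= 0`.
#' @return numeric vector in `[0, 1)`.
#' @export
langevin <- function(beta) {
  out <- numeric(length(beta))
  small <- abs(beta) < 1e-4
  # L(b) = b/3 - b^3/45 + 2 b^5/945 - ...
  b <- beta[small]
  out[small] <- b / 3 - b^3 / 45 + 2 * b^5 / 945
  b <- beta[!small]
  out[!small] <- 1 / tanh(b) - 1 / b
  out
}

.inv_langevin_newton <- function(x, tol = 1e-14) {
  if (x == 0) return(0)
  beta <- 3 * x / (1 - x^3)          # Puso start: already within a few percent
  for (i in 1:100) {
    fx <- langevin(beta) - x
    # L'(b) = 1/b^2 - 1/sinh(b)^2, positive and decreasing
    dfx <- if (beta < 1e-4) 1 / 3 - beta^2 / 15 else 1 / beta^2 - 1 / sinh(beta)^2
    step <- fx / dfx
    beta_new <- beta - step
    if (beta_new <= 0) beta_new <- beta / 2
    if (abs(beta_new - beta) <= tol * max(1, beta)) return(beta_new)
    beta <- beta_new
  }
  beta
}

# d beta_puso / dx
.inv_langevin_puso_deriv <- function(x) {
  (3 + 6 * x^3) / (1 - x^3)^2
}

#' Entropic free energy of a Langevin chain
#'
#' Free energy (in units of kT) of a freely jointed chain of `n` segments at
#' chain stretch `lambda`, with normalized average contour length `r_bar`:
#' \deqn{\psi^S = kT\, n \left[ x\,\beta(x) + \ln\frac{\beta(x)}{\sinh\beta(x)} \right],
#'   \qquad x = \bar r \lambda / n,}
#' the Arruda-Boyce/Langevin-statistics form, measured from the ideal-coil
#' state so that \eqn{\psi^S(x = 0) = 0}. For \eqn{x \le 0.05} the Gaussian
#' limit \eqn{\psi^S \approx kT\,n\,(3/2)x^2} holds to within 2\%.
#'
#' @param n segment number (continuous, > 0); vectorized.
#' @param lambda chain stretch (>= 0).
#' @param r_bar normalized average contour length (> 0).
#' @param kT thermal energy unit; the package convention is `kT = 1` with all
#'   stress scale carried by the chain density and moduli.
#' @param method inverse-Langevin method, see [inverse_langevin()].
#' @return energy in kT units, non-negative.
#' @export
entropic_chain_energy <- function(n, lambda, r_bar, kT = 1, method = "puso") {
  stopifnot(is.numeric(n), is.numeric(lambda), is.numeric(r_bar))
  if (any(n <= 0)) stop("segment number `n` must be positive")
  if (r_bar <= 0) stop("`r_bar` must be positive")
  x <- r_bar * lambda / n
  if (any(x >= 1)) {
    stop(sprintf(
      "chain at or beyond full stretch (x = %s >= 1): entropic energy undefined, enthalpic regime applies",
      format(max(x))
    ))
  }
  beta <- inverse_langevin(x, method = method)
  kT * n * .langevin_energy_kernel(x, beta)
}

# x*beta + log(beta/sinh(beta)), stable near beta = 0
.langevin_energy_kernel <- function(x, beta) {
  out <- numeric(length(beta))
  small <- beta < 1e-4
  b <- beta[small]
  # log(b/sinh b) = -b^2/6 + b^4/180 - ...
  out[small] <- x[small] * b - b^2 / 6 + b^4 / 180
  b <- beta[!small]
  out[!small] <- x[!small] * b + log(b) - log(sinh(b))
  # sinh overflows for b > ~710; log(sinh b) ~ b - log 2
  big <- !small & beta > 700
  if (any(big)) {
    b <- beta[big]
    out[big] <- x[big] * b + log(b) - (b - log(2))
  }
  out
}

# d psi^S / d lambda for the implemented (Puso) energy:
#   psi = n g(x), g'(x) = beta + beta'(x) (x - L(beta)),  x = r_bar lambda / n
# so d psi/d lambda = r_bar g'(x). The (x - L(beta)) correction is the
# Puso-approximation residual; it vanishes for the exact inverse.
.dpsiS_dlambda <- function(n, lambda, r_bar) {
  x <- r_bar * lambda / n
  beta <- 3 * x / (1 - x^3)
  r_bar * (beta + .inv_langevin_puso_deriv(x) * (x - langevin(beta)))
}

#' Full-stretch segment-number bound
#'
#' A chain of `n` segments reaches full stretch when its relative extension
#' \eqn{x = \bar r \lambda / n} reaches 1. Chains remain entropic only for
#' \eqn{n \ge n_{min}^S = \nu \bar r \lambda}, where the sliding ratio
#' \eqn{\nu \ge 1} keeps the evaluated states strictly below the Langevin
#' singularity.
#'
#' @param nu sliding-ratio parameter, `nu >= 1`.
#' @param r_bar normalized average contour length (> 0).
#' @param lambda chain stretch (>= 0); vectorized.
#' @return `n_min_S = nu * r_bar * lambda`.
#' @export
full_stretch_bound <- function(nu, r_bar, lambda) {
  if (!is.numeric(nu) || nu <= 0) stop("`nu` must be positive (>= 1 in use)")
  if (!is.numeric(r_bar) || r_bar <= 0) stop("`r_bar` must be positive")
  if (any(lambda < 0)) stop("`lambda` must be non-negative")
  nu * r_bar * lambda
}

#' Enthalpic segment-number bound
#'
#' Past full stretch a polysaccharide chain lengthens by backbone/monomer
#' deformation of about 10\%; a chain survives in the enthalpic regime down
#' to \eqn{n_{min}^H = (10/11)\, n_{min}^S}, i.e. its contour may grow by
#' exactly the factor 11/10 before rupture.
#'
#' @param n_min_S full-stretch bound(s), > 0.
#' @return `n_min_H = (10/11) * n_min_S`.
#' @export
enthalpic_bound <- function(n_min_S) {
  if (any(n_min_S <= 0)) stop("`n_min_S` must be positive")
  (10 / 11) * n_min_S
}
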