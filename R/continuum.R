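#' Incompressible uniaxial kinematics
#'
#' Principal stretches \eqn{(\Lambda, \Lambda^{-1/2}, \Lambda^{-1/2})}
#' (det F = 1 by construction), giving the invariants of the right
#' Cauchy-Green tensor \eqn{I_1 = \Lambda^2 + 2/\Lambda},
#' \eqn{I_2 = 2\Lambda + 1/\Lambda^2}, and the chain-level stretch under the
#' selected mapping.
#'
#' @param Lambda macroscopic principal stretch (> 0).
#' @param chain_stretch `"eightchain"` (chain stretch \eqn{\sqrt{I_1/3}}) or
#'   `"affine"` (chain stretch \eqn{\Lambda}).
#' @return an object of class `"deformation_state"`: list with `Lambda`,
#'   `I1`, `I2`, `lam_chain`.
#' @examples
#' uniaxial_kinematics(2)
#' @export
uniaxial_kinematics <- function(Lambda, chain_stretch = c("eightchain", "affine")) {
  chain_stretch <- match.arg(chain_stretch)
  if (!is.numeric(Lambda) || any(Lambda <= 0)) {
    stop("macro stretch `Lambda` must be positive")
  }
  I1 <- Lambda^2 + 2 / Lambda
  I2 <- 2 * Lambda + 1 / Lambda^2
  lam <- switch(chain_stretch,
                eightchain = sqrt(I1 / 3),
                affine = Lambda)
  structure(list(Lambda = Lambda, I1 = I1, I2 = I2, lam_chain = lam,
                 chain_stretch = chain_stretch),
            class = "deformation_state")
}

# d lam_chain / d Lambda for the two mappings
.dlam_dLambda <- function(state) {
  switch(state$chain_stretch,
         eightchain = (state$Lambda - state$Lambda^-2) / (3 * state$lam_chain),
         affine = rep(1, length(state$Lambda)))
}

# f(x, y) = alpha^y (exp(y (x - 3)) - 1) and its x-derivative
.hyper_f <- function(x, y, alpha) alpha^y * (exp(y * (x - 3)) - 1)
.hyper_fx <- function(x, y, alpha) y * alpha^y * exp(y * (x - 3))

#' Hyperelastic energy of the neutral network
#'
#' Two-invariant exponential-family energy for the purely elastic
#' polyacrylamide network:
#' \deqn{\Psi^N = \mu\left[ f(I_1,\alpha) + f(I_2,-\alpha^{1/6})
#'   + \ln\!\big(\tfrac{1}{\alpha} f(I_1,1) + 1\big) \right],
#'   \quad f(x,y) = \alpha^y\big(e^{y(x-3)}-1\big).}
#' The logarithmic term reduces analytically to \eqn{I_1 - 3}
#' (neo-Hookean); it is nevertheless evaluated through `f` with a validity
#' guard on the logarithm argument. \eqn{\Psi^N = 0} at the identity and its
#' uniaxial stress contribution vanishes there because both invariants are
#' stationary at \eqn{\Lambda = 1}.
#'
#' @param state a `"deformation_state"` from [uniaxial_kinematics()].
#' @param mu shear modulus (stress units, > 0 for a physical network).
#' @param alpha dimensionless scalar parameter (> 0).
#' @return energy in stress units.
#' @export
neutral_energy <- function(state, mu, alpha) {
  if (alpha <= 0) stop("`alpha` must be positive")
  larg <- .hyper_f(state$I1, 1, alpha) / alpha + 1
  if (any(larg <= 0)) {
    stop("model validity: logarithm argument of the neutral energy is non-positive")
  }
  mu * (.hyper_f(state$I1, alpha, alpha) +
          .hyper_f(state$I2, -alpha^(1 / 6), alpha) +
          log(larg))
}

# d Psi^N / d Lambda (closed form)
.dneutral_dLambda <- function(state, mu, alpha) {
  y2 <- -alpha^(1 / 6)
  larg <- .hyper_f(state$I1, 1, alpha) / alpha + 1
  psi1 <- mu * (.hyper_fx(state$I1, alpha, alpha) +
                  .hyper_fx(state$I1, 1, alpha) / alpha / larg)
  psi2 <- mu * .hyper_fx(state$I2, y2, alpha)
  dI1 <- 2 * state$Lambda - 2 * state$Lambda^-2
  dI2 <- 2 - 2 * state$Lambda^-3
  psi1 * dI1 + psi2 * dI2
}

#' Damage state
#'
#' The only internal variable of the model: the running maximum of the
#' chain-level stretch, which drives the irreversible availability sets and
#' hence the Mullins softening.
#'
#' @param lam_max historical maximum chain stretch (>= 1 for programs
#'   starting at the reference state).
#' @return an object of class `"damage_state"`.
#' @export
damage_state <- function(lam_max = 1) {
  stopifnot(is.numeric(lam_max), length(lam_max) == 1L, lam_max > 0)
  structure(list(lam_max = lam_max), class = "damage_state")
}

#' Update the damage state
#'
#' Max-accumulator: `lam_max` never decreases; idempotent on non-increasing
#' paths.
#'
#' @param damage a `"damage_state"`.
#' @param state a `"deformation_state"` (its `lam_chain` is accumulated).
#' @return updated `"damage_state"`.
#' @export
update_damage <- function(damage, state) {
  damage_state(max(damage$lam_max, state$lam_chain))
}

#' Total macroscopic energy of the double-network hydrogel
#'
#' \eqn{\Psi^M = \Psi^P + \Psi^N}: the polyelectrolyte population energy
#' (entropic + enthalpic, with network alteration and damage history) plus
#' the hyperelastic neutral-network energy. Purely additive; no coupling
#' terms.
#'
#' @param state a `"deformation_state"`.
#' @param damage a `"damage_state"` (frozen during differentiation).
#' @param params a `"dnh_params"` object.
#' @param control a `"dnh_control"` object.
#' @return energy in stress units.
#' @export
total_energy <- function(state, damage, params, control = dnh_control()) {
  lam <- state$lam_chain
  lam_max <- max(damage$lam_max, 0)
  psiP <- polyelectrolyte_energy(
    lam, lam_max,
    n_max = params$n_max, r_bar = params$r_bar, kappa = params$kappa,
    N_P = params$N_P, nu = params$nu, E = params$E,
    include_enthalpic = control$include_enthalpic,
    rel.tol = control$rel.tol, abs.tol = control$abs.tol,
    phi_cap = control$phi_cap
  )
  psiP + neutral_energy(state, params$mu, params$alpha)
}

#' Nominal (first Piola-Kirchhoff) uniaxial stress
#'
#' \eqn{P_{11} = \partial \Psi^M / \partial \Lambda} at frozen damage, with
#' the hydrostatic pressure eliminated by the traction-free lateral
#' condition; for this isotropic energy on the isochoric uniaxial path the
#' two routes coincide. Evaluated as an analytic chain-rule derivative:
#' population Leibniz terms for the moving set boundaries, closed-form
#' invariant derivatives for the neutral part, and the chain-stretch mapping
#' factor \eqn{d\lambda/d\Lambda}. At the reference state on the virgin path
#' the stress is exactly zero under the eight-chain mapping.
#'
#' @param Lambda macroscopic stretch(es), >= 1 in normal use; vectorized.
#' @param damage a `"damage_state"`; defaults to the virgin state consistent
#'   with the largest `Lambda` evaluated having no history.
#' @param params a `"dnh_params"` object.
#' @param control a `"dnh_control"` object.
#' @return nominal stress(es) in stress units.
#' @examples
#' p <- dnh_default_params()
#' nominal_stress(c(1, 2, 4), damage_state(1), p)
#' @export
nominal_stress <- function(Lambda, damage, params, control = dnh_control()) {
  vapply(Lambda, function(L) {
    state <- uniaxial_kinematics(L, control$chain_stretch)
    lam <- state$lam_chain
    lam_max <- max(damage$lam_max, lam)
    dpsiP <- .dpolyelectrolyte_dlambda(
      lam, lam_max,
      n_max = params$n_max, r_bar = params$r_bar, kappa = params$kappa,
      N_P = params$N_P, nu = params$nu, E = params$E,
      include_enthalpic = control$include_enthalpic,
      rel.tol = control$rel.tol, abs.tol = control$abs.tol,
      phi_cap = control$phi_cap
    )
    out <- dpsiP * .dlam_dLambda(state) + .dneutral_dLambda(state, params$mu, params$alpha)
    if (!is.finite(out)) {
      stop(sprintf(
        "numerical failure: non-finite stress at Lambda = %g (lam = %g, lam_max = %g)",
        L, lam, lam_max
      ))
    }
    out
  }, numeric(1L))
}
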