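#' Material parameters of the double-network hydrogel model
#'
#' The model has exactly eight material parameters. Five describe the
#' entropic (inelastic) behaviour of the ionically cross-linked
#' polyelectrolyte (alginate) network, one its enthalpic behaviour, and two
#' the hyperelastic neutral (polyacrylamide) network:
#' \describe{
#'   \item{n_max}{maximum segment number in the network (dimensionless).}
#'   \item{r_bar}{normalized average contour length of a chain
#'     (dimensionless).}
#'   \item{kappa}{cross-linking density of the network (dimensionless).}
#'   \item{N_P}{number density of active polymer chains in the
#'     polyelectrolyte network; under the kT = 1 convention it carries the
#'     stress unit.}
#'   \item{nu}{sliding ratio of a chain during rupture (dimensionless,
#'     >= 1); guards the Langevin singularity at full stretch.}
#'   \item{E}{elastic modulus of the material (stress units); sets the
#'     enthalpic contribution of fully stretched chains and is normally
#'     taken from the small-strain slope of the data, see
#'     [estimate_modulus()].}
#'   \item{mu}{shear modulus of the neutral network (stress units).}
#'   \item{alpha}{dimensionless scalar parameter of the neutral-network
#'     energy.}
#' }
#' Thermal energy is normalized to kT = 1; all stress scale is carried by
#' `N_P`, `E` and `mu`, in the declared `stress_unit`.
#'
#' @param n_max,r_bar,kappa,N_P,nu,E,mu,alpha numeric scalars, see Details.
#' @param stress_unit unit tag for `N_P`, `E`, `mu` and all stresses
#'   (metadata only; default `"kPa"`).
#' @return an object of class `"dnh_params"` (named list).
#' @examples
#' p <- dnh_params(n_max = 20, r_bar = 2, kappa = 2, N_P = 100,
#'                 nu = 1.05, E = 60, mu = 1, alpha = 0.05)
#' p
#' @export
dnh_params <- function(n_max, r_bar, kappa, N_P, nu, E, mu, alpha,
                       stress_unit = "kPa") {
  p <- list(n_max = n_max, r_bar = r_bar, kappa = kappa, N_P = N_P,
            nu = nu, E = E, mu = mu, alpha = alpha)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("parameter `%s` must be a finite numeric scalar", nm))
    }
  }
  if (n_max <= 0 || r_bar <= 0 || kappa <= 0 || alpha <= 0) {
    stop("`n_max`, `r_bar`, `kappa` and `alpha` must be strictly positive")
  }
  if (N_P < 0 || E < 0 || mu < 0) {
    stop("`N_P`, `E` and `mu` must be non-negative")
  }
  if (nu < 1) stop("sliding ratio `nu` must be >= 1")
  p$stress_unit <- stress_unit
  class(p) <- "dnh_params"
  p
}

#' @export
print.dnh_params <- function(x, ...) {
  cat("Double-network hydrogel material parameters (kT = 1, stresses in ",
      x$stress_unit, ")\n", sep = "")
  cat(sprintf("  entropic:    n_max = %g, r_bar = %g, kappa = %g, N_P = %g, nu = %g\n",
              x$n_max, x$r_bar, x$kappa, x$N_P, x$nu))
  cat(sprintf("  enthalpic:   E = %g\n", x$E))
  cat(sprintf("  hyperelastic: mu = %g, alpha = %g\n", x$mu, x$alpha))
  invisible(x)
}

#' @export
as.double.dnh_params <- function(x, ...) {
  unlist(x[dnh_param_names()])
}

#' Names of the eight material parameters
#'
#' @return character vector of length 8, in canonical order.
#' @export
dnh_param_names <- function() {
  c("n_max", "r_bar", "kappa", "N_P", "nu", "E", "mu", "alpha")
}

#' Default material parameters
#'
#' A representative parameter set for an alginate/polyacrylamide
#' double-network hydrogel in kPa: it produces a J- then S-shaped virgin
#' uniaxial curve with enthalpic hardening growing through stretches 6-11
#' and pronounced Mullins softening under cyclic loading, with stresses of
#' order 100 kPa at large stretch — the regime reported for these gels.
#'
#' @return a `"dnh_params"` object.
#' @export
dnh_default_params <- function() {
  dnh_params(n_max = 20, r_bar = 2, kappa = 2, N_P = 100,
             nu = 1.05, E = 60, mu = 1, alpha = 0.05)
}

#' Model evaluation options
#'
#' @param chain_stretch mapping from macro stretch to chain stretch:
#'   `"eightchain"` (default) uses the eight-chain amplitude
#'   \eqn{\lambda = \sqrt{I_1/3}}, stationary at the identity so the
#'   reference state is exactly stress-free; `"affine"` uses
#'   \eqn{\lambda = \Lambda} directly.
#' @param include_enthalpic logical; `FALSE` removes the enthalpic term
#'   (ablated model).
#' @param rel.tol,abs.tol adaptive-quadrature tolerances for the population
#'   integrals.
#' @param phi_cap validity cap on the network-alteration factor.
#' @return an object of class `"dnh_control"` (named list).
#' @export
dnh_control <- function(chain_stretch = c("eightchain", "affine"),
                        include_enthalpic = TRUE,
                        rel.tol = 1e-8, abs.tol = 1e-10,
                        phi_cap = 1e6) {
  chain_stretch <- match.arg(chain_stretch)
  stopifnot(is.logical(include_enthalpic), length(include_enthalpic) == 1L,
            rel.tol > 0, abs.tol > 0, phi_cap > 0)
  structure(
    list(chain_stretch = chain_stretch,
         include_enthalpic = include_enthalpic,
         rel.tol = rel.tol, abs.tol = abs.tol, phi_cap = phi_cap),
    class = "dnh_control"
  )
}
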