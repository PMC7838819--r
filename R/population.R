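#' Chain-length probability density of the polyelectrolyte network
#'
#' Density over segment number \eqn{n} for a randomly polymerized,
#' ionically cross-linked network. A Gaussian-like kernel in \eqn{n}
#' (through \eqn{G_2 = 3\bar r^2/(2n)}) is modulated by the cross-linking
#' density \eqn{\kappa} through both the prefactor and the exponent:
#' \deqn{P(n,\bar r,\kappa) = \kappa \sqrt{6/(\pi n)}\; e^{G_1},}
#' \deqn{G_1 = -G_2 - \frac{\kappa^2}{4\pi}\left(G_3 + n e^{-G_2} - e^{-G_2 n}\right),}
#' \deqn{G_3 = \sqrt{G_2 n \pi}\,\left[\mathrm{erf}(\sqrt{G_2}) - \mathrm{erf}(\sqrt{G_2 n})\right].}
#' The density is positive, vanishes as \eqn{n \to 0^+} (Gaussian kernel)
#' and as \eqn{n \to \infty} (exponential tail with rate
#' \eqn{\kappa^2/4\pi}), and is unimodal. It is not normalized to unit mass;
#' normalization of the network happens at the segment level through the
#' network-alteration factor [alteration_factor()].
#'
#' @param n segment number(s), > 0; vectorized.
#' @param r_bar normalized average contour length (> 0).
#' @param kappa cross-linking density parameter (> 0).
#' @return density values (per unit n).
#' @export
segment_pdf <- function(n, r_bar, kappa) {
  if (any(!is.finite(n)) || any(n <= 0)) stop("segment number `n` must be positive")
  if (r_bar <= 0) stop("`r_bar` must be positive")
  if (kappa <= 0) stop("`kappa` must be positive")
  G2 <- 3 * r_bar^2 / (2 * n)
  G3 <- sqrt(G2 * n * pi) * (erf(sqrt(G2)) - erf(sqrt(G2 * n)))
  G1 <- -G2 - kappa^2 / (4 * pi) * (G3 + n * exp(-G2) - exp(-G2 * n))
  kappa * sqrt(6 / (pi * n)) * exp(G1)
}

#' Error function
#'
#' \eqn{\mathrm{erf}(x) = 2\Phi(x\sqrt2) - 1}, via the normal CDF.
#' @param x numeric vector.
#' @return numeric vector.
#' @export
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Segment-number domain of a chain subpopulation
#'
#' Constructor for the interval of segment numbers over which population
#' integrals run. An interval with `upper <= lower` is flagged empty and all
#' integrals over it are exactly zero.
#'
#' @param lower,upper interval bounds.
#' @param kind `"entropic"` or `"enthalpic"`.
#' @return an object of class `"segment_domain"`: list with `lower`, `upper`,
#'   `kind`, `empty`.
#' @export
segment_domain <- function(lower, upper, kind = c("entropic", "enthalpic")) {
  kind <- match.arg(kind)
  structure(
    list(lower = lower, upper = upper, kind = kind,
         empty = !is.finite(lower) || !is.finite(upper) || upper <= lower),
    class = "segment_domain"
  )
}

#' @export
print.segment_domain <- function(x, ...) {
  cat(sprintf("<segment_domain: %s> %s\n", x$kind,
              if (x$empty) "empty"
              else sprintf("[%.6g, %.6g]", x$lower, x$upper)))
  invisible(x)
}

#' Entropic availability set D
#'
#' Chains behave entropically while longer than the current full-stretch
#' bound; chains ruptured at the historical maximum stretch (those shorter
#' than the enthalpic bound evaluated at `lam_max`) never return. The set is
#' \deqn{D = [\,\max(\nu\bar r\lambda,\ (10/11)\nu\bar r\lambda_{max}),\ n_{max}\,].}
#'
#' @param lam_current current chain stretch (>= 0).
#' @param lam_max historical maximum chain stretch.
#' @param nu sliding-ratio parameter.
#' @param r_bar normalized average contour length.
#' @param n_max maximum segment number in the network.
#' @return a `"segment_domain"` of kind `"entropic"` (possibly empty).
#' @export
entropic_domain <- function(lam_current, lam_max, nu, r_bar, n_max) {
  lower <- max(full_stretch_bound(nu, r_bar, lam_current),
               enthalpic_bound(full_stretch_bound(nu, r_bar, lam_max)))
  segment_domain(lower, n_max, "entropic")
}

#' Enthalpic availability set D^H
#'
#' Fully stretched but surviving chains: segment numbers between the
#' enthalpic (rupture) bound at the historical maximum stretch and the
#' current full-stretch bound,
#' \deqn{D^H = [\,(10/11)\nu\bar r\lambda_{max},\ \nu\bar r\lambda\,].}
#' The set empties under deep unloading (\eqn{\lambda < (10/11)\lambda_{max}}):
#' every once-stretched chain has either relaxed back into the entropic set
#' or ruptured. The lower bound is pinned to the damage history so that the
#' frozen-damage energy is smooth at \eqn{\lambda = \lambda_{max}}.
#'
#' @inheritParams entropic_domain
#' @return a `"segment_domain"` of kind `"enthalpic"` (possibly empty).
#' @export
enthalpic_domain <- function(lam_current, lam_max, nu, r_bar) {
  lower <- enthalpic_bound(full_stretch_bound(nu, r_bar, lam_max))
  upper <- full_stretch_bound(nu, r_bar, lam_current)
  segment_domain(lower, upper, "enthalpic")
}

# adaptive quadrature over a segment_domain; exactly 0 on empty domains
.domain_integral <- function(f, domain, rel.tol = 1e-8, abs.tol = 1e-10) {
  if (domain$empty) return(0)
  stats::integrate(f, lower = domain$lower, upper = domain$upper,
                   rel.tol = rel.tol, abs.tol = abs.tol,
                   stop.on.error = TRUE)$value
}

#' Network-alteration normalization factor
#'
#' The network alteration rule holds the total number of active segments
#' constant as chains rupture:
#' \deqn{\Phi = \left[\int_D P(n,\bar r,\kappa)\, n\, \mathrm{d}n\right]^{-1},}
#' computed on the instantaneous (damaged) entropic set. \eqn{\Phi} grows as
#' damage removes chains; a value above `cap` signals a nearly exhausted
#' network and raises a model-validity error instead of returning an
#' astronomically amplified energy.
#'
#' @param domain a `"segment_domain"`, normally from [entropic_domain()].
#' @param r_bar,kappa population parameters, see [segment_pdf()].
#' @param cap singularity guard on \eqn{\Phi}.
#' @param rel.tol,abs.tol quadrature tolerances.
#' @return scalar \eqn{\Phi > 0}.
#' @export
alteration_factor <- function(domain, r_bar, kappa, cap = 1e6,
                              rel.tol = 1e-8, abs.tol = 1e-10) {
  if (domain$empty) {
    stop("singular network: entropic set is empty, alteration factor undefined")
  }
  m <- .domain_integral(function(n) segment_pdf(n, r_bar, kappa) * n,
                        domain, rel.tol = rel.tol, abs.tol = abs.tol)
  if (m <= 0 || !is.finite(m)) {
    stop("singular network: segment integral over D is zero or non-finite")
  }
  phi <- 1 / m
  if (phi > cap) {
    stop(sprintf(
      "model validity: alteration factor Phi = %.3g exceeds cap %.3g (network nearly exhausted)",
      phi, cap
    ))
  }
  phi
}

#' Polyelectrolyte network energy
#'
#' Population energy of the alginate network at chain stretch `lambda` with
#' damage history `lam_max` (running maximum of chain stretch):
#' \deqn{\Psi^P = \Phi\left[ N^P \int_D P(n)\,\psi^S(n,\lambda)\,\mathrm{d}n
#'   + N^P \int_{D^H} P(n)\,\psi^S_{full}(n)\,\mathrm{d}n
#'   + E \int_{D^H} P(n)\,\mathrm{d}n \right],}
#' with the entropic set \eqn{D} and enthalpic set \eqn{D^H} from
#' [entropic_domain()] and [enthalpic_domain()] and the kT = 1 convention
#' (stress scale carried by `N_P` and `E`). A fully stretched surviving
#' chain retains its full-stretch entropic energy
#' \eqn{\psi^S_{full}(n) = n\,g(1/\nu)} (the per-chain energy is continuous
#' across the full-stretch boundary); the enthalpic modulus term
#' \eqn{E\int_{D^H} P\,\mathrm{d}n} is the additional energy of backbone
#' lengthening. An empty \eqn{D^H} contributes exactly zero.
#'
#' @param lambda chain stretch.
#' @param lam_max damage history (historical maximum chain stretch).
#' @param n_max,r_bar,kappa,N_P,nu,E material parameters (see
#'   [dnh_params()]).
#' @param include_enthalpic logical; `FALSE` drops the enthalpic term (the
#'   ablated model, equivalent to `E = 0`).
#' @param rel.tol,abs.tol quadrature tolerances.
#' @param phi_cap singularity guard, see [alteration_factor()].
#' @return energy in stress units.
#' @export
polyelectrolyte_energy <- function(lambda, lam_max, n_max, r_bar, kappa,
                                   N_P, nu, E,
                                   include_enthalpic = TRUE,
                                   rel.tol = 1e-8, abs.tol = 1e-10,
                                   phi_cap = 1e6) {
  D <- entropic_domain(lambda, lam_max, nu, r_bar, n_max)
  DH <- enthalpic_domain(lambda, lam_max, nu, r_bar)
  phi <- alteration_factor(D, r_bar, kappa, cap = phi_cap,
                           rel.tol = rel.tol, abs.tol = abs.tol)
  A <- .domain_integral(
    function(n) segment_pdf(n, r_bar, kappa) *
      entropic_chain_energy(n, lambda, r_bar),
    D, rel.tol = rel.tol, abs.tol = abs.tol
  )
  # fully stretched survivors: entropic energy pinned at x = 1/nu
  A_cap <- if (DH$empty) 0 else {
    .full_stretch_kernel(nu) * .domain_integral(
      function(n) segment_pdf(n, r_bar, kappa) * n,
      DH, rel.tol = rel.tol, abs.tol = abs.tol
    )
  }
  B <- if (include_enthalpic && E != 0) {
    .domain_integral(function(n) segment_pdf(n, r_bar, kappa),
                     DH, rel.tol = rel.tol, abs.tol = abs.tol)
  } else 0
  phi * (N_P * (A + A_cap) + E * B * as.numeric(include_enthalpic))
}

# g(1/nu) = x beta + log(beta/sinh beta) at x = 1/nu: per-segment entropic
# energy of a chain held at the guarded full-stretch state
.full_stretch_kernel <- function(nu) {
  x <- 1 / nu
  if (x >= 1) stop("`nu` must exceed 1 for a finite full-stretch energy")
  .langevin_energy_kernel(x, 3 * x / (1 - x^3))
}

# d Psi^P / d lambda at frozen damage (lam_max fixed). While the lower bound
# of D moves with lambda (lambda > (10/11) lam_max), the entropic Leibniz
# outflow at n = s*lambda cancels exactly against the inflow into the capped
# full-stretch term (the per-chain energy is continuous there), leaving the
# Phi' term and the D^H boundary fluxes; below the switch the damaged set is
# static, Phi is constant in lambda and D^H is empty.
.dpolyelectrolyte_dlambda <- function(lambda, lam_max, n_max, r_bar, kappa,
                                      N_P, nu, E,
                                      include_enthalpic = TRUE,
                                      rel.tol = 1e-8, abs.tol = 1e-10,
                                      phi_cap = 1e6) {
  s <- nu * r_bar
  D <- entropic_domain(lambda, lam_max, nu, r_bar, n_max)
  if (D$empty) stop("singular network: entropic set is empty")
  DH <- enthalpic_domain(lambda, lam_max, nu, r_bar)
  E_eff <- if (include_enthalpic) E else 0

  M <- .domain_integral(function(n) segment_pdf(n, r_bar, kappa) * n,
                        D, rel.tol = rel.tol, abs.tol = abs.tol)
  phi <- 1 / M
  if (phi > phi_cap) stop("model validity: alteration factor exceeds cap")

  Aprime <- .domain_integral(
    function(n) segment_pdf(n, r_bar, kappa) * .dpsiS_dlambda(n, lambda, r_bar),
    D, rel.tol = rel.tol, abs.tol = abs.tol
  )

  moving <- s * lambda >= D$lower - 1e-12 * max(1, D$lower)  # lower bound tracks lambda
  if (moving) {
    P_l <- segment_pdf(s * lambda, r_bar, kappa)
    A <- .domain_integral(
      function(n) segment_pdf(n, r_bar, kappa) *
        entropic_chain_energy(n, lambda, r_bar),
      D, rel.tol = rel.tol, abs.tol = abs.tol
    )
    A_cap <- if (DH$empty) 0 else {
      .full_stretch_kernel(nu) * .domain_integral(
        function(n) segment_pdf(n, r_bar, kappa) * n,
        DH, rel.tol = rel.tol, abs.tol = abs.tol
      )
    }
    B <- if (E_eff != 0) {
      .domain_integral(function(n) segment_pdf(n, r_bar, kappa),
                       DH, rel.tol = rel.tol, abs.tol = abs.tol)
    } else 0
    Mprime <- -s * P_l * (s * lambda)
    # entropic outflow -s P psi^S(s lambda) cancels the capped-term inflow
    # +s P (s lambda) g(1/nu): only the interior derivative of A survives
    Bprime <- if (E_eff != 0 && !DH$empty) s * P_l else 0
    -(Mprime / M^2) * (N_P * (A + A_cap) + E_eff * B) +
      phi * (N_P * Aprime + E_eff * Bprime)
  } else {
    phi * N_P * Aprime
  }
}
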