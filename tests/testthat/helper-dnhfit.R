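# Shared fixtures for the dnhfit test suite. Everything is generated in
# code; the canonical parameter set is the package default.

fixture_params <- function(...) {
  p <- as.list(as.numeric(dnh_default_params()))
  p[names(list(...))] <- list(...)
  dnh_params(p$n_max, p$r_bar, p$kappa, p$N_P, p$nu, p$E, p$mu, p$alpha)
}

# random valid parameter sets around the default, reproducible
random_params <- function(n, seed = 1, rel = 0.3) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  base <- as.numeric(dnh_default_params())
  out <- vector("list", n)
  k <- 0L
  while (k < n) {
    v <- base * (1 + runif(8, -rel, rel))
    names(v) <- names(base)
    v[["nu"]] <- max(1.02, min(1.4, v[["nu"]]))
    # keep the entropic set comfortably populated up to chain stretch ~5.5
    if (v[["n_max"]] < 1.35 * v[["nu"]] * v[["r_bar"]] * 5.5) next
    k <- k + 1L
    out[[k]] <- dnh_params(v[["n_max"]], v[["r_bar"]], v[["kappa"]], v[["N_P"]],
                           v[["nu"]], v[["E"]], v[["mu"]], v[["alpha"]])
  }
  out
}

# independent fixed-order Gauss-Legendre quadrature (oracle for the adaptive
# production scheme); falls back to a composite Simpson rule if pracma is
# unavailable
gauss_integral <- function(f, lower, upper, n = 200) {
  if (upper <= lower) return(0)
  if (requireNamespace("pracma", quietly = TRUE)) {
    gl <- pracma::gaussLegendre(n, lower, upper)
    sum(gl$w * f(gl$x))
  } else {
    x <- seq(lower, upper, length.out = 2L * n + 1L)
    h <- x[2] - x[1]
    w <- c(1, rep(c(4, 2), n - 1L), 4, 1) * h / 3
    sum(w * f(x))
  }
}

# virgin-path frozen-damage state helpers
virgin_damage <- function(Lambda, control = dnh_control()) {
  damage_state(uniaxial_kinematics(Lambda, control$chain_stretch)$lam_chain)
}
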