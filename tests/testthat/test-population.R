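# Chain-population statistics: segment-number density, availability sets,
# network-alteration normalization, and the population energy integrals.

test_that("segment density matches the frozen high-precision transcription", {
  # 30-digit independent evaluation of the same density, r_bar = 2, kappa = 1
  frozen <- c(`1` = 0.00342557750011026, `2` = 0.048507996842514059,
              `4` = 0.14780283736208947, `8` = 0.18439598269973349,
              `16` = 0.11311788961412364)
  got <- segment_pdf(as.numeric(names(frozen)), 2, 1)
  expect_equal(unname(got), unname(frozen), tolerance = 1e-12)
})

test_that("segment density is positive, vanishes at both ends, rejects n <= 0", {
  n <- exp(seq(log(0.05), log(500), length.out = 200))
  d <- segment_pdf(n, 2, 1.5)
  expect_true(all(d >= 0))
  expect_lt(segment_pdf(1e-3, 2, 1.5), 1e-200)
  expect_lt(segment_pdf(400, 2, 1.5), 1e-20)
  expect_error(segment_pdf(0, 2, 1), "positive")
  expect_error(segment_pdf(-1, 2, 1), "positive")
})

test_that("segment density is proportional to kappa in the dilute limit", {
  n <- c(2, 8, 20)
  r1 <- segment_pdf(n, 2, 1e-7) / 1e-7
  r2 <- segment_pdf(n, 2, 2e-7) / 2e-7
  expect_equal(r1, r2, tolerance = 1e-6)
  # and the kappa -> 0 limit is the bare Gaussian-kernel prefactor
  expect_equal(r1, sqrt(6 / (pi * n)) * exp(-3 * 4 / (2 * n)), tolerance = 1e-5)
})

test_that("segment density is unimodal over the working range", {
  n <- seq(0.2, 120, by = 0.05)
  for (par in list(c(2, 1), c(2, 2), c(1, 1.5), c(3, 0.8))) {
    d <- segment_pdf(n, par[1], par[2])
    slope_sign <- sign(diff(d))
    changes <- sum(diff(slope_sign[slope_sign != 0]) != 0)
    expect_equal(changes, 1)
  }
})

test_that("entropic availability set follows the damage history rule", {
  d <- entropic_domain(2, 2, 1, 1, 50)      # virgin loading
  expect_equal(c(d$lower, d$upper), c(2, 50))
  expect_false(d$empty)
  # unloaded to lambda = 1 after lambda_max = 11: ruptured chains never return
  d <- entropic_domain(1, 11, 1, 1, 50)
  expect_equal(d$lower, 10)
  # on the virgin path the history rule reduces to the no-history set
  d1 <- entropic_domain(3, 3, 1.05, 2, 60)
  expect_equal(d1$lower, full_stretch_bound(1.05, 2, 3))
  # exhausted network flags empty rather than erroring
  expect_true(entropic_domain(5, 5, 1, 1, 4)$empty)
})

test_that("enthalpic availability set opens at full stretch and closes on deep unload", {
  d <- enthalpic_domain(11, 11, 1, 1)
  expect_equal(c(d$lower, d$upper), c(10, 11))
  expect_true(enthalpic_domain(1, 11, 1, 1)$empty)  # upper 1 < lower 10
  d <- enthalpic_domain(1, 1, 1, 1)
  expect_equal(c(d$lower, d$upper), c(10 / 11, 1))
})

test_that("alteration factor satisfies the normalization identity", {
  for (par in list(c(2, 1), c(1.5, 2.5), c(3, 0.7))) {
    dom <- segment_domain(2.5, 40, "entropic")
    phi <- alteration_factor(dom, par[1], par[2])
    m <- gauss_integral(function(n) segment_pdf(n, par[1], par[2]) * n,
                        dom$lower, dom$upper, n = 400)
    expect_equal(phi * m, 1, tolerance = 1e-8)
  }
})

test_that("alteration factor is non-decreasing as damage shrinks the set", {
  lowers <- seq(2, 14, by = 2)
  phi <- vapply(lowers, function(l) {
    alteration_factor(segment_domain(l, 20, "entropic"), 2, 2)
  }, numeric(1))
  expect_true(all(diff(phi) > 0))
})

test_that("degenerate or empty sets raise singular-network errors", {
  expect_error(alteration_factor(segment_domain(5, 5, "entropic"), 2, 1),
               "empty")
  expect_error(alteration_factor(segment_domain(19.9, 20, "entropic"), 2, 6,
                                 cap = 1e3),
               "cap")
})

test_that("population energy: ablation switch and empty enthalpic set", {
  p <- dnh_default_params()
  args <- list(3, 3, p$n_max, p$r_bar, p$kappa, p$N_P, p$nu)
  full <- do.call(polyelectrolyte_energy, c(args, E = p$E))
  ezero <- do.call(polyelectrolyte_energy, c(args, E = 0))
  abl <- do.call(polyelectrolyte_energy,
                 c(args, E = p$E, include_enthalpic = FALSE))
  expect_equal(ezero, abl, tolerance = 1e-12)
  expect_gt(full, abl)
  # deep unload: D^H empty, enthalpic term contributes exactly zero
  deep_full <- polyelectrolyte_energy(1, 5, p$n_max, p$r_bar, p$kappa,
                                      p$N_P, p$nu, p$E)
  deep_abl <- polyelectrolyte_energy(1, 5, p$n_max, p$r_bar, p$kappa,
                                     p$N_P, p$nu, p$E,
                                     include_enthalpic = FALSE)
  expect_identical(deep_full, deep_abl)
})

test_that("population energy matches the frozen regression grid and the
           fixed-order Gauss oracle", {
  p <- dnh_default_params()
  frozen <- c(`1.5` = 35.427806686795, `3` = 100.927452739982,
              `6` = 236.919830238235, `9` = 845.832015704665)
  for (lam_chr in names(frozen)) {
    lam <- as.numeric(lam_chr)
    got <- polyelectrolyte_energy(lam, lam, p$n_max, p$r_bar, p$kappa,
                                  p$N_P, p$nu, p$E)
    expect_equal(got, unname(frozen[lam_chr]), tolerance = 1e-9)
    # independent fixed-order quadrature oracle
    s <- p$nu * p$r_bar
    pdf <- function(n) segment_pdf(n, p$r_bar, p$kappa)
    A <- gauss_integral(function(n) pdf(n) * entropic_chain_energy(n, lam, p$r_bar),
                        s * lam, p$n_max, n = 400)
    M <- gauss_integral(function(n) pdf(n) * n, s * lam, p$n_max, n = 400)
    Acap <- gauss_integral(function(n) pdf(n) * n,
                           (10 / 11) * s * lam, s * lam, n = 200) *
      entropic_chain_energy(s * lam, lam, p$r_bar) / (s * lam)
    B <- gauss_integral(pdf, (10 / 11) * s * lam, s * lam, n = 200)
    oracle <- (p$N_P * (A + Acap) + p$E * B) / M
    expect_equal(got, oracle, tolerance = 1e-6)
  }
})

test_that("population energy is continuous across the set-switch stretch", {
  p <- dnh_default_params()
  lam_max <- 4
  lam_c <- (10 / 11) * lam_max
  eps <- 1e-7
  left <- polyelectrolyte_energy(lam_c - eps, lam_max, p$n_max, p$r_bar,
                                 p$kappa, p$N_P, p$nu, p$E)
  right <- polyelectrolyte_energy(lam_c + eps, lam_max, p$n_max, p$r_bar,
                                  p$kappa, p$N_P, p$nu, p$E)
  expect_equal(left, right, tolerance = 1e-5)
})

test_that("halving the quadrature tolerance leaves the energy unchanged to 1e-6", {
  p <- dnh_default_params()
  for (lam in c(1.5, 4, 8)) {
    loose <- polyelectrolyte_energy(lam, lam, p$n_max, p$r_bar, p$kappa,
                                    p$N_P, p$nu, p$E,
                                    rel.tol = 1e-8, abs.tol = 1e-10)
    tight <- polyelectrolyte_energy(lam, lam, p$n_max, p$r_bar, p$kappa,
                                    p$N_P, p$nu, p$E,
                                    rel.tol = 5e-9, abs.tol = 5e-11)
    expect_equal(loose, tight, tolerance = 1e-6)
  }
})
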