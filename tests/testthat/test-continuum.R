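# Macroscopic mechanics: kinematics, neutral-network energy, total energy,
# nominal stress and damage bookkeeping.

test_that("incompressible uniaxial kinematics gives the textbook invariants", {
  s <- uniaxial_kinematics(1)
  expect_equal(c(s$I1, s$I2), c(3, 3))
  expect_equal(uniaxial_kinematics(2)$I1, 5)
  expect_equal(uniaxial_kinematics(2)$I2, 4.25)
  expect_equal(uniaxial_kinematics(4)$I1, 16.5)
  expect_equal(uniaxial_kinematics(4)$I2, 8.0625)
  expect_error(uniaxial_kinematics(0), "positive")
  expect_error(uniaxial_kinematics(-1), "positive")
})

test_that("chain-stretch mappings coincide at the identity and order in tension", {
  expect_equal(uniaxial_kinematics(1, "eightchain")$lam_chain, 1)
  expect_equal(uniaxial_kinematics(1, "affine")$lam_chain, 1)
  expect_equal(uniaxial_kinematics(3, "affine")$lam_chain, 3)
  expect_equal(uniaxial_kinematics(3, "eightchain")$lam_chain,
               sqrt((9 + 2 / 3) / 3))
  expect_lt(uniaxial_kinematics(3, "eightchain")$lam_chain, 3)
})

test_that("neutral energy matches the frozen high-precision transcription", {
  # 30-digit independent evaluation of the two-invariant energy,
  # mu = 10, alpha = 0.5
  frozen <- c(`1.5` = 2.1650218700243019, `3` = 240.42581505916297,
              `6` = 122384793.44802201)
  for (L in names(frozen)) {
    got <- neutral_energy(uniaxial_kinematics(as.numeric(L)), 10, 0.5)
    expect_equal(got, unname(frozen[L]), tolerance = 1e-12)
  }
})

test_that("neutral energy vanishes at the identity and scales linearly in mu", {
  expect_equal(neutral_energy(uniaxial_kinematics(1), 10, 0.5), 0,
               tolerance = 1e-12)
  st <- uniaxial_kinematics(2.5)
  expect_equal(neutral_energy(st, 8, 0.7), 2 * neutral_energy(st, 4, 0.7),
               tolerance = 1e-12)
})

test_that("neutral stress contribution is zero at the identity and matches a
           finite difference elsewhere", {
  dpsi <- dnhfit:::.dneutral_dLambda
  expect_equal(dpsi(uniaxial_kinematics(1), 5, 0.8), 0, tolerance = 1e-12)
  for (L in c(1.3, 2, 4)) {
    h <- 1e-6 * L
    fd <- (neutral_energy(uniaxial_kinematics(L + h), 5, 0.8) -
             neutral_energy(uniaxial_kinematics(L - h), 5, 0.8)) / (2 * h)
    expect_equal(dpsi(uniaxial_kinematics(L), 5, 0.8), fd, tolerance = 1e-7)
  }
})

test_that("total energy is the plain sum of network contributions", {
  ctrl <- dnh_control()
  st <- uniaxial_kinematics(2.5)
  dmg <- damage_state(st$lam_chain)
  # switching off the polyelectrolyte network leaves the neutral energy
  p0 <- dnh_params(n_max = 20, r_bar = 2, kappa = 2, N_P = 0, nu = 1.05,
                   E = 0, mu = 1.3, alpha = 0.05)
  expect_equal(total_energy(st, dmg, p0, ctrl),
               neutral_energy(st, p0$mu, p0$alpha), tolerance = 1e-12)
  # generic set: total = polyelectrolyte + neutral, no coupling
  p <- dnh_default_params()
  psiP <- polyelectrolyte_energy(st$lam_chain, dmg$lam_max, p$n_max, p$r_bar,
                                 p$kappa, p$N_P, p$nu, p$E)
  expect_equal(total_energy(st, dmg, p, ctrl),
               psiP + neutral_energy(st, p$mu, p$alpha), tolerance = 1e-12)
})

test_that("reference state is in equilibrium on the virgin path", {
  p <- dnh_default_params()
  scale <- p$N_P + p$E + p$mu
  expect_lt(abs(nominal_stress(1, damage_state(1), p)), 1e-8 * scale)
})

test_that("analytic stress agrees with the central finite difference of the
           total energy at frozen damage", {
  ctrl <- dnh_control()
  for (p in list(dnh_default_params(), fixture_params(kappa = 1.4, mu = 0.5),
                 fixture_params(r_bar = 1.5, n_max = 30))) {
    for (L in c(1.05, 1.7, 3, 5.5, 8)) {
      dmg <- virgin_damage(L)
      h <- 1e-5 * max(1, L)
      fd <- (total_energy(uniaxial_kinematics(L + h), dmg, p, ctrl) -
               total_energy(uniaxial_kinematics(L - h), dmg, p, ctrl)) / (2 * h)
      an <- nominal_stress(L, dmg, p, ctrl)
      expect_equal(an, fd, tolerance = 1e-6)
    }
  }
})

test_that("stress also matches the finite difference on unloaded (damaged) states", {
  ctrl <- dnh_control()
  p <- dnh_default_params()
  dmg <- virgin_damage(6)   # history from a cycle to Lambda = 6
  for (L in c(1.5, 2.5, 4)) {  # all below the damage stretch
    h <- 1e-5 * L
    fd <- (total_energy(uniaxial_kinematics(L + h), dmg, p, ctrl) -
             total_energy(uniaxial_kinematics(L - h), dmg, p, ctrl)) / (2 * h)
    expect_equal(nominal_stress(L, dmg, p, ctrl), fd, tolerance = 1e-6)
  }
})

test_that("reloading below the historical maximum is softer than the virgin path", {
  p <- dnh_default_params()
  virgin <- nominal_stress(1.5, virgin_damage(1.5), p)
  reloaded <- nominal_stress(1.5, virgin_damage(3), p)
  expect_lte(reloaded, virgin)
  expect_lt(reloaded, 0.95 * virgin)   # softening is substantial, not marginal
})

test_that("virgin uniaxial stress is non-negative and non-decreasing (J/S shape)", {
  p <- dnh_default_params()
  L <- c(1, 1.05, 1.2, 1.5, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  s <- dnh_simulate(p, loading_program(10, points_per_segment = 60))$stress
  expect_true(all(s >= -1e-9))
  expect_true(all(diff(s) > -1e-9))
  expect_gt(nominal_stress(10, virgin_damage(10), p),
            nominal_stress(5, virgin_damage(5), p))
})

test_that("damage state is a max-accumulator", {
  d <- damage_state(2)
  st3 <- uniaxial_kinematics(3, "affine")
  st2 <- uniaxial_kinematics(2, "affine")
  expect_equal(update_damage(d, st3)$lam_max, 3)
  expect_equal(update_damage(damage_state(3), st2)$lam_max, 3)
  # monotone non-decreasing along an arbitrary program
  path <- c(1, 2, 1.5, 3, 2, 2.8, 4, 1)
  d <- damage_state(1)
  trace <- numeric(0)
  for (L in path) {
    d <- update_damage(d, uniaxial_kinematics(L, "affine"))
    trace <- c(trace, d$lam_max)
  }
  expect_true(all(diff(trace) >= 0))
  expect_equal(max(trace), 4)
})
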