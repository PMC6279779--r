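test_that("Debye length matches the closed form and the textbook constant", {
  expect_equal(debye_length(electrolyte_spec(0.1, 298, 78.5)), 0.96,
               tolerance = 0.01)
  expect_equal(debye_length(electrolyte_spec(0.05, 298, 78.5)), 1.36,
               tolerance = 0.01)
  # 0.304 nm / sqrt(c) at 298 K, eps_r 78.5, within 0.5%
  for (c0 in c(0.001, 0.01, 0.15, 1)) {
    expect_equal(debye_length(electrolyte_spec(c0)), 0.304 / sqrt(c0),
                 tolerance = 0.005)
  }
  # exact square-root scaling
  expect_equal(debye_length(electrolyte_spec(0.2)),
               debye_length(electrolyte_spec(0.05)) / 2, tolerance = 1e-12)
  expect_error(electrolyte_spec(-1), "c0")
  expect_equal(thermal_voltage_mV(electrolyte_spec(0.05, 298)), 25.7,
               tolerance = 0.005)
})

test_that("Gouy-Chapman profile is exact at zero and in the linear limit", {
  spec <- electrolyte_spec(0.1)
  z <- seq(0, 5, by = 0.1)
  expect_equal(gouy_chapman_potential(0, spec, z), rep(0, length(z)))
  # linearized Debye-Hueckel limit at small wall potential
  psi <- gouy_chapman_potential(0.1, spec, z)
  expect_equal(psi / 0.1, exp(-z / debye_length(spec)), tolerance = 0.01)
  # direct evaluation at one Debye length for a strongly charged wall
  lD <- debye_length(spec)
  expect_equal(gouy_chapman_potential(4, spec, lD),
               4 * atanh(tanh(1) * exp(-1)), tolerance = 1e-12)
})

test_that("uncharged walls give the trivial PB solution", {
  sol <- solve_pb_gap(electrolyte_spec(0.05), 3, c(0, 0))
  expect_true(all(abs(sol$psi) < 1e-12))
  expect_equal(sol$c_plus, rep(0.05, length(sol$z)), tolerance = 1e-12)
  expect_equal(sol$c_minus, rep(0.05, length(sol$z)), tolerance = 1e-12)
})

test_that("PB solution obeys boundary values and the Boltzmann relation", {
  spec <- electrolyte_spec(0.05)
  sol <- solve_pb_gap(spec, 3, c(1.1, -0.7))
  expect_equal(sol$psi[1], 1.1, tolerance = 1e-10)
  expect_equal(sol$psi[length(sol$psi)], -0.7, tolerance = 1e-10)
  expect_equal(sol$c_plus, spec$c0 * exp(-sol$psi), tolerance = 1e-9)
  expect_equal(sol$c_minus, spec$c0 * exp(sol$psi), tolerance = 1e-9)
  expect_lt(sol$residual, 1e-8)
})

test_that("well-separated walls superpose onto the single-plane solution", {
  spec <- electrolyte_spec(0.05)
  lD <- debye_length(spec)
  sol <- solve_pb_gap(spec, 20 * lD, c(1.1, 1.1), n_grid = 2001)
  mid <- sol$psi[1001]
  expect_lt(abs(mid - 2 * gouy_chapman_potential(1.1, spec, 10 * lD)), 1e-4)
  # pointwise agreement with the analytic half-space profile near one wall
  near <- sol$z <= 4 * lD
  expect_lt(max(abs(
    sol$psi[near] - gouy_chapman_potential(1.1, spec, sol$z[near]) -
      gouy_chapman_potential(1.1, spec, 20 * lD - sol$z[near]))), 1e-4)
})

test_that("small-potential PB solutions match the linearized closed form", {
  spec <- electrolyte_spec(0.05)
  lD <- debye_length(spec)
  sol <- solve_pb_gap(spec, 3, c(0.1, 0.1), n_grid = 1001)
  x <- sol$z / lD
  L <- 3 / lD
  lin <- (0.1 * sinh(L - x) + 0.1 * sinh(x)) / sinh(L)
  expect_equal(sol$psi, lin, tolerance = 0.01)
})

test_that("grid refinement is converged at the midpoint", {
  spec <- electrolyte_spec(0.05)
  a <- solve_pb_gap(spec, 3, c(1.1, 1.1), n_grid = 2001)$psi[1001]
  b <- solve_pb_gap(spec, 3, c(1.1, 1.1), n_grid = 4001)$psi[2001]
  expect_lt(abs(a - b), 1e-6)
})

test_that("ionic space charge balances the wall surface charge", {
  spec <- electrolyte_spec(0.05)
  for (walls in list(c(1.1, 1.1), c(3, 3), c(2, -1))) {
    sol <- solve_pb_gap(spec, 4, walls, n_grid = 2001)
    expect_lt(gap_charge_balance(sol)$imbalance, 1e-3)
  }
})

test_that("strongly charged walls converge via continuation", {
  spec <- electrolyte_spec(0.05)
  sol <- solve_pb_gap(spec, 3, c(15, 15), n_grid = 1501)
  expect_equal(sol$psi[1], 15, tolerance = 1e-9)
  expect_true(all(diff(sol$psi[1:750]) < 1e-9))  # monotone decay to midgap
  expect_error(solve_pb_gap(spec, 3, c(25, 0)), "validated range")
})

test_that("the confined 50 mM gap keeps a field and depletes cations", {
  spec <- electrolyte_spec(0.05)  # Debye length 1.36 nm
  sol <- solve_pb_gap(spec, 3, c(1.1, 1.1))
  mid <- sol$psi[ceiling(length(sol$psi) / 2)]
  expect_gt(mid, 0.3)                      # potential persists across the gap
  expect_lt(min(sol$c_plus), spec$c0)      # cations depleted
  expect_gt(max(sol$c_minus), spec$c0)     # anions accumulated
  dep <- depletion_summary(sol)
  expect_equal(dep$c_plus_min, spec$c0 * exp(-1.1), tolerance = 0.01)
  expect_true(dep$z_min %in% range(sol$z)) # positive walls: minimum at walls
})

test_that("depletion summaries follow the Boltzmann factor at the walls", {
  spec <- electrolyte_spec(0.05)
  sol0 <- solve_pb_gap(spec, 3, c(0, 0))
  expect_equal(depletion_summary(sol0)$c_plus_min, 0.05, tolerance = 1e-9)
  sol3 <- solve_pb_gap(spec, 3, c(3, 3))
  expect_equal(depletion_summary(sol3)$c_plus_min, 0.05 * exp(-3),
               tolerance = 0.01)
})
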