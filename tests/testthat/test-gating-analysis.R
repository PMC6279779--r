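test_that("fits group exactly by potentials at 1 mV resolution", {
  fits <- c(lapply(rnorm(80, 3.5, 0.3), fake_fit, U_P = 0.45, U_S = 0.25),
            lapply(rnorm(80, 3.4, 0.3), fake_fit, U_P = 0.35, U_S = 0.15))
  g <- group_by_condition(fits)
  expect_length(g, 2L)
  expect_identical(unname(lengths(g)), c(80L, 80L))

  # 0.1 mV apart lands in the same group
  f2 <- c(lapply(1:3, function(i) fake_fit(3, U_P = 0.45, U_S = 0.25)),
          lapply(1:3, function(i) fake_fit(3, U_P = 0.45001, U_S = 0.25)))
  expect_length(group_by_condition(f2), 1L)

  bad <- c(fits[1:3], list(fake_fit(3, U_P = 0.45, U_S = NA)))
  expect_error(group_by_condition(bad), "missing electrode potentials")
})

test_that("gating series aggregates by gate at constant bias", {
  set.seed(42)
  gates <- seq(-0.45, -0.05, by = 0.05)
  fits <- unlist(lapply(gates, function(Vg)
    lapply(rnorm(10, beta_at_gate(gating_model(), Vg), 0.01), fake_fit,
           U_P = -Vg + 0.2, U_S = -Vg)), recursive = FALSE)
  ser <- gating_series(group_by_condition(fits))
  expect_identical(nrow(ser$series), 9L)
  expect_equal(ser$bias, 0.2)
  expect_equal(ser$series$gate, gates)
  expect_true(all(ser$series$n == 10))
  mn <- find_gate_minimum(ser)
  expect_true(mn$found)
  expect_equal(mn$Vg_min, -0.25, tolerance = 0.005)
  expect_equal(mn$beta_min, 0.5, tolerance = 0.02)

  mixed <- c(fits[1:20], list(fake_fit(3, U_P = 0.9, U_S = 0.25)),
             list(fake_fit(3, U_P = 0.9, U_S = 0.25)))
  expect_error(gating_series(group_by_condition(mixed)), "mixed bias")
})

test_that("degenerate single-value groups give zero spread", {
  fits <- unlist(lapply(c(-0.3, -0.2), function(Vg)
    lapply(1:4, function(i) fake_fit(2, U_P = -Vg + 0.2, U_S = -Vg))),
    recursive = FALSE)
  ser <- gating_series(group_by_condition(fits))
  expect_true(all(ser$series$beta_sd == 0))
})

test_that("noiseless model-evaluated series pinpoints the resonance", {
  gates <- seq(-0.40, -0.10, by = 0.05)
  fits <- unlist(lapply(gates, function(Vg)
    lapply(1:2, function(i)
      fake_fit(beta_at_gate(gating_model(), Vg), U_P = -Vg + 0.2,
               U_S = -Vg))), recursive = FALSE)
  ser <- gating_series(group_by_condition(fits))
  mn <- find_gate_minimum(ser)
  expect_equal(mn$Vg_min, -0.25, tolerance = 1e-3)
  expect_equal(mn$beta_min, 0.5, tolerance = 0.01)
  expect_false(mn$edge)
})

test_that("a symmetric parabola yields its exact vertex", {
  xs <- c(-0.3, -0.25, -0.2)
  ys <- 2 + 30 * (xs + 0.25)^2
  fits <- unlist(lapply(seq_along(xs), function(i)
    lapply(1:2, function(j) fake_fit(ys[i], U_P = -xs[i] + 0.2,
                                     U_S = -xs[i]))), recursive = FALSE)
  mn <- find_gate_minimum(gating_series(group_by_condition(fits)))
  expect_equal(mn$Vg_min, -0.25, tolerance = 1e-12)
  expect_equal(mn$beta_min, 2, tolerance = 1e-12)
})

test_that("monotone series fall back to an edge-flagged argmin", {
  fits <- unlist(lapply(1:4, function(i)
    lapply(1:2, function(j) fake_fit(i, U_P = 0.2 - i / 10,
                                     U_S = -i / 10))), recursive = FALSE)
  mn <- find_gate_minimum(gating_series(group_by_condition(fits)))
  expect_true(mn$edge)
  expect_equal(mn$beta_min, 1)
})

test_that("flat series report no minimum rather than a spurious one", {
  set.seed(1)
  fits <- unlist(lapply(1:5, function(i)
    lapply(rnorm(6, 3.5, 0.4), fake_fit, U_P = 0.2 - i / 10,
           U_S = -i / 10)), recursive = FALSE)
  mn <- find_gate_minimum(gating_series(group_by_condition(fits)))
  expect_false(mn$found)
  expect_true(is.na(mn$beta_min))
})

test_that("on/off ratios divide the ensemble means with propagated spread", {
  fits <- unlist(lapply(c(-0.25, -0.15), function(Vg)
    lapply(if (Vg == -0.25) c(0.49, 0.5, 0.51) else c(3.48, 3.49, 3.50),
           fake_fit, U_P = -Vg + 0.2, U_S = -Vg)), recursive = FALSE)
  ser <- gating_series(group_by_condition(fits))
  r <- on_off_ratio(ser, Vg_on = -0.25, Vg_off = -0.15)
  expect_equal(r$ratio, 3.49 / 0.5, tolerance = 1e-3)
  expect_gt(r$sd, 0)
  expect_equal(on_off_ratio(ser, -0.25, -0.25)$ratio, 1)
  expect_error(on_off_ratio(ser, -0.25, -0.4), "not present")
})

test_that("the model's own well reproduces the printed on/off scale", {
  m <- gating_model()
  expect_equal(beta_at_gate(m, -0.15) / beta_at_gate(m, -0.25), 6.98,
               tolerance = 0.01)
})

test_that("absolute energy scale is affine, order-reversing and anchored", {
  expect_equal(absolute_energy(0), -4.6)
  expect_equal(absolute_energy(0.35), -4.95)  # hCc midpoint
  expect_equal(absolute_energy(0.28), -4.88)  # pCc1 midpoint
  U <- seq(-1, 1, by = 0.25)
  E <- absolute_energy(U)
  expect_true(all(diff(E) < 0))
  expect_equal(diff(E) / diff(U), rep(-1, length(U) - 1))
})

test_that("current ratios follow the two-exponential closed form", {
  expect_equal(current_ratio_at(0, 0.5, 2.8), 1)
  expect_equal(current_ratio_at(1, 0.5, 2.8), 10, tolerance = 0.005)
  expect_equal(current_ratio_at(1, 2, 2), 1)
  expect_error(current_ratio_at(-1, 0.5, 2.8), ">= 0")
})
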