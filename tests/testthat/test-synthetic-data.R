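test_that("gate-dependent beta follows the resonance well", {
  m <- gating_model()  # beta_off 3.5, beta_min 0.5, V0 -0.25, width 0.03
  expect_equal(beta_at_gate(m, -0.25), 0.5)
  # closed form away from resonance, evaluated independently
  expect_equal(beta_at_gate(m, -0.15),
               3.5 - 3 * exp(-0.1^2 / (2 * 0.03^2)), tolerance = 1e-12)
  expect_equal(round(beta_at_gate(m, -0.15), 2), 3.49)
  off <- gating_model(active = FALSE)
  expect_equal(beta_at_gate(off, c(-0.4, -0.25, 0.1)), rep(3.5, 3))
})

test_that("noiseless generation reproduces the closed-form current exactly", {
  p <- sim_preset(beta_mean = 9, noise_mult_sigma = 0, noise_add_sigma = 0)
  cv <- make_retraction_curve(p, seed = 1)
  expect_equal(cv$I, 2e-12 + (0.4e-9 - 2e-12) * exp(-9 * cv$z),
               tolerance = 1e-12)
  expect_identical(length(cv$z), 1024L)
  expect_equal(max(cv$z), 15)
})

test_that("a noiseless bare-gold curve crosses 10 pA well under 1 nm", {
  p <- sim_preset(beta_mean = 9, leakage = 1e-15,
                  noise_mult_sigma = 0, noise_add_sigma = 0)
  cv <- make_retraction_curve(p, seed = 1)
  z10 <- cv$z[which(cv$I < 10e-12)[1]]
  expect_lt(z10, 1)
  expect_equal(z10, crossing_z(10e-12, 9, leak = 1e-15), tolerance = 0.05)
  expect_equal(z10, 0.41, tolerance = 0.05)
})

test_that("fixed seeds give bit-identical ensembles", {
  p <- ects_preset("bare_gold")
  a <- make_curve_set(p, n = 10, seed = 7)
  b <- make_curve_set(p, n = 10, seed = 7)
  expect_identical(a$curves, b$curves)
  c2 <- make_curve_set(p, n = 10, seed = 8)
  expect_false(identical(a$curves, c2$curves))
})

test_that("generated currents respect the floor and the amplifier ceiling", {
  for (nm in c("bare_gold", "pCc1_hCc", "pure_water")) {
    cs <- make_curve_set(ects_preset(nm), n = 8, seed = 3)
    for (cv in cs$curves) {
      expect_true(all(cv$I >= 0))
      expect_true(all(cv$I <= 10e-9))
    }
  }
})

test_that("ensemble metadata and geometry match the preset", {
  cs <- make_curve_set(ects_preset("pCc1_hCc"), n = 12, seed = 2)
  expect_length(cs$curves, 12L)
  expect_true(all(vapply(cs$curves, function(cv)
    cv$condition == "pCc1-hCc", logical(1))))
  ap <- make_curve_set(ects_preset("approach"), n = 3, seed = 2)
  expect_identical(ap[[1]]$mode, "approach")
  expect_length(ap[[1]]$z, 4096L)
  expect_equal(max(ap[[1]]$z), 100)
})

test_that("noiseless round trip recovers the generative decay factor", {
  for (beta in c(1.5, 3, 9)) {
    p <- sim_preset(beta_mean = beta, noise_mult_sigma = 0,
                    noise_add_sigma = 0)
    f <- fit_decay(make_retraction_curve(p, seed = 1))
    expect_equal(f$beta, beta, tolerance = 1e-6)
  }
})

test_that("noisy ensembles recover the generative mean within 2 SE", {
  for (nm in c("bare_gold", "inhibited")) {
    p <- ects_preset(nm)
    s <- summarize_beta(fit_decay_set(make_curve_set(p, 150, seed = 11)))
    target <- truncnorm_mean(p$beta_mean, p$beta_sd)
    expect_lt(abs(s$mean - target), 2 * s$sd / sqrt(s$n))
  }
})

test_that("gating datasets are keyed by gate with consistent potentials", {
  ds <- make_gating_dataset(gating_model(), gates = c(-0.3, -0.25, -0.2),
                            n_per_gate = 3, preset = ects_preset("gated"),
                            seed = 4)
  expect_named(ds, c("-0.3", "-0.25", "-0.2"))
  cv <- ds[["-0.25"]][[1]]
  expect_equal(cv$U_S, 0.25)
  expect_equal(cv$U_bias, 0.2)
  expect_error(make_gating_dataset(gating_model(), numeric(0), 3,
                                   ects_preset("gated")), "non-empty")
  expect_error(make_gating_dataset(gating_model(), -0.25, 1,
                                   ects_preset("gated")), ">= 2")
})

test_that("zero-dispersion noiseless gating gives exactly the well minimum", {
  p <- ects_preset("gated", beta_sd = 0, noise_mult_sigma = 0,
                   noise_add_sigma = 0)
  ds <- make_gating_dataset(gating_model(), gates = -0.25, n_per_gate = 3,
                            preset = p, seed = 1)
  betas <- vapply(fit_decay_set(ds[[1]]), `[[`, numeric(1), "beta")
  expect_equal(betas, rep(0.5, 3), tolerance = 1e-6)
})

test_that("an inactive gating model yields a flat fitted series", {
  p <- ects_preset("gated", gating = gating_model(active = FALSE),
                   beta_sd = 0.1)
  ds <- make_gating_dataset(gating_model(active = FALSE),
                            gates = seq(-0.45, -0.05, by = 0.1),
                            n_per_gate = 12, preset = p, seed = 9,
                            bias = 0.5)
  fits <- unlist(lapply(ds, fit_decay_set), recursive = FALSE)
  ser <- gating_series(group_by_condition(fits))
  expect_lt(diff(range(ser$series$beta_mean)), 0.2)
  expect_false(find_gate_minimum(ser)$found)
})

test_that("preset validation rejects inconsistent physics", {
  expect_error(sim_preset(beta_mean = -1), "beta_mean")
  expect_error(sim_preset(beta_mean = 9, leakage = 1e-9), "leakage")
  expect_error(sim_preset(beta_mean = 9, n_points = 8), "n_points")
  expect_error(ects_preset("bare_gold", nonsense = 1), "unknown preset field")
  expect_error(make_curve_set(ects_preset("bare_gold"), n = 0), ">= 1")
})
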