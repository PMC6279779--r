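# Shared oracles and fixture builders, independent of the code paths they
# check.

# Mean of a Normal(mu, sd) truncated below at `lo` (closed form). This is the
# true mean of the generator's curve-level beta draws.
truncnorm_mean <- function(mu, sd, lo = 0.05) {
  if (sd == 0) return(max(mu, lo))
  a <- (lo - mu) / sd
  mu + sd * dnorm(a) / (1 - pnorm(a))
}

# Closed-form z at which a noiseless curve I = leak + (sp - leak) exp(-b z)
# crosses current level `I_level`.
crossing_z <- function(I_level, beta, set_point = 0.4e-9, leak = 2e-12) {
  log((set_point - leak) / (I_level - leak)) / beta
}

# Build a noiseless single-exponential iz_curve directly (no generator).
exp_curve <- function(beta, leak = 2e-12, set_point = 0.4e-9, z_span = 15,
                      n = 256, ...) {
  z <- seq(0, z_span, length.out = n)
  iz_curve(z, leak + (set_point - leak) * exp(-beta * z),
           set_point = set_point, ...)
}

# A minimal hand-built decay_fit for tests of the gating aggregation layer.
fake_fit <- function(beta, U_P = NA_real_, U_S = NA_real_,
                     flags = c(too_few_points = FALSE,
                               saturated_start = FALSE,
                               leakage_dominated = FALSE,
                               dropped_points = FALSE)) {
  structure(list(beta = beta, I0 = 0.4e-9, leakage_est = 2e-12,
                 window = c(start = 1, end = 100), r2 = 0.99, flags = flags,
                 condition = "test", U_P = U_P, U_S = U_S,
                 mode = "retraction"),
            class = "decay_fit")
}
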