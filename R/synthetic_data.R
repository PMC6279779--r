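# Forward model of an ECTS I-z acquisition. The ideal current is
#   I*(z) = leakage + (set_point - leakage) * exp(-B(z)),
# with B(z) = beta * z for a constant decay factor, or the cumulative
# integral of the position-dependent slope derived from an oscillating local
# barrier profile. Per-point measurement averages `samples_per_point` noisy
# draws (lognormal multiplicative x additive Gaussian) and clips to
# [0, saturation], mimicking the preamplifier.

#' Simulation preset for the I-z forward model
#'
#' Bundles generative and acquisition parameters for one experimental
#' condition. Defaults reproduce the standard retraction acquisition: 0.4 nA
#' set point, 10 nA amplifier saturation, 2 pA faradaic leakage floor, 15 nm
#' retraction sampled at 1024 points with 20 averaged samples per point.
#'
#' @param beta_mean Generative distance decay factor, nm^-1 (> 0).
#' @param beta_sd Curve-to-curve Gaussian spread of beta, nm^-1 (>= 0);
#'   draws are truncated below at 0.05 nm^-1.
#' @param leakage Distance-independent faradaic leakage current, A.
#' @param set_point Initial feedback current, A.
#' @param saturation Preamplifier saturation current, A.
#' @param z_span Piezo travel, nm.
#' @param n_points Number of recorded points (>= 16).
#' @param samples_per_point Averaged raw samples per recorded point.
#' @param noise_mult_sigma Sigma of the lognormal multiplicative noise on I.
#' @param noise_add_sigma SD of additive current noise, A.
#' @param oscillation Optional [oscillation_spec()] for a spatially
#'   oscillating local barrier.
#' @param gating Optional [gating_model()]; when present, each curve's beta is
#'   centred on [beta_at_gate()] at the preset's gate potential.
#' @param mode `"retraction"` or `"approach"`.
#' @param condition Condition label stamped into curve metadata.
#' @param U_P,U_S Probe and sample potentials, V vs SSC.
#' @param speed Piezo speed, nm/s.
#' @return An object of class `sim_preset`.
#' @export
sim_preset <- function(beta_mean, beta_sd = 0,
                       leakage = 2e-12, set_point = 0.4e-9,
                       saturation = 10e-9, z_span = 15, n_points = 1024L,
                       samples_per_point = 20L,
                       noise_mult_sigma = 0.15, noise_add_sigma = 0.5e-12,
                       oscillation = NULL, gating = NULL,
                       mode = "retraction", condition = "unknown",
                       U_P = 0.6, U_S = -0.2, speed = 12) {
  p <- structure(
    list(beta_mean = beta_mean, beta_sd = beta_sd, leakage = leakage,
         set_point = set_point, saturation = saturation, z_span = z_span,
         n_points = as.integer(n_points),
         samples_per_point = as.integer(samples_per_point),
         noise_mult_sigma = noise_mult_sigma,
         noise_add_sigma = noise_add_sigma,
         oscillation = oscillation, gating = gating,
         mode = match.arg(mode, c("retraction", "approach")),
         condition = condition, U_P = U_P, U_S = U_S, speed = speed),
    class = "sim_preset")
  validate_sim_preset(p)
  p
}

validate_sim_preset <- function(p) {
  if (!inherits(p, "sim_preset")) stop("not a sim_preset", call. = FALSE)
  if (!is.numeric(p$beta_mean) || p$beta_mean <= 0)
    stop("invalid preset: beta_mean must be > 0", call. = FALSE)
  if (p$beta_sd < 0) stop("invalid preset: beta_sd must be >= 0",
                          call. = FALSE)
  if (!(p$leakage > 0 && p$leakage < p$set_point &&
        p$set_point < p$saturation))
    stop("invalid preset: need 0 < leakage < set_point < saturation",
         call. = FALSE)
  if (p$n_points < 16L) stop("invalid preset: n_points must be >= 16",
                             call. = FALSE)
  if (p$z_span <= 0) stop("invalid preset: z_span must be > 0",
                          call. = FALSE)
  if (p$samples_per_point < 1L)
    stop("invalid preset: samples_per_point must be >= 1", call. = FALSE)
  invisible(p)
}

#' Oscillating local-barrier specification
#'
#' Describes a cosine modulation of the local tunneling barrier between
#' `phi_low` and `phi_high` with spatial period `period`, as produced by
#' discrete water layers in the gap.
#'
#' @param period Spatial period, nm (> 0). Default 0.35 nm, the diameter of a
#'   water molecule.
#' @param phi_low,phi_high Barrier range, eV (0 <= phi_low < phi_high).
#' @return An object of class `oscillation_spec`.
#' @export
oscillation_spec <- function(period = 0.35, phi_low = 0.5, phi_high = 1.2) {
  if (period <= 0) stop("period must be > 0", call. = FALSE)
  if (!(phi_low >= 0 && phi_low < phi_high))
    stop("need 0 <= phi_low < phi_high", call. = FALSE)
  structure(list(period = period, phi_low = phi_low, phi_high = phi_high),
            class = "oscillation_spec")
}

#' Electrochemical gating model for the decay factor
#'
#' Gaussian resonance well: away from the resonance gate potential the decay
#' factor sits at `beta_off`; at `V0` it dips to `beta_min`:
#' \deqn{\beta(V_g) = \beta_{off} - (\beta_{off} - \beta_{min})
#'   \exp\left(-\frac{(V_g - V_0)^2}{2 w^2}\right).}
#' With `active = FALSE` (large bias, probe far from the redox midpoints) the
#' model returns `beta_off` at every gate.
#'
#' Defaults put the well minimum at -0.25 V gate potential with
#' `beta_min = 0.5` nm^-1 and an off-resonance plateau of 3.5 nm^-1, and carry
#' the midpoint redox potentials of cytochrome c1 (0.28 V) and cytochrome c
#' (0.35 V vs SSC) as reference constants.
#'
#' @param beta_off Off-resonance decay factor, nm^-1.
#' @param beta_min Decay factor at resonance, nm^-1 (`0 < beta_min < beta_off`).
#' @param V0 Resonance gate potential, V.
#' @param width Well width, V (> 0).
#' @param E0_pCc1,E0_hCc Midpoint redox potentials, V vs SSC.
#' @param active If `FALSE`, gating is switched off and `beta_off` applies
#'   everywhere.
#' @return An object of class `gating_model`.
#' @export
gating_model <- function(beta_off = 3.5, beta_min = 0.5, V0 = -0.25,
                         width = 0.03, E0_pCc1 = 0.28, E0_hCc = 0.35,
                         active = TRUE) {
  if (!(beta_off > beta_min && beta_min > 0))
    stop("need beta_off > beta_min > 0", call. = FALSE)
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  structure(list(beta_off = beta_off, beta_min = beta_min, V0 = V0,
                 width = width, E0_pCc1 = E0_pCc1, E0_hCc = E0_hCc,
                 active = isTRUE(active)),
            class = "gating_model")
}

#' Decay factor at a given electrochemical gate potential
#'
#' Evaluates the Gaussian resonance well of a [gating_model()]. Vectorised
#' over `Vg`.
#'
#' @param model A [gating_model()].
#' @param Vg Gate potential(s), V.
#' @return Decay factor(s), nm^-1.
#' @export
#' @examples
#' m <- gating_model()
#' beta_at_gate(m, -0.25)  # 0.5 at the well minimum
beta_at_gate <- function(model, Vg) {
  stopifnot(inherits(model, "gating_model"))
  if (!model$active) return(rep(model$beta_off, length(Vg)))
  model$beta_off - (model$beta_off - model$beta_min) *
    exp(-(Vg - model$V0)^2 / (2 * model$width^2))
}

# Cosine barrier profile (eV) at positions z for an oscillation_spec.
.phi_profile <- function(osc, z) {
  mid <- (osc$phi_high + osc$phi_low) / 2
  amp <- (osc$phi_high - osc$phi_low) / 2
  mid + amp * cos(2 * pi * z / osc$period)
}

# Cumulative decay exponent B(z) such that d(B)/dz = beta_eff(z). For an
# oscillating barrier beta_eff(z) = slope_from_barrier(phi(z)); the cosine
# integral is done on the curve's own grid by the trapezoidal rule, which at
# 1024 points over a few nm is exact to well below measurement noise.
.decay_exponent <- function(preset, beta, z) {
  if (is.null(preset$oscillation)) return(beta * z)
  be <- slope_from_barrier(.phi_profile(preset$oscillation, z))
  c(0, cumsum((be[-1L] + be[-length(be)]) / 2 * diff(z)))
}

.MIN_BETA <- 0.05  # nm^-1, truncation of beta draws (non-decaying guard)

.draw_beta <- function(preset, gate = NULL) {
  centre <- if (!is.null(preset$gating) && !is.null(gate))
    beta_at_gate(preset$gating, gate) else preset$beta_mean
  if (preset$beta_sd == 0) return(max(centre, .MIN_BETA))
  repeat {
    b <- stats::rnorm(1L, centre, preset$beta_sd)
    if (b > .MIN_BETA) return(b)
  }
}

#' Simulate one I-z curve
#'
#' Draws a curve-level decay factor from the preset's Gaussian (truncated at
#' 0.05 nm^-1), evaluates the ideal exponential current between the leakage
#' floor and the set point, applies per-sample lognormal multiplicative and
#' Gaussian additive noise, averages `samples_per_point` samples per recorded
#' point and clips to `[0, saturation]`.
#'
#' @param preset A [sim_preset()].
#' @param seed RNG seed (integer) for reproducibility; `NULL` uses the current
#'   RNG state.
#' @param gate Optional gate potential, V, routed to the preset's
#'   [gating_model()] if one is attached.
#' @return An [iz_curve()] with metadata filled from the preset.
#' @export
#' @examples
#' cv <- make_retraction_curve(sim_preset(beta_mean = 9), seed = 1)
make_retraction_curve <- function(preset, seed = NULL, gate = NULL) {
  validate_sim_preset(preset)
  if (!is.null(seed)) set.seed(as.integer(seed))
  z <- seq(0, preset$z_span, length.out = preset$n_points)
  beta <- .draw_beta(preset, gate)
  ideal <- preset$leakage +
    (preset$set_point - preset$leakage) * exp(-.decay_exponent(preset, beta, z))
  n <- preset$n_points; k <- preset$samples_per_point
  if (preset$noise_mult_sigma == 0 && preset$noise_add_sigma == 0) {
    I <- ideal
  } else {
    mult <- matrix(stats::rlnorm(n * k, 0, preset$noise_mult_sigma), n, k)
    add <- matrix(stats::rnorm(n * k, 0, preset$noise_add_sigma), n, k)
    I <- rowMeans(ideal * mult + add)
  }
  I <- pmin(pmax(I, 0), preset$saturation)
  iz_curve(z, I, U_P = preset$U_P, U_S = preset$U_S, mode = preset$mode,
           condition = preset$condition, speed = preset$speed,
           set_point = preset$set_point, validate = FALSE)
}

# Deterministic child seed stream (kept below 2^31-1).
.child_seed <- function(seed, i) {
  (as.numeric(seed) %% 65521) * 32749 + 104729 + i
}

#' Simulate an ensemble of I-z curves
#'
#' Generates `n` independent curves with child seeds derived deterministically
#' from `seed`, so a fixed seed yields a bit-identical ensemble.
#'
#' @param preset A [sim_preset()].
#' @param n Number of curves (>= 1).
#' @param seed Integer master seed.
#' @param gate Optional gate potential forwarded per curve.
#' @return A [curve_set()]; provenance records the preset, seed and gate.
#' @export
#' @examples
#' cs <- make_curve_set(sim_preset(beta_mean = 9, beta_sd = 2,
#'                                 condition = "bare_gold"),
#'                      n = 5, seed = 1)
make_curve_set <- function(preset, n, seed = 1L, gate = NULL) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  validate_sim_preset(preset)
  n <- as.integer(n)
  curves <- lapply(seq_len(n), function(i)
    make_retraction_curve(preset, seed = .child_seed(seed, i), gate = gate))
  curve_set(curves,
            provenance = list(preset = unclass(preset), seed = seed,
                              gate = gate, n = n),
            validate = FALSE)
}

#' Simulate a full electrochemical gating dataset
#'
#' One [curve_set()] per gate potential, each with curve-level beta centred on
#' [beta_at_gate()] and spread `preset$beta_sd`. Curve metadata carries
#' `U_S = -Vg` and `U_P = U_S + bias` so the ensemble is consistent with a
#' constant-bias acquisition under the package's default gate mapping
#' `Vg = -U_S`.
#'
#' @param model A [gating_model()].
#' @param gates Non-empty numeric vector of gate potentials, V.
#' @param n_per_gate Curves per gate (>= 2).
#' @param preset Acquisition [sim_preset()] (its `beta_mean` is overridden per
#'   gate by the model).
#' @param seed Integer master seed.
#' @param bias Constant bias `U_P - U_S`, V (default 0.2).
#' @return Named list mapping each gate (formatted in volts) to a
#'   [curve_set()].
#' @export
make_gating_dataset <- function(model, gates, n_per_gate, preset,
                                seed = 1L, bias = 0.2) {
  stopifnot(inherits(model, "gating_model"))
  if (length(gates) == 0L) stop("gates must be non-empty", call. = FALSE)
  if (n_per_gate < 2) stop("n_per_gate must be >= 2", call. = FALSE)
  validate_sim_preset(preset)
  out <- vector("list", length(gates))
  names(out) <- sprintf("%.6g", gates)
  for (g in seq_along(gates)) {
    Vg <- gates[g]
    p <- preset
    p$gating <- model
    p$U_S <- -Vg
    p$U_P <- p$U_S + bias
    out[[g]] <- make_curve_set(p, n = n_per_gate,
                               seed = .child_seed(seed, 100000L + g) %% 2147483647,
                               gate = Vg)
    out[[g]]$provenance$gate <- Vg
  }
  out
}

#' Shipped experimental-condition presets
#'
#' Named presets matching the study conditions the package models:
#' \describe{
#'   \item{bare_gold}{beta 9 +/- 2 nm^-1, tunneling between bare gold
#'     electrodes in 50 mM buffer.}
#'   \item{pCc1_hCc}{beta 1.5 +/- 0.8 nm^-1, long-distance transfer between
#'     the cytochrome c1 / cytochrome c redox pair.}
#'   \item{inhibited}{beta 3 +/- 1 nm^-1, pair interaction blocked by excess
#'     wild-type cytochrome c.}
#'   \item{self_ET}{beta 3 +/- 1 nm^-1, non-specific cytochrome c / cytochrome
#'     c contact.}
#'   \item{pure_water}{beta 1.5 +/- 1.5 nm^-1, bare gold in pure water (same
#'     centre as the protein pair, more broadly distributed).}
#'   \item{oscillating_gold}{low-noise bare-gold acquisition with a 0.5-1.2 eV
#'     barrier oscillating at 0.35 nm period, over a 3 nm span with a 1 fA
#'     leakage floor so several oscillation periods sit above the floor.}
#'   \item{gated}{default [gating_model()] attached; beta set per gate.}
#'   \item{approach}{protein-pair approach acquisition: 100 nm span, 4096
#'     points, 35 samples per point.}
#' }
#'
#' @param name Preset name.
#' @param ... Field overrides passed to modify the returned preset.
#' @return A [sim_preset()].
#' @export
#' @examples
#' ects_preset("bare_gold")
#' ects_preset("pCc1_hCc", beta_sd = 0)  # override
ects_preset <- function(name = c("bare_gold", "pCc1_hCc", "inhibited",
                                 "self_ET", "pure_water",
                                 "oscillating_gold", "gated", "approach"),
                        ...) {
  name <- match.arg(name)
  p <- switch(name,
    bare_gold = sim_preset(beta_mean = 9, beta_sd = 2,
                           condition = "bare_gold"),
    pCc1_hCc = sim_preset(beta_mean = 1.5, beta_sd = 0.8,
                          condition = "pCc1-hCc"),
    inhibited = sim_preset(beta_mean = 3, beta_sd = 1,
                           condition = "pCc1-hCc+WT_hCc"),
    self_ET = sim_preset(beta_mean = 3, beta_sd = 1, condition = "self_ET"),
    pure_water = sim_preset(beta_mean = 1.5, beta_sd = 1.5,
                            condition = "pure_water_gold"),
    oscillating_gold = sim_preset(beta_mean = 9, beta_sd = 0,
                                  leakage = 1e-15, z_span = 3,
                                  noise_mult_sigma = 0.02,
                                  noise_add_sigma = 0,
                                  oscillation = oscillation_spec(),
                                  condition = "bare_gold_oscillating"),
    gated = sim_preset(beta_mean = 3.5, beta_sd = 0.3,
                       gating = gating_model(), condition = "pCc1-hCc",
                       U_P = 0.45, U_S = 0.25),
    approach = sim_preset(beta_mean = 1.5, beta_sd = 0.8, z_span = 100,
                          n_points = 4096L, samples_per_point = 35L,
                          mode = "approach", condition = "pCc1-hCc"))
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(unclass(p)))
    if (length(bad)) stop("unknown preset field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (k in names(over)) p[[k]] <- over[[k]]
    validate_sim_preset(p)
  }
  p
}
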