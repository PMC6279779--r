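# Diffuse-double-layer electrostatics for a 1:1 electrolyte: Debye screening
# length, the exact Gouy-Chapman potential of a single charged plane, and a
# nonlinear 1-D Poisson-Boltzmann solver for the potential between two
# parallel walls at fixed potential (a confined electrolyte gap). Potentials
# are handled in reduced thermal units kT/e throughout (25.7 mV per kT/e at
# 298 K); conversion helpers are exposed.

.EPS0 <- 8.8541878128e-12   # F/m
.KB <- 1.380649e-23         # J/K
.NA_AVOGADRO <- 6.02214076e23

#' Electrolyte specification
#'
#' A symmetric 1:1 electrolyte characterised by bulk concentration,
#' temperature and relative permittivity. The default (50 mM, 298 K, 78.5)
#' treats a 50 mM sodium phosphate buffer as an effective 1:1 salt —
#' phosphate speciation is deliberately ignored.
#'
#' @param c0 Bulk salt concentration, mol/L (> 0).
#' @param T Temperature, K (> 0).
#' @param eps_r Relative permittivity (> 1).
#' @return An object of class `electrolyte_spec`.
#' @export
electrolyte_spec <- function(c0 = 0.05, T = 298, eps_r = 78.5) {
  if (!(c0 > 0)) stop("c0 must be > 0", call. = FALSE)
  if (!(T > 0)) stop("T must be > 0", call. = FALSE)
  if (!(eps_r > 1)) stop("eps_r must be > 1", call. = FALSE)
  structure(list(c0 = c0, T = T, eps_r = eps_r), class = "electrolyte_spec")
}

#' Debye screening length
#'
#' `kappa^-1 = sqrt(eps0 eps_r kB T / (2 NA e^2 1000 c0))`, returned in nm.
#' At 298 K and eps_r 78.5 this reduces to the textbook 0.304 nm / sqrt(c[M]):
#' about 1 nm at 100 mM, the physiological screening scale.
#'
#' @param spec An [electrolyte_spec()].
#' @return Debye length, nm.
#' @export
#' @examples
#' debye_length(electrolyte_spec(c0 = 0.1))  # ~0.96 nm
debye_length <- function(spec) {
  stopifnot(inherits(spec, "electrolyte_spec"))
  l_m <- sqrt(.EPS0 * spec$eps_r * .KB * spec$T /
                (2 * .NA_AVOGADRO * .E_CHARGE^2 * 1000 * spec$c0))
  l_m * 1e9
}

#' Thermal voltage of an electrolyte, mV per kT/e
#'
#' @param spec An [electrolyte_spec()].
#' @return kT/e in mV (25.7 mV at 298 K).
#' @export
thermal_voltage_mV <- function(spec) {
  stopifnot(inherits(spec, "electrolyte_spec"))
  .KB * spec$T / .E_CHARGE * 1e3
}

#' Analytic Gouy-Chapman potential of a single charged plane
#'
#' Exact solution of the nonlinear Poisson-Boltzmann equation for a 1:1
#' electrolyte half-space: `psi(z) = 4 atanh(gamma exp(-z/kappa^-1))` with
#' `gamma = tanh(psi0/4)`. In the small-potential limit this reduces to the
#' Debye-Hueckel exponential `psi0 exp(-z/kappa^-1)`.
#'
#' @param psi0 Wall potential, kT/e.
#' @param spec An [electrolyte_spec()].
#' @param z Distance grid from the wall, nm.
#' @return Potential profile, kT/e.
#' @export
gouy_chapman_potential <- function(psi0, spec, z) {
  stopifnot(inherits(spec, "electrolyte_spec"))
  gamma <- tanh(psi0 / 4)
  4 * atanh(gamma * exp(-z / debye_length(spec)))
}

#' Solve the 1-D Poisson-Boltzmann equation in a confined gap
#'
#' Solves `d2psi/dx2 = sinh(psi)` (x in units of the Debye length) between
#' two walls held at fixed (Dirichlet) potentials, by damped Newton iteration
#' on a second-order finite-difference grid, with continuation from the
#' linearised (Debye-Hueckel) solution for strongly charged walls. Ion
#' concentrations follow the Boltzmann relation `c+- = c0 exp(-+psi)`.
#'
#' @param spec An [electrolyte_spec()].
#' @param gap_width Wall separation, nm (> 0).
#' @param wall_potentials Length-2 numeric, potentials of the (left, right)
#'   walls in kT/e; |psi| <= 20 (validated range).
#' @param n_grid Number of grid points (>= 50; default 801).
#' @param tol Residual max-norm tolerance (default 1e-10 in scaled units).
#' @param max_iter Newton iterations per continuation step.
#' @return An object of class `pb_gap_solution`: `z` (nm), `psi` (kT/e),
#'   `c_plus`, `c_minus` (mol/L), `gap_width`, `surface_potentials`,
#'   `residual` (final max-norm).
#' @export
#' @examples
#' sol <- solve_pb_gap(electrolyte_spec(0.05), gap_width = 3,
#'                     wall_potentials = c(1.1, 1.1))
#' min(sol$c_plus)
solve_pb_gap <- function(spec, gap_width, wall_potentials, n_grid = 801L,
                         tol = 1e-10, max_iter = 60L) {
  stopifnot(inherits(spec, "electrolyte_spec"))
  if (!(gap_width > 0)) stop("gap_width must be > 0", call. = FALSE)
  if (length(wall_potentials) != 2L || any(!is.finite(wall_potentials)))
    stop("wall_potentials must be two finite numbers", call. = FALSE)
  if (any(abs(wall_potentials) > 20))
    stop("|wall potential| > 20 kT/e is outside the validated range",
         call. = FALSE)
  n_grid <- as.integer(n_grid)
  if (n_grid < 50L) stop("n_grid must be >= 50", call. = FALSE)

  lD <- debye_length(spec)
  L <- gap_width / lD                    # scaled gap
  x <- seq(0, L, length.out = n_grid)
  h <- x[2L] - x[1L]
  pl <- wall_potentials[1L]; pr <- wall_potentials[2L]
  # On fine grids the 1/h^2 difference operator amplifies round-off; the
  # residual cannot drop below ~eps * |psi| / h^2, so floor the tolerance
  # there (still orders of magnitude below the discretisation error).
  tol <- max(tol,
             8 * .Machine$double.eps * (1 + max(abs(c(pl, pr)))) / h^2)

  lin_solution <- function(a, b) {
    # psi'' = psi with psi(0)=a, psi(L)=b
    if (L > 700) {  # avoid sinh overflow on huge gaps
      a * exp(-x) + b * exp(-(L - x))
    } else {
      (a * sinh(L - x) + b * sinh(x)) / sinh(L)
    }
  }

  newton <- function(psi, a, b) {
    psi[1L] <- a; psi[n_grid] <- b
    res_norm <- Inf
    for (it in seq_len(max_iter)) {
      interior <- 2:(n_grid - 1L)
      F <- (psi[interior - 1L] - 2 * psi[interior] + psi[interior + 1L]) / h^2 -
        sinh(psi[interior])
      res_norm <- max(abs(F))
      if (res_norm <= tol) return(list(psi = psi, residual = res_norm))
      # tridiagonal Jacobian: sub/sup = 1/h^2, diag = -2/h^2 - cosh(psi_i)
      m <- n_grid - 2L
      dg <- -2 / h^2 - cosh(psi[interior])
      off <- rep(1 / h^2, m - 1L)
      delta <- .thomas_solve(off, dg, off, -F)
      # damped update: backtrack until the residual decreases
      step <- 1
      for (bt in seq_len(40L)) {
        trial <- psi
        trial[interior] <- psi[interior] + step * delta
        Ft <- (trial[interior - 1L] - 2 * trial[interior] +
                 trial[interior + 1L]) / h^2 - sinh(trial[interior])
        if (max(abs(Ft)) < res_norm) { psi <- trial; break }
        step <- step / 2
        if (bt == 40L) psi[interior] <- psi[interior] + step * delta
      }
    }
    interior <- 2:(n_grid - 1L)
    F <- (psi[interior - 1L] - 2 * psi[interior] + psi[interior + 1L]) / h^2 -
      sinh(psi[interior])
    list(psi = psi, residual = max(abs(F)), failed = max(abs(F)) > tol)
  }

  # continuation in wall potential for strongly charged walls
  max_wall <- max(abs(c(pl, pr)), 1e-12)
  n_steps <- max(1L, ceiling(max_wall / 2))
  psi <- lin_solution(pl / n_steps, pr / n_steps)
  sol <- NULL
  for (s in seq_len(n_steps)) {
    f <- s / n_steps
    sol <- newton(psi, pl * f, pr * f)
    if (isTRUE(sol$failed))
      stop(sprintf("PB solver did not converge (last residual %.3g)",
                   sol$residual), call. = FALSE)
    psi <- sol$psi
  }
  psi <- sol$psi
  structure(
    list(z = x * lD, psi = psi,
         c_plus = spec$c0 * exp(-psi), c_minus = spec$c0 * exp(psi),
         gap_width = gap_width, surface_potentials = c(pl, pr),
         spec = spec, residual = sol$residual),
    class = "pb_gap_solution")
}

# Thomas algorithm for a tridiagonal system (sub, diag, sup, rhs).
.thomas_solve <- function(sub, dg, sup, rhs) {
  m <- length(dg)
  if (m == 1L) return(rhs / dg)
  cp <- numeric(m - 1L); dp <- numeric(m)
  cp[1L] <- sup[1L] / dg[1L]
  dp[1L] <- rhs[1L] / dg[1L]
  for (i in 2:m) {
    denom <- dg[i] - sub[i - 1L] * cp[i - 1L]
    if (i < m) cp[i] <- sup[i] / denom
    dp[i] <- (rhs[i] - sub[i - 1L] * dp[i - 1L]) / denom
  }
  xs <- numeric(m)
  xs[m] <- dp[m]
  for (i in (m - 1L):1L) xs[i] <- dp[i] - cp[i] * xs[i + 1L]
  xs
}

#' @export
print.pb_gap_solution <- function(x, ...) {
  cat(sprintf("<pb_gap_solution> %.3g nm gap, walls (%.3g, %.3g) kT/e, %d points, residual %.2g\n",
              x$gap_width, x$surface_potentials[1L], x$surface_potentials[2L],
              length(x$z), x$residual))
  cat(sprintf("  midgap psi = %.4g kT/e, min c+ = %.4g M\n",
              x$psi[ceiling(length(x$psi) / 2)], min(x$c_plus)))
  invisible(x)
}

#' Cation depletion summary of a PB gap solution
#'
#' Grid minimum of the cation concentration with a parabolically interpolated
#' location — the quantity that expresses ion depletion (and hence weakened
#' screening) inside the confined gap.
#'
#' @param sol A [solve_pb_gap()] solution.
#' @return List with `c_plus_min` (mol/L) and `z_min` (nm).
#' @export
depletion_summary <- function(sol) {
  stopifnot(inherits(sol, "pb_gap_solution"))
  i <- which.min(sol$c_plus)
  z_min <- sol$z[i]; c_min <- sol$c_plus[i]
  if (i > 1L && i < length(sol$z)) {
    y1 <- sol$c_plus[i - 1L]; y2 <- c_min; y3 <- sol$c_plus[i + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom > 0) {
      delta <- 0.5 * (y1 - y3) / denom
      hz <- sol$z[i + 1L] - sol$z[i]
      z_min <- sol$z[i] + delta * hz
      c_min <- y2 - 0.25 * (y1 - y3) * delta
    }
  }
  list(c_plus_min = c_min, z_min = z_min)
}

#' Wall surface charge and electroneutrality check
#'
#' Surface charge density of each wall from the potential gradient at the
#' wall (one-sided second-order difference), and the integrated net ionic
#' space charge of the gap; in a consistent solution the two balance.
#' Reduced units: charge in units of `eps0 eps_r kT / (e lD)` per unit area.
#'
#' @param sol A [solve_pb_gap()] solution.
#' @return List with `sigma_walls` (left, right), `space_charge`, and
#'   `imbalance` (relative mismatch).
#' @export
gap_charge_balance <- function(sol) {
  stopifnot(inherits(sol, "pb_gap_solution"))
  lD <- debye_length(sol$spec)
  x <- sol$z / lD
  h <- x[2L] - x[1L]
  n <- length(x)
  psi <- sol$psi
  # sigma = -dpsi/dx pointing into the gap at each wall
  dpsi_l <- (-3 * psi[1L] + 4 * psi[2L] - psi[3L]) / (2 * h)
  dpsi_r <- (3 * psi[n] - 4 * psi[n - 1L] + psi[n - 2L]) / (2 * h)
  sigma <- c(left = -dpsi_l, right = dpsi_r)
  # net ionic charge density in scaled units is -sinh(psi); trapezoid
  rho <- -sinh(psi)
  q_space <- sum((rho[-1L] + rho[-n]) / 2 * diff(x))
  tot_wall <- sum(sigma)
  list(sigma_walls = sigma, space_charge = q_space,
       imbalance = abs(q_space + tot_wall) /
         max(abs(tot_wall), abs(q_space), 1e-300))
}
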