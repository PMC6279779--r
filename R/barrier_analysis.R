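# Local tunneling barrier analysis. For a square barrier the current decays as
# I ~ exp(-2 kappa z) with kappa = sqrt(2 m_e Phi)/hbar, so
#   Phi = (hbar^2 / 8 m_e) * (dlnI/dz)^2  ~=  0.00952 eV nm^2 * slope^2,
# the only physics constant in this module (vacuum square-barrier form;
# equivalently Phi[eV] ~= 0.952 * (dlnI/dz [A^-1])^2).

# hbar^2 / (8 m_e), expressed in eV nm^2.
.HBAR <- 1.054571817e-34      # J s
.M_E <- 9.1093837015e-31      # kg
.E_CHARGE <- 1.602176634e-19  # C
.PHI_PREFACTOR <- .HBAR^2 / (8 * .M_E) / .E_CHARGE * 1e18  # 0.0095246 eV nm^2

#' Local barrier height from a logarithmic current slope
#'
#' Square-barrier relation `Phi = (hbar^2/8 m_e) (dlnI/dz)^2`, i.e.
#' `Phi[eV] = 0.00952 * slope[nm^-1]^2`. Even in the sign of the slope, so
#' retraction (negative dlnI/dz) and approach conventions agree. Vectorised.
#'
#' @param slope Logarithmic current slope dlnI/dz, nm^-1.
#' @return Local barrier height, eV.
#' @export
#' @examples
#' barrier_from_slope(9)    # ~0.77 eV
#' barrier_from_slope(1.5)  # ~0.021 eV
barrier_from_slope <- function(slope) {
  stopifnot(all(is.finite(slope)))
  .PHI_PREFACTOR * slope^2
}

#' Logarithmic current slope from a local barrier height
#'
#' Exact inverse of [barrier_from_slope()] on `phi >= 0`:
#' `slope = sqrt(phi / 0.00952)`.
#'
#' @param phi Local barrier height, eV (>= 0).
#' @return Decay slope magnitude, nm^-1.
#' @export
slope_from_barrier <- function(phi) {
  if (any(phi < 0)) stop("phi must be >= 0", call. = FALSE)
  sqrt(phi / .PHI_PREFACTOR)
}

#' Local barrier height profile along a curve
#'
#' Sliding-window least-squares slope of `ln(I - leakage)` over windows of
#' physical length `window_nm`, mapped through [barrier_from_slope()]. Points
#' with `I <= 3 * leakage_est` (inside the leakage floor) are excluded before
#' windowing; the profile is evaluated at window centres.
#'
#' @param curve An [iz_curve()].
#' @param window_nm Sliding window length, nm. The default 0.15 nm resolves a
#'   0.35 nm oscillation while averaging point noise.
#' @param leakage_est Leakage estimate, A; default from [estimate_leakage()].
#' @return An object of class `barrier_profile`: `z` (window centres, nm),
#'   `slope` (dlnI/dz, nm^-1), `phi` (eV), `window_nm`.
#' @export
#' @examples
#' z <- seq(0, 1.5, length.out = 512)
#' cv <- iz_curve(z, 1e-15 + 0.4e-9 * exp(-9 * z), validate = FALSE)
#' bp <- barrier_profile(cv, leakage_est = 1e-15)
#' mean(bp$phi)  # ~0.77 eV
barrier_profile <- function(curve, window_nm = 0.15, leakage_est = NULL) {
  validate_iz_curve_light(curve)
  if (is.null(leakage_est)) leakage_est <- estimate_leakage(curve)$leakage
  keep <- curve$I > 3 * leakage_est
  z <- curve$z[keep]
  y <- curve$I[keep] - leakage_est
  if (length(z) < 5L)
    stop("fewer than 5 points above the leakage floor", call. = FALSE)
  dz <- stats::median(diff(z))
  k <- max(2L, round(window_nm / dz))  # points per window (k+1 samples)
  if (k + 1L > length(z))
    stop("window_nm longer than the usable curve", call. = FALSE)
  if (k + 1L < 5L)
    stop("window_nm covers fewer than 5 points; increase window or sampling",
         call. = FALSE)
  ly <- log(y)
  n_win <- length(z) - k
  # rolling OLS slope via cumulative sums (uniform-enough grid not assumed)
  cz <- cumsum(c(0, z)); cz2 <- cumsum(c(0, z^2))
  cy <- cumsum(c(0, ly)); czy <- cumsum(c(0, z * ly))
  i0 <- seq_len(n_win); i1 <- i0 + k
  nwin <- k + 1
  sz <- cz[i1 + 1L] - cz[i0]
  sz2 <- cz2[i1 + 1L] - cz2[i0]
  sy <- cy[i1 + 1L] - cy[i0]
  szy <- czy[i1 + 1L] - czy[i0]
  slope <- (nwin * szy - sz * sy) / (nwin * sz2 - sz^2)
  centre <- (z[i0] + z[i1]) / 2
  structure(list(z = centre, slope = slope,
                 phi = barrier_from_slope(slope), window_nm = window_nm),
            class = "barrier_profile")
}

#' @export
print.barrier_profile <- function(x, ...) {
  cat(sprintf("<barrier_profile> %d windows of %.3g nm, z [%.3g, %.3g] nm, phi [%.3g, %.3g] eV\n",
              length(x$z), x$window_nm, min(x$z), max(x$z),
              min(x$phi), max(x$phi)))
  invisible(x)
}

#' Average several barrier profiles onto a common grid
#'
#' Linear interpolation of each profile onto the overlap of all z ranges,
#' then a pointwise mean — the ensemble view used for periodicity detection.
#'
#' @param profiles List of [barrier_profile()] objects.
#' @param n_grid Grid size of the common axis (default 512).
#' @return A `barrier_profile` on the common grid (slope is the
#'   back-converted mean profile).
#' @export
average_barrier_profiles <- function(profiles, n_grid = 512L) {
  stopifnot(length(profiles) >= 1L)
  lo <- max(vapply(profiles, function(p) min(p$z), numeric(1)))
  hi <- min(vapply(profiles, function(p) max(p$z), numeric(1)))
  if (hi <= lo) stop("profiles do not overlap in z", call. = FALSE)
  zg <- seq(lo, hi, length.out = n_grid)
  phi <- rowMeans(vapply(profiles, function(p)
    stats::approx(p$z, p$phi, xout = zg)$y, numeric(n_grid)))
  structure(list(z = zg, slope = sqrt(pmax(phi, 0) / .PHI_PREFACTOR),
                 phi = phi, window_nm = profiles[[1L]]$window_nm),
            class = "barrier_profile")
}

#' Dominant spatial period of a barrier profile
#'
#' Detects periodic modulation (water layering) in `phi(z)`: the profile is
#' linearly detrended, its autocorrelation computed, and the first
#' autocorrelation peak at a lag inside the candidate range refined by
#' three-point parabolic interpolation. A profile whose first peak does not
#' rise above the noise floor is reported as aperiodic rather than given a
#' number.
#'
#' @param profile A [barrier_profile()].
#' @param candidate_range Lag range searched, nm (default 0.1-1 nm).
#' @param min_confidence Minimum autocorrelation value at the peak for the
#'   signal to count as periodic (default 0.2).
#' @return List with `period` (nm, `NA` if aperiodic), `confidence`
#'   (autocorrelation at the peak) and logical `aperiodic`.
#' @export
dominant_period <- function(profile, candidate_range = c(0.1, 1),
                            min_confidence = 0.2) {
  stopifnot(inherits(profile, "barrier_profile"))
  z <- profile$z; phi <- profile$phi
  span <- diff(range(z))
  if (span < 3 * candidate_range[1L])
    stop("profile shorter than 3 candidate periods", call. = FALSE)
  dz <- stats::median(diff(z))
  # resample to a uniform grid so lags map to physical distance
  n <- max(64L, as.integer(round(span / dz)) + 1L)
  zg <- seq(min(z), max(z), length.out = n)
  yg <- stats::approx(z, phi, xout = zg)$y
  dzg <- zg[2L] - zg[1L]
  y <- stats::residuals(stats::lm.fit(cbind(1, zg), yg))  # linear detrend
  if (stats::sd(y) == 0)
    return(list(period = NA_real_, confidence = 0, aperiodic = TRUE))
  ac <- stats::acf(y, lag.max = n - 2L, plot = FALSE,
                   demean = FALSE)$acf[, 1L, 1L]
  # undo the 1/n (triangular-taper) normalisation, which drags peaks toward
  # shorter lags on short profiles
  ac <- ac * n / (n - seq_along(ac) + 1L)
  lags <- (seq_along(ac) - 1L) * dzg
  in_range <- which(lags >= candidate_range[1L] & lags <= candidate_range[2L])
  if (length(in_range) < 3L)
    return(list(period = NA_real_, confidence = 0, aperiodic = TRUE))
  # first local maximum of the acf within the candidate range
  peak <- NA_integer_
  for (i in in_range) {
    if (i > 1L && i < length(ac) && ac[i] >= ac[i - 1L] && ac[i] > ac[i + 1L]) {
      peak <- i; break
    }
  }
  if (is.na(peak) || ac[peak] < min_confidence)
    return(list(period = NA_real_, confidence = if (is.na(peak)) 0 else ac[peak],
                aperiodic = TRUE))
  # parabolic refinement through (peak-1, peak, peak+1)
  y1 <- ac[peak - 1L]; y2 <- ac[peak]; y3 <- ac[peak + 1L]
  denom <- y1 - 2 * y2 + y3
  delta <- if (denom == 0) 0 else 0.5 * (y1 - y3) / denom
  list(period = (peak - 1L + delta) * dzg, confidence = y2,
       aperiodic = FALSE)
}
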