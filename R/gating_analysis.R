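# Electrochemical gating: ensemble beta statistics as a function of the
# electrochemical gate potential at constant bias. The default gate mapping is
# Vg = -U_S, which places the resonance minimum at -0.25 V when the sample
# potential sits at 0.25 V, between the two midpoint redox potentials.

#' Default electrochemical gate mapping
#'
#' Maps an electrode-potential pair to the gate axis: `Vg = -U_S`. The mapping
#' is injectable everywhere it is used because the gate-axis convention is an
#' instrument-level definition.
#'
#' @param U_P,U_S Probe and sample potentials, V vs SSC.
#' @return Gate potential, V.
#' @export
gate_map_neg_Us <- function(U_P, U_S) -U_S

#' Group decay fits by electrode-potential condition
#'
#' Exact grouping of fits on their `(U_P, U_S)` metadata after rounding both
#' potentials to 1 mV. Fits missing either potential are rejected.
#'
#' @param fits List of `decay_fit` objects carrying `U_P` and `U_S`.
#' @return Named list of fit lists; names are `"U_P/U_S"` in volts at mV
#'   resolution.
#' @export
group_by_condition <- function(fits) {
  U_P <- vapply(fits, `[[`, numeric(1), "U_P")
  U_S <- vapply(fits, `[[`, numeric(1), "U_S")
  bad <- which(!is.finite(U_P) | !is.finite(U_S))
  if (length(bad))
    stop("fit(s) missing electrode potentials: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  key <- sprintf("%.3f/%.3f", round(U_P, 3), round(U_S, 3))
  split(fits, factor(key, levels = unique(key)))
}

#' Build a beta-vs-gate series from grouped fits
#'
#' Per-gate mean and standard deviation of the decay factor over usable
#' fits, sorted by gate potential. All groups must share the same bias
#' (`U_P - U_S`) to 1e-9 V — a gating experiment holds the bias constant while
#' both electrode potentials shift together.
#'
#' @param groups Output of [group_by_condition()] (>= 2 groups).
#' @param gate_map Function `(U_P, U_S) -> Vg`; default [gate_map_neg_Us()].
#' @return An object of class `gating_series`: data frame `series` with
#'   columns `gate`, `beta_mean`, `beta_sd`, `n`, plus scalar `bias` (V).
#' @export
gating_series <- function(groups, gate_map = gate_map_neg_Us) {
  if (length(groups) < 2L)
    stop("need >= 2 potential groups for a gating series", call. = FALSE)
  rows <- lapply(names(groups), function(key) {
    fits <- groups[[key]]
    clean <- fits[vapply(fits, is_clean_fit, logical(1))]
    if (length(clean) < 2L)
      stop("group ", key, ": fewer than 2 usable fits", call. = FALSE)
    betas <- vapply(clean, `[[`, numeric(1), "beta")
    U_P <- clean[[1L]]$U_P; U_S <- clean[[1L]]$U_S
    data.frame(gate = gate_map(U_P, U_S), beta_mean = mean(betas),
               beta_sd = stats::sd(betas), n = length(betas),
               bias = U_P - U_S)
  })
  df <- do.call(rbind, rows)
  if (diff(range(df$bias)) > 1e-9)
    stop("mixed bias across groups: ",
         paste(sprintf("%.3f V", sort(unique(round(df$bias, 3)))),
               collapse = ", "), call. = FALSE)
  df <- df[order(df$gate), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(series = df[, c("gate", "beta_mean", "beta_sd", "n")],
                 bias = df$bias[1L]),
            class = "gating_series")
}

#' @export
print.gating_series <- function(x, ...) {
  cat(sprintf("<gating_series> %d gates at %.3g V bias\n",
              nrow(x$series), x$bias))
  print(x$series, digits = 3)
  invisible(x)
}

#' Locate the resonance minimum of a gating series
#'
#' Three-point parabolic interpolation through the grid minimum and its
#' neighbours — appropriate for the coarse (0.05-0.1 V) gate grids of a
#' gating experiment. At a grid edge the raw argmin is returned with an
#' `edge` flag. A series whose total variation is smaller than its typical
#' per-gate SD is reported as having no minimum.
#'
#' @param series A [gating_series()] with >= 3 gates.
#' @return List with `Vg_min` (V), `beta_min` (nm^-1), logicals `edge` and
#'   `found` (`FALSE`, with `NA` location, for a flat series).
#' @export
find_gate_minimum <- function(series) {
  stopifnot(inherits(series, "gating_series"))
  df <- series$series
  if (nrow(df) < 3L) stop("need >= 3 gates", call. = FALSE)
  rng <- diff(range(df$beta_mean))
  if (rng < stats::median(df$beta_sd))
    return(list(Vg_min = NA_real_, beta_min = NA_real_, edge = FALSE,
                found = FALSE))
  i <- which.min(df$beta_mean)
  if (i == 1L || i == nrow(df))
    return(list(Vg_min = df$gate[i], beta_min = df$beta_mean[i],
                edge = TRUE, found = TRUE))
  x <- df$gate[(i - 1L):(i + 1L)]
  y <- df$beta_mean[(i - 1L):(i + 1L)]
  cf <- solve(cbind(1, x, x^2), y)  # exact parabola through 3 points
  if (cf[3L] <= 0) {  # degenerate (non-convex): keep the grid point
    return(list(Vg_min = df$gate[i], beta_min = df$beta_mean[i],
                edge = FALSE, found = TRUE))
  }
  vx <- -cf[2L] / (2 * cf[3L])
  list(Vg_min = unname(vx),
       beta_min = unname(cf[1L] + cf[2L] * vx + cf[3L] * vx^2),
       edge = FALSE, found = TRUE)
}

#' On/off ratio of the decay factor between two gates
#'
#' Ratio of the off-resonance to the on-resonance ensemble mean beta, with
#' the SD propagated in quadrature on the relative scale.
#'
#' @param series A [gating_series()].
#' @param Vg_on,Vg_off Gate potentials present in the series (matched to
#'   1 mV).
#' @return List with `ratio` and `sd`.
#' @export
on_off_ratio <- function(series, Vg_on, Vg_off) {
  stopifnot(inherits(series, "gating_series"))
  df <- series$series
  pick <- function(Vg) {
    i <- which(abs(df$gate - Vg) < 5e-4)
    if (length(i) != 1L)
      stop(sprintf("gate %.3f V not present in series", Vg), call. = FALSE)
    i
  }
  on <- pick(Vg_on); off <- pick(Vg_off)
  r <- df$beta_mean[off] / df$beta_mean[on]
  rel <- sqrt((df$beta_sd[on] / df$beta_mean[on])^2 +
              (df$beta_sd[off] / df$beta_mean[off])^2)
  list(ratio = r, sd = abs(r) * rel)
}

#' Electrode potential on the absolute (vacuum) energy scale
#'
#' `E[eV] = -e * U[V vs SSC] - 4.6 eV`, the conversion used to place electrode
#' Fermi levels and protein redox levels on a common energy diagram. Affine
#' and order-reversing. Vectorised.
#'
#' @param U Potential(s), V vs SSC.
#' @return Energy, eV.
#' @export
#' @examples
#' absolute_energy(0.35)  # hCc midpoint: -4.95 eV
absolute_energy <- function(U) {
  stopifnot(all(is.finite(U)))
  -U - 4.6
}

#' Current ratio between two decay regimes at a distance
#'
#' For two noiseless exponentials sharing the same set point, the on/off
#' current ratio at gap displacement `z` is `exp((beta_off - beta_on) z)`.
#'
#' @param z Gap displacement, nm (>= 0).
#' @param beta_on,beta_off Decay factors, nm^-1.
#' @param set_point Shared set point, A (cancels; kept for signature clarity).
#' @return Dimensionless ratio (current on resonance / current off
#'   resonance).
#' @export
#' @examples
#' current_ratio_at(1, beta_on = 0.5, beta_off = 2.8)  # ~10
current_ratio_at <- function(z, beta_on, beta_off, set_point = 0.4e-9) {
  if (any(z < 0)) stop("z must be >= 0", call. = FALSE)
  exp((beta_off - beta_on) * z)
}
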