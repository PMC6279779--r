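#' Construct a single current-distance (I-z) curve
#'
#' An `iz_curve` holds one probe-current-versus-gap-displacement record from an
#' electrochemical tunneling spectroscopy (ECTS) acquisition, together with the
#' electrode-potential metadata needed downstream. Units are fixed across the
#' package: `z` in nm (0 at the set-point position, increasing with
#' retraction), `I` in A, potentials in V vs the Ag/AgCl (SSC) reference.
#'
#' Approach-mode curves are stored with `z` sorted ascending like retraction
#' curves; the `mode` flag records how the data were physically acquired and
#' consumers reverse as needed.
#'
#' @param z Numeric vector of gap displacements (nm), strictly increasing,
#'   length >= 16.
#' @param I Numeric vector of probe currents (A), same length as `z`, all
#'   finite.
#' @param U_P Probe potential, V vs SSC.
#' @param U_S Sample potential, V vs SSC.
#' @param mode Acquisition mode, `"retraction"` or `"approach"`.
#' @param condition Free-text condition label (e.g. `"bare_gold"`,
#'   `"pCc1-hCc"`).
#' @param speed Piezo speed, nm/s (may be `NA`).
#' @param set_point Feedback set-point current, A.
#' @param validate Run [validate_iz_curve()] on the result (default `TRUE`).
#'
#' @return An object of class `iz_curve`: a list with fields `z`, `I`, `U_P`,
#'   `U_S`, `U_bias` (derived, `U_P - U_S`), `mode`, `condition`, `speed`,
#'   `set_point`.
#' @export
#' @examples
#' z <- seq(0, 15, length.out = 64)
#' cv <- iz_curve(z, 2e-12 + 0.4e-9 * exp(-9 * z),
#'                U_P = 0.6, U_S = -0.2, condition = "bare_gold")
#' cv$U_bias  # 0.8 V
iz_curve <- function(z, I, U_P = NA_real_, U_S = NA_real_,
                     mode = "retraction", condition = "unknown",
                     speed = NA_real_, set_point = 0.4e-9,
                     validate = TRUE) {
  obj <- structure(
    list(z = as.numeric(z), I = as.numeric(I),
         U_P = as.numeric(U_P), U_S = as.numeric(U_S),
         U_bias = as.numeric(U_P) - as.numeric(U_S),
         mode = match.arg(mode, c("retraction", "approach")),
         condition = as.character(condition),
         speed = as.numeric(speed), set_point = as.numeric(set_point)),
    class = "iz_curve")
  if (validate) validate_iz_curve(obj)
  obj
}

#' Validate an I-z curve
#'
#' Checks the structural invariants of an [iz_curve()]: strictly ascending `z`
#' of length >= 16, finite currents, bias consistency (`U_bias == U_P - U_S`
#' to 1e-9 V), and for retraction curves that the current at `z = 0` starts
#' within 25% of the set point.
#'
#' @param curve An `iz_curve`.
#' @param index Optional curve index used to make error messages traceable
#'   inside a [curve_set()].
#' @return `curve`, invisibly, if valid; otherwise an error naming the curve
#'   and offending field.
#' @export
validate_iz_curve <- function(curve, index = NA_integer_) {
  tag <- if (is.na(index)) "curve" else sprintf("curve %d", index)
  if (!inherits(curve, "iz_curve"))
    stop(tag, ": not an iz_curve object", call. = FALSE)
  z <- curve$z; I <- curve$I
  if (length(z) < 16L)
    stop(tag, ", field z: length ", length(z), " < 16", call. = FALSE)
  if (length(I) != length(z))
    stop(tag, ", field I: length mismatch with z", call. = FALSE)
  if (any(!is.finite(z)) || any(diff(z) <= 0))
    stop(tag, ", field z: must be finite and strictly ascending",
         call. = FALSE)
  if (any(!is.finite(I)))
    stop(tag, ", field I: non-finite current values", call. = FALSE)
  if (!is.na(curve$U_P) && !is.na(curve$U_S) &&
      abs(curve$U_bias - (curve$U_P - curve$U_S)) > 1e-9)
    stop(tag, ", field U_bias: inconsistent with U_P - U_S", call. = FALSE)
  if (curve$mode == "retraction" && is.finite(curve$set_point) &&
      curve$set_point > 0) {
    if (abs(I[1L] - curve$set_point) > 0.25 * curve$set_point)
      stop(tag, ", field I: retraction curve starts at ",
           format(I[1L]), " A, not within 25% of set point ",
           format(curve$set_point), " A", call. = FALSE)
  }
  invisible(curve)
}

#' Construct an ordered set of I-z curves
#'
#' @param curves List of [iz_curve()] objects (non-empty).
#' @param provenance Named list of generator/file metadata carried alongside
#'   the curves (seeds, presets, defaulted header keys, source path).
#' @param validate Validate each member curve (default `TRUE`).
#' @return An object of class `curve_set`.
#' @export
curve_set <- function(curves, provenance = list(), validate = TRUE) {
  if (!is.list(curves) || length(curves) == 0L)
    stop("curve_set requires a non-empty list of curves", call. = FALSE)
  if (validate)
    for (i in seq_along(curves)) validate_iz_curve(curves[[i]], index = i)
  structure(list(curves = curves, provenance = provenance),
            class = "curve_set")
}

#' @export
length.curve_set <- function(x) length(x$curves)

#' @export
`[[.curve_set` <- function(x, i) x$curves[[i]]

#' @export
print.iz_curve <- function(x, ...) {
  cat(sprintf(
    "<iz_curve> %s, %s, %d points, z [%.3g, %.3g] nm, I [%.3g, %.3g] A\n",
    x$condition, x$mode, length(x$z), min(x$z), max(x$z),
    min(x$I), max(x$I)))
  cat(sprintf("  U_P = %s V, U_S = %s V, U_bias = %s V vs SSC\n",
              format(x$U_P), format(x$U_S), format(x$U_bias)))
  invisible(x)
}

#' @export
print.curve_set <- function(x, ...) {
  conds <- vapply(x$curves, function(cv) cv$condition, character(1))
  cat(sprintf("<curve_set> %d curves (%s)\n", length(x$curves),
              paste(unique(conds), collapse = ", ")))
  invisible(x)
}

#' Semilogarithmic plot of I-z curves
#'
#' Standard diagnostic view: |I| on a log axis against z, one line per curve.
#'
#' @param x A `curve_set` or single `iz_curve`.
#' @param max_curves Plot at most this many curves (default 50).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.curve_set <- function(x, max_curves = 50L, ...) {
  idx <- seq_len(min(length(x$curves), max_curves))
  zs <- lapply(x$curves[idx], `[[`, "z")
  Is <- lapply(x$curves[idx], function(cv) pmax(abs(cv$I), 1e-15))
  graphics::plot(range(unlist(zs)), range(unlist(Is)), type = "n",
                 log = "y", xlab = "z (nm)", ylab = "|I| (A)", ...)
  for (k in idx) graphics::lines(zs[[k]], Is[[k]],
                                 col = grDevices::adjustcolor(2, 0.4))
  invisible(x)
}

#' @export
plot.iz_curve <- function(x, ...) {
  plot.curve_set(curve_set(list(x)), ...)
}
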