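# Plain-text "ectsv" dialect: UTF-8; header lines '# key = value' with keys
# condition, mode, U_P_V, U_S_V, speed_nm_s, set_point_A, seed; body a
# two-column TSV 'z_nm<TAB>I_A'; curves separated by a '# ---' line.

.ectsv_header_keys <- c("condition", "mode", "U_P_V", "U_S_V",
                        "speed_nm_s", "set_point_A", "seed")

#' Read an ensemble of I-z curves from an ectsv file
#'
#' Parses the package's metadata-headed TSV dialect: each curve section starts
#' with `# key = value` header lines, followed by two tab-separated numeric
#' columns `z_nm` and `I_A`; sections are separated by a `# ---` line. A
#' `# key =` line with an empty value is treated as an absent key. Missing
#' optional keys are defaulted (`mode` to `"retraction"`, `condition` to
#' `"unknown"`, `set_point_A` to 0.4e-9) and the defaulted keys are recorded
#' in the returned provenance.
#'
#' @param path Path to an ectsv file.
#' @return A [curve_set()] with one [iz_curve()] per file section; provenance
#'   records the source path and any defaulted keys per curve.
#' @export
#' @seealso [write_curve_table()]
read_curve_table <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    stop("empty ectsv file: ", path, call. = FALSE)

  sep <- grepl("^#\\s*---\\s*$", lines)
  section_id <- cumsum(sep) + 1L
  curves <- list()
  defaulted <- list()
  for (s in unique(section_id)) {
    sl_idx <- which(section_id == s & !sep)
    sl <- lines[sl_idx]
    keep <- nzchar(trimws(sl))
    sl <- sl[keep]; sl_idx <- sl_idx[keep]
    if (length(sl) == 0L) next  # trailing separator
    is_hdr <- startsWith(trimws(sl), "#")
    meta <- list()
    for (j in which(is_hdr)) {
      h <- sub("^\\s*#\\s*", "", sl[j])
      if (!grepl("=", h, fixed = TRUE))
        stop(sprintf("malformed header at line %d: '%s'", sl_idx[j], sl[j]),
             call. = FALSE)
      kv <- strsplit(h, "=", fixed = TRUE)[[1L]]
      key <- trimws(kv[1L])
      val <- trimws(paste(kv[-1L], collapse = "="))
      if (!nzchar(key))
        stop(sprintf("malformed header at line %d: empty key", sl_idx[j]),
             call. = FALSE)
      if (nzchar(val)) meta[[key]] <- val  # 'key =' means absent
    }
    body <- sl[!is_hdr]
    body_idx <- sl_idx[!is_hdr]
    if (length(body) == 0L)
      stop(sprintf("curve section %d has no data rows", length(curves) + 1L),
           call. = FALSE)
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad))
      stop(sprintf("malformed data row at line %d: expected 2 tab-separated columns",
                   body_idx[bad[1L]]), call. = FALSE)
    m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = 2L, byrow = TRUE)
    if (anyNA(m))
      stop(sprintf("non-numeric data in curve section %d", length(curves) + 1L),
           call. = FALSE)

    idx <- length(curves) + 1L
    miss <- setdiff(c("condition", "mode", "set_point_A"), names(meta))
    if (length(miss)) defaulted[[as.character(idx)]] <- miss
    cv <- iz_curve(
      z = m[, 1L], I = m[, 2L],
      U_P = if (is.null(meta$U_P_V)) NA_real_ else as.numeric(meta$U_P_V),
      U_S = if (is.null(meta$U_S_V)) NA_real_ else as.numeric(meta$U_S_V),
      mode = if (is.null(meta$mode)) "retraction" else meta$mode,
      condition = if (is.null(meta$condition)) "unknown" else meta$condition,
      speed = if (is.null(meta$speed_nm_s)) NA_real_
              else as.numeric(meta$speed_nm_s),
      set_point = if (is.null(meta$set_point_A)) 0.4e-9
                  else as.numeric(meta$set_point_A),
      validate = FALSE)
    if (any(diff(cv$z) <= 0))
      stop(sprintf("curve %d, field z: not strictly ascending", idx),
           call. = FALSE)
    validate_iz_curve(cv, index = idx)
    curves[[idx]] <- cv
  }
  if (length(curves) == 0L)
    stop("no curve sections with data rows in ", path, call. = FALSE)
  curve_set(curves,
            provenance = list(source = path, defaulted_keys = defaulted),
            validate = FALSE)
}

#' Write an ensemble of I-z curves to an ectsv file
#'
#' Emits the dialect read by [read_curve_table()] with full-precision
#' (17-significant-digit) floats, one `# ---` separator line between curves.
#' `NA` metadata values are written as bare `# key =` lines and read back as
#' absent.
#'
#' @param curves A [curve_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_table <- function(curves, path) {
  if (!inherits(curves, "curve_set"))
    stop("curves must be a curve_set", call. = FALSE)
  fmt_meta <- function(v) {
    if (is.null(v) || (length(v) == 1L && is.na(v))) "" else
      if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
  }
  blocks <- vapply(curves$curves, function(cv) {
    hdr <- c(condition = cv$condition, mode = cv$mode,
             U_P_V = fmt_meta(cv$U_P), U_S_V = fmt_meta(cv$U_S),
             speed_nm_s = fmt_meta(cv$speed),
             set_point_A = fmt_meta(cv$set_point))
    hdr_lines <- sprintf("# %s = %s", names(hdr), unname(hdr))
    hdr_lines <- sub(" $", "", hdr_lines)  # 'key =' for empty values
    body <- sprintf("%.17g\t%.17g", cv$z, cv$I)
    paste(c(hdr_lines, body), collapse = "\n")
  }, character(1))
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e)
                    stop("cannot open for writing: ", path, call. = FALSE))
  on.exit(close(con))
  writeLines(paste(blocks, collapse = "\n# ---\n"), con)
  invisible(path)
}
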