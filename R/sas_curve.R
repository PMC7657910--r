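#' One-dimensional scattering curve
#'
#' Container for a reduced small-angle (or ultra-small-angle) scattering
#' curve: intensity versus momentum transfer with 1-sigma uncertainties and
#' slit-smearing metadata.
#'
#' @param q momentum transfer, reciprocal angstrom; strictly increasing and
#'   positive. USANS curves typically span ~2e-5 to 2e-3, SANS ~0.01 to 0.45.
#' @param I intensity, arbitrary but consistent units; must be finite.
#' @param sigma 1-sigma uncertainty on `I`, same units, non-negative. May be
#'   zero for noiseless model curves.
#' @param smeared logical flag: is the curve slit-smeared (Bonse-Hart
#'   geometry) rather than point-resolved?
#' @param dq_v vertical slit half-width, reciprocal angstrom; required when
#'   `smeared` is `TRUE`.
#' @param units unit string recorded for `q` (default `"1/A"`).
#' @return An object of class `sas_curve`: a list with fields `q`, `I`,
#'   `sigma`, `smeared`, `dq_v`, `units`, plus any extra header metadata in
#'   `meta`.
#' @export
sas_curve <- function(q, I, sigma = NULL, smeared = FALSE, dq_v = NULL,
                      units = "1/A") {
  q <- as.numeric(q); I <- as.numeric(I)
  if (length(q) == 0L) stopf("empty curve: no q values")
  if (length(q) != length(I)) stopf("q and I lengths differ")
  if (any(!is.finite(q)) || any(q <= 0)) stopf("q must be positive and finite")
  if (any(diff(q) <= 0)) stopf("q must be strictly increasing")
  if (any(!is.finite(I))) stopf("I must be finite")
  if (is.null(sigma)) sigma <- rep(0, length(q))
  sigma <- as.numeric(sigma)
  if (length(sigma) != length(q)) stopf("sigma length mismatch")
  if (any(!is.finite(sigma)) || any(sigma < 0)) stopf("sigma must be finite and >= 0")
  smeared <- isTRUE(smeared)
  if (smeared && (is.null(dq_v) || !is.finite(dq_v) || dq_v <= 0))
    stopf("smeared curves require a positive slit half-width dq_v")
  structure(list(q = q, I = I, sigma = sigma, smeared = smeared,
                 dq_v = if (smeared) dq_v else dq_v, units = units,
                 meta = list()),
            class = "sas_curve")
}

#' @export
print.sas_curve <- function(x, ...) {
  cat(sprintf("<sas_curve> %d points, q in [%.4g, %.4g] %s%s\n",
              length(x$q), min(x$q), max(x$q), x$units,
              if (x$smeared) sprintf(", slit-smeared (dq_v = %.4g)", x$dq_v) else ""))
  invisible(x)
}

#' @export
as.data.frame.sas_curve <- function(x, ...) {
  data.frame(q = x$q, I = x$I, sigma = x$sigma)
}

#' Read a scattering curve from a 3-column ASCII file
#'
#' Accepts whitespace- and/or comma-delimited columns (q, I, sigma) with `#`
#' comment lines. Header keys of the form `# key: value` are parsed; the keys
#' `units`, `smeared` and `dq_v` populate the curve metadata, any others are
#' preserved in `$meta`.
#'
#' @param path file path.
#' @param sigma_frac fraction of I used to impute sigma (with a warning) when
#'   the file has only two columns.
#' @return A [sas_curve()].
#' @export
read_sas <- function(path, sigma_frac = 0.02) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("empty input file: %s", path)
  is_hdr <- grepl("^\\s*#", lines)
  hdr <- lines[is_hdr]
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_][A-Za-z0-9_.]*)\\s*[:=]\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  body <- lines[!is_hdr]
  if (length(body) == 0L) stopf("no data rows in %s", path)
  rows <- lapply(seq_along(body), function(i) {
    parts <- strsplit(trimws(body[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (any(is.na(vals)) || length(vals) < 2L)
      stopf("malformed row at data line %d of %s: '%s'", i, path, body[i])
    vals
  })
  ncols <- min(vapply(rows, length, 1L))
  mat <- t(vapply(rows, function(v) v[seq_len(ncols)], numeric(ncols)))
  if (ncols < 3L) {
    warnf("no sigma column in %s; imputing sigma = %.3g * I", path, sigma_frac)
    sig <- abs(mat[, 2]) * sigma_frac
  } else sig <- mat[, 3]
  smeared <- isTRUE(tolower(meta$smeared %||% "false") %in% c("true", "1", "yes"))
  dq_v <- if (!is.null(meta$dq_v)) as.numeric(meta$dq_v) else NULL
  cv <- sas_curve(mat[, 1], mat[, 2], sig, smeared = smeared, dq_v = dq_v,
                  units = meta$units %||% "1/A")
  cv$meta <- meta[setdiff(names(meta), c("units", "smeared", "dq_v", "columns"))]
  cv
}

#' Write a scattering curve to a 3-column ASCII file
#'
#' @param curve a [sas_curve()].
#' @param path output path.
#' @export
write_sas <- function(curve, path) {
  stopifnot(inherits(curve, "sas_curve"))
  hdr <- c(sprintf("# units: %s", curve$units),
           sprintf("# smeared: %s", tolower(curve$smeared)))
  if (!is.null(curve$dq_v) && is.finite(curve$dq_v))
    hdr <- c(hdr, sprintf("# dq_v: %.17g", curve$dq_v))
  for (k in names(curve$meta)) hdr <- c(hdr, sprintf("# %s: %s", k, curve$meta[[k]]))
  hdr <- c(hdr, "# columns: q I sigma")
  dat <- sprintf("%.17g %.17g %.17g", curve$q, curve$I, curve$sigma)
  writeLines(c(hdr, dat), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
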