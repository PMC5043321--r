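# Physical constants (SI, CODATA 2018 exact values)
.PLANCK_H <- 6.62607015e-34 # J s
.SPEED_C <- 2.99792458e8    # m s^-1

#' Recognised spectral unit roles
#'
#' A `rnl_spectrum` carries a `unit_role` tag declaring what its values mean:
#' `"energy_radiance"` (uW cm^-2 nm^-1 sr^-1), `"quantum_radiance"`
#' (quanta s^-1 cm^-2 nm^-1 sr^-1), `"transmittance"` (0-1),
#' `"sensitivity"` (relative, dimensionless) or `"reflectance"` (0-1).
#'
#' @export
spectrum_roles <- function() {
  c("energy_radiance", "quantum_radiance", "transmittance",
    "sensitivity", "reflectance")
}

#' Canonical wavelength grid
#'
#' All cross-spectrum operations in the package default to this grid:
#' 300-700 nm in 1 nm steps, the integration bounds of the quantum-catch
#' integral.
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
canonical_grid <- function() seq(300, 700, by = 1)

#' Construct a spectrum
#'
#' @param wavelength Strictly increasing wavelengths in nm.
#' @param value Non-negative values, same length as `wavelength`.
#' @param unit_role One of [spectrum_roles()].
#' @return An object of class `rnl_spectrum`: a list with elements
#'   `wl`, `value`, `unit_role`.
#' @examples
#' s <- spectrum(300:700, rep(1, 401), "sensitivity")
#' @export
spectrum <- function(wavelength, value, unit_role) {
  unit_role <- match.arg(unit_role, spectrum_roles())
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value))
    stop("wavelength and value must have the same length", call. = FALSE)
  if (length(wavelength) < 1L)
    stop("spectrum must contain at least one point", call. = FALSE)
  if (anyNA(wavelength) || anyNA(value))
    stop("spectrum contains missing values", call. = FALSE)
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(value < 0))
    stop("spectrum values must be non-negative", call. = FALSE)
  if (unit_role %in% c("transmittance", "reflectance") && any(value > 1))
    stop(unit_role, " values must lie in [0, 1]", call. = FALSE)
  structure(list(wl = wavelength, value = value, unit_role = unit_role),
            class = "rnl_spectrum")
}

#' @export
print.rnl_spectrum <- function(x, ...) {
  cat(sprintf("<rnl_spectrum> %s, %d points, %g-%g nm\n",
              x$unit_role, length(x$wl), min(x$wl), max(x$wl)))
  invisible(x)
}

#' @export
as.data.frame.rnl_spectrum <- function(x, ...) {
  data.frame(wavelength = x$wl, value = x$value)
}

is_spectrum <- function(x) inherits(x, "rnl_spectrum")

assert_role <- function(spec, role) {
  if (!is_spectrum(spec)) stop("not an rnl_spectrum", call. = FALSE)
  if (spec$unit_role != role)
    stop(sprintf("expected unit_role '%s', got '%s'", role, spec$unit_role),
         call. = FALSE)
  invisible(spec)
}

#' Read a spectrum from a delimited text file
#'
#' Column 1 is wavelength (nm); `value_col` selects among the remaining value
#' columns. Comma or tab delimiters are auto-detected, `#` starts a comment,
#' and a single header line is skipped if present.
#'
#' @param path Path to a CSV/TSV file.
#' @param unit_role One of [spectrum_roles()].
#' @param value_col Which value column to read (2 = first value column).
#' @return An `rnl_spectrum`.
#' @export
read_spectrum <- function(path, unit_role, value_col = 2L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no data lines in ", path, call. = FALSE)
  body <- lines[idx]
  sep <- if (grepl("\t", body[[1L]])) "\t" else ","
  parse_line <- function(ln) strsplit(ln, sep, fixed = TRUE)[[1L]]
  first <- suppressWarnings(as.numeric(parse_line(body[[1L]])))
  has_header <- anyNA(first)
  start <- if (has_header) 2L else 1L
  if (start > length(body)) stop("no data rows in ", path, call. = FALSE)
  rows <- lapply(seq(start, length(body)), function(i) {
    fields <- suppressWarnings(as.numeric(parse_line(body[[i]])))
    if (anyNA(fields) || length(fields) < value_col)
      stop(sprintf("parse error in %s at line %d: '%s'",
                   path, idx[i], body[[i]]), call. = FALSE)
    fields
  })
  wl <- vapply(rows, `[[`, numeric(1), 1L)
  val <- vapply(rows, `[[`, numeric(1), value_col)
  spectrum(wl, val, unit_role)
}

#' Write a spectrum to CSV
#'
#' @param spec An `rnl_spectrum`.
#' @param path Output path.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(is_spectrum(spec))
  lines <- c("wavelength,value",
             sprintf("%.17g,%.17g", spec$wl, spec$value))
  writeLines(lines, path)
  invisible(path)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation. Extrapolation beyond the data range is an error
#' unless `fill` supplies a constant to use outside the range.
#'
#' @param spec An `rnl_spectrum`.
#' @param grid Target wavelengths (nm), strictly increasing.
#' @param fill Optional constant for wavelengths outside the data range.
#' @return The resampled `rnl_spectrum` with the same `unit_role`.
#' @export
resample <- function(spec, grid = canonical_grid(), fill = NULL) {
  stopifnot(is_spectrum(spec))
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  outside <- grid < min(spec$wl) | grid > max(spec$wl)
  if (any(outside) && is.null(fill))
    stop(sprintf("grid extends outside spectrum range [%g, %g] nm; set fill= to allow",
                 min(spec$wl), max(spec$wl)), call. = FALSE)
  if (length(spec$wl) == 1L) {
    v <- rep(spec$value, length(grid))
  } else {
    v <- stats::approx(spec$wl, spec$value, xout = grid, rule = 1)$y
  }
  if (any(outside)) v[outside] <- fill
  spectrum(grid, v, spec$unit_role)
}

#' Coarser common grid of two spectra
#'
#' The overlapping wavelength range of both spectra, stepped at the coarser of
#' the two median step sizes. Used internally before any pairwise operation.
#'
#' @param s1,s2 `rnl_spectrum` objects.
#' @return Numeric wavelength grid.
#' @export
common_grid <- function(s1, s2) {
  lo <- max(min(s1$wl), min(s2$wl))
  hi <- min(max(s1$wl), max(s2$wl))
  if (lo >= hi) stop("spectra have disjoint wavelength ranges", call. = FALSE)
  step <- max(stats::median(diff(s1$wl)), stats::median(diff(s2$wl)))
  seq(lo, hi, by = step)
}

#' Convert energy radiance to quantum radiance
#'
#' Multiplies per wavelength by lambda / (h c): a photon at wavelength lambda
#' carries energy h c / lambda, so equal energy corresponds to more quanta at
#' longer wavelengths. Input in uW cm^-2 nm^-1 sr^-1, output in
#' quanta s^-1 cm^-2 nm^-1 sr^-1.
#'
#' @param spec An `rnl_spectrum` with `unit_role = "energy_radiance"`.
#' @return An `rnl_spectrum` with `unit_role = "quantum_radiance"`.
#' @export
energy_to_quanta <- function(spec) {
  assert_role(spec, "energy_radiance")
  # uW -> W is 1e-6; nm -> m is 1e-9
  photons <- spec$value * 1e-6 * (spec$wl * 1e-9) / (.PLANCK_H * .SPEED_C)
  spectrum(spec$wl, photons, "quantum_radiance")
}

#' Convert quantum radiance back to energy radiance
#'
#' Exact inverse of [energy_to_quanta()].
#'
#' @param spec An `rnl_spectrum` with `unit_role = "quantum_radiance"`.
#' @return An `rnl_spectrum` with `unit_role = "energy_radiance"`.
#' @export
quanta_to_energy <- function(spec) {
  assert_role(spec, "quantum_radiance")
  energy <- spec$value * (.PLANCK_H * .SPEED_C) / (spec$wl * 1e-9) / 1e-6
  spectrum(spec$wl, energy, "energy_radiance")
}

#' Arithmetic mean of several spectra
#'
#' Plain unweighted mean on the coarsest common grid; used e.g. to average
#' repeated radiance measurements taken at several angles or positions.
#'
#' @param specs List of `rnl_spectrum` objects sharing a `unit_role`.
#' @return An `rnl_spectrum`.
#' @export
spectrum_mean <- function(specs) {
  stopifnot(length(specs) >= 1L, all(vapply(specs, is_spectrum, logical(1))))
  roles <- unique(vapply(specs, `[[`, character(1), "unit_role"))
  if (length(roles) != 1L)
    stop("cannot average spectra with mixed unit roles", call. = FALSE)
  grid <- Reduce(function(g, s) common_grid(spectrum(g, numeric(length(g)) , roles), s),
                 specs[-1L], init = specs[[1L]]$wl)
  mat <- vapply(specs, function(s) resample(s, grid)$value,
                numeric(length(grid)))
  spectrum(grid, rowMeans(as.matrix(mat)), roles)
}

#' Trapezoid integral of a spectrum
#'
#' The single quadrature rule used throughout the package.
#'
#' @param spec An `rnl_spectrum`.
#' @return Numeric scalar.
#' @export
spectrum_integral <- function(spec) {
  stopifnot(is_spectrum(spec))
  if (length(spec$wl) < 2L) return(0)
  pracma::trapz(spec$wl, spec$value)
}

#' Serialize a spectrum to JSON
#'
#' @param spec An `rnl_spectrum`.
#' @param path Optional path; if `NULL` the JSON string is returned.
#' @export
spectrum_to_json <- function(spec, path = NULL) {
  stopifnot(is_spectrum(spec))
  obj <- list(unit_role = spec$unit_role, wavelength = spec$wl,
              value = spec$value)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Deserialize a spectrum from JSON
#'
#' @param json JSON string or path produced by [spectrum_to_json()].
#' @export
spectrum_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  spectrum(obj$wavelength, obj$value, obj$unit_role)
}
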