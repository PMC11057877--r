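#' Wavelength grid
#'
#' The common wavelength grid onto which every spectrum is resampled before
#' integration. The default covers 300-700 nm at 1 nm, the visible range of
#' *Amphiprion ocellaris* including the ultraviolet.
#'
#' @param start,stop Range in nm; `start < stop`.
#' @param step Grid step in nm, > 0.
#'
#' @return A numeric wavelength vector (nm), strictly increasing.
#' @export
#' @examples
#' wl_grid()[1:5]
wl_grid <- function(start = 300, stop = 700, step = 1) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (!(start < stop)) abort_chroma("wavelength grid requires start < stop")
  if (step <= 0) abort_chroma("wavelength grid step must be > 0")
  seq(start, stop, by = step)
}

spectrum_kinds <- c("radiance", "absorbance", "transmittance")

#' Build and validate a spectrum tibble
#'
#' A spectrum is an ordinary tibble with columns `wavelength` (nm, strictly
#' increasing) and `value` (non-negative). `kind` records what the values are:
#' `"radiance"` (photons s^-1 cm^-2 nm^-1), `"absorbance"` (normalised,
#' unitless) or `"transmittance"` (fraction in [0, 1]).
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param value Numeric vector of non-negative values, same length.
#' @param kind One of `"radiance"`, `"absorbance"`, `"transmittance"`.
#'
#' @return A tibble with columns `wavelength` and `value`.
#' @export
#' @examples
#' spectrum(c(400, 500), c(1, 2), kind = "radiance")
spectrum <- function(wavelength, value, kind = c("radiance", "absorbance", "transmittance")) {
  kind <- match.arg(kind)
  s <- tibble::tibble(wavelength = as.numeric(wavelength), value = as.numeric(value))
  validate_spectrum(s, kind)
}

#' @rdname spectrum
#' @param s A spectrum tibble to validate.
#' @export
validate_spectrum <- function(s, kind = NULL) {
  if (!all(c("wavelength", "value") %in% names(s))) {
    abort_chroma("a spectrum needs `wavelength` and `value` columns")
  }
  if (nrow(s) < 2) abort_chroma("a spectrum needs at least 2 points")
  if (anyNA(s$wavelength) || anyNA(s$value)) abort_chroma("spectrum contains missing values")
  if (any(diff(s$wavelength) <= 0)) {
    abort_chroma("spectrum wavelengths must be strictly increasing (duplicates not allowed)")
  }
  if (any(s$value < 0)) abort_chroma("spectrum values must be non-negative")
  if (!is.null(kind)) {
    kind <- match.arg(kind, spectrum_kinds)
    if (kind == "transmittance" && any(s$value > 1 + 1e-9)) {
      abort_chroma("transmittance values must lie in [0, 1]")
    }
  }
  tibble::as_tibble(s)
}

#' Read a two-column spectrum file
#'
#' Reads delimited text with wavelength in column 1 and value in column 2.
#' Comma, tab or whitespace delimited; lines starting with `#` are comments;
#' a single non-numeric header line is tolerated.
#'
#' @param path Path to the file.
#' @param kind Spectrum kind, see [spectrum()].
#'
#' @return A validated spectrum tibble.
#' @export
read_spectrum <- function(path, kind = c("radiance", "absorbance", "transmittance")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort_chroma(paste0("no such spectrum file: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) abort_chroma(paste0(path, ": no data rows"))
  parse_row <- function(line) {
    fields <- strsplit(trimws(line), "[,;\t ]+")[[1]]
    suppressWarnings(as.numeric(fields[1:2]))
  }
  parsed <- lapply(lines[idx], parse_row)
  bad <- vapply(parsed, function(p) anyNA(p) || length(p) < 2, logical(1))
  # allow one header line at the top only
  if (any(bad)) {
    if (bad[1] && !any(bad[-1])) {
      parsed <- parsed[-1]
      idx <- idx[-1]
    } else {
      abort_chroma(paste0(path, ": malformed row at line ", idx[which(bad & seq_along(bad) > 1)][1] %||% idx[1]))
    }
  }
  m <- do.call(rbind, parsed)
  wl <- m[, 1]
  if (any(diff(wl) <= 0)) {
    at <- idx[which(diff(wl) <= 0)[1] + 1]
    abort_chroma(paste0(path, ": wavelengths not strictly increasing at line ", at))
  }
  if (any(m[, 2] < 0)) {
    at <- idx[which(m[, 2] < 0)[1]]
    abort_chroma(paste0(path, ": negative value at line ", at))
  }
  spectrum(wl, m[, 2], kind = kind)
}

#' Write a spectrum to a two-column CSV
#'
#' @param s Spectrum tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  s <- validate_spectrum(s)
  utils::write.csv(s[, c("wavelength", "value")], path, row.names = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation onto `grid`. Requesting wavelengths outside the source
#' range is an error unless `zero_fill = TRUE`, in which case out-of-range
#' points are filled with 0 (appropriate for emission spectra that end before
#' the grid does; never appropriate for transmittance).
#'
#' @param s Spectrum tibble.
#' @param grid Numeric wavelength vector, see [wl_grid()].
#' @param zero_fill Fill out-of-range wavelengths with zero instead of erroring.
#'
#' @return A spectrum tibble on `grid`.
#' @export
resample_spectrum <- function(s, grid = wl_grid(), zero_fill = FALSE) {
  s <- validate_spectrum(s)
  rng <- range(s$wavelength)
  outside <- grid < rng[1] | grid > rng[2]
  if (any(outside) && !zero_fill) {
    abort_chroma(sprintf(
      "grid [%g, %g] exceeds source range [%g, %g]; set zero_fill = TRUE to pad with zeros",
      min(grid), max(grid), rng[1], rng[2]
    ))
  }
  v <- stats::approx(s$wavelength, s$value, xout = grid, rule = 1)$y
  v[is.na(v)] <- 0
  tibble::tibble(wavelength = as.numeric(grid), value = v)
}

#' Normalise a spectrum
#'
#' `mode = "max"` divides by the maximum value; `mode = "at_wavelength"`
#' divides by the value at `at` (lens transmission profiles are normalised to
#' their value at 700 nm).
#'
#' @param s Spectrum tibble.
#' @param mode `"max"` or `"at_wavelength"`.
#' @param at Wavelength (nm) for `mode = "at_wavelength"`.
#'
#' @return A spectrum tibble with the normalising value mapped to 1.
#' @export
normalise_spectrum <- function(s, mode = c("max", "at_wavelength"), at = 700) {
  mode <- match.arg(mode)
  s <- validate_spectrum(s)
  k <- switch(mode,
    max = max(s$value),
    at_wavelength = stats::approx(s$wavelength, s$value, xout = at, rule = 1)$y
  )
  if (is.na(k)) abort_chroma(sprintf("normalisation wavelength %g nm outside spectrum range", at))
  if (k <= 0) abort_chroma("normalising constant must be > 0")
  dplyr::mutate(s, value = .data$value / k)
}

#' Trapezoidal integral of the product of two spectra
#'
#' Both spectra must already sit on `grid` (use [resample_spectrum()]); this is
#' the integral that underlies every receptor quantum catch.
#'
#' @param a,b Spectrum tibbles on `grid`.
#' @param grid Common wavelength grid.
#'
#' @return A single non-negative number.
#' @export
integrate_product <- function(a, b, grid = wl_grid()) {
  a <- validate_spectrum(a)
  b <- validate_spectrum(b)
  if (!isTRUE(all.equal(a$wavelength, as.numeric(grid))) ||
      !isTRUE(all.equal(b$wavelength, as.numeric(grid)))) {
    abort_chroma("spectra are not aligned to the integration grid; resample first")
  }
  trapz(grid, a$value * b$value)
}

# trapezoid rule on an arbitrary (increasing) abscissa
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

abort_chroma <- function(msg) {
  rlang::abort(msg, class = "chromafish_error")
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0) y else x
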