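#' Govardovskii visual-pigment absorbance template
#'
#' Normalised absorbance of an A1 (retinal) or A2 (3,4-didehydroretinal)
#' visual pigment with peak absorbance at `lambda_max`, following the
#' Govardovskii et al. (2000) parameterisation: an alpha band in
#' `x = lambda_max / lambda` plus a Gaussian beta band. The curve is
#' renormalised so its maximum on the grid is exactly 1.
#'
#' @param lambda_max Peak wavelength in nm, within 330-600.
#' @param chromophore `"A1"` or `"A2"`.
#' @param grid Wavelength grid, see [wl_grid()].
#'
#' @return An absorbance spectrum tibble on `grid`, peak value 1.
#' @export
#' @examples
#' tpl <- pigment_template(386)
#' tpl$wavelength[which.max(tpl$value)]
pigment_template <- function(lambda_max, chromophore = c("A1", "A2"), grid = wl_grid()) {
  chromophore <- match.arg(chromophore)
  if (!is.numeric(lambda_max) || length(lambda_max) != 1 || is.na(lambda_max)) {
    abort_chroma("lambda_max must be a single number")
  }
  if (lambda_max < 330 || lambda_max > 600) {
    abort_chroma("lambda_max outside the template validity range [330, 600] nm")
  }
  lambda <- as.numeric(grid)
  x <- lambda_max / lambda
  if (chromophore == "A1") {
    a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
    alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                    exp(-14.9 * (1.104 - x)) + 0.674)
    bA <- 0.26
    lmb <- 189 + 0.315 * lambda_max
    bw <- -40.5 + 0.195 * lambda_max
  } else {
    A <- 62.7 + 1.834 * exp((lambda_max - 625) / 54.2)
    a <- 0.875 + 0.0268 * exp((lambda_max - 665) / 40.7)
    alpha <- 1 / (exp(A * (a - x)) + exp(20.85 * (0.9101 - x)) +
                    exp(-10.37 * (1.1123 - x)) + 0.5343)
    bA <- 0.37
    lmb <- 216.7 + 0.287 * lambda_max
    bw <- 150.5 + 0.112 * lambda_max
  }
  beta <- bA * exp(-((lambda - lmb) / bw)^2)
  v <- alpha + beta
  tibble::tibble(wavelength = lambda, value = v / max(v))
}

#' Estimate lambda-max from an absorbance scan
#'
#' Implements long-limb regression template fitting: the scan is normalised to
#' maximum 1; points on the long-wavelength limb (wavelengths beyond the
#' smoothed argmax) with normalised absorbance between 0.3 and 0.7 are fitted
#' by least squares of absorbance on wavelength; the wavelength at which the
#' regression line crosses 0.5 (`lambda50`) is then mapped to `lambda_max` by
#' numerically inverting the template's own long-limb 50% crossing (bisection
#' to 0.01 nm). With `chromophore = "auto"` both A1 and A2 templates are fitted
#' and the one with lower residual sum of squares over the full curve is kept.
#'
#' Normalisation uses a noise-robust peak estimate (quadratic fit to the
#' region around the smoothed argmax) rather than the raw maximum, which is
#' upward-biased for noisy scans.
#'
#' @param scan Absorbance spectrum tibble (one scan).
#' @param chromophore `"A1"`, `"A2"` or `"auto"`.
#' @param smooth Apply a 5-point boxcar to the whole scan before analysis
#'   (off by default; the peak search always smooths internally).
#'
#' @return A one-row tibble: `lambda_max`, `chromophore`, `lambda50`, `rss`,
#'   `n_points_used`, `slope`.
#' @export
estimate_lambda_max <- function(scan, chromophore = c("auto", "A1", "A2"), smooth = FALSE) {
  chromophore <- match.arg(chromophore)
  scan <- validate_spectrum(scan)
  if (smooth) scan$value <- boxcar(scan$value, 5)
  pk <- robust_peak(scan$wavelength, scan$value)
  if (pk$height <= 0) abort_chroma("scan peak height is not positive")
  scan$value <- scan$value / pk$height
  i_max <- pk$i_max
  limb <- scan[scan$wavelength > scan$wavelength[i_max], ]
  band <- limb[limb$value >= 0.3 & limb$value <= 0.7, ]
  if (nrow(band) < 3) {
    abort_chroma("fewer than 3 points in the 30-70% long-wavelength limb band")
  }
  fit <- stats::lm(value ~ wavelength, data = band)
  slope <- stats::coef(fit)[["wavelength"]]
  if (slope >= 0) abort_chroma("long-wavelength limb is not descending (slope >= 0)")
  lambda50 <- (0.5 - stats::coef(fit)[["(Intercept)"]]) / slope

  fit_one <- function(chrom) {
    lmax <- invert_template_lambda50(lambda50, chrom)
    tpl <- pigment_template(lmax, chrom, grid = scan$wavelength)
    tibble::tibble(
      lambda_max = lmax, chromophore = chrom, lambda50 = lambda50,
      rss = sum((scan$value - tpl$value)^2),
      n_points_used = nrow(band), slope = slope
    )
  }
  if (chromophore == "auto") {
    fits <- dplyr::bind_rows(fit_one("A1"), fit_one("A2"))
    fits[which.min(fits$rss), ]
  } else {
    fit_one(chromophore)
  }
}

# wavelength (> lambda_max) where the template crosses 0.5 on the long limb
template_lambda50 <- function(lambda_max, chromophore) {
  grid <- seq(lambda_max, min(lambda_max + 200, 800), by = 0.25)
  tpl <- pigment_template(lambda_max, chromophore, grid = grid)
  v <- tpl$value
  below <- which(v < 0.5)
  if (length(below) == 0) abort_chroma("template never falls below 0.5 on the long limb")
  j <- below[1]
  # linear interpolation between the bracketing grid points
  w <- grid[j - 1] + (0.5 - v[j - 1]) * (grid[j] - grid[j - 1]) / (v[j] - v[j - 1])
  w
}

# bisection: find lambda_max whose template long-limb 50% crossing is lambda50
invert_template_lambda50 <- function(lambda50, chromophore, tol = 0.01) {
  f <- function(lmax) template_lambda50(lmax, chromophore) - lambda50
  lo <- 330
  hi <- 600
  flo <- f(lo)
  fhi <- f(hi)
  if (flo > 0 || fhi < 0) {
    abort_chroma(sprintf(
      "lambda50 = %.1f nm cannot be bracketed by templates with lambda_max in [330, 600]",
      lambda50
    ))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Bin pigment scans by similar lambda-max and refit the bin means
#'
#' Scans are grouped by single linkage on their estimated `lambda_max`: scans
#' whose estimates differ by at most `gap` nm (directly or through a chain of
#' intermediates) share a bin. Within each bin the normalised absorbance
#' spectra are averaged on a common grid, renormalised, and re-fitted with
#' [estimate_lambda_max()].
#'
#' @param scans List of absorbance spectrum tibbles.
#' @param fits Tibble of per-scan fits, one row per scan (from
#'   [estimate_lambda_max()]); recomputed when omitted.
#' @param gap Linkage threshold in nm (default 10).
#' @param chromophore Passed on to the refit.
#'
#' @return A tibble with one row per bin: `bin`, `n_scans`, fit columns, and a
#'   `mean_scan` list-column holding the averaged spectrum.
#' @export
bin_scans <- function(scans, fits = NULL, gap = 10, chromophore = "auto") {
  if (length(scans) == 0) abort_chroma("no scans to bin")
  if (is.null(fits)) {
    fits <- purrr::map_dfr(scans, estimate_lambda_max, chromophore = chromophore)
  }
  stopifnot(nrow(fits) == length(scans))
  ord <- order(fits$lambda_max)
  lm_sorted <- fits$lambda_max[ord]
  # single linkage in 1-D: cut where consecutive gaps exceed the threshold
  cuts <- c(0, cumsum(diff(lm_sorted) > gap))
  bin_of <- integer(length(scans))
  bin_of[ord] <- cuts + 1
  purrr::map_dfr(sort(unique(bin_of)), function(b) {
    members <- which(bin_of == b)
    grids <- lapply(scans[members], function(s) s$wavelength)
    lo <- max(vapply(grids, min, numeric(1)))
    hi <- min(vapply(grids, max, numeric(1)))
    grid <- wl_grid(lo, hi, 1)
    mean_v <- rowMeans(vapply(
      scans[members],
      function(s) resample_spectrum(normalise_spectrum(s, "max"), grid)$value,
      numeric(length(grid))
    ))
    mean_scan <- tibble::tibble(wavelength = grid, value = mean_v / max(mean_v))
    refit <- estimate_lambda_max(mean_scan, chromophore = chromophore)
    dplyr::bind_cols(
      tibble::tibble(bin = b, n_scans = length(members)),
      refit,
      tibble::tibble(mean_scan = list(mean_scan))
    )
  })
}

#' Lens T50 from a transmission profile
#'
#' Normalises the profile to its value at 700 nm and locates T50, the
#' wavelength at which 50% of incident light is transmitted, as the
#' longest-wavelength upward crossing of 0.5 (linear interpolation between the
#' bracketing grid points). Multiple crossings trigger a warning and the
#' longest-wavelength one is used.
#'
#' @param transmission Transmittance spectrum tibble (raw or normalised).
#'
#' @return A list with `t50` (nm) and `transmittance` (the normalised profile).
#' @export
lens_t50 <- function(transmission) {
  s <- validate_spectrum(transmission)
  s <- normalise_spectrum(s, "at_wavelength", at = 700)
  v <- s$value
  up <- which(v[-length(v)] < 0.5 & v[-1] >= 0.5)
  if (length(up) == 0) abort_chroma("transmission profile never crosses 0.5 upward")
  if (length(up) > 1) {
    rlang::warn("multiple 0.5 crossings in lens profile; using the longest-wavelength one")
  }
  j <- up[length(up)]
  w <- s$wavelength
  t50 <- w[j] + (0.5 - v[j]) * (w[j + 1] - w[j]) / (v[j + 1] - v[j])
  list(t50 = t50, transmittance = s)
}

#' Filter a receptor absorbance curve through the lens
#'
#' Pointwise product of receptor absorbance and lens transmittance on the
#' receptor's grid, renormalised to peak 1. This yields the in-situ spectral
#' sensitivity used in all quantum-catch calculations.
#'
#' @param receptor Absorbance spectrum tibble.
#' @param lens A lens profile from [lens_t50()], or a transmittance spectrum.
#'
#' @return An absorbance spectrum tibble, peak value 1.
#' @export
apply_lens <- function(receptor, lens) {
  receptor <- validate_spectrum(receptor)
  trans <- if (is.list(lens) && !is.data.frame(lens)) lens$transmittance else lens
  trans <- resample_spectrum(validate_spectrum(trans), receptor$wavelength)
  v <- receptor$value * pmin(trans$value, 1)
  if (max(v) <= 0) abort_chroma("lens-filtered receptor curve is identically zero")
  tibble::tibble(wavelength = receptor$wavelength, value = v / max(v))
}

# noise-robust peak: argmax of a 5-point boxcar, height from a quadratic fit
# to the raw values within +/- 25 nm of it
robust_peak <- function(wl, v) {
  sm <- boxcar(v, 5)
  i_max <- which.max(sm)
  win <- abs(wl - wl[i_max]) <= 25
  if (sum(win) >= 5) {
    fit <- stats::lm(v[win] ~ stats::poly(wl[win], 2))
    height <- max(stats::fitted(fit))
  } else {
    height <- v[i_max]
  }
  list(i_max = i_max, height = height)
}

boxcar <- function(v, width) {
  k <- rep(1 / width, width)
  as.numeric(stats::filter(v, k, sides = 2)) -> sm
  sm[is.na(sm)] <- v[is.na(sm)]
  sm
}
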