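#' Construct a visual system
#'
#' Bundles an ordered set of receptor classes — lens-filtered spectral
#' sensitivities, per-class Weber-fraction numerators `sigma` and relative
#' cone abundances `eta` — into the object every colour-model function takes.
#' Per-channel noise is derived as `e = sigma / sqrt(eta)`
#' (see [receptor_noise()]). Receptors must be ordered by increasing
#' `lambda_max`; 2 to 4 classes are supported (dichromat through tetrachromat).
#'
#' @param sensitivities Named list of sensitivity spectrum tibbles, one per
#'   receptor class, already filtered by the lens (see [apply_lens()]), in
#'   order of increasing lambda-max. Names are the receptor labels
#'   (e.g. `U`, `M1`, `M2`, `L`).
#' @param sigma Numeric vector of Weber numerators, one per class (recycled if
#'   length 1).
#' @param eta Numeric vector of relative cone abundances, one per class
#'   (recycled if length 1).
#' @param grid Wavelength grid all sensitivities are resampled to.
#'
#' @return An object of class `visual_system`: a list with `receptors` (a
#'   tibble with columns `receptor`, `lambda_max`, `sigma`, `eta`, `e`, and a
#'   `sensitivity` list-column) and `grid`.
#' @export
visual_system <- function(sensitivities, sigma, eta = 1, grid = wl_grid()) {
  n <- length(sensitivities)
  if (n < 2 || n > 4) abort_chroma("visual_system supports 2-4 receptor classes")
  labels <- names(sensitivities) %||% paste0("R", seq_len(n))
  if (is.null(names(sensitivities)) || any(!nzchar(labels))) {
    abort_chroma("sensitivities must be a named list (receptor labels)")
  }
  sigma <- rep_len(as.numeric(sigma), n)
  eta <- rep_len(as.numeric(eta), n)
  sens <- lapply(sensitivities, function(s) resample_spectrum(validate_spectrum(s), grid))
  lmax <- vapply(sens, function(s) s$wavelength[which.max(s$value)], numeric(1))
  if (any(diff(lmax) <= 0)) {
    abort_chroma("receptors must be ordered by strictly increasing lambda_max")
  }
  e <- receptor_noise(sigma, eta)$e
  receptors <- tibble::tibble(
    receptor = labels, lambda_max = lmax,
    sigma = sigma, eta = eta, e = e,
    sensitivity = unname(sens)
  )
  structure(
    list(
      receptors = receptors,
      grid = as.numeric(grid),
      # sensitivity matrix cached for fast quantum-catch integrals
      R = vapply(sens, function(s) s$value, numeric(length(grid)))
    ),
    class = "visual_system"
  )
}

#' @export
print.visual_system <- function(x, ...) {
  cat(sprintf(
    "<visual_system: %d receptors on %g-%g nm>\n",
    nrow(x$receptors), min(x$grid), max(x$grid)
  ))
  print(dplyr::select(x$receptors, -"sensitivity"))
  invisible(x)
}

n_receptors <- function(vs) nrow(vs$receptors)

#' Per-channel receptor noise
#'
#' The noise level of each receptor channel is the Weber-fraction numerator
#' `sigma` (coefficient of variation of noise in a single cone) attenuated by
#' the square root of the relative abundance `eta` of that cone class:
#' `e = sigma / sqrt(eta)`.
#'
#' @param sigma Per-class Weber numerators, > 0.
#' @param eta Per-class relative cone abundances, > 0.
#'
#' @return A tibble with columns `sigma`, `eta`, `e`.
#' @export
#' @examples
#' receptor_noise(c(0.11, 0.14, 0.14, 0.14), c(1, 2, 1, 1))
receptor_noise <- function(sigma, eta) {
  if (any(sigma <= 0) || any(eta <= 0)) abort_chroma("sigma and eta must be > 0")
  n <- max(length(sigma), length(eta))
  sigma <- rep_len(as.numeric(sigma), n)
  eta <- rep_len(as.numeric(eta), n)
  tibble::tibble(sigma = sigma, eta = eta, e = sigma / sqrt(eta))
}

#' Receptor quantum catches with von Kries adaptation
#'
#' For each receptor class i, the background-relative quantum catch is
#' `q_i = integral(S(l) R_i(l) dl) / integral(S_b(l) R_i(l) dl)`: the raw
#' catch of the stimulus scaled by the adapting coefficient `k_i`, the inverse
#' of the background catch (von Kries normalisation). The log-signal is
#' `f_i = ln(q_i)`. Viewing the background itself gives `q = 1`, `f = 0` in
#' every class — the achromatic point.
#'
#' @param stimulus Radiance spectrum tibble on the model grid.
#' @param background Adapting background radiance spectrum tibble on the grid.
#' @param vs A [visual_system()].
#'
#' @return A tibble with one row per receptor: `receptor`, `q`, `f`.
#' @export
quantum_catch <- function(stimulus, background, vs) {
  stopifnot(inherits(vs, "visual_system"))
  s <- resample_spectrum(validate_spectrum(stimulus), vs$grid, zero_fill = TRUE)
  b <- resample_spectrum(validate_spectrum(background), vs$grid, zero_fill = TRUE)
  raw_s <- catch_integrals(s$value, vs)
  raw_b <- catch_integrals(b$value, vs)
  labels <- vs$receptors$receptor
  if (any(raw_b <= 0)) {
    abort_chroma(paste0(
      "zero background catch (von Kries k undefined) in receptor: ",
      paste(labels[raw_b <= 0], collapse = ", ")
    ))
  }
  if (any(raw_s <= 0)) {
    abort_chroma(paste0(
      "zero stimulus catch (log-signal undefined) in receptor: ",
      paste(labels[raw_s <= 0], collapse = ", ")
    ))
  }
  q <- raw_s / raw_b
  tibble::tibble(receptor = labels, q = q, f = log(q))
}

# trapezoid integrals of radiance (vector on grid) against every sensitivity
catch_integrals <- function(values, vs) {
  g <- vs$grid
  w <- diff(g)
  prod <- values * vs$R
  n <- length(g)
  as.numeric(w %*% (prod[-1, , drop = FALSE] + prod[-n, , drop = FALSE]) / 2)
}

catch_f <- function(qc) {
  if (is.data.frame(qc)) qc$f else log(qc)
}

#' Chromatic distance under the log receptor-noise-limited model
#'
#' The Vorobyev-Osorio RNL distance between two stimuli, in units of
#' just-noticeable differences. Log-signal differences `df_i = f_i^a - f_i^b`
#' are whitened by the channel noises `e_i` and projected onto the chromatic
#' subspace (the orthogonal complement of the achromatic direction, in which
#' all receptors change together); delta-S is the Euclidean norm of that
#' projection. For 2-4 receptors this reproduces the published dichromat,
#' trichromat and tetrachromat closed forms.
#'
#' @param a,b Quantum-catch tibbles from [quantum_catch()] (or bare numeric
#'   `q` vectors).
#' @param vs A [visual_system()] supplying the noise vector `e`.
#'
#' @return A single non-negative number (delta-S).
#' @export
rnl_delta_s <- function(a, b, vs) {
  e <- vs$receptors$e
  fa <- catch_f(a)
  fb <- catch_f(b)
  if (length(fa) != length(e) || length(fb) != length(e)) {
    abort_chroma("catch vectors do not match the visual system's receptor count")
  }
  delta_s_from_df(fa - fb, e)
}

# whitened projection orthogonal to the achromatic direction
delta_s_from_df <- function(df, e) {
  u <- df / e
  w <- 1 / e
  w <- w / sqrt(sum(w^2))
  proj <- u - sum(u * w) * w
  sqrt(sum(proj^2))
}
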