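#' Noise-corrected Cartesian coordinates in tetrahedral colour space
#'
#' Maps a quantum-catch vector of a tetrachromatic visual system to a point
#' `(x, y, z)` such that (i) Euclidean distance between any two mapped points
#' equals their [rnl_delta_s()], (ii) the achromatic reference maps to the
#' origin, and (iii) the axes follow the opponent contrasts of the tetrahedral
#' space: increasing `L - (M1 + M2)` signal projects to +x, `M1 - (M2 + L)` to
#' +y, and `U - (M1 + M2 + L)` to +z. The map is a whitening of the chromatic
#' subspace followed by a fixed rotation (Gram-Schmidt on the three opponent
#' contrasts, signs anchored so that exciting L, M1 or U alone moves the point
#' in +x, +y or +z respectively).
#'
#' @param catch Quantum-catch tibble from [quantum_catch()] (or numeric `q`).
#' @param vs A tetrachromatic [visual_system()].
#' @param reference Achromatic reference catch; defaults to the background
#'   itself (`q = 1` in every class).
#'
#' @return A one-row tibble with columns `x`, `y`, `z` and `delta_s` (the
#'   distance from the reference, equal to the Euclidean norm of `(x, y, z)`).
#' @export
noise_corrected_xyz <- function(catch, vs, reference = NULL) {
  if (n_receptors(vs) != 4) {
    abort_chroma("noise-corrected xyz coordinates require a tetrachromatic visual system")
  }
  e <- vs$receptors$e
  f <- catch_f(catch)
  f0 <- if (is.null(reference)) rep(0, 4) else catch_f(reference)
  df <- f - f0
  B <- chromatic_basis(e)
  xyz <- as.numeric(crossprod(B, df / e))
  tibble::tibble(x = xyz[1], y = xyz[2], z = xyz[3], delta_s = sqrt(sum(xyz^2)))
}

# Orthonormal basis (4 x 3) of the chromatic subspace in whitened signal space.
# Columns are the x, y, z axes; receptor order (U, M1, M2, L) is assumed.
chromatic_basis <- function(e) {
  w <- 1 / e
  w <- w / sqrt(sum(w^2))
  contrasts <- cbind(
    x = c(0, -1, -1, 1),  # L - (M1 + M2)
    y = c(0, 1, -1, -1),  # M1 - (M2 + L)
    z = c(1, -1, -1, -1)  # U - (M1 + M2 + L)
  )
  basis <- matrix(0, 4, 3, dimnames = list(NULL, colnames(contrasts)))
  prev <- list(w)
  for (j in 1:3) {
    v <- contrasts[, j] / e
    for (p in prev) v <- v - sum(v * p) * p
    v <- v / sqrt(sum(v^2))
    basis[, j] <- v
    prev <- c(prev, list(v))
  }
  # anchor signs: exciting L / M1 / U alone must project positively on x / y / z
  anchor <- c(x = 4L, y = 2L, z = 1L)
  for (j in 1:3) if (basis[anchor[j], j] < 0) basis[, j] <- -basis[, j]
  basis
}

#' Hue angles of a colour vector
#'
#' Spherical angles of a point in the noise-corrected space: elevation `theta`
#' is the signed angle (degrees) between the vector and its projection onto
#' the xy plane of the double cones (positive above the plane, i.e. net UV
#' excitation; -90 to 90); azimuth `phi` is the bearing in the xy plane from
#' the +x (L-cone) axis measured through +y, mapped to [0, 360) by adding 360
#' to negative angles. At the poles (`x = y = 0`) the azimuth is undefined and
#' reported as `NA`.
#'
#' @param v A tibble with columns `x`, `y`, `z` (one or more rows), or a
#'   length-3 numeric vector.
#'
#' @return A tibble with columns `theta` and `phi` in degrees.
#' @export
#' @examples
#' hue_angles(c(1, 1, 0)) # theta 0, phi 45
hue_angles <- function(v) {
  if (is.numeric(v)) v <- tibble::tibble(x = v[1], y = v[2], z = v[3])
  stopifnot(all(c("x", "y", "z") %in% names(v)))
  r <- sqrt(v$x^2 + v$y^2 + v$z^2)
  if (any(r == 0)) abort_chroma("hue angles of the zero vector are undefined")
  theta <- asin(pmin(pmax(v$z / r, -1), 1)) * 180 / pi
  phi <- atan2(v$y, v$x) * 180 / pi
  phi <- ifelse(phi < 0, phi + 360, phi)
  phi[v$x == 0 & v$y == 0] <- NA_real_
  tibble::tibble(theta = theta, phi = phi)
}

#' Find complementary colour pairs from azimuth angles
#'
#' Colours on opposite sides of the achromatic point have azimuths about 180
#' degrees apart; their mixture is achromatic. Returns every unordered pair of
#' labels whose circular azimuth difference lies within `tolerance` degrees of
#' 180, sorted by closeness to exact polarity. When `sets` also carries an
#' elevation column `theta`, only pairs with opposite elevation signs are
#' considered — lying on opposite sides of the achromatic point constrains the
#' whole vector, not just its bearing in the double-cone plane. A label may
#' appear in more than one candidate pair.
#'
#' @param sets Tibble with columns `label` and `phi` (degrees), optionally
#'   `theta`.
#' @param tolerance Acceptance half-width in degrees, in (0, 90); default 15.
#'
#' @return A tibble with columns `label_a`, `label_b`, `delta_phi` (circular
#'   difference) and `deviation` (absolute distance from 180).
#' @export
complementary_pairs <- function(sets, tolerance = 15) {
  if (!(tolerance > 0 && tolerance < 90)) abort_chroma("tolerance must lie in (0, 90) degrees")
  stopifnot(all(c("label", "phi") %in% names(sets)))
  sets <- sets[!is.na(sets$phi), ]
  n <- nrow(sets)
  if (n < 2) {
    return(tibble::tibble(
      label_a = character(), label_b = character(),
      delta_phi = numeric(), deviation = numeric()
    ))
  }
  pairs <- utils::combn(n, 2)
  d <- abs(sets$phi[pairs[1, ]] - sets$phi[pairs[2, ]]) %% 360
  d <- ifelse(d > 180, 360 - d, d)
  keep <- rep(TRUE, ncol(pairs))
  if ("theta" %in% names(sets)) {
    keep <- sign(sets$theta[pairs[1, ]]) * sign(sets$theta[pairs[2, ]]) < 0
  }
  out <- tibble::tibble(
    label_a = sets$label[pairs[1, ]],
    label_b = sets$label[pairs[2, ]],
    delta_phi = d,
    deviation = abs(180 - d)
  )[keep, ]
  dplyr::arrange(out[out$deviation <= tolerance, ], .data$deviation)
}

#' Is a stimulus a non-spectral colour?
#'
#' A colour is non-spectral (the human analogue of purple) when it excites
#' spectrally non-adjacent receptor classes more than some intermediate class:
#' with receptors ordered by lambda-max, there exist i < j < k with
#' `q_i > q_j` and `q_k > q_j`. Such colours cannot be matched by mixing a
#' monochromatic light with grey.
#'
#' @param catch Quantum-catch tibble from [quantum_catch()] (or numeric `q`
#'   in receptor order).
#'
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' classify_non_spectral(c(2, 1, 1, 2)) # UV-red: TRUE
classify_non_spectral <- function(catch) {
  q <- if (is.data.frame(catch)) catch$q else as.numeric(catch)
  n <- length(q)
  if (n < 3) abort_chroma("non-spectral classification needs at least 3 receptors")
  for (j in 2:(n - 1)) {
    if (max(q[1:(j - 1)]) > q[j] && max(q[(j + 1):n]) > q[j]) return(TRUE)
  }
  FALSE
}
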