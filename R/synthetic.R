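#' Configuration for the synthetic experiment
#'
#' Defaults reproduce the study conditions the package emulates: a
#' five-channel LED display peaking at 367/395/466/526/629 nm, four cone
#' classes at 386/497/515/535 nm filtered by a lens with T50 = 334 nm,
#' receptor noise sigma = 0.11 (single UV cone) and 0.14 (double cones) with
#' cone abundance ratio 1:2:1:1, nine colour lines of 6-11 targets radiating
#' from the achromatic point, 13 grey distractors, and planted logistic
#' psychometric functions whose thresholds are the nine reported set means.
#'
#' @param led_peaks LED channel peak wavelengths (nm).
#' @param led_fwhm LED emission full width at half maximum (nm).
#' @param background_level Flat background screen radiance (same photon units
#'   as the channels, whose peak radiance is 1).
#' @param cone_lambda_max Cone peak wavelengths (nm), increasing.
#' @param lens_t50 Lens 50%-transmission wavelength (nm).
#' @param lens_slope Logistic slope of the lens profile (per nm).
#' @param sigma_single,sigma_double Weber numerators for single / double
#'   cones.
#' @param cone_ratio Relative cone abundances (U, M1, M2, L).
#' @param trials_per_level Behavioural trials per fish per target level.
#' @param fish_per_set Fish tested per colour set.
#' @param n_greys Grey distractors.
#' @param max_ds Largest delta-S on each colour line.
#' @param sets Tibble describing the nine colour lines: `label`, `theta`,
#'   `phi` (direction angles, degrees), `n_targets`, and the planted
#'   psychometric location `m` and spread `s`.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(led_peaks = c(367, 395, 466, 526, 629),
                             led_fwhm = 20,
                             background_level = 0.02,
                             cone_lambda_max = c(386, 497, 515, 535),
                             lens_t50 = 334,
                             lens_slope = 0.1,
                             sigma_single = 0.11,
                             sigma_double = 0.14,
                             cone_ratio = c(1, 2, 1, 1),
                             trials_per_level = 10,
                             fish_per_set = 5,
                             n_greys = 13,
                             max_ds = 3,
                             sets = default_colour_sets()) {
  cfg <- list(
    led_peaks = led_peaks, led_fwhm = led_fwhm,
    background_level = background_level,
    cone_lambda_max = cone_lambda_max,
    lens_t50 = lens_t50, lens_slope = lens_slope,
    sigma_single = sigma_single, sigma_double = sigma_double,
    cone_ratio = cone_ratio,
    trials_per_level = trials_per_level, fish_per_set = fish_per_set,
    n_greys = n_greys, max_ds = max_ds, sets = sets
  )
  structure(cfg, class = "synthetic_config")
}

#' Default colour-line directions and planted thresholds
#'
#' Nine colour sets named as in the study: four UV-positive lines (positive
#' elevation: UV, UV-blue, violet-green, UV-red) and five UV-negative ones.
#' Direction angles are synthetic stand-ins chosen inside the synthetic
#' display's gamut (the published per-target LED weights are external
#' supplementary data and not reproducible from the article text) but keep
#' the study's geometry: two complementary pairs sit at exactly polar
#' azimuths (UV/green and purple/violet-green) while every other azimuth pair
#' is at least 20 degrees away from polarity. Planted thresholds `m` are the
#' nine reported set means; spreads `s` are steeper for the sets reported to
#' have steep psychometric functions (orange, red, violet-green, UV-red).
#' `max_ds` is each line's largest delta-S, limited by the display gamut
#' along its direction.
#'
#' @return A tibble with columns `label`, `theta`, `phi`, `n_targets`,
#'   `max_ds`, `m`, `s`.
#' @export
default_colour_sets <- function() {
  tibble::tribble(
    ~label,         ~theta, ~phi, ~n_targets, ~max_ds, ~m,  ~s,
    "UV",               65,   30,        10,     3.0, 0.8, 0.30,
    "UV-blue",          12,  140,         6,     2.0, 0.8, 0.30,
    "violet-green",     50,  120,         9,     3.0, 0.4, 0.15,
    "UV-red",           58,   60,        11,     2.0, 0.9, 0.15,
    "blue",            -55,  190,         9,     3.0, 1.5, 0.30,
    "green",           -70,  210,         9,     3.0, 1.2, 0.30,
    "red",             -10,  340,         9,     2.0, 1.0, 0.15,
    "orange",           -4,  350,         7,     2.0, 0.8, 0.15,
    "purple",          -70,  300,         6,     3.0, 1.6, 0.30
  )
}

# spherical angles (deg) to unit xyz
angles_to_direction <- function(theta, phi) {
  t <- theta * pi / 180
  p <- phi * pi / 180
  c(cos(t) * cos(p), cos(t) * sin(p), sin(t))
}

#' Generate the synthetic LED display
#'
#' Five Gaussian emission channels at the configured peaks and FWHM (peak
#' radiance 1, arbitrary photon units) over a low, spectrally flat background
#' screen radiance.
#'
#' @param cfg A [synthetic_config()].
#' @param grid Wavelength grid.
#' @return An [led_display()].
#' @export
gen_led_display <- function(cfg = synthetic_config(), grid = wl_grid()) {
  sd <- cfg$led_fwhm / (2 * sqrt(2 * log(2)))
  channels <- lapply(cfg$led_peaks, function(peak) {
    tibble::tibble(wavelength = as.numeric(grid), value = exp(-(grid - peak)^2 / (2 * sd^2)))
  })
  names(channels) <- paste0("ch", round(cfg$led_peaks))
  background <- tibble::tibble(
    wavelength = as.numeric(grid),
    value = rep(cfg$background_level, length(grid))
  )
  led_display(channels, background, grid = grid)
}

#' Generate the synthetic visual system
#'
#' A1 pigment templates at the configured lambda-max values, filtered by a
#' logistic lens (midpoint `lens_t50`, slope `lens_slope`), renormalised, with
#' noise derived from the configured sigma values and cone ratio.
#'
#' @param cfg A [synthetic_config()].
#' @param grid Wavelength grid.
#' @return A [visual_system()].
#' @export
gen_visual_system <- function(cfg = synthetic_config(), grid = wl_grid()) {
  lens <- gen_lens(cfg$lens_t50, cfg$lens_slope, grid)
  sens <- lapply(cfg$cone_lambda_max, function(lm) {
    apply_lens(pigment_template(lm, "A1", grid), lens)
  })
  names(sens) <- receptor_labels(length(sens))
  n <- length(sens)
  sigma <- c(cfg$sigma_single, rep(cfg$sigma_double, n - 1))
  visual_system(sens, sigma = sigma, eta = cfg$cone_ratio, grid = grid)
}

receptor_labels <- function(n) {
  c("U", paste0("M", seq_len(max(n - 2, 0))), "L")[1:n]
}

#' Generate a logistic lens transmission profile
#'
#' @param t50 Midpoint (nm): the 50%-transmission wavelength.
#' @param slope Logistic steepness (per nm).
#' @param grid Wavelength grid.
#' @return A transmittance spectrum tibble.
#' @export
gen_lens <- function(t50 = 334, slope = 0.1, grid = wl_grid()) {
  tibble::tibble(
    wavelength = as.numeric(grid),
    value = stats::plogis(slope * (grid - t50))
  )
}

#' Generate synthetic microspectrophotometry absorbance scans
#'
#' A pigment template plus independent Gaussian noise per wavelength and an
#' optional linear baseline drift; values are clipped at zero (absorbance
#' cannot be negative). Deterministic under `seed`.
#'
#' @param lambda_max True pigment peak (nm).
#' @param n Number of scans.
#' @param noise_sd Gaussian noise standard deviation (absorbance units).
#' @param drift Maximum baseline drift across the scan range (uniform in
#'   `[-drift, drift]` per scan).
#' @param chromophore `"A1"` or `"A2"`.
#' @param seed Integer seed; required when `noise_sd > 0` or `drift > 0`.
#' @param grid Wavelength grid.
#'
#' @return A list of `n` absorbance spectrum tibbles.
#' @export
gen_msp_scans <- function(lambda_max, n = 1, noise_sd = 0.05, drift = 0,
                          chromophore = "A1", seed = 1, grid = wl_grid()) {
  tpl <- pigment_template(lambda_max, chromophore, grid)
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      v <- tpl$value + stats::rnorm(length(grid), 0, noise_sd)
      if (drift > 0) {
        d <- stats::runif(1, -drift, drift)
        v <- v + d * seq(-0.5, 0.5, length.out = length(grid))
      }
      tibble::tibble(wavelength = tpl$wavelength, value = pmax(v, 0))
    })
  })
}

#' Generate behavioural choice data from planted psychometric functions
#'
#' For each colour set, fish and target level, draws Bernoulli
#' correct/incorrect trials with probability given by the planted logistic
#' psychometric function `gamma + (1 - gamma - lapse) * F((dS - m)/s)`.
#' Zero-contrast control rows with success probability `gamma` are appended
#' per fish. Deterministic under `seed`. Warns when a planted location lies
#' outside the delta-S range of its line (the threshold is then unrecoverable
#' by design).
#'
#' @param lines Target tibble with columns `label` and `delta_s` (one row per
#'   target; e.g. rows of [build_colour_line()] results).
#' @param planted Tibble with columns `label`, `m`, `s` (per-set psychometric
#'   parameters); defaults taken from `cfg$sets`.
#' @param cfg A [synthetic_config()] (supplies trial counts and fish).
#' @param gamma Guess rate for control trials.
#' @param lapse Planted lapse rate.
#' @param n_controls Control trials per fish.
#' @param seed Integer seed; required.
#'
#' @return A trial tibble: `fish_id`, `colour_set`, `level`, `delta_s`,
#'   `correct`.
#' @export
gen_choice_data <- function(lines, planted = NULL, cfg = synthetic_config(),
                            gamma = 0, lapse = 0, n_controls = 2, seed) {
  if (missing(seed)) abort_chroma("gen_choice_data requires a seed")
  stopifnot(all(c("label", "delta_s") %in% names(lines)))
  if (is.null(planted)) planted <- cfg$sets[, c("label", "m", "s")]
  labels <- unique(lines$label)
  withr::with_seed(seed, {
    purrr::map_dfr(labels, function(lab) {
      pl <- planted[planted$label == lab, ]
      if (nrow(pl) == 0) abort_chroma(paste0("no planted parameters for set ", lab))
      ds <- sort(lines$delta_s[lines$label == lab])
      if (pl$m > max(ds) || pl$m < min(ds)) {
        rlang::warn(sprintf(
          "planted threshold %.2f dS lies outside the '%s' line range [%.2f, %.2f]",
          pl$m, lab, min(ds), max(ds)
        ))
      }
      purrr::map_dfr(seq_len(cfg$fish_per_set), function(fish) {
        p <- psy_curve(ds, pl$m, pl$s, gamma, lapse, "logistic")
        test <- tibble::tibble(
          fish_id = sprintf("%s_f%02d", lab, fish),
          colour_set = lab,
          level = rep(seq_along(ds), each = cfg$trials_per_level),
          delta_s = rep(ds, each = cfg$trials_per_level),
          correct = stats::rbinom(length(ds) * cfg$trials_per_level, 1,
                                  rep(p, each = cfg$trials_per_level))
        )
        controls <- tibble::tibble(
          fish_id = test$fish_id[1], colour_set = lab,
          level = 0L, delta_s = 0,
          correct = stats::rbinom(n_controls, 1, gamma)
        )
        dplyr::bind_rows(test, controls)
      })
    })
  })
}
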