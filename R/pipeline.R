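#' Generate a complete synthetic experiment
#'
#' Builds every input of the analysis pipeline with known ground truth: the
#' LED display, the visual system, the nine colour lines, the grey distractor
#' set, and behavioural choice data from the planted psychometric functions.
#' Deterministic given (`cfg`, `seed`).
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed; required.
#'
#' @return A list of class `chroma_experiment`: `cfg`, `seed`, `display`,
#'   `vs`, `targets` (tibble over all lines), `greys`, `trials`, and `truth`
#'   (the planted per-set parameters).
#' @export
generate_experiment <- function(cfg = synthetic_config(), seed) {
  if (missing(seed)) abort_chroma("generate_experiment requires a seed")
  display <- gen_led_display(cfg)
  vs <- gen_visual_system(cfg)
  sets <- cfg$sets
  if (!"max_ds" %in% names(sets)) sets$max_ds <- cfg$max_ds
  targets <- purrr::pmap_dfr(
    sets[, c("label", "theta", "phi", "n_targets", "max_ds")],
    function(label, theta, phi, n_targets, max_ds) {
      build_colour_line(
        display, vs,
        direction = angles_to_direction(theta, phi),
        n = n_targets, max_ds = max_ds, label = label
      )
    }
  )
  greys <- select_grey_set(display, vs, n = cfg$n_greys, seed = seed + 1L)
  trials <- gen_choice_data(targets, cfg = cfg, seed = seed + 2L)
  structure(
    list(
      cfg = cfg, seed = seed, display = display, vs = vs,
      targets = targets, greys = greys, trials = trials,
      truth = cfg$sets
    ),
    class = "chroma_experiment"
  )
}

#' @export
print.chroma_experiment <- function(x, ...) {
  cat(sprintf(
    "<chroma_experiment: %d colour sets, %d targets, %d greys, %d trials (seed %d)>\n",
    length(unique(x$targets$label)), nrow(x$targets), nrow(x$greys),
    nrow(x$trials), x$seed
  ))
  invisible(x)
}

#' Score stimuli through the full colour model
#'
#' Recomputes, for every target, the quantum catches, delta-S from the
#' achromatic point, noise-corrected coordinates, hue angles and the
#' non-spectral flag; and reports per-set direction angles plus candidate
#' complementary pairs.
#'
#' @param experiment A `chroma_experiment` from [generate_experiment()], or a
#'   list with `display`, `vs` and `targets`.
#' @param tolerance Complementarity tolerance in degrees.
#'
#' @return A list with `targets` (per-target scores), `sets` (per-set angles,
#'   means over the line) and `complementary` (pair table).
#' @export
score_stimuli <- function(experiment, tolerance = 15) {
  display <- experiment$display
  vs <- experiment$vs
  targets <- experiment$targets
  scored <- purrr::pmap_dfr(
    targets[, c("label", "level", "weights")],
    function(label, level, weights) {
      qc <- quantum_catch(mix_leds(display, weights), display$background, vs)
      p <- noise_corrected_xyz(qc, vs)
      ang <- hue_angles(p)
      tibble::tibble(
        label = label, level = level, delta_s = p$delta_s,
        x = p$x, y = p$y, z = p$z, theta = ang$theta, phi = ang$phi,
        non_spectral = classify_non_spectral(qc)
      )
    }
  )
  sets <- dplyr::summarise(
    dplyr::group_by(scored, .data$label),
    theta = mean(.data$theta), phi = mean_circular(.data$phi),
    non_spectral = any(.data$non_spectral),
    .groups = "drop"
  )
  comp <- complementary_pairs(sets, tolerance = tolerance)
  list(targets = scored, sets = sets, complementary = comp)
}

mean_circular <- function(phi) {
  phi <- phi[!is.na(phi)]
  if (length(phi) == 0) return(NA_real_)
  r <- phi * pi / 180
  m <- atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
  if (m < 0) m + 360 else m
}

#' Run the full analysis pipeline on an experiment
#'
#' Orchestrates the stages end-to-end: score the stimuli (delta-S, hue
#' angles, non-spectral flags, complementary pairs), fit per-fish
#' psychometric thresholds and summarise them per colour set, and - when
#' `scan = TRUE` - scan trichromat/tetrachromat model variants over the sigma
#' grid. Deterministic given the experiment and `seed`.
#'
#' @param experiment A `chroma_experiment` from [generate_experiment()].
#' @param seed Seed for the threshold bootstrap.
#' @param n_boot Bootstrap resamples per psychometric fit (0 to skip).
#' @param scan Run the model-variant scan (the slowest stage).
#' @param sigma_grid Sigma grid for the scan.
#'
#' @return A list of class `chroma_report`: `scores`, `fits`, `set_summary`,
#'   and (if requested) `model_scan` plus `best_model`.
#' @export
run_pipeline <- function(experiment, seed = experiment$seed, n_boot = 0,
                         scan = FALSE, sigma_grid = seq(0.05, 0.15, by = 0.01)) {
  stopifnot(inherits(experiment, "chroma_experiment"))
  scores <- score_stimuli(experiment)
  fits <- fit_thresholds(experiment$trials, n_boot = n_boot, seed = seed + 3L)
  set_angles <- dplyr::rename(scores$sets, colour_set = "label")
  set_summary <- summarise_thresholds(fits, set_angles = set_angles)
  out <- list(
    scores = scores, fits = fits, set_summary = set_summary,
    seed = seed
  )
  if (scan) {
    stimuli <- dplyr::mutate(
      experiment$targets[, c("label", "level", "weights")],
      colour_set = .data$label,
      spectrum = purrr::map(.data$weights, ~ mix_leds(experiment$display, .x))
    )
    out$model_scan <- scan_models(
      experiment$trials, stimuli, experiment$display$background,
      experiment$vs, sigma_grid = sigma_grid
    )
    out$best_model <- out$model_scan[1, ]
  }
  structure(out, class = "chroma_report")
}

#' @export
print.chroma_report <- function(x, ...) {
  cat("<chroma_report>\n\nPer-set discrimination thresholds (dS):\n")
  print(x$set_summary)
  if (!is.null(x$best_model)) {
    cat(sprintf(
      "\nBest model: %s (sigma single %.2f, double %.2f; deviation %.3f)\n",
      x$best_model$variant, x$best_model$sigma_single,
      x$best_model$sigma_double, x$best_model$metric
    ))
  }
  invisible(x)
}

#' Fit lambda-max for a batch of pigment scans
#'
#' Convenience wrapper: fits every scan, then bins and refits the bin means
#' (see [bin_scans()]).
#'
#' @param scans List of absorbance spectrum tibbles.
#' @param chromophore Passed to [estimate_lambda_max()].
#' @return A list with `per_scan` (tibble of per-scan fits) and `bins`
#'   (tibble of per-bin refits).
#' @export
fit_pigments <- function(scans, chromophore = "auto") {
  per_scan <- purrr::map_dfr(scans, estimate_lambda_max, chromophore = chromophore)
  bins <- bin_scans(scans, fits = per_scan, chromophore = chromophore)
  list(per_scan = per_scan, bins = bins)
}
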