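#' Build a visual-model variant
#'
#' Derives a candidate visual system from a fitted tetrachromat: optionally
#' drops one receptor class (yielding a trichromat; remaining abundances are
#' kept unchanged so each surviving channel's noise is preserved) and
#' reassigns the Weber numerators by cone class (`sigma_single` for the UV
#' single cone, `sigma_double` for the double cones).
#'
#' @param vs The full tetrachromatic [visual_system()].
#' @param drop Label of the receptor to drop, or `NULL` for the full model.
#' @param sigma_single,sigma_double Weber numerators by cone class.
#' @param single_labels Labels counted as single cones (default `"U"`).
#'
#' @return A [visual_system()] with 3 or 4 receptors.
#' @export
build_variant <- function(vs, drop = NULL, sigma_single, sigma_double,
                          single_labels = "U") {
  stopifnot(inherits(vs, "visual_system"))
  rec <- vs$receptors
  if (!is.null(drop)) {
    if (length(drop) != 1) abort_chroma("only one receptor may be dropped per variant")
    if (!drop %in% rec$receptor) abort_chroma(paste0("unknown receptor label: ", drop))
    rec <- rec[rec$receptor != drop, ]
  }
  if (nrow(rec) < 3) abort_chroma("a variant needs at least 3 receptors")
  sigma <- ifelse(rec$receptor %in% single_labels, sigma_single, sigma_double)
  sens <- stats::setNames(rec$sensitivity, rec$receptor)
  visual_system(sens, sigma = sigma, eta = rec$eta, grid = vs$grid)
}

#' Mean deviation of thresholds from 1 delta-S
#'
#' The model-selection metric: under a correctly specified RNL model the
#' discrimination threshold of every colour line should sit at 1 delta-S (one
#' just-noticeable difference), so the candidate model whose refitted
#' thresholds have the smallest mean absolute deviation from 1 fits best.
#'
#' @param thresholds Numeric vector of per-colour-set thresholds (delta-S).
#' @return Mean of `|threshold - 1|`.
#' @export
deviation_metric <- function(thresholds) {
  thresholds <- thresholds[!is.na(thresholds)]
  if (length(thresholds) == 0) abort_chroma("no thresholds to score")
  mean(abs(thresholds - 1))
}

#' Scan candidate visual models against behavioural data
#'
#' For every combination of receptor complement (the full tetrachromat and
#' each drop-one trichromat by default) and Weber numerator pair on the grid,
#' recomputes each target's delta-S from its spectrum under that model, refits
#' every fish-by-set psychometric curve against the rescaled delta-S axis, and
#' scores the model by [deviation_metric()] on the per-set mean thresholds.
#' Variants that make a discriminated stimulus indiscriminable by construction
#' (delta-S = 0) are flagged, not fatal.
#'
#' @param trials Trial tibble (`fish_id`, `colour_set`, `level`, `correct`).
#' @param stimuli Stimulus tibble with `colour_set`, `level` and a `spectrum`
#'   list-column of target radiance spectra.
#' @param background Radiance spectrum of the adapting background.
#' @param vs The full tetrachromatic [visual_system()] (supplies
#'   sensitivities and abundances; sigma comes from the grid).
#' @param sigma_grid Numeric vector of Weber numerators scanned for both cone
#'   classes (default 0.05-0.15 in steps of 0.01, scanned jointly).
#' @param drops Receptor complements to scan: `NA` for the full model plus
#'   each label to drop.
#' @param reference Reference stimulus spectrum against which delta-S is
#'   computed (defaults to the average distractor, i.e. the background).
#'
#' @return A tibble sorted by ascending metric: `variant`, `sigma_single`,
#'   `sigma_double`, `metric`, `n_flagged`, and a `set_thresholds`
#'   list-column.
#' @export
scan_models <- function(trials, stimuli, background, vs,
                        sigma_grid = seq(0.05, 0.15, by = 0.01),
                        drops = c(NA, vs$receptors$receptor),
                        reference = NULL) {
  stopifnot(inherits(vs, "visual_system"))
  stopifnot(all(c("colour_set", "level", "spectrum") %in% names(stimuli)))
  if (is.null(reference)) reference <- background

  # log catches per stimulus depend on the receptor complement only, never on
  # sigma: precompute once for the full system
  f_ref <- quantum_catch(reference, background, vs)$f
  fmat <- t(vapply(
    stimuli$spectrum,
    function(s) quantum_catch(s, background, vs)$f,
    numeric(n_receptors(vs))
  ))
  dfmat <- sweep(fmat, 2, f_ref) # per-stimulus log-signal differences
  labels <- vs$receptors$receptor

  grid_cells <- tidyr::expand_grid(
    drop = drops, sigma_single = sigma_grid, sigma_double = sigma_grid
  )

  # aggregate choice counts once; the per-cell work is then index lookups
  if ("correct" %in% names(trials)) {
    agg <- dplyr::summarise(
      dplyr::group_by(trials, .data$fish_id, .data$colour_set, .data$level),
      n_trials = dplyr::n(), n_correct = sum(.data$correct), .groups = "drop"
    )
  } else {
    agg <- dplyr::summarise(
      dplyr::group_by(trials, .data$fish_id, .data$colour_set, .data$level),
      n_trials = sum(.data$n_trials), n_correct = sum(.data$n_correct),
      .groups = "drop"
    )
  }
  stim_idx <- match(
    paste(agg$colour_set, agg$level),
    paste(stimuli$colour_set, stimuli$level)
  )
  agg <- agg[!is.na(stim_idx), ] # control rows reference no stimulus
  stim_idx <- stim_idx[!is.na(stim_idx)]
  cells <- split(seq_len(nrow(agg)), paste(agg$fish_id, agg$colour_set, sep = "\r"))
  cell_set <- vapply(cells, function(rows) agg$colour_set[rows[1]], character(1))
  eta <- vs$receptors$eta

  res <- purrr::pmap_dfr(grid_cells, function(drop, sigma_single, sigma_double) {
    keep <- if (is.na(drop)) rep(TRUE, length(labels)) else labels != drop
    sigma <- ifelse(labels[keep] == "U", sigma_single, sigma_double)
    e <- sigma / sqrt(eta[keep])
    # whitened chromatic projection, vectorised over stimuli
    U <- dfmat[, keep, drop = FALSE] %*% diag(1 / e)
    w <- (1 / e) / sqrt(sum(1 / e^2))
    ds <- sqrt(pmax(rowSums(U^2) - as.numeric(U %*% w)^2, 0))
    n_flagged <- sum(ds < 1e-8)
    thr <- vapply(cells, function(rows) {
      scan_cell_threshold(ds[stim_idx[rows]], agg$n_correct[rows], agg$n_trials[rows])
    }, numeric(1))
    set_means <- tapply(thr, cell_set, mean, na.rm = TRUE)
    sets <- tibble::tibble(
      colour_set = names(set_means),
      mean_threshold = as.numeric(set_means)
    )
    tibble::tibble(
      variant = paste(labels[keep], collapse = "-"),
      drop = drop, sigma_single = sigma_single, sigma_double = sigma_double,
      metric = deviation_metric(sets$mean_threshold),
      n_flagged = n_flagged,
      set_thresholds = list(sets)
    )
  })
  dplyr::arrange(res, .data$metric)
}

# fast per-cell threshold under gamma = lapse = 0: the logistic psychometric
# MLE equals the binomial GLM with logit link (threshold = -b0/b1); falls back
# to the general multi-start fit when the GLM is degenerate
scan_cell_threshold <- function(ds, k, n) {
  if (all(k == n) || all(k == 0) || max(k / n) < 0.5) return(NA_real_)
  fit <- suppressWarnings(try(
    stats::glm.fit(cbind(1, ds), k / n, weights = n, family = stats::binomial()),
    silent = TRUE
  ))
  if (!inherits(fit, "try-error") && fit$converged && is.finite(fit$coefficients[2]) &&
      fit$coefficients[2] > 0) {
    return(unname(-fit$coefficients[1] / fit$coefficients[2]))
  }
  out <- try(
    fit_psy_ml(
      tibble::tibble(delta_s = ds, n_trials = n, n_correct = k),
      gamma = 0, lapse = "fixed", lapse_value = 0, family = "logistic"
    ),
    silent = TRUE
  )
  if (inherits(out, "try-error")) NA_real_ else out$threshold
}
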