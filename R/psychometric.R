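#' Fit a psychometric function to choice data
#'
#' Maximum-likelihood fit of
#' `P(correct | dS) = gamma + (1 - gamma - lapse) * F((dS - m) / s)`
#' to binomial choice data for one fish and one colour set, with `F` the
#' logistic (default) or cumulative-normal sigmoid. The guess rate `gamma` is
#' fixed (0 by default: in the study's control trials fish never pecked the
#' zero-contrast target); the lapse rate can be fixed (0 by default) or
#' estimated, capped at 0.5 to keep the 0.5-probability threshold
#' identifiable. Optimisation uses five deterministic starts (a binomial-GLM
#' warm start plus a coarse grid over location and spread). The discrimination
#' threshold is the delta-S at which the fitted curve crosses 0.5 probability
#' correct, see [threshold_from_fit()]. Confidence intervals come from a
#' seeded nonparametric bootstrap (trials resampled within each level).
#'
#' @param data Tibble of trials: either raw rows with columns `delta_s` and
#'   `correct` (0/1), or aggregated rows with `delta_s`, `n_trials`,
#'   `n_correct`. Control rows (`delta_s == 0`) are excluded from the fit.
#' @param gamma Fixed guess rate in `[0, 1)`.
#' @param lapse `"fixed"` or `"free"`.
#' @param lapse_value Lapse rate used when `lapse = "fixed"`.
#' @param family `"logistic"` or `"gaussian"` sigmoid.
#' @param n_boot Bootstrap resamples for the 95% CI (0 skips the bootstrap).
#' @param seed Seed for the bootstrap.
#'
#' @return An object of class `psychometric_fit` with elements `m`, `s`,
#'   `lapse`, `gamma`, `loglik`, `threshold`, `ci`, `boundary`, `converged`,
#'   `family`, and the aggregated `data`.
#' @export
fit_psychometric <- function(data, gamma = 0, lapse = c("fixed", "free"),
                             lapse_value = 0, family = c("logistic", "gaussian"),
                             n_boot = 500, seed = 1) {
  lapse <- match.arg(lapse)
  family <- match.arg(family)
  if (gamma < 0 || gamma >= 1) abort_chroma("gamma must lie in [0, 1)")
  agg <- aggregate_trials(data)
  agg <- agg[agg$delta_s > 0, ]
  if (nrow(agg) < 3) abort_chroma("need at least 3 distinct non-control delta_s levels")
  if (any(agg$n_trials < 1)) abort_chroma("every level needs at least one trial")

  fit <- fit_psy_ml(agg, gamma, lapse, lapse_value, family)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && !fit$boundary) {
    thr_boot <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        res <- agg
        res$n_correct <- stats::rbinom(nrow(agg), agg$n_trials, agg$n_correct / agg$n_trials)
        bf <- try(fit_psy_ml(res, gamma, lapse, lapse_value, family), silent = TRUE)
        if (inherits(bf, "try-error") || bf$boundary) NA_real_ else bf$threshold
      }, numeric(1))
    })
    if (sum(!is.na(thr_boot)) >= n_boot / 2) {
      ci <- unname(stats::quantile(thr_boot, c(0.025, 0.975), na.rm = TRUE))
    }
  }
  structure(
    c(fit, list(ci = ci, gamma = gamma, family = family, data = agg)),
    class = "psychometric_fit"
  )
}

aggregate_trials <- function(data) {
  if (all(c("n_trials", "n_correct") %in% names(data))) {
    agg <- dplyr::summarise(
      dplyr::group_by(data, .data$delta_s),
      n_trials = sum(.data$n_trials), n_correct = sum(.data$n_correct),
      .groups = "drop"
    )
  } else if ("correct" %in% names(data)) {
    agg <- dplyr::summarise(
      dplyr::group_by(data, .data$delta_s),
      n_trials = dplyr::n(), n_correct = sum(.data$correct),
      .groups = "drop"
    )
  } else {
    abort_chroma("trial data needs either `correct` or `n_trials`/`n_correct` columns")
  }
  if (any(agg$n_correct > agg$n_trials) || any(agg$n_correct < 0)) {
    abort_chroma("n_correct must lie in [0, n_trials]")
  }
  if (any(agg$delta_s < 0)) abort_chroma("delta_s must be >= 0")
  dplyr::arrange(agg, .data$delta_s)
}

psy_curve <- function(ds, m, s, gamma, lapse, family) {
  Fv <- switch(family,
    logistic = stats::plogis((ds - m) / s),
    gaussian = stats::pnorm((ds - m) / s)
  )
  gamma + (1 - gamma - lapse) * Fv
}

fit_psy_ml <- function(agg, gamma, lapse, lapse_value, family) {
  x <- agg$delta_s
  k <- agg$n_correct
  n <- agg$n_trials
  p_obs <- k / n
  # degenerate likelihood, or performance never reaching 0.5: no threshold
  boundary <- all(k == n) || all(k == 0) || max(p_obs) < 0.5

  free_lapse <- lapse == "free"
  nll <- function(par) {
    m <- par[1]
    s <- exp(par[2])
    lam <- if (free_lapse) 0.5 * stats::plogis(par[3]) else lapse_value
    p <- psy_curve(x, m, s, gamma, lam, family)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (n - k) * log(1 - p))
  }

  # deterministic warm starts: binomial GLM plus a coarse location/spread grid
  starts <- list()
  glm_fit <- suppressWarnings(try(
    stats::glm(cbind(k, n - k) ~ x, family = stats::binomial()),
    silent = TRUE
  ))
  glm_ok <- !inherits(glm_fit, "try-error") && is.finite(stats::coef(glm_fit)[2]) &&
    stats::coef(glm_fit)[2] > 0
  if (glm_ok) {
    b <- stats::coef(glm_fit)
    starts <- c(starts, list(unname(c(-b[1] / b[2], log(1 / b[2])))))
  }
  # with gamma = 0 and lapse fixed at 0, the logistic psychometric IS a
  # binomial GLM with logit link: its fit is the global optimum, so a single
  # polish from there suffices; otherwise use all five starts
  fast_path <- glm_ok && !free_lapse && gamma == 0 && lapse_value == 0 &&
    family == "logistic" && !boundary
  if (!fast_path) {
    rng <- range(x)
    for (mq in stats::quantile(x, c(0.25, 0.5, 0.75))) {
      starts <- c(starts, list(unname(c(mq, log(diff(rng) / 4)))))
    }
    starts <- c(starts, list(c(mean(rng), log(diff(rng)))))
    starts <- utils::head(starts, 5)
  }
  starts <- lapply(starts, function(st) {
    if (free_lapse) c(st, stats::qlogis(0.1)) else st
  })

  best <- NULL
  for (st in starts) {
    opt <- try(
      stats::optim(st, nll, method = "Nelder-Mead",
                   control = list(maxit = if (fast_path) 400 else 2000,
                                  reltol = 1e-10)),
      silent = TRUE
    )
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) abort_chroma("psychometric fit failed to converge from any start")

  m <- unname(best$par[1])
  s <- exp(unname(best$par[2]))
  lam <- if (free_lapse) 0.5 * stats::plogis(best$par[3]) else lapse_value
  upper <- 1 - lam
  no_thr <- boundary || upper <= 0.5
  out <- list(
    m = m, s = s, lapse = lam, loglik = -best$value,
    boundary = boundary, converged = best$convergence == 0
  )
  out$threshold <- if (no_thr) NA_real_ else {
    solve_threshold(m, s, gamma, lam, family)
  }
  out
}

# bisection solve of P(dS) = 0.5 on the fitted curve
solve_threshold <- function(m, s, gamma, lapse, family, tol = 1e-6) {
  f <- function(ds) psy_curve(ds, m, s, gamma, lapse, family) - 0.5
  lo <- m - 60 * s
  hi <- m + 60 * s
  if (f(lo) > 0 || f(hi) < 0) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Threshold at 0.5 probability correct
#'
#' Solves `P(dS) = 0.5` on a fitted psychometric curve by bisection
#' (tolerance 1e-6). With guess and lapse rates of zero this equals the fitted
#' location `m`. Errors when the curve's upper asymptote does not exceed 0.5.
#'
#' @param fit A `psychometric_fit` from [fit_psychometric()].
#' @return The threshold delta-S.
#' @export
threshold_from_fit <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  upper <- 1 - fit$lapse
  if (upper <= 0.5 || fit$gamma >= 0.5) {
    abort_chroma("fitted curve's asymptotes pin it at/below 0.5: threshold undefined")
  }
  if (fit$boundary) abort_chroma("degenerate (all-correct or all-incorrect) data: threshold undefined")
  solve_threshold(fit$m, fit$s, fit$gamma, fit$lapse, fit$family)
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit: m = %.3f, s = %.3f, lapse = %.3f, threshold = %.3f dS%s>\n",
    x$m, x$s, x$lapse, x$threshold,
    if (x$boundary) " [boundary]" else ""
  ))
  invisible(x)
}

#' Fit thresholds for every fish-by-colour-set cell of a trial table
#'
#' @param trials Trial tibble with columns `fish_id`, `colour_set`, `delta_s`
#'   and `correct` (or aggregated counts).
#' @param ... Passed to [fit_psychometric()].
#'
#' @return A tibble with one row per fish x colour set: threshold, `m`, `s`,
#'   `lapse`, CI bounds, and a `fit` list-column.
#' @export
fit_thresholds <- function(trials, ...) {
  stopifnot(all(c("fish_id", "colour_set", "delta_s") %in% names(trials)))
  cells <- dplyr::group_split(dplyr::group_by(trials, .data$fish_id, .data$colour_set))
  purrr::map_dfr(cells, function(cell) {
    fit <- fit_psychometric(cell, ...)
    tibble::tibble(
      fish_id = cell$fish_id[1], colour_set = cell$colour_set[1],
      threshold = fit$threshold, m = fit$m, s = fit$s, lapse = fit$lapse,
      ci_lo = fit$ci[1], ci_hi = fit$ci[2],
      boundary = fit$boundary, fit = list(fit)
    )
  })
}

#' Summarise discrimination thresholds by colour set
#'
#' Mean and standard error of the per-fish thresholds for each colour set,
#' with each set's hue angles attached when available, and a UV-contrast sign
#' label (`UV+` for sets with positive elevation, `UV-` otherwise).
#'
#' @param fits Per-fish fit tibble from [fit_thresholds()].
#' @param set_angles Optional tibble with columns `colour_set`, `theta`,
#'   `phi` giving each set's direction angles.
#'
#' @return A tibble with one row per colour set: `n_fish`, `mean_threshold`,
#'   `sem`, and angles/UV sign when supplied.
#' @export
summarise_thresholds <- function(fits, set_angles = NULL) {
  if (nrow(fits) == 0) abort_chroma("no fits to summarise")
  out <- dplyr::summarise(
    dplyr::group_by(fits, .data$colour_set),
    n_fish = sum(!is.na(.data$threshold)),
    mean_threshold = mean(.data$threshold, na.rm = TRUE),
    sem = if (sum(!is.na(.data$threshold)) > 1) {
      stats::sd(.data$threshold, na.rm = TRUE) / sqrt(sum(!is.na(.data$threshold)))
    } else {
      NA_real_
    },
    .groups = "drop"
  )
  if (!is.null(set_angles)) {
    out <- dplyr::left_join(out, set_angles, by = "colour_set")
    out$uv_sign <- ifelse(out$theta > 0, "UV+", "UV-")
  }
  out
}
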