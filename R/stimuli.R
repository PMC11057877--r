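#' Multi-primary LED display
#'
#' Bundles the radiance spectra of the display's LED channels and of the
#' background screen (all LEDs off). Pixel colours are produced by mixing the
#' channels linearly on top of the background, see [mix_leds()].
#'
#' @param channels Named list of radiance spectrum tibbles, one per LED
#'   channel at full drive.
#' @param background Radiance spectrum tibble of the screen with all LEDs off;
#'   must be strictly positive on the grid so that quantum catches are
#'   well defined.
#' @param grid Wavelength grid everything is resampled to.
#'
#' @return An object of class `led_display`.
#' @export
led_display <- function(channels, background, grid = wl_grid()) {
  if (length(channels) < 1) abort_chroma("a display needs at least one LED channel")
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    abort_chroma("channels must be a named list")
  }
  ch <- lapply(channels, function(s) resample_spectrum(validate_spectrum(s), grid, zero_fill = TRUE))
  bg <- resample_spectrum(validate_spectrum(background), grid, zero_fill = TRUE)
  if (any(bg$value <= 0)) {
    abort_chroma("background radiance must be strictly positive on the grid")
  }
  peaks <- vapply(ch, function(s) s$wavelength[which.max(s$value)], numeric(1))
  structure(
    list(
      channels = ch,
      background = bg,
      grid = as.numeric(grid),
      peaks = peaks,
      # channel radiance matrix for fast mixing
      C = vapply(ch, function(s) s$value, numeric(length(grid)))
    ),
    class = "led_display"
  )
}

#' @export
print.led_display <- function(x, ...) {
  cat(sprintf(
    "<led_display: %d channels peaking at %s nm>\n",
    length(x$channels), paste(round(x$peaks), collapse = "/")
  ))
  invisible(x)
}

#' Mix LED channels into a stimulus spectrum
#'
#' Weighted sum of the channel radiances plus the background screen radiance.
#' Weights are drive fractions in [0, 1].
#'
#' @param display An [led_display()].
#' @param weights Numeric vector of per-channel weights in [0, 1].
#'
#' @return A radiance spectrum tibble on the display grid.
#' @export
mix_leds <- function(display, weights) {
  stopifnot(inherits(display, "led_display"))
  weights <- as.numeric(weights)
  if (length(weights) != ncol(display$C)) {
    abort_chroma("one weight per LED channel required")
  }
  if (any(weights < 0 | weights > 1)) abort_chroma("LED weights must lie in [0, 1]")
  tibble::tibble(
    wavelength = display$grid,
    value = display$background$value + as.numeric(display$C %*% weights)
  )
}

# xyz locus of a weight vector, relative to the background (achromatic point)
weights_to_xyz <- function(display, weights, vs) {
  qc <- quantum_catch(mix_leds(display, weights), display$background, vs)
  noise_corrected_xyz(qc, vs)
}

# precompute catch integrals so weight -> locus evaluations reduce to a few
# matrix products (the display and visual system share the grid)
led_model <- function(display, vs) {
  if (!isTRUE(all.equal(display$grid, vs$grid))) {
    abort_chroma("display and visual system must share the wavelength grid")
  }
  bgc <- catch_integrals(display$background$value, vs)
  M <- vapply(
    seq_len(ncol(display$C)),
    function(j) catch_integrals(display$C[, j], vs),
    numeric(n_receptors(vs))
  )
  e <- vs$receptors$e
  list(bgc = bgc, M = M, e = e,
       B = if (n_receptors(vs) == 4) chromatic_basis(e) else NULL)
}

lm_f <- function(model, w) log1p(as.numeric(model$M %*% w) / model$bgc)

lm_xyz <- function(model, w) as.numeric(crossprod(model$B, lm_f(model, w) / model$e))

#' Build a colour line radiating from the achromatic point
#'
#' Finds LED weight vectors whose noise-corrected loci lie on the ray from the
#' achromatic point (the background) along `direction`, at `n` delta-S levels
#' spanning `(0, max_ds]`. Weights are found by box-constrained least-squares
#' projection (continuation from the previous level); a target whose achieved
#' locus misses the requested point by more than `tol` delta-S means the
#' display gamut is exceeded and is an error.
#'
#' @param display An [led_display()].
#' @param vs A tetrachromatic [visual_system()].
#' @param direction Length-3 numeric, the xyz direction (normalised
#'   internally).
#' @param n Number of targets on the line (6-11 in the study design).
#' @param max_ds Largest delta-S on the line, > 0.
#' @param label Optional line label, stored on the result.
#' @param tol Acceptable miss distance in delta-S units (default 0.02).
#'
#' @return A tibble with one row per target: `label`, `level`, `delta_s`
#'   (achieved), `x`, `y`, `z`, `theta`, `phi`, and a `weights` list-column.
#' @export
build_colour_line <- function(display, vs, direction, n = 9, max_ds = 3,
                              label = NULL, tol = 0.02) {
  stopifnot(inherits(display, "led_display"), inherits(vs, "visual_system"))
  direction <- as.numeric(direction)
  if (length(direction) != 3 || sqrt(sum(direction^2)) == 0) {
    abort_chroma("direction must be a non-zero xyz vector")
  }
  if (max_ds <= 0) abort_chroma("max_ds must be > 0 (empty colour line)")
  if (n < 1) abort_chroma("n must be >= 1")
  direction <- direction / sqrt(sum(direction^2))
  levels <- seq(max_ds / n, max_ds, length.out = n)
  nw <- ncol(display$C)
  model <- led_model(display, vs)
  w <- rep(0, nw)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    target <- levels[i] * direction
    sol <- solve_weights(model, target, nw, warm = w, tol = tol)
    if (is.null(sol)) {
      abort_chroma(sprintf(
        "display gamut exceeded on line%s at level %.2f dS",
        if (is.null(label)) "" else paste0(" '", label, "'"), levels[i]
      ))
    }
    w <- sol
    p <- weights_to_xyz(display, w, vs)
    ang <- hue_angles(p)
    rows[[i]] <- tibble::tibble(
      label = label %||% NA_character_, level = i,
      delta_s = p$delta_s, x = p$x, y = p$y, z = p$z,
      theta = ang$theta, phi = ang$phi, weights = list(w)
    )
  }
  dplyr::bind_rows(rows)
}

# box-constrained least-squares projection of a target xyz point onto the
# display gamut, with deterministic multi-start (warm start, single-channel
# and balanced seeds); returns NULL when every start misses by more than tol
solve_weights <- function(model, target, nw, warm = NULL, tol = 0.02) {
  obj <- function(wt) sum((lm_xyz(model, wt) - target)^2)
  starts <- list(rep(0.02, nw), rep(0.1, nw))
  if (!is.null(warm)) starts <- c(list(warm), starts)
  for (j in seq_len(nw)) {
    st <- rep(0.01, nw)
    st[j] <- 0.3
    starts <- c(starts, list(st))
  }
  best <- NULL
  for (st in starts) {
    fit <- stats::optim(st, obj,
      method = "L-BFGS-B", lower = rep(0, nw), upper = rep(1, nw),
      control = list(factr = 1e4, maxit = 500)
    )
    if (is.null(best) || fit$value < best$value) best <- fit
    if (sqrt(best$value) <= tol / 4) break
  }
  if (sqrt(best$value) > tol) NULL else best$par
}

# weights of a roughly achromatic mix: minimise dS from the background while
# holding the mean channel drive at `scale` (soft penalty)
neutral_weights <- function(display, vs, scale = 0.08) {
  nw <- ncol(display$C)
  model <- led_model(display, vs)
  obj <- function(wt) {
    u <- lm_f(model, wt) / model$e
    sum(crossprod(model$B, u)^2) + 25 * (mean(wt) - scale)^2
  }
  fit <- stats::optim(rep(scale, nw), obj,
    method = "L-BFGS-B", lower = rep(0, nw), upper = rep(1, nw),
    control = list(factr = 1e5, maxit = 400)
  )
  fit$par
}

#' Select a set of grey distractors
#'
#' Searches for `n` LED weight vectors near the display's neutral locus that
#' jointly satisfy the study's distractor rules: every grey lies within
#' `max_from_grey` delta-S of the achromatic point and every pair of greys is
#' between `pair_range[1]` and `pair_range[2]` delta-S apart (so distractors
#' vary in intensity and slightly in chromaticity without any of them
#' approaching a target). Placement is constructive: a near-achromatic centre
#' plus up to 12 points on a randomly rotated icosahedral shell whose radius
#' satisfies both pairwise bounds by construction; each shell point is then
#' realised as LED weights by box-constrained projection and the constraints
#' audited strictly on the realised loci, restarting with a fresh rotation on
#' failure. Deterministic given `seed`.
#'
#' @param display An [led_display()].
#' @param vs A tetrachromatic [visual_system()].
#' @param n Number of greys, at most 13 (centre + icosahedron; study default
#'   13).
#' @param seed Integer seed; required.
#' @param max_from_grey Radius around the achromatic point (delta-S).
#' @param pair_range Closed interval for pairwise distances (delta-S).
#' @param max_restarts Seeded restarts before giving up with diagnostics.
#'
#' @return A tibble with one row per grey: `grey`, `delta_s` (from the
#'   achromatic point), `x`, `y`, `z`, per-receptor quantum catch columns
#'   `q_<receptor>`, and a `weights` list-column.
#' @export
select_grey_set <- function(display, vs, n = 13, seed,
                            max_from_grey = 1, pair_range = c(0.3, 0.8),
                            max_restarts = 60) {
  stopifnot(inherits(display, "led_display"), inherits(vs, "visual_system"))
  if (missing(seed)) abort_chroma("select_grey_set requires a seed")
  lo <- pair_range[1]
  hi <- pair_range[2]
  rmax <- max_from_grey
  if (n > 13) abort_chroma("select_grey_set places at most 13 greys (centre + icosahedral shell)")
  if (n > 1 && lo > hi / 2) {
    abort_chroma(sprintf(
      "pairwise bounds [%g, %g] are infeasible: the minimum separation exceeds half the maximum diameter",
      lo, hi
    ))
  }
  w0 <- neutral_weights(display, vs)
  model <- led_model(display, vs)
  nw <- length(w0)
  # shell radius satisfying centre-vertex (R >= lo) and diameter (2R <= hi)
  R <- (1.1 * lo + 0.9 * hi / 2) / 2
  if (n > 1 && (R + 0.05 >= rmax)) {
    abort_chroma("pairwise bounds do not fit inside the allowed radius around grey")
  }
  gr <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(0, 1, gr), c(0, -1, gr), c(0, 1, -gr), c(0, -1, -gr),
    c(1, gr, 0), c(-1, gr, 0), c(1, -gr, 0), c(-1, -gr, 0),
    c(gr, 0, 1), c(-gr, 0, 1), c(gr, 0, -1), c(-gr, 0, -1)
  )
  V <- V / sqrt(rowSums(V^2))

  audit <- function(P) {
    r <- sqrt(rowSums(P^2))
    ok <- all(r < rmax)
    if (n > 1) {
      d <- stats::dist(P)
      ok <- ok && all(d >= lo) && all(d <= hi)
    }
    ok
  }

  W_ok <- NULL
  withr::with_seed(seed, {
    for (attempt in seq_len(max_restarts)) {
      cw <- pmin(pmax(w0 * stats::runif(nw, 0.5, 2.5), 0), 1)
      c0 <- lm_xyz(model, cw)
      if (sqrt(sum(c0^2)) > rmax - R - 0.05) next
      Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
      slots <- rbind(c0, sweep(V %*% t(Q) * R, 2, c0, "+"))[seq_len(n), , drop = FALSE]
      W <- matrix(NA_real_, n, nw)
      W[1, ] <- cw
      ok <- TRUE
      for (i in seq_len(n)[-1]) {
        sol <- solve_weights(model, slots[i, ], nw, warm = cw, tol = 0.01)
        if (is.null(sol)) {
          ok <- FALSE
          break
        }
        W[i, ] <- sol
      }
      if (!ok) next
      P <- t(apply(W, 1, function(w) lm_xyz(model, w)))
      if (audit(P)) {
        W_ok <- W
        break
      }
    }
  })
  if (is.null(W_ok)) {
    abort_chroma(sprintf(
      "grey-set constraints unmet after %d restarts; bounds [%g, %g] within %g dS may be jointly infeasible for %d greys",
      max_restarts, lo, hi, rmax, n
    ))
  }
  purrr::map_dfr(seq_len(n), function(i) {
    w <- W_ok[i, ]
    qc <- quantum_catch(mix_leds(display, w), display$background, vs)
    p <- noise_corrected_xyz(qc, vs)
    q <- stats::setNames(as.list(qc$q), paste0("q_", qc$receptor))
    dplyr::bind_cols(
      tibble::tibble(grey = i, delta_s = p$delta_s, x = p$x, y = p$y, z = p$z),
      tibble::as_tibble(q),
      tibble::tibble(weights = list(w))
    )
  })
}

#' Choose intensity-bracketing grey distractors for one target
#'
#' Returns the smallest subset of greys, with size in `k_range`, whose
#' per-receptor quantum-catch range strictly brackets the target's catches in
#' every receptor class — so the target is never the brightest or dimmest
#' pixel in any channel and cannot be found by intensity alone. Among feasible
#' subsets of the smallest feasible size, the one whose greys are closest to
#' the target in delta-S is preferred.
#'
#' @param target_catch Quantum-catch tibble of the target ([quantum_catch()]).
#' @param greys A grey-set tibble from [select_grey_set()].
#' @param vs The [visual_system()] (supplies noise for the tie-break
#'   distances).
#' @param k_range Allowed subset sizes (study design: 6-10).
#'
#' @return The subset of `greys` rows, with an added `ds_to_target` column.
#' @export
match_intensity_distractors <- function(target_catch, greys, vs, k_range = c(6, 10)) {
  qcols <- grep("^q_", names(greys), value = TRUE)
  if (length(qcols) != n_receptors(vs)) {
    abort_chroma("grey set and visual system disagree on receptor count")
  }
  tq <- target_catch$q
  G <- as.matrix(greys[, qcols])
  m <- nrow(greys)
  # feasible only if some grey is strictly above and some strictly below in
  # every receptor
  if (!all(apply(G, 2, max) > tq) || !all(apply(G, 2, min) < tq)) {
    abort_chroma("target quantum catches cannot be strictly bracketed by the grey set")
  }
  ds_to_target <- vapply(seq_len(m), function(i) {
    rnl_delta_s(as.numeric(G[i, ]), tq, vs)
  }, numeric(1))
  for (k in seq(k_range[1], k_range[2])) {
    if (k > m) break
    combos <- utils::combn(m, k)
    feasible <- which(apply(combos, 2, function(idx) {
      sub <- G[idx, , drop = FALSE]
      all(apply(sub, 2, max) > tq) && all(apply(sub, 2, min) < tq)
    }))
    if (length(feasible) > 0) {
      cost <- vapply(feasible, function(j) sum(ds_to_target[combos[, j]]), numeric(1))
      best <- combos[, feasible[which.min(cost)]]
      out <- greys[best, ]
      out$ds_to_target <- ds_to_target[best]
      return(out)
    }
  }
  abort_chroma(sprintf(
    "no grey subset of size %d-%d brackets the target on all receptors",
    k_range[1], min(k_range[2], m)
  ))
}
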