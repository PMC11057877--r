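# Shared fixtures, all built in code.

# Gaussian "sensitivity" spectrum, peak 1 at mu
gauss_spec <- function(mu, sd = 30, grid = wl_grid()) {
  tibble::tibble(wavelength = as.numeric(grid), value = exp(-(grid - mu)^2 / (2 * sd^2)))
}

# flat spectrum
flat_spec <- function(value = 1, grid = wl_grid()) {
  tibble::tibble(wavelength = as.numeric(grid), value = rep(value, length(grid)))
}

# small dichromat / trichromat / tetrachromat systems with Gaussian receptors
toy_vs <- function(n = 4, sigma = 0.1, eta = 1, grid = wl_grid()) {
  mus <- switch(as.character(n),
    "2" = c(400, 550),
    "3" = c(380, 480, 560),
    "4" = c(380, 470, 520, 570)
  )
  sens <- lapply(mus, gauss_spec, grid = grid)
  names(sens) <- receptor_labels_test(n)
  visual_system(sens, sigma = sigma, eta = eta, grid = grid)
}

receptor_labels_test <- function(n) {
  c("U", paste0("M", seq_len(max(n - 2, 0))), "L")[1:n]
}

# study-condition system and display, memoised per test run
study_vs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- gen_visual_system()
    cache
  }
})

study_display <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- gen_led_display()
    cache
  }
})

# experiment with thresholds planted at 1 dS under sigma (0.11, 0.14), for
# model-scan tests; memoised per test run
mini_scan_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sets <- default_colour_sets()
      sets$m <- 1
      sets$s <- 0.2
      cfg <- synthetic_config(sets = sets, fish_per_set = 3)
      exp <- generate_experiment(cfg, seed = 301)
      exp$stimuli <- tibble::tibble(
        colour_set = exp$targets$label,
        level = exp$targets$level,
        spectrum = lapply(exp$targets$weights, function(w) mix_leds(exp$display, w))
      )
      cache <<- exp
    }
    cache
  }
})

# random positive quantum-catch tibble for a system
random_catch <- function(vs, spread = 0.5) {
  q <- exp(stats::runif(nrow(vs$receptors), -spread, spread))
  tibble::tibble(receptor = vs$receptors$receptor, q = q, f = log(q))
}

# closed-form trichromat RNL distance (independent oracle)
trichromat_ds_oracle <- function(df, e) {
  num <- e[1]^2 * (df[3] - df[2])^2 + e[2]^2 * (df[3] - df[1])^2 +
    e[3]^2 * (df[2] - df[1])^2
  den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
  sqrt(num / den)
}

# closed-form tetrachromat RNL distance (independent oracle)
tetrachromat_ds_oracle <- function(df, e) {
  num <- (e[1] * e[2])^2 * (df[4] - df[3])^2 +
    (e[1] * e[3])^2 * (df[4] - df[2])^2 +
    (e[1] * e[4])^2 * (df[3] - df[2])^2 +
    (e[2] * e[3])^2 * (df[4] - df[1])^2 +
    (e[2] * e[4])^2 * (df[3] - df[1])^2 +
    (e[3] * e[4])^2 * (df[2] - df[1])^2
  den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
    (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
  sqrt(num / den)
}
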