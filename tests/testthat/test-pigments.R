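test_that("pigment templates peak at lambda_max with value 1", {
  for (chrom in c("A1", "A2")) {
    tpl <- pigment_template(500, chrom)
    expect_equal(tpl$wavelength[which.max(tpl$value)], 500, tolerance = 1)
    expect_equal(max(tpl$value), 1)
  }
  expect_error(pigment_template(300, "A1"), "validity range")
  expect_error(pigment_template(650, "A1"), "validity range")
})

test_that("A2 templates are broader than A1 at the same lambda_max", {
  fwhm <- function(tpl) {
    above <- tpl$wavelength[tpl$value >= 0.5]
    max(above) - min(above)
  }
  a1 <- pigment_template(500, "A1")
  a2 <- pigment_template(500, "A2")
  expect_gt(fwhm(a2), fwhm(a1))
})

test_that("lambda_max estimation is exact on noiseless templates", {
  for (chrom in c("A1", "A2")) {
    for (lmax in seq(360, 560, by = 20)) {
      fit <- estimate_lambda_max(pigment_template(lmax, chrom), chromophore = chrom)
      expect_lt(abs(fit$lambda_max - lmax), 0.5)
      expect_gt(fit$lambda50, fit$lambda_max)
    }
  }
})

test_that("auto chromophore selection recovers the generating template", {
  fit <- estimate_lambda_max(pigment_template(500, "A1"), chromophore = "auto")
  expect_identical(fit$chromophore, "A1")

  # noisy A2 scans: auto picks A2 nearly always
  scans <- gen_msp_scans(500, n = 100, noise_sd = 0.05, chromophore = "A2", seed = 301)
  picks <- vapply(scans, function(s) estimate_lambda_max(s)$chromophore, character(1))
  expect_gte(mean(picks == "A2"), 0.95)
})

test_that("lambda_max recovery from noisy scans is nearly unbiased", {
  # the four cone classes of the study system
  for (lmax in c(386, 497, 515, 535)) {
    scans <- gen_msp_scans(lmax, n = 100, noise_sd = 0.05, seed = 100 + lmax)
    est <- vapply(scans, function(s) estimate_lambda_max(s, "A1")$lambda_max, numeric(1))
    expect_lt(abs(mean(est) - lmax), 2)
  }
})

test_that("estimate_lambda_max rejects degenerate scans", {
  # ascending-only limb (no descending flank beyond the peak)
  s <- tibble::tibble(wavelength = 300:700, value = seq(0, 1, length.out = 401))
  expect_error(estimate_lambda_max(s), "band|descending")
})

test_that("bin_scans groups by single linkage with a 10 nm gap", {
  scans <- lapply(c(497, 499, 515), function(l) pigment_template(l, "A1"))
  bins <- bin_scans(scans, chromophore = "A1")
  expect_equal(nrow(bins), 2)
  expect_equal(sort(bins$n_scans), c(1, 2))
  # the merged bin refits near the member mean
  merged <- bins[bins$n_scans == 2, ]
  expect_lt(abs(merged$lambda_max - 498), 1.5)

  # chains merge: adjacent gaps of 9 nm chain into one bin
  chain <- lapply(c(500, 509, 518), function(l) pigment_template(l, "A1"))
  expect_equal(nrow(bin_scans(chain, chromophore = "A1")), 1)

  # brute-force check: scans further apart than 10 nm and unchained never merge
  far <- lapply(c(400, 450, 520), function(l) pigment_template(l, "A1"))
  expect_equal(nrow(bin_scans(far, chromophore = "A1")), 3)

  single <- bin_scans(scans[1], chromophore = "A1")
  expect_equal(nrow(single), 1)
  expect_lt(abs(single$lambda_max - 497), 0.5)
  expect_error(bin_scans(list()), "no scans")
})

test_that("lens_t50 locates the 50% crossing", {
  # step function rising at 400 nm
  step <- tibble::tibble(wavelength = 300:700, value = as.numeric(300:700 >= 400))
  expect_equal(lens_t50(step)$t50, 400, tolerance = 1)

  # logistic with midpoint 334
  expect_lt(abs(lens_t50(gen_lens(334))$t50 - 334), 0.5)

  flat <- tibble::tibble(wavelength = 300:700, value = rep(1, 401))
  expect_error(lens_t50(flat), "crosses")

  # multiple crossings: longest-wavelength upward crossing wins, with warning
  wl <- 300:700
  v <- stats::plogis(0.1 * (wl - 320)) * (1 - 0.5 * exp(-(wl - 380)^2 / 200))
  bumpy <- tibble::tibble(wavelength = wl, value = v / v[length(v)])
  expect_warning(res <- lens_t50(bumpy), "multiple")
  expect_gt(res$t50, 380)
})

test_that("per-fish T50 values average as reported", {
  t50s <- vapply(c(322, 340, 341), function(m) lens_t50(gen_lens(m))$t50, numeric(1))
  expect_equal(round(mean(t50s)), 334)
})

test_that("apply_lens filters and renormalises receptor curves", {
  rec <- pigment_template(386, "A1")
  ident <- flat_spec(1)
  expect_equal(apply_lens(rec, ident)$value, rec$value)

  lens <- lens_t50(gen_lens(334))
  filtered <- apply_lens(rec, lens)
  argmax <- filtered$wavelength[which.max(filtered$value)]
  expect_gte(argmax, 386) # short-wavelength attenuation only moves peaks longward
  expect_equal(max(filtered$value), 1)

  # all-zero product is degenerate
  uvonly <- tibble::tibble(wavelength = 300:700, value = as.numeric(300:700 <= 400))
  blocked <- tibble::tibble(wavelength = 300:700, value = as.numeric(300:700 >= 420))
  expect_error(apply_lens(uvonly, blocked), "zero")
})
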