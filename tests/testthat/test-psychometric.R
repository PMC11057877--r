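simulate_trials <- function(m, s, levels, n_per, seed, gamma = 0, lapse = 0) {
  withr::with_seed(seed, {
    tibble::tibble(
      delta_s = rep(levels, each = n_per),
      correct = stats::rbinom(
        length(levels) * n_per, 1,
        rep(gamma + (1 - gamma - lapse) * stats::plogis((levels - m) / s), each = n_per)
      )
    )
  })
}

test_that("noiseless proportions recover the generating curve exactly", {
  levels <- seq(0.25, 2, length.out = 8)
  p <- stats::plogis((levels - 1.5) / 0.3)
  big_n <- 1e6
  data <- tibble::tibble(
    delta_s = levels,
    n_trials = big_n,
    n_correct = round(p * big_n)
  )
  fit <- fit_psychometric(data, n_boot = 0)
  expect_equal(fit$m, 1.5, tolerance = 0.01)
  expect_equal(fit$s, 0.3, tolerance = 0.01)
  expect_equal(fit$threshold, 1.5, tolerance = 0.01)
})

test_that("ML fit agrees with the binomial GLM closed form when gamma = lapse = 0", {
  data <- simulate_trials(0.9, 0.25, seq(0.2, 2, length.out = 8), 20, seed = 31)
  fit <- fit_psychometric(data, n_boot = 0)
  agg <- dplyr::count(data, delta_s, wt = correct, name = "k")
  agg$n <- 20
  glm_fit <- stats::glm(cbind(k, n - k) ~ delta_s, family = binomial(), data = agg)
  b <- coef(glm_fit)
  expect_equal(fit$m, unname(-b[1] / b[2]), tolerance = 1e-3)
  expect_equal(fit$s, unname(1 / b[2]), tolerance = 1e-3)
})

test_that("fit is invariant to row order and aggregation", {
  data <- simulate_trials(0.8, 0.2, seq(0.2, 1.6, length.out = 8), 10, seed = 32)
  f1 <- fit_psychometric(data, n_boot = 0)
  f2 <- fit_psychometric(data[sample(nrow(data)), ], n_boot = 0)
  agg <- dplyr::summarise(dplyr::group_by(data, delta_s),
                          n_trials = dplyr::n(), n_correct = sum(correct),
                          .groups = "drop")
  f3 <- fit_psychometric(agg, n_boot = 0)
  expect_equal(f1$m, f2$m)
  expect_equal(f1$m, f3$m)
  expect_equal(f1$threshold, f3$threshold)
})

test_that("threshold solver matches the closed-form logistic inversion", {
  mk_fit <- function(m, s, gamma, lapse) {
    structure(
      list(m = m, s = s, lapse = lapse, gamma = gamma, family = "logistic",
           boundary = FALSE, ci = c(NA, NA)),
      class = "psychometric_fit"
    )
  }
  expect_equal(threshold_from_fit(mk_fit(1, 0.2, 0, 0)), 1, tolerance = 1e-6)
  # 0.8 F((x-1)/0.2) = 0.5 => x = 1 + 0.2 log(0.625/0.375)
  oracle <- 1 + 0.2 * log(0.625 / 0.375)
  expect_equal(threshold_from_fit(mk_fit(1, 0.2, 0, 0.2)), oracle, tolerance = 1e-6)
  # floor at 0.5: degenerate
  expect_error(threshold_from_fit(mk_fit(1, 0.2, 0.5, 0)), "undefined")
  expect_error(threshold_from_fit(mk_fit(1, 0.2, 0, 0.5)), "undefined")
})

test_that("degenerate data raise the boundary flag and no threshold", {
  levels <- seq(0.2, 1.6, length.out = 8)
  allcor <- tibble::tibble(delta_s = levels, n_trials = 10, n_correct = 10)
  fit <- fit_psychometric(allcor, n_boot = 0)
  expect_true(fit$boundary)
  expect_true(is.na(fit$threshold))

  # performance that never reaches 0.5
  low <- tibble::tibble(delta_s = levels, n_trials = 10, n_correct = 4)
  fit_low <- fit_psychometric(low, n_boot = 0)
  expect_true(fit_low$boundary)
  expect_true(is.na(fit_low$threshold))
})

test_that("control rows at delta_s = 0 are excluded from the likelihood", {
  data <- simulate_trials(0.8, 0.2, seq(0.2, 1.6, length.out = 8), 10, seed = 33)
  with_controls <- dplyr::bind_rows(
    data, tibble::tibble(delta_s = 0, correct = 0L)[rep(1, 5), ]
  )
  f1 <- fit_psychometric(data, n_boot = 0)
  f2 <- fit_psychometric(with_controls, n_boot = 0)
  expect_equal(f1$m, f2$m)
})

test_that("threshold recovery is accurate over the study's range", {
  # subset of the acceptance-scale sweep, for the unit suite
  set.seed(34)
  err <- c()
  for (m in c(0.4, 1.0, 1.6)) {
    for (rep in 1:15) {
      data <- simulate_trials(m, 0.25, seq(0.25, 2.4, length.out = 8), 10,
                              seed = 7000 + 100 * m + rep)
      fit <- fit_psychometric(data, n_boot = 0)
      if (!is.na(fit$threshold)) err <- c(err, abs(fit$threshold - m))
    }
  }
  expect_gt(length(err), 40)
  expect_lt(median(err), 0.1)
})

test_that("bootstrap CIs are reproducible and cover the point estimate", {
  data <- simulate_trials(0.8, 0.2, seq(0.2, 1.6, length.out = 8), 10, seed = 35)
  f1 <- fit_psychometric(data, n_boot = 100, seed = 9)
  f2 <- fit_psychometric(data, n_boot = 100, seed = 9)
  expect_identical(f1$ci, f2$ci)
  expect_true(f1$ci[1] <= f1$threshold && f1$threshold <= f1$ci[2])
})

test_that("cumulative-normal sigmoid is available as an alternative family", {
  levels <- seq(0.25, 2, length.out = 8)
  p <- stats::pnorm((levels - 1.2) / 0.3)
  data <- tibble::tibble(delta_s = levels, n_trials = 1e5, n_correct = round(p * 1e5))
  fit <- fit_psychometric(data, family = "gaussian", n_boot = 0)
  expect_equal(fit$threshold, 1.2, tolerance = 0.02)
})

test_that("tidy and glance return the broom-shaped summaries", {
  data <- simulate_trials(0.8, 0.2, seq(0.2, 1.6, length.out = 8), 10, seed = 36)
  fit <- fit_psychometric(data, n_boot = 0)
  td <- tidy(fit)
  expect_equal(td$term, c("m", "s", "lapse"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("threshold", "logLik", "n_trials") %in% names(gl)))
})

test_that("summarise_thresholds aggregates per colour set", {
  fits <- tibble::tibble(
    fish_id = c("a", "b", "c", "d"),
    colour_set = c("UV", "UV", "UV", "blue"),
    threshold = c(1.4, 1.5, 1.6, 1.1)
  )
  s <- summarise_thresholds(fits)
  uv <- s[s$colour_set == "UV", ]
  expect_equal(uv$mean_threshold, 1.5)
  expect_equal(uv$sem, sd(c(1.4, 1.5, 1.6)) / sqrt(3), tolerance = 1e-9)
  expect_true(is.na(s$sem[s$colour_set == "blue"]))
  expect_error(summarise_thresholds(fits[0, ]), "no fits")

  angles <- tibble::tibble(colour_set = c("UV", "blue"), theta = c(65, -55), phi = c(30, 190))
  s2 <- summarise_thresholds(fits, set_angles = angles)
  expect_equal(s2$uv_sign[s2$colour_set == "UV"], "UV+")
  expect_equal(s2$uv_sign[s2$colour_set == "blue"], "UV-")
})
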