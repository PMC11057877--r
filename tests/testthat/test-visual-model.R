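test_that("receptor_noise implements e = sigma / sqrt(eta)", {
  expect_equal(receptor_noise(0.05, 1)$e, 0.05)
  expect_equal(receptor_noise(0.05, 2)$e, 0.05 / sqrt(2), tolerance = 1e-6)
  # the study's parameter set
  e <- receptor_noise(c(0.11, 0.14, 0.14, 0.14), c(1, 2, 1, 1))$e
  expect_equal(e, c(0.11, 0.09899, 0.14, 0.14), tolerance = 1e-4)
  expect_error(receptor_noise(-0.1, 1), "> 0")
  expect_error(receptor_noise(0.1, 0), "> 0")
})

test_that("visual_system validates receptor ordering and count", {
  sens <- list(U = gauss_spec(500), L = gauss_spec(400))
  expect_error(visual_system(sens, sigma = 0.1), "increasing")
  expect_error(visual_system(list(U = gauss_spec(400)), sigma = 0.1), "2-4")
  vs <- toy_vs(3)
  expect_equal(nrow(vs$receptors), 3)
})

test_that("quantum catches obey von Kries adaptation", {
  vs <- toy_vs(4)
  bg <- flat_spec(1)
  qc <- quantum_catch(bg, bg, vs)
  expect_equal(qc$q, rep(1, 4))
  expect_equal(qc$f, rep(0, 4))

  doubled <- dplyr::mutate(bg, value = value * 2)
  expect_equal(quantum_catch(doubled, bg, vs)$q, rep(2, 4))
})

test_that("a UV-centred stimulus maximally drives the UV receptor", {
  vs <- study_vs()
  bg <- flat_spec(1)
  stim <- dplyr::mutate(bg, value = value + gauss_spec(380, 10)$value)
  qc <- quantum_catch(stim, bg, vs)
  expect_equal(which.max(qc$q), 1)
})

test_that("quantum_catch errors name the failing receptor", {
  vs <- toy_vs(4)
  dark <- flat_spec(0)
  expect_error(quantum_catch(flat_spec(1), dark, vs), "background catch.*U")
  expect_error(quantum_catch(dark, flat_spec(1), vs), "stimulus catch.*U")
})

test_that("delta-S matches the dichromat closed form", {
  vs <- toy_vs(2, sigma = 0.05)
  e <- vs$receptors$e
  set.seed(21)
  for (i in 1:1000) {
    a <- random_catch(vs)
    b <- random_catch(vs)
    df <- a$f - b$f
    oracle <- abs(df[1] - df[2]) / sqrt(sum(e^2))
    expect_equal(rnl_delta_s(a, b, vs), oracle, tolerance = 1e-12)
  }
})

test_that("delta-S matches trichromat and tetrachromat closed forms", {
  set.seed(22)
  vs3 <- toy_vs(3, sigma = c(0.08, 0.1, 0.12), eta = c(1, 2, 2))
  vs4 <- toy_vs(4, sigma = c(0.11, 0.14, 0.14, 0.14), eta = c(1, 2, 1, 1))
  for (i in 1:200) {
    a3 <- random_catch(vs3); b3 <- random_catch(vs3)
    expect_equal(
      rnl_delta_s(a3, b3, vs3),
      trichromat_ds_oracle(a3$f - b3$f, vs3$receptors$e),
      tolerance = 1e-10
    )
    a4 <- random_catch(vs4); b4 <- random_catch(vs4)
    expect_equal(
      rnl_delta_s(a4, b4, vs4),
      tetrachromat_ds_oracle(a4$f - b4$f, vs4$receptors$e),
      tolerance = 1e-10
    )
  }
})

test_that("the spec'd dichromat example evaluates correctly", {
  # df = (0.1, 0), e = (0.05, 0.05): dS = 0.1 / sqrt(0.005)
  vs <- toy_vs(2, sigma = 0.05)
  a <- tibble::tibble(receptor = c("U", "L"), q = exp(c(0.1, 0)), f = c(0.1, 0))
  b <- tibble::tibble(receptor = c("U", "L"), q = c(1, 1), f = c(0, 0))
  expect_equal(rnl_delta_s(a, b, vs), 0.1 / sqrt(0.005), tolerance = 1e-9)
})

test_that("delta-S is symmetric, zero at identity, blind to intensity", {
  set.seed(23)
  for (n in 2:4) {
    vs <- toy_vs(n, sigma = runif(n, 0.05, 0.15))
    a <- random_catch(vs)
    b <- random_catch(vs)
    expect_equal(rnl_delta_s(a, a, vs), 0)
    expect_equal(rnl_delta_s(a, b, vs), rnl_delta_s(b, a, vs))
    # uniform shift of all log signals is an intensity change: dS = 0
    shifted <- dplyr::mutate(a, f = f + 0.7, q = exp(f + 0.7))
    expect_equal(rnl_delta_s(a, shifted, vs), 0, tolerance = 1e-12)
  }
})

test_that("delta-S is invariant to common rescaling of stimulus and background", {
  vs <- study_vs()
  bg <- flat_spec(1)
  s1 <- dplyr::mutate(bg, value = value + gauss_spec(420, 30)$value)
  s2 <- dplyr::mutate(bg, value = value + gauss_spec(550, 30)$value)
  base <- rnl_delta_s(quantum_catch(s1, bg, vs), quantum_catch(s2, bg, vs), vs)
  k <- 7.3
  bg2 <- dplyr::mutate(bg, value = value * k)
  s1k <- dplyr::mutate(s1, value = value * k)
  s2k <- dplyr::mutate(s2, value = value * k)
  scaled <- rnl_delta_s(quantum_catch(s1k, bg2, vs), quantum_catch(s2k, bg2, vs), vs)
  expect_equal(base, scaled, tolerance = 1e-10)
})

test_that("general-n delta-S approaches the reduced system when one channel is silenced", {
  # a receptor with df = 0 and e -> infinity drops out of the distance
  vs3 <- toy_vs(3, sigma = c(0.08, 0.1, 0.12))
  sens4 <- list(
    U = gauss_spec(380), M1 = gauss_spec(480), M2 = gauss_spec(520), L = gauss_spec(560)
  )
  vs4 <- visual_system(sens4, sigma = c(0.08, 0.1, 1e6, 0.12), eta = 1)
  set.seed(24)
  for (i in 1:50) {
    f3 <- runif(3, -0.5, 0.5)
    a3 <- tibble::tibble(receptor = vs3$receptors$receptor, q = exp(f3), f = f3)
    f4 <- c(f3[1], f3[2], 0, f3[3])
    a4 <- tibble::tibble(receptor = vs4$receptors$receptor, q = exp(f4), f = f4)
    b3 <- tibble::tibble(receptor = vs3$receptors$receptor, q = 1, f = 0)
    b4 <- tibble::tibble(receptor = vs4$receptors$receptor, q = 1, f = 0)
    expect_equal(rnl_delta_s(a4, b4, vs4), rnl_delta_s(a3, b3, vs3), tolerance = 1e-4)
  }
})

test_that("noise-corrected xyz preserves pairwise delta-S", {
  vs <- study_vs()
  set.seed(25)
  pts <- replicate(60, random_catch(vs), simplify = FALSE)
  xyz <- lapply(pts, function(p) unlist(noise_corrected_xyz(p, vs)[, c("x", "y", "z")]))
  idx <- cbind(sample(60, 1000, TRUE), sample(60, 1000, TRUE))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    eucl <- sqrt(sum((xyz[[i]] - xyz[[j]])^2))
    expect_equal(eucl, rnl_delta_s(pts[[i]], pts[[j]], vs), tolerance = 1e-9)
  }
})

test_that("xyz respects the origin and axis-sign conventions", {
  vs <- study_vs()
  origin <- tibble::tibble(receptor = vs$receptors$receptor, q = 1, f = 0)
  expect_equal(unlist(noise_corrected_xyz(origin, vs)[, c("x", "y", "z")]),
               c(x = 0, y = 0, z = 0))

  bump <- function(i) {
    f <- rep(0, 4); f[i] <- 0.2
    tibble::tibble(receptor = vs$receptors$receptor, q = exp(f), f = f)
  }
  expect_gt(noise_corrected_xyz(bump(1), vs)$z, 0) # +U -> +z
  expect_gt(noise_corrected_xyz(bump(2), vs)$y, 0) # +M1 -> +y
  expect_gt(noise_corrected_xyz(bump(4), vs)$x, 0) # +L -> +x

  expect_error(noise_corrected_xyz(bump(1), toy_vs(3)), "tetrachromatic")
})

test_that("norm of xyz equals delta-S from the achromatic point", {
  vs <- study_vs()
  set.seed(26)
  origin <- tibble::tibble(receptor = vs$receptors$receptor, q = 1, f = 0)
  for (i in 1:50) {
    p <- random_catch(vs)
    v <- noise_corrected_xyz(p, vs)
    expect_equal(sqrt(v$x^2 + v$y^2 + v$z^2), rnl_delta_s(p, origin, vs),
                 tolerance = 1e-9)
    expect_equal(v$delta_s, rnl_delta_s(p, origin, vs), tolerance = 1e-9)
  }
})

test_that("delta-S satisfies the triangle inequality", {
  vs <- study_vs()
  set.seed(27)
  for (i in 1:200) {
    a <- random_catch(vs); b <- random_catch(vs); c <- random_catch(vs)
    expect_lte(
      rnl_delta_s(a, c, vs),
      rnl_delta_s(a, b, vs) + rnl_delta_s(b, c, vs) + 1e-12
    )
  }
})

test_that("hue angles follow the spherical conventions", {
  expect_equal(hue_angles(c(0, 0, 1))$theta, 90)
  expect_true(is.na(hue_angles(c(0, 0, 1))$phi))
  expect_equal(unlist(hue_angles(c(1, 1, 0))), c(theta = 0, phi = 45))
  expect_equal(unlist(hue_angles(c(1, 0, 1))), c(theta = 45, phi = 0))
  expect_equal(hue_angles(c(1, -1, 0))$phi, 315)
  expect_error(hue_angles(c(0, 0, 0)), "zero vector")
})

test_that("complementary pairs are detected from the reported hue angles", {
  # reported azimuths plus elevation signs; same-side pairs are excluded
  sets <- tibble::tibble(
    label = c("green", "UV", "purple", "violet-green"),
    phi = c(297, 127, 128, 298),
    theta = c(-78, 81, -58, 53)
  )
  pairs <- complementary_pairs(sets, tolerance = 15)
  expect_equal(nrow(pairs), 2)
  got <- lapply(seq_len(2), function(i) sort(c(pairs$label_a[i], pairs$label_b[i])))
  expect_true(any(vapply(got, identical, logical(1), c("UV", "green"))))
  expect_true(any(vapply(got, identical, logical(1), c("purple", "violet-green"))))
  expect_equal(pairs$deviation, c(10, 10))

  expect_equal(nrow(complementary_pairs(
    tibble::tibble(label = c("A", "B"), phi = c(0, 90)), 15
  )), 0)
  expect_equal(nrow(complementary_pairs(
    tibble::tibble(label = c("A", "B"), phi = c(0, 180)), 15
  )), 1)
  expect_error(complementary_pairs(sets, tolerance = 95), "\\(0, 90\\)")
})

test_that("non-spectral classification needs a dip between excited flanks", {
  expect_true(classify_non_spectral(c(2, 1, 1, 2)))
  expect_false(classify_non_spectral(c(1, 2, 2, 1)))
  expect_false(classify_non_spectral(c(1, 1, 1, 1)))
  expect_true(classify_non_spectral(c(1.5, 1, 2, 1.8)))
  expect_false(classify_non_spectral(c(1, 2, 3, 4)))
  expect_error(classify_non_spectral(c(1, 2)), "3 receptors")
})
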