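test_that("theoretical_mz applies the positive-mode proton relation", {
  expect_equal(theoretical_mz(13286.2, 7), (13286.2 + 7 * 1.00728) / 7)
  expect_equal(theoretical_mz(5000, 1), 5000 + 1.00728)
  expect_error(theoretical_mz(5000, 0), "positive integer")
})

test_that("charge inference recovers synthetic ladders across the working range", {
  for (M in c(12000, 13286.2, 14230, 15000)) {
    for (zmin in 4:10) {
      zs <- zmin:(zmin + 2)
      pl <- peak_list(theoretical_mz(M, zs), rep(1, length(zs)),
                      mode = "raw_mz")
      inferred <- infer_charges(pl)
      expect_equal(sort(inferred$charge), sort(zs),
                   info = sprintf("M=%.1f z=%d", M, zmin))
    }
  }
})

test_that("charge inference rejects underdetermined or inconsistent input", {
  single <- peak_list(1899.04, 1, mode = "raw_mz")
  expect_error(infer_charges(single), "ambiguous")
  garbled <- peak_list(c(1000, 1003.7), c(1, 1), mode = "raw_mz")
  expect_error(infer_charges(garbled), "ambiguous")
})

test_that("envelope deconvolution round-trips noiselessly", {
  M <- 14230.0
  zs <- 6:8
  pl <- infer_charges(peak_list(theoretical_mz(M, zs), c(1, 2, 1),
                                mode = "raw_mz"))
  est <- neutral_mass_from_envelope(pl)
  expect_equal(est$mass, M, tolerance = M * 1e-9)
  expect_equal(est$sd, 0, tolerance = 1e-6)
  one <- neutral_mass_from_envelope(
    data.frame(mz = theoretical_mz(13286.2, 7), charge = 7, intensity = 1))
  expect_equal(one$mass, 13286.2, tolerance = 1e-6)
})

test_that("inconsistent envelopes are rejected", {
  env <- data.frame(mz = c(theoretical_mz(13286.2, 7),
                           theoretical_mz(13400, 8)),
                    charge = c(7, 8), intensity = c(1, 1))
  expect_error(neutral_mass_from_envelope(env), "spread")
})

test_that("weighted-mean mass estimator is unbiased on symmetric noise", {
  M <- 13286.2
  zs <- 5:9
  n_rep <- 1000
  set.seed(42)
  est <- replicate(n_rep, {
    mz <- theoretical_mz(M, zs) + rnorm(length(zs), 0, 0.05)
    neutral_mass_from_envelope(
      data.frame(mz = mz, charge = zs, intensity = rep(1, length(zs))))$mass
  })
  se <- sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - M), 3 * se)
})

test_that("deconvolute groups multi-species raw peak lists", {
  masses <- c(13286.2, 14230.0)
  zs <- 5:9
  mz <- c(theoretical_mz(masses[1], zs), theoretical_mz(masses[2], zs))
  pl <- peak_list(mz, rep(1, length(mz)), mode = "raw_mz",
                  charge = rep(zs, 2))
  out <- deconvolute(pl)
  expect_equal(nrow(out), 2)
  expect_equal(out$mass, masses, tolerance = 1e-6)
  # and with charges withheld
  pl2 <- peak_list(mz, rep(1, length(mz)), mode = "raw_mz")
  out2 <- deconvolute(pl2)
  expect_equal(out2$mass, masses, tolerance = 1e-3)
})

test_that("deconvoluted-mode peak lists bypass charge inference", {
  pl <- peak_list(c(13286.2, 13349.6), c(2, 1), mode = "deconvoluted_mass")
  out <- deconvolute(pl)
  expect_equal(out$mass, c(13286.2, 13349.6))
  expect_equal(out$intensity, c(2, 1))
})

test_that("pick_peaks finds apexes by parabolic interpolation", {
  x <- seq(1600, 2000, by = 0.2)
  centers <- c(1661.78, 1899.04)
  y <- 1.0 * exp(-(x - centers[1])^2 / (2 * 0.5^2)) +
       0.8 * exp(-(x - centers[2])^2 / (2 * 0.5^2))
  pk <- pick_peaks(x, y)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$mz, centers, tolerance = 0.02)

  expect_equal(nrow(pick_peaks(x, rep(0, length(x)))), 0)

  # shoulder below the relative threshold is excluded
  y2 <- y + 0.02 * exp(-(x - 1750)^2 / (2 * 0.5^2))
  pk2 <- pick_peaks(x, y2, min_rel_intensity = 0.05)
  expect_equal(nrow(pk2), 2)
})

test_that("peak CSV round-trips through both dialects", {
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(mass = c(13286.2, 13349.6), intensity = c(2, 1)),
            tmp, row.names = FALSE)
  pl <- read_peak_list(tmp)
  expect_identical(attr(pl, "mode"), "deconvoluted_mass")
  write.csv(data.frame(mz = c(1899.04, 1661.78), intensity = c(1, 1),
                       charge = c(7, 8)), tmp, row.names = FALSE)
  pl2 <- read_peak_list(tmp)
  expect_identical(attr(pl2, "mode"), "raw_mz")
  expect_true("charge" %in% names(pl2))
  write.csv(data.frame(foo = 1, bar = 2), tmp, row.names = FALSE)
  expect_error(read_peak_list(tmp), "must have")
  unlink(tmp)
})
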