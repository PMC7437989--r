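test_that("windowed integration matches analytic areas and handles baselines", {
  x <- seq(1000, 1300, by = 0.5)
  fwhm <- 12
  s <- raman_spectrum(x, pseudo_voigt(x, 1, 1150, fwhm, 1))  # pure Gaussian
  got <- integrate_band(s, c(1150 - 5 * fwhm, 1150 + 5 * fwhm),
                        local_baseline = "none")$area
  expect_equal(got, 1, tolerance = 0.005)

  # zero spectrum integrates to zero; constant removed by endpoints line
  z <- raman_spectrum(x, numeric(length(x)))
  expect_equal(integrate_band(z, c(1100, 1200), "none")$area, 0)
  cst <- raman_spectrum(x, rep(3.7, length(x)))
  expect_equal(integrate_band(cst, c(1100, 1200), "endpoints-line")$area, 0)

  # negative windows are clipped and flagged
  neg <- raman_spectrum(x, rep(-1, length(x)))
  r <- integrate_band(neg, c(1100, 1200), "none")
  expect_equal(r$area, 0)
  expect_true("clipped_negative" %in% r$flags)

  expect_error(integrate_band(s, c(1900, 2000)), "outside")
})

test_that("window capture fractions match numerical integrals", {
  x <- seq(0, 4000, by = 0.05)
  for (gf in c(0, 0.5, 1)) {
    y <- pseudo_voigt(x, 1, 2000, 15, gf)
    for (w in list(c(1980, 2020), c(1970, 2050))) {
      num <- pracma::trapz(x[x >= w[1] & x <= w[2]], y[x >= w[1] & x <= w[2]])
      expect_equal(pv_window_fraction(w, 2000, 15, gf), num, tolerance = 1e-4)
    }
  }
})

test_that("a single isolated band is fitted essentially exactly", {
  x <- seq(1040, 1110, by = 1)
  truth <- c(area = 0.8, center = 1075, fwhm = 11, gf = 0.35)
  s <- raman_spectrum(x, pseudo_voigt(x, truth["area"], truth["center"],
                                      truth["fwhm"], truth["gf"]))
  fit <- fit_region(s, peak_component(1075, fwhm = 10), fix_mixing = FALSE)
  expect_true(fit$converged)
  expect_equal(fit$components$area, unname(truth["area"]), tolerance = 1e-6)
  expect_equal(fit$components$center, unname(truth["center"]), tolerance = 1e-6)
  expect_equal(fit$components$gaussian_fraction, unname(truth["gf"]),
               tolerance = 1e-4)
})

test_that("the overlapped stretch region deconvolves to the generating areas", {
  # noiseless synthetic stretch region with known A1065 = 0.15, A1085 = 0.20
  x <- seq(1040, 1110, by = 1)
  y <- pseudo_voigt(x, 0.15, 1065, 10, 0.5) + pseudo_voigt(x, 0.20, 1085, 18, 0.5)
  fit <- fit_region(raman_spectrum(x, y),
                    rbind(peak_component(1065, 10), peak_component(1085, 18)))
  expect_true(fit$converged)
  expect_equal(fit$components$area, c(0.15, 0.20), tolerance = 0.01)
})

test_that("fully degenerate components still preserve the summed area", {
  # two identical components are individually unidentifiable; the tied
  # solution must still account for the total area
  x <- seq(1040, 1110, by = 1)
  y <- pseudo_voigt(x, 0.4, 1075, 12, 0.5)
  fit <- fit_region(raman_spectrum(x, y),
                    rbind(peak_component(1075, 12), peak_component(1075, 12)),
                    fix_mixing = TRUE)
  expect_equal(sum(fit$components$area), 0.4, tolerance = 0.01)
})

test_that("fit guards reject underdetermined and empty regions", {
  x <- seq(1040, 1050, by = 1)
  s <- raman_spectrum(x, rexp(length(x)))
  init <- rbind(peak_component(1042, 5), peak_component(1045, 5),
                peak_component(1048, 5))
  expect_error(fit_region(s, init), "underdetermined")
  z <- raman_spectrum(seq(1040, 1110), numeric(71))
  expect_error(fit_region(z, peak_component(1075)), "all-zero")
})

test_that("fitted component areas add up to the region integral when separated", {
  # Gaussian components so the window holds essentially all the area
  # (Lorentzian tails would make the trapezoidal side systematically low)
  x <- seq(1030, 1120, by = 1)
  y <- pseudo_voigt(x, 0.3, 1055, 10, 1) + pseudo_voigt(x, 0.5, 1095, 10, 1)
  fit <- fit_region(raman_spectrum(x, y),
                    rbind(peak_component(1055, 10, gaussian_fraction = 1),
                          peak_component(1095, 10, gaussian_fraction = 1)),
                    fix_mixing = TRUE)
  direct <- integrate_band(raman_spectrum(x, y), c(1030, 1120), "none")$area
  expect_equal(sum(fit$components$area), direct, tolerance = 0.02 * direct)
})

test_that("all five areas are recovered within 1% from a noiseless spectrum", {
  areas <- ref_areas()
  s <- render_ref(baseline = c(50, -10))
  corrected <- correct_baseline(s)$spectrum
  got <- measure_band_areas(corrected)
  for (nm in c("A_1416", "A_1085", "A_1295_1305", "A_1130", "A_1065")) {
    expect_equal(got[[nm]], areas[[nm]], tolerance = 0.01,
                 label = sprintf("%s recovered", nm))
  }
})

test_that("measured areas scale linearly with a global intensity multiplier", {
  s <- correct_baseline(render_ref(baseline = 0))$spectrum
  ks <- c(0.5, 1, 2, 10, 100)
  a1130 <- vapply(ks, function(k) {
    measure_band_areas(raman_spectrum(s$wavenumbers, s$intensities * k))$A_1130
  }, 1.0)
  fit <- stats::lm(a1130 ~ ks)
  expect_gt(summary(fit)$r.squared, 0.9999)
  expect_equal(unname(stats::coef(fit)[2]), ref_areas()$A_1130,
               tolerance = 1e-3)
})

test_that("insufficient spectral coverage is reported with the band identity", {
  s <- render_ref()
  short <- extract_region(s, 1000, 1350)
  expect_error(measure_band_areas(short), "coverage")
})

test_that("noisy A_1130 recovery is unbiased within 2 standard errors", {
  areas <- ref_areas()
  vals <- vapply(1:50, function(sd) {
    sn <- render_ref(noise = noise_spec(scale = 1, floor = 100), seed = sd)
    measure_band_areas(correct_baseline(sn)$spectrum)$A_1130
  }, 1.0)
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - areas$A_1130), 2 * se + 1e-9)
})
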