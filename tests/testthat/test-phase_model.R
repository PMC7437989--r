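test_that("phase equations reproduce their unit and hand-computed cases", {
  # unit case: only crystalline signal
  p <- compute_phase_composition(band_areas(0.46, 0, 1, 0.8, 0.1))
  expect_equal(p$alpha_o, 1)
  expect_equal(p$alpha_a, 0)
  expect_equal(p$alpha_b, 0)

  # hand evaluation: 0.2714/0.46 = 0.59, 0.1975/0.79 = 0.25, rest 0.16
  p2 <- compute_phase_composition(band_areas(0.2714, 0.1975, 1, 0.8, 0.1))
  expect_equal(p2$alpha_o, 0.59, tolerance = 1e-12)
  expect_equal(p2$alpha_a, 0.25, tolerance = 1e-12)
  expect_equal(p2$alpha_b, 0.16, tolerance = 1e-12)
  expect_length(p2$flags, 0)
})

test_that("negative third-phase content is returned and flagged, never clipped", {
  p <- compute_phase_composition(band_areas(0.46, 0.79, 1, 0.8, 0.1))
  expect_equal(p$alpha_b, -1)
  expect_true("negative_alpha_b" %in% p$flags)
})

test_that("the three phases always sum to one by construction", {
  set.seed(77)
  for (i in 1:1000) {
    a <- band_areas(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0.1, 3),
                    runif(1, 0, 2), runif(1, 0, 2))
    p <- compute_phase_composition(a)
    expect_identical(p$alpha_o + p$alpha_a + p$alpha_b, 1)
  }
})

test_that("conformer equations: unit cases, exact product identity, monotone trends", {
  cc <- compute_conformer_content(band_areas(0, 0, 1, 0.8, 0.1))
  expect_equal(cc$all_trans, 1)
  cc2 <- compute_conformer_content(band_areas(1, 0, 1, 1, 0.1))
  expect_equal(cc2$ortho_trans, 1.78)

  # ortho_trans * A_1130 = 1.78 * A_1416 exactly
  set.seed(12)
  for (i in 1:50) {
    a <- band_areas(runif(1, 0.01, 2), runif(1), runif(1, 0.1, 3),
                    runif(1, 0.01, 2), runif(1))
    cc <- compute_conformer_content(a)
    expect_equal(cc$ortho_trans * a$A_1130, 1.78 * a$A_1416,
                 tolerance = 1e-14)
  }

  # increasing A_1130 raises all-trans and lowers ortho-trans strictly
  a1130 <- seq(0.2, 1.4, by = 0.2)
  at <- ot <- numeric(length(a1130))
  for (i in seq_along(a1130)) {
    cc <- compute_conformer_content(band_areas(0.3, 0.2, 1, a1130[i], 0.1))
    at[i] <- cc$all_trans; ot[i] <- cc$ortho_trans
  }
  expect_true(all(diff(at) > 0))
  expect_true(all(diff(ot) < 0))

  und <- compute_conformer_content(band_areas(0.3, 0.2, 1, 0, 0.1))
  expect_true(is.na(und$ortho_trans))
  expect_true("undefined_ortho_trans" %in% und$flags)
})

test_that("calibration constants default to their published precision", {
  k <- pe_calibration()
  expect_identical(k$c_o, 0.46)
  expect_identical(k$c_a, 0.79)
  expect_identical(k$c_t, 0.80)
  expect_identical(k$c_ot, 1.78)
  expect_error(pe_calibration(c_o = -1), "positive")
})

test_that("orientation ratio follows the generator and flags A1065 = 0", {
  expect_equal(orientation_ratio(band_areas(0, 0, 1, 0.5, 0.5))$ratio_1130_1065, 1)
  o <- orientation_ratio(band_areas(0, 0, 1, 0.5, 0))
  expect_true(is.na(o$ratio_1130_1065))
  expect_true(length(o$flags) > 0)

  # doubling A_1130 in the generator doubles the measured ratio
  base <- ref_areas()
  doubled <- band_areas(base$A_1416, base$A_1085, base$A_1295_1305,
                        2 * base$A_1130, base$A_1065)
  r1 <- analyze_spectrum(render_spectrum(base, noise = noise_spec(scale = 0)))
  r2 <- analyze_spectrum(render_spectrum(doubled, noise = noise_spec(scale = 0)))
  expect_equal(r2$ratio_1130_1065 / r1$ratio_1130_1065, 2, tolerance = 0.02)
})

test_that("polarization comparison separates noise from real 1130 cm^-1 changes", {
  base <- ref_areas()
  s <- render_ref()
  expect_equal(compare_polarizations(s, s)$metric, 0)
  expect_true(compare_polarizations(s, s)$coincident)

  # independent noise draws of the same underlying spectrum stay coincident
  mets <- vapply(1:20, function(i) {
    a <- render_ref(noise = noise_spec(scale = 1), seed = i)
    b <- render_ref(noise = noise_spec(scale = 1), seed = 500 + i)
    compare_polarizations(a, b)$metric
  }, 1.0)
  expect_true(all(mets < 0.05))

  # a doubled 1130 cm^-1 band exceeds the noise-only distribution
  doubled <- band_areas(base$A_1416, base$A_1085, base$A_1295_1305,
                        2 * base$A_1130, base$A_1065)
  a <- render_ref(noise = noise_spec(scale = 1), seed = 3)
  b <- render_spectrum(doubled, baseline = c(50, -10),
                       noise = noise_spec(scale = 1), seed = 903)
  expect_gt(compare_polarizations(a, b)$metric,
            stats::quantile(mets, 0.99))

  s_hi <- raman_spectrum(seq(2000, 2100), rexp(101))
  expect_error(compare_polarizations(s, s_hi), "common")
})
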