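test_that("inversion of the phase equations is exact on unit fractions", {
  a <- invert_composition(phase_targets(1, 0, 1), a_ref = 1)
  expect_equal(a$A_1416, 0.46)
  expect_equal(a$A_1085, 0)
  expect_equal(a$A_1130, 0.80)
  expect_equal(a$A_1295_1305, 1)
})

test_that("forward equations recover inverted targets exactly (identity property)", {
  # the published alpha_o = 0.59 anchor case plus random valid targets
  a <- invert_composition(phase_targets(0.59, 0.25, 0.66), a_ref = 1)
  expect_equal(compute_phase_composition(a)$alpha_o, 0.59)

  set.seed(424242)
  for (i in 1:100) {
    ao <- runif(1, 0, 0.9)
    aa <- runif(1, 0, 1 - ao)
    at <- runif(1, ao, 1)
    tg <- phase_targets(ao, aa, at)
    a <- invert_composition(tg, a_ref = runif(1, 0.1, 1e5))
    ph <- compute_phase_composition(a)
    cc <- compute_conformer_content(a)
    expect_equal(ph$alpha_o, ao, tolerance = 1e-12)
    expect_equal(ph$alpha_a, aa, tolerance = 1e-12)
    expect_equal(cc$all_trans, at, tolerance = 1e-12)
  }
  expect_error(invert_composition(phase_targets(0.5, 0.2, 0.6), a_ref = 0),
               "positive")
})

test_that("target validation enforces the simplex and all-trans bounds", {
  expect_error(phase_targets(-0.1, 0.2, 0.5), "invalid")
  expect_error(phase_targets(0.6, 0.5, 0.7), "invalid")   # sum > 1
  expect_error(phase_targets(0.6, 0.2, 0.5), "invalid")   # all_trans < alpha_o
  expect_silent(phase_targets(0, 0, 0))
})

test_that("rendered bands integrate back to their areas", {
  # single unit-area Gaussian: numerical integral over +-5 FWHM ~ 1
  shapes <- band_shape_spec()
  shapes$gaussian_fraction <- 1
  a <- band_areas(A_1416 = 0, A_1085 = 0, A_1295_1305 = 0, A_1130 = 1, A_1065 = 0)
  s <- render_spectrum(a, shapes = shapes, noise = noise_spec(scale = 0))
  got <- integrate_band(s, c(1130 - 50, 1130 + 50), local_baseline = "none")$area
  expect_equal(got, 1, tolerance = 0.005)

  # pseudo-Voigt mixture: full-span integral matches the analytic capture
  a2 <- ref_areas(a_ref = 1)
  s2 <- render_spectrum(a2, noise = noise_spec(scale = 0))
  total <- integrate_band(s2, c(1000, 1500), local_baseline = "none")$area
  sh <- band_shape_spec()
  aa_frac <- 0.25
  amp <- c(a2$A_1065, a2$A_1085, a2$A_1130, 0.55 * a2$A_1295_1305,
           0.45 * a2$A_1295_1305, a2$A_1416, 1.2 * aa_frac, 0.9 * aa_frac)
  expected <- sum(amp * vapply(seq_len(nrow(sh)), function(i) {
    pv_window_fraction(c(1000, 1500), sh$center[i], sh$fwhm[i],
                       sh$gaussian_fraction[i])
  }, 1.0))
  expect_equal(total, expected, tolerance = 1e-3)
})

test_that("render obeys degenerate and sampling contracts", {
  zero <- band_areas(0, 0, 0, 0, 0)
  s <- render_spectrum(zero, noise = noise_spec(scale = 0))
  expect_true(all(s$intensities == 0))
  expect_error(render_spectrum(zero, step = 6), "undersample")
})

test_that("noise is reproducible from the seed and differs across seeds", {
  a <- ref_areas()
  s1 <- render_ref(noise = noise_spec(scale = 1), seed = 99)
  s2 <- render_ref(noise = noise_spec(scale = 1), seed = 99)
  s3 <- render_ref(noise = noise_spec(scale = 1), seed = 100)
  expect_identical(s1$intensities, s2$intensities)
  expect_false(identical(s1$intensities, s3$intensities))
})

test_that("simulated studies have the cohort structure and are seed-reproducible", {
  sc <- default_study_scenario(seed = 5)
  st <- simulate_study(sc)
  expect_length(st$spectra, 4 * 3 * 2 * 12)
  expect_equal(nrow(st$records), 288)
  expect_equal(sum(st$truth$level == "cup"), 24)
  expect_equal(nrow(st$gravimetry), 24)
  expect_setequal(unique(st$gravimetry$role), c("loaded", "soak_control"))

  st2 <- simulate_study(sc)
  expect_identical(st$spectra[[17]]$intensities, st2$spectra[[17]]$intensities)
  expect_identical(st$truth, st2$truth)

  st3 <- simulate_study(default_study_scenario(seed = 6))
  expect_false(identical(st$spectra[[17]]$intensities,
                         st3$spectra[[17]]$intensities))
})

test_that("zero-SD scenarios propagate group targets to every point", {
  sc <- wear_mechanism_scenario("ortho_from_amorphous")
  st <- simulate_study(sc)
  pts <- st$truth[st$truth$level == "point" & st$truth$state == "unworn", ]
  expect_true(all(pts$alpha_o == 0.59))
  expect_true(all(pts$alpha_a == 0.25))
})

test_that("cup-level recovered alpha_o dispersion grows with within-cup SD", {
  sds <- c(0, 0.02, 0.06)
  disp <- vapply(sds, function(psd) {
    g <- group_spec(unworn = ref_targets(), cup_sd = c(0, 0, 0),
                    point_sd = rep(psd, 3), mass_loss = c(100, 0))
    sc <- study_scenario(groups = list(STD = g), n_cups = 1L, n_points = 12L,
                         noise = noise_spec(scale = 0), soak = c(5, 0),
                         seed = 31L)
    st <- simulate_study(sc)
    pts <- st$truth[st$truth$level == "point", ]
    stats::sd(pts$alpha_o)
  }, 1.0)
  expect_true(all(diff(disp) > 0))
})

test_that("scenario JSON round-trips and packaged fixtures load", {
  sc <- default_study_scenario(seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_scenario(sc, f)
  sc2 <- read_scenario(f)
  expect_equal(sc2$groups$STD$unworn$alpha_o, sc$groups$STD$unworn$alpha_o)
  expect_equal(sc2$seed, sc$seed)
  expect_identical(simulate_study(sc2)$truth, simulate_study(sc)$truth)

  fx <- scenario_fixture("fig7_std_unworn")
  expect_s3_class(fx, "study_scenario")
  expect_equal(fx$groups$STD$unworn$alpha_o, 0.59)
  expect_equal(fx$noise$scale, 0)
  expect_error(scenario_fixture("nope"), "fixture")
})
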