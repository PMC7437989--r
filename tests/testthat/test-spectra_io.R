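test_that("ascii-xy parsing handles separators, comments, and direct arrays", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "1040 10", "1045, 12", "1050\t13  # inline"), f)
  s <- read_spectrum(f, format = "ascii-xy")
  expect_equal(s$wavenumbers, c(1040, 1045, 1050))
  expect_equal(s$intensities, c(10, 12, 13))

  writeLines(c("1040 10", "1045 twelve"), f)
  expect_error(read_spectrum(f, format = "ascii-xy"), "line 2")
})

test_that("both formats round-trip to 1e-9 and auto-detect", {
  s <- raman_spectrum(seq(1000, 1500, by = 2.5),
                      abs(sin(seq_len(201))) * 123.456,
                      meta = list(cup_id = "STD_L1"))
  for (fmt in c("ascii-xy", "jcamp-dx")) {
    f <- withr::local_tempfile(fileext = if (fmt == "ascii-xy") ".txt" else ".jdx")
    write_spectrum(s, f, format = fmt)
    s2 <- read_spectrum(f)  # format sniffed
    expect_equal(s2$wavenumbers, s$wavenumbers, tolerance = 1e-12)
    expect_equal(s2$intensities, s$intensities, tolerance = 1e-12)
  }
})

test_that("jcamp XYDATA tables with X factors are expanded correctly", {
  f <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=demo", "##JCAMP-DX=4.24", "##XUNITS=1/CM",
               "##XFACTOR=2", "##YFACTOR=0.5", "##FIRSTX=2000", "##LASTX=2012",
               "##NPOINTS=7", "##DELTAX=1",
               "##XYDATA=(X++(Y..Y))",
               "1000 2 4 6 8", "1004 10 12 14", "##END="), f)
  s <- read_spectrum(f, format = "jcamp-dx")
  expect_equal(s$wavenumbers, seq(2000, 2012, by = 2))
  expect_equal(s$intensities, seq(1, 7))
})

test_that("descending axes are normalized and duplicates rejected", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1050 13", "1045 12", "1040 10"), f)
  s_desc <- read_spectrum(f, format = "ascii-xy")
  writeLines(c("1040 10", "1045 12", "1050 13"), f)
  s_asc <- read_spectrum(f, format = "ascii-xy")
  expect_identical(s_desc$wavenumbers, s_asc$wavenumbers)
  expect_identical(s_desc$intensities, s_asc$intensities)

  writeLines(c("1040 10", "1040 11", "1050 13"), f)
  expect_error(read_spectrum(f, format = "ascii-xy"), "monotonic")
})

test_that("coverage of the quantification range is enforced when requested", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("%d %g", 1040:1120, rexp(81)), f)
  expect_silent(read_spectrum(f, format = "ascii-xy"))
  expect_error(read_spectrum(f, format = "ascii-xy", span = c(1040, 1480)),
               "coverage")
})

test_that("manifest validation counts, rejects bad vocabulary, allows gravimetry-only cups", {
  dir <- withr::local_tempdir()
  spec_rows <- expand.grid(material = c("STD", "XL-50", "XL-75", "VE"),
                           cup = 1:3, state = c("unworn", "worn"),
                           point_index = 1:12, stringsAsFactors = FALSE)
  spec_rows$cup_id <- paste0(gsub("-", "", spec_rows$material), "_", spec_rows$cup)
  spec_rows$path <- sprintf("s%04d.txt", seq_len(nrow(spec_rows)))
  tiny <- raman_spectrum(c(1040, 1045, 1050), c(1, 2, 1))
  for (p in spec_rows$path) write_spectrum(tiny, file.path(dir, p))
  df <- data.frame(role = "spectrum", path = spec_rows$path,
                   cup_id = spec_rows$cup_id, material = spec_rows$material,
                   state = spec_rows$state, point_index = spec_rows$point_index,
                   polarization = "unpolarized", measured_mass_change_mg = NA)
  grav <- data.frame(role = "soak_control", path = "", cup_id = "STD_S1",
                     material = "STD", state = "", point_index = NA,
                     polarization = "", measured_mass_change_mg = 5.12)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(rbind(df, grav), mpath, row.names = FALSE)
  m <- read_cohort_manifest(mpath)
  expect_equal(nrow(m$records), 4 * 3 * 2 * 12)
  expect_equal(nrow(m$gravimetry), 1)

  bad <- rbind(df, grav)
  bad$material[1] <- "XL-90"
  write.csv(bad, mpath, row.names = FALSE)
  expect_error(read_cohort_manifest(mpath), "XL-90")

  dup <- rbind(df, df[1, ], grav)
  write.csv(dup, mpath, row.names = FALSE)
  expect_error(read_cohort_manifest(mpath), "duplicate")

  missing_file <- df
  missing_file$path[5] <- "nope.txt"
  write.csv(rbind(missing_file, grav), mpath, row.names = FALSE)
  expect_error(read_cohort_manifest(mpath), "missing spectrum file")
})

test_that("spectrum constructor rejects non-finite data and bad metadata", {
  expect_error(raman_spectrum(c(1, 2), c(1, NA)), "finite")
  expect_error(raman_spectrum(c(1, 2), c(1, Inf)), "finite")
  expect_error(raman_spectrum(c(1, 2, 3), c(1, 2)), "length")
  expect_error(raman_spectrum(1, 1), "at least 2")
  expect_error(raman_spectrum(c(1, 2), c(0, 0), meta = list(state = "broken")),
               "state")
  # alternate material spelling is normalized, unknown rejected
  expect_silent(raman_spectrum(c(1, 2), c(0, 0), meta = list(material = "XL50")))
  expect_error(raman_spectrum(c(1, 2), c(0, 0), meta = list(material = "PEEK")),
               "material")
})
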