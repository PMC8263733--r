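test_that("ir_spectrum canonicalizes order and enforces invariants", {
  s <- ir_spectrum(c(1000, 999), c(0.5, 0.6))
  expect_equal(s$wavenumbers, c(999, 1000))
  expect_equal(s$absorbance, c(0.6, 0.5))
  expect_error(ir_spectrum(1000, 0.5), "at least 2")
  expect_error(ir_spectrum(c(1, 2), c(0.5, NA)), "finite")
  expect_error(ir_spectrum(c(1, 1), c(0.5, 0.6)), "duplicate")
  expect_error(ir_spectrum(c(1, 2, 3), c(0.5, 0.6)), "same length")
})

test_that("read_spectrum_csv parses dialects and flags bad rows", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1000,0.5", "999,0.6"), p)
  s <- read_spectrum_csv(p)
  expect_equal(s$wavenumbers, c(999, 1000))
  expect_equal(s$absorbance, c(0.6, 0.5))
  expect_equal(s$meta$source, p)

  writeLines(c("wavenumber,absorbance", "1000,0.5", "999,0.6"), p)
  expect_equal(read_spectrum_csv(p)$absorbance, c(0.6, 0.5))

  writeLines(c("1000 0.5", "999\t0.6"), p)  # whitespace dialect
  expect_equal(read_spectrum_csv(p)$wavenumbers, c(999, 1000))

  writeLines(c("1000,abc", "999,0.6"), p)
  expect_error(read_spectrum_csv(p), "line 1")
  writeLines(c("1000,0.5", "1000,0.6"), p)
  expect_error(read_spectrum_csv(p), "duplicate")
})

test_that("CSV round trip is bit-for-bit", {
  s <- generate_component("dsDNA_A", 1, spectral_region(900, 1100))
  p <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(s, p)
  s2 <- read_spectrum_csv(p)
  expect_identical(s2$wavenumbers, s$wavenumbers)
  expect_identical(s2$absorbance, s$absorbance)
  # and the file itself is stable under a second round trip
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(s2, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("JCAMP-DX XYDATA decodes FIRSTX/DELTAX/XFACTOR/YFACTOR", {
  p <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=minimal", "##JCAMP-DX=4.24",
               "##FIRSTX=650", "##DELTAX=2", "##XFACTOR=1",
               "##YFACTOR=0.001", "##NPOINTS=3",
               "##XYDATA=(X++(Y..Y))", "650 100 200 300", "##END="), p)
  s <- read_spectrum_jcampdx(p)
  expect_equal(s$wavenumbers, c(650, 652, 654))
  expect_equal(s$absorbance, c(0.1, 0.2, 0.3))
  expect_equal(s$meta$title, "minimal")
})

test_that("JCAMP-DX XYPOINTS equals the equivalent CSV", {
  pj <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=pairs", "##XYPOINTS=(XY..XY)",
               "650, 0.1; 652, 0.2; 654, 0.3", "##END="), pj)
  pc <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("650,0.1", "652,0.2", "654,0.3"), pc)
  sj <- read_spectrum_jcampdx(pj)
  sc <- read_spectrum_csv(pc)
  expect_equal(sj$wavenumbers, sc$wavenumbers)
  expect_equal(sj$absorbance, sc$absorbance)
})

test_that("JCAMP-DX rejects bad or unsupported files with clear errors", {
  p <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=x", "##FIRSTX=650", "##DELTAX=0", "##NPOINTS=2",
               "##XYDATA=(X++(Y..Y))", "650 1 2", "##END="), p)
  expect_error(read_spectrum_jcampdx(p), "DELTAX")
  writeLines(c("##TITLE=x", "##XYDATA=(X++(Y..Y))", "650 1 2", "##END="), p)
  expect_error(read_spectrum_jcampdx(p), "FIRSTX.*DELTAX|missing")
  writeLines(c("##TITLE=x", "##FIRSTX=650", "##DELTAX=2", "##NPOINTS=3",
               "##XYDATA=(X++(Y..Y))", "650A1B2C3", "##END="), p)
  expect_error(read_spectrum_jcampdx(p), "SQZ|AFFN")
  writeLines(c("##TITLE=x", "no data at all"), p)
  expect_error(read_spectrum_jcampdx(p), "XYDATA or ..XYPOINTS")
})

test_that("resample interpolates linearly, includes endpoints, refuses extrapolation", {
  # exact on a linear absorbance profile
  wn <- seq(900, 1100, by = 2)
  s <- ir_spectrum(wn, 0.001 * wn + 0.2)
  r <- resample(s, 1, spectral_region(900, 1100))
  expect_equal(r$wavenumbers, seq(900, 1100, by = 1))
  expect_equal(r$absorbance, 0.001 * r$wavenumbers + 0.2, tolerance = 1e-12)
  # identity when already on the target grid
  r2 <- resample(r, 1, spectral_region(900, 1100))
  expect_equal(r2$absorbance, r$absorbance)
  # idempotence on a curved spectrum
  g <- generate_component("dsDNA_A", 1, spectral_region(900, 1300))
  a <- resample(g, 2, spectral_region(950, 1250))
  b <- resample(a, 2, spectral_region(950, 1250))
  expect_equal(a$absorbance, b$absorbance)
  expect_error(resample(s, 1, spectral_region(400, 500)), "outside")
})

test_that("extract_region keeps pairs unchanged and errors on empty overlap", {
  s <- generate_component("dsDNA_A", 1, spectral_region(650, 4000))
  r <- extract_region(s, fingerprint_region())
  expect_true(all(r$wavenumbers >= 900 & r$wavenumbers <= 1500))
  idx <- match(r$wavenumbers, s$wavenumbers)
  expect_identical(r$absorbance, s$absorbance[idx])
  same <- extract_region(s, spectral_region(650, 4000))
  expect_identical(same$absorbance, s$absorbance)
  expect_error(extract_region(s, spectral_region(5000, 6000)), "overlap")
})
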