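test_that("detect_bands finds isolated bands and nothing on flat input", {
  g <- generate_component(component_preset("one", list(band_component(1100, 20, 1))),
                          1, spectral_region(1000, 1200))
  d <- second_derivative(g)
  bands <- detect_bands(d, spectral_region(1020, 1180))
  expect_equal(nrow(bands), 1L)
  expect_lte(abs(bands$position - 1100), 1)

  flat <- second_derivative(ir_spectrum(seq(900, 1500), rep(0.3, 601)))
  expect_equal(nrow(detect_bands(flat, spectral_region(950, 1450))), 0L)
  expect_error(detect_bands(d, spectral_region(1000, 1005)), "edge")
})

test_that("detect_bands positions are invariant under positive scaling", {
  s <- generate_component("trehalose_dry", 1, fp_1800())
  b1 <- detect_bands(fingerprint_d2(s), spectral_region(960, 1170))
  s2 <- ir_spectrum(s$wavenumbers, 0.037 * s$absorbance, s$meta)
  b2 <- detect_bands(fingerprint_d2(s2), spectral_region(960, 1170))
  expect_identical(b1$position, b2$position)
})

test_that("dried trehalose shows exactly five bands in 960-1170", {
  d <- fingerprint_d2(generate_component("trehalose_dry", 1, fp_1800()))
  bands <- detect_bands(d, spectral_region(960, 1170))
  expect_equal(nrow(bands), 5L)
})

test_that("extract_markers recovers the dried (A-form) assignments", {
  m <- pipeline_markers("dsDNA_A", "dried")
  expect_equal(m$cc$position, 965)
  expect_equal(m$co$position, 1050)
  expect_equal(m$po2_sym$position, 1089)
  expect_equal(m$po2_asym$position, 1235)
  expect_equal(m$state_assumed, "dried")
})

test_that("extract_markers recovers the hydrated (B-form) assignments", {
  m <- pipeline_markers(formulation_spec(c(dsDNA_B = 1), hydration = 1),
                        "hydrated")
  expect_equal(m$cc$position, 970)
  expect_equal(m$co$position, 1052)
  expect_equal(m$po2_asym$position, 1225)
})

test_that("a DNA-free spectrum yields absent markers, not errors", {
  m <- pipeline_markers("albumin", "dried")
  expect_null(m$cc); expect_null(m$co)
  expect_null(m$po2_sym); expect_null(m$po2_asym)
  expect_equal(classify_conformation(m), "indeterminate")
  expect_error(phosphate_ratio(m), "po2_asym|asym")
})

test_that("phosphate_ratio is 1 for bands built with equal |d2| minima", {
  # same amplitude and width => identical curvature at both centers
  p <- component_preset("sym_pair", list(band_component(1089, 20, 1),
                                         band_component(1235, 20, 1)))
  m <- pipeline_markers(p, "dried")
  r <- phosphate_ratio(m)
  expect_equal(r$ratio, 1, tolerance = 1e-6)
  expect_equal(r$sym_position_used, 1089)
  expect_equal(r$asym_position_used, 1235)
})

test_that("temperature-excess degradation of the sym band raises the ratio", {
  s <- generate_component("dsDNA_A", 1, fp_1800())
  r0 <- phosphate_ratio(extract_markers(fingerprint_d2(s), "dried"))
  hot <- degrade(s, degradation_spec(0.8, affected_bands = 1089,
                                     amplitude_drift = -0.4, center_drift = 0))
  r1 <- phosphate_ratio(extract_markers(fingerprint_d2(hot), "dried"))
  expect_gt(r1$ratio, r0$ratio)
})

test_that("classify_conformation votes by nearest endpoint with majority rule", {
  mk <- function(cc = NULL, co = NULL, asym = NULL) {
    m <- list(state_assumed = "dried")
    if (!is.null(cc)) m$cc <- list(position = cc, intensity = 1, prominence = 1)
    if (!is.null(co)) m$co <- list(position = co, intensity = 1, prominence = 1)
    if (!is.null(asym)) m$po2_asym <- list(position = asym, intensity = 1,
                                           prominence = 1)
    structure(m, class = "marker_set")
  }
  expect_equal(classify_conformation(mk(965, 1050, 1235)), "A_like")
  expect_equal(classify_conformation(mk(970, 1052, 1225)), "B")
  expect_equal(classify_conformation(mk(965)), "indeterminate")
  expect_equal(classify_conformation(mk(965, 1052)), "indeterminate") # tie
  expect_equal(classify_conformation(mk(965, 1050, 1229)), "A_like")  # gap abstains
})

test_that("full pipeline calls B when hydrated and A_like when dried", {
  expect_equal(classify_conformation(
    pipeline_markers(formulation_spec(c(dsDNA_A = 1), hydration = 1))), "B")
  expect_equal(classify_conformation(
    pipeline_markers(formulation_spec(c(dsDNA_A = 1), hydration = 0))), "A_like")
})

test_that("classification survives the full matrix and 10% noise (fixed seeds)", {
  # min DNA band amplitude is 0.55 (C-C backbone); 10% of that as noise sd
  for (seed in 1:5) {
    spec <- formulation_spec(c(dsDNA_A = 1, trehalose_dry = 0.5, albumin = 0.3),
                             hydration = 0, noise_sd = 0.055, seed = seed)
    m <- pipeline_markers(spec, "dried")
    expect_equal(classify_conformation(m), "A_like",
                 label = paste("seed", seed))
  }
  for (seed in 1:5) {
    spec <- formulation_spec(c(dsDNA_A = 1, trehalose_dry = 0.5, albumin = 0.3,
                               water_OH = 0.4),
                             hydration = 1, noise_sd = 0.055, seed = 10 + seed)
    m <- pipeline_markers(spec, "hydrated")
    expect_equal(classify_conformation(m), "B", label = paste("seed", seed))
  }
})

test_that("marker shifts are reversible upon rehydration", {
  dried <- pipeline_markers(formulation_spec(c(dsDNA_A = 1), hydration = 0))
  rehydrated <- pipeline_markers(formulation_spec(c(dsDNA_A = 1), hydration = 1),
                                 "hydrated")
  fresh <- pipeline_markers(formulation_spec(c(dsDNA_B = 1), hydration = 1),
                            "hydrated")
  for (nm in c("cc", "co", "po2_sym", "po2_asym"))
    expect_equal(rehydrated[[nm]]$position, fresh[[nm]]$position, label = nm)
  expect_false(dried$po2_asym$position == fresh$po2_asym$position)
})

test_that("markers_as_row flattens to one CSV-ready row", {
  row <- markers_as_row(pipeline_markers("dsDNA_A"))
  expect_equal(nrow(row), 1L)
  expect_equal(row$po2_asym_position, 1235)
  expect_equal(row$conformation, "A_like")
  expect_gt(row$phosphate_ratio, 0)
})
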