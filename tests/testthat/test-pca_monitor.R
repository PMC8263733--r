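test_that("build_matrix normalizes rows on a common grid", {
  s <- generate_component("dsDNA_A", 1, fp_1800())
  m <- build_matrix(list(s, s, s))
  expect_equal(nrow(m$x), 3L)
  expect_equal(sqrt(rowSums(m$x^2)), rep(1, 3), tolerance = 1e-12)
  expect_identical(m$x[1, ], m$x[2, ])
  # rows differing only by scale normalize to identical rows
  s2 <- ir_spectrum(s$wavenumbers, 5 * s$absorbance)
  m2 <- build_matrix(list(s, s2, s))
  expect_equal(m2$x[1, ], m2$x[2, ], tolerance = 1e-12)
  expect_error(build_matrix(list(s, s)), "at least 3")
  narrow <- generate_component("dsDNA_A", 1, spectral_region(1000, 1200))
  expect_error(build_matrix(list(s, s, narrow)), "cover")
})

test_that("fit_pca matches the SVD oracle and reconstructs exactly", {
  spectra <- matrix_replicates(8, seed0 = 500, severity = 0, noise_sd = 0.004)
  m <- build_matrix(spectra)
  model <- fit_pca(m)                     # all PCs (rank = 7)
  xc <- sweep(m$x, 2, colMeans(m$x))
  sv <- svd(xc)
  evf_oracle <- sv$d^2 / sum(sv$d^2)
  k <- ncol(model$scores)
  expect_equal(model$explained_variance_fraction, evf_oracle[seq_len(k)],
               tolerance = 1e-9)
  for (j in seq_len(k)) {
    oracle_scores <- sv$u[, j] * sv$d[j]
    expect_equal(min(sum((model$scores[, j] - oracle_scores)^2),
                     sum((model$scores[, j] + oracle_scores)^2)),
                 0, tolerance = 1e-12, label = paste("PC", j))
  }
  # loadings orthonormal; fractions non-increasing and summing to <= 1
  expect_equal(crossprod(model$loadings), diag(k), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(model$explained_variance_fraction) <= 1e-12))
  expect_lte(sum(model$explained_variance_fraction), 1 + 1e-9)
  # full-rank reconstruction of the centered matrix
  expect_equal(model$scores %*% t(model$loadings), xc, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sum(model$explained_variance_fraction), 1, tolerance = 1e-9)
})

test_that("data on a line give PC1 explained fraction 1", {
  base <- generate_component("dsDNA_A", 1, fp_1800())$absorbance
  dir <- generate_component("albumin", 1, fp_1800())$absorbance
  wn <- generate_component("dsDNA_A", 1, fp_1800())$wavenumbers
  spectra <- lapply(c(0, 1, 2, 3.5), function(t)
    ir_spectrum(wn, base + t * 1e-4 * dir))
  # build the matrix without per-row normalization (normalization would bend
  # the line), mimicking build_matrix's container directly
  x <- do.call(rbind, lapply(spectra, function(s)
    extract_region(s, fingerprint_region())$absorbance))
  m <- structure(list(x = x, wavenumbers = wn[wn <= 1500], row_labels = NULL),
                 class = "spectra_matrix")
  model <- fit_pca(m, 1)
  expect_equal(model$explained_variance_fraction[1], 1, tolerance = 1e-9)
})

test_that("fit_pca is deterministic in sign and stable under row permutation", {
  spectra <- matrix_replicates(6, seed0 = 600, noise_sd = 0.004)
  m1 <- build_matrix(spectra)
  m2 <- build_matrix(spectra[c(4, 2, 6, 1, 5, 3)])
  p1 <- fit_pca(m1, 3); p2 <- fit_pca(m2, 3)
  for (j in 1:3) {
    i <- which.max(abs(p1$loadings[, j]))
    expect_gt(p1$loadings[i, j], 0)
    # same loadings (sign fixed) regardless of row order
    expect_equal(p2$loadings[, j], p1$loadings[, j], tolerance = 1e-8)
  }
  expect_equal(p2$scores[4, ], p1$scores[1, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(fit_pca(m1, 10), "n_components")
})

test_that("drift_report separates degraded spectra but not noise-only replicates", {
  baseline <- matrix_replicates(5, seed0 = 700, severity = 0)
  degraded <- matrix_replicates(5, seed0 = 710, severity = 0.8)
  model <- fit_pca(build_matrix(c(baseline, degraded)), 3)
  rep <- drift_report(model, 1:5, 6:10)
  expect_false(attr(rep, "clustered"))
  expect_gt(max(rep$standardized_distance), 1)

  # identical group: zero distance, clustered
  same <- drift_report(model, 1:5, 1:5)
  expect_equal(same$standardized_distance, rep(0, 3))
  expect_true(attr(same, "clustered"))

  # severity-0 degradation is the identity, so baseline replicates and
  # their degrade(0) images have identical distribution: clustered
  noise_a <- matrix_replicates(6, seed0 = 720, severity = 0)
  noise_b <- lapply(noise_a, degrade, d = degradation_spec(0))
  m0 <- fit_pca(build_matrix(c(noise_a, noise_b)), 3)
  rep0 <- drift_report(m0, 1:6, 7:12)
  expect_equal(rep0$standardized_distance, rep(0, 3))
  expect_true(attr(rep0, "clustered"))

  expect_error(drift_report(model, integer(0), 6:10), "empty")
})

test_that("write_pca_csv emits the three tables", {
  model <- fit_pca(build_matrix(matrix_replicates(4, seed0 = 800,
                                                  noise_sd = 0.004)), 2)
  stem <- file.path(withr::local_tempdir(), "pca")
  paths <- write_pca_csv(model, stem)
  expect_true(all(file.exists(paste0(stem, c("_scores.csv", "_loadings.csv",
                                             "_variance.csv")))))
  v <- read.csv(paste0(stem, "_variance.csv"))
  expect_equal(v$explained_variance_fraction,
               model$explained_variance_fraction, tolerance = 1e-12)
})
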