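# shared fixture builders; everything is generated in code at test time

fp_1800 <- function() spectral_region(900, 1800)

# full preprocessing pipeline on a preset or formulation spec
pipeline_markers <- function(x, state = "dried", region = fp_1800(), ...) {
  s <- if (inherits(x, "formulation_spec")) generate_formulation(x, 1, region)
       else generate_component(x, 1, region)
  extract_markers(fingerprint_d2(s), state, ...)
}

# independent Savitzky-Golay oracle: per-point polynomial fit via lm()
sg_d2_oracle <- function(y, h, window_points, poly_order) {
  k <- (window_points - 1L) %/% 2L
  n <- length(y)
  out <- rep(NA_real_, n)
  x <- seq(-k, k) * h
  for (i in (k + 1L):(n - k)) {
    fit <- stats::lm(y[(i - k):(i + k)] ~ poly(x, poly_order, raw = TRUE))
    out[i] <- 2 * stats::coef(fit)[[3]]
  }
  out
}

# brute-force 80%-height position on a dense grid
voh_oracle <- function(f, lo = 3000, hi = 3700, step = 0.01,
                       height_fraction = 0.8) {
  nu <- seq(lo, hi, by = step)
  a <- f(nu)
  amax <- max(a)
  level <- height_fraction * amax
  imax <- which.max(a)
  left <- nu[min(which(a[seq_len(imax)] >= level))]
  right <- nu[imax - 1L + max(which(a[seq(imax, length(a))] >= level))]
  (left + right) / 2
}

# seeded noisy matrix-formulation replicates for PCA tests
matrix_replicates <- function(n, seed0, severity = 0, noise_sd = 0.002) {
  lapply(seq_len(n), function(i) {
    s <- generate_formulation(
      formulation_spec(c(dsDNA_A = 1, trehalose_dry = 0.5, albumin = 0.3),
                       hydration = 0, noise_sd = noise_sd, seed = seed0 + i),
      1, fp_1800())
    if (severity > 0)
      s <- degrade(s, degradation_spec(severity, amplitude_drift = -0.3,
                                       center_drift = 2))
    s
  })
}
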