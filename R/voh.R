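#' OH-stretch band position by the 80 percent peak-height rule
#'
#' In the 3000-3700 cm\eqn{^{-1}} region the broad OH-stretching band is
#' located by finding its maximum absorbance A*, then the outermost
#' wavenumbers on each flank where the absorbance crosses 0.8 A* (linear
#' interpolation between the bracketing grid points); the band position is
#' the mean of the two crossings. "Full peak height" is measured from zero
#' absorbance: inputs are assumed baseline-corrected; set
#' `subtract_baseline = TRUE` to remove a straight line through the region
#' endpoints first for real-instrument data.
#'
#' @param s an [ir_spectrum()] covering the OH region
#' @param region search region, default [oh_region()] (3000-3700)
#' @param height_fraction crossing level as a fraction of peak height
#'   (default 0.8)
#' @param subtract_baseline subtract a linear baseline through the region
#'   endpoints before analysis (default FALSE)
#' @return the band position, cm\eqn{^{-1}}
#' @export
voh_position <- function(s, region = oh_region(), height_fraction = 0.8,
                         subtract_baseline = FALSE) {
  stopifnot(is_ir_spectrum(s), height_fraction > 0, height_fraction < 1)
  s <- extract_region(s, region)
  wn <- s$wavenumbers
  a <- s$absorbance
  if (subtract_baseline) {
    base <- a[1] + (a[length(a)] - a[1]) * (wn - wn[1]) / (wn[length(wn)] - wn[1])
    a <- a - base
  }
  imax <- which.max(a)
  amax <- a[imax]
  if (amax <= 0) stop("no positive peak in the OH region")
  level <- height_fraction * amax

  cross_at <- function(i) {
    # linear interpolation of the crossing between grid points i and i+1
    wn[i] + (level - a[i]) * (wn[i + 1] - wn[i]) / (a[i + 1] - a[i])
  }
  # outermost crossing on the low-wavenumber flank: first upward crossing
  below <- which(a[seq_len(imax)] < level)
  if (!length(below) || a[1] >= level)
    stop("band clipped: left flank does not fall below ", height_fraction,
         " of peak height inside the region")
  il <- below[1]                      # a[il] < level; find the next upcross
  while (il < imax && !(a[il] < level && a[il + 1] >= level)) il <- il + 1L
  left <- cross_at(il)
  # outermost crossing on the high-wavenumber flank: last downward crossing
  n <- length(a)
  above_right <- which(a[seq(imax, n)] < level)
  if (!length(above_right) || a[n] >= level)
    stop("band clipped: right flank does not fall below ", height_fraction,
         " of peak height inside the region")
  ir <- n
  while (ir > imax && !(a[ir] < level && a[ir - 1] >= level)) ir <- ir - 1L
  right <- cross_at(ir - 1L)
  (left + right) / 2
}

#' Temperature series of OH-stretch positions
#'
#' @param temperatures degC, strictly increasing, length >= 2
#' @param positions matching OH-stretch band positions, cm\eqn{^{-1}},
#'   within 3000-3700
#' @param sample_label text label
#' @return an object of class `voh_series`
#' @export
voh_series <- function(temperatures, positions, sample_label = "") {
  stopifnot(is.numeric(temperatures), is.numeric(positions),
            length(temperatures) == length(positions),
            length(temperatures) >= 2L)
  if (any(diff(temperatures) <= 0))
    stop("temperatures must be strictly increasing")
  if (any(positions < 3000 | positions > 3700))
    stop("positions must lie within 3000-3700 cm-1")
  structure(list(temperatures = as.numeric(temperatures),
                 positions = as.numeric(positions),
                 sample_label = sample_label),
            class = "voh_series")
}

#' Measure an OH-position temperature series from spectra
#'
#' Convenience wrapper: applies [voh_position()] to each spectrum of a
#' temperature series.
#'
#' @param spectra list of [ir_spectrum()]s
#' @param temperatures matching degC values
#' @param sample_label text label
#' @param ... passed to [voh_position()]
#' @return a [voh_series()]
#' @export
measure_voh_series <- function(spectra, temperatures, sample_label = "", ...) {
  stopifnot(length(spectra) == length(temperatures))
  ord <- order(temperatures)
  pos <- vapply(spectra[ord], voh_position, numeric(1), ...)
  voh_series(temperatures[ord], pos, sample_label)
}

#' Fit the wavenumber temperature coefficient (WTC)
#'
#' Ordinary least-squares line of OH-stretch position on temperature,
#' restricted to `fit_range` (endpoints inclusive; out-of-range points are
#' silently excluded but counted). The slope is the WTC in cm\eqn{^{-1}}
#' per degC: large for liquids, small for glassy (vitrified) matrices.
#'
#' @param series a [voh_series()]
#' @param fit_range `c(lo, hi)` degC, default `c(25, 50)`
#' @return an object of class `wtc_result`: `wtc`, `intercept`,
#'   `fit_range`, `n_points`, `n_excluded`, `residual_rms`, `sample_label`
#' @export
fit_wtc <- function(series, fit_range = c(25, 50)) {
  stopifnot(inherits(series, "voh_series"),
            is.numeric(fit_range), length(fit_range) == 2L,
            fit_range[1] < fit_range[2])
  inr <- series$temperatures >= fit_range[1] & series$temperatures <= fit_range[2]
  if (sum(inr) < 3L)
    stop(sprintf("fit_wtc needs >= 3 points inside %g-%g degC, found %d",
                 fit_range[1], fit_range[2], sum(inr)))
  t <- series$temperatures[inr]
  p <- series$positions[inr]
  fit <- stats::lm(p ~ t)
  structure(list(wtc = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 fit_range = fit_range,
                 n_points = sum(inr),
                 n_excluded = sum(!inr),
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 sample_label = series$sample_label),
            class = "wtc_result")
}

#' @export
print.wtc_result <- function(x, ...) {
  cat(sprintf("<wtc_result> %s: WTC = %.4f cm-1/degC (intercept %.2f, n = %d, rms %.3g)\n",
              if (nzchar(x$sample_label)) x$sample_label else "(unlabelled)",
              x$wtc, x$intercept, x$n_points, x$residual_rms))
  invisible(x)
}

#' Compare two WTC fits
#'
#' Reports which sample has the larger WTC and the difference `a - b`;
#' no significance claim is made. Liquid matrices are expected to show the
#' larger WTC; glass formation reduces the thermal expansion of hydrogen
#' bonding.
#'
#' @param a,b `wtc_result` objects
#' @return list with `difference` (`a$wtc - b$wtc`), `larger`
#'   (`"a"`, `"b"`, or `"equal"`), and the two labelled WTC values
#' @export
compare_wtc <- function(a, b) {
  stopifnot(inherits(a, "wtc_result"), inherits(b, "wtc_result"))
  d <- a$wtc - b$wtc
  list(difference = d,
       larger = if (d > 0) "a" else if (d < 0) "b" else "equal",
       wtc_a = stats::setNames(a$wtc, a$sample_label),
       wtc_b = stats::setNames(b$wtc, b$sample_label))
}
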