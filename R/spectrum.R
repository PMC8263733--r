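#' Construct an FTIR spectrum
#'
#' The basic currency of the package: a wavenumber grid (cm\eqn{^{-1}}),
#' matching absorbance values, and free-form metadata. Wavenumbers are
#' stored strictly ascending regardless of input order; instruments commonly
#' emit descending grids and one canonical order removes sign ambiguities in
#' all derivative and peak code downstream.
#'
#' @param wavenumbers numeric vector of wavenumbers in cm\eqn{^{-1}};
#'   any order, but no duplicates. Length >= 2.
#' @param absorbance numeric vector of unitless absorbance values, same
#'   length as `wavenumbers`, all finite.
#' @param meta named list of free-form metadata (sample id, temperature,
#'   formulation label, hydration state, ...).
#' @return An object of class `ir_spectrum` with fields `wavenumbers`
#'   (strictly ascending), `absorbance`, and `meta`.
#' @examples
#' s <- ir_spectrum(c(1000, 999), c(0.5, 0.6))
#' s$wavenumbers  # 999 1000
#' @export
ir_spectrum <- function(wavenumbers, absorbance, meta = list()) {
  if (!is.numeric(wavenumbers) || !is.numeric(absorbance))
    stop("wavenumbers and absorbance must be numeric")
  if (length(wavenumbers) != length(absorbance))
    stop("wavenumbers and absorbance must have the same length")
  if (length(wavenumbers) < 2L)
    stop("a spectrum needs at least 2 points")
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers)))
    stop("wavenumbers must be finite")
  if (anyNA(absorbance) || any(!is.finite(absorbance)))
    stop("absorbance values must be finite (no NA/Inf)")
  if (anyDuplicated(wavenumbers))
    stop("duplicate wavenumber values are not allowed")
  ord <- order(wavenumbers)
  structure(
    list(wavenumbers = as.numeric(wavenumbers[ord]),
         absorbance  = as.numeric(absorbance[ord]),
         meta        = as.list(meta)),
    class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %d points, %.6g-%.6g cm-1\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  if (length(x$meta)) {
    flat <- vapply(x$meta, function(v) paste(format(v), collapse = ","),
                   character(1))
    cat("  meta:", paste(names(flat), flat, sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
length.ir_spectrum <- function(x) length(x$wavenumbers)

is_ir_spectrum <- function(x) inherits(x, "ir_spectrum")

#' Spectral region
#'
#' A closed wavenumber interval `[lo, hi]`.
#'
#' @param lo,hi region bounds in cm\eqn{^{-1}}, `lo < hi`.
#' @return An object of class `spectral_region`.
#' @seealso [fingerprint_region()], [oh_region()]
#' @export
spectral_region <- function(lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1L ||
      length(hi) != 1L || !is.finite(lo) || !is.finite(hi))
    stop("lo and hi must be single finite numbers")
  if (lo >= hi) stop("spectral_region requires lo < hi")
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi)),
            class = "spectral_region")
}

#' @export
print.spectral_region <- function(x, ...) {
  cat(sprintf("<spectral_region> %g-%g cm-1\n", x$lo, x$hi))
  invisible(x)
}

#' Canonical fingerprint region, 900-1500 cm-1
#'
#' The region rich in nucleic-acid and carbohydrate bands, used for
#' second-derivative marker analysis and for PCA.
#' @return a [spectral_region()]
#' @export
fingerprint_region <- function() spectral_region(900, 1500)

#' Canonical OH-stretch region, 3000-3700 cm-1
#'
#' The region holding the broad OH-stretching band of water/sugar matrices.
#' @return a [spectral_region()]
#' @export
oh_region <- function() spectral_region(3000, 3700)

as_region <- function(region) {
  if (inherits(region, "spectral_region")) return(region)
  if (is.numeric(region) && length(region) == 2L)
    return(spectral_region(region[1], region[2]))
  stop("region must be a spectral_region or a numeric (lo, hi) pair")
}

#' Extract a sub-spectrum by region
#'
#' Keeps every point with `lo <= wavenumber <= hi`; retained (wavenumber,
#' absorbance) pairs are never altered. Metadata is preserved.
#'
#' @param s an [ir_spectrum()]
#' @param region a [spectral_region()] (or numeric `c(lo, hi)`)
#' @return the restricted `ir_spectrum`
#' @export
extract_region <- function(s, region) {
  stopifnot(is_ir_spectrum(s))
  region <- as_region(region)
  keep <- s$wavenumbers >= region$lo & s$wavenumbers <= region$hi
  if (sum(keep) < 2L)
    stop(sprintf("region %g-%g cm-1 has no (or <2 points) overlap with spectrum support %g-%g cm-1",
                 region$lo, region$hi, min(s$wavenumbers), max(s$wavenumbers)))
  ir_spectrum(s$wavenumbers[keep], s$absorbance[keep], s$meta)
}

#' Resample a spectrum onto a uniform grid
#'
#' Linear interpolation onto a uniform grid `seq(region$lo, region$hi,
#' by = grid_step)`; both endpoints included. The region must lie within
#' the spectrum's support -- no extrapolation is ever performed. The
#' canonical analysis grid is 1 cm\eqn{^{-1}} (the instrument resolution
#' the generator emulates is 4 cm\eqn{^{-1}}; interpolation to 1
#' cm\eqn{^{-1}} makes nearest-cm\eqn{^{-1}} position reporting
#' well-defined).
#'
#' @param s an [ir_spectrum()]
#' @param grid_step grid spacing in cm\eqn{^{-1}} (default 1)
#' @param region target [spectral_region()]; default the full support
#' @return an `ir_spectrum` on the uniform grid; `meta$grid_step` records
#'   the step.
#' @export
resample <- function(s, grid_step = 1, region = NULL) {
  stopifnot(is_ir_spectrum(s), is.numeric(grid_step), grid_step > 0)
  if (is.null(region))
    region <- spectral_region(min(s$wavenumbers), max(s$wavenumbers))
  region <- as_region(region)
  if (region$lo < min(s$wavenumbers) || region$hi > max(s$wavenumbers))
    stop(sprintf("region %g-%g cm-1 outside spectrum support %g-%g cm-1 (no extrapolation)",
                 region$lo, region$hi, min(s$wavenumbers), max(s$wavenumbers)))
  grid <- seq(region$lo, region$hi, by = grid_step)
  if (abs(grid[length(grid)] - region$hi) > 1e-9)
    grid <- c(grid, region$hi)
  a <- stats::approx(s$wavenumbers, s$absorbance, xout = grid,
                     method = "linear", ties = "ordered")$y
  meta <- s$meta
  meta$grid_step <- grid_step
  ir_spectrum(grid, a, meta)
}

# uniform-grid check shared by derivative and generator code
grid_step_of <- function(s, tol = 1e-6) {
  d <- diff(s$wavenumbers)
  h <- d[1]
  if (any(abs(d - h) > tol * max(h, 1)))
    return(NA_real_)
  h
}
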