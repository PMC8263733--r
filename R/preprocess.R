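#' Vector-normalize a spectrum over a region
#'
#' Restricts the spectrum to `region` and divides the absorbance by its
#' Euclidean norm over that region, so the output has unit L2 norm. This is
#' the normalization applied to fingerprint spectra before both the
#' second-derivative marker analysis and PCA.
#'
#' @param s an [ir_spectrum()]
#' @param region a [spectral_region()]; default the fingerprint region
#' @return the normalized, region-restricted `ir_spectrum`;
#'   `meta$normalized = TRUE`
#' @export
vector_normalize <- function(s, region = fingerprint_region()) {
  stopifnot(is_ir_spectrum(s))
  s <- extract_region(s, region)
  nrm <- sqrt(sum(s$absorbance^2))
  if (nrm == 0) stop("cannot vector-normalize: absorbance is identically zero on the region")
  meta <- s$meta
  meta$normalized <- TRUE
  ir_spectrum(s$wavenumbers, s$absorbance / nrm, meta)
}

# Savitzky-Golay convolution weights for the d-th derivative:
# least-squares fit of a degree-p polynomial over offsets -k..k, evaluated
# at the window center. Returns the weight vector (length 2k+1) such that
# sum(w * y[window]) estimates d!/1 * c_d, i.e. the d-th derivative for
# unit spacing.
sg_coefficients <- function(window_points, poly_order, derivative = 2L) {
  k <- (window_points - 1L) %/% 2L
  x <- seq(-k, k)
  J <- outer(x, 0:poly_order, `^`)
  # pseudo-inverse row for the derivative-order coefficient
  A <- solve(crossprod(J), t(J))
  factorial(derivative) * A[derivative + 1L, ]
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' Fits a moving polynomial of order `poly_order` over `window_points`
#' points and returns its second derivative, scaled by the squared grid
#' step so units are absorbance per cm\eqn{^2} and band-intensity ratios do
#' not depend on the grid step. The default 21-point window matches the
#' standard chemometric smoothing factor for resolving overlapping
#' fingerprint bands. The half-window at each edge cannot be estimated
#' without padding (which would fabricate curvature), so those points are
#' returned as `NA` and excluded from downstream peak searches.
#'
#' @param s an [ir_spectrum()] on a uniform grid (use [resample()] first)
#' @param window_points odd integer >= `poly_order + 2` (default 21)
#' @param poly_order polynomial order (default 3; orders 2 and 3 give
#'   identical second derivatives on symmetric bands, 3 tracks asymmetric
#'   band shapes better)
#' @return an object of class `derivative_spectrum` with fields
#'   `wavenumbers`, `d2` (NA in the edge half-windows), and `provenance`
#'   (`window_points`, `poly_order`, `grid_step`, `normalized`).
#' @export
second_derivative <- function(s, window_points = 21L, poly_order = 3L) {
  stopifnot(is_ir_spectrum(s))
  window_points <- as.integer(window_points)
  poly_order <- as.integer(poly_order)
  if (window_points %% 2L == 0L || window_points < poly_order + 2L)
    stop("window_points must be odd and >= poly_order + 2")
  h <- grid_step_of(s)
  if (is.na(h))
    stop("second_derivative requires a uniform grid; resample() first")
  n <- length(s$wavenumbers)
  if (n < window_points)
    stop(sprintf("spectrum has %d points but the window needs %d", n, window_points))
  w <- sg_coefficients(window_points, poly_order, 2L)
  k <- (window_points - 1L) %/% 2L
  d2 <- rep(NA_real_, n)
  # convolution via filter(); sides = 2 centres the window
  d2[(k + 1L):(n - k)] <- stats::filter(s$absorbance, rev(w),
                                        sides = 2)[(k + 1L):(n - k)]
  d2 <- d2 / h^2
  structure(list(wavenumbers = s$wavenumbers, d2 = d2,
                 provenance = list(window_points = window_points,
                                   poly_order = poly_order,
                                   grid_step = h,
                                   normalized = isTRUE(s$meta$normalized)),
                 meta = s$meta),
            class = "derivative_spectrum")
}

#' @export
print.derivative_spectrum <- function(x, ...) {
  cat(sprintf("<derivative_spectrum> %d points, %g-%g cm-1 (SG %d/%d, %d valid)\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
              x$provenance$window_points, x$provenance$poly_order,
              sum(!is.na(x$d2))))
  invisible(x)
}

#' Standard fingerprint preprocessing
#'
#' The canonical pipeline applied before marker extraction: resample to a
#' uniform grid over the fingerprint region, vector-normalize, and take the
#' Savitzky-Golay second derivative. When `normalize_after = TRUE` the
#' alternative path (differentiate first, then scale the derivative to unit
#' norm) is used instead.
#'
#' @param s an [ir_spectrum()]
#' @param region analysis region (default fingerprint, 900-1500)
#' @param grid_step uniform grid step (default 1 cm\eqn{^{-1}})
#' @param window_points,poly_order Savitzky-Golay parameters
#' @param normalize_after normalize the derivative instead of the
#'   absorbance (default FALSE)
#' @return a `derivative_spectrum`
#' @export
fingerprint_d2 <- function(s, region = fingerprint_region(), grid_step = 1,
                           window_points = 21L, poly_order = 3L,
                           normalize_after = FALSE) {
  s <- resample(s, grid_step, region)
  if (!normalize_after) {
    d <- second_derivative(vector_normalize(s, region), window_points, poly_order)
  } else {
    d <- second_derivative(s, window_points, poly_order)
    nrm <- sqrt(sum(d$d2[!is.na(d$d2)]^2))
    if (nrm == 0) stop("cannot normalize an identically-zero derivative")
    d$d2 <- d$d2 / nrm
    d$provenance$normalized <- TRUE
  }
  d
}

#' Write a derivative spectrum as CSV
#'
#' Columns `wavenumber,d2`; edge-invalid points carry `NA`.
#' @param d a `derivative_spectrum`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_derivative_csv <- function(d, path) {
  stopifnot(inherits(d, "derivative_spectrum"))
  utils::write.csv(data.frame(wavenumber = d$wavenumbers, d2 = d$d2),
                   path, row.names = FALSE)
  invisible(path)
}
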