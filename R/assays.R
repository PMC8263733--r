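#' Gravimetric water content
#'
#' Water content of a dried specimen, in g water per g dry weight:
#' the weight lost on overnight baking (80 degC) divided by the dry weight,
#' both after subtracting the slide weight:
#' \deqn{(w_{dry} - w_{bake}) / (w_{bake} - w_{slide})}
#'
#' @param weight_after_drying slide + sample weight after drying, g
#' @param weight_after_bake slide + sample weight after overnight bake, g
#' @param slide_weight bare slide weight, g (default 0)
#' @return water content, g/g
#' @export
water_content <- function(weight_after_drying, weight_after_bake,
                          slide_weight = 0) {
  if (weight_after_bake <= slide_weight)
    stop("weight_after_bake must exceed slide_weight (no dry mass left?)")
  if (weight_after_drying < weight_after_bake)
    stop("weight_after_drying must be >= weight_after_bake (evaporation cannot add mass)")
  (weight_after_drying - weight_after_bake) / (weight_after_bake - slide_weight)
}

#' Drying curve container
#'
#' @param times minutes, strictly increasing, length >= 3
#' @param weights slide + sample weights, g, all above `slide_weight`
#' @param slide_weight bare slide weight, g
#' @return an object of class `drying_curve`
#' @export
drying_curve <- function(times, weights, slide_weight = 0) {
  stopifnot(is.numeric(times), is.numeric(weights),
            length(times) == length(weights), length(times) >= 3L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(weights <= slide_weight)) stop("weights must all exceed slide_weight")
  structure(list(times = as.numeric(times), weights = as.numeric(weights),
                 slide_weight = slide_weight),
            class = "drying_curve")
}

#' Drying endpoint from a weight-versus-time curve
#'
#' The stable ("dry") state is declared at the earliest time t such that
#' over the window of `window` consecutive readings starting at t, the
#' sample weight (slide subtracted) changes relatively by less than
#' `rel_tol` (default 0.5 percent over 3 readings). When no window
#' qualifies, `NA` is returned ("not reached") rather than an error.
#'
#' @param curve a [drying_curve()]
#' @param rel_tol relative stability tolerance (default 0.005)
#' @param window number of consecutive readings that must be stable
#'   (default 3)
#' @return endpoint time in minutes, or `NA` when never stable
#' @export
drying_endpoint <- function(curve, rel_tol = 0.005, window = 3L) {
  stopifnot(inherits(curve, "drying_curve"), rel_tol > 0, window >= 2L)
  w <- curve$weights - curve$slide_weight
  n <- length(w)
  for (i in seq_len(n - window + 1L)) {
    seg <- w[i:(i + window - 1L)]
    if (max(abs(seg - seg[1])) / seg[1] < rel_tol)
      return(curve$times[i])
  }
  NA_real_
}

#' Convert percent weight/volume to molarity
#'
#' `percent_wv` g per 100 mL at molar mass `molar_mass` g/mol equals
#' `10 * percent_wv / molar_mass` mol/L, reported in mM at full precision
#' (round only at the presentation layer). 1.71 percent w/v trehalose or
#' sucrose (342.30 g/mol) is 50 mM to the nearest mM; 1.71 percent glucose
#' is 95 (about 100) mM.
#'
#' @param percent_wv concentration in g per 100 mL, >= 0
#' @param molar_mass g/mol, > 0
#' @return concentration in mM
#' @export
percent_wv_to_molar <- function(percent_wv, molar_mass) {
  if (!is.numeric(molar_mass) || molar_mass <= 0)
    stop("molar_mass must be > 0")
  if (percent_wv < 0) stop("percent_wv must be >= 0")
  # g/100mL -> 10*p g/L -> 10*p/M mol/L -> *1000 mM
  10000 * percent_wv / molar_mass
}

#' 8-bit greyscale image container
#'
#' @param pixels integer/numeric matrix with values in 0-255
#' @param calibration optional function mapping grey values to optical
#'   units (identity by default)
#' @return an object of class `grey_image`
#' @export
grey_image <- function(pixels, calibration = NULL) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || anyNA(pixels) ||
      any(pixels < 0 | pixels > 255))
    stop("pixels must be numeric in [0, 255]")
  structure(list(pixels = pixels, calibration = calibration),
            class = "grey_image")
}

#' Read an ASCII PGM (P2) greyscale image
#'
#' The plain-text portable greymap format; maximum grey value must be 255
#' (8-bit). Binary P5 and other image formats are not supported -- convert
#' externally (RGB inputs should be converted with the Rec. 601 luma
#' weights 0.299/0.587/0.114 before analysis).
#'
#' @param path file path
#' @return a [grey_image()]
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  tok <- unlist(strsplit(trimws(lines), "[[:space:]]+"))
  tok <- tok[nzchar(tok)]
  if (length(tok) < 4L || tok[1] != "P2")
    stop("not an ASCII PGM (P2) file: ", path)
  dims <- suppressWarnings(as.integer(tok[2:4]))
  if (anyNA(dims)) stop("bad PGM header in ", path)
  w <- dims[1]; h <- dims[2]; maxval <- dims[3]
  if (maxval != 255) stop("only 8-bit PGM (maxval 255) is supported")
  px <- suppressWarnings(as.numeric(tok[-(1:4)]))
  if (anyNA(px) || length(px) != w * h)
    stop(sprintf("PGM data error in %s: expected %d pixels, got %d",
                 path, w * h, sum(!is.na(px))))
  grey_image(matrix(px, nrow = h, ncol = w, byrow = TRUE))
}

#' Formazan index from a greyscale micrograph
#'
#' Darker (lower grey) means more blue/purple formazan precipitate, i.e.
#' more ROS accumulation. The index makes the inversion explicit:
#' `max(0, background_grey - mean(grey))`, so the index grows with
#' coloration intensity. The mean is taken over all pixels or over an
#' optional logical mask.
#'
#' @param img a [grey_image()]
#' @param background_grey grey value of the unstained background, 0-255
#' @param mask optional logical matrix of the same dimensions selecting
#'   the pixels to average
#' @return formazan index, unitless 0-255
#' @export
formazan_grey <- function(img, background_grey, mask = NULL) {
  stopifnot(inherits(img, "grey_image"),
            is.numeric(background_grey), length(background_grey) == 1L,
            background_grey >= 0, background_grey <= 255)
  px <- img$pixels
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dim(px)))
      stop("mask must be a logical matrix matching the image dimensions")
    if (!any(mask)) stop("empty mask")
    px <- px[mask]
  }
  max(0, background_grey - mean(px))
}

#' Blank-subtracted absorbance
#'
#' Helper for single-beam spectrophotometric readouts (e.g. A530 of
#' DMSO-extracted formazan): sample absorbance minus blank.
#' @param a_sample,a_blank absorbance readings
#' @return `a_sample - a_blank`
#' @export
absorbance_blanked <- function(a_sample, a_blank) a_sample - a_blank

#' Simulate an exponential drying curve
#'
#' Weight model: `slide + w_dry + w_water0 * exp(-t / tau)` plus optional
#' iid Gaussian weighing noise, reproducible from the seed.
#'
#' @param tau drying time constant, min
#' @param w_dry dry sample weight, g
#' @param w_water0 initial water weight, g
#' @param slide slide weight, g
#' @param step sampling interval, min
#' @param n number of readings
#' @param noise_sd weighing noise sd, g (default 0)
#' @param seed integer, required when `noise_sd > 0`
#' @return a [drying_curve()]
#' @export
simulate_drying_curve <- function(tau, w_dry, w_water0, slide = 0,
                                  step = 2, n = 30, noise_sd = 0,
                                  seed = NULL) {
  stopifnot(tau > 0, w_dry > 0, w_water0 >= 0, step > 0, n >= 3,
            noise_sd >= 0)
  if (noise_sd > 0 && is.null(seed))
    stop("seed is required when noise_sd > 0")
  times <- step * (seq_len(n) - 1L)
  w <- slide + w_dry + w_water0 * exp(-times / tau)
  if (noise_sd > 0)
    w <- w + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  drying_curve(times, w, slide)
}

#' Simulate a formazan-stained micrograph
#'
#' A uniform background with a darker centered disc: darkness `d` on
#' background `b` over a disc of the given radius. Useful as ground truth
#' for [formazan_grey()]: the index equals `d * (disc area fraction)` up
#' to pixel discretization.
#'
#' @param nrow,ncol image dimensions, pixels
#' @param background background grey (0-255)
#' @param darkness grey-value drop inside the disc
#' @param radius disc radius in pixels
#' @return a [grey_image()]
#' @export
simulate_formazan_image <- function(nrow = 64, ncol = 64, background = 200,
                                    darkness = 100, radius = 16) {
  stopifnot(background - darkness >= 0, radius > 0)
  ci <- (nrow + 1) / 2; cj <- (ncol + 1) / 2
  px <- outer(seq_len(nrow), seq_len(ncol), function(i, j)
    ifelse((i - ci)^2 + (j - cj)^2 <= radius^2,
           background - darkness, background))
  grey_image(px)
}
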