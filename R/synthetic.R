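#' Parametric absorbance band
#'
#' One component band of a synthetic spectrum: Gaussian
#' \eqn{A \exp(-4\ln 2\,(\nu-c)^2/w^2)} or Lorentzian
#' \eqn{A / (1 + 4(\nu-c)^2/w^2)}, where \eqn{c} is the center,
#' \eqn{w} the full width at half maximum and \eqn{A} the amplitude.
#'
#' @param center band center, cm\eqn{^{-1}}, within 650-4000
#' @param fwhm full width at half maximum, cm\eqn{^{-1}}, > 0
#' @param amplitude peak absorbance, > 0
#' @param shape `"gaussian"` (default) or `"lorentzian"`
#' @return an object of class `band_component`
#' @export
band_component <- function(center, fwhm, amplitude, shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(center), length(center) == 1L,
            is.numeric(fwhm), length(fwhm) == 1L,
            is.numeric(amplitude), length(amplitude) == 1L)
  if (center < 650 || center > 4000)
    stop("band center must lie within 650-4000 cm-1")
  if (fwhm <= 0) stop("fwhm must be > 0")
  if (amplitude <= 0) stop("amplitude must be > 0")
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 shape = shape),
            class = "band_component")
}

#' Evaluate a band profile on a wavenumber grid
#'
#' @param b a [band_component()]
#' @param grid numeric vector of wavenumbers (uniform ascending)
#' @return absorbance values, same length as `grid`; the peak value equals
#'   the amplitude when the center falls on a grid node.
#' @export
band_profile <- function(b, grid) {
  stopifnot(inherits(b, "band_component"), is.numeric(grid))
  d <- grid - b$center
  if (b$shape == "gaussian") {
    b$amplitude * exp(-4 * log(2) * d^2 / b$fwhm^2)
  } else {
    b$amplitude / (1 + 4 * d^2 / b$fwhm^2)
  }
}

#' Bundle of bands describing one substance
#'
#' @param name substance label
#' @param bands list of [band_component()]
#' @param voh_params optional `c(center0, wtc)`: OH-stretch band position at
#'   25 degC (cm\eqn{^{-1}}) and its wavenumber temperature coefficient
#'   (cm\eqn{^{-1}} per degC)
#' @return an object of class `component_preset`
#' @export
component_preset <- function(name, bands, voh_params = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.list(bands))
  for (b in bands)
    if (!inherits(b, "band_component")) stop("bands must be band_component objects")
  if (!is.null(voh_params)) {
    stopifnot(is.numeric(voh_params), length(voh_params) == 2L)
    names(voh_params) <- c("center0", "wtc")
  }
  structure(list(name = name, bands = bands, voh_params = voh_params),
            class = "component_preset")
}

# dsDNA fingerprint marker bands as a function of hydration h in [0,1].
# Endpoint centers are the literature assignments: h=1 (hydrated, B-form)
# 970/1052/1089/1225; h=0 (dried, A-form) 965/1050/1089/1235. Centers morph
# linearly; the symmetric PO2- stretch gains intensity on drying by the
# factor (1 + k*(1-h)).
dna_bands <- function(hydration, sym_boost_k = 0.5) {
  stopifnot(hydration >= 0, hydration <= 1)
  h <- hydration
  list(
    band_component(965 + 5 * h,  16, 0.55),            # nu C-C backbone
    band_component(1050 + 2 * h, 16, 0.65),            # nu C-O deoxyribose
    band_component(1089,         18, 1.00 * (1 + sym_boost_k * (1 - h))),  # nu PO2- sym
    band_component(1235 - 10 * h, 24, 0.85)            # nu PO2- asym
  )
}

#' Shipped substance presets
#'
#' Band positions follow the literature assignments for dried nucleic acids
#' and preservation-matrix components; widths and amplitudes are simulator
#' choices (fingerprint FWHM 15-30 cm\eqn{^{-1}}) tuned so that on a 1
#' cm\eqn{^{-1}} grid the second-derivative minimum of the composite falls
#' within 1 cm\eqn{^{-1}} of every planted center.
#'
#' Available presets: `dsDNA_A` (dried, A-form: 965, 1050, 1089, 1235
#' cm\eqn{^{-1}}), `dsDNA_B` (hydrated, B-form: 970, 1052, 1089, 1225),
#' `ssDNA`, `RNA` (ribose-ring bands at 993 and 1125 plus phosphate bands),
#' `trehalose_dry` (five bands inside 960-1170), `sucrose_dry`, `albumin`
#' (amide I ~1650, amide II ~1550), and the OH-stretch matrix presets
#' `water_OH`, `matrix_OH_liquid`, `matrix_OH_glassy` carrying
#' `voh_params`: a broad (FWHM ~300 cm\eqn{^{-1}}) Gaussian whose center
#' moves linearly with temperature at the preset's WTC. The shipped OH
#' positions order as water > liquid sugar matrix > dried glass, and the
#' glassy WTC is much smaller than the liquid ones, mirroring the reduced
#' thermal expansion of hydrogen bonds in a vitrified matrix.
#'
#' @param name one of the preset names above
#' @return a [component_preset()]
#' @export
preset <- function(name) {
  switch(name,
    dsDNA_A = component_preset("dsDNA_A", dna_bands(0)),
    dsDNA_B = component_preset("dsDNA_B", dna_bands(1)),
    ssDNA = component_preset("ssDNA", list(
      band_component(965, 18, 0.50),
      band_component(1053, 18, 0.60),
      band_component(1089, 20, 0.80),
      band_component(1240, 26, 0.70))),
    RNA = component_preset("RNA", list(
      band_component(993, 16, 0.60),
      band_component(1089, 18, 0.90),
      band_component(1125, 16, 0.65),
      band_component(1240, 26, 0.75))),
    trehalose_dry = component_preset("trehalose_dry", list(
      band_component(994, 16, 0.75),
      band_component(1033, 16, 0.90),
      band_component(1058, 15, 0.70),
      band_component(1105, 16, 0.65),
      band_component(1150, 16, 0.80))),
    sucrose_dry = component_preset("sucrose_dry", list(
      band_component(990, 17, 0.70),
      band_component(1050, 17, 0.85),
      band_component(1085, 15, 0.60),
      band_component(1120, 16, 0.60),
      band_component(1160, 16, 0.70))),
    albumin = component_preset("albumin", list(
      band_component(1652, 30, 1.00),   # amide I
      band_component(1548, 28, 0.80))), # amide II
    water_OH = component_preset("water_OH", list(
      band_component(3400, 300, 1.00)), voh_params = c(3400, 0.50)),
    matrix_OH_liquid = component_preset("matrix_OH_liquid", list(
      band_component(3370, 320, 1.00)), voh_params = c(3370, 0.40)),
    matrix_OH_glassy = component_preset("matrix_OH_glassy", list(
      band_component(3300, 340, 1.00)), voh_params = c(3300, 0.12)),
    stop("unknown preset: ", name)
  )
}

#' Names of all shipped presets
#' @return character vector
#' @export
preset_names <- function() {
  c("dsDNA_A", "dsDNA_B", "ssDNA", "RNA", "trehalose_dry", "sucrose_dry",
    "albumin", "water_OH", "matrix_OH_liquid", "matrix_OH_glassy")
}

#' Generate the noise-free spectrum of one preset
#'
#' Sum of the preset's band profiles on a uniform grid.
#'
#' @param p a [component_preset()] or a preset name
#' @param grid_step grid spacing, cm\eqn{^{-1}} (default 1)
#' @param region [spectral_region()] within 650-4000; default 650-4000
#' @return an [ir_spectrum()]; `meta$preset` records the preset name. An
#'   empty band list yields an all-zero spectrum with `meta$empty = TRUE`
#'   and a warning.
#' @export
generate_component <- function(p, grid_step = 1, region = spectral_region(650, 4000)) {
  if (is.character(p)) p <- preset(p)
  stopifnot(inherits(p, "component_preset"))
  region <- as_region(region)
  if (region$lo < 650 || region$hi > 4000)
    stop("region must lie within 650-4000 cm-1")
  grid <- seq(region$lo, region$hi, by = grid_step)
  a <- numeric(length(grid))
  for (b in p$bands) a <- a + band_profile(b, grid)
  meta <- list(preset = p$name, grid_step = grid_step)
  if (!length(p$bands)) {
    warning("preset '", p$name, "' has no bands; returning zero spectrum")
    meta$empty <- TRUE
  }
  ir_spectrum(grid, a, meta)
}

#' Specification of a synthetic formulation spectrum
#'
#' @param components named numeric vector or list mapping preset names to
#'   non-negative weights; at least one weight must be positive
#' @param hydration fraction in `[0,1]`: 1 = fully hydrated (B-form DNA),
#'   0 = dried (A-form DNA). DNA marker band centers interpolate linearly
#'   between the endpoint assignments and the symmetric phosphate amplitude
#'   grows by `(1 + sym_boost_k*(1-hydration))`.
#' @param temperature sample temperature, degC; moves the OH-stretch center
#'   of presets carrying `voh_params` by `wtc*(temperature - 25)`.
#' @param noise_sd standard deviation of additive iid Gaussian noise
#'   (absorbance units); 0 = noise-free
#' @param seed integer seed, required when `noise_sd > 0`
#' @param sym_boost_k drying intensity gain of the symmetric phosphate band
#'   (default 0.5; the magnitude is a simulator choice)
#' @return an object of class `formulation_spec`
#' @export
formulation_spec <- function(components, hydration = 0, temperature = 25,
                             noise_sd = 0, seed = NULL, sym_boost_k = 0.5) {
  components <- unlist(components)
  if (is.null(names(components)) || any(!nzchar(names(components))))
    stop("components must be a named preset -> weight map")
  if (any(components < 0)) stop("component weights must be >= 0")
  if (!any(components > 0)) stop("at least one component weight must be positive")
  unknown <- setdiff(names(components), preset_names())
  if (length(unknown)) stop("unknown preset(s): ", paste(unknown, collapse = ", "))
  stopifnot(hydration >= 0, hydration <= 1, noise_sd >= 0)
  if (noise_sd > 0 && is.null(seed))
    stop("seed is required when noise_sd > 0 (no implicit global randomness)")
  structure(list(components = components, hydration = hydration,
                 temperature = temperature, noise_sd = noise_sd,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 sym_boost_k = sym_boost_k),
            class = "formulation_spec")
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a composite formulation spectrum
#'
#' Weighted sum of component spectra. dsDNA components are morphed by the
#' spec's hydration (see [formulation_spec()]); OH-matrix components are
#' shifted by temperature according to their preset WTC; finally zero-mean
#' Gaussian noise of sd `noise_sd` is added, reproducibly from the seed.
#'
#' @param spec a [formulation_spec()]
#' @param grid_step grid spacing, cm\eqn{^{-1}} (default 1)
#' @param region [spectral_region()] within 650-4000; default 650-4000
#' @return an [ir_spectrum()]; meta records hydration, temperature, seed.
#' @export
generate_formulation <- function(spec, grid_step = 1,
                                 region = spectral_region(650, 4000)) {
  stopifnot(inherits(spec, "formulation_spec"))
  region <- as_region(region)
  if (region$lo < 650 || region$hi > 4000)
    stop("region must lie within 650-4000 cm-1")
  grid <- seq(region$lo, region$hi, by = grid_step)
  a <- numeric(length(grid))
  for (nm in names(spec$components)) {
    w <- spec$components[[nm]]
    if (w == 0) next
    p <- preset(nm)
    if (nm %in% c("dsDNA_A", "dsDNA_B")) {
      # hydration, not the preset alias, decides the marker positions
      p$bands <- dna_bands(spec$hydration, spec$sym_boost_k)
    }
    if (!is.null(p$voh_params)) {
      ctr <- p$voh_params[["center0"]] +
        p$voh_params[["wtc"]] * (spec$temperature - 25)
      p$bands <- lapply(p$bands, function(b) {
        if (abs(b$center - p$voh_params[["center0"]]) < 1e-9) b$center <- ctr
        b
      })
    }
    for (b in p$bands) a <- a + w * band_profile(b, grid)
  }
  if (spec$noise_sd > 0)
    a <- a + with_seed(spec$seed, stats::rnorm(length(a), 0, spec$noise_sd))
  ir_spectrum(grid, a,
              meta = list(formulation = paste(names(spec$components),
                                              collapse = "+"),
                          hydration = spec$hydration,
                          temperature = spec$temperature,
                          noise_sd = spec$noise_sd, seed = spec$seed,
                          grid_step = grid_step))
}

#' Specification of storage degradation
#'
#' A synthetic stand-in for the spectral drift seen after dried storage:
#' selected band neighbourhoods are rescaled and shifted in proportion to a
#' severity in `[0,1]`. Severity 0 is the exact identity.
#'
#' @param severity fraction in `[0,1]`
#' @param affected_bands numeric vector of band centers, cm\eqn{^{-1}}
#' @param amplitude_drift signed fractional amplitude change per unit
#'   severity (e.g. -0.3 = lose 30 percent at severity 1)
#' @param center_drift band-center shift in cm\eqn{^{-1}} per unit severity
#' @param width neighbourhood FWHM, cm\eqn{^{-1}} (default 30)
#' @param seed integer, stored for provenance; the transform itself is
#'   deterministic
#' @return an object of class `degradation_spec`
#' @export
degradation_spec <- function(severity, affected_bands = c(1089, 1235),
                             amplitude_drift = -0.3, center_drift = 2,
                             width = 30, seed = NULL) {
  if (!is.numeric(severity) || length(severity) != 1L ||
      severity < 0 || severity > 1)
    stop("severity must be a single number in [0,1]")
  stopifnot(is.numeric(affected_bands), length(affected_bands) >= 1L, width > 0)
  structure(list(severity = severity, affected_bands = affected_bands,
                 amplitude_drift = amplitude_drift,
                 center_drift = center_drift, width = width,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "degradation_spec")
}

#' Apply storage degradation to a spectrum
#'
#' For each affected band center \eqn{c}, a Gaussian weight
#' \eqn{w(\nu)} of FWHM `width` blends the original absorbance with a
#' rescaled, center-shifted copy:
#' \deqn{A'(\nu) = (1-w)A(\nu) + w\,(1+a\,s)\,A(\nu - \delta s)}
#' with \eqn{s} the severity, \eqn{a} the amplitude drift and \eqn{\delta}
#' the center drift. Severity 0 returns the input exactly.
#'
#' @param s an [ir_spectrum()] on a uniform grid
#' @param d a [degradation_spec()]
#' @return the degraded `ir_spectrum`
#' @export
degrade <- function(s, d) {
  stopifnot(is_ir_spectrum(s), inherits(d, "degradation_spec"))
  if (is.na(grid_step_of(s)))
    stop("degrade requires a uniform grid; resample() first")
  if (d$severity == 0) return(s)
  wn <- s$wavenumbers
  a <- s$absorbance
  shift <- d$center_drift * d$severity
  scale <- 1 + d$amplitude_drift * d$severity
  shifted <- stats::approx(wn + shift, a, xout = wn, rule = 2,
                           ties = "ordered")$y
  w <- rep(0, length(wn))
  for (ctr in d$affected_bands)
    w <- pmax(w, exp(-4 * log(2) * (wn - ctr)^2 / d$width^2))
  out <- (1 - w) * a + w * scale * shifted
  meta <- s$meta
  meta$degraded_severity <- d$severity
  ir_spectrum(wn, out, meta)
}
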