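#' Default marker search windows (cm-1)
#'
#' Windows bracket both the hydrated (B-form) and dried (A-form) endpoint
#' positions of each DNA marker with margin: C-C backbone 950-985, C-O
#' deoxyribose 1040-1065, symmetric phosphate 1075-1100, asymmetric
#' phosphate 1200-1260.
#' @return named list of `c(lo, hi)` pairs
#' @export
marker_windows <- function() {
  list(cc       = c(950, 985),
       co       = c(1040, 1065),
       po2_sym  = c(1075, 1100),
       po2_asym = c(1200, 1260))
}

# peak prominence on a vector of heights (larger = stronger peak).
# For peak i: descend on each side until a higher value is met (or the end);
# the key saddle is the higher of the two side minima; prominence =
# height - key saddle.
peak_prominence <- function(y, idx) {
  vapply(idx, function(i) {
    h <- y[i]
    left_min <- h; j <- i
    while (j > 1L) {
      j <- j - 1L
      if (y[j] > h) break
      if (y[j] < left_min) left_min <- y[j]
    }
    right_min <- h; j <- i
    while (j < length(y)) {
      j <- j + 1L
      if (y[j] > h) break
      if (y[j] < right_min) right_min <- y[j]
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Detect bands as second-derivative minima
#'
#' Absorbance bands appear as local minima of the second derivative. A
#' point is a candidate when its `d2` is negative and not larger than both
#' neighbours; candidates are kept when their prominence (computed on
#' `-d2`) reaches `min_prominence` times the maximum `|d2|` over the
#' region. Positions are reported at grid nodes (nearest cm\eqn{^{-1}} on
#' the canonical 1 cm\eqn{^{-1}} grid); intensity is `|d2|` at the
#' minimum.
#'
#' @param d a `derivative_spectrum` (see [second_derivative()])
#' @param region search [spectral_region()]
#' @param min_prominence prominence threshold as a fraction of the maximum
#'   `|d2|` in the region (default 0.02, suppressing noise wiggles at the
#'   tested noise levels)
#' @param ref_max reference `|d2|` maximum the threshold fraction is
#'   applied to; default the maximum over `region`. Pass the
#'   fingerprint-region maximum to use one common absolute threshold
#'   across several search windows.
#' @return data.frame with columns `position`, `intensity`, `prominence`,
#'   sorted ascending by position; zero rows when nothing is detected.
#' @export
detect_bands <- function(d, region, min_prominence = 0.02, ref_max = NULL) {
  stopifnot(inherits(d, "derivative_spectrum"))
  region <- as_region(region)
  sel <- which(d$wavenumbers >= region$lo & d$wavenumbers <= region$hi &
                 !is.na(d$d2))
  if (length(sel) < 3L)
    stop("search region lies (almost) entirely in the edge-invalid zone of the derivative")
  y <- -d$d2[sel]            # bands are maxima of -d2
  wn <- d$wavenumbers[sel]
  n <- length(y)
  left <- c(-Inf, y[-n]); right <- c(y[-1], -Inf)
  cand <- which(y > 0 & y >= left & y >= right & (y > left | y > right))
  cand <- cand[cand > 1L & cand < n]
  if (!length(cand))
    return(data.frame(position = numeric(0), intensity = numeric(0),
                      prominence = numeric(0)))
  prom <- peak_prominence(y, cand)
  if (is.null(ref_max)) ref_max <- max(abs(d$d2[sel]))
  thr <- min_prominence * ref_max
  keep <- prom >= thr
  out <- data.frame(position = wn[cand[keep]],
                    intensity = y[cand[keep]],
                    prominence = prom[keep])
  out[order(out$position), , drop = FALSE]
}

#' Extract the four DNA conformation marker bands
#'
#' For each marker window (see [marker_windows()]) the most intense
#' detected band is taken; a window without a detected band yields an
#' absent marker (`NA`), which is a value, not an error. Ties on intensity
#' break by larger prominence, then lower wavenumber.
#'
#' @param d a `derivative_spectrum` covering at least 940-1270
#'   cm\eqn{^{-1}} of valid derivative
#' @param state `"hydrated"` or `"dried"` -- recorded with the result and
#'   used only for reporting which ratio convention applies
#' @param windows marker windows, as [marker_windows()]
#' @param min_prominence see [detect_bands()]; the threshold fraction is
#'   applied relative to the fingerprint-region maximum `|d2|`
#' @return an object of class `marker_set`: a list with one entry per
#'   marker (each `NULL` or a list `position`, `intensity`, `prominence`)
#'   plus `state_assumed`.
#' @export
extract_markers <- function(d, state = c("dried", "hydrated"),
                            windows = marker_windows(),
                            min_prominence = 0.02) {
  state <- match.arg(state)
  stopifnot(inherits(d, "derivative_spectrum"))
  valid <- d$wavenumbers[!is.na(d$d2)]
  if (min(valid) > 940 || max(valid) < 1270)
    stop("derivative must cover 940-1270 cm-1 (valid, non-edge points)")
  # one common prominence threshold over the fingerprint span of the markers
  span <- spectral_region(min(vapply(windows, `[`, numeric(1), 1)),
                          max(vapply(windows, `[`, numeric(1), 2)))
  sel <- d$wavenumbers >= span$lo & d$wavenumbers <= span$hi & !is.na(d$d2)
  ref_max <- max(abs(d$d2[sel]))
  out <- list()
  for (nm in names(windows)) {
    w <- windows[[nm]]
    bands <- detect_bands(d, spectral_region(w[1], w[2]),
                          min_prominence = min_prominence, ref_max = ref_max)
    if (!nrow(bands)) { out[[nm]] <- NULL; next }
    ord <- order(-bands$intensity, -bands$prominence, bands$position)
    b <- bands[ord[1], ]
    out[[nm]] <- list(position = b$position, intensity = b$intensity,
                      prominence = b$prominence)
  }
  structure(c(out, list(state_assumed = state)), class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("<marker_set> state:", x$state_assumed, "\n")
  for (nm in c("cc", "co", "po2_sym", "po2_asym")) {
    if (is.null(x[[nm]])) cat(sprintf("  %-8s absent\n", nm))
    else cat(sprintf("  %-8s %g cm-1  |d2| = %.4g\n", nm,
                     x[[nm]]$position, x[[nm]]$intensity))
  }
  invisible(x)
}

#' Asymmetric/symmetric phosphate band intensity ratio
#'
#' The conformational statistic
#' I(nu PO2- asym)/I(nu PO2- sym), with intensities taken as `|d2|` at the
#' detected band minima (the window-minimum convention; the positions
#' actually used are recorded in the result).
#'
#' @param m a `marker_set` with both phosphate markers present
#' @return list with `ratio`, `asym_position_used`, `sym_position_used`
#' @export
phosphate_ratio <- function(m) {
  stopifnot(inherits(m, "marker_set"))
  if (is.null(m$po2_asym)) stop("phosphate_ratio: asymmetric phosphate band (po2_asym) absent")
  if (is.null(m$po2_sym)) stop("phosphate_ratio: symmetric phosphate band (po2_sym) absent")
  list(ratio = m$po2_asym$intensity / m$po2_sym$intensity,
       asym_position_used = m$po2_asym$position,
       sym_position_used = m$po2_sym$position)
}

#' Call the DNA conformation from marker positions
#'
#' Each of the three shifting markers votes by nearest endpoint: C-C
#' backbone 970 (B) vs 965 (A-like); C-O 1052 (B) vs 1050 (A-like);
#' asymmetric phosphate <= 1228 (B) vs >= 1230 (A-like), with the 1228-1230
#' gap left unassigned to avoid knife-edge calls. The majority of assigned
#' votes wins; fewer than two usable markers, or a tie, is `indeterminate`.
#'
#' @param m a `marker_set`
#' @return `"B"`, `"A_like"`, or `"indeterminate"`
#' @export
classify_conformation <- function(m) {
  stopifnot(inherits(m, "marker_set"))
  votes <- character(0)
  usable <- 0L
  if (!is.null(m$cc)) {
    usable <- usable + 1L
    votes <- c(votes, if (abs(m$cc$position - 965) < abs(m$cc$position - 970))
      "A_like" else if (abs(m$cc$position - 970) < abs(m$cc$position - 965))
        "B" else NA_character_)
  }
  if (!is.null(m$co)) {
    usable <- usable + 1L
    votes <- c(votes, if (abs(m$co$position - 1050) < abs(m$co$position - 1052))
      "A_like" else if (abs(m$co$position - 1052) < abs(m$co$position - 1050))
        "B" else NA_character_)
  }
  if (!is.null(m$po2_asym)) {
    usable <- usable + 1L
    p <- m$po2_asym$position
    votes <- c(votes, if (p >= 1230) "A_like" else if (p <= 1228) "B"
               else NA_character_)
  }
  if (usable < 2L) return("indeterminate")
  votes <- votes[!is.na(votes)]
  nA <- sum(votes == "A_like"); nB <- sum(votes == "B")
  if (nA > nB) "A_like" else if (nB > nA) "B" else "indeterminate"
}

#' Flatten a marker set to a one-row data frame
#'
#' For batch CSV output: positions and intensities of the four markers
#' (`NA` when absent), the phosphate ratio when computable, and the
#' conformational call.
#'
#' @param m a `marker_set`
#' @return one-row data.frame
#' @export
markers_as_row <- function(m) {
  stopifnot(inherits(m, "marker_set"))
  val <- function(nm, f) if (is.null(m[[nm]])) NA_real_ else m[[nm]][[f]]
  ratio <- tryCatch(phosphate_ratio(m)$ratio, error = function(e) NA_real_)
  data.frame(state_assumed = m$state_assumed,
             cc_position = val("cc", "position"),
             co_position = val("co", "position"),
             po2_sym_position = val("po2_sym", "position"),
             po2_asym_position = val("po2_asym", "position"),
             po2_sym_intensity = val("po2_sym", "intensity"),
             po2_asym_intensity = val("po2_asym", "intensity"),
             phosphate_ratio = ratio,
             conformation = classify_conformation(m),
             stringsAsFactors = FALSE)
}
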