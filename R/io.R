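#' Read a two-column spectrum from delimited text
#'
#' The canonical exchange format: two columns (wavenumber cm\eqn{^{-1}},
#' absorbance), UTF-8, "." decimal, comma- or whitespace-separated. A single
#' header line is auto-detected (non-numeric first token) and skipped.
#' Rows may arrive in descending instrument order; output is always
#' ascending.
#'
#' @param path file path
#' @param sep field separator; `NULL` (default) auto-detects comma vs
#'   whitespace per line
#' @param header `NA` (default) auto-detects a single leading header line;
#'   `TRUE`/`FALSE` force it
#' @return an [ir_spectrum()]; `meta$source` records `path`.
#' @export
read_spectrum_csv <- function(path, sep = NULL, header = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty spectrum file: ", path)

  split_line <- function(line) {
    line <- trimws(line)
    if (!is.null(sep)) return(strsplit(line, sep, fixed = TRUE)[[1]])
    if (grepl(",", line, fixed = TRUE))
      return(trimws(strsplit(line, ",", fixed = TRUE)[[1]]))
    strsplit(line, "[[:space:]]+")[[1]]
  }
  first <- split_line(lines[1])
  skip <- isTRUE(header) ||
    (is.na(header) && suppressWarnings(is.na(as.numeric(first[1]))))
  if (skip) lines <- lines[-1]
  if (length(lines) < 2L)
    stop("need at least 2 data rows in ", path)

  n <- length(lines)
  wn <- numeric(n); ab <- numeric(n)
  for (i in seq_len(n)) {
    tok <- split_line(lines[i])
    tok <- tok[nzchar(tok)]
    if (length(tok) < 2L)
      stop(sprintf("format error in %s at data line %d: expected 2 columns, got %d",
                   path, i, length(tok)))
    v <- suppressWarnings(as.numeric(tok[1:2]))
    if (anyNA(v))
      stop(sprintf("format error in %s at data line %d: non-numeric value '%s'",
                   path, i, tok[which(is.na(v))[1]]))
    wn[i] <- v[1]; ab[i] <- v[2]
  }
  if (anyDuplicated(wn))
    stop("duplicate wavenumber in ", path, ": ", wn[anyDuplicated(wn)])
  ir_spectrum(wn, ab, meta = list(source = path))
}

#' Write a spectrum as canonical CSV
#'
#' Two comma-separated columns with header `wavenumber,absorbance`, full
#' double precision (17 significant digits), ascending order.
#' `read_spectrum_csv()` of the written file reproduces the spectrum
#' bit-for-bit.
#'
#' @param s an [ir_spectrum()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(is_ir_spectrum(s))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("wavenumber,absorbance", con)
  writeLines(sprintf("%.17g,%.17g", s$wavenumbers, s$absorbance), con)
  invisible(path)
}

#' Read a JCAMP-DX 4.24 infrared spectrum
#'
#' Supports the uncompressed AFFN subset: `##XYDATA=(X++(Y..Y))` with
#' `FIRSTX`/`DELTAX`/`XFACTOR`/`YFACTOR` decoding, and `##XYPOINTS=(XY..XY)`
#' pair tables. The SQZ/DIF/DUP compression schemes are rejected with a
#' clear error. Output order is canonical ascending.
#'
#' @param path file path
#' @return an [ir_spectrum()]; `meta$source` records `path`, `meta$title`
#'   the `##TITLE` if present.
#' @export
read_spectrum_jcampdx <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  # collect label lines (##LABEL=value) and data blocks
  ldr_idx <- grep("^\\s*##", lines)
  labels <- list()
  for (i in ldr_idx) {
    m <- regmatches(lines[i], regexec("^\\s*##([^=]*)=(.*)$", lines[i]))[[1]]
    if (length(m) == 3L) {
      key <- toupper(gsub("[ _-]", "", m[2]))
      labels[[key]] <- trimws(m[3])
      attr(labels[[key]], "line") <- i
    }
  }
  num <- function(key) suppressWarnings(as.numeric(labels[[key]]))

  data_block <- function(start_key) {
    i0 <- attr(labels[[start_key]], "line")
    rest <- lines[seq(i0 + 1L, length(lines))]
    stop_at <- grep("^\\s*##", rest)
    if (length(stop_at)) rest <- rest[seq_len(stop_at[1] - 1L)]
    rest[nzchar(trimws(rest))]
  }
  check_affn <- function(txt) {
    # SQZ uses @A-I/a-i, DIF %J-R/j-r, DUP S-Zs: any letter or @/% flags them
    if (any(grepl("[@%A-DF-Za-df-z]", txt)))  # E allowed for exponents
      stop("JCAMP-DX SQZ/DIF/DUP compressed data are not supported; ",
           "only AFFN numerals are accepted")
  }

  if (!is.null(labels[["XYDATA"]])) {
    need <- c("FIRSTX", "DELTAX", "NPOINTS")
    missing <- need[vapply(need, function(k) is.null(labels[[k]]), logical(1))]
    if (length(missing))
      stop("JCAMP-DX file missing required labels: ",
           paste0("##", missing, collapse = ", "))
    xf <- if (is.null(labels[["XFACTOR"]])) 1 else num("XFACTOR")
    yf <- if (is.null(labels[["YFACTOR"]])) 1 else num("YFACTOR")
    firstx <- num("FIRSTX"); deltax <- num("DELTAX")
    npts <- num("NPOINTS")
    if (is.na(deltax) || deltax == 0) stop("JCAMP-DX DELTAX must be nonzero")
    block <- data_block("XYDATA")
    check_affn(block)
    wn <- numeric(0); ab <- numeric(0)
    for (line in block) {
      tok <- strsplit(trimws(line), "[[:space:],;]+")[[1]]
      v <- suppressWarnings(as.numeric(tok))
      if (anyNA(v)) stop("unparseable JCAMP-DX data line: ", line)
      if (length(v) < 2L) stop("JCAMP-DX data line needs X then Y values: ", line)
      x0 <- v[1] * xf
      ys <- v[-1] * yf
      wn <- c(wn, x0 + deltax * xf * (seq_along(ys) - 1L))
      ab <- c(ab, ys)
    }
    if (!is.na(npts) && length(ab) != npts)
      warning(sprintf("JCAMP-DX NPOINTS=%d but %d points read", npts, length(ab)))
  } else if (!is.null(labels[["XYPOINTS"]])) {
    block <- data_block("XYPOINTS")
    check_affn(block)
    tok <- unlist(strsplit(trimws(block), "[[:space:],;]+"))
    tok <- tok[nzchar(tok)]
    v <- suppressWarnings(as.numeric(tok))
    if (anyNA(v) || length(v) %% 2L != 0L)
      stop("unparseable JCAMP-DX XYPOINTS table")
    wn <- v[seq(1, length(v), by = 2)]
    ab <- v[seq(2, length(v), by = 2)]
  } else {
    stop("JCAMP-DX file missing required labels: ##XYDATA or ##XYPOINTS")
  }
  meta <- list(source = path)
  if (!is.null(labels[["TITLE"]])) meta$title <- as.character(labels[["TITLE"]])
  ir_spectrum(wn, ab, meta)
}
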