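#' Assemble a normalized spectra matrix for PCA
#'
#' Each spectrum is resampled to the common analysis grid over `region`,
#' restricted to it, and vector-normalized, giving one unit-norm row per
#' spectrum.
#'
#' @param spectra list of at least 3 [ir_spectrum()]s with overlapping
#'   support covering `region`
#' @param region analysis region, default [fingerprint_region()]
#' @param grid_step common grid step (default 1 cm\eqn{^{-1}})
#' @param row_labels optional data.frame (or vector) of per-spectrum labels
#'   (formulation, storage condition, replicate, ...)
#' @return an object of class `spectra_matrix`: `x` (rows = spectra),
#'   `wavenumbers`, `row_labels`
#' @export
build_matrix <- function(spectra, region = fingerprint_region(),
                         grid_step = 1, row_labels = NULL) {
  if (length(spectra) < 3L) stop("PCA needs at least 3 spectra")
  region <- as_region(region)
  lo <- max(vapply(spectra, function(s) min(s$wavenumbers), numeric(1)))
  hi <- min(vapply(spectra, function(s) max(s$wavenumbers), numeric(1)))
  if (lo > region$lo || hi < region$hi)
    stop(sprintf("common spectral support %g-%g cm-1 does not cover the region %g-%g",
                 lo, hi, region$lo, region$hi))
  rows <- lapply(spectra, function(s) {
    vector_normalize(resample(s, grid_step, region), region)$absorbance
  })
  x <- do.call(rbind, rows)
  wn <- resample(spectra[[1]], grid_step, region)$wavenumbers
  if (!is.null(row_labels)) {
    row_labels <- as.data.frame(row_labels)
    if (nrow(row_labels) != length(spectra))
      stop("row_labels must have one row per spectrum")
  }
  structure(list(x = x, wavenumbers = wn, row_labels = row_labels),
            class = "spectra_matrix")
}

#' Covariance-matrix PCA of a spectra matrix
#'
#' Rows are mean-centered and the covariance matrix eigendecomposed
#' (covariance, not correlation, per the chemometric convention for
#' vector-normalized spectra). Scores are the centered rows projected on
#' the loadings. The sign of each loading is fixed so that its
#' largest-magnitude element is positive, making results deterministic.
#'
#' @param m a `spectra_matrix` from [build_matrix()]
#' @param n_components number of PCs to keep;
#'   `<= min(nrow - 1, ncol)`. Default all.
#' @return an object of class `spectra_pca`: `loadings` (columns = PCs),
#'   `scores` (rows = spectra), `explained_variance_fraction`,
#'   `mean_spectrum`, `wavenumbers`, `row_labels`
#' @export
fit_pca <- function(m, n_components = NULL) {
  stopifnot(inherits(m, "spectra_matrix"))
  x <- m$x
  n <- nrow(x)
  max_pc <- min(n - 1L, ncol(x))
  if (is.null(n_components)) n_components <- max_pc
  if (n_components < 1L || n_components > max_pc)
    stop(sprintf("n_components must be in 1..%d", max_pc))
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  # eigendecomposition of the (column) covariance via crossprod; for wide
  # matrices go through the small n x n Gram matrix for efficiency
  if (ncol(xc) <= n) {
    ev <- eigen(crossprod(xc) / (n - 1), symmetric = TRUE)
    load <- ev$vectors[, seq_len(n_components), drop = FALSE]
    lambda <- ev$values
  } else {
    g <- eigen(tcrossprod(xc) / (n - 1), symmetric = TRUE)
    lambda <- g$values
    pos <- which(lambda > max(lambda) * 1e-12)
    load <- crossprod(xc, g$vectors[, pos, drop = FALSE])
    load <- sweep(load, 2, sqrt(colSums(load^2)), "/")
    if (n_components > length(pos))
      stop(sprintf("n_components must be in 1..%d (matrix rank)", length(pos)))
    load <- load[, seq_len(n_components), drop = FALSE]
  }
  lambda <- pmax(lambda, 0)
  evf <- lambda[seq_len(n_components)] / sum(lambda)
  # deterministic sign: largest-|.| element of each loading positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  scores <- xc %*% load
  colnames(load) <- colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(loadings = load, scores = scores,
                 explained_variance_fraction = evf,
                 mean_spectrum = mu, wavenumbers = m$wavenumbers,
                 row_labels = m$row_labels),
            class = "spectra_pca")
}

#' @export
print.spectra_pca <- function(x, ...) {
  cat(sprintf("<spectra_pca> %d spectra x %d wavenumbers, %d PCs\n",
              nrow(x$scores), length(x$wavenumbers), ncol(x$scores)))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' Group-drift summary in PC score space
#'
#' For each requested PC the distance between group centroids is expressed
#' in units of the pooled within-group standard deviation. The overall
#' `clustered` flag is TRUE when every requested PC has standardized
#' distance below `threshold` (default 1 pooled SD) -- the two groups then
#' "cluster together" in the monitored score plane.
#'
#' @param model a `spectra_pca`
#' @param group_a,group_b row indices (or logical masks over rows) of the
#'   two groups
#' @param pcs PC indices to assess (default 1:3, capped at the number of
#'   computed PCs)
#' @param threshold standardized-distance threshold (default 1)
#' @return data.frame with one row per PC (`pc`, `standardized_distance`)
#'   plus attributes `clustered` (logical) and `threshold`
#' @export
drift_report <- function(model, group_a, group_b, pcs = 1:3, threshold = 1) {
  stopifnot(inherits(model, "spectra_pca"))
  n <- nrow(model$scores)
  idx <- function(g) {
    if (is.logical(g)) g <- which(g)
    g <- as.integer(g)
    if (!length(g)) stop("drift_report: empty group")
    if (any(g < 1L | g > n)) stop("group index out of range")
    g
  }
  ia <- idx(group_a); ib <- idx(group_b)
  pcs <- pcs[pcs <= ncol(model$scores)]
  if (!length(pcs)) stop("no requested PC was computed")
  dist_std <- vapply(pcs, function(j) {
    sa <- model$scores[ia, j]; sb <- model$scores[ib, j]
    na <- length(sa); nb <- length(sb)
    va <- if (na > 1) stats::var(sa) else 0
    vb <- if (nb > 1) stats::var(sb) else 0
    dof <- max(na + nb - 2L, 1L)
    pooled <- sqrt(((na - 1) * va + (nb - 1) * vb) / dof)
    d <- abs(mean(sa) - mean(sb))
    if (pooled == 0) { if (d == 0) 0 else Inf } else d / pooled
  }, numeric(1))
  out <- data.frame(pc = pcs, standardized_distance = dist_std)
  attr(out, "clustered") <- all(dist_std < threshold)
  attr(out, "threshold") <- threshold
  out
}

#' Write PCA results as CSV files
#'
#' Three files: `<stem>_scores.csv`, `<stem>_loadings.csv`,
#' `<stem>_variance.csv`.
#'
#' @param model a `spectra_pca`
#' @param stem output path stem
#' @return character vector of the paths written, invisibly
#' @export
write_pca_csv <- function(model, stem) {
  stopifnot(inherits(model, "spectra_pca"))
  sc <- as.data.frame(model$scores)
  if (!is.null(model$row_labels)) sc <- cbind(model$row_labels, sc)
  paths <- paste0(stem, c("_scores.csv", "_loadings.csv", "_variance.csv"))
  utils::write.csv(sc, paths[1], row.names = FALSE)
  utils::write.csv(cbind(data.frame(wavenumber = model$wavenumbers),
                         as.data.frame(model$loadings)),
                   paths[2], row.names = FALSE)
  utils::write.csv(data.frame(pc = seq_along(model$explained_variance_fraction),
                              explained_variance_fraction =
                                model$explained_variance_fraction),
                   paths[3], row.names = FALSE)
  invisible(paths)
}
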