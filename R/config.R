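#' Pipeline configuration
#'
#' One validated object carrying every tunable of the analysis pipeline,
#' with the canonical defaults. All fields are checked against the owning
#' stage's preconditions at construction time.
#'
#' @param grid_step analysis grid step, cm\eqn{^{-1}} (default 1)
#' @param fingerprint `c(lo, hi)` of the fingerprint region (default
#'   900-1500)
#' @param oh `c(lo, hi)` of the OH-stretch region (default 3000-3700)
#' @param sg_window,sg_order Savitzky-Golay window (odd) and polynomial
#'   order (defaults 21, 3)
#' @param markers named list of marker windows (default [marker_windows()])
#' @param min_prominence band-detection prominence fraction (default 0.02)
#' @param wtc_fit_range `c(lo, hi)` degC for the WTC fit (default 25-50)
#' @param pca_components number of PCs to keep (default 3)
#' @param drift_threshold standardized-distance threshold (default 1)
#' @param seed integer base seed for simulation commands (default 1)
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(grid_step = 1,
                            fingerprint = c(900, 1500),
                            oh = c(3000, 3700),
                            sg_window = 21L, sg_order = 3L,
                            markers = marker_windows(),
                            min_prominence = 0.02,
                            wtc_fit_range = c(25, 50),
                            pca_components = 3L,
                            drift_threshold = 1,
                            seed = 1L) {
  stopifnot(grid_step > 0, min_prominence >= 0, drift_threshold > 0,
            pca_components >= 1L)
  fingerprint <- as.numeric(fingerprint); oh <- as.numeric(oh)
  as_region(fingerprint); as_region(oh)   # validate lo < hi
  sg_window <- as.integer(sg_window); sg_order <- as.integer(sg_order)
  if (sg_window %% 2L == 0L || sg_window < sg_order + 2L)
    stop("sg_window must be odd and >= sg_order + 2")
  wtc_fit_range <- as.numeric(wtc_fit_range)
  if (length(wtc_fit_range) != 2L || wtc_fit_range[1] >= wtc_fit_range[2])
    stop("wtc_fit_range must be c(lo, hi) with lo < hi")
  markers <- lapply(markers, as.numeric)
  for (w in markers) if (length(w) != 2L || w[1] >= w[2])
    stop("each marker window must be c(lo, hi) with lo < hi")
  structure(list(grid_step = grid_step, fingerprint = fingerprint, oh = oh,
                 sg_window = sg_window, sg_order = sg_order,
                 markers = markers, min_prominence = min_prominence,
                 wtc_fit_range = wtc_fit_range,
                 pca_components = as.integer(pca_components),
                 drift_threshold = drift_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [pipeline_config()]. `config_load(config_dump(cfg))` reproduces `cfg`.
#'
#' @param path YAML file path
#' @return a [pipeline_config()]
#' @export
config_load <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to a YAML file
#'
#' @param config a [pipeline_config()]
#' @param path output path
#' @return `path`, invisibly
#' @export
config_dump <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
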