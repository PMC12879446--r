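# Run configuration: the acquisition and analysis parameters of the study,
# with validation. Defaults are the published protocol values.

woi_default_config <- list(
  wavelengths_nm = c(530, 590, 625),
  frame_rate_hz = 16,
  downsample_shape = c(75L, 100L),
  downsample_frame_rate_hz = 8,
  band_hz = c(0.02, 0.167),
  smoothing = c(kernel_size = 5, sigma_px = 1.3),
  censor_threshold = 1,
  n_parcels = 30L,
  min_clusters = 8L,
  seed = 1L,
  paths = list()
)

#' Construct a validated run configuration
#'
#' Holds every tunable parameter of the imaging pipeline. Defaults reproduce
#' the published acquisition and analysis protocol: three LED channels
#' (530/590/625 nm), 16 frames/s per channel after light separation,
#' spatial/temporal downsampling to 75x100 pixels at 8 frames/s, a
#' 0.02-0.167 Hz analysis band, 5x5-pixel Gaussian smoothing with sigma 1.3,
#' a censoring threshold of 1 on the per-frame mean squared HbO2 contrast,
#' 30 parcels, and a minimum of 8 hierarchical clusters.
#'
#' @param ... Named overrides of any default field. Unknown names are an
#'   error when `strict = TRUE`, otherwise a warning.
#' @param strict Reject unknown keys (default `TRUE`).
#' @return An object of class `run_config` (a named list).
#' @examples
#' cfg <- run_config()
#' cfg$band_hz
#' run_config(n_parcels = 20)$n_parcels
#' @export
run_config <- function(..., strict = TRUE) {
  over <- list(...)
  cfg <- woi_default_config
  if (length(over) > 0L) {
    if (is.null(names(over)) || any(names(over) == "")) {
      stop("all overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0L) {
      msg <- paste("unknown config key(s):", paste(unknown, collapse = ", "))
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
      over <- over[setdiff(names(over), unknown)]
    }
    cfg[names(over)] <- over
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  cfg$wavelengths_nm <- as.numeric(cfg$wavelengths_nm)
  cfg$downsample_shape <- as.integer(cfg$downsample_shape)
  cfg$band_hz <- as.numeric(cfg$band_hz)
  cfg$n_parcels <- as.integer(cfg$n_parcels)
  cfg$min_clusters <- as.integer(cfg$min_clusters)
  sm <- unlist(cfg$smoothing)
  if (length(sm) != 2L) stop("smoothing must be (kernel_size, sigma_px)", call. = FALSE)
  names(sm) <- c("kernel_size", "sigma_px")
  cfg$smoothing <- sm

  stopifnot_cfg(length(cfg$wavelengths_nm) >= 2L, "need at least 2 wavelengths")
  stopifnot_cfg(all(cfg$wavelengths_nm > 0), "wavelengths must be positive")
  stopifnot_cfg(cfg$frame_rate_hz > 0, "frame_rate_hz must be positive")
  stopifnot_cfg(cfg$downsample_frame_rate_hz > 0,
                "downsample_frame_rate_hz must be positive")
  stopifnot_cfg(cfg$downsample_frame_rate_hz <= cfg$frame_rate_hz,
                "downsampled rate cannot exceed acquisition rate")
  stopifnot_cfg(length(cfg$downsample_shape) == 2L && all(cfg$downsample_shape >= 1L),
                "downsample_shape must be two positive integers")
  stopifnot_cfg(length(cfg$band_hz) == 2L, "band_hz must be (low, high)")
  stopifnot_cfg(cfg$band_hz[1L] > 0, "band low cutoff must be positive")
  stopifnot_cfg(cfg$band_hz[1L] < cfg$band_hz[2L],
                "band low cutoff must be below the high cutoff")
  stopifnot_cfg(cfg$band_hz[2L] < cfg$downsample_frame_rate_hz / 2,
                "band high cutoff must be below the Nyquist frequency")
  stopifnot_cfg(sm["kernel_size"] >= 1 && sm["kernel_size"] %% 2 == 1,
                "smoothing kernel_size must be an odd positive integer")
  stopifnot_cfg(sm["sigma_px"] > 0, "smoothing sigma_px must be positive")
  stopifnot_cfg(cfg$censor_threshold > 0, "censor_threshold must be positive")
  stopifnot_cfg(cfg$min_clusters >= 2L, "min_clusters must be at least 2")
  stopifnot_cfg(cfg$n_parcels >= cfg$min_clusters,
                "n_parcels must be at least min_clusters")
  structure(cfg, class = "run_config")
}

stopifnot_cfg <- function(ok, msg) {
  if (!isTRUE(ok)) stop("invalid configuration: ", msg, call. = FALSE)
}

#' Load a run configuration from YAML or JSON
#'
#' Omitted keys take the protocol defaults (see [run_config()]); an empty
#' file yields the full default configuration. Unknown keys are rejected
#' (`strict = TRUE`) or warned about.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param strict Reject unknown keys (default `TRUE`).
#' @return A `run_config`.
#' @export
load_config <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, call. = FALSE)
  )
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a mapping", call. = FALSE)
  do.call(run_config, c(raw, list(strict = strict)))
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat("  wavelengths_nm:", paste(x$wavelengths_nm, collapse = "/"), "\n")
  cat("  frame rate:", x$frame_rate_hz, "->", x$downsample_frame_rate_hz, "Hz\n")
  cat("  downsample shape:", paste(x$downsample_shape, collapse = "x"), "\n")
  cat("  band:", paste(x$band_hz, collapse = "-"), "Hz\n")
  cat("  smoothing:", x$smoothing["kernel_size"], "px kernel, sigma",
      x$smoothing["sigma_px"], "\n")
  cat("  censor threshold:", x$censor_threshold, "\n")
  cat("  parcels:", x$n_parcels, " min clusters:", x$min_clusters, "\n")
  invisible(x)
}
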