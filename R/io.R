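# On-disk artifacts: raw reflectance stacks (multi-page TIFF + JSON sidecar),
# processed hemoglobin stacks (RDS), correlation matrices and cluster tables
# (CSV), statistics reports (JSON).

#' Construct a raw reflectance stack
#'
#' @param frames Numeric array `time x rows x cols x wavelength` of camera
#'   counts (or continuous reflectance when `bit_depth` is `NULL`).
#' @param wavelengths_nm LED wavelengths, one per channel.
#' @param frame_rate_hz Per-channel frame rate after light separation.
#' @param bit_depth Integer bit depth of the quantized counts, or `NULL`
#'   for continuous (unquantized) data.
#' @return A `raw_stack`.
#' @export
raw_stack <- function(frames, wavelengths_nm, frame_rate_hz, bit_depth = 16L) {
  d <- dim(frames)
  if (length(d) != 4L) stop("frames must be a time x rows x cols x wavelength array",
                            call. = FALSE)
  if (d[4L] != length(wavelengths_nm)) {
    stop("number of channels does not match wavelengths_nm", call. = FALSE)
  }
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be positive", call. = FALSE)
  structure(list(frames = frames,
                 wavelengths_nm = as.numeric(wavelengths_nm),
                 frame_rate_hz = frame_rate_hz,
                 bit_depth = if (is.null(bit_depth)) NULL else as.integer(bit_depth)),
            class = "raw_stack")
}

#' @export
print.raw_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<raw_stack> %d frames x %dx%d px x %d channels (%s nm) @ %g Hz%s\n",
              d[1L], d[2L], d[3L], d[4L],
              paste(x$wavelengths_nm, collapse = "/"), x$frame_rate_hz,
              if (is.null(x$bit_depth)) ", continuous"
              else sprintf(", %d-bit", x$bit_depth)))
  invisible(x)
}

#' Write a raw stack as an interleaved multi-page TIFF
#'
#' Pages are channel-interleaved in acquisition order (frame 1 channel 1,
#' frame 1 channel 2, ..., frame 2 channel 1, ...). The interleave order,
#' wavelengths, frame rate and bit depth are declared in a JSON sidecar
#' (`<path>.json`), never inferred from the pixel data. Quantized stacks
#' round-trip bit-exactly; continuous stacks are not supported on disk.
#'
#' @param stack A [raw_stack()] with integer counts (`bit_depth` 8 or 16).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_raw_stack <- function(stack, path) {
  stopifnot(inherits(stack, "raw_stack"))
  if (is.null(stack$bit_depth) || !stack$bit_depth %in% c(8L, 16L)) {
    stop("on-disk stacks must be quantized to 8 or 16 bits", call. = FALSE)
  }
  maxv <- 2^stack$bit_depth - 1
  d <- dim(stack$frames)
  pages <- vector("list", d[1L] * d[4L])
  k <- 0L
  for (t in seq_len(d[1L])) {
    for (w in seq_len(d[4L])) {
      k <- k + 1L
      pages[[k]] <- stack$frames[t, , , w] / maxv
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  meta <- list(wavelengths_nm = stack$wavelengths_nm,
               frame_rate_hz = stack$frame_rate_hz,
               bit_depth = stack$bit_depth,
               n_frames = d[1L],
               shape = d[2:3],
               interleave = "channel")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raw stack written by [write_raw_stack()]
#'
#' The channel interleave layout is taken from the JSON sidecar (or from
#' `layout`); the page count must be divisible by the number of channels.
#'
#' @param path TIFF path.
#' @param layout Optional metadata list overriding the sidecar (fields
#'   `wavelengths_nm`, `frame_rate_hz`, `bit_depth`).
#' @return A [raw_stack()].
#' @export
read_raw_stack <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("stack file not found: ", path, call. = FALSE)
  meta <- layout
  sidecar <- paste0(path, ".json")
  if (is.null(meta)) {
    if (!file.exists(sidecar)) {
      stop("no layout given and no metadata sidecar found: ", sidecar, call. = FALSE)
    }
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  for (f in c("wavelengths_nm", "frame_rate_hz", "bit_depth")) {
    if (is.null(meta[[f]])) stop("stack metadata missing field: ", f, call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  nw <- length(meta$wavelengths_nm)
  if (length(pages) %% nw != 0L) {
    stop(sprintf("layout error: %d pages not divisible by %d channels",
                 length(pages), nw), call. = FALSE)
  }
  nt <- length(pages) %/% nw
  shp <- dim(pages[[1L]])
  maxv <- 2^meta$bit_depth - 1
  frames <- array(0, dim = c(nt, shp[1L], shp[2L], nw))
  k <- 0L
  for (t in seq_len(nt)) {
    for (w in seq_len(nw)) {
      k <- k + 1L
      frames[t, , , w] <- round(pages[[k]] * maxv)
    }
  }
  raw_stack(frames, meta$wavelengths_nm, meta$frame_rate_hz, meta$bit_depth)
}

#' Write / read a processed hemoglobin stack
#'
#' Processed stacks (hemoglobin contrasts plus mask, censoring record and
#' provenance) are serialized as a single RDS container.
#'
#' @param hemo A `hemo_stack`.
#' @param path Output path (`.rds`).
#' @return `path` (writer) or the `hemo_stack` (reader).
#' @export
write_hemo_stack <- function(hemo, path) {
  stopifnot(inherits(hemo, "hemo_stack"))
  saveRDS(hemo, path)
  invisible(path)
}

#' @rdname write_hemo_stack
#' @export
read_hemo_stack <- function(path) {
  if (!file.exists(path)) stop("hemo stack not found: ", path, call. = FALSE)
  x <- readRDS(path)
  if (!inherits(x, "hemo_stack")) stop("file does not contain a hemo_stack", call. = FALSE)
  x
}

#' Write / read a labeled correlation matrix as CSV
#'
#' The CSV carries the unit labels as the first columns (`id`, `hemisphere`,
#' `cluster`, `region`) followed by one numeric column per unit.
#'
#' @param corr A `corr_matrix`.
#' @param path Output path.
#' @return `path` (writer) or a `corr_matrix` (reader).
#' @export
write_corr_matrix <- function(corr, path) {
  stopifnot(inherits(corr, "corr_matrix"))
  lab <- attr(corr, "labels")
  df <- cbind(lab, as.data.frame(unclass(corr)[seq_len(nrow(corr)), , drop = FALSE]))
  names(df) <- c(names(lab), paste0("u", seq_len(ncol(corr))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_corr_matrix
#' @export
read_corr_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  valcols <- grep("^u[0-9]+$", names(df), value = TRUE)
  lab <- df[, setdiff(names(df), valcols), drop = FALSE]
  vals <- as.matrix(df[, valcols, drop = FALSE])
  dimnames(vals) <- NULL
  corr_matrix_from_values(vals, lab)
}

#' Write a statistics report as JSON
#'
#' @param report Named list of results (e.g. randomization and rank-sum
#'   results); coerced to JSON with full numeric precision.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
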