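# Brain masks with hemisphere labels and an optional vein mask.
#
# Convention used throughout the package: images are nrow x ncol matrices,
# 1-based, column-major (R-native); the linear pixel index of in-mask pixels
# is `which(mask$brain)`. Rows run anterior -> posterior, columns left ->
# right, so the hemisphere split is a column convention.

#' Construct a mask set
#'
#' @param hemisphere Integer matrix with the label encoding
#'   0 = background, 1 = left hemisphere, 2 = right hemisphere,
#'   3 = in-brain but excluded from hemisphere analysis (e.g. the midline
#'   vein stripe).
#' @param vein Optional logical matrix of vein pixels; defaults to
#'   `hemisphere == 3`. Must be a subset of the brain mask.
#' @return A `mask_set` with fields `brain` (logical matrix), `hemisphere`
#'   (integer matrix as above), and `vein` (logical matrix).
#' @export
mask_set <- function(hemisphere, vein = NULL) {
  if (!is.matrix(hemisphere)) stop("hemisphere must be a matrix", call. = FALSE)
  h <- matrix(as.integer(round(hemisphere)), nrow(hemisphere), ncol(hemisphere))
  if (!all(h %in% 0:3)) {
    stop("hemisphere labels must be in {0 background, 1 left, 2 right, 3 excluded}",
         call. = FALSE)
  }
  brain <- h > 0L
  if (is.null(vein)) vein <- h == 3L
  vein <- matrix(as.logical(vein), nrow(h), ncol(h))
  if (any(vein & !brain)) stop("vein mask must be a subset of the brain mask", call. = FALSE)
  if (!any(brain)) warning("empty brain mask", call. = FALSE)
  structure(list(brain = brain, hemisphere = h, vein = vein),
            class = "mask_set")
}

#' Read a mask set from a labeled TIFF image
#'
#' The image must be 8-bit with pixel values encoding 0 = background,
#' 1 = left, 2 = right, 3 = in-brain excluded (vein). A pixel may carry only
#' one label; the encoding makes double-labeling unrepresentable, but label
#' values outside 0-3 are rejected.
#'
#' @param path Path to the TIFF file.
#' @param expected_shape Optional `(rows, cols)`; a mismatch is an error
#'   (no silent resizing).
#' @return A [mask_set()].
#' @export
read_mask <- function(path, expected_shape = NULL) {
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  lab <- round(img * 255)
  if (!is.null(expected_shape) && !all(dim(lab) == expected_shape)) {
    stop(sprintf("mask shape %dx%d does not match expected %dx%d",
                 nrow(lab), ncol(lab), expected_shape[1L], expected_shape[2L]),
         call. = FALSE)
  }
  if (!all(lab %in% 0:3)) {
    stop("mask image contains labels outside the documented encoding 0-3",
         call. = FALSE)
  }
  mask_set(lab)
}

#' Write a mask set as a labeled 8-bit TIFF
#'
#' @param mask A [mask_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_set"))
  h <- mask$hemisphere
  h[mask$vein] <- 3L
  tiff::writeTIFF(h / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> %dx%d: %d brain px (%d left, %d right, %d excluded), %d vein px\n",
              nrow(x$brain), ncol(x$brain), sum(x$brain),
              sum(x$hemisphere == 1L), sum(x$hemisphere == 2L),
              sum(x$hemisphere == 3L), sum(x$vein)))
  invisible(x)
}

# Hemisphere labels (0/1/2/3) for the in-mask pixels, in mask-index order.
hemisphere_labels <- function(mask) {
  mask$hemisphere[mask$brain]
}
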