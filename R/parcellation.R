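# SVD-seeded iterative parcellation, vein exclusion, and hierarchical
# cluster cutting.
#
# Pixels are partitioned by (1) seeding parcels from the signed loadings of
# the leading singular vectors of the pixel-pixel correlation matrix, then
# (2) iterating {parcel mean traces -> pixel-parcel correlations -> argmax
# reassignment} to a fixed point. Parcels are then grouped by average-
# linkage hierarchical clustering on 1 - r of their mean traces, cut at the
# shallowest level yielding at least `min_clusters` clusters.

#' Pixel-pixel Pearson correlation matrix
#'
#' @param hemo A [hemo_stack()] (HbO2 contrast is used).
#' @return Symmetric unit-diagonal matrix over in-mask pixels, with the
#'   linear image indices of the pixels attached as attribute `pixel_index`.
#' @export
pixel_correlation_matrix <- function(hemo) {
  stopifnot(inherits(hemo, "hemo_stack"))
  if (nrow(hemo$hbo2) < 2L) stop("need at least 2 frames", call. = FALSE)
  r <- fast_cor(hemo$hbo2, what = "pixel trace")
  attr(r, "pixel_index") <- mask_indices(hemo$mask$brain)
  r
}

new_parcel_map <- function(assignment, pixel_index, shape, iterations_run = 0L,
                           converged = FALSE, parcel_traces = NULL) {
  structure(list(assignment = as.integer(assignment),
                 pixel_index = as.integer(pixel_index),
                 shape = as.integer(shape),
                 n_parcels = max(assignment, 0L),
                 iterations_run = as.integer(iterations_run),
                 converged = converged,
                 parcel_traces = parcel_traces),
            class = "parcel_map")
}

#' @export
print.parcel_map <- function(x, ...) {
  cat(sprintf("<parcel_map> %d pixels -> %d parcels; %d iterations, %s\n",
              length(x$assignment), x$n_parcels, x$iterations_run,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Raster image of a parcel (or cluster) assignment
#'
#' @param parcels A `parcel_map`.
#' @param values Optional per-pixel values to paint instead of parcel ids.
#' @return Integer/numeric matrix of the map's shape; 0/NA outside.
#' @export
parcel_raster <- function(parcels, values = parcels$assignment) {
  img <- matrix(if (is.integer(values)) 0L else NA_real_,
                parcels$shape[1L], parcels$shape[2L])
  img[parcels$pixel_index] <- values
  img
}

# Compact parcel ids to 1..P (dropping empties); returns the new assignment.
compact_ids <- function(assignment) {
  keep <- sort(unique(assignment[assignment > 0L]))
  match(assignment, keep, nomatch = 0L)
}

#' Seed parcels from the SVD of the correlation matrix
#'
#' Takes the leading `ceiling(n_parcels / 2)` singular vectors of the
#' pixel correlation matrix; each vector spawns a positive and a negative
#' candidate parcel, and every pixel joins the candidate where its signed
#' loading `max(+/- v_j(p), 0)` is largest. The unit-norm singular vectors
#' make raw loadings comparable across vectors; weighting them by the
#' singular values (`weight = "singular"`) is available but lets the top
#' one or two global patterns absorb nearly every pixel, collapsing the
#' seeding. Empty candidates are dropped, so up to
#' `2 * ceiling(n_parcels / 2)` parcels are produced (30 requested -> 15
#' vectors).
#'
#' @param corr Output of [pixel_correlation_matrix()].
#' @param n_parcels Requested parcel count.
#' @param shape Image `(rows, cols)` (defaults to the square root layout of
#'   the correlation attribute; pass explicitly when available).
#' @param weight `"none"` (default) or `"singular"` (scores scaled by the
#'   singular values).
#' @return An initial `parcel_map` (not yet iterated).
#' @export
svd_initial_parcels <- function(corr, n_parcels, shape = NULL,
                                weight = c("none", "singular")) {
  weight <- match.arg(weight)
  n_parcels <- as.integer(n_parcels)
  if (n_parcels < 2L) stop("n_parcels must be at least 2", call. = FALSE)
  m <- as.integer(ceiling(n_parcels / 2))
  sv <- svd(corr, nu = m, nv = 0L)
  scores <- matrix(0, nrow(corr), 2L * m)
  for (j in seq_len(m)) {
    v <- sv$u[, j]
    s <- if (weight == "singular") sv$d[j] else 1
    scores[, 2L * j - 1L] <- s * pmax(v, 0)
    scores[, 2L * j] <- s * pmax(-v, 0)
  }
  assignment <- max.col(scores, ties.method = "first")
  assignment <- compact_ids(assignment)
  if (max(assignment) < 2L) {
    stop("degenerate data: fewer than 2 non-empty initial parcels", call. = FALSE)
  }
  pixidx <- attr(corr, "pixel_index")
  if (is.null(pixidx)) pixidx <- seq_len(nrow(corr))
  if (is.null(shape)) shape <- c(max(pixidx), 1L)
  new_parcel_map(assignment, pixidx, shape)
}

# Parcel mean traces: time x P. Sums accumulate over pixels in index order
# (rowsum), matching a per-parcel rowMeans reference bit for bit.
parcel_mean_traces <- function(x, assignment) {
  counts <- tabulate(assignment)
  sums <- rowsum(t(x), assignment)   # P x time
  t(sums / counts)
}

#' Iterate parcel assignments to a fixed point
#'
#' Repeats {compute parcel mean traces; correlate every pixel trace with
#' every parcel trace; reassign each pixel to its maximum-correlation
#' parcel} until no assignment changes. Ties keep the current parcel if it
#' attains the maximum, otherwise the lowest parcel id wins. Parcels
#' emptied by a pass are dropped between iterations. If an earlier
#' assignment state recurs without reaching a fixed point (oscillation),
#' iteration stops with `converged = FALSE` and a warning.
#'
#' @param hemo A [hemo_stack()].
#' @param initial Initial `parcel_map` (e.g. from [svd_initial_parcels()]).
#' @param max_iter Iteration cap (default 100).
#' @return A `parcel_map` with `parcel_traces`, `iterations_run`, and
#'   `converged` populated.
#' @export
iterate_parcels <- function(hemo, initial, max_iter = 100L) {
  stopifnot(inherits(hemo, "hemo_stack"), inherits(initial, "parcel_map"))
  x <- hemo$hbo2
  if (ncol(x) != length(initial$assignment)) {
    stop("parcel map does not match the stack's pixel count", call. = FALSE)
  }
  a <- compact_ids(initial$assignment)
  seen <- character(0)
  converged <- FALSE
  iter <- 0L
  traces <- parcel_mean_traces(x, a)
  while (iter < max_iter) {
    iter <- iter + 1L
    C <- stats::cor(x, traces)
    best <- max.col(C, ties.method = "first")   # lowest id on exact ties
    mx <- C[cbind(seq_along(best), best)]
    keep_cur <- C[cbind(seq_along(a), a)] >= mx
    new_a <- ifelse(keep_cur, a, best)
    new_a <- compact_ids(new_a)
    if (identical(new_a, a)) {
      converged <- TRUE
      break
    }
    key <- paste(new_a, collapse = ",")
    if (key %in% seen) {
      warning("parcel assignment oscillates; stopping without a fixed point",
              call. = FALSE)
      a <- new_a
      traces <- parcel_mean_traces(x, a)
      break
    }
    seen <- c(seen, key)
    a <- new_a
    traces <- parcel_mean_traces(x, a)
  }
  new_parcel_map(a, initial$pixel_index, initial$shape,
                 iterations_run = iter, converged = converged,
                 parcel_traces = traces)
}

#' Audit the fixed-point property of a parcellation
#'
#' Checks, for every pixel, that the correlation with its own parcel's mean
#' trace is at least the correlation with every other parcel's trace.
#'
#' @param hemo A [hemo_stack()].
#' @param parcels A converged `parcel_map`.
#' @return `TRUE` when the audit passes; otherwise the offending pixel
#'   indices as an integer vector (invisibly `FALSE`-ish, length > 0).
#' @export
audit_parcel_fixed_point <- function(hemo, parcels) {
  x <- hemo$hbo2
  traces <- parcel_mean_traces(x, parcels$assignment)
  C <- stats::cor(x, traces)
  own <- C[cbind(seq_along(parcels$assignment), parcels$assignment)]
  bad <- which(apply(C, 1L, max) > own)
  if (length(bad) == 0L) TRUE else bad
}

#' Parcel centroids
#'
#' @param parcels A `parcel_map`.
#' @return `n_parcels x 2` matrix of (row, col) pixel-centroid coordinates.
#' @export
parcel_centroids <- function(parcels) {
  rc <- pixel_coords(parcels$pixel_index, parcels$shape)
  cbind(row = tapply(rc[, 1L], parcels$assignment, mean),
        col = tapply(rc[, 2L], parcels$assignment, mean))[as.character(seq_len(parcels$n_parcels)), , drop = FALSE]
}

#' Flag vein parcels near the midline
#'
#' Parcels concentrated in the midline column band (pixel centroid inside
#' the band and at least `min_fraction` of their pixels within it), or
#' whose ids are listed explicitly, are flagged as vein; their pixels are
#' returned as a mask so a second parcellation pass can exclude them. The
#' pixel-fraction requirement keeps bilaterally symmetric parcels - whose
#' centroid also sits on the midline but whose pixels do not - from being
#' misflagged.
#'
#' @param parcels A first-pass `parcel_map`.
#' @param midline_band `(first, last)` column range of the midline area.
#' @param parcel_ids Optional explicit parcel ids overriding the band rule.
#' @param min_fraction Minimum fraction of a parcel's pixels inside the
#'   band (default 0.5).
#' @return Logical matrix (image shape) of vein pixels.
#' @export
detect_vein_parcels <- function(parcels, midline_band = NULL, parcel_ids = NULL,
                                min_fraction = 0.5) {
  stopifnot(inherits(parcels, "parcel_map"))
  if (is.null(parcel_ids)) {
    if (is.null(midline_band)) stop("give midline_band or parcel_ids", call. = FALSE)
    if (midline_band[1L] <= 1L && midline_band[2L] >= parcels$shape[2L]) {
      stop("midline band covers the whole image", call. = FALSE)
    }
    cen <- parcel_centroids(parcels)
    cols <- pixel_coords(parcels$pixel_index, parcels$shape)[, 2L]
    in_band <- cols >= midline_band[1L] & cols <= midline_band[2L]
    frac <- tapply(in_band, parcels$assignment, mean)[as.character(seq_len(parcels$n_parcels))]
    parcel_ids <- which(cen[, "col"] >= midline_band[1L] &
                          cen[, "col"] <= midline_band[2L] &
                          frac >= min_fraction)
  }
  vein <- matrix(FALSE, parcels$shape[1L], parcels$shape[2L])
  sel <- parcels$assignment %in% parcel_ids
  vein[parcels$pixel_index[sel]] <- TRUE
  vein
}

#' Drop pixels (e.g. the vein) from a processed stack
#'
#' Removes the given pixels from both contrasts and marks them excluded
#' (hemisphere label 3) in the mask... they remain in the brain outline's
#' vein record for provenance.
#'
#' @param hemo A [hemo_stack()].
#' @param drop_mask Logical matrix of pixels to exclude.
#' @return A `hemo_stack` over the remaining pixels.
#' @export
exclude_pixels <- function(hemo, drop_mask) {
  stopifnot(inherits(hemo, "hemo_stack"))
  idx <- mask_indices(hemo$mask$brain)
  drop <- drop_mask[idx]
  if (!any(drop)) return(hemo)
  h <- hemo$mask$hemisphere
  h[drop_mask & hemo$mask$brain] <- 0L
  vein <- hemo$mask$vein | (drop_mask & hemo$mask$brain)
  vein[h == 0L] <- FALSE
  newmask <- mask_set(h, vein)
  out <- hemo_stack(hemo$hbo2[, !drop, drop = FALSE],
                    hemo$hbr[, !drop, drop = FALSE],
                    newmask, hemo$frame_rate_hz,
                    censored_frames = hemo$censored_frames,
                    frames_kept = hemo$frames_kept,
                    provenance = hemo$provenance)
  add_provenance(out, "exclude_pixels", list(n_dropped = sum(drop)))
}

#' Hierarchical clustering of parcels with a minimal-depth cut
#'
#' Distance is `1 - r` between parcel mean traces; the average-linkage tree
#' is cut at the largest merge height whose induced partition still has at
#' least `min_clusters` clusters (the shallowest qualifying grouping
#' level). Cluster ids are contiguous, ordered by first parcel appearance.
#'
#' @param parcel_traces `time x parcel` matrix of mean traces.
#' @param min_clusters Minimum cluster count (default 8).
#' @param method Linkage passed to [stats::hclust()] (default "average").
#' @return A `cluster_assignment`: `parcel_to_cluster`, `linkage`
#'   ([stats::hclust()] tree), `cut_height`, `n_clusters`, `min_clusters`.
#' @export
cluster_parcels <- function(parcel_traces, min_clusters = 8L, method = "average") {
  p <- ncol(parcel_traces)
  min_clusters <- as.integer(min_clusters)
  if (min_clusters > p) {
    stop(sprintf("min_clusters (%d) exceeds the number of parcels (%d)",
                 min_clusters, p), call. = FALSE)
  }
  d <- stats::as.dist(1 - fast_cor(parcel_traces, what = "parcel trace"))
  tree <- stats::hclust(d, method = method)
  if (min_clusters == p) {
    membership <- seq_len(p)
    cut_height <- if (length(tree$height) > 0L) min(tree$height) / 2 else 0
  } else {
    # candidate cut heights; choose the largest with >= min_clusters clusters
    uh <- sort(unique(tree$height), decreasing = TRUE)
    cut_height <- NA_real_
    membership <- NULL
    for (h in uh) {
      mem <- stats::cutree(tree, h = h)
      if (max(mem) >= min_clusters) {
        cut_height <- h
        membership <- mem
        break
      }
    }
    if (is.null(membership)) {   # only cutting below every merge qualifies
      membership <- seq_len(p)
      cut_height <- min(tree$height) / 2
    }
  }
  structure(list(parcel_to_cluster = as.integer(membership),
                 linkage = tree,
                 cut_height = cut_height,
                 n_clusters = max(membership),
                 min_clusters = min_clusters),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d parcels -> %d clusters (cut height %.4g, min %d)\n",
              length(x$parcel_to_cluster), x$n_clusters, x$cut_height,
              x$min_clusters))
  if (!is.null(x$hemisphere_split)) {
    cat("  hemisphere split:", nrow(x$hemisphere_split), "parcels reordered\n")
  }
  invisible(x)
}

#' Split clusters by hemisphere and derive the canonical parcel order
#'
#' Each parcel is assigned the hemisphere holding the majority of its
#' pixels (exact ties go left, with a warning); every cluster is split into
#' hemisphere-specific groups. The canonical ordering is geometry-derived,
#' hence invariant to input parcel numbering: left hemisphere first, then
#' right; within a hemisphere, clusters sorted by mean anterior-posterior
#' (row) centroid; within a cluster, parcels by their own centroid.
#'
#' @param clusters A [cluster_parcels()] result.
#' @param parcels The `parcel_map` the clusters were built from.
#' @param mask The [mask_set()] carrying hemisphere labels.
#' @return `clusters` with a `hemisphere_split` data.frame (`parcel`,
#'   `hemisphere`, `cluster`, `hemi_cluster`, `order`) attached.
#' @export
split_clusters_by_hemisphere <- function(clusters, parcels, mask) {
  stopifnot(inherits(clusters, "cluster_assignment"),
            inherits(parcels, "parcel_map"), inherits(mask, "mask_set"))
  labs <- mask$hemisphere[parcels$pixel_index]
  P <- parcels$n_parcels
  hemi <- integer(P)
  for (p in seq_len(P)) {
    sel <- parcels$assignment == p
    nl <- sum(labs[sel] == 1L); nr <- sum(labs[sel] == 2L)
    if (nl == nr) {
      warning(sprintf("parcel %d split 50/50 across hemispheres; assigned left", p),
              call. = FALSE)
    }
    hemi[p] <- if (nl >= nr) 1L else 2L
  }
  cen <- parcel_centroids(parcels)
  df <- data.frame(parcel = seq_len(P),
                   hemisphere = c("left", "right")[hemi],
                   cluster = clusters$parcel_to_cluster,
                   centroid_row = cen[, "row"],
                   centroid_col = cen[, "col"],
                   stringsAsFactors = FALSE)
  # hemisphere-specific cluster ids and the geometry-derived ordering
  grp <- paste(df$hemisphere, df$cluster)
  cl_row <- tapply(df$centroid_row, grp, mean)[grp]
  ord <- order(hemi, cl_row, df$centroid_row, df$centroid_col)
  df$order <- match(seq_len(P), ord)
  hemi_key <- unique(grp[ord])
  df$hemi_cluster <- match(grp, hemi_key)
  clusters$hemisphere_split <- df[, c("parcel", "hemisphere", "cluster",
                                      "hemi_cluster", "centroid_row",
                                      "centroid_col", "order")]
  clusters
}

#' Divide the cluster map by hemisphere at pixel level
#'
#' Homotopic correlations can be strong enough that a parcel (and hence a
#' cluster) spans both hemispheres; dividing the parcellation map itself by
#' hemisphere yields hemisphere-specific groups even then. Every
#' (cluster, pixel-hemisphere) combination becomes one group; pixels with
#' an excluded hemisphere label get 0.
#'
#' @param parcels A `parcel_map`.
#' @param clusters A [cluster_parcels()] result.
#' @param mask The [mask_set()] carrying hemisphere labels.
#' @return Integer vector over the parcellation's pixels: hemisphere-
#'   specific cluster id (contiguous, left groups first within a cluster),
#'   0 for excluded pixels.
#' @export
hemi_cluster_map <- function(parcels, clusters, mask) {
  stopifnot(inherits(parcels, "parcel_map"),
            inherits(clusters, "cluster_assignment"))
  cl <- clusters$parcel_to_cluster[parcels$assignment]
  hemi <- mask$hemisphere[parcels$pixel_index]
  ok <- hemi %in% c(1L, 2L) & !is.na(cl)
  key <- ifelse(ok, cl * 2L + (hemi - 1L), NA_integer_)
  ids <- sort(unique(key[ok]))
  out <- match(key, ids, nomatch = 0L)
  out[is.na(key)] <- 0L
  out
}

#' Run the full parcellation stage
#'
#' First pass: SVD seeding and iteration over all in-mask pixels; vein
#' parcels are detected in the configured midline band and their pixels
#' excluded; second pass re-runs seeding and iteration on the remaining
#' pixels; parcels are then clustered and split by hemisphere.
#'
#' @param hemo A preprocessed [hemo_stack()].
#' @param config A [run_config()].
#' @param midline_band `(first, last)` columns of the vein search band;
#'   default: the middle 10% of the image. Set `NULL` to skip vein
#'   exclusion.
#' @param max_iter Iteration cap per pass.
#' @return List: `parcels` (`parcel_map`), `clusters`
#'   (`cluster_assignment` with hemisphere split), `vein_mask`, and the
#'   post-exclusion `hemo`.
#' @export
parcellate <- function(hemo, config = run_config(), midline_band = "auto",
                       max_iter = 100L) {
  stopifnot(inherits(hemo, "hemo_stack"))
  shape <- dim(hemo$mask$brain)
  if (identical(midline_band, "auto")) {
    w <- max(1L, round(0.05 * shape[2L]))
    mid <- (shape[2L] + 1) / 2
    midline_band <- c(floor(mid - w), ceiling(mid + w))
  }
  run_pass <- function(h) {
    corr <- pixel_correlation_matrix(h)
    init <- svd_initial_parcels(corr, config$n_parcels, shape = shape)
    iterate_parcels(h, init, max_iter = max_iter)
  }
  vein_mask <- matrix(FALSE, shape[1L], shape[2L])
  if (!is.null(midline_band)) {
    first_pass <- run_pass(hemo)
    vein_mask <- detect_vein_parcels(first_pass, midline_band = midline_band)
    hemo <- exclude_pixels(hemo, vein_mask)
  }
  parcels <- run_pass(hemo)
  clusters <- cluster_parcels(parcels$parcel_traces, config$min_clusters)
  clusters <- split_clusters_by_hemisphere(clusters, parcels, hemo$mask)
  list(parcels = parcels, clusters = clusters, vein_mask = vein_mask,
       hemo = hemo)
}

#' Export the parcel/cluster table
#'
#' @param parcels A `parcel_map`.
#' @param clusters A `cluster_assignment` with hemisphere split.
#' @param path Optional CSV output path.
#' @return The table (`parcel_id`, `cluster_id`, `hemi_cluster`,
#'   `hemisphere`, `centroid_row`, `centroid_col`), invisibly written to
#'   `path` when given.
#' @export
cluster_table <- function(parcels, clusters, path = NULL) {
  df <- clusters$hemisphere_split
  out <- data.frame(parcel_id = df$parcel,
                    cluster_id = df$cluster,
                    hemi_cluster = df$hemi_cluster,
                    hemisphere = df$hemisphere,
                    centroid_row = df$centroid_row,
                    centroid_col = df$centroid_col)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
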