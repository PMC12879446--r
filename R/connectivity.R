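# Parcel-, cluster- and region-level connectivity: labeled correlation
# matrices, hemisphere/cluster reordering with addressable quadrants,
# homotopic pair extraction, and seed-based pixel correlation maps.

#' Construct a labeled correlation matrix
#'
#' @param values Symmetric unit-diagonal numeric matrix.
#' @param labels data.frame with one row per unit; recognised columns:
#'   `id`, `hemisphere`, `cluster`, `region`.
#' @param level One of `"pixel"`, `"parcel"`, `"cluster"`, `"region"`.
#' @param ordering Short description of the row/column sort key.
#' @return A `corr_matrix` (a numeric matrix with label attributes).
#' @export
corr_matrix_from_values <- function(values, labels = NULL, level = "region",
                                    ordering = "input") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-8) stop("matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(values) - 1)) > 1e-8) stop("diagonal must be 1", call. = FALSE)
  if (min(values) < -1 - 1e-8 || max(values) > 1 + 1e-8) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  if (is.null(labels)) labels <- data.frame(id = seq_len(nrow(values)))
  if (nrow(labels) != nrow(values)) stop("one label row per unit required", call. = FALSE)
  structure(values, labels = labels, level = level, ordering = ordering,
            class = c("corr_matrix", class(values)))
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("<corr_matrix> %dx%d at %s level (ordering: %s)\n",
              nrow(x), ncol(x), attr(x, "level"), attr(x, "ordering")))
  invisible(x)
}

#' Mean traces of pixel groups
#'
#' Averages the HbO2 traces of every unit's member pixels (pixel-level
#' averaging; switch `from = "hbr"` for the deoxy contrast).
#'
#' @param hemo A [hemo_stack()].
#' @param membership Integer vector over in-mask pixels: unit id per pixel,
#'   0 = unassigned. Every unit 1..max must be non-empty.
#' @param from Contrast to average (`"hbo2"` or `"hbr"`).
#' @return `time x unit` matrix of mean traces.
#' @export
unit_traces <- function(hemo, membership, from = c("hbo2", "hbr")) {
  from <- match.arg(from)
  x <- hemo[[from]]
  membership <- as.integer(membership)
  if (length(membership) != ncol(x)) {
    stop("membership must have one entry per in-mask pixel", call. = FALSE)
  }
  nu <- max(membership, 0L)
  if (nu < 1L) stop("no units defined", call. = FALSE)
  counts <- tabulate(membership, nbins = nu)
  if (any(counts == 0L)) {
    stop("empty unit(s): ", paste(which(counts == 0L), collapse = ", "),
         call. = FALSE)
  }
  sel <- membership > 0L
  tr <- parcel_mean_traces(x[, sel, drop = FALSE], membership[sel])
  colnames(tr) <- NULL
  tr
}

#' Correlation matrix of unit traces
#'
#' @param traces `time x unit` matrix (e.g. [unit_traces()] output).
#' @param labels Optional label data.frame (see [corr_matrix_from_values()]).
#' @param level Level tag for the result.
#' @return A `corr_matrix`.
#' @export
correlation_matrix <- function(traces, labels = NULL, level = "region") {
  if (nrow(traces) < 2L) stop("need at least 2 frames", call. = FALSE)
  corr_matrix_from_values(fast_cor(traces, what = "unit trace"),
                          labels = labels, level = level)
}

#' Reorder a correlation matrix by hemisphere and cluster
#'
#' Permutes units so the left hemisphere block comes first, grouped by
#' cluster within each hemisphere (and by the labels' `order` column when
#' present). The permutation is attached as attribute `permutation`;
#' quadrants are addressable with [corr_quadrant()].
#'
#' @param corr A `corr_matrix` whose labels carry `hemisphere` and
#'   `cluster` columns.
#' @param clusters Optional `cluster_assignment` with hemisphere split,
#'   used to derive the order for parcel-level matrices.
#' @return The reordered `corr_matrix`.
#' @export
reorder_by_hemisphere_cluster <- function(corr, clusters = NULL) {
  lab <- attr(corr, "labels")
  if (!is.null(clusters)) {
    hs <- clusters$hemisphere_split
    if (nrow(hs) != nrow(corr)) stop("cluster table does not match matrix size", call. = FALSE)
    perm <- order(hs$order)
    lab <- data.frame(id = hs$parcel, hemisphere = hs$hemisphere,
                      cluster = hs$cluster, hemi_cluster = hs$hemi_cluster)[perm, ]
  } else {
    if (is.null(lab$hemisphere) || is.null(lab$cluster)) {
      stop("labels must carry hemisphere and cluster columns", call. = FALSE)
    }
    hnum <- match(lab$hemisphere, c("left", "right"))
    if (anyNA(hnum)) stop("unlabeled unit(s): hemisphere must be left/right", call. = FALSE)
    ord_col <- if (!is.null(lab$order)) lab$order else seq_len(nrow(lab))
    perm <- order(hnum, lab$cluster, ord_col)
    lab <- lab[perm, ]
  }
  out <- corr_matrix_from_values(unclass(corr)[perm, perm, drop = FALSE],
                                 labels = lab, level = attr(corr, "level"),
                                 ordering = "hemisphere,cluster")
  attr(out, "permutation") <- perm
  out
}

#' Address a quadrant of a hemisphere-ordered correlation matrix
#'
#' @param corr A [reorder_by_hemisphere_cluster()] result.
#' @param which `"left"` (within-left block), `"right"`, or `"cross"`
#'   (left rows x right columns).
#' @return The quadrant as a plain matrix with label attributes
#'   `row_labels`/`col_labels`.
#' @export
corr_quadrant <- function(corr, which = c("left", "right", "cross")) {
  which <- match.arg(which)
  lab <- attr(corr, "labels")
  li <- lab$hemisphere == "left"
  ri <- lab$hemisphere == "right"
  sel <- switch(which,
                left = list(r = li, c = li),
                right = list(r = ri, c = ri),
                cross = list(r = li, c = ri))
  q <- unclass(corr)[sel$r, sel$c, drop = FALSE]
  attr(q, "row_labels") <- lab[sel$r, , drop = FALSE]
  attr(q, "col_labels") <- lab[sel$c, , drop = FALSE]
  q
}

#' Build a region table with homotopic partners
#'
#' @param region data.frame with columns `region` (id), `name`,
#'   `hemisphere` (`"left"`/`"right"`). Regions sharing a name across
#'   hemispheres are declared homotopic partners.
#' @return A `region_table` (the data.frame plus a `partner` column: the
#'   partner's region id or `NA`).
#' @export
region_table <- function(region) {
  stopifnot(all(c("region", "name", "hemisphere") %in% names(region)))
  if (anyDuplicated(region[, c("name", "hemisphere")])) {
    stop("at most one region per (name, hemisphere)", call. = FALSE)
  }
  partner <- rep(NA_integer_, nrow(region))
  for (i in seq_len(nrow(region))) {
    j <- which(region$name == region$name[i] &
                 region$hemisphere != region$hemisphere[i])
    if (length(j) == 1L) partner[i] <- region$region[j]
  }
  region$partner <- partner
  structure(region, class = c("region_table", "data.frame"))
}

#' Split correlations into homotopic and non-homotopic pairs
#'
#' Homotopic values are `r(region, partner)`, once per pair. Non-homotopic
#' values are all remaining unique off-diagonal pairs, each tagged by
#' whether the two regions lie in the same hemisphere (`"within"`) or
#' opposite hemispheres (`"cross"`); together the two groups exhaust the
#' `n(n-1)/2` unit pairs.
#'
#' @param corr A `corr_matrix` whose labels carry region ids matching
#'   `table$region`.
#' @param table A [region_table()].
#' @return List: `homotopic` (named numeric), `non_homotopic` (data.frame
#'   `region_a`, `region_b`, `r`, `category`).
#' @export
extract_homotopic <- function(corr, table) {
  lab <- attr(corr, "labels")
  ids <- if (!is.null(lab$region)) lab$region else lab$id
  pos <- match(table$region, ids)
  if (anyNA(pos[!is.na(table$partner)])) {
    stop("region(s) with a declared partner missing from the matrix", call. = FALSE)
  }
  n <- nrow(corr)
  hemi <- table$hemisphere[match(ids, table$region)]
  partner_of <- table$partner[match(ids, table$region)]
  homo <- numeric(0)
  hn <- character(0)
  nh_a <- nh_b <- integer(0); nh_r <- numeric(0); nh_cat <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (!is.na(partner_of[i]) && partner_of[i] == ids[j]) {
        homo <- c(homo, unclass(corr)[i, j])
        hn <- c(hn, table$name[match(ids[i], table$region)])
      } else {
        nh_a <- c(nh_a, ids[i]); nh_b <- c(nh_b, ids[j])
        nh_r <- c(nh_r, unclass(corr)[i, j])
        nh_cat <- c(nh_cat, if (!is.na(hemi[i]) && !is.na(hemi[j]) &&
                                hemi[i] == hemi[j]) "within" else "cross")
      }
    }
  }
  names(homo) <- hn
  list(homotopic = homo,
       non_homotopic = data.frame(region_a = nh_a, region_b = nh_b, r = nh_r,
                                  category = nh_cat, stringsAsFactors = FALSE))
}

#' Pooled homotopic / non-homotopic pair counts across subjects
#'
#' Given each subject's bilaterally paired region names, counts the pooled
#' homotopic pairs (one per name) and the pooled within-hemisphere
#' non-homotopic pairs (`m * (m - 1)` for `m` names, i.e. distinct-name
#' pairs in each hemisphere).
#'
#' @param region_sets List of character vectors: each subject's region
#'   names (present in both hemispheres).
#' @return Named integer vector `c(homotopic = ..., non_homotopic = ...)`.
#' @export
pooled_pair_counts <- function(region_sets) {
  m <- vapply(region_sets, function(s) length(unique(s)), integer(1L))
  c(homotopic = sum(m), non_homotopic = sum(m * (m - 1L)))
}

#' Example per-subject region coverage
#'
#' The region sets seen by each of 8 subjects in a two-placement imaging
#' design (rostral windows add the nidopallium edge; caudal windows cover
#' more hippocampal formation), consistent with per-region bilateral-pair
#' multiplicities nidopallium 2, mesopallium 7, somatosensory Wulst 8,
#' visual Wulst 8, hippocampal formation 5. This coverage table is a
#' synthetic reconstruction for bookkeeping checks, not measured data.
#'
#' @return Named list of 8 character vectors.
#' @export
example_subject_regions <- function() {
  ssw <- "somatosensory Wulst"; vw <- "visual Wulst"
  hip <- "hippocampal formation"; mes <- "mesopallium"; nid <- "nidopallium"
  list(caudal_1 = c(ssw, vw, hip, mes),
       caudal_2 = c(ssw, vw, hip, mes),
       caudal_3 = c(ssw, vw, hip, mes),
       caudal_4 = c(ssw, vw, hip, mes),
       caudal_5 = c(ssw, vw, hip, mes),
       rostral_1 = c(ssw, vw, mes, nid),
       rostral_2 = c(ssw, vw, mes),
       rostral_3 = c(ssw, vw, nid))
}

#' Seed-based pixel correlation map
#'
#' Correlates the mean HbO2 trace of a seed pixel set against every in-mask
#' pixel trace.
#'
#' @param hemo A [hemo_stack()].
#' @param seed_pixels Logical matrix (image shape), logical vector over
#'   in-mask pixels, or integer indices into the in-mask pixel set.
#' @return Numeric matrix of the image shape: `r` inside the mask, `NA`
#'   (sentinel) outside.
#' @export
seed_correlation_map <- function(hemo, seed_pixels) {
  stopifnot(inherits(hemo, "hemo_stack"))
  npix <- ncol(hemo$hbo2)
  if (is.matrix(seed_pixels)) {
    seed_pixels <- seed_pixels[mask_indices(hemo$mask$brain)]
  }
  sel <- if (is.logical(seed_pixels)) which(seed_pixels) else as.integer(seed_pixels)
  if (length(sel) == 0L || any(sel < 1L) || any(sel > npix)) {
    stop("seed must be a non-empty subset of in-mask pixels", call. = FALSE)
  }
  g <- rowMeans(hemo$hbo2[, sel, drop = FALSE])
  if (stats::sd(g) == 0) stop("zero-variance seed trace", call. = FALSE)
  r <- as.vector(stats::cor(g, hemo$hbo2))
  img <- matrix(NA_real_, dim(hemo$mask$brain)[1L], dim(hemo$mask$brain)[2L])
  img[mask_indices(hemo$mask$brain)] <- r
  img
}
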