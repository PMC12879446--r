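# Consistency and contrast statistics: matrix-shuffling randomization tests
# with ECDF quantiles, split-half stability, a Kolmogorov-Smirnov normality
# screen, and the Wilcoxon rank-sum contrast of homotopic vs non-homotopic
# correlations.

# Unique off-diagonal entries of a symmetric matrix (upper triangle,
# column-major), and the inverse write-back.
upper_entries <- function(m) m[upper.tri(m)]

write_upper <- function(m, v) {
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Mean absolute difference between two correlation matrices
#'
#' Mean over the unique off-diagonal pairs of `|a_ij - b_ij|` - the
#' dissimilarity ("matrix delta") used by the randomization tests.
#'
#' @param a,b `corr_matrix` objects (or plain symmetric matrices) with
#'   matching labels and size.
#' @return Scalar delta.
#' @export
matrix_delta <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("matrix size mismatch", call. = FALSE)
  la <- attr(a, "labels"); lb <- attr(b, "labels")
  if (!is.null(la) && !is.null(lb) && !isTRUE(all.equal(la$id, lb$id))) {
    stop("matrix labels do not match", call. = FALSE)
  }
  mean(abs(upper_entries(unclass(a)) - upper_entries(unclass(b))))
}

#' Shuffle a correlation matrix
#'
#' Randomly permutes the unique off-diagonal entries and writes them back
#' symmetrically; the diagonal and the off-diagonal value multiset are
#' preserved.
#'
#' @param corr A square symmetric matrix (n >= 3).
#' @param seed Integer seed.
#' @return The shuffled matrix (same class/attributes).
#' @export
shuffle_matrix <- function(corr, seed = 1L) {
  if (nrow(corr) < 3L) stop("shuffling needs n >= 3", call. = FALSE)
  v <- upper_entries(unclass(corr))
  vs <- with_seed(seed, sample(v))
  out <- write_upper(unclass(corr), vs)
  attributes(out) <- attributes(corr)
  out[upper.tri(out)] <- vs
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

new_randomization_result <- function(observed_delta, null_deltas, n_shuffles,
                                     pair_ids, seed) {
  structure(list(observed_delta = observed_delta,
                 null_deltas = null_deltas,
                 quantile = mean(null_deltas <= observed_delta),
                 n_shuffles = as.integer(n_shuffles),
                 pair_ids = pair_ids,
                 seed = as.integer(seed)),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("<randomization_result> observed delta %.4f, ECDF quantile %.4g (%d pairs x %d shuffles)\n",
              x$observed_delta, x$quantile, length(x$pair_ids), x$n_shuffles))
  invisible(x)
}

# Shared machinery: observed group-mean delta vs pooled shuffle null.
randomization_test <- function(mats, n_shuffles, seed) {
  n <- length(mats)
  pairs <- utils::combn(n, 2L)
  observed <- mean(apply(pairs, 2L, function(p) matrix_delta(mats[[p[1L]]], mats[[p[2L]]])))
  vs <- lapply(mats, function(m) upper_entries(unclass(m)))
  null_deltas <- with_seed(seed, {
    unlist(lapply(seq_len(ncol(pairs)), function(k) {
      va <- vs[[pairs[1L, k]]]; vb <- vs[[pairs[2L, k]]]
      vapply(seq_len(n_shuffles), function(s) {
        mean(abs(sample(va) - sample(vb)))   # both matrices shuffled per draw
      }, numeric(1L))
    }))
  })
  pair_ids <- apply(pairs, 2L, paste, collapse = "-")
  new_randomization_result(observed, null_deltas, n_shuffles, pair_ids, seed)
}

#' Between-individual consistency randomization test
#'
#' Observed statistic: the group mean of the matrix deltas over all
#' unordered pairs of individuals. Null: for every pair and each of
#' `n_shuffles` repetitions, both matrices are independently shuffled
#' ([shuffle_matrix()] semantics) and their delta recorded; nulls are
#' pooled across pairs. The reported quantile is the empirical CDF of the
#' pooled null evaluated at the observed delta - small quantiles mean the
#' individuals are more similar than chance.
#'
#' @param matrices List (length >= 2) of label-compatible `corr_matrix`
#'   objects, one per individual.
#' @param n_shuffles Shuffles per pair (default 1000).
#' @param seed Integer seed.
#' @return A `randomization_result`.
#' @export
between_individual_test <- function(matrices, n_shuffles = 1000L, seed = 1L) {
  if (length(matrices) < 2L) stop("need at least 2 individuals", call. = FALSE)
  sizes <- vapply(matrices, nrow, integer(1L))
  if (length(unique(sizes)) != 1L) {
    stop("individuals have incompatible matrix sizes: ",
         paste(sizes, collapse = ", "), call. = FALSE)
  }
  ids <- lapply(matrices, function(m) {
    lab <- attr(m, "labels"); if (is.null(lab)) NULL else lab$id
  })
  ref <- ids[[1L]]
  if (!is.null(ref)) {
    bad <- which(!vapply(ids, function(x) isTRUE(all.equal(x, ref)), logical(1L)))
    if (length(bad) > 0L) {
      stop("individuals with incompatible labels: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  randomization_test(matrices, n_shuffles, seed)
}

#' Split-half stability test
#'
#' Splits the retained frames into first and second halves, computes the
#' region correlation matrix of each half, and applies the
#' [between_individual_test()] machinery to the resulting pair: small
#' quantiles mean the two halves are more similar than shuffled matrices
#' would be.
#'
#' @param hemo A [hemo_stack()] (censoring already applied; the split
#'   respects the retained frames).
#' @param membership Pixel-to-region membership (see [unit_traces()]).
#' @param table Optional [region_table()] used only for labels.
#' @param n_shuffles,seed Randomization parameters.
#' @return A `randomization_result`.
#' @export
split_half_test <- function(hemo, membership, table = NULL,
                            n_shuffles = 1000L, seed = 1L) {
  nt <- nrow(hemo$hbo2)
  if (nt < 4L) stop("need at least 4 frames to split", call. = FALSE)
  cut <- nt %/% 2L
  halves <- lapply(list(seq_len(cut), (cut + 1L):nt), function(rows) {
    h <- hemo
    h$hbo2 <- h$hbo2[rows, , drop = FALSE]
    h$hbr <- h$hbr[rows, , drop = FALSE]
    tr <- unit_traces(h, membership)
    labels <- if (!is.null(table)) {
      data.frame(id = table$region, region = table$region,
                 hemisphere = table$hemisphere)
    } else NULL
    correlation_matrix(tr, labels = labels)
  })
  randomization_test(halves, n_shuffles, seed)
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of the standardized values against a standard
#' normal; used to justify rank-based contrasts downstream.
#'
#' @param values Numeric vector (n >= 5, nonzero variance).
#' @return List with `statistic` and `p`.
#' @export
normality_check <- function(values) {
  if (length(values) < 5L) stop("need at least 5 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("zero-variance sample", call. = FALSE)
  z <- (values - mean(values)) / s
  kt <- suppressWarnings(stats::ks.test(z, "pnorm"))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test with midranks for ties. For `n1 + n2 <= 10` the
#' p-value is computed by full enumeration of all rank arrangements
#' (`P(|W - E[W]| >= |w - E[W]|)`, valid with ties); otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#' The z score is always reported from the normal approximation, matching
#' the convention of reporting `z` alongside rank-sum p-values: swapping
#' the samples negates `z` and preserves `p`.
#'
#' @param x,y Numeric samples (non-empty).
#' @return A `rank_sum_result`: `statistic` (rank sum of `x`), `z_value`,
#'   `p_two_sided`, `n1`, `n2`, `method`.
#' @export
rank_sum_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)   # midranks
  W <- sum(r[seq_len(n1)])
  N <- n1 + n2
  EW <- n1 * (N + 1) / 2

  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  varW <- n1 * n2 / 12 * (N + 1 - tie_term)

  degenerate <- varW <= 0
  z <- if (degenerate) 0 else {
    # continuity-corrected normal approximation
    adj <- if (W > EW) -0.5 else if (W < EW) 0.5 else 0
    (W - EW + adj) / sqrt(varW)
  }

  if (degenerate) {
    p <- 1
    method <- "degenerate"
  } else if (N <= 10L) {
    combos <- utils::combn(N, n1)
    Ws <- colSums(matrix(r[combos], nrow = n1))
    p <- mean(abs(Ws - EW) >= abs(W - EW) - 1e-12)
    method <- "exact"
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  structure(list(statistic = W, z_value = z, p_two_sided = p,
                 n1 = n1, n2 = n2, method = method),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("<rank_sum_result> W = %g, z = %.3f, two-sided p = %.4g (%s; n = %d, %d)\n",
              x$statistic, x$z_value, x$p_two_sided, x$method, x$n1, x$n2))
  invisible(x)
}

#' Homotopic vs non-homotopic contrast
#'
#' Convenience wrapper: extracts homotopic and non-homotopic correlation
#' values from a region matrix, screens normality, and runs the rank-sum
#' contrast (homotopic sample first, so strong homotopic correlations give
#' a large positive rank sum).
#'
#' @param corr A region-level `corr_matrix`.
#' @param table A [region_table()].
#' @param non_homotopic_category Which non-homotopic pairs enter the
#'   contrast: `"all"`, `"within"` hemisphere, or `"cross"`.
#' @return List: `homotopic`, `non_homotopic` (values), `normality`,
#'   `rank_sum` (a `rank_sum_result`).
#' @export
homotopic_contrast <- function(corr, table,
                               non_homotopic_category = c("all", "within", "cross")) {
  non_homotopic_category <- match.arg(non_homotopic_category)
  ex <- extract_homotopic(corr, table)
  nh <- ex$non_homotopic
  if (non_homotopic_category != "all") {
    nh <- nh[nh$category == non_homotopic_category, , drop = FALSE]
  }
  vals <- c(ex$homotopic, nh$r)
  normality <- if (length(vals) >= 5L && stats::sd(vals) > 0) {
    normality_check(vals)
  } else NULL
  list(homotopic = ex$homotopic, non_homotopic = nh$r,
       normality = normality,
       rank_sum = rank_sum_test(ex$homotopic, nh$r))
}
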