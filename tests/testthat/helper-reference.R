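# Independent reference implementations used as oracles. These deliberately
# recompute everything with explicit loops and base building blocks, with no
# caching or vectorized shortcuts shared with the package code.

# Naive Pearson matrix via pairwise stats::cor calls.
ref_cor_matrix <- function(x) {
  n <- ncol(x)
  r <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) r[i, j] <- stats::cor(x[, i], x[, j])
    }
  }
  r
}

# Brute-force iterative parcellation: recompute parcel means and pixel-parcel
# correlations from scratch each pass, same tie rules as documented (keep
# current on ties, else lowest parcel id).
ref_iterate_parcels <- function(x, assignment, max_iter = 100L) {
  compact <- function(a) match(a, sort(unique(a[a > 0L])), nomatch = 0L)
  a <- compact(as.integer(assignment))
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    P <- max(a)
    traces <- matrix(0, nrow(x), P)
    for (p in seq_len(P)) {
      traces[, p] <- rowMeans(x[, a == p, drop = FALSE])
    }
    new_a <- integer(length(a))
    for (i in seq_along(a)) {
      cs <- numeric(P)
      for (p in seq_len(P)) cs[p] <- stats::cor(x[, i], traces[, p])
      mx <- max(cs)
      new_a[i] <- if (cs[a[i]] >= mx) a[i] else which(cs == mx)[1L]
    }
    new_a <- compact(new_a)
    if (identical(new_a, a)) {
      converged <- TRUE
      break
    }
    a <- new_a
  }
  list(assignment = a, iterations = iter, converged = converged)
}

# Masked-normalized Gaussian smoothing oracle: zero-fill outside the mask,
# convolve value and mask images separately with explicit loops, divide.
ref_masked_smooth <- function(img, brain, kernel_size, sigma) {
  h <- kernel_size %/% 2L
  rows <- nrow(img); cols <- ncol(img)
  out <- matrix(0, rows, cols)
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      if (!brain[r, cc]) next
      num <- 0; den <- 0
      for (dr in -h:h) {
        for (dc in -h:h) {
          r2 <- r + dr; c2 <- cc + dc
          if (r2 >= 1 && r2 <= rows && c2 >= 1 && c2 <= cols && brain[r2, c2]) {
            w <- exp(-(dr^2 + dc^2) / (2 * sigma^2))
            num <- num + w * img[r2, c2]
            den <- den + w
          }
        }
      }
      out[r, cc] <- num / den
    }
  }
  out
}

# Mean absolute off-diagonal difference via a double loop.
ref_matrix_delta <- function(a, b) {
  n <- nrow(a)
  acc <- 0; cnt <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      acc <- acc + abs(a[i, j] - b[i, j])
      cnt <- cnt + 1
    }
  }
  acc / cnt
}

# Build a hemo_stack directly from trace matrices (bypasses the optics),
# for parcellation/connectivity unit tests. `region_map` assigns one trace
# column per region id; pixels get their region's trace plus iid noise.
make_trace_hemo <- function(region_map, traces, noise_sd = 0.1, seed = 1L,
                            frame_rate_hz = 8) {
  hemi <- matrix(0L, nrow(region_map), ncol(region_map))
  hemi[region_map > 0L] <- ifelse(
    col(region_map)[region_map > 0L] <= ncol(region_map) / 2, 1L, 2L)
  mask <- mask_set(hemi)
  idx <- which(as.vector(mask$brain))
  reg <- as.vector(region_map)[idx]
  nt <- nrow(traces)
  set.seed(seed)
  x <- traces[, reg, drop = FALSE] +
    matrix(rnorm(nt * length(idx), sd = noise_sd), nt, length(idx))
  hemo_stack(x, -0.7 * x, mask, frame_rate_hz)
}
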