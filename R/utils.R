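# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions never clobber a user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Column-standardize a time x unit matrix: zero mean, unit (n-1) variance.
# Errors (or returns the offending columns) when a column is constant.
standardize_cols <- function(x, what = "series") {
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  ss <- sqrt(colSums(xc^2) / (n - 1))
  bad <- which(ss <= 0 | !is.finite(ss))
  if (length(bad) > 0L) {
    stop(sprintf("zero-variance %s at %d column(s): %s", what, length(bad),
                 paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  sweep(xc, 2L, ss, "/")
}

# Pearson correlation of all column pairs via BLAS; x is time x unit.
fast_cor <- function(x, what = "series") {
  z <- standardize_cols(x, what = what)
  r <- crossprod(z) / (nrow(z) - 1)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

# Linear pixel indices (column-major, 1-based) of TRUE cells in a mask matrix.
mask_indices <- function(m) which(as.vector(m))

# Row/col coordinates for linear pixel indices in an nrow x ncol image.
pixel_coords <- function(idx, shape) {
  rows <- ((idx - 1L) %% shape[1L]) + 1L
  cols <- ((idx - 1L) %/% shape[1L]) + 1L
  cbind(row = rows, col = cols)
}

# Deterministic sub-seed derivation, kept well below .Machine$integer.max.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1009) %% 2147483647)
}
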