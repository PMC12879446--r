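# Synthetic-data generator: bilaterally mirrored region layouts, band-limited
# latent time courses with a prescribed correlation structure, and a forward
# Beer-Lambert optics model with realistic nuisance components (second-order
# temporal drift, smooth vignetting, a midline vein stripe carrying its own
# signal, per-hemisphere nuisance traces, pixel noise, quantization).
#
# The generator defines the package's study conditions: every downstream
# stage is validated against its known ground truth.

#' Build a mirrored region layout
#'
#' Places `n_regions_per_hemisphere` elliptical regions in anterior-posterior
#' bands within each hemisphere, mirrored exactly about the vertical midline,
#' with a vein stripe of `vein_width` columns straddling the midline. Region
#' ids are 1..k on the left and k+1..2k on the right; pair (i, k+i) is
#' homotopic. The brain mask is the union of the regions and the vein stripe.
#'
#' @param shape `(rows, cols)` of the image.
#' @param n_regions_per_hemisphere Regions per hemisphere (k).
#' @param vein_width Width in columns of the midline vein stripe.
#' @param seed Integer seed recorded for provenance (the layout itself is a
#'   deterministic function of the geometry arguments).
#' @return A `ground_truth` skeleton: `region_map` (integer matrix, 0 =
#'   background), `region_labels` (data.frame), `homotopic_pairs` (k x 2),
#'   `vein` (logical matrix), `mask` ([mask_set()]), `shape`, `seed`.
#' @export
make_layout <- function(shape, n_regions_per_hemisphere, vein_width = 2L,
                        seed = 1L) {
  rows <- as.integer(shape[1L]); cols <- as.integer(shape[2L])
  k <- as.integer(n_regions_per_hemisphere)
  if (k < 1L) stop("need at least one region per hemisphere", call. = FALSE)
  vein_width <- as.integer(vein_width)

  half <- floor((cols - vein_width) / 2)   # usable columns per hemisphere
  band_h <- floor(rows / k)                # rows per region band
  # each ellipse needs >= 3 rows and >= 4 columns of usable space
  if (band_h < 4L || half < 6L) {
    stop(sprintf(
      "layout error: %d regions per hemisphere do not fit in a %dx%d image",
      k, rows, cols), call. = FALSE)
  }

  region_map <- matrix(0L, rows, cols)
  a <- band_h / 2 - 1       # vertical semi-axis
  b <- half / 2 - 1.5       # horizontal semi-axis
  c0 <- (1 + half) / 2      # left-hemisphere ellipse center column
  for (i in seq_len(k)) {
    r0 <- (i - 1L) * band_h + (band_h + 1) / 2
    for (r in seq_len(rows)) {
      for (cc in seq_len(half)) {
        if (((r - r0) / a)^2 + ((cc - c0) / b)^2 <= 1) {
          region_map[r, cc] <- i                      # left
          region_map[r, cols + 1L - cc] <- k + i      # mirrored right
        }
      }
    }
  }
  if (any(tabulate(region_map[region_map > 0L], 2L * k) == 0L)) {
    stop("layout error: degenerate ellipse produced an empty region", call. = FALSE)
  }

  vein <- matrix(FALSE, rows, cols)
  if (vein_width > 0L) {
    mid <- (cols + 1) / 2
    vc <- seq.int(ceiling(mid - vein_width / 2), length.out = vein_width)
    vein[, vc] <- TRUE
  }
  region_map[vein] <- 0L   # vein obscures the underlying tissue

  hemi <- matrix(0L, rows, cols)
  hemi[region_map %in% seq_len(k)] <- 1L
  hemi[region_map %in% (k + seq_len(k))] <- 2L
  hemi[vein] <- 3L

  labels <- data.frame(
    region = seq_len(2L * k),
    name = rep(paste0("R", seq_len(k)), 2L),
    hemisphere = rep(c("left", "right"), each = k),
    stringsAsFactors = FALSE
  )
  structure(list(region_map = region_map,
                 region_labels = labels,
                 homotopic_pairs = cbind(left = seq_len(k), right = k + seq_len(k)),
                 vein = vein,
                 mask = mask_set(hemi, vein),
                 shape = c(rows, cols),
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Default latent correlation targets
#'
#' Homotopic pairs correlate at `homotopic`, anterior-posterior neighbours
#' within a hemisphere at `neighbor`, all other pairs at 0 - bracketing the
#' homotopic correlation strengths observed in resting-state avian imaging
#' (region-level values roughly 0.5-0.8).
#'
#' @param n_pairs Number of homotopic pairs k (matrix is 2k x 2k).
#' @param homotopic,neighbor Target Pearson correlations.
#' @return A symmetric positive semidefinite correlation matrix.
#' @export
default_latent_corr <- function(n_pairs, homotopic = 0.6, neighbor = 0.2) {
  k <- as.integer(n_pairs)
  A <- diag(k)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) A[i, i + 1L] <- A[i + 1L, i] <- neighbor
  }
  C <- rbind(cbind(A, diag(homotopic, k)), cbind(diag(homotopic, k), A))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("default targets produce a non-PSD matrix; reduce homotopic/neighbor",
         call. = FALSE)
  }
  C
}

#' Sample band-limited latent traces with an exact correlation structure
#'
#' Draws Gaussian noise, band-limits it with the package's zero-phase
#' Butterworth design, then imposes `latent_corr` exactly at the realized
#' sample size (empirical whitening followed by colouring with a positive
#' semidefinite square root of the target). Traces are zero-mean with unit
#' sample variance, and their empirical correlation matrix equals
#' `latent_corr` up to numerical precision, also for singular targets
#' (perfectly correlated duplicates come out identical).
#'
#' @param latent_corr Symmetric PSD target correlation matrix (k x k).
#' @param n_frames Number of time points (must exceed k).
#' @param band_hz `(low, high)` passband of the latent dynamics, Hz.
#' @param frame_rate_hz Sampling rate, Hz.
#' @param seed Integer seed.
#' @param repair Clamp small negative eigenvalues to zero instead of
#'   erroring on a non-PSD target (default `FALSE`).
#' @return `n_frames x k` matrix of latent traces.
#' @export
sample_latent_traces <- function(latent_corr, n_frames, band_hz = c(0.03, 0.12),
                                 frame_rate_hz = 8, seed = 1L, repair = FALSE) {
  C <- as.matrix(latent_corr)
  k <- ncol(C)
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-10))) {
    stop("latent_corr must be symmetric", call. = FALSE)
  }
  if (n_frames <= k + 2L) stop("n_frames must exceed the number of regions", call. = FALSE)
  eC <- eigen((C + t(C)) / 2, symmetric = TRUE)
  tol <- 1e-10 * max(abs(eC$values))
  if (min(eC$values) < -tol && !repair) {
    stop("latent_corr is not positive semidefinite (min eigenvalue ",
         format(min(eC$values), digits = 4),
         "); set repair = TRUE to clamp", call. = FALSE)
  }
  lam <- pmax(eC$values, 0)

  X <- with_seed(seed, matrix(stats::rnorm(n_frames * k), n_frames, k))
  X <- bandpass_series(X, band_hz, frame_rate_hz)
  X <- sweep(X, 2L, colMeans(X), "-")
  # empirical whitening: exact unit sample covariance
  S <- crossprod(X) / (n_frames - 1)
  eS <- eigen(S, symmetric = TRUE)
  if (min(eS$values) <= 1e-10 * max(eS$values)) {
    stop("degenerate noise realization; use a longer series", call. = FALSE)
  }
  W <- eS$vectors %*% diag(1 / sqrt(eS$values), k) %*% t(eS$vectors)
  # colouring: G'G = C
  G <- diag(sqrt(lam), k) %*% t(eC$vectors)
  (X %*% W) %*% G
}

#' Assemble the ground truth for a synthetic scenario
#'
#' Extends a [make_layout()] skeleton with latent region traces, the vein's
#' own independent trace, per-hemisphere nuisance traces, drift
#' coefficients, and a smooth vignette field. All random draws derive
#' deterministically from `seed`.
#'
#' @param shape,n_regions_per_hemisphere,vein_width Passed to [make_layout()].
#' @param n_frames,frame_rate_hz Length and rate of the generated series.
#' @param latent_corr Target region correlation matrix; default
#'   [default_latent_corr()] over the layout's regions.
#' @param latent_band_hz Passband of the latent dynamics, chosen inside the
#'   0.02-0.167 Hz analysis band.
#' @param seed Integer seed.
#' @return A `ground_truth` with all fields populated.
#' @export
make_ground_truth <- function(shape = c(36L, 40L), n_regions_per_hemisphere = 5L,
                              n_frames = 4800L, frame_rate_hz = 8,
                              latent_corr = NULL,
                              latent_band_hz = c(0.03, 0.12),
                              vein_width = 2L, seed = 1L) {
  gt <- make_layout(shape, n_regions_per_hemisphere, vein_width, seed)
  k <- nrow(gt$homotopic_pairs)
  if (is.null(latent_corr)) latent_corr <- default_latent_corr(k)
  if (ncol(latent_corr) != 2L * k) {
    stop("latent_corr must be 2k x 2k for k homotopic pairs", call. = FALSE)
  }
  gt$latent_corr <- latent_corr
  # one block-diagonal draw: 2k region latents + 3 nuisance traces (vein,
  # left/right hemisphere) + 2 within-region gradient sub-components per
  # region, all exactly mutually correlated as specified at the realized n
  n_sub <- 2L * (2L * k)
  big <- matrix(0, 2L * k + 3L + n_sub, 2L * k + 3L + n_sub)
  big[seq_len(2L * k), seq_len(2L * k)] <- latent_corr
  diag(big)[(2L * k + 1L):nrow(big)] <- 1
  all_tr <- sample_latent_traces(big, n_frames, band_hz = latent_band_hz,
                                 frame_rate_hz = frame_rate_hz,
                                 seed = derive_seed(seed, 1L))
  gt$latent_traces <- all_tr[, seq_len(2L * k), drop = FALSE]
  aux <- all_tr[, 2L * k + 1:3, drop = FALSE]
  gt$subcomponent_traces <- all_tr[, (2L * k + 4L):ncol(all_tr), drop = FALSE]
  gt$n_frames <- as.integer(n_frames)
  gt$frame_rate_hz <- frame_rate_hz
  gt$latent_band_hz <- latent_band_hz
  rows <- gt$shape[1L]; cols <- gt$shape[2L]
  rr <- (seq_len(rows) - (rows + 1) / 2) / (rows / 2)
  cc <- (seq_len(cols) - (cols + 1) / 2) / (cols / 2)
  gt$nuisance <- list(
    vein_trace = aux[, 1L],
    hemi_traces = aux[, 2:3],            # columns: left, right
    drift_coef = c(0.01, -0.015),        # fractional linear/quadratic drift
    vignette = 1 - 0.25 * (outer(rr^2, rep(1, cols)) + outer(rep(1, rows), cc^2))
  )
  # within-region gradient weights: anterior-posterior and medial-lateral
  # deviations from the region centroid, centered exactly to zero mean over
  # each region (so region-mean traces carry no sub-component signal) and
  # scaled to unit variance over the region's pixels
  w <- matrix(0, rows * cols, 2L)
  rc_all <- pixel_coords(seq_len(rows * cols), gt$shape)
  for (reg in seq_len(2L * k)) {
    px <- which(as.vector(gt$region_map) == reg)
    for (axis in 1:2) {
      z <- rc_all[px, axis] - mean(rc_all[px, axis])
      s <- stats::sd(z)
      w[px, axis] <- if (is.na(s) || s == 0) 0 else z / s
    }
  }
  gt$subcomponent_weights <- w
  gt
}

#' @export
print.ground_truth <- function(x, ...) {
  k <- nrow(x$homotopic_pairs)
  cat(sprintf("<ground_truth> %dx%d px, %d mirrored region pairs, %d vein px",
              x$shape[1L], x$shape[2L], k, sum(x$vein)))
  if (!is.null(x$latent_traces)) {
    cat(sprintf(", %d frames @ %g Hz", nrow(x$latent_traces), x$frame_rate_hz))
  }
  cat("\n")
  invisible(x)
}

#' Render a synthetic multi-wavelength reflectance stack
#'
#' Forward model, per pixel p and wavelength lambda:
#' `dHbO2(p,t) = amplitude * latent_region(p)(t) [+ hemispheric nuisance]
#' + pixel noise`; `dHbR = -hbr_alpha * dHbO2 + noise`;
#' `dA(lambda) = E[lambda,] %*% (dHbO2, dHbR)`;
#' `reflectance = baseline(lambda) * vignette(p) * drift(t) * exp(-dA)`,
#' quantized to `bit_depth` bits. Vein-stripe pixels carry the vein's own
#' trace instead of any region signal; background pixels carry noise only.
#'
#' @param gt A fully populated [make_ground_truth()] object.
#' @param model A [spectroscopy_model()].
#' @param noise List: `pixel_sd` (sd of per-pixel HbO2 noise, concentration
#'   units), `hbr_alpha` (HbR = -alpha HbO2 coupling), `hbr_sd`.
#' @param artifacts List: `drift`, `vignette`, `vein` (logicals) and
#'   `hemi_nuisance` (amplitude multiplier, 0 disables).
#' @param amplitude Concentration amplitude (uM) of a unit latent trace.
#' @param vein_amplitude Amplitude of the vein's replacement signal.
#' @param heterogeneity Relative amplitude of the within-region gradient
#'   sub-components (0 disables; region-mean traces are unaffected either
#'   way because the gradient weights are zero mean over each region).
#' @param baseline_frac Baseline reflectance as a fraction of full scale.
#' @param bit_depth Output quantization (8 or 16), or `NULL` for continuous
#'   output (used by exact-inversion checks).
#' @return A [raw_stack()] at the ground truth's frame rate.
#' @export
render_reflectance <- function(gt, model = spectroscopy_model(),
                               noise = list(pixel_sd = 0.3, hbr_alpha = 0.7,
                                            hbr_sd = 0.05),
                               artifacts = list(drift = TRUE, vignette = TRUE,
                                                vein = TRUE, hemi_nuisance = 1),
                               amplitude = 0.3, vein_amplitude = 0.9,
                               heterogeneity = 0.4,
                               baseline_frac = 0.55, bit_depth = 16L) {
  stopifnot(inherits(gt, "ground_truth"), !is.null(gt$latent_traces))
  nt <- nrow(gt$latent_traces)
  rows <- gt$shape[1L]; cols <- gt$shape[2L]
  npix <- rows * cols
  reg <- as.vector(gt$region_map)
  veinpx <- as.vector(gt$vein)
  hemi_px <- as.vector(gt$mask$hemisphere)

  noise <- utils::modifyList(list(pixel_sd = 0.3, hbr_alpha = 0.7, hbr_sd = 0.05),
                             as.list(noise))
  artifacts <- utils::modifyList(list(drift = TRUE, vignette = TRUE, vein = TRUE,
                                      hemi_nuisance = 1), as.list(artifacts))

  # concentration fields (time x pixel), uM
  dhbo2 <- matrix(0, nt, npix)
  has_reg <- reg > 0L
  dhbo2[, has_reg] <- amplitude * gt$latent_traces[, reg[has_reg], drop = FALSE]
  if (heterogeneity > 0 && !is.null(gt$subcomponent_traces)) {
    # smooth within-region functional gradients: two independent
    # sub-component traces per region, weighted by zero-mean spatial ramps
    ha <- amplitude * heterogeneity
    px <- which(has_reg)
    u1 <- gt$subcomponent_traces[, 2L * (reg[px] - 1L) + 1L, drop = FALSE]
    u2 <- gt$subcomponent_traces[, 2L * reg[px], drop = FALSE]
    dhbo2[, px] <- dhbo2[, px] +
      ha * (u1 * rep(gt$subcomponent_weights[px, 1L], each = nt) +
              u2 * rep(gt$subcomponent_weights[px, 2L], each = nt))
  }
  if (isTRUE(artifacts$vein) && any(veinpx)) {
    dhbo2[, veinpx] <- vein_amplitude * gt$nuisance$vein_trace
  }
  if (artifacts$hemi_nuisance > 0) {
    w <- artifacts$hemi_nuisance * amplitude
    left <- hemi_px == 1L; right <- hemi_px == 2L
    dhbo2[, left] <- dhbo2[, left] + w * gt$nuisance$hemi_traces[, 1L]
    dhbo2[, right] <- dhbo2[, right] + w * gt$nuisance$hemi_traces[, 2L]
  }
  if (noise$pixel_sd > 0) {
    dhbo2 <- dhbo2 + with_seed(derive_seed(gt$seed, 3L),
                               matrix(stats::rnorm(nt * npix, sd = noise$pixel_sd),
                                      nt, npix))
  }
  dhbr <- -noise$hbr_alpha * dhbo2
  if (noise$hbr_sd > 0) {
    dhbr <- dhbr + with_seed(derive_seed(gt$seed, 4L),
                             matrix(stats::rnorm(nt * npix, sd = noise$hbr_sd),
                                    nt, npix))
  }

  drift <- if (isTRUE(artifacts$drift)) {
    tau <- seq(-1, 1, length.out = nt)
    1 + gt$nuisance$drift_coef[1L] * tau + gt$nuisance$drift_coef[2L] * tau^2
  } else rep(1, nt)
  vig <- if (isTRUE(artifacts$vignette)) as.vector(gt$nuisance$vignette) else rep(1, npix)

  maxv <- if (is.null(bit_depth)) 1 else 2^as.integer(bit_depth) - 1
  lam_base <- baseline_frac * maxv * c(1, 0.85, 0.7)[seq_along(model$wavelengths_nm)]

  frames <- array(0, dim = c(nt, rows, cols, length(model$wavelengths_nm)))
  n_clipped <- 0L
  for (i in seq_along(model$wavelengths_nm)) {
    dA <- model$E[i, 1L] * dhbo2 + model$E[i, 2L] * dhbr
    R <- exp(-dA) * rep(vig, each = nt) * drift * lam_base[i]
    if (!is.null(bit_depth)) {
      R <- round(R)
      n_clipped <- n_clipped + sum(R < 0) + sum(R > maxv)
      R[R < 0] <- 0
      R[R > maxv] <- maxv
    }
    frames[, , , i] <- R
  }
  if (n_clipped > 0L) {
    warning(sprintf("reflectance clipped at %d sample(s); reduce amplitudes or drift",
                    n_clipped), call. = FALSE)
  }
  raw_stack(frames, model$wavelengths_nm, gt$frame_rate_hz, bit_depth)
}

#' Simulate a complete synthetic scenario
#'
#' Convenience wrapper: [make_ground_truth()] then [render_reflectance()].
#' The defaults are the package's benchmark study conditions: a 36x40 pixel
#' field with 5 mirrored region pairs (10 regions), 4800 frames at 8
#' frames/s (two concatenated 5-minute runs), homotopic latent correlation
#' 0.6, pixel noise of the same amplitude as the signal, and all nuisance
#' components enabled.
#'
#' @param seed Integer seed driving every random component.
#' @param ... Overrides forwarded to [make_ground_truth()].
#' @param model A [spectroscopy_model()].
#' @param noise,artifacts,heterogeneity,bit_depth Forwarded to
#'   [render_reflectance()].
#' @return List with `raw` ([raw_stack()]), `mask` ([mask_set()]),
#'   `ground_truth`, and `model`.
#' @export
simulate_scenario <- function(seed = 1L, ..., model = spectroscopy_model(),
                              noise = list(), artifacts = list(),
                              heterogeneity = 0.4, bit_depth = 16L) {
  gt <- make_ground_truth(seed = seed, ...)
  raw <- render_reflectance(gt, model = model, noise = noise,
                            artifacts = artifacts,
                            heterogeneity = heterogeneity,
                            bit_depth = bit_depth)
  list(raw = raw, mask = gt$mask, ground_truth = gt, model = model)
}
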