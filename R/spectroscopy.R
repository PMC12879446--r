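# Modified Beer-Lambert spectroscopy: the linear map between chromophore
# concentration changes and differential absorption at each LED wavelength,
#   dA(lambda) = L(lambda) * [ eps_HbO2(lambda) dHbO2 + eps_HbR(lambda) dHbR ],
# and its least-squares inversion.

# Approximate molar extinction coefficients (cm^-1 per uM, i.e. tabulated
# cm^-1/M values scaled by 1e-6) for oxy- and deoxy-hemoglobin at the three
# LED wavelengths, rounded from standard hemoglobin absorption compilations.
# These are order-of-magnitude defaults for simulation and for the relative
# (contrast) units used throughout; replace via `spectroscopy_model()` with
# calibrated tables for quantitative work.
woi_default_extinction <- matrix(
  c(0.0400, 0.0390,   # 530 nm: near-isosbestic, both species absorb strongly
    0.0100, 0.0270,   # 590 nm: HbR absorbs ~3x HbO2
    0.0007, 0.0060),  # 625 nm: red, HbR-dominated
  nrow = 3L, byrow = TRUE,
  dimnames = list(c("530", "590", "625"), c("HbO2", "HbR"))
)

# Differential pathlength factors (effective photon path, cm) per wavelength;
# longer at red wavelengths where tissue absorbs less.
woi_default_pathlength <- c("530" = 0.45, "590" = 0.55, "625" = 1.10)

#' Construct a spectroscopy model
#'
#' Bundles the chromophore extinction coefficients and per-wavelength
#' differential pathlength factors that define the modified Beer-Lambert
#' system. The shipped defaults are approximate tabulated values for
#' (HbO2, HbR) at 530/590/625 nm; both tables are replaceable.
#'
#' @param wavelengths_nm LED wavelengths. Defaults must be a subset of the
#'   shipped table when `extinction` is not supplied.
#' @param extinction `wavelength x 2` matrix of extinction coefficients
#'   (columns ordered HbO2, HbR), in cm^-1 per concentration unit.
#' @param pathlength Numeric vector of per-wavelength pathlength factors (cm).
#' @return A `spectroscopy_model` with fields `wavelengths_nm`, `extinction`,
#'   `pathlength`, and the precomputed system matrix `E = diag(L) %*% extinction`.
#' @export
spectroscopy_model <- function(wavelengths_nm = c(530, 590, 625),
                               extinction = NULL, pathlength = NULL) {
  wl <- as.character(wavelengths_nm)
  if (is.null(extinction)) {
    missing_wl <- setdiff(wl, rownames(woi_default_extinction))
    if (length(missing_wl) > 0L) {
      stop("no shipped extinction values for wavelength(s): ",
           paste(missing_wl, collapse = ", "), call. = FALSE)
    }
    extinction <- woi_default_extinction[wl, , drop = FALSE]
  }
  extinction <- as.matrix(extinction)
  if (nrow(extinction) != length(wavelengths_nm) || ncol(extinction) != 2L) {
    stop("extinction must be a wavelength x 2 (HbO2, HbR) matrix", call. = FALSE)
  }
  if (any(extinction <= 0)) stop("extinction entries must be positive", call. = FALSE)
  if (is.null(pathlength)) pathlength <- woi_default_pathlength[wl]
  pathlength <- as.numeric(pathlength)
  if (length(pathlength) != length(wavelengths_nm) || any(pathlength <= 0)) {
    stop("pathlength must be one positive factor per wavelength", call. = FALSE)
  }
  E <- diag(pathlength, nrow = length(pathlength)) %*% extinction
  if (qr(E)$rank < 2L) {
    stop("extinction x pathlength system is rank deficient; ",
         "chromophores are not separable at these wavelengths", call. = FALSE)
  }
  structure(list(wavelengths_nm = as.numeric(wavelengths_nm),
                 extinction = extinction, pathlength = pathlength,
                 chromophores = c("HbO2", "HbR"), E = E),
            class = "spectroscopy_model")
}

#' @export
print.spectroscopy_model <- function(x, ...) {
  cat("<spectroscopy_model>", length(x$wavelengths_nm), "wavelengths (",
      paste(x$wavelengths_nm, collapse = "/"), "nm ), chromophores",
      paste(x$chromophores, collapse = ", "), "\n")
  cat("  condition number of E:", format(kappa(x$E, exact = TRUE), digits = 4), "\n")
  invisible(x)
}

#' Forward Beer-Lambert absorption
#'
#' Maps concentration-change time series to differential absorption per
#' wavelength: `dA_lambda = E[lambda, 1] * dHbO2 + E[lambda, 2] * dHbR`.
#'
#' @param model A [spectroscopy_model()].
#' @param hbo2,hbr `time x pixel` matrices of concentration changes.
#' @return List of `time x pixel` absorption matrices, one per wavelength.
#' @export
forward_absorption <- function(model, hbo2, hbr) {
  stopifnot(inherits(model, "spectroscopy_model"))
  if (!all(dim(hbo2) == dim(hbr))) stop("hbo2/hbr shape mismatch", call. = FALSE)
  lapply(seq_along(model$wavelengths_nm), function(i) {
    model$E[i, 1L] * hbo2 + model$E[i, 2L] * hbr
  })
}

#' Invert the spectroscopy system
#'
#' Solves the per-pixel, per-time least-squares problem
#' `dA(lambda) = E %*% (dHbO2, dHbR)` for the chromophore concentration
#' changes; with three wavelengths this is the Moore-Penrose pseudoinverse
#' solution, with two it reduces to the exact 2x2 inverse. Sign convention:
#' increased absorption maps to positive concentration change for a
#' positively absorbing chromophore.
#'
#' @param dabs List of `time x pixel` differential-absorption matrices, one
#'   per model wavelength (as produced by [forward_absorption()] or by the
#'   negated log-mean transform of reflectance).
#' @param model A [spectroscopy_model()].
#' @param max_condition Condition-number limit above which the system is
#'   treated as rank deficient.
#' @return List with `time x pixel` matrices `hbo2` and `hbr`.
#' @export
invert_spectroscopy <- function(dabs, model, max_condition = 1e8) {
  stopifnot(inherits(model, "spectroscopy_model"))
  if (!is.list(dabs) || length(dabs) != length(model$wavelengths_nm)) {
    stop("dabs must be a list with one matrix per model wavelength", call. = FALSE)
  }
  d <- dim(dabs[[1L]])
  for (m in dabs) {
    if (!all(dim(m) == d)) stop("dabs matrices must share dimensions", call. = FALSE)
  }
  E <- model$E
  cond <- kappa(E, exact = TRUE)
  if (!is.finite(cond) || cond > max_condition) {
    stop(sprintf("spectroscopy system is rank deficient (condition number %.3g)",
                 cond), call. = FALSE)
  }
  # Stack wavelengths as rows of an nw x (time*pixel) matrix and solve once.
  A <- do.call(rbind, lapply(dabs, as.vector))
  dc <- solve(crossprod(E), crossprod(E, A))   # 2 x (time*pixel)
  list(hbo2 = matrix(dc[1L, ], d[1L], d[2L]),
       hbr = matrix(dc[2L, ], d[1L], d[2L]))
}
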