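# Modified Beer-Lambert forward/inverse optics shared by the generator and the
# preprocessing chain.

# Base-10 molar extinction coefficients, cm^-1 / (mol/L), Gratzer/Cope
# tabulation as shipped with standard fNIRS toolchains. Declared constants.
.EXTINCTION <- rbind(
  "695" = c(hbo = 280.6,  hbr = 1923.3),
  "830" = c(hbo = 974.0,  hbr = 693.04)
)

#' Molar extinction coefficients for oxy-/deoxy-haemoglobin
#'
#' Base-10 extinction coefficients (cm^-1 per mol/L) at the two instrument
#' wavelengths, from the standard Gratzer/Cope tabulation.
#'
#' @param wavelengths_nm Numeric vector of wavelengths; 695 and 830 nm are
#'   tabulated.
#' @return Matrix with one row per wavelength, columns `hbo` and `hbr`.
#' @export
extinction_coefficients <- function(wavelengths_nm = c(695, 830)) {
  key <- as.character(round(wavelengths_nm))
  if (!all(key %in% rownames(.EXTINCTION)))
    stop("extinction_coefficients: only 695 and 830 nm are tabulated")
  .EXTINCTION[key, , drop = FALSE]
}

#' Convert raw light intensity to optical density change
#'
#' OD(t) = -log10(I(t) / mean(I over the reference window)), computed per
#' channel and wavelength. Non-positive or missing intensities are flagged as
#' missing (NA) rather than propagated as infinities.
#'
#' @param intensity Numeric vector, or matrix (channels x time), or 3-d array
#'   (channels x time x wavelengths), strictly positive except missing samples.
#' @param reference_window Integer indices of the samples defining the
#'   reference intensity (default: the whole series).
#' @return Optical density with the same shape; missing/invalid samples NA.
#' @export
intensity_to_od <- function(intensity, reference_window = NULL) {
  od1 <- function(x) {
    bad <- !is.finite(x) | x <= 0
    x[bad] <- NA_real_
    ref <- if (is.null(reference_window)) x else x[reference_window]
    iref <- mean(ref, na.rm = TRUE)
    if (!is.finite(iref) || iref <= 0)
      stop("intensity_to_od: reference window has no positive intensity")
    -log10(x / iref)
  }
  if (is.null(dim(intensity))) return(od1(intensity))
  out <- intensity
  if (length(dim(intensity)) == 2L) {
    for (i in seq_len(nrow(intensity))) out[i, ] <- od1(intensity[i, ])
  } else if (length(dim(intensity)) == 3L) {
    for (i in seq_len(dim(intensity)[1])) for (w in seq_len(dim(intensity)[3]))
      out[i, , w] <- od1(intensity[i, , w])
  } else stop("intensity_to_od: unsupported input shape")
  out
}

# 2x2 MBLL system matrix mapping concentration changes (uM) to OD changes.
.mbll_matrix <- function(wavelengths_nm, dpf, distance_cm) {
  eps <- extinction_coefficients(wavelengths_nm)
  m <- eps * dpf * distance_cm * 1e-6  # uM -> mol/L
  if (abs(det(m)) < 1e-12 * max(abs(m))^2)
    stop("beer_lambert: extinction matrix is singular for these wavelengths")
  m
}

#' Invert the modified Beer-Lambert law
#'
#' Solves, per sample, the 2x2 linear system
#' `dOD_lambda = (eps_HbO,lambda * dHbO + eps_HbR,lambda * dHbR) * d * DPF`
#' for the chromophore concentration changes (in micromolar), and returns
#' HbO, HbR and their sum HbT.
#'
#' @param od Matrix time x 2 (one column per wavelength), or 3-d array
#'   channels x time x 2.
#' @param wavelengths_nm The two wavelengths, default `c(695, 830)`.
#' @param dpf Differential pathlength factor (default 6.0).
#' @param distance_cm Source-detector distance in cm (default 3.0).
#' @return For matrix input, a time x 3 matrix with columns `hbo`, `hbr`,
#'   `hbt` (micromolar); for array input, channels x time x 3.
#' @export
beer_lambert_invert <- function(od, wavelengths_nm = c(695, 830), dpf = 6.0,
                                distance_cm = 3.0) {
  m <- .mbll_matrix(wavelengths_nm, dpf, distance_cm)
  minv <- solve(m)
  inv1 <- function(od2) {  # time x 2 -> time x 3
    conc <- od2 %*% t(minv)
    cbind(hbo = conc[, 1], hbr = conc[, 2], hbt = conc[, 1] + conc[, 2])
  }
  if (length(dim(od)) == 2L) return(inv1(od))
  if (length(dim(od)) == 3L) {
    out <- array(NA_real_, c(dim(od)[1], dim(od)[2], 3),
                 dimnames = list(dimnames(od)[[1]], NULL, c("hbo", "hbr", "hbt")))
    for (i in seq_len(dim(od)[1])) out[i, , ] <- inv1(od[i, , ])
    return(out)
  }
  stop("beer_lambert_invert: od must be time x 2 or channels x time x 2")
}

# Forward projection used by the generator: concentrations (uM) -> OD changes.
.hemo_to_od <- function(hbo, hbr, wavelengths_nm = c(695, 830), dpf = 6.0,
                        distance_cm = 3.0) {
  m <- .mbll_matrix(wavelengths_nm, dpf, distance_cm)
  cbind(hbo, hbr) %*% t(m)  # time x 2
}
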