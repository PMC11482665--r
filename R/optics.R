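# Closed-form optical design calculations for finite-conjugate camera-module
# microscopes. Sign convention: Cartesian, light travels left to right;
# object distances are negative, real image distances positive, so that
# M = -a'/a is positive for a real magnified image and the Gaussian lens
# equation reads 1/f' = 1/a' - 1/a.

#' Solve the Gaussian lens equation for a conjugate pair
#'
#' Given the focal length and exactly one of the object distance \code{aMm}
#' (negative) or image distance \code{aPrimeMm} (positive), returns the full
#' conjugate pair satisfying 1/f' = 1/a' - 1/a.
#'
#' @param focalLengthMm focal length f' (mm, positive)
#' @param aMm object distance (mm, negative), or NULL
#' @param aPrimeMm image distance (mm, positive), or NULL
#' @return a \linkS4class{ConjugatePair}
#' @examples
#' lensSolve(4, aMm = -8)        # symmetric 2f-2f: a' = 8 mm
#' lensSolve(4, aPrimeMm = 8)    # inverse: a = -8 mm
#' @export
lensSolve <- function(focalLengthMm, aMm = NULL, aPrimeMm = NULL) {
  if (!is.numeric(focalLengthMm) || focalLengthMm <= 0)
    stop("focal length must be positive")
  if (is.null(aMm) == is.null(aPrimeMm))
    stop("supply exactly one of aMm or aPrimeMm")
  f <- focalLengthMm
  if (!is.null(aMm)) {
    a <- as.numeric(aMm)
    if (a == 0) stop("object distance must be nonzero")
    if (a == -f) stop("image at infinity: object at the front focal plane")
    ap <- 1 / (1 / f + 1 / a)
    if (!is.finite(ap) || ap <= 0)
      stop("no real image for this object distance (virtual image)")
  } else {
    ap <- as.numeric(aPrimeMm)
    if (ap == 0) stop("image distance must be nonzero")
    if (ap == f) stop("object at infinity: image at the back focal plane")
    a <- 1 / (1 / ap - 1 / f)
    if (!is.finite(a) || a >= 0)
      stop("no real object for this image distance")
  }
  ConjugatePair(a, ap)
}

#' Numerical aperture from the f-number
#'
#' NA = 1/(2 f#), the small-angle approximation for a lens used near its
#' design conjugates.
#'
#' @param fNumber lens f-number (> 0)
#' @return dimensionless numerical aperture
#' @examples
#' numericalAperture(2.2)   # ~0.227
#' @export
numericalAperture <- function(fNumber) {
  if (!is.numeric(fNumber) || any(fNumber <= 0))
    stop("f-number must be positive")
  1 / (2 * fNumber)
}

#' Diffraction-limited resolution
#'
#' Abbe-type two-point resolution d = lambda / (2 NA), returned in
#' micrometres.
#'
#' @param wavelengthNm wavelength (nm, > 0)
#' @param na numerical aperture (0 < NA <= 1.5)
#' @return resolution in micrometres
#' @examples
#' diffractionLimit(550, numericalAperture(2.2))   # ~1.21 um
#' @export
diffractionLimit <- function(wavelengthNm, na) {
  if (!is.numeric(wavelengthNm) || any(wavelengthNm <= 0))
    stop("wavelength must be positive")
  if (!is.numeric(na) || any(na <= 0) || any(na > 1.5))
    stop("numerical aperture must lie in (0, 1.5]")
  (wavelengthNm / 1000) / (2 * na)
}

#' Effective (object-side) pixel size
#'
#' Sensor pixel pitch divided by the magnitude of the lateral magnification:
#' the sample-plane distance spanned by one sensor pixel.
#'
#' @param pixelPitchUm sensor pixel pitch (um)
#' @param magnification lateral magnification (nonzero)
#' @return effective pixel size in micrometres
#' @examples
#' effectivePixel(2.2, 4)     # 0.55 um
#' @export
effectivePixel <- function(pixelPitchUm, magnification) {
  if (!is.numeric(pixelPitchUm) || any(pixelPitchUm <= 0))
    stop("pixel pitch must be positive")
  if (!is.numeric(magnification) || any(magnification == 0))
    stop("magnification must be nonzero")
  pixelPitchUm / abs(magnification)
}

#' Nyquist sampling margin
#'
#' Ratio of the optical resolution to twice the effective pixel size; values
#' >= 1 mean the sensor samples the optical resolution adequately (ignoring
#' any colour-filter mosaic, which halves per-channel sampling).
#'
#' @param opticalResolutionUm two-point optical resolution (um)
#' @param effectivePixelUm effective pixel size (um)
#' @return dimensionless margin (>= 1: satisfied)
#' @examples
#' nyquistMargin(1.2, 0.55)   # ~1.09
#' @export
nyquistMargin <- function(opticalResolutionUm, effectivePixelUm) {
  if (!is.numeric(opticalResolutionUm) || any(opticalResolutionUm <= 0) ||
      !is.numeric(effectivePixelUm) || any(effectivePixelUm <= 0))
    stop("resolution and effective pixel size must be positive")
  opticalResolutionUm / (2 * effectivePixelUm)
}

#' Axial step size of a PWM-discretised focus actuator
#'
#' A voice-coil (or similar) actuator with a given mechanical travel driven
#' at a given PWM bit resolution moves in steps of travel / 2^bits.
#'
#' @param travelMm full mechanical travel (mm, > 0)
#' @param resolutionBits PWM resolution in bits (>= 1)
#' @return axial step size in micrometres
#' @examples
#' actuatorStep(1, 8)     # ~3.9 um
#' actuatorStep(50, 8)    # ~195 um (long-travel stage)
#' @export
actuatorStep <- function(travelMm, resolutionBits) {
  if (!is.numeric(travelMm) || any(travelMm <= 0))
    stop("travel must be positive")
  if (!is.numeric(resolutionBits) || any(resolutionBits < 1))
    stop("resolution must be at least 1 bit")
  travelMm * 1000 / 2^resolutionBits
}

#' Full optical design report
#'
#' Computes the derived quantities of a finite-conjugate configuration in
#' one call: numerical aperture, diffraction limit, magnification, effective
#' pixel size and Nyquist margin. The conjugates can be given directly
#' (\code{aMm} + \code{aPrimeMm}) or solved from the focal length and one
#' distance. Inputs are never cross-validated against each other: each
#' quantity is computed from the parameters that define it.
#'
#' @param config an \linkS4class{OpticalConfig}
#' @param aMm object distance (mm, negative), optional
#' @param aPrimeMm image distance (mm, positive), optional
#' @return named list: \code{na}, \code{resolution_um}, \code{magnification},
#'   \code{effective_pixel_um}, \code{nyquist_margin} (the last three NULL if
#'   no conjugates were determinable)
#' @examples
#' opticsReport(OpticalConfig(), aMm = -4, aPrimeMm = 18)
#' @export
opticsReport <- function(config = OpticalConfig(), aMm = NULL,
                         aPrimeMm = NULL) {
  na <- numericalAperture(config@fNumber)
  d <- diffractionLimit(config@wavelengthNm, na)
  out <- list(na = na, resolution_um = d)
  pair <- NULL
  if (!is.null(aMm) && !is.null(aPrimeMm)) {
    pair <- ConjugatePair(aMm, aPrimeMm)
  } else if (!is.null(aMm) || !is.null(aPrimeMm)) {
    pair <- lensSolve(config@focalLengthMm, aMm = aMm, aPrimeMm = aPrimeMm)
  }
  if (!is.null(pair)) {
    m <- magnification(pair)
    eff <- effectivePixel(config@pixelPitchUm, m)
    out$magnification <- m
    out$effective_pixel_um <- eff
    out$nyquist_margin <- nyquistMargin(d, eff)
  }
  out
}
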