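# Accessors and show methods for the package's S4 containers.

#' @name accessors
#' @title Accessors for pocketscope containers
#' @description Slot accessors; user code should use these rather than
#'   reaching into slots with \code{@}.
#' @param x a pocketscope S4 object
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "Frame", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))
#' @rdname accessors
#' @export
setMethod("bitDepth", "Frame", function(x) x@bitDepth)

#' @rdname accessors
#' @export
setGeneric("frameMeta", function(x) standardGeneric("frameMeta"))
#' @rdname accessors
#' @export
setMethod("frameMeta", "Frame", function(x) x@metadata)

#' @rdname accessors
#' @export
setGeneric("maxValue", function(x) standardGeneric("maxValue"))
#' @rdname accessors
#' @export
setMethod("maxValue", "Frame", function(x) 2^x@bitDepth - 1)

#' @rdname accessors
#' @export
setGeneric("zPositions", function(x) standardGeneric("zPositions"))
#' @rdname accessors
#' @export
setMethod("zPositions", "FocusStack", function(x) x@z)
#' @rdname accessors
#' @export
setMethod("zPositions", "SharpnessCurve", function(x) x@z)

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "FocusStack", function(x) x@frames)
#' @rdname accessors
#' @export
setMethod("frames", "TimelapseSeries", function(x) x@frames)

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setMethod("scores", "SharpnessCurve", function(x) x@score)

#' @rdname accessors
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))
#' @rdname accessors
#' @export
setMethod("metricName", "SharpnessCurve", function(x) x@metricName)

#' @rdname accessors
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))
#' @rdname accessors
#' @export
setMethod("timestamps", "TimelapseSeries", function(x) x@timestamps)

#' @rdname accessors
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))
#' @rdname accessors
#' @export
setMethod("fieldValues", "ComplexField", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("pitchUm", function(x) standardGeneric("pitchUm"))
#' @rdname accessors
#' @export
setMethod("pitchUm", "ComplexField", function(x) x@pitchUm)
#' @rdname accessors
#' @export
setMethod("pitchUm", "Hologram", function(x) x@pixelPitchUm)

#' @rdname accessors
#' @export
setGeneric("hologramFrame", function(x) standardGeneric("hologramFrame"))
#' @rdname accessors
#' @export
setMethod("hologramFrame", "Hologram", function(x) x@frame)

#' @rdname accessors
#' @export
setGeneric("wavelengthNm", function(x) standardGeneric("wavelengthNm"))
#' @rdname accessors
#' @export
setMethod("wavelengthNm", "Hologram", function(x) x@wavelengthNm)

#' @rdname accessors
#' @export
setGeneric("particles", function(x) standardGeneric("particles"))
#' @rdname accessors
#' @export
setMethod("particles", "ParticleScene", function(x) x@particles)

#' @rdname accessors
#' @export
setGeneric("sceneDepthUm", function(x) standardGeneric("sceneDepthUm"))
#' @rdname accessors
#' @export
setMethod("sceneDepthUm", "ParticleScene", function(x) x@zUm)

#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname accessors
#' @export
setMethod("positions", "Spectrum", function(x) x@position)

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "Spectrum", function(x) x@intensity)

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setMethod("wavelengths", "Spectrum", function(x) x@wavelength)

#' @rdname accessors
#' @export
setGeneric("calSlope", function(x) standardGeneric("calSlope"))
#' @rdname accessors
#' @export
setMethod("calSlope", "WavelengthCalibration", function(x) x@coefficients[2])

#' @rdname accessors
#' @export
setGeneric("calIntercept", function(x) standardGeneric("calIntercept"))
#' @rdname accessors
#' @export
setMethod("calIntercept", "WavelengthCalibration",
          function(x) x@coefficients[1])

#' @rdname accessors
#' @export
setGeneric("rmsResidual", function(x) standardGeneric("rmsResidual"))
#' @rdname accessors
#' @export
setMethod("rmsResidual", "WavelengthCalibration", function(x) x@rmsResidual)

#' @rdname accessors
#' @export
setGeneric("pairwiseShifts", function(x) standardGeneric("pairwiseShifts"))
#' @rdname accessors
#' @export
setMethod("pairwiseShifts", "DriftTrack", function(x) x@pairwise)

#' @rdname accessors
#' @export
setGeneric("cumulativeShifts", function(x) standardGeneric("cumulativeShifts"))
#' @rdname accessors
#' @export
setMethod("cumulativeShifts", "DriftTrack", function(x) x@cumulative)

#' @rdname accessors
#' @export
setGeneric("peakQuality", function(x) standardGeneric("peakQuality"))
#' @rdname accessors
#' @export
setMethod("peakQuality", "DriftTrack", function(x) x@peakQuality)

#' Magnification of a conjugate pair
#'
#' Lateral magnification M = -a'/a in the Cartesian convention (a < 0 for a
#' real object), so a real magnified image has M > 0.
#'
#' @param pair a \linkS4class{ConjugatePair}, or the object distance a (mm,
#'   negative) when \code{aPrimeMm} is given
#' @param aPrimeMm image distance (mm); only when \code{pair} is numeric
#' @return dimensionless magnification
#' @examples
#' magnification(ConjugatePair(-4, 18))   # 4.5
#' magnification(-18, 18)                 # 1
#' @export
magnification <- function(pair, aPrimeMm = NULL) {
  if (is(pair, "ConjugatePair")) {
    a <- pair@aMm; ap <- pair@aPrimeMm
  } else {
    a <- as.numeric(pair); ap <- as.numeric(aPrimeMm)
  }
  if (length(a) != 1L || !is.finite(a) || a == 0)
    stop("object distance must be a nonzero finite number")
  -ap / a
}

# --- show methods ----------------------------------------------------------

setMethod("show", "Frame", function(object) {
  d <- dim(object@pixels)
  kind <- if (length(d) == 3L) "RGB" else "grayscale"
  cat(sprintf("Frame: %d x %d %s, %d-bit\n", d[1], d[2], kind,
              object@bitDepth))
  md <- object@metadata
  if (length(md))
    cat("  metadata:", paste(names(md), collapse = ", "), "\n")
})

setMethod("show", "FocusStack", function(object) {
  cat(sprintf("FocusStack: %d frames, z in [%g, %g] um\n",
              length(object@frames), min(object@z), max(object@z)))
})

setMethod("show", "SharpnessCurve", function(object) {
  cat(sprintf("SharpnessCurve (%s): %d points, peak score %g at z = %g um\n",
              object@metricName, length(object@z),
              max(object@score), object@z[which.max(object@score)]))
})

setMethod("show", "AcquisitionPlan", function(object) {
  cat(sprintf("AcquisitionPlan: every %g s, exposures [%s] ms, offsets [%s] um, deep sleep %s\n",
              object@intervalS,
              paste(object@exposureSeriesMs, collapse = "/"),
              paste(object@focusOffsetsUm, collapse = ", "),
              if (object@deepSleep) "on" else "off"))
})

setMethod("show", "ConjugatePair", function(object) {
  cat(sprintf("ConjugatePair: a = %g mm, a' = %g mm (M = %g)\n",
              object@aMm, object@aPrimeMm, -object@aPrimeMm / object@aMm))
})

setMethod("show", "Hologram", function(object) {
  d <- dim(object@frame@pixels)
  src <- if (is.finite(object@sourceDistanceMm))
    sprintf("point source at %g mm", object@sourceDistanceMm)
  else "plane wave"
  cat(sprintf("Hologram: %d x %d, lambda = %g nm, pitch = %g um, %s%s\n",
              d[1], d[2], object@wavelengthNm, object@pixelPitchUm, src,
              if (is.null(object@background)) "" else ", with background"))
})

setMethod("show", "ComplexField", function(object) {
  d <- dim(object@values)
  cat(sprintf("ComplexField: %d x %d, pitch = %g um\n", d[1], d[2],
              object@pitchUm))
})

setMethod("show", "ParticleScene", function(object) {
  cat(sprintf("ParticleScene: %d particle(s) at z = %g um\n",
              nrow(object@particles), object@zUm))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d samples%s\n", length(object@position),
              if (length(object@wavelength)) sprintf(", %.0f-%.0f nm",
                min(object@wavelength), max(object@wavelength))
              else " (uncalibrated)"))
})

setMethod("show", "WavelengthCalibration", function(object) {
  co <- object@coefficients
  cat(sprintf("WavelengthCalibration: lambda = %.4g + %.4g p%s nm (rms %.3g nm, n = %d)\n",
              co[1], co[2],
              if (length(co) > 2) sprintf(" + %.4g p^2", co[3]) else "",
              object@rmsResidual, object@nPoints))
})

setMethod("show", "TimelapseSeries", function(object) {
  cat(sprintf("TimelapseSeries: %d frames over %g s\n",
              length(object@frames), diff(range(object@timestamps))))
})

setMethod("show", "DriftTrack", function(object) {
  n <- nrow(object@pairwise)
  fin <- object@cumulative[n, ]
  cat(sprintf("DriftTrack: %d pairs, final cumulative shift (%.2f, %.2f) px\n",
              n, fin[1], fin[2]))
})
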