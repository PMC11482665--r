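#' @import methods
NULL

# ---------------------------------------------------------------------------
# Frame: the universal carrier for 2-D image data
# ---------------------------------------------------------------------------

#' Frame: a single image frame
#'
#' A \code{Frame} holds a 2-D grayscale intensity grid (matrix) or an RGB
#' grid (H x W x 3 array) in native integer scale \code{[0, 2^bitDepth - 1]},
#' together with acquisition metadata (exposure time, timestamp, focus
#' position, ...). Pixel values may be fractional (e.g. after flat-field
#' correction) but must stay within the bit-depth range.
#'
#' @slot pixels matrix (grayscale) or H x W x 3 array (RGB)
#' @slot bitDepth integer, sensor bit depth (values live in
#'   \code{[0, 2^bitDepth - 1]})
#' @slot metadata named list; recognised keys include \code{exposure_ms},
#'   \code{timestamp_s}, \code{z_position_um}
#' @exportClass Frame
setClass("Frame",
  slots = c(pixels = "array", bitDepth = "integer", metadata = "list"))

setValidity("Frame", function(object) {
  d <- dim(object@pixels)
  if (is.null(d) || !(length(d) == 2L || (length(d) == 3L && d[3] == 3L)))
    return("pixels must be a 2-D matrix or an H x W x 3 RGB array")
  if (any(d[1:2] < 1L)) return("frame must be non-empty")
  if (length(object@bitDepth) != 1L || object@bitDepth < 1L)
    return("bitDepth must be a single positive integer")
  px <- object@pixels
  if (!all(is.finite(px))) return("pixel values must be finite")
  mx <- 2^object@bitDepth - 1
  if (min(px) < 0 || max(px) > mx)
    return(sprintf("pixel values must lie in [0, %g]", mx))
  TRUE
})

#' Construct a Frame
#'
#' @param pixels matrix or H x W x 3 array of intensities in
#'   \code{[0, 2^bitDepth - 1]}
#' @param bitDepth sensor bit depth (default 8)
#' @param metadata named list of acquisition metadata
#' @return a \linkS4class{Frame}
#' @examples
#' f <- Frame(matrix(0:255, 16, 16), bitDepth = 8L)
#' @export
Frame <- function(pixels, bitDepth = 8L, metadata = list()) {
  if (is.vector(pixels)) stop("pixels must be a matrix or 3-D array")
  new("Frame", pixels = pixels, bitDepth = as.integer(bitDepth),
      metadata = metadata)
}

# ---------------------------------------------------------------------------
# FocusStack
# ---------------------------------------------------------------------------

#' FocusStack: frames ordered by focus position
#'
#' An ordered set of frames acquired while sweeping the lens or stage along
#' the optical axis. Positions are strictly monotonic and all frames share
#' one shape.
#'
#' @slot z numeric vector of focus positions (micrometres)
#' @slot frames list of \linkS4class{Frame}, parallel to \code{z}
#' @slot metadata list (e.g. ground truth for synthetic stacks)
#' @exportClass FocusStack
setClass("FocusStack",
  slots = c(z = "numeric", frames = "list", metadata = "list"))

setValidity("FocusStack", function(object) {
  n <- length(object@frames)
  if (n < 2L) return("a focus stack needs at least two frames")
  if (length(object@z) != n) return("z and frames must have equal length")
  dz <- diff(object@z)
  if (!(all(dz > 0) || all(dz < 0)))
    return("z positions must be strictly monotonic")
  if (!all(vapply(object@frames, is, logical(1), "Frame")))
    return("frames must all be Frame objects")
  d1 <- dim(object@frames[[1]]@pixels)[1:2]
  same <- vapply(object@frames,
                 function(f) identical(dim(f@pixels)[1:2], d1), logical(1))
  if (!all(same)) return("all frames must share one shape")
  TRUE
})

#' Construct a FocusStack
#' @param frames list of \linkS4class{Frame}
#' @param z numeric vector of focus positions (um), strictly monotonic
#' @param metadata optional list
#' @return a \linkS4class{FocusStack}
#' @export
FocusStack <- function(frames, z, metadata = list()) {
  new("FocusStack", z = as.numeric(z), frames = frames, metadata = metadata)
}

# ---------------------------------------------------------------------------
# SharpnessCurve
# ---------------------------------------------------------------------------

#' SharpnessCurve: per-layer sharpness scores of a focus stack
#'
#' @slot z numeric focus positions (um)
#' @slot score numeric non-negative sharpness scores, one per position
#' @slot metricName label of the metric that produced the scores
#' @exportClass SharpnessCurve
setClass("SharpnessCurve",
  slots = c(z = "numeric", score = "numeric", metricName = "character"))

setValidity("SharpnessCurve", function(object) {
  if (length(object@z) != length(object@score))
    return("z and score must have equal length")
  if (length(object@z) < 1L) return("curve must be non-empty")
  TRUE
})

#' Construct a SharpnessCurve
#' @param z focus positions (um)
#' @param score sharpness scores
#' @param metricName metric label
#' @return a \linkS4class{SharpnessCurve}
#' @export
SharpnessCurve <- function(z, score, metricName = "unknown") {
  new("SharpnessCurve", z = as.numeric(z), score = as.numeric(score),
      metricName = metricName)
}

# ---------------------------------------------------------------------------
# AcquisitionPlan
# ---------------------------------------------------------------------------

#' AcquisitionPlan: timelapse bracketing schedule
#'
#' Describes one timelapse event: how often to wake, which exposure ladder
#' to sweep, which focus offsets to bracket, and whether to deep-sleep in
#' between.
#'
#' @slot intervalS seconds between timelapse events (> 0)
#' @slot exposureSeriesMs strictly increasing positive exposure times (ms)
#' @slot focusOffsetsUm signed focus offsets around the nominal position (um)
#' @slot deepSleep logical; sleep between events to save power
#' @exportClass AcquisitionPlan
setClass("AcquisitionPlan",
  slots = c(intervalS = "numeric", exposureSeriesMs = "numeric",
            focusOffsetsUm = "numeric", deepSleep = "logical"))

setValidity("AcquisitionPlan", function(object) {
  e <- object@exposureSeriesMs
  if (length(e) < 1L || any(e <= 0)) return("exposures must be positive")
  if (any(diff(e) <= 0)) return("exposures must be strictly increasing")
  if (length(object@intervalS) != 1L || object@intervalS <= 0)
    return("interval must be a single positive number of seconds")
  TRUE
})

#' Construct an AcquisitionPlan
#' @param intervalS seconds between timelapse events
#' @param exposureSeriesMs strictly increasing exposure ladder (ms)
#' @param focusOffsetsUm signed focus-bracket offsets (um)
#' @param deepSleep sleep between events
#' @return an \linkS4class{AcquisitionPlan}
#' @seealso \code{\link{defaultBracketPlan}}
#' @export
AcquisitionPlan <- function(intervalS, exposureSeriesMs,
                            focusOffsetsUm = c(-8, -4, 0, 4, 8),
                            deepSleep = TRUE) {
  new("AcquisitionPlan", intervalS = as.numeric(intervalS),
      exposureSeriesMs = as.numeric(exposureSeriesMs),
      focusOffsetsUm = as.numeric(focusOffsetsUm),
      deepSleep = isTRUE(deepSleep))
}

# ---------------------------------------------------------------------------
# Optics containers
# ---------------------------------------------------------------------------

#' ConjugatePair: object/image distances of a finite-conjugate setup
#'
#' Cartesian sign convention with light travelling left to right: the object
#' distance \code{a} is negative (object left of the lens) and the image
#' distance \code{aPrime} is positive for a real image.
#'
#' @slot aMm object distance (mm, negative)
#' @slot aPrimeMm image distance (mm, positive)
#' @exportClass ConjugatePair
setClass("ConjugatePair", slots = c(aMm = "numeric", aPrimeMm = "numeric"))

setValidity("ConjugatePair", function(object) {
  if (length(object@aMm) != 1L || length(object@aPrimeMm) != 1L)
    return("distances must be single numbers")
  if (!(object@aMm < 0)) return("object distance a must be negative (object side)")
  if (!(object@aPrimeMm > 0)) return("image distance a' must be positive (real image)")
  TRUE
})

#' Construct a ConjugatePair
#' @param aMm object distance (mm, negative)
#' @param aPrimeMm image distance (mm, positive)
#' @return a \linkS4class{ConjugatePair}
#' @export
ConjugatePair <- function(aMm, aPrimeMm) {
  new("ConjugatePair", aMm = as.numeric(aMm), aPrimeMm = as.numeric(aPrimeMm))
}

#' OpticalConfig: static optical parameters of a camera-lens module
#'
#' @slot focalLengthMm lens focal length (mm)
#' @slot fNumber lens f-number (>= 0.5)
#' @slot wavelengthNm design wavelength (nm)
#' @slot pixelPitchUm sensor pixel pitch (um)
#' @slot sensorPx integer (width, height) in pixels
#' @exportClass OpticalConfig
setClass("OpticalConfig",
  slots = c(focalLengthMm = "numeric", fNumber = "numeric",
            wavelengthNm = "numeric", pixelPitchUm = "numeric",
            sensorPx = "integer"))

setValidity("OpticalConfig", function(object) {
  if (object@focalLengthMm <= 0) return("focal length must be positive")
  if (object@fNumber < 0.5) return("f-number must be >= 0.5")
  if (object@wavelengthNm <= 0) return("wavelength must be positive")
  if (object@pixelPitchUm <= 0) return("pixel pitch must be positive")
  if (length(object@sensorPx) != 2L || any(object@sensorPx < 1L))
    return("sensorPx must be two positive integers")
  TRUE
})

#' Construct an OpticalConfig
#'
#' Defaults describe a typical fixed-focus 2-megapixel CMOS camera module
#' (f' = 4 mm, f/2.2, 2.2 um pitch, 1600 x 1200 px).
#'
#' @param focalLengthMm focal length (mm)
#' @param fNumber f-number
#' @param wavelengthNm design wavelength (nm)
#' @param pixelPitchUm pixel pitch (um)
#' @param sensorPx integer (width, height)
#' @return an \linkS4class{OpticalConfig}
#' @export
OpticalConfig <- function(focalLengthMm = 4, fNumber = 2.2,
                          wavelengthNm = 550, pixelPitchUm = 2.2,
                          sensorPx = c(1600L, 1200L)) {
  new("OpticalConfig", focalLengthMm = as.numeric(focalLengthMm),
      fNumber = as.numeric(fNumber), wavelengthNm = as.numeric(wavelengthNm),
      pixelPitchUm = as.numeric(pixelPitchUm),
      sensorPx = as.integer(sensorPx))
}

# ---------------------------------------------------------------------------
# Holography containers
# ---------------------------------------------------------------------------

#' Hologram: an inline hologram frame plus its optical context
#'
#' @slot frame grayscale \linkS4class{Frame} with the recorded intensity
#' @slot wavelengthNm illumination wavelength (nm, 350--800)
#' @slot pixelPitchUm sensor pixel pitch (um)
#' @slot sourceDistanceMm distance point source to sample (mm);
#'   \code{Inf} means plane-wave illumination
#' @slot background optional grayscale \linkS4class{Frame} recorded without
#'   the sample, or \code{NULL}
#' @exportClass Hologram
setClass("Hologram",
  slots = c(frame = "Frame", wavelengthNm = "numeric",
            pixelPitchUm = "numeric", sourceDistanceMm = "numeric",
            background = "ANY"))

setValidity("Hologram", function(object) {
  if (object@wavelengthNm < 350 || object@wavelengthNm > 800)
    return("wavelength must lie in [350, 800] nm")
  if (object@pixelPitchUm <= 0) return("pixel pitch must be positive")
  if (length(dim(object@frame@pixels)) != 2L)
    return("hologram frame must be grayscale")
  bg <- object@background
  if (!is.null(bg)) {
    if (!is(bg, "Frame")) return("background must be a Frame or NULL")
    if (!identical(dim(bg@pixels), dim(object@frame@pixels)))
      return("background must match the hologram frame shape")
  }
  TRUE
})

#' Construct a Hologram
#' @param frame grayscale \linkS4class{Frame}
#' @param wavelengthNm illumination wavelength (nm)
#' @param pixelPitchUm pixel pitch (um)
#' @param sourceDistanceMm source-to-sample distance (mm); \code{Inf} for
#'   plane-wave illumination (default)
#' @param background optional background \linkS4class{Frame}
#' @return a \linkS4class{Hologram}
#' @export
Hologram <- function(frame, wavelengthNm = 450, pixelPitchUm = 2.2,
                     sourceDistanceMm = Inf, background = NULL) {
  new("Hologram", frame = frame, wavelengthNm = as.numeric(wavelengthNm),
      pixelPitchUm = as.numeric(pixelPitchUm),
      sourceDistanceMm = as.numeric(sourceDistanceMm),
      background = background)
}

#' ComplexField: a sampled complex optical field
#'
#' @slot values complex matrix (amplitude and phase)
#' @slot pitchUm lateral sampling pitch (um)
#' @exportClass ComplexField
setClass("ComplexField", slots = c(values = "matrix", pitchUm = "numeric"))

setValidity("ComplexField", function(object) {
  if (!is.complex(object@values)) return("values must be complex")
  if (!all(is.finite(Re(object@values)) & is.finite(Im(object@values))))
    return("field values must be finite")
  if (object@pitchUm <= 0) return("pitch must be positive")
  TRUE
})

#' Construct a ComplexField
#' @param values complex (or numeric, coerced) matrix
#' @param pitchUm sampling pitch (um)
#' @return a \linkS4class{ComplexField}
#' @export
ComplexField <- function(values, pitchUm) {
  if (!is.complex(values)) values <- values + 0i
  new("ComplexField", values = values, pitchUm = as.numeric(pitchUm))
}

#' ParticleScene: absorbing particles at one depth above the sensor
#'
#' Continuous scene coordinates: the centre of pixel (row r, column c) is at
#' x = (c - 0.5) * pitch, y = (r - 0.5) * pitch, origin at the top-left
#' corner of the field of view.
#'
#' @slot particles data.frame with columns \code{x_um}, \code{y_um},
#'   \code{radius_um}, \code{opacity} (0 transparent .. 1 opaque)
#' @slot zUm particle plane height above the sensor (um)
#' @exportClass ParticleScene
setClass("ParticleScene", slots = c(particles = "data.frame", zUm = "numeric"))

setValidity("ParticleScene", function(object) {
  p <- object@particles
  need <- c("x_um", "y_um", "radius_um", "opacity")
  if (!all(need %in% names(p)))
    return("particles needs columns x_um, y_um, radius_um, opacity")
  if (nrow(p) > 0) {
    if (any(p$radius_um <= 0)) return("radii must be positive")
    if (any(p$opacity < 0 | p$opacity > 1)) return("opacity must lie in [0, 1]")
  }
  if (length(object@zUm) != 1L || object@zUm <= 0)
    return("zUm must be a single positive depth")
  TRUE
})

#' Construct a ParticleScene
#' @param particles data.frame(x_um, y_um, radius_um, opacity); may be empty
#' @param zUm depth of the particle plane above the sensor (um)
#' @return a \linkS4class{ParticleScene}
#' @export
ParticleScene <- function(particles, zUm) {
  if (nrow(particles) == 0)
    particles <- data.frame(x_um = numeric(0), y_um = numeric(0),
                            radius_um = numeric(0), opacity = numeric(0))
  new("ParticleScene", particles = particles, zUm = as.numeric(zUm))
}

# ---------------------------------------------------------------------------
# Spectrometry containers
# ---------------------------------------------------------------------------

#' DispersionAxis: the user-selected spectral segment on the sensor
#'
#' Endpoints are continuous 1-based pixel coordinates \code{(x, y)} with x
#' the column and y the row index.
#'
#' @slot p0 numeric (x, y) of the segment start
#' @slot p1 numeric (x, y) of the segment end
#' @slot bandWidth odd integer; pixels averaged perpendicular to the axis
#' @exportClass DispersionAxis
setClass("DispersionAxis",
  slots = c(p0 = "numeric", p1 = "numeric", bandWidth = "integer"))

setValidity("DispersionAxis", function(object) {
  if (length(object@p0) != 2L || length(object@p1) != 2L)
    return("endpoints must be (x, y) pairs")
  if (all(object@p0 == object@p1)) return("endpoints must differ")
  b <- object@bandWidth
  if (length(b) != 1L || b < 1L || b %% 2L == 0L)
    return("bandWidth must be an odd integer >= 1")
  TRUE
})

#' Construct a DispersionAxis
#' @param p0,p1 numeric (x, y) endpoints, 1-based pixel coordinates
#' @param bandWidth odd integer band width (default 1)
#' @return a \linkS4class{DispersionAxis}
#' @export
DispersionAxis <- function(p0, p1, bandWidth = 1L) {
  new("DispersionAxis", p0 = as.numeric(p0), p1 = as.numeric(p1),
      bandWidth = as.integer(bandWidth))
}

#' Spectrum: a 1-D spectrum sampled along the dispersion axis
#'
#' @slot position distances along the axis (px)
#' @slot intensity matrix with columns \code{r}, \code{g}, \code{b},
#'   \code{lum}; for grayscale sources all four coincide
#' @slot wavelength calibrated wavelength axis (nm) or \code{numeric(0)} if
#'   uncalibrated
#' @exportClass Spectrum
setClass("Spectrum",
  slots = c(position = "numeric", intensity = "matrix",
            wavelength = "numeric"))

setValidity("Spectrum", function(object) {
  n <- length(object@position)
  if (nrow(object@intensity) != n)
    return("intensity rows must match position length")
  if (!all(c("r", "g", "b", "lum") %in% colnames(object@intensity)))
    return("intensity needs columns r, g, b, lum")
  if (any(object@intensity < 0)) return("intensities must be non-negative")
  if (length(object@wavelength) > 0 && length(object@wavelength) != n)
    return("wavelength must be empty or match position length")
  TRUE
})

#' Construct a Spectrum
#' @param position distances along the dispersion axis (px)
#' @param intensity matrix with columns r, g, b, lum
#' @param wavelength optional wavelength axis (nm)
#' @return a \linkS4class{Spectrum}
#' @export
Spectrum <- function(position, intensity, wavelength = numeric(0)) {
  new("Spectrum", position = as.numeric(position), intensity = intensity,
      wavelength = as.numeric(wavelength))
}

#' WavelengthCalibration: pixel-to-wavelength mapping
#'
#' Polynomial map \eqn{\lambda(p) = c_0 + c_1 p (+ c_2 p^2)}; the linear
#' model is the default for visible-range slit spectrometers.
#'
#' @slot coefficients numeric; intercept (nm), slope (nm/px) and optionally
#'   a quadratic term (nm/px^2)
#' @slot rmsResidual root-mean-square fit residual (nm)
#' @slot nPoints number of calibration points used
#' @exportClass WavelengthCalibration
setClass("WavelengthCalibration",
  slots = c(coefficients = "numeric", rmsResidual = "numeric",
            nPoints = "integer"))

setValidity("WavelengthCalibration", function(object) {
  if (length(object@coefficients) < 2L)
    return("calibration needs at least intercept and slope")
  if (object@coefficients[2] == 0) return("slope must be nonzero")
  if (object@nPoints < 2L) return("calibration needs >= 2 points")
  TRUE
})

# ---------------------------------------------------------------------------
# Timelapse containers
# ---------------------------------------------------------------------------

#' TimelapseSeries: frames with strictly increasing timestamps
#'
#' @slot frames list of \linkS4class{Frame}, all one shape
#' @slot timestamps seconds since the start of the series
#' @slot metadata list (e.g. ground truth for synthetic series)
#' @exportClass TimelapseSeries
setClass("TimelapseSeries",
  slots = c(frames = "list", timestamps = "numeric", metadata = "list"))

setValidity("TimelapseSeries", function(object) {
  n <- length(object@frames)
  if (n < 2L) return("a timelapse needs at least two frames")
  if (length(object@timestamps) != n)
    return("timestamps must be parallel to frames")
  if (any(diff(object@timestamps) <= 0))
    return("timestamps must be strictly increasing")
  if (!all(vapply(object@frames, is, logical(1), "Frame")))
    return("frames must all be Frame objects")
  d1 <- dim(object@frames[[1]]@pixels)[1:2]
  same <- vapply(object@frames,
                 function(f) identical(dim(f@pixels)[1:2], d1), logical(1))
  if (!all(same)) return("all frames must share one shape")
  TRUE
})

#' Construct a TimelapseSeries
#' @param frames list of \linkS4class{Frame}
#' @param timestamps strictly increasing seconds since start
#' @param metadata optional list
#' @return a \linkS4class{TimelapseSeries}
#' @export
TimelapseSeries <- function(frames, timestamps, metadata = list()) {
  new("TimelapseSeries", frames = frames,
      timestamps = as.numeric(timestamps), metadata = metadata)
}

#' DriftTrack: lateral drift of a timelapse
#'
#' Pairwise shifts between successive frames (phase correlation) and their
#' prefix sums. A pair whose registration failed is recorded as \code{NA}
#' with quality 0 and contributes zero to the cumulative track.
#'
#' @slot pairwise (n-1) x 2 matrix of per-pair shifts (dx, dy) in px
#' @slot cumulative (n-1) x 2 matrix of running sums (px)
#' @slot peakQuality correlation peak ratio per pair
#' @slot pixelSizeUm effective pixel size for um conversion (NA if unknown)
#' @exportClass DriftTrack
setClass("DriftTrack",
  slots = c(pairwise = "matrix", cumulative = "matrix",
            peakQuality = "numeric", pixelSizeUm = "numeric"))

setValidity("DriftTrack", function(object) {
  if (ncol(object@pairwise) != 2L || ncol(object@cumulative) != 2L)
    return("shift matrices must have two columns (dx, dy)")
  if (nrow(object@pairwise) != nrow(object@cumulative))
    return("pairwise and cumulative must have equal rows")
  if (length(object@peakQuality) != nrow(object@pairwise))
    return("peakQuality must be parallel to pairwise")
  TRUE
})
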