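# Spectrum extraction along the first diffraction order and pixel-to-
# wavelength calibration for grating spectrometers built on camera modules.

#' Extract a 1-D spectrum along a dispersion axis
#'
#' Samples the frame at 1-px steps along the segment from \code{p0} to
#' \code{p1} (bilinear interpolation), averaging over \code{bandWidth}
#' pixels perpendicular to the axis at each step (unweighted mean).
#' Saturated pixels (at or above 0.99 of full scale) are excluded from the
#' perpendicular mean and counted; samples falling outside the frame are
#' clamped to the border and counted in a warning.
#'
#' @param frame a \linkS4class{Frame} (grayscale or RGB)
#' @param axis a \linkS4class{DispersionAxis}
#' @return a \linkS4class{Spectrum} with per-channel (r, g, b) and luminance
#'   intensities; for grayscale input all channels coincide
#' @export
extractSpectrum <- function(frame, axis) {
  if (!is(frame, "Frame")) stop("frame must be a Frame")
  if (!is(axis, "DispersionAxis")) stop("axis must be a DispersionAxis")
  px <- frame@pixels
  d <- dim(px)
  nr <- d[1]; nc <- d[2]
  if (any(axis@p0 < 1) || any(axis@p1 < 1) ||
      axis@p0[1] > nc || axis@p1[1] > nc ||
      axis@p0[2] > nr || axis@p1[2] > nr)
    stop("axis endpoints must lie within the frame")
  delta <- axis@p1 - axis@p0
  len <- sqrt(sum(delta^2))
  u <- delta / len                    # along-axis unit vector (x, y)
  v <- c(-u[2], u[1])                 # perpendicular unit vector
  t <- seq(0, len, by = 1)
  off <- seq(-(axis@bandWidth - 1) / 2, (axis@bandWidth - 1) / 2)
  # sample coordinates: length(t) rows x bandWidth cols
  X <- outer(t, rep(1, length(off))) * u[1] + outer(rep(1, length(t)), off) * v[1] + axis@p0[1]
  Y <- outer(t, rep(1, length(off))) * u[2] + outer(rep(1, length(t)), off) * v[2] + axis@p0[2]
  mx <- maxValue(frame)
  satLevel <- 0.99 * mx
  sampleChannel <- function(m) {
    vals <- .bilinear(m, as.vector(X), as.vector(Y))
    matrix(vals, nrow = length(t))
  }
  chans <- if (length(d) == 3L) {
    list(r = sampleChannel(px[, , 1]), g = sampleChannel(px[, , 2]),
         b = sampleChannel(px[, , 3]))
  } else {
    list(r = sampleChannel(px), g = NULL, b = NULL)
  }
  nClamped <- sum(as.vector(X) < 1 | as.vector(X) > nc |
                  as.vector(Y) < 1 | as.vector(Y) > nr)
  if (nClamped > 0)
    warning(sprintf("%d band sample(s) outside the frame were clamped",
                    nClamped))
  bandMean <- function(m) {
    if (is.null(m)) return(NULL)
    satur <- m >= satLevel
    keep <- !satur
    s <- rowSums(m * keep)
    nOk <- rowSums(keep)
    out <- ifelse(nOk > 0, s / pmax(nOk, 1), rowMeans(m))
    out
  }
  if (length(d) == 3L) {
    r <- bandMean(chans$r); g <- bandMean(chans$g); b <- bandMean(chans$b)
    lum <- .LUM_WEIGHTS[1] * r + .LUM_WEIGHTS[2] * g + .LUM_WEIGHTS[3] * b
  } else {
    r <- g <- b <- lum <- bandMean(chans$r)
  }
  nSat <- if (length(d) == 3L)
    sum(chans$r >= satLevel | chans$g >= satLevel | chans$b >= satLevel)
  else sum(chans$r >= satLevel)
  sp <- Spectrum(position = t,
                 intensity = cbind(r = pmax(r, 0), g = pmax(g, 0),
                                   b = pmax(b, 0), lum = pmax(lum, 0)))
  attr(sp, "saturated_samples") <- nSat
  attr(sp, "clamped_samples") <- nClamped
  sp
}

#' Fit a pixel-to-wavelength calibration
#'
#' Ordinary least-squares fit of wavelength against pixel position, linear
#' by default. A quadratic option exists for geometries where the grating
#' equation introduces mild nonlinearity, but visible-range linearity is the
#' standard assumption for slit spectrometers.
#'
#' @param pairs data.frame with columns \code{position} (px) and
#'   \code{wavelength} (nm); the column names \code{position_px} /
#'   \code{wavelength_nm} are also accepted
#' @param degree polynomial degree, 1 (default) or 2
#' @return a \linkS4class{WavelengthCalibration}
#' @examples
#' fitCalibration(data.frame(position = c(100, 300),
#'                           wavelength = c(450, 650)))
#' @export
fitCalibration <- function(pairs, degree = 1L) {
  nm <- names(pairs)
  pcol <- if ("position" %in% nm) "position" else "position_px"
  wcol <- if ("wavelength" %in% nm) "wavelength" else "wavelength_nm"
  if (!all(c(pcol, wcol) %in% nm))
    stop("pairs needs position and wavelength columns")
  p <- as.numeric(pairs[[pcol]]); w <- as.numeric(pairs[[wcol]])
  if (length(p) < 2L) stop("calibration needs at least 2 points")
  if (length(unique(p)) < degree + 1L)
    stop("not enough distinct positions for the requested degree")
  if (!degree %in% 1:2) stop("degree must be 1 or 2")
  fit <- if (degree == 1L) stats::lm(w ~ p)
         else stats::lm(w ~ p + I(p^2))
  co <- unname(stats::coef(fit))
  rms <- sqrt(mean(stats::residuals(fit)^2))
  new("WavelengthCalibration", coefficients = co, rmsResidual = rms,
      nPoints = length(p))
}

#' Apply a wavelength calibration to a spectrum
#'
#' Populates the spectrum's wavelength axis from its pixel positions. For a
#' linear calibration the axis is strictly monotonic with the sign of the
#' slope.
#'
#' @param s a \linkS4class{Spectrum}
#' @param cal a \linkS4class{WavelengthCalibration}
#' @return the calibrated \linkS4class{Spectrum}
#' @export
applyCalibration <- function(s, cal) {
  if (!is(s, "Spectrum")) stop("s must be a Spectrum")
  if (!is(cal, "WavelengthCalibration"))
    stop("cal must be a WavelengthCalibration")
  co <- cal@coefficients
  p <- s@position
  w <- co[1] + co[2] * p
  if (length(co) > 2L) w <- w + co[3] * p^2
  Spectrum(position = p, intensity = s@intensity, wavelength = w)
}

#' Absorbance spectrum from sample and reference
#'
#' Beer-Lambert absorbance A = -log10(I_sample / I_reference), channel by
#' channel, with intensities floored at 1e-6 of the spectra's joint full
#' scale to keep the logarithm finite.
#'
#' @param sample,reference \linkS4class{Spectrum} objects on the identical
#'   position grid
#' @return a \linkS4class{Spectrum} of absorbance values (clamped at 0 from
#'   below); the wavelength axis is carried over from \code{sample} if set,
#'   else from \code{reference}
#' @export
absorbance <- function(sample, reference) {
  if (!is(sample, "Spectrum") || !is(reference, "Spectrum"))
    stop("sample and reference must be Spectrum objects")
  if (length(sample@position) != length(reference@position) ||
      any(abs(sample@position - reference@position) > 1e-9))
    stop("sample and reference must share one position grid")
  eps <- 1e-6 * max(sample@intensity, reference@intensity, 1)
  A <- -log10(pmax(sample@intensity, eps) / pmax(reference@intensity, eps))
  A <- pmax(A, 0)
  colnames(A) <- colnames(sample@intensity)
  wl <- if (length(sample@wavelength)) sample@wavelength
        else reference@wavelength
  Spectrum(position = sample@position, intensity = A, wavelength = wl)
}

#' Locate peaks in a spectrum channel
#'
#' Smooths the chosen channel with a moving average and returns the local
#' maxima whose prominence (height above the higher of the two flanking
#' minima) exceeds \code{minProminence} of the curve's range. Used to count
#' emission peaks, e.g. the two-lobe signature of a white LED.
#'
#' @param s a \linkS4class{Spectrum}
#' @param channel one of \code{"r"}, \code{"g"}, \code{"b"}, \code{"lum"}
#' @param smoothWindow odd moving-average window (px)
#' @param minProminence minimum prominence as a fraction of the smoothed
#'   curve's range
#' @return data.frame with columns \code{position}, \code{intensity} (and
#'   \code{wavelength} when calibrated)
#' @export
spectrumPeaks <- function(s, channel = "lum", smoothWindow = 11L,
                          minProminence = 0.1) {
  if (!is(s, "Spectrum")) stop("s must be a Spectrum")
  y <- s@intensity[, channel]
  if (smoothWindow > 1L) {
    r <- (smoothWindow - 1L) %/% 2L
    k <- rep(1 / (2 * r + 1), 2 * r + 1)
    n <- length(y)
    yp <- c(rep(y[1], r), y, rep(y[n], r))
    y <- as.numeric(stats::filter(yp, k, sides = 2))[(r + 1):(r + n)]
  }
  idx <- .localMaxima(y)
  if (length(idx) == 0)
    return(data.frame(position = numeric(0), intensity = numeric(0)))
  rng <- diff(range(y))
  keep <- vapply(idx, function(i) {
    leftMin <- min(y[1:i]); rightMin <- min(y[i:length(y)])
    prom <- y[i] - max(leftMin, rightMin)
    rng > 0 && prom >= minProminence * rng
  }, logical(1))
  idx <- idx[keep]
  out <- data.frame(position = s@position[idx], intensity = y[idx])
  if (length(s@wavelength)) out$wavelength <- s@wavelength[idx]
  out
}
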