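# Long-duration timelapse analytics: flat-field (shading) correction,
# phase-correlation drift tracking, temporal variance projection and
# per-exposure intensity time series.

#' Flat-field (shading) correction
#'
#' Removes vignetting and illumination inhomogeneity:
#' \code{out = (frame - dark) / ((flat - dark) / mean(flat - dark))}, with
#' the dark frame defaulting to zero. Because the gain map is normalized to
#' unit mean, mean brightness is preserved. The result is clipped to the
#' frame's bit-depth range.
#'
#' @param frame \linkS4class{Frame} to correct
#' @param flat flat-field reference \linkS4class{Frame} (same shape)
#' @param dark optional dark \linkS4class{Frame} (same shape)
#' @return corrected \linkS4class{Frame}
#' @export
flatFieldCorrect <- function(frame, flat, dark = NULL) {
  if (!is(frame, "Frame") || !is(flat, "Frame"))
    stop("frame and flat must be Frame objects")
  if (!identical(dim(frame@pixels), dim(flat@pixels)))
    stop("frame and flat must share one shape")
  dk <- if (is.null(dark)) 0 else {
    if (!identical(dim(dark@pixels), dim(frame@pixels)))
      stop("dark must match the frame shape")
    dark@pixels
  }
  denom <- flat@pixels - dk
  m <- mean(denom)
  if (abs(m) < .Machine$double.eps * 100)
    stop("flat field has zero mean after dark subtraction")
  gain <- denom / m
  eps <- 1e-6
  gain[abs(gain) < eps] <- eps
  out <- (frame@pixels - dk) / gain
  mx <- maxValue(frame)
  Frame(.clip(out, 0, mx), frame@bitDepth,
        metadata = c(frame@metadata, list(flat_field_corrected = TRUE)))
}

#' Translation between two frames by phase correlation
#'
#' Estimates the lateral shift from \code{f1} to \code{f2} as the peak of
#' the phase correlation surface (inverse transform of the spectrally
#' whitened cross-power spectrum), optionally refined to subpixel precision
#' by a three-point parabolic fit per axis. Frames are mean-subtracted and
#' Hann-windowed before the FFT to suppress edge effects. Sign convention:
#' \code{f2} looks like \code{f1} shifted by (+dx columns, +dy rows).
#'
#' @param f1,f2 \linkS4class{Frame} objects of one shape, non-constant
#' @param subpixel apply parabolic subpixel refinement (default TRUE)
#' @param window apply a Hann window (default TRUE)
#' @param method \code{"phase"} (whitened, default) or \code{"cross"} (raw
#'   cross-correlation) for comparison
#' @return named numeric vector \code{c(dx, dy, quality)}; quality is the
#'   ratio of the correlation peak to the largest value outside its 5 x 5
#'   neighbourhood
#' @export
pairShift <- function(f1, f2, subpixel = TRUE, window = TRUE,
                      method = c("phase", "cross")) {
  if (!is(f1, "Frame") || !is(f2, "Frame"))
    stop("f1 and f2 must be Frame objects")
  method <- match.arg(method)
  g1 <- .lum(f1); g2 <- .lum(f2)
  if (!identical(dim(g1), dim(g2))) stop("frames must share one shape")
  if (stats::sd(g1) == 0 || stats::sd(g2) == 0)
    stop("shift is undefined for a constant frame")
  nr <- nrow(g1); nc <- ncol(g1)
  if (window) {
    w <- .hann2(nr, nc)
    a <- (g1 - mean(g1)) * w
    b <- (g2 - mean(g2)) * w
  } else {
    a <- g1 - mean(g1)
    b <- g2 - mean(g2)
  }
  X <- .fft2(b) * Conj(.fft2(a))
  if (method == "phase") {
    mag <- Mod(X)
    X <- X / pmax(mag, max(mag) * 1e-12)
  }
  r <- Re(.ifft2(X))
  pk <- which.max(r)
  iy <- (pk - 1) %% nr          # 0-based row
  ix <- (pk - 1) %/% nr         # 0-based col
  wrap <- function(i, n) if (i > n / 2) i - n else i
  dy <- wrap(iy, nr); dx <- wrap(ix, nc)
  if (subpixel) {
    cy <- iy + 1L; cx <- ix + 1L
    ym1 <- r[(iy - 1) %% nr + 1L, cx]; yp1 <- r[(iy + 1) %% nr + 1L, cx]
    xm1 <- r[cy, (ix - 1) %% nc + 1L]; xp1 <- r[cy, (ix + 1) %% nc + 1L]
    dy <- dy + .parabolicOffset(ym1, r[cy, cx], yp1)
    dx <- dx + .parabolicOffset(xm1, r[cy, cx], xp1)
  }
  # peak quality: peak over the best competitor outside a 5x5 zone
  ry <- ((iy + (-2:2)) %% nr) + 1L
  rx <- ((ix + (-2:2)) %% nc) + 1L
  r2 <- r
  r2[ry, rx] <- -Inf
  competitor <- max(r2)
  quality <- if (competitor > 0) r[iy + 1L, ix + 1L] / competitor else Inf
  c(dx = dx, dy = dy, quality = quality)
}

#' Drift track of a timelapse series
#'
#' Registers every pair of successive frames with \code{\link{pairShift}}
#' and accumulates the pairwise shifts into a cumulative track (prefix
#' sums). A pair that fails to register (e.g. a constant frame) is recorded
#' as \code{NA} with quality 0 and contributes zero drift. Successive-pair
#' registration tracks slow drift faithfully but accumulates per-pair error
#' over very long series.
#'
#' @param series a \linkS4class{TimelapseSeries}
#' @param subpixel,window,method passed to \code{\link{pairShift}}
#' @param pixelSizeUm effective pixel size for micron conversion (NA if
#'   unknown)
#' @return a \linkS4class{DriftTrack}
#' @export
driftTrack <- function(series, subpixel = TRUE, window = TRUE,
                       method = c("phase", "cross"), pixelSizeUm = NA_real_) {
  if (!is(series, "TimelapseSeries")) stop("series must be a TimelapseSeries")
  method <- match.arg(method)
  n <- length(series@frames)
  pw <- matrix(NA_real_, n - 1L, 2L, dimnames = list(NULL, c("dx", "dy")))
  q <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    res <- tryCatch(
      pairShift(series@frames[[i]], series@frames[[i + 1L]],
                subpixel = subpixel, window = window, method = method),
      error = function(e) NULL)
    if (!is.null(res)) {
      pw[i, ] <- res[c("dx", "dy")]
      q[i] <- res["quality"]
    }
  }
  filled <- pw
  filled[is.na(filled)] <- 0
  cum <- apply(filled, 2, cumsum)
  if (n == 2L) cum <- matrix(cum, 1L, 2L)
  colnames(cum) <- c("dx", "dy")
  new("DriftTrack", pairwise = pw, cumulative = cum, peakQuality = q,
      pixelSizeUm = as.numeric(pixelSizeUm))
}

#' Drift track as a data frame
#'
#' @param track a \linkS4class{DriftTrack}
#' @return data.frame with pair index, pairwise and cumulative shifts in px
#'   (and in um when the track carries a pixel size)
#' @export
driftTrackTable <- function(track) {
  if (!is(track, "DriftTrack")) stop("track must be a DriftTrack")
  out <- data.frame(pair = seq_len(nrow(track@pairwise)),
                    dx_px = track@pairwise[, 1], dy_px = track@pairwise[, 2],
                    cum_dx_px = track@cumulative[, 1],
                    cum_dy_px = track@cumulative[, 2],
                    quality = track@peakQuality)
  if (is.finite(track@pixelSizeUm)) {
    out$cum_dx_um <- out$cum_dx_px * track@pixelSizeUm
    out$cum_dy_um <- out$cum_dy_px * track@pixelSizeUm
  }
  out
}

#' Temporal variance projection
#'
#' Per-pixel variance of the luminance over time, min-max rescaled to the
#' series' bit depth. Moving objects leave bright traces along their
#' trajectories; the projection is invariant to frame order.
#'
#' @param series a \linkS4class{TimelapseSeries}
#' @return a \linkS4class{Frame} with the rescaled variance map
#' @export
varianceProjection <- function(series) {
  if (!is(series, "TimelapseSeries")) stop("series must be a TimelapseSeries")
  n <- length(series@frames)
  s1 <- 0; s2 <- 0
  for (f in series@frames) {
    g <- .lum(f)
    s1 <- s1 + g
    s2 <- s2 + g^2
  }
  v <- (s2 - s1^2 / n) / (n - 1)
  v <- pmax(v, 0)
  bd <- series@frames[[1]]@bitDepth
  mx <- 2^bd - 1
  rng <- max(v) - min(v)
  px <- if (rng > 0) (v - min(v)) / rng * mx else v * 0
  Frame(px, bd, metadata = list(variance_projection = TRUE, n_frames = n))
}

#' Mean-intensity time series per exposure group
#'
#' Mean luminance of every frame against its timestamp, grouped by the
#' frames' \code{exposure_ms} metadata (one series per exposure of a
#' bracketing schedule). Frames without exposure metadata fall into a single
#' group with a warning.
#'
#' @param series a \linkS4class{TimelapseSeries}
#' @return data.frame with columns \code{timestamp_s}, \code{exposure_ms},
#'   \code{mean_intensity}
#' @export
intensitySeries <- function(series) {
  if (!is(series, "TimelapseSeries")) stop("series must be a TimelapseSeries")
  expo <- vapply(series@frames, function(f) {
    e <- f@metadata$exposure_ms
    if (is.null(e)) NA_real_ else as.numeric(e)
  }, numeric(1))
  if (all(is.na(expo))) {
    warning("no exposure metadata: treating all frames as one group")
    expo <- rep(0, length(expo))
  } else if (any(is.na(expo))) {
    warning("frames without exposure metadata grouped as exposure 0")
    expo[is.na(expo)] <- 0
  }
  data.frame(timestamp_s = series@timestamps,
             exposure_ms = expo,
             mean_intensity = vapply(series@frames,
                                     function(f) mean(.lum(f)), numeric(1)))
}
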