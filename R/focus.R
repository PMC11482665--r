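# Sharpness metrics, focus-stack autofocus, extended depth of field, and
# exposure/focus bracketing.

#' JPEG-size sharpness score
#'
#' Estimates relative sharpness as the byte length of the frame's luminance
#' plane encoded as a baseline JPEG at fixed settings. JPEG spends more bits
#' on images with stronger high-spatial-frequency content, so within one
#' encoder configuration a larger file means a sharper frame. The score is
#' comparative only: it carries no absolute meaning and must not be compared
#' across different qualities or encoders.
#'
#' @param frame a \linkS4class{Frame} (grayscale or RGB; RGB is reduced to
#'   luminance before encoding, which also sidesteps chroma subsampling)
#' @param quality JPEG quality, 1-100 (default 85); keep fixed across all
#'   frames being compared
#' @return integer byte count with attributes recording the encoder settings
#' @examples
#' flat <- Frame(matrix(128, 64, 64))
#' tex  <- Frame(matrix(sample(0:255, 64 * 64, TRUE), 64, 64))
#' jpegSizeSharpness(tex) > jpegSizeSharpness(flat)
#' @export
jpegSizeSharpness <- function(frame, quality = 85L) {
  if (!is(frame, "Frame")) stop("frame must be a Frame")
  if (quality < 1 || quality > 100) stop("quality must be in [1, 100]")
  g <- .lum(frame) / maxValue(frame)
  bytes <- length(jpeg::writeJPEG(g, raw(), quality = quality / 100))
  structure(bytes, encoder = "libjpeg-baseline-grayscale",
            quality = as.integer(quality))
}

# Orthonormal DCT-II basis matrix of size n.
.dctMatrix <- function(n = 8L) {
  k <- 0:(n - 1)
  D <- sqrt(2 / n) * cos(pi * outer(k, k + 0.5) / n)
  D[1, ] <- sqrt(1 / n)
  D
}

#' DCT high-frequency sharpness score
#'
#' Splits the luminance plane into 8 x 8 blocks (cropping any remainder),
#' takes each block's orthonormal 2-D DCT, and returns the fraction of block
#' energy carried by coefficients outside the top-left 2 x 2 (the DC term
#' and the lowest horizontal/vertical/diagonal frequencies), averaged over
#' blocks. A constant frame scores 0; blur moves energy into the low block
#' and lowers the score.
#'
#' @param frame a \linkS4class{Frame}, at least 8 x 8
#' @return score in [0, 1)
#' @export
dctSharpness <- function(frame) {
  if (!is(frame, "Frame")) stop("frame must be a Frame")
  g <- .lum(frame)
  if (nrow(g) < 8L || ncol(g) < 8L) stop("frame must be at least 8 x 8")
  h8 <- nrow(g) %/% 8L; w8 <- ncol(g) %/% 8L
  g <- g[seq_len(8L * h8), seq_len(8L * w8)]
  nb <- h8 * w8
  # reorder into an 8 x 8 x nBlocks array
  arr <- array(g, c(8L, h8, 8L, w8))
  blocks <- aperm(arr, c(1, 3, 2, 4))
  dim(blocks) <- c(8L, 8L, nb)
  D <- .dctMatrix(8L)
  t1 <- D %*% matrix(blocks, nrow = 8L)                 # row transform
  a2 <- aperm(array(t1, c(8L, 8L, nb)), c(2, 1, 3))
  t2 <- D %*% matrix(a2, nrow = 8L)                     # column transform
  coef <- aperm(array(t2, c(8L, 8L, nb)), c(2, 1, 3))
  E <- coef^2
  tot <- colSums(matrix(E, nrow = 64L))
  low <- colSums(matrix(E[1:2, 1:2, , drop = FALSE], nrow = 4L))
  frac <- ifelse(tot > 0, 1 - low / tot, 0)
  mean(frac)
}

#' Sharpness curve of a focus stack
#'
#' Scores every layer of a focus stack with the chosen metric, in stack
#' order.
#'
#' @param stack a \linkS4class{FocusStack}
#' @param metric \code{"dct"} or \code{"jpeg_size"}
#' @param quality JPEG quality when \code{metric = "jpeg_size"}
#' @return a \linkS4class{SharpnessCurve}
#' @seealso \code{\link{bestFocus}}
#' @export
sharpnessCurve <- function(stack, metric = c("dct", "jpeg_size"),
                           quality = 85L) {
  if (!is(stack, "FocusStack")) stop("stack must be a FocusStack")
  metric <- match.arg(metric)
  fn <- switch(metric,
               dct = dctSharpness,
               jpeg_size = function(f) as.numeric(jpegSizeSharpness(f, quality)))
  SharpnessCurve(z = stack@z,
                 score = vapply(stack@frames, fn, numeric(1)),
                 metricName = metric)
}

#' Best focus position from a sharpness curve
#'
#' Returns the z of the maximal score. Ties are broken by proximity to the
#' median z of the curve (a drifted focus is more likely near the centre of
#' the sweep), then by the smaller z.
#'
#' @param curve a \linkS4class{SharpnessCurve}
#' @return focus position z in micrometres
#' @export
bestFocus <- function(curve) {
  if (!is(curve, "SharpnessCurve")) stop("curve must be a SharpnessCurve")
  s <- curve@score
  if (all(is.na(s))) stop("cannot evaluate focus: all scores are NaN")
  mx <- max(s, na.rm = TRUE)
  cand <- which(!is.na(s) & s == mx)
  if (length(cand) > 1L) {
    med <- stats::median(curve@z)
    d <- abs(curve@z[cand] - med)
    cand <- cand[d == min(d)]
    if (length(cand) > 1L) cand <- cand[which.min(curve@z[cand])]
  }
  curve@z[cand]
}

#' Extended depth-of-field composite
#'
#' Builds a single all-in-focus frame from a focus stack by pure per-pixel
#' selection: each output pixel is copied from the layer with the highest
#' local sharpness at that pixel, measured as luminance variance in a
#' \code{window} x \code{window} neighbourhood. No blending is performed, so
#' every output value exists in some input layer at the same coordinates.
#'
#' @param stack a \linkS4class{FocusStack} of aligned frames
#' @param window odd window size for the local variance (default 9)
#' @return a \linkS4class{Frame}
#' @export
edofComposite <- function(stack, window = 9L) {
  if (!is(stack, "FocusStack")) stop("stack must be a FocusStack")
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  n <- length(stack@frames)
  f1 <- stack@frames[[1]]
  bestVar <- matrix(-Inf, nrow(f1@pixels), ncol(f1@pixels))
  bestIdx <- matrix(1L, nrow(f1@pixels), ncol(f1@pixels))
  for (i in seq_len(n)) {
    g <- .lum(stack@frames[[i]])
    v <- .boxMean(g^2, window) - .boxMean(g, window)^2
    upd <- v > bestVar
    bestVar[upd] <- v[upd]
    bestIdx[upd] <- i
  }
  out <- f1@pixels
  rgb <- length(dim(out)) == 3L
  for (i in seq_len(n)) {
    sel <- bestIdx == i
    if (!any(sel)) next
    if (rgb) {
      for (ch in 1:3) {
        o <- out[, , ch]; p <- stack@frames[[i]]@pixels[, , ch]
        o[sel] <- p[sel]; out[, , ch] <- o
      }
    } else out[sel] <- stack@frames[[i]]@pixels[sel]
  }
  Frame(out, f1@bitDepth,
        metadata = c(f1@metadata, list(edof = TRUE, edof_window = window)))
}

#' Default exposure/focus bracketing plan
#'
#' The stock autonomous-deployment schedule: once a minute, sweep the
#' exposure ladder 1/2/5/10/20/50/100/200/500 ms at each focus-bracket
#' offset, then return to deep sleep. The near-geometric exposure ladder
#' spans battery discharge over multi-week deployments; the focus offsets
#' default to two actuator steps (about 4 um each) on either side of the
#' nominal focus.
#'
#' @return an \linkS4class{AcquisitionPlan}
#' @examples
#' plan <- defaultBracketPlan()
#' length(plan@exposureSeriesMs)   # 9
#' @export
defaultBracketPlan <- function() {
  AcquisitionPlan(intervalS = 60,
                  exposureSeriesMs = c(1, 2, 5, 10, 20, 50, 100, 200, 500),
                  focusOffsetsUm = c(-8, -4, 0, 4, 8),
                  deepSleep = TRUE)
}

#' Select the best-exposed frame of a bracketing series
#'
#' Scores each frame by the fraction of pixels in the well-exposed band
#' [0.1, 0.9] of full scale. Frames whose saturated fraction (pixels at or
#' above 0.99 of full scale) exceeds 1\% are excluded; if every frame
#' exceeds the cap, the least-saturated frame wins. Ties go to the shorter
#' exposure (less motion blur, less power), then to the earlier frame.
#'
#' @param frameList list of \linkS4class{Frame}, all one shape, each ideally
#'   carrying \code{exposure_ms} metadata
#' @param saturationCap maximum tolerated saturated fraction (default 0.01)
#' @return 1-based index of the selected frame
#' @export
selectBestExposure <- function(frameList, saturationCap = 0.01) {
  if (!is.list(frameList) || length(frameList) < 1L)
    stop("need at least one frame")
  if (!all(vapply(frameList, is, logical(1), "Frame")))
    stop("frameList must contain Frame objects")
  d1 <- dim(frameList[[1]]@pixels)[1:2]
  if (!all(vapply(frameList, function(f)
    identical(dim(f@pixels)[1:2], d1), logical(1))))
    stop("all frames must share one shape")
  n <- length(frameList)
  expo <- vapply(frameList, function(f) {
    e <- f@metadata$exposure_ms
    if (is.null(e)) Inf else as.numeric(e)
  }, numeric(1))
  sat <- well <- numeric(n)
  for (i in seq_len(n)) {
    g <- .lum(frameList[[i]])
    mx <- maxValue(frameList[[i]])
    sat[i] <- mean(g >= 0.99 * mx)
    well[i] <- mean(g >= 0.1 * mx & g <= 0.9 * mx)
  }
  ok <- sat <= saturationCap
  if (any(ok)) {
    cand <- which(ok & well == max(well[ok]))
  } else {
    cand <- which(sat == min(sat))
  }
  if (length(cand) > 1L) {
    cand <- cand[expo[cand] == min(expo[cand])]
  }
  cand[1]
}
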