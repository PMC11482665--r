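# Seeded synthetic fixtures emulating the imaging physics of camera-module
# microscopes: resolution bar targets, defocus stacks, drifting timelapses
# and spectrometer frames. Every generator is a pure function of its
# parameters and seed.

# Fractional coverage of pixels [i-1, i) by dark three-bar pattern with bar
# width w (px): bars at [0, w), [2w, 3w), [4w, 5w) along a length-5w profile.
.barCoverage <- function(nPix, w) {
  cov <- numeric(nPix)
  starts <- c(0, 2, 4) * w
  for (s in starts) {
    e <- s + w
    lo <- pmax(seq_len(nPix) - 1, s)
    hi <- pmin(seq_len(nPix), e)
    cov <- cov + pmax(hi - lo, 0)
  }
  cov
}

#' Synthetic three-bar resolution target
#'
#' Renders three-bar groups (dark bars on a bright background) at each
#' requested line width, in both horizontal and vertical orientation, then
#' applies Gaussian optical blur and optional shot/read noise. The layout
#' and true bar/gap positions are stored in the frame metadata for
#' \code{\link{resolvedLinewidth}}.
#'
#' @param lineWidthsUm bar line widths (um); each must be at least the
#'   effective pixel size
#' @param effectivePixelUm object-side pixel size (um/px)
#' @param contrast Michelson contrast of the unblurred bars (0..1]
#' @param blurSigmaUm Gaussian blur sigma (um)
#' @param noiseSd Gaussian read-noise SD as a fraction of full scale
#' @param shotNoise add Poisson shot noise (default FALSE)
#' @param seed RNG seed
#' @param bitDepth output bit depth
#' @return a \linkS4class{Frame} with \code{bar_groups} metadata
#' @export
makeBarTarget <- function(lineWidthsUm, effectivePixelUm, contrast = 1,
                          blurSigmaUm = 0, noiseSd = 0, shotNoise = FALSE,
                          seed = 1L, bitDepth = 8L) {
  if (any(lineWidthsUm < effectivePixelUm))
    stop("line width below the sampling floor (one effective pixel)")
  if (contrast <= 0 || contrast > 1) stop("contrast must lie in (0, 1]")
  set.seed(seed)
  mx <- 2^bitDepth - 1
  hi <- 0.92 * mx
  lo <- hi * (1 - contrast) / (1 + contrast)
  wpx <- lineWidthsUm / effectivePixelUm
  pad <- 10L
  sizes <- ceiling(5 * wpx)
  H <- pad + sum(sizes + pad)
  W <- pad + 2L * (max(sizes) + pad)
  canvas <- matrix(hi, H, W)
  groups <- list()
  r0 <- pad + 1L
  for (i in seq_along(wpx)) {
    w <- wpx[i]; sz <- sizes[i]
    cH <- pad + 1L                       # horizontal bars: profile along rows
    cV <- pad + max(sizes) + pad + 1L    # vertical bars: profile along cols
    covH <- .barCoverage(sz, w)
    canvas[r0:(r0 + sz - 1L), cH:(cH + sz - 1L)] <-
      hi - (hi - lo) * matrix(covH, sz, sz)
    canvas[r0:(r0 + sz - 1L), cV:(cV + sz - 1L)] <-
      hi - (hi - lo) * matrix(covH, sz, sz, byrow = TRUE)
    barOff <- c(0.5, 2.5, 4.5) * w
    gapOff <- c(1.5, 3.5) * w
    groups[[i]] <- list(
      width_um = lineWidthsUm[i],
      h = list(col = cH + sz / 2, barRows = r0 - 1 + barOff + 0.5,
               gapRows = r0 - 1 + gapOff + 0.5),
      v = list(row = r0 + sz / 2, barCols = cV - 1 + barOff + 0.5,
               gapCols = cV - 1 + gapOff + 0.5))
    r0 <- r0 + sz + pad
  }
  if (blurSigmaUm > 0)
    canvas <- .blurGauss(canvas, blurSigmaUm / effectivePixelUm)
  if (shotNoise) canvas <- matrix(stats::rpois(length(canvas),
                                               pmax(canvas, 0)), H, W)
  if (noiseSd > 0)
    canvas <- canvas + stats::rnorm(length(canvas), 0, noiseSd * mx)
  Frame(.clip(canvas, 0, mx), bitDepth,
        metadata = list(bar_groups = groups,
                        effective_pixel_um = effectivePixelUm,
                        contrast = contrast, blur_sigma_um = blurSigmaUm,
                        seed = seed))
}

#' Smallest resolved line width of a bar target
#'
#' Reads the three-bar line profiles recorded in the target's metadata and
#' returns the smallest line width whose profile keeps a Michelson contrast
#' (gap peaks vs bar troughs) of at least \code{contrastThreshold} in both
#' orientations. Returns \code{NA} (unresolved) when no group passes.
#'
#' @param frame a bar-target \linkS4class{Frame} from
#'   \code{\link{makeBarTarget}}
#' @param groups group metadata (defaults to the frame's own)
#' @param contrastThreshold Michelson contrast floor (default 0.26)
#' @return smallest resolved line width in micrometres, or \code{NA}
#' @export
resolvedLinewidth <- function(frame, groups = NULL,
                              contrastThreshold = 0.26) {
  if (!is(frame, "Frame")) stop("frame must be a Frame")
  if (is.null(groups)) groups <- frame@metadata$bar_groups
  if (is.null(groups)) stop("no bar-target metadata available")
  g <- .lum(frame)
  michelson <- function(pk, tr) {
    pk <- mean(pk); tr <- mean(tr)
    if (pk + tr <= 0) return(0)
    max((pk - tr) / (pk + tr), 0)   # heavy blur can invert; floor at zero
  }
  resolved <- vapply(groups, function(gr) {
    hPk <- .bilinear(g, rep(gr$h$col, 2), gr$h$gapRows)
    hTr <- .bilinear(g, rep(gr$h$col, 3), gr$h$barRows)
    vPk <- .bilinear(g, gr$v$gapCols, rep(gr$v$row, 2))
    vTr <- .bilinear(g, gr$v$barCols, rep(gr$v$row, 3))
    michelson(hPk, hTr) >= contrastThreshold &&
      michelson(vPk, vTr) >= contrastThreshold
  }, logical(1))
  widths <- vapply(groups, function(gr) gr$width_um, numeric(1))
  if (!any(resolved)) return(NA_real_)
  min(widths[resolved])
}

#' Synthetic defocus stack
#'
#' Generates a focus stack whose blur grows linearly with distance from the
#' true focal plane: layer at z is blurred with
#' \code{sigma(z) = sigma0 + rate * |z - z0|} pixels. Defocus as a Gaussian
#' point-spread function is a simplification, but it is monotone in |z - z0|,
#' which is all contrast-based focus metrics require.
#'
#' @param scene optional scene matrix in native units; a seeded random
#'   texture is generated when NULL
#' @param shape scene shape when generating the texture
#' @param zGridUm focus positions (um), strictly monotonic
#' @param z0Um true focal position (must lie within the grid span)
#' @param blurRatePxPerUm blur growth rate (px per um of defocus)
#' @param sigma0Px residual blur at perfect focus (px)
#' @param noiseSd Gaussian read-noise SD, fraction of full scale
#' @param seed RNG seed
#' @param bitDepth bit depth
#' @return a \linkS4class{FocusStack} with \code{true_z0_um} metadata
#' @export
makeDefocusStack <- function(scene = NULL, shape = c(128L, 128L),
                             zGridUm = seq(0, 100, by = 10), z0Um = 50,
                             blurRatePxPerUm = 0.4, sigma0Px = 0.5,
                             noiseSd = 0.01, seed = 1L, bitDepth = 8L) {
  if (length(zGridUm) < 2L) stop("z grid must have at least two positions")
  if (z0Um < min(zGridUm) || z0Um > max(zGridUm))
    stop("z0 must lie within the grid span")
  set.seed(seed)
  mx <- 2^bitDepth - 1
  if (is.null(scene)) {
    scene <- .blurGauss(matrix(stats::runif(prod(shape)), shape[1], shape[2]),
                        0.7)
    scene <- (scene - min(scene)) / diff(range(scene)) * 0.8 * mx + 0.1 * mx
  }
  layers <- lapply(zGridUm, function(z) {
    sig <- sigma0Px + blurRatePxPerUm * abs(z - z0Um)
    img <- .blurGauss(scene, sig)
    if (noiseSd > 0)
      img <- img + stats::rnorm(length(img), 0, noiseSd * mx)
    Frame(.clip(img, 0, mx), bitDepth,
          metadata = list(z_position_um = z))
  })
  FocusStack(layers, zGridUm,
             metadata = list(true_z0_um = z0Um, seed = seed,
                             blur_rate_px_per_um = blurRatePxPerUm))
}

#' Synthetic drifting timelapse
#'
#' Generates a timelapse of a band-limited random scene translated by the
#' given per-frame shifts (Fourier shift, cyclic), with optional radial
#' vignetting, per-frame multiplicative dimming (battery-discharge model), a
#' bright moving particle along a path, and Gaussian read noise.
#'
#' @param scene optional scene matrix; seeded random texture when NULL
#' @param shape scene shape when generating the texture
#' @param shiftsPx (n-1) x 2 matrix of per-frame shifts (dx, dy) in px
#' @param vignetteStrength 0 (none) .. <1; radial falloff
#'   \code{1 - s (r/rmax)^2}
#' @param dimmingPerFrame fractional brightness loss per frame (e.g. 0.001)
#' @param particlePath optional n x 2 matrix of particle centres (x, y) in
#'   1-based px; must stay inside the frame
#' @param particleRadiusPx Gaussian radius of the particle (px)
#' @param particleAmplitude particle brightness, fraction of full scale
#' @param noiseSd Gaussian read-noise SD, fraction of full scale
#' @param intervalS seconds between frames
#' @param exposuresMs optional exposure metadata, recycled over frames
#' @param seed RNG seed
#' @param bitDepth bit depth
#' @return a \linkS4class{TimelapseSeries} with ground-truth metadata
#' @export
makeDriftingTimelapse <- function(scene = NULL, shape = c(128L, 128L),
                                  shiftsPx, vignetteStrength = 0,
                                  dimmingPerFrame = 0, particlePath = NULL,
                                  particleRadiusPx = 2.5,
                                  particleAmplitude = 0.5, noiseSd = 0.01,
                                  intervalS = 60, exposuresMs = NULL,
                                  seed = 1L, bitDepth = 8L) {
  shiftsPx <- as.matrix(shiftsPx)
  if (ncol(shiftsPx) != 2L) stop("shiftsPx must have two columns (dx, dy)")
  n <- nrow(shiftsPx) + 1L
  set.seed(seed)
  mx <- 2^bitDepth - 1
  if (is.null(scene)) {
    scene <- .blurGauss(matrix(stats::runif(prod(shape)), shape[1], shape[2]),
                        1.5)
    scene <- (scene - min(scene)) / diff(range(scene)) * 0.6 * mx + 0.2 * mx
  }
  nr <- nrow(scene); nc <- ncol(scene)
  if (!is.null(particlePath)) {
    particlePath <- as.matrix(particlePath)
    if (nrow(particlePath) != n) stop("particlePath must have one row per frame")
    m <- 2 * particleRadiusPx
    if (any(particlePath[, 1] < 1 + m | particlePath[, 1] > nc - m |
            particlePath[, 2] < 1 + m | particlePath[, 2] > nr - m))
      stop("particle path leaves the frame")
  }
  vig <- if (vignetteStrength > 0) {
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
    r2 <- outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+")
    1 - vignetteStrength * r2 / max(r2)
  } else 1
  cum <- rbind(c(0, 0), apply(shiftsPx, 2, cumsum))
  if (n == 2L) cum <- rbind(c(0, 0), matrix(cum[-1], 1L))
  framesOut <- vector("list", n)
  for (k in seq_len(n)) {
    img <- if (all(cum[k, ] == 0)) scene
           else .fourierShift(scene, cum[k, 1], cum[k, 2])
    img <- img * vig * (1 - dimmingPerFrame)^(k - 1)
    if (!is.null(particlePath)) {
      d2 <- outer((seq_len(nr) - particlePath[k, 2])^2,
                  (seq_len(nc) - particlePath[k, 1])^2, "+")
      img <- img + particleAmplitude * mx *
        exp(-d2 / (2 * particleRadiusPx^2))
    }
    if (noiseSd > 0) img <- img + stats::rnorm(length(img), 0, noiseSd * mx)
    md <- list(timestamp_s = (k - 1) * intervalS)
    if (!is.null(exposuresMs))
      md$exposure_ms <- exposuresMs[(k - 1) %% length(exposuresMs) + 1]
    framesOut[[k]] <- Frame(.clip(img, 0, mx), bitDepth, metadata = md)
  }
  TimelapseSeries(framesOut, (seq_len(n) - 1) * intervalS,
                  metadata = list(true_shifts_px = shiftsPx,
                                  dimming_per_frame = dimmingPerFrame,
                                  vignette_strength = vignetteStrength,
                                  seed = seed))
}

#' Synthetic spectrometer frame
#'
#' Renders a camera frame as seen behind a transmission grating: Gaussian
#' emission lines laid out along a (possibly tilted) dispersion axis, each
#' coloured by a piecewise-linear wavelength-to-RGB approximation, over a
#' faint background with seeded Gaussian noise.
#'
#' The dispersion axis passes through \code{origin} (x, y) at
#' \code{tiltDeg}; a line's axis position p maps to wavelength
#' \code{wavelengthAtOriginNm + dispersionNmPerPx * p}.
#'
#' @param lines data.frame with columns \code{amplitude} (0..1),
#'   \code{width_px}, and either \code{position_px} or \code{wavelength_nm};
#'   zero rows give a background-only frame
#' @param shape frame shape (rows, cols)
#' @param dispersionNmPerPx linear dispersion (nm per px)
#' @param wavelengthAtOriginNm wavelength at axis position 0
#' @param origin (x, y) of axis position 0, 1-based px
#' @param tiltDeg axis tilt in degrees (0 = horizontal)
#' @param perpSigmaPx perpendicular extent of the spectrum band (px)
#' @param noiseSd Gaussian noise SD, fraction of full scale
#' @param seed RNG seed
#' @param bitDepth bit depth
#' @return an RGB \linkS4class{Frame} with ground-truth metadata
#' @export
makeSpectrumFrame <- function(lines, shape = c(240L, 640L),
                              dispersionNmPerPx = 1,
                              wavelengthAtOriginNm = 400,
                              origin = c(16, shape[1] / 2), tiltDeg = 0,
                              perpSigmaPx = 12, noiseSd = 0, seed = 1L,
                              bitDepth = 8L) {
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  mx <- 2^bitDepth - 1
  th <- tiltDeg * pi / 180
  cs <- cos(th); sn <- sin(th)
  xg <- matrix(rep(seq_len(nc), each = nr), nr, nc) - origin[1]
  yg <- matrix(rep(seq_len(nr), nc), nr, nc) - origin[2]
  tAx <- xg * cs + yg * sn          # along-axis position
  sAx <- -xg * sn + yg * cs         # perpendicular offset
  perp <- exp(-sAx^2 / (2 * perpSigmaPx^2))
  img <- array(0.02, c(nr, nc, 3))
  if (nrow(lines) > 0) {
    pos <- if ("position_px" %in% names(lines)) lines$position_px
           else (lines$wavelength_nm - wavelengthAtOriginNm) / dispersionNmPerPx
    wl <- if ("wavelength_nm" %in% names(lines)) lines$wavelength_nm
          else wavelengthAtOriginNm + dispersionNmPerPx * lines$position_px
    maxT <- (nc - origin[1]) * abs(cs) + (nr - origin[2]) * abs(sn)
    if (any(pos < 0 | pos > maxT + 1))
      stop("line position falls outside the frame after tilt")
    for (i in seq_len(nrow(lines))) {
      rgb <- .wavelengthToRgb(wl[i])
      prof <- lines$amplitude[i] *
        exp(-(tAx - pos[i])^2 / (2 * lines$width_px[i]^2)) * perp
      for (ch in 1:3) img[, , ch] <- img[, , ch] + 0.9 * rgb[ch] * prof
    }
  }
  img <- img * mx
  if (noiseSd > 0)
    img <- img + stats::rnorm(length(img), 0, noiseSd * mx)
  Frame(.clip(img, 0, mx), bitDepth,
        metadata = list(dispersion_nm_per_px = dispersionNmPerPx,
                        wavelength_at_origin_nm = wavelengthAtOriginNm,
                        origin = origin, tilt_deg = tiltDeg,
                        lines = lines, seed = seed))
}

#' Emission lines of a typical phosphor white LED
#'
#' A narrow blue pump peak plus a broad phosphor band, leaving the
#' characteristic dip in the green region between them. Intended as input
#' for \code{\link{makeSpectrumFrame}}.
#'
#' @return data.frame of emission lines (wavelength_nm, amplitude, width_px)
#' @export
whiteLedLines <- function() {
  data.frame(wavelength_nm = c(450, 560, 600),
             amplitude = c(1, 0.55, 0.6),
             width_px = c(10, 28, 30))
}
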