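# Inline (lensless) holography: forward simulation, angular-spectrum
# propagation, numerical refocusing and depth scanning.
#
# The propagator itself is the exact unitary band-limited angular-spectrum
# operator on the periodic FFT grid, so that zero-distance identity,
# round-trip unitarity, Parseval energy conservation and linearity hold to
# machine precision. Boundary handling (zero-padding to the next power of
# two plus a 16-px cosine edge taper against wraparound) is applied by the
# hologram pipeline (reconstruct / zScan / simulateInline) around the raw
# propagator.

# Effective propagation distance under spherical illumination from a point
# source at distance L: a hologram recorded at sample height z reconstructs
# at z_eff = z L / (L + z) (with lateral magnification (L + z) / L). For a
# plane wave (L = Inf), z_eff = z.
.effectiveZ <- function(zUm, sourceDistanceMm) {
  if (!is.finite(sourceDistanceMm)) return(zUm)
  L <- sourceDistanceMm * 1000
  zUm * L / (L + zUm)
}

# Angular-spectrum / Fresnel transfer function on an nr x nc grid.
.asmTransfer <- function(nr, nc, pitchUm, distanceUm, lambdaUm,
                         method = "angular") {
  fy <- .fftfreq(nr, pitchUm)
  fx <- .fftfreq(nc, pitchUm)
  f2 <- outer(fy^2, fx^2, "+")
  band <- f2 < 1 / lambdaUm^2
  H <- matrix(0 + 0i, nr, nc)
  if (method == "angular") {
    arg <- (1 / lambdaUm^2 - f2)[band]
    H[band] <- exp(2i * pi * distanceUm * sqrt(arg))
  } else {  # paraxial Fresnel approximation, same evanescent cutoff
    H[band] <- exp(2i * pi * distanceUm / lambdaUm) *
      exp(-1i * pi * lambdaUm * distanceUm * f2[band])
  }
  H
}

#' Propagate a complex field by scalar diffraction
#'
#' Applies the band-limited angular-spectrum transfer function
#' \eqn{\exp(i 2 \pi d \sqrt{1/\lambda^2 - f_x^2 - f_y^2})} in the spatial
#' frequency domain; evanescent components are zeroed. Negative distances
#' backpropagate. On the propagating band the operator is unitary: energy is
#' conserved and propagation by +d then -d restores the field. A paraxial
#' Fresnel mode is provided for cross-checking.
#'
#' @param field a \linkS4class{ComplexField}
#' @param distanceUm signed propagation distance (um); negative means
#'   backpropagation
#' @param wavelengthNm wavelength (nm)
#' @param method \code{"angular"} (exact scalar diffraction, default) or
#'   \code{"fresnel"} (paraxial)
#' @return the propagated \linkS4class{ComplexField}
#' @export
angularSpectrumPropagate <- function(field, distanceUm, wavelengthNm,
                                     method = c("angular", "fresnel")) {
  if (!is(field, "ComplexField")) stop("field must be a ComplexField")
  method <- match.arg(method)
  u <- field@values
  if (!all(is.finite(Re(u)) & is.finite(Im(u))))
    stop("field contains non-finite values")
  if (distanceUm == 0) return(field)
  lambdaUm <- wavelengthNm / 1000
  nr <- nrow(u); nc <- ncol(u)
  zMax <- field@pitchUm^2 * min(nr, nc) / lambdaUm
  if (abs(distanceUm) > zMax)
    warning(sprintf(
      "propagation distance %g um exceeds the aliasing-free range (~%g um) for this sampling",
      distanceUm, zMax))
  H <- .asmTransfer(nr, nc, field@pitchUm, distanceUm, lambdaUm, method)
  ComplexField(.ifft2(.fft2(u) * H), field@pitchUm)
}

#' Normalize a hologram to an amplitude field
#'
#' Standard inline-holography preprocessing: divides the recorded intensity
#' by the background frame (elementwise) when one is available, otherwise by
#' the frame's mean, and takes the square root as the amplitude estimate;
#' the phase is set to zero. Background pixels below 1e-6 of full scale are
#' floored there, and the number of floored pixels is reported in a warning.
#'
#' @param h a \linkS4class{Hologram}
#' @return a \linkS4class{ComplexField} with unit-level background
#' @export
normalizeHologram <- function(h) {
  if (!is(h, "Hologram")) stop("h must be a Hologram")
  f <- h@frame@pixels
  if (!is.null(h@background)) {
    b <- h@background@pixels
    eps <- 1e-6 * maxValue(h@background)
    nFloored <- sum(b < eps)
    if (nFloored > 0)
      warning(sprintf("%d background pixel(s) floored at the epsilon level",
                      nFloored))
    contrast <- f / pmax(b, eps)
  } else {
    m <- mean(f)
    if (m <= 0) stop("cannot normalize: frame mean is zero")
    contrast <- f / m
  }
  ComplexField(sqrt(pmax(contrast, 0)) + 0i, h@pixelPitchUm)
}

# Pad a complex matrix to a square next-power-of-two grid filled with the
# unit background, apodizing the embedded region's border with a raised
# cosine taper so the wraparound seam is suppressed. Returns the padded
# matrix; the original occupies [1:nr, 1:nc].
.padField <- function(u, taper = 16L) {
  nr <- nrow(u); nc <- ncol(u)
  P <- .nextPow2(max(nr, nc))
  ramp <- function(n) {
    w <- rep(1, n)
    t <- min(taper, floor(n / 2))
    if (t > 0) {
      edge <- 0.5 - 0.5 * cos(pi * (seq_len(t) - 0.5) / t)
      w[seq_len(t)] <- edge
      w[n + 1 - seq_len(t)] <- edge
    }
    w
  }
  W <- outer(ramp(nr), ramp(nc))
  out <- matrix(1 + 0i, P, P)
  out[seq_len(nr), seq_len(nc)] <- 1 + (u - 1) * W
  out
}

# Shared refocusing core: normalized + padded hologram spectrum, so a z-scan
# pays the forward FFT only once.
.holoSpectrum <- function(h, taper = 16L) {
  field <- suppressWarnings(normalizeHologram(h))
  padded <- .padField(field@values, taper)
  list(Fu = .fft2(padded), nr = nrow(h@frame@pixels),
       nc = ncol(h@frame@pixels), P = nrow(padded))
}

.refocusIntensity <- function(spec, h, zUm, method = "angular") {
  zeff <- .effectiveZ(zUm, h@sourceDistanceMm)
  lambdaUm <- h@wavelengthNm / 1000
  H <- .asmTransfer(spec$P, spec$P, h@pixelPitchUm, -zeff, lambdaUm, method)
  u <- .ifft2(spec$Fu * H)
  Mod(u[seq_len(spec$nr), seq_len(spec$nc)])^2
}

#' Numerically refocus an inline hologram
#'
#' Normalizes the hologram, backpropagates the amplitude field by the
#' (source-geometry-corrected) sample distance, and returns the squared
#' modulus rescaled to the frame's bit depth. No twin-image suppression is
#' performed: plain backpropagation leaves the out-of-focus conjugate image
#' superimposed, as is inherent to single-shot inline holograms.
#'
#' @param h a \linkS4class{Hologram}
#' @param zUm sample-to-sensor distance (um, > 0)
#' @param method propagator, \code{"angular"} or \code{"fresnel"}
#' @return a \linkS4class{Frame} with the refocused intensity
#' @seealso \code{\link{zScan}} to find the focus distance
#' @export
reconstruct <- function(h, zUm, method = c("angular", "fresnel")) {
  if (!is(h, "Hologram")) stop("h must be a Hologram")
  method <- match.arg(method)
  if (!is.numeric(zUm) || length(zUm) != 1L || zUm <= 0)
    stop("z must be a single positive distance (um)")
  spec <- .holoSpectrum(h)
  I <- .refocusIntensity(spec, h, zUm, method)
  mx <- max(I)
  bd <- h@frame@bitDepth
  px <- if (mx > 0) I / mx * (2^bd - 1) else matrix(0, nrow(I), ncol(I))
  Frame(px, bd, metadata = list(z_um = zUm, refocused = TRUE,
                                method = method))
}

#' Scan reconstruction depths for the best focus
#'
#' Reconstructs the hologram on a uniform z grid, scores each plane, and
#' returns the best-scoring depth (ties go to the smaller z) together with
#' the full focus curve.
#'
#' The default criterion, \code{"gradient"}, is the gradient energy of the
#' reconstructed amplitude after a 3 x 3 box smoothing, normalized to be
#' scale invariant: \code{mean(|grad sqrt(I)|^2) / mean(sqrt(I))^2}.
#' Absorbing particles have their sharpest amplitude edges exactly at focus;
#' working on the amplitude rather than the intensity keeps the residual
#' defocused fringe oscillations from dominating the measure, and the light
#' smoothing suppresses the white read/quantization-noise gradient floor
#' that would otherwise drown the signal of small sparse particles. Two alternatives are exposed
#' for comparison: \code{"darkness"}, the dark-deviation energy
#' \code{mean(pmax(1 - I/mean(I), 0)^2)}, and \code{"variance"}, the
#' classical normalized intensity variance \code{var(I)/mean(I)^2}. Both can
#' be fooled on multi-particle scenes, where the out-of-focus fringe system
#' carries more dark mass or raw variance than the focused dips.
#'
#' @param h a \linkS4class{Hologram}
#' @param zMinUm,zMaxUm scan range (um), 0 < zMin < zMax
#' @param steps number of grid points (>= 3)
#' @param criterion \code{"gradient"} (default), \code{"darkness"} or
#'   \code{"variance"}
#' @param method propagator mode
#' @return list with \code{bestZUm} and \code{curve}, a data.frame with
#'   columns \code{z_um} and \code{score}
#' @export
zScan <- function(h, zMinUm, zMaxUm, steps,
                  criterion = c("gradient", "darkness", "variance"),
                  method = c("angular", "fresnel")) {
  if (!is(h, "Hologram")) stop("h must be a Hologram")
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  if (!(zMinUm > 0 && zMaxUm > zMinUm)) stop("need 0 < zMin < zMax")
  if (steps < 3L) stop("need at least 3 scan steps")
  zs <- seq(zMinUm, zMaxUm, length.out = steps)
  spec <- .holoSpectrum(h)
  score <- vapply(zs, function(z) {
    I <- .refocusIntensity(spec, h, z, method)
    m <- mean(I)
    if (m <= 0) return(0)
    switch(criterion,
      gradient = {
        A <- .boxMean(sqrt(I), 3L)
        gx <- A[, -1] - A[, -ncol(A)]
        gy <- A[-1, ] - A[-nrow(A), ]
        (mean(gx^2) + mean(gy^2)) / mean(A)^2
      },
      darkness = mean(pmax(1 - I / m, 0)^2),
      variance = stats::var(as.vector(I)) / m^2)
  }, numeric(1))
  list(bestZUm = zs[which.max(score)],
       curve = data.frame(z_um = zs, score = score))
}

#' Simulate an inline hologram of a particle scene
#'
#' Forward model of a lensless inline microscope: a unit illumination wave
#' passes the particle plane (each particle an absorbing disc of the given
#' opacity), propagates the sample-to-sensor distance by the angular
#' spectrum method, and its squared modulus is recorded with optional
#' Gaussian read noise and quantization. With a finite source distance the
#' spherical illumination is mapped to the equivalent plane-wave problem at
#' the effective distance z L / (L + z).
#'
#' @param scene a \linkS4class{ParticleScene}
#' @param wavelengthNm illumination wavelength (nm)
#' @param pixelPitchUm sensor pixel pitch (um)
#' @param sourceDistanceMm point-source distance (mm); \code{Inf} = plane
#'   wave (default)
#' @param shape sensor shape (rows, cols)
#' @param noiseSd Gaussian read-noise SD as a fraction of full scale
#' @param seed RNG seed (mandatory for reproducibility)
#' @param bitDepth output bit depth
#' @param backgroundLevel background intensity as a fraction of full scale
#'   (default 0.4, leaving headroom for constructive fringes)
#' @return a \linkS4class{Hologram}
#' @export
simulateInline <- function(scene, wavelengthNm = 450, pixelPitchUm = 2.2,
                           sourceDistanceMm = Inf, shape = c(512L, 512L),
                           noiseSd = 0, seed = 1L, bitDepth = 8L,
                           backgroundLevel = 0.4) {
  if (!is(scene, "ParticleScene")) stop("scene must be a ParticleScene")
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  p <- scene@particles
  fovX <- nc * pixelPitchUm; fovY <- nr * pixelPitchUm
  if (nrow(p) > 0) {
    if (any(p$radius_um < pixelPitchUm / 2))
      stop("particle radius below half the pixel pitch is unresolvable")
    if (any(p$x_um - p$radius_um < 0 | p$x_um + p$radius_um > fovX |
            p$y_um - p$radius_um < 0 | p$y_um + p$radius_um > fovY))
      stop("particle outside the field of view")
  }
  xs <- (seq_len(nc) - 0.5) * pixelPitchUm
  ys <- (seq_len(nr) - 0.5) * pixelPitchUm
  mask <- matrix(1, nr, nc)
  for (i in seq_len(nrow(p))) {
    d2 <- outer((ys - p$y_um[i])^2, (xs - p$x_um[i])^2, "+")
    mask[d2 <= p$radius_um[i]^2] <- mask[d2 <= p$radius_um[i]^2] *
      (1 - p$opacity[i])
  }
  zeff <- .effectiveZ(scene@zUm, sourceDistanceMm)
  padded <- .padField(mask + 0i)
  lambdaUm <- wavelengthNm / 1000
  H <- .asmTransfer(nrow(padded), ncol(padded), pixelPitchUm, zeff, lambdaUm)
  u <- .ifft2(.fft2(padded) * H)
  I <- Mod(u[seq_len(nr), seq_len(nc)])^2
  mx <- 2^bitDepth - 1
  val <- I * backgroundLevel * mx
  if (noiseSd > 0) val <- val + stats::rnorm(length(val), 0, noiseSd * mx)
  px <- matrix(.clip(round(val), 0, mx), nr, nc)
  Hologram(Frame(px, bitDepth,
                 metadata = list(simulated = TRUE, z_um = scene@zUm,
                                 seed = seed)),
           wavelengthNm = wavelengthNm, pixelPitchUm = pixelPitchUm,
           sourceDistanceMm = sourceDistanceMm)
}

#' Random particle scene for closure tests
#'
#' Draws a seeded random scene of non-overlapping absorbing particles placed
#' in the central region of the field of view (away from the apodized
#' border), at a random depth within \code{zRangeUm}. Centre separations of
#' at least the sum of radii plus \code{minSeparationUm} keep particles
#' individually resolvable.
#'
#' @param seed RNG seed
#' @param nParticles number of particles; random in 1..5 when NULL
#' @param shape sensor shape (rows, cols)
#' @param pixelPitchUm pixel pitch (um)
#' @param zRangeUm depth range to draw from (um)
#' @param radiusRangeUm particle radius range (um)
#' @param opacityRange particle opacity range
#' @param marginFrac fraction of the field kept clear at each border
#' @param minSeparationUm extra clearance between particle edges (um);
#'   defaults to 3 pixel pitches
#' @return a \linkS4class{ParticleScene}
#' @export
randomParticleScene <- function(seed, nParticles = NULL,
                                shape = c(512L, 512L), pixelPitchUm = 2.2,
                                zRangeUm = c(800, 2500),
                                radiusRangeUm = c(5, 10),
                                opacityRange = c(0.8, 1),
                                marginFrac = 0.25,
                                minSeparationUm = 3 * pixelPitchUm) {
  set.seed(seed)
  if (is.null(nParticles)) nParticles <- sample.int(5L, 1L)
  fovX <- shape[2] * pixelPitchUm; fovY <- shape[1] * pixelPitchUm
  z <- stats::runif(1, zRangeUm[1], zRangeUm[2])
  xs <- ys <- rs <- os <- numeric(0)
  tries <- 0L
  while (length(xs) < nParticles && tries < 1000L) {
    tries <- tries + 1L
    r <- stats::runif(1, radiusRangeUm[1], radiusRangeUm[2])
    x <- stats::runif(1, marginFrac * fovX, (1 - marginFrac) * fovX)
    y <- stats::runif(1, marginFrac * fovY, (1 - marginFrac) * fovY)
    if (length(xs) > 0) {
      sep <- sqrt((xs - x)^2 + (ys - y)^2)
      if (any(sep < rs + r + minSeparationUm)) next
    }
    xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r)
    os <- c(os, stats::runif(1, opacityRange[1], opacityRange[2]))
  }
  ParticleScene(data.frame(x_um = xs, y_um = ys, radius_um = rs,
                           opacity = os), zUm = z)
}

#' Refine particle centres in a refocused frame
#'
#' Localizes dark (absorbing) particles near given approximate positions by
#' the centroid of the intensity dip: within a window around each seed
#' position, pixels darker than half the dip depth are weighted by their
#' depth below the window maximum and their centroid is returned. Refocused
#' absorbing discs have flat-bottomed intensity minima, so a centroid is a
#' far more stable localizer than the argmin. When several seed positions
#' are given, each window pixel contributes only to its nearest seed, so a
#' close neighbour's dip cannot bias the centroid.
#'
#' @param frame refocused intensity \linkS4class{Frame}
#' @param centersPx n x 2 matrix of approximate centres (x, y) in 1-based px
#' @param windowPx odd window size (default 15)
#' @return n x 2 matrix of refined centres (x, y) in px
#' @export
refineDipCenters <- function(frame, centersPx, windowPx = 15L) {
  if (!is(frame, "Frame")) stop("frame must be a Frame")
  centersPx <- as.matrix(centersPx)
  g <- .lum(frame)
  r <- (windowPx - 1L) %/% 2L
  n <- nrow(centersPx)
  out <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("x", "y")))
  for (i in seq_len(n)) {
    cx <- round(centersPx[i, 1]); cy <- round(centersPx[i, 2])
    rows <- .clip(cy + (-r:r), 1, nrow(g))
    cols <- .clip(cx + (-r:r), 1, ncol(g))
    win <- g[rows, cols]
    X <- matrix(cols, nrow(win), ncol(win), byrow = TRUE)
    Y <- matrix(rows, nrow(win), ncol(win))
    depth <- max(win) - win
    depth[depth < 0.5 * max(depth)] <- 0
    if (n > 1L) {  # Voronoi masking against the other seeds
      d2own <- (X - centersPx[i, 1])^2 + (Y - centersPx[i, 2])^2
      for (j in seq_len(n)[-i]) {
        d2other <- (X - centersPx[j, 1])^2 + (Y - centersPx[j, 2])^2
        depth[d2other < d2own] <- 0
      }
    }
    if (sum(depth) == 0) { out[i, ] <- c(cx, cy); next }
    out[i, 1] <- sum(X * depth) / sum(depth)
    out[i, 2] <- sum(Y * depth) / sum(depth)
  }
  out
}
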