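# Internal numeric helpers shared across modules.

.LUM_WEIGHTS <- c(0.2126, 0.7152, 0.0722)  # Rec. 709 luminance

# Luminance plane of a Frame (or raw matrix/array), in native units.
.lum <- function(x) {
  px <- if (is(x, "Frame")) x@pixels else x
  d <- dim(px)
  if (length(d) == 2L) return(px)
  .LUM_WEIGHTS[1] * px[, , 1] + .LUM_WEIGHTS[2] * px[, , 2] +
    .LUM_WEIGHTS[3] * px[, , 3]
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.nextPow2 <- function(n) 2^ceiling(log2(n))

# FFT sample frequencies, spacing d (matches numpy fftfreq ordering).
.fftfreq <- function(n, d = 1) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / (n * d)
}

.fft2 <- function(x) stats::fft(x)
.ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Separable Gaussian blur with edge replication.
.blurGauss <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  .convSep(m, k, r)
}

# Separable box mean over a w x w window (w odd), edge replication.
.boxMean <- function(m, w) {
  if (w <= 1L) return(m)
  r <- (w - 1L) / 2L
  k <- rep(1 / w, w)
  .convSep(m, k, r)
}

# Apply 1-D kernel k (radius r) along rows then columns, replicating edges.
.convSep <- function(m, k, r) {
  f1 <- function(x) {
    n <- nrow(x)
    xp <- x[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- stats::filter(xp, k, sides = 2)
    matrix(out[(r + 1):(r + n), ], nrow = n)
  }
  t(f1(t(f1(m))))
}

# Subpixel cyclic translation via Fourier phase ramp. Shifts content by
# (+dx columns, +dy rows): out(r, c) = in(r - dy, c - dx).
.fourierShift <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  fy <- .fftfreq(nr); fx <- .fftfreq(nc)
  ramp <- exp(-2i * pi * (outer(fy * dy, fx * dx, "+")))
  Re(.ifft2(.fft2(m) * ramp))
}

# 2-D Hann window.
.hann2 <- function(nr, nc) {
  wy <- 0.5 - 0.5 * cos(2 * pi * seq_len(nr) / (nr + 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * seq_len(nc) / (nc + 1))
  outer(wy, wx)
}

# Vectorised bilinear sampling of matrix m at continuous 1-based coordinates
# (x = column, y = row). Coordinates are clamped into the frame; the number
# of clamped samples is returned as an attribute.
.bilinear <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  clamped <- sum(x < 1 | x > nc | y < 1 | y > nr)
  x <- .clip(x, 1, nc); y <- .clip(y, 1, nr)
  x0 <- .clip(floor(x), 1, nc - 1L); y0 <- .clip(floor(y), 1, nr - 1L)
  if (nc == 1L) x0 <- rep(1, length(x))
  if (nr == 1L) y0 <- rep(1, length(y))
  tx <- x - x0; ty <- y - y0
  x1 <- pmin(x0 + 1, nc); y1 <- pmin(y0 + 1, nr)
  v <- (1 - tx) * (1 - ty) * m[cbind(y0, x0)] +
       tx * (1 - ty) * m[cbind(y0, x1)] +
       (1 - tx) * ty * m[cbind(y1, x0)] +
       tx * ty * m[cbind(y1, x1)]
  attr(v, "clamped") <- clamped
  v
}

# Offset of the vertex of a parabola through (-1, ym1), (0, y0), (1, yp1);
# returns 0 when the three points are degenerate.
.parabolicOffset <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps * (abs(y0) + 1))
    return(0)
  d <- 0.5 * (ym1 - yp1) / denom
  .clip(d, -0.5, 0.5)
}

# Smallest-width local maxima indices of a numeric vector (strict plateaus
# resolved to their first index).
.localMaxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  idx <- integer(0)
  i <- 2L
  while (i < n) {
    if (y[i] > y[i - 1]) {
      j <- i
      while (j < n && y[j + 1] == y[j]) j <- j + 1L
      if (j < n && y[j + 1] < y[j]) idx <- c(idx, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  idx
}

# Approximate RGB colour of a visible wavelength (piecewise linear map,
# 380-780 nm; not radiometrically calibrated).
.wavelengthToRgb <- function(nm) {
  r <- g <- b <- 0
  if (nm >= 380 && nm < 440) { r <- (440 - nm) / 60; b <- 1 }
  else if (nm < 490) { g <- (nm - 440) / 50; b <- 1 }
  else if (nm < 510) { g <- 1; b <- (510 - nm) / 20 }
  else if (nm < 580) { r <- (nm - 510) / 70; g <- 1 }
  else if (nm < 645) { r <- 1; g <- (645 - nm) / 65 }
  else if (nm <= 780) { r <- 1 }
  # taper at the visual range edges
  fade <- 1
  if (nm >= 380 && nm < 420) fade <- 0.3 + 0.7 * (nm - 380) / 40
  if (nm > 700 && nm <= 780) fade <- 0.3 + 0.7 * (780 - nm) / 80
  if (nm < 380 || nm > 780) fade <- 0
  c(r, g, b) * fade
}

# Validation-flavoured stop used by the CLI to map to exit code 2.
.valStop <- function(...) {
  stop(structure(class = c("pocketscope_validation", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}
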