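# Shared fixtures and independent oracles, all generated in code.

# Seeded band-limited texture frame in native 8-bit units.
texFrame <- function(seed = 1, n = 128, blur = 1.5) {
  set.seed(seed)
  m <- pocketscope:::.blurGauss(matrix(runif(n * n), n, n), blur)
  m <- (m - min(m)) / diff(range(m)) * 200 + 25
  Frame(m, 8L)
}

# Integer cyclic roll: out(r, c) = in(r - dy, c - dx).
rollMat <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
}

# Independent 8x8 orthonormal DCT-II straight from the definition
# (quadruple loop; oracle for the vectorised implementation).
dctOracle <- function(B) {
  C <- matrix(0, 8, 8)
  for (u in 0:7) for (v in 0:7) {
    s <- 0
    for (i in 0:7) for (j in 0:7)
      s <- s + B[i + 1, j + 1] *
        cos(pi * u * (2 * i + 1) / 16) * cos(pi * v * (2 * j + 1) / 16)
    au <- if (u == 0) sqrt(1 / 8) else sqrt(2 / 8)
    av <- if (v == 0) sqrt(1 / 8) else sqrt(2 / 8)
    C[u + 1, v + 1] <- au * av * s
  }
  C
}

# Band-limited complex field for propagation property tests.
bandLimitedField <- function(seed = 1, n = 128, pitch = 2.2,
                             bandFrac = 0.25) {
  set.seed(seed)
  u <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  Fu <- stats::fft(u)
  f <- pocketscope:::.fftfreq(n)
  mask <- outer(f^2, f^2, "+") < (bandFrac * max(abs(f)))^2
  ub <- stats::fft(Fu * mask, inverse = TRUE) / length(Fu)
  ComplexField(ub, pitch)
}

rmsC <- function(a, b) sqrt(mean(Mod(a - b)^2))

# Unimodality up to a noise tolerance: scores must be non-decreasing up to
# the peak and non-increasing after, with wiggles below tol ignored.
isUnimodal <- function(s, tol = 0.01 * diff(range(s))) {
  p <- which.max(s)
  all(diff(s[seq_len(p)]) >= -tol) &&
    all(diff(s[p:length(s)]) <= tol)
}

# Uniform frame with exposure metadata (for bracketing tests).
levelFrame <- function(level, exposureMs = NULL, n = 64, noiseSd = 2,
                       seed = 1) {
  set.seed(seed)
  px <- pocketscope:::.clip(matrix(rnorm(n * n, level * 255, noiseSd), n, n),
                            0, 255)
  md <- if (is.null(exposureMs)) list() else list(exposure_ms = exposureMs)
  Frame(px, 8L, metadata = md)
}

# Unit-mean radial shading field (vignetting model).
shadingField <- function(n = 128, strength = 0.5) {
  ctr <- (n + 1) / 2
  r2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
  fall <- 1 - strength * r2 / max(r2)
  fall / mean(fall)
}
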