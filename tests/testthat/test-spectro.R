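test_that("spectrum extraction locates a Gaussian stripe to subpixel accuracy", {
  fr <- makeSpectrumFrame(data.frame(position_px = 300, amplitude = 1,
                                     width_px = 3), seed = 2)
  ax <- DispersionAxis(c(16, 120), c(620, 120), 11L)
  s <- extractSpectrum(fr, ax)
  peak <- positions(s)[which.max(intensities(s)[, "lum"])]
  expect_lte(abs(peak - 300), 0.5)
  # constant frame gives a flat spectrum
  sc <- extractSpectrum(Frame(matrix(90, 128, 256)),
                        DispersionAxis(c(10, 64), c(250, 64), 5L))
  expect_equal(max(intensities(sc)[, "lum"]) -
                 min(intensities(sc)[, "lum"]), 0, tolerance = 1e-9)
  expect_error(extractSpectrum(fr, DispersionAxis(c(-3, 10), c(50, 10))),
               "within")
})

test_that("extraction is equivariant to stripe translation along the axis", {
  ax <- DispersionAxis(c(16, 120), c(620, 120), 5L)
  for (k in c(-40, 25, 60)) {
    f0 <- makeSpectrumFrame(data.frame(position_px = 250, amplitude = 1,
                                       width_px = 4), seed = 9)
    fk <- makeSpectrumFrame(data.frame(position_px = 250 + k, amplitude = 1,
                                       width_px = 4), seed = 9)
    p0 <- positions(extractSpectrum(f0, ax))[
      which.max(intensities(extractSpectrum(f0, ax))[, "lum"])]
    pk <- positions(extractSpectrum(fk, ax))[
      which.max(intensities(extractSpectrum(fk, ax))[, "lum"])]
    expect_lte(abs((pk - p0) - k), 0.5)
  }
})

test_that("wider bands keep the peak position and reduce noise", {
  noiseless <- makeSpectrumFrame(data.frame(position_px = 200, amplitude = 1,
                                            width_px = 4), seed = 1)
  ax1 <- DispersionAxis(c(16, 120), c(620, 120), 1L)
  ax11 <- DispersionAxis(c(16, 120), c(620, 120), 11L)
  p1 <- positions(extractSpectrum(noiseless, ax1))[
    which.max(intensities(extractSpectrum(noiseless, ax1))[, "lum"])]
  p11 <- positions(extractSpectrum(noiseless, ax11))[
    which.max(intensities(extractSpectrum(noiseless, ax11))[, "lum"])]
  expect_equal(p1, p11)
  # seeded noisy variant: band averaging lowers the variance of the flat part
  noisy <- makeSpectrumFrame(data.frame(position_px = 200, amplitude = 1,
                                        width_px = 4),
                             noiseSd = 0.02, seed = 7)
  tail1 <- intensities(extractSpectrum(noisy, ax1))[400:600, "lum"]
  tail11 <- intensities(extractSpectrum(noisy, ax11))[400:600, "lum"]
  expect_lt(stats::var(tail11), stats::var(tail1))
})

test_that("calibration fits match closed-form least squares", {
  # two points: exact line
  cal2 <- fitCalibration(data.frame(position = c(100, 300),
                                    wavelength = c(450, 650)))
  expect_equal(calSlope(cal2), 1)
  expect_equal(calIntercept(cal2), 350)
  expect_equal(rmsResidual(cal2), 0, tolerance = 1e-10)
  # three collinear points: zero residual
  cal3 <- fitCalibration(data.frame(position = c(0, 100, 200),
                                    wavelength = c(400, 500, 600)))
  expect_equal(rmsResidual(cal3), 0, tolerance = 1e-10)
  # worked three-point example, verified against the closed form
  p <- c(100, 200, 300); w <- c(450, 540, 650)
  slope <- sum((p - mean(p)) * (w - mean(w))) / sum((p - mean(p))^2)
  intercept <- mean(w) - slope * mean(p)
  rms <- sqrt(mean((w - intercept - slope * p)^2))
  cal <- fitCalibration(data.frame(position = p, wavelength = w))
  expect_equal(calSlope(cal), slope)            # 1.0
  expect_equal(calIntercept(cal), intercept)    # 346.67
  expect_equal(rmsResidual(cal), rms)           # ~4.71
  expect_equal(signif(calSlope(cal), 3), 1)
  expect_equal(signif(calIntercept(cal), 5), 346.67)
  expect_equal(signif(rmsResidual(cal), 3), 4.71)
  expect_error(fitCalibration(data.frame(position = 1, wavelength = 450)),
               "2 points")
})

test_that("calibration recovery from noisy synthetic lines is reliable", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(s)
    p <- seq(50, 550, 100)
    wl <- 380 + 0.9 * p
    noisy <- p + stats::rnorm(6, 0, 0.3)
    cal <- fitCalibration(data.frame(position = noisy, wavelength = wl))
    if (abs(calSlope(cal) - 0.9) / 0.9 < 0.05 &&
        abs(calIntercept(cal) - 380) < 5) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.9)
})

test_that("applying a calibration populates a monotonic wavelength axis", {
  s <- Spectrum(position = c(0, 1, 2),
                intensity = cbind(r = 1:3, g = 1:3, b = 1:3, lum = 1:3))
  cal <- new("WavelengthCalibration", coefficients = c(400, 2),
             rmsResidual = 0, nPoints = 2L)
  out <- applyCalibration(s, cal)
  expect_equal(wavelengths(out), c(400, 402, 404))
  # negative slope: strictly decreasing axis
  neg <- new("WavelengthCalibration", coefficients = c(700, -1.5),
             rmsResidual = 0, nPoints = 2L)
  expect_true(all(diff(wavelengths(applyCalibration(s, neg))) < 0))
  # calibration points reproduce within the rms residual
  p <- c(100, 200, 300); w <- c(450, 540, 650)
  cal3 <- fitCalibration(data.frame(position = p, wavelength = w))
  sp <- Spectrum(position = p,
                 intensity = cbind(r = p, g = p, b = p, lum = p))
  back <- wavelengths(applyCalibration(sp, cal3))
  expect_lte(max(abs(back - w)), rmsResidual(cal3) * sqrt(3) + 1e-9)
})

test_that("absorbance follows Beer-Lambert on matched grids", {
  mkSpec <- function(v) Spectrum(position = 0:4,
                                 intensity = cbind(r = v, g = v, b = v,
                                                   lum = v))
  ref <- mkSpec(rep(100, 5))
  expect_equal(intensities(absorbance(ref, ref))[, "lum"], rep(0, 5))
  expect_equal(intensities(absorbance(mkSpec(rep(10, 5)), ref))[, "lum"],
               rep(1, 5))
  oneBand <- mkSpec(c(100, 100, 1, 100, 100))
  A <- intensities(absorbance(oneBand, ref))[, "lum"]
  expect_equal(A, c(0, 0, 2, 0, 0))
  expect_error(absorbance(mkSpec(rep(1, 5)),
                          Spectrum(position = 0:3,
                                   intensity = cbind(r = 1:4, g = 1:4,
                                                     b = 1:4, lum = 1:4))),
               "position grid")
})

test_that("a white-LED frame yields two luminance peaks around a green dip", {
  fr <- makeSpectrumFrame(whiteLedLines(), noiseSd = 0.005, seed = 5)
  s <- extractSpectrum(fr, DispersionAxis(c(16, 120), c(620, 120), 11L))
  pk <- spectrumPeaks(s)
  expect_equal(nrow(pk), 2)
  # dip between the peaks sits in the green region (wavelength = 400 + pos)
  lum <- intensities(s)[, "lum"]
  between <- positions(s) > min(pk$position) & positions(s) < max(pk$position)
  dipPos <- positions(s)[between][which.min(lum[between])]
  dipWl <- 400 + dipPos
  expect_gt(dipWl, 460)
  expect_lt(dipWl, 550)
})
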