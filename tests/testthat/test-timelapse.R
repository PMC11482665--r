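test_that("flat-field correction restores a vignetted scene", {
  set.seed(31)
  scn <- pocketscope:::.blurGauss(matrix(runif(128 * 128), 128), 1) * 150 + 30
  fallN <- shadingField(128, 0.5)
  vign <- Frame(pocketscope:::.clip(scn * fallN, 0, 255))
  flat <- Frame(pocketscope:::.clip(fallN * 150, 0, 255))
  corr <- flatFieldCorrect(vign, flat)
  expect_lt(sqrt(mean((pixels(corr) - scn)^2)) / 255, 0.01)
  # frame = flat: constant output at mean(flat)
  self <- flatFieldCorrect(flat, flat)
  expect_equal(stats::sd(pixels(self)), 0, tolerance = 1e-9)
  expect_equal(mean(pixels(self)), mean(pixels(flat)), tolerance = 1e-9)
  # constant flat: identity
  f <- texFrame(seed = 7)
  ident <- flatFieldCorrect(f, Frame(matrix(180, 128, 128)))
  expect_equal(pixels(ident), pixels(f), tolerance = 1e-9)
  # mean preservation with a normalized flat
  expect_lt(abs(mean(pixels(corr)) / mean(scn) - 1), 0.01)
  expect_error(flatFieldCorrect(f, Frame(matrix(0, 128, 128))), "zero mean")
  expect_error(flatFieldCorrect(f, Frame(matrix(1, 4, 4))), "shape")
})

test_that("flat-field correction honours a dark frame", {
  set.seed(32)
  scn <- matrix(runif(64 * 64, 40, 200), 64)
  dark <- matrix(10, 64, 64)
  fallN <- shadingField(64, 0.4)
  raw <- Frame(pocketscope:::.clip((scn - 10) * fallN + 10, 0, 255))
  flat <- Frame(pocketscope:::.clip(140 * fallN + 10, 0, 255))
  corr <- flatFieldCorrect(raw, flat, dark = Frame(dark))
  expect_lt(sqrt(mean((pixels(corr) - (scn - 10))^2)) / 255, 0.01)
})

test_that("pair shift recovers integer cyclic shifts exactly", {
  f1 <- texFrame(seed = 41)
  f2 <- Frame(rollMat(pixels(f1), 3, -2))
  res <- pairShift(f1, f2, subpixel = FALSE)
  expect_identical(unname(res[c("dx", "dy")]), c(3, -2))
  resSub <- pairShift(f1, f2)
  expect_lte(max(abs(resSub[c("dx", "dy")] - c(3, -2))), 0.1)
  # identical frames: zero shift
  z <- pairShift(f1, f1)
  expect_lte(max(abs(z[c("dx", "dy")])), 1e-6)
  expect_gt(z["quality"], 1)
  expect_error(pairShift(Frame(matrix(5, 32, 32)),
                         Frame(matrix(5, 32, 32))), "constant")
})

test_that("pair shift resolves half-pixel displacements", {
  f1 <- texFrame(seed = 42)
  shifted <- pocketscope:::.fourierShift(pixels(f1), 0.5, 0)
  f2 <- Frame(pocketscope:::.clip(shifted, 0, 255))
  res <- pairShift(f1, f2)
  expect_lte(abs(res["dx"] - 0.5), 0.15)
  expect_lte(abs(res["dy"]), 0.15)
})

test_that("pair shift is antisymmetric on seeded fixtures", {
  for (s in c(1, 5, 9)) {
    f1 <- texFrame(seed = s)
    f2 <- Frame(pocketscope:::.clip(
      pocketscope:::.fourierShift(pixels(f1), 2.3, -1.6), 0, 255))
    ab <- pairShift(f1, f2)
    ba <- pairShift(f2, f1)
    expect_lte(max(abs(ab[c("dx", "dy")] + ba[c("dx", "dy")])), 0.1)
  }
})

test_that("drift tracking accumulates pairwise shifts", {
  shifts <- matrix(c(rep(1, 9), rep(0, 9)), ncol = 2)
  ser <- makeDriftingTimelapse(shiftsPx = shifts, seed = 4, noiseSd = 0.01)
  tr <- driftTrack(ser)
  expect_equal(nrow(pairwiseShifts(tr)), 9)
  fin <- cumulativeShifts(tr)[9, ]
  expect_lte(abs(fin["dx"] - 9), 0.5)
  expect_lte(abs(fin["dy"]), 0.5)
  # static series: all-zero track
  static <- makeDriftingTimelapse(shiftsPx = matrix(0, 5, 2), seed = 5,
                                  noiseSd = 0.005)
  trs <- driftTrack(static)
  expect_lte(max(abs(pairwiseShifts(trs))), 0.1)
  # micron conversion via pixel size
  trUm <- driftTrack(ser, pixelSizeUm = 0.55)
  tab <- driftTrackTable(trUm)
  expect_equal(tab$cum_dx_um, tab$cum_dx_px * 0.55)
})

test_that("an injected jump is localized to the correct pair", {
  shifts <- matrix(0.5, 9, 2)
  shifts[6, ] <- c(15, -12)   # sudden jump at pair 6
  ser <- makeDriftingTimelapse(shiftsPx = shifts, seed = 8, noiseSd = 0.01)
  tr <- driftTrack(ser)
  mag <- sqrt(rowSums(pairwiseShifts(tr)^2))
  expect_equal(which.max(mag), 6L)
})

test_that("drift recovery stays within half a pixel per pair", {
  for (s in 1:20) {
    set.seed(s * 13)
    shifts <- matrix(stats::runif(14, -8, 8), ncol = 2)
    ser <- makeDriftingTimelapse(shiftsPx = shifts, noiseSd = 0.02, seed = s)
    tr <- driftTrack(ser)
    expect_lte(max(abs(pairwiseShifts(tr) - shifts)), 0.5)
  }
})

test_that("cumulative drift of concatenated series adds up", {
  set.seed(77)
  shifts <- matrix(stats::runif(16, -3, 3), ncol = 2)
  ser <- makeDriftingTimelapse(shiftsPx = shifts, seed = 20, noiseSd = 0.01)
  full <- driftTrack(ser)
  n <- length(frames(ser))
  firstHalf <- TimelapseSeries(frames(ser)[1:5], timestamps(ser)[1:5])
  secondHalf <- TimelapseSeries(frames(ser)[5:n], timestamps(ser)[5:n])
  cumA <- cumulativeShifts(driftTrack(firstHalf))[4, ]
  cumB <- cumulativeShifts(driftTrack(secondHalf))[n - 5, ]
  cumFull <- cumulativeShifts(full)[n - 1, ]
  expect_lte(max(abs((cumA + cumB) - cumFull)), 0.2)
})

test_that("variance projection highlights the moving particle", {
  path <- cbind(seq(20, 100, length.out = 20), seq(20, 100, length.out = 20))
  ser <- makeDriftingTimelapse(shiftsPx = matrix(0, 19, 2),
                               particlePath = path, seed = 6)
  vp <- varianceProjection(ser)
  thr <- stats::quantile(pixels(vp), 0.99)
  hot <- which(pixels(vp) >= thr, arr.ind = TRUE)
  # trajectory is the diagonal x = y: perpendicular distance |col-row|/sqrt(2)
  expect_lte(max(abs(hot[, 2] - hot[, 1]) / sqrt(2)), 3)
  # constant series: all-zero projection
  cst <- TimelapseSeries(list(Frame(matrix(50, 32, 32)),
                              Frame(matrix(50, 32, 32)),
                              Frame(matrix(50, 32, 32))), c(0, 1, 2))
  expect_equal(max(pixels(varianceProjection(cst))), 0)
  # permutation invariance
  perm <- TimelapseSeries(frames(ser)[c(5:20, 1:4)],
                          timestamps(ser))
  expect_equal(pixels(varianceProjection(perm)), pixels(vp),
               tolerance = 1e-9)
})

test_that("intensity series groups by exposure and tracks dimming", {
  # constant frames at a fixed level give a flat series
  cst <- TimelapseSeries(lapply(1:4, function(i)
    Frame(matrix(80, 16, 16), metadata = list(exposure_ms = 10))),
    (0:3) * 60)
  is0 <- intensitySeries(cst)
  expect_equal(unique(is0$mean_intensity), 80)
  expect_equal(unique(is0$exposure_ms), 10)
  # linear dimming: fitted relative slope within 10% of the generator's
  ser <- makeDriftingTimelapse(shiftsPx = matrix(0, 71, 2),
                               dimmingPerFrame = 0.001, noiseSd = 0.002,
                               exposuresMs = 10, seed = 7)
  is1 <- intensitySeries(ser)
  fit <- stats::lm(mean_intensity ~ timestamp_s, data = is1)
  perFrame <- -stats::coef(fit)[2] * 60 / is1$mean_intensity[1]
  expect_lt(stats::coef(fit)[2], 0)
  expect_lt(abs(perFrame - 0.001) / 0.001, 0.1)
  # two exposure groups with correct sizes
  ser2 <- makeDriftingTimelapse(shiftsPx = matrix(0, 9, 2),
                                exposuresMs = c(10, 50), seed = 9)
  is2 <- intensitySeries(ser2)
  expect_equal(as.vector(table(is2$exposure_ms)), c(5L, 5L))
  # missing exposure metadata: single group with a warning
  noMd <- TimelapseSeries(list(Frame(matrix(10, 8, 8)),
                               Frame(matrix(20, 8, 8))), c(0, 1))
  expect_warning(is3 <- intensitySeries(noMd), "exposure")
  expect_equal(length(unique(is3$exposure_ms)), 1L)
})
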