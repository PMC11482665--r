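test_that("hologram normalization yields a unit-level amplitude field", {
  f <- texFrame(seed = 8, n = 64)
  # frame equal to its own background: unit amplitude everywhere
  h <- Hologram(f, 450, 2.2, background = f)
  expect_equal(Mod(fieldValues(normalizeHologram(h))),
               matrix(1, 64, 64), tolerance = 1e-12)
  # constant frame, no background
  hc <- Hologram(Frame(matrix(120, 32, 32)), 450, 2.2)
  expect_equal(Mod(fieldValues(normalizeHologram(hc))),
               matrix(1, 32, 32), tolerance = 1e-12)
  # simulated hologram: mean amplitude within 1% of 1
  sc <- ParticleScene(data.frame(x_um = 280, y_um = 300, radius_um = 7,
                                 opacity = 1), zUm = 1200)
  hs <- simulateInline(sc, shape = c(256L, 256L), seed = 3)
  expect_lt(abs(mean(Mod(fieldValues(normalizeHologram(hs)))) - 1), 0.01)
  # zero background pixels are floored and reported
  bg <- Frame(matrix(c(0, rep(100, 255)), 16, 16))
  hz <- Hologram(Frame(matrix(50, 16, 16)), 450, 2.2, background = bg)
  expect_warning(normalizeHologram(hz), "floored")
})

test_that("angular-spectrum propagation is unitary on the propagating band", {
  f0 <- bandLimitedField(seed = 1, n = 128)
  # zero distance is the identity
  expect_identical(fieldValues(angularSpectrumPropagate(f0, 0, 450)),
                   fieldValues(f0))
  # +z then -z round trip
  fp <- angularSpectrumPropagate(f0, 800, 450)
  fb <- angularSpectrumPropagate(fp, -800, 450)
  expect_lt(rmsC(fieldValues(fb), fieldValues(f0)), 1e-6)
  # energy conservation (Parseval + unit-modulus transfer)
  e0 <- sum(Mod(fieldValues(f0))^2)
  ep <- sum(Mod(fieldValues(fp))^2)
  expect_lt(abs(ep / e0 - 1), 1e-6)
  # aliasing guard warns beyond pitch^2 N / lambda
  expect_warning(angularSpectrumPropagate(f0, 1e7, 450), "aliasing")
})

test_that("propagation is linear", {
  fA <- bandLimitedField(seed = 2, n = 64)
  fB <- bandLimitedField(seed = 3, n = 64)
  a <- 2.5; b <- -1.2 + 0.7i
  lhs <- angularSpectrumPropagate(
    ComplexField(a * fieldValues(fA) + b * fieldValues(fB), 2.2), 600, 450)
  rhs <- a * fieldValues(angularSpectrumPropagate(fA, 600, 450)) +
    b * fieldValues(angularSpectrumPropagate(fB, 600, 450))
  expect_lt(rmsC(fieldValues(lhs), rhs), 1e-9)
})

test_that("fresnel mode agrees with angular spectrum in the paraxial regime", {
  f0 <- bandLimitedField(seed = 4, n = 128, bandFrac = 0.1)
  ua <- fieldValues(angularSpectrumPropagate(f0, 400, 450))
  uf <- fieldValues(angularSpectrumPropagate(f0, 400, 450,
                                             method = "fresnel"))
  # same intensity structure up to a global phase
  expect_lt(rmsC(ua * Conj(ua[1, 1]) / Mod(ua[1, 1]),
                 uf * Conj(uf[1, 1]) / Mod(uf[1, 1])) /
              sqrt(mean(Mod(ua)^2)), 0.02)
})

test_that("simulation produces fringes and is seed-deterministic", {
  # empty scene, no noise: constant hologram at the background level
  empty <- ParticleScene(data.frame(x_um = numeric(0), y_um = numeric(0),
                                    radius_um = numeric(0),
                                    opacity = numeric(0)), zUm = 1500)
  he <- simulateInline(empty, shape = c(128L, 128L), seed = 1)
  expect_equal(max(pixels(hologramFrame(he))) -
                 min(pixels(hologramFrame(he))), 0)
  expect_equal(mean(pixels(hologramFrame(he))), 0.4 * 255, tolerance = 0.01)
  # single opaque disc: concentric fringes near the particle, flat corners
  sc <- ParticleScene(data.frame(x_um = 280, y_um = 280, radius_um = 8,
                                 opacity = 1), zUm = 1200)
  h <- simulateInline(sc, shape = c(256L, 256L), seed = 2)
  px <- pixels(hologramFrame(h))
  centre <- px[108:148, 108:148]
  corner <- px[1:24, 1:24]
  expect_gt(stats::sd(centre), 10 * max(stats::sd(corner), 0.5))
  # same seed, bit-identical output
  h2 <- simulateInline(sc, shape = c(256L, 256L), seed = 2)
  expect_identical(pixels(hologramFrame(h)), pixels(hologramFrame(h2)))
  # particle outside the field of view is rejected
  bad <- ParticleScene(data.frame(x_um = -5, y_um = 50, radius_um = 8,
                                  opacity = 1), zUm = 1200)
  expect_error(simulateInline(bad, shape = c(128L, 128L), seed = 1),
               "outside")
})

test_that("reconstruction refocuses particles at the true depth", {
  sc <- ParticleScene(data.frame(x_um = c(230, 340), y_um = c(300, 220),
                                 radius_um = c(8, 7), opacity = c(1, 0.9)),
                      zUm = 1200)
  h <- simulateInline(sc, shape = c(256L, 256L), seed = 5, noiseSd = 0.005)
  rec <- reconstruct(h, 1200)
  truth <- cbind(particles(sc)$x_um / 2.2 + 0.5,
                 particles(sc)$y_um / 2.2 + 0.5)
  found <- refineDipCenters(rec, truth)
  expect_lt(max(sqrt(rowSums((found - truth)^2))), 2)
  # constant hologram reconstructs to a constant frame
  hc <- Hologram(Frame(matrix(102, 128, 128)), 450, 2.2)
  rc <- reconstruct(hc, 1000)
  expect_equal(max(pixels(rc)) - min(pixels(rc)), 0, tolerance = 1e-6)
  # grossly wrong depth: lower Michelson contrast around the particle
  recBad <- reconstruct(h, 120)
  mich <- function(fr, cx, cy) {
    w <- pixels(fr)[round(cy) + (-7:7), round(cx) + (-7:7)]
    (max(w) - min(w)) / (max(w) + min(w))
  }
  expect_gt(mich(rec, truth[1, 1], truth[1, 2]),
            mich(recBad, truth[1, 1], truth[1, 2]))
  expect_error(reconstruct(h, -5), "positive")
})

test_that("z scan recovers the scene depth and degrades gracefully", {
  sc <- randomParticleScene(11, shape = c(256L, 256L),
                            zRangeUm = c(800, 2000))
  h <- simulateInline(sc, shape = c(256L, 256L), seed = 61, noiseSd = 0.005)
  res <- zScan(h, 500, 2500, 21)
  step <- (2500 - 500) / 20
  expect_lte(abs(res$bestZUm - sceneDepthUm(sc)), step)
  expect_equal(nrow(res$curve), 21)
  # empty hologram: flat curve, tie resolved to zMin
  he <- Hologram(Frame(matrix(102, 128, 128)), 450, 2.2)
  rese <- zScan(he, 500, 3000, 11)
  expect_equal(rese$bestZUm, 500)
  expect_equal(max(rese$curve$score) - min(rese$curve$score), 0)
  expect_error(zScan(h, -1, 100, 5), "zMin")
  expect_error(zScan(h, 500, 2500, 2), "steps")
})

test_that("refining the z grid does not degrade the depth estimate", {
  # doubling the step count keeps the error within the better of the coarse
  # error and one fine grid step (discretization can flip sides of truth)
  fineStep <- (2500 - 500) / 16
  for (s in c(3, 7, 11, 12)) {
    sc <- randomParticleScene(s, shape = c(256L, 256L),
                              zRangeUm = c(800, 2000))
    h <- simulateInline(sc, shape = c(256L, 256L), seed = s + 50,
                        noiseSd = 0.005)
    coarse <- zScan(h, 500, 2500, 9)$bestZUm
    fine <- zScan(h, 500, 2500, 17)$bestZUm
    expect_lte(abs(fine - sceneDepthUm(sc)),
               max(abs(coarse - sceneDepthUm(sc)), fineStep) + 1e-9)
  }
})
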