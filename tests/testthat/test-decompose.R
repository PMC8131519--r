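bruteForceAlias <- function(f, dt = 0.186, N = 4860) {
  t <- (0:(N - 1)) * dt
  X <- Mod(fft(cos(2 * pi * f * t)))[1:(N / 2)]
  fr <- (0:(N / 2 - 1)) / (N * dt)
  fr[which.max(X)]
}

test_that("alias arithmetic matches the brute-force FFT-peak oracle", {
  fs <- fsDefault()
  for (f in c(30.03, 30.91, 31.8, 40.77, 41.67, 42.55)) {
    al <- aliasFrequency(f, fs)
    expect_equal(al$apparent, bruteForceAlias(f), tolerance = 0.005)
    expect_true(al$reversed)  # all protocol tones fold with reversed sense
  }
  # below Nyquist: preserved, unchanged
  al <- aliasFrequency(2.0, 5.376)
  expect_equal(al$apparent, 2.0)
  expect_false(al$reversed)
  # fold points rejected
  expect_error(aliasFrequency(fs * 5, fs), "fold")
  expect_error(aliasFrequency(fs * 5.5, fs), "fold")
})

test_that("the two frequency regimens alias to matching apparent positions", {
  fs <- fsDefault()
  f31 <- c(30.03, 30.91, 31.8)
  f42 <- c(40.77, 41.67, 42.55)
  for (i in 1:3) {
    a31 <- aliasFrequency(f31[i], fs)$apparent
    a42 <- aliasFrequency(f42[i], fs)$apparent
    expect_lt(abs(a31 - a42), 0.02)
  }
})

test_that("spectral configuration records aliases and warns on crowding", {
  sp <- spectralConfig(acquisitionConfig())
  expect_equal(sp@samplingRate, fsDefault())
  expect_equal(sp@apparentFrequencies, c(2.2281, 1.3481, 0.4581),
               tolerance = 1e-4)
  expect_true(all(sp@reversed))
  crowded <- acquisitionConfig(frequencies = c(30.03, 30.33, 31.8))
  expect_warning(spectralConfig(crowded), "4 sigma")
})

test_that("1,458 phase images decompose into 4,374 wave images and 486 frames", {
  cfg <- countConfig(nImages = 1458L)
  flat <- flatFields(8, lapply(1:3, function(f) as.list(rep(2e-5, 3))))
  raw <- sampleAcquisition(flat, cfg, matrix(50, 8, 8), noiseSd = 0, seed = 1)
  wf <- decomposeSeries(preprocessSeries(raw, sigma = 0))
  expect_identical(nWaveImages(wf), 4374L)
  expect_identical(nFrames(wf), 486L)
  expect_equal(diff(frameTimes(wf)), rep(0.186, 485))
  # fan-out conservation holds for other lengths too
  cfg2 <- countConfig(nImages = 300L)
  raw2 <- sampleAcquisition(flat, cfg2, matrix(50, 8, 8), noiseSd = 0, seed = 1)
  wf2 <- decomposeSeries(preprocessSeries(raw2, sigma = 0))
  expect_identical(nWaveImages(wf2), 3L * 300L)
})

test_that("a steady tone reconstructs with a flat, amplitude-true envelope", {
  cfg <- countConfig(nImages = 1458L)
  # keep the three-tone total phase below pi: spatially constant fields give
  # the unwrapper no gradients to integrate
  u0 <- 8e-6 * exp(0.7i)
  flat <- flatFields(8, lapply(1:3, function(f) as.list(rep(u0, 3))))
  raw <- sampleAcquisition(flat, cfg, matrix(50, 8, 8), noiseSd = 0, seed = 1)
  wf <- decomposeSeries(preprocessSeries(raw, sigma = 0))
  xi <- cfg@encodingSensitivity
  tt <- frameTimes(wf)
  interior <- tt > 3 / (2 * pi * 0.1) & tt < max(tt) - 3 / (2 * pi * 0.1)
  for (fi in 1:3) {
    env <- Mod(wf@fields[[fi]][[1]][4, 4, ])
    expect_lt(max(abs(env[interior] - xi * Mod(u0))) / (xi * Mod(u0)), 0.01)
  }
})

test_that("an amplitude step reconstructs with the Gaussian-filter rise time", {
  cfg <- countConfig(nImages = 1458L)
  cfg@frequencies <- 30.03
  u0 <- 2.4e-5
  step <- function(fi, ci, t) matrix(u0 * (1 + 0.07 * (t >= 45)), 8, 8)
  raw <- sampleAcquisition(step, cfg, matrix(50, 8, 8), noiseSd = 0, seed = 1)
  wf <- decomposeSeries(preprocessSeries(raw, sigma = 0))
  env <- Mod(wf@fields[[1]][[1]][4, 4, ])
  tt <- frameTimes(wf)
  p1 <- mean(env[tt > 10 & tt < 40]); p2 <- mean(env[tt > 50 & tt < 80])
  expect_equal(p2 / p1, 1.07, tolerance = 0.005)
  st <- 1 / (2 * pi * 0.1)
  mid <- tt > 40 & tt < 50
  t10 <- approx(env[mid], tt[mid], xout = p1 + 0.1 * (p2 - p1))$y
  t90 <- approx(env[mid], tt[mid], xout = p1 + 0.9 * (p2 - p1))$y
  expect_equal(t90 - t10, 2.563 * st, tolerance = 0.15 * 2.563 * st)
})

test_that("decomposition is linear in the input phase", {
  cfg <- countConfig(nImages = 300L)
  mk <- function(amp) {
    flat <- flatFields(8, lapply(1:3, function(f) as.list(rep(amp, 3))))
    raw <- sampleAcquisition(flat, cfg, matrix(50, 8, 8), noiseSd = 0, seed = 1)
    ps <- preprocessSeries(raw, sigma = 0)
    ps
  }
  psA <- mk(1e-5); psB <- mk(2e-5 * exp(0.4i))
  # combine at the phase level: a*x + b*y
  comb <- psA
  comb@phase <- 2 * psA@phase + 0.5 * psB@phase
  wfC <- decomposeSeries(comb)
  wfA <- decomposeSeries(psA); wfB <- decomposeSeries(psB)
  lhs <- wfC@fields[[1]][[2]]
  rhs <- 2 * wfA@fields[[1]][[2]] + 0.5 * wfB@fields[[1]][[2]]
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("reversed-alias conjugation restores the propagation direction", {
  # plane wave sampled stroboscopically: the recovered field's spatial phase
  # gradient must match the ground truth; without conjugation it flips sign
  cfg <- acquisitionConfig(scanDuration = 486 * 0.062, matrixSize = c(16L, 16L),
                           voxelSize = c(0.003, 0.003, 0.005),
                           frequencies = 30.03)
  g <- 1370 * exp(0.1i)
  u <- planeWaveField(g, 30.03, c(0, 1), 16, 0.003, u0 = 2e-5)
  fields <- function(fi, ci, t) u
  raw <- sampleAcquisition(fields, cfg, matrix(50, 16, 16), noiseSd = 0, seed = 1)
  wf <- decomposeSeries(preprocessSeries(raw, sigma = 0))
  rec <- wf@fields[[1]][[1]][, , 100]
  gradRec <- Arg(rec[8, 9] * Conj(rec[8, 8]))
  gradTrue <- Arg(u[8, 9] * Conj(u[8, 8]))
  expect_equal(sign(gradRec), sign(gradTrue))
  expect_equal(gradRec, gradTrue, tolerance = 0.02)
  # negative control: conjugating the recovered field flips the gradient
  expect_equal(sign(Arg(Conj(rec)[8, 9] * Conj(Conj(rec)[8, 8]))), -sign(gradTrue))
})

test_that("apparent-frequency collisions abort and partial interleaves truncate", {
  cfg <- countConfig(nImages = 300L)
  flat <- flatFields(8, lapply(1:3, function(f) as.list(rep(2e-5, 3))))
  raw <- sampleAcquisition(flat, cfg, matrix(50, 8, 8), noiseSd = 0, seed = 1)
  ps <- preprocessSeries(raw, sigma = 0)
  collide <- new("SpectralConfig", samplingRate = fsDefault(), bandpassSigma = 0.1,
                 frequencies = c(30.0, 30.05, 31.8),
                 apparentFrequencies = c(2.2, 2.25, 0.458),
                 reversed = c(TRUE, TRUE, TRUE))
  expect_error(decomposeSeries(ps, collide), "collide")
  # trailing partial interleave triggers a warning and truncation
  ps2 <- ps
  ps2@phase <- ps2@phase[, , 1:299]
  ps2@timestamps <- ps2@timestamps[1:299]
  ps2@componentLabels <- ps2@componentLabels[1:299]
  expect_warning(wf2 <- decomposeSeries(ps2), "truncating")
  expect_identical(nFrames(wf2), 99L)
})
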