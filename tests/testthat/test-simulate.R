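test_that("sampled series has the configured length, labels and wrapped phase", {
  cfg <- countConfig(nImages = 1458L)
  flat <- flatFields(8, lapply(1:3, function(f) as.list(rep(2e-5, 3))))
  s <- sampleAcquisition(flat, cfg, matrix(50, 8, 8), noiseSd = 0.5, seed = 7)
  expect_identical(nFrames(s), 1458L)
  expect_equal(componentLabels(s), rep(0:2, 486))
  expect_true(all(abs(Arg(imageData(s))) <= pi))
  # arbitrary durations
  cfg2 <- countConfig(nImages = 100L)
  s2 <- sampleAcquisition(flat, cfg2, matrix(50, 8, 8), noiseSd = 0, seed = 1)
  expect_identical(nFrames(s2), 100L)
})

test_that("zero noise and zero encoding give identically zero phase", {
  cfg <- countConfig(nImages = 30L)
  cfg@encodingSensitivity <- 0
  flat <- flatFields(8, lapply(1:3, function(f) as.list(rep(1e-4, 3))))
  s <- sampleAcquisition(flat, cfg, matrix(50, 8, 8), noiseSd = 0, seed = 1)
  expect_true(all(Arg(imageData(s)) == 0))
})

test_that("the same seed reproduces the series bit-identically", {
  cfg <- countConfig(nImages = 60L)
  flat <- flatFields(8, lapply(1:3, function(f) as.list(rep(2e-5, 3))))
  s1 <- sampleAcquisition(flat, cfg, matrix(50, 8, 8), noiseSd = 1.8, seed = 42)
  s2 <- sampleAcquisition(flat, cfg, matrix(50, 8, 8), noiseSd = 1.8, seed = 42)
  expect_identical(imageData(s1), imageData(s2))
  s3 <- sampleAcquisition(flat, cfg, matrix(50, 8, 8), noiseSd = 1.8, seed = 43)
  expect_false(identical(imageData(s3), imageData(s1)))
})

test_that("a pure 30.03-Hz tone appears at its aliased slow-time position", {
  cfg <- countConfig(nImages = 1458L)
  cfg@frequencies <- 30.03
  flat <- list(lapply(1:3, function(c) matrix(3e-6, 8, 8)))
  s <- sampleAcquisition(flat, cfg, matrix(50, 8, 8), noiseSd = 0, seed = 1)
  sel <- componentLabels(s) == 0L
  x <- Arg(imageData(s)[4, 4, sel])
  X <- Mod(fft(x))
  nFr <- sum(sel)
  fr <- (seq_len(nFr) - 1) / (nFr * 0.186)
  peak <- fr[which.max(X[fr > 0 & fr <= fsDefault() / 2])
             + sum(fr <= 0)]
  expect_equal(peak, 2.23, tolerance = 0.01)
})

test_that("raising the encoding sensitivity past pi provably wraps the phase", {
  cfg <- countConfig(nImages = 12L)
  cfg@frequencies <- 30.03
  cfg@encodingSensitivity <- 4   # with 1 m displacement: 4 rad > pi
  flat <- list(lapply(1:3, function(c) matrix(1 + 0i, 8, 8)))
  s <- sampleAcquisition(flat, cfg, matrix(50, 8, 8), noiseSd = 0, seed = 1)
  trueMax <- max(abs(4 * Re(exp(2i * pi * 30.03 * frameTimes(s)))))
  expect_gt(trueMax, pi)                       # the encoded phase exceeds pi
  expect_lte(max(abs(Arg(imageData(s)))), pi)  # but the stored phase is wrapped
})

test_that("fields must cover the scan duration", {
  cfg <- countConfig(nImages = 30L)
  bad <- function(fi, ci, t) if (t > 1) stop("field slow-time support does not cover the scan duration") else matrix(0i, 8, 8)
  expect_error(sampleAcquisition(bad, cfg, matrix(50, 8, 8), noiseSd = 0, seed = 1),
               "support")
})

test_that("phantom geometry: CSF holes, rim sources, magnitude levels", {
  cfg <- testConfig(nImages = 30L)
  ph <- brainPhantom(cfg)
  expect_true(any(ph@holeMask))
  expect_true(all(ph@magnitudeMap[ph@holeMask] == 5))
  expect_true(all(ph@magnitudeMap[ph@tissueMask & !ph@holeMask] == 50))
  expect_true(all(ph@magnitudeMap[!ph@tissueMask] == 8))
  # sources include the rim, the holes and the FoV border
  expect_true(all(ph@sourceMask[ph@holeMask]))
  expect_true(all(ph@sourceMask[1, ]))
  # parenchyma polygon excludes a margin around every source
  poly <- parenchymaPolygon(ph, margin = 2)
  expect_true(any(poly))
  near <- which(ph@sourceMask, arr.ind = TRUE)
  pp <- which(poly, arr.ind = TRUE)
  dmin <- min(vapply(seq_len(nrow(pp)), function(i)
    sqrt(min((near[, 1] - pp[i, 1])^2 + (near[, 2] - pp[i, 2])^2)), 0))
  expect_gte(dmin, 2)
})
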