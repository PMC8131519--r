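makeElastogram <- function(nFr = 486L, n = 10L, gstar = 1400, phi = 0.8,
                           dur = 1458 * 0.062) {
  tt <- (3 * (0:(nFr - 1)) + 1) * 0.062
  g <- array(gstar, c(n, n, nFr)); p <- array(phi, c(n, n, nFr))
  v <- array(TRUE, c(n, n, nFr))
  new("ElastogramSeries", gstar = g, phi = p, valid = v,
      frameTimes = tt, scanDuration = dur,
      settings = list(rho = 1000, spacing = 0.002, stencil = "5-point",
                      frequencies = c(30.03, 30.91, 31.8), nComponents = 3L))
}

test_that("margin trimming leaves the 80-s window and 432 of 486 frames", {
  es <- makeElastogram()
  tr <- trimMargins(es, 5)
  expect_identical(nFrames(tr), 432L)
  expect_true(all(frameTimes(tr) >= 5 & frameTimes(tr) <= 90.396 - 5))
  expect_equal(es@scanDuration - 2 * 5, 80.396, tolerance = 1e-9)
  expect_identical(trimMargins(es, 0), es)
  expect_error(trimMargins(es, 50), "margin")
})

test_that("ROI thresholds remove CSF-like holes and respect the polygon", {
  meanMag <- matrix(50, 12, 12)
  meanG <- matrix(1400, 12, 12)
  holes <- matrix(FALSE, 12, 12); holes[5:8, 5:6] <- TRUE
  meanMag[holes] <- 5
  meanG[holes] <- 600
  roi <- makeROI(meanMag, meanG)
  expect_false(any(roi[holes]))
  expect_true(all(roi[!holes]))
  # uniform tissue above both thresholds: mask = all valid pixels
  valid <- matrix(TRUE, 12, 12); valid[1, ] <- FALSE
  expect_identical(makeROI(matrix(50, 12, 12), matrix(1400, 12, 12),
                           valid = valid), valid)
  # zero thresholds: mask = polygon (within valid)
  poly <- matrix(FALSE, 12, 12); poly[3:6, 3:6] <- TRUE
  expect_identical(makeROI(meanMag, meanG, magnitudeThreshold = 0,
                           gstarThreshold = 0, polygon = poly), poly)
  expect_error(makeROI(matrix(1, 4, 4), matrix(1, 4, 4)), "empty")
})

test_that("phase intervals reject overlap and statistics are exact on constants", {
  expect_error(phaseIntervals(bsl = c(2.5, 40)), "overlap")
  es <- trimMargins(makeElastogram(), 5)
  roi <- matrix(TRUE, 10, 10)
  tc <- roiTimeCourse(es, roi)
  st <- phaseStatistics(tc)
  expect_equal(st$mean_gstar, rep(1400, 4))
  expect_equal(st$sd_gstar, rep(0, 4))
  expect_equal(st$mean_phi, rep(0.8, 4))
  expect_equal(st$cv_gstar_pct, rep(0, 4))
  expect_error(phaseStatistics(tc, list(X = c(200, 201))), "frames")
})

test_that("difference series plus baseline mean reconstructs the absolute series", {
  es <- trimMargins(makeElastogram(), 5)
  set.seed(4)
  es@gstar <- es@gstar + array(rnorm(length(es@gstar), sd = 20), dim(es@gstar))
  tc <- roiTimeCourse(es, matrix(TRUE, 10, 10))
  expect_equal(tc$dgstar_pa + attr(tc, "bslGstar"), tc$gstar_pa, tolerance = 1e-12)
  expect_equal(tc$dphi_rad + attr(tc, "bslPhi"), tc$phi_rad, tolerance = 1e-12)
})

test_that("interval statistics are invariant to frame order within the interval", {
  es <- trimMargins(makeElastogram(), 5)
  set.seed(8)
  es@gstar <- es@gstar + array(rnorm(length(es@gstar), sd = 15), dim(es@gstar))
  tc <- roiTimeCourse(es, matrix(TRUE, 10, 10))
  st1 <- phaseStatistics(tc)
  sel <- tc$time_s >= 2.5 & tc$time_s <= 22.5
  tc2 <- tc
  tc2[sel, ] <- tc2[rev(which(sel)), ]
  tc2$time_s[sel] <- tc$time_s[sel]
  st2 <- phaseStatistics(tc2)
  expect_equal(st2$mean_gstar[1], st1$mean_gstar[1], tolerance = 1e-12)
  expect_equal(st2$sd_gstar[1], st1$sd_gstar[1], tolerance = 1e-12)
})

test_that("peak detection: maxima, boundary argmax, flat series", {
  es <- trimMargins(makeElastogram(), 5)
  tt <- es@frameTimes
  bump <- 100 * exp(-(tt - 32.4)^2 / 8)
  for (k in seq_along(tt)) es@gstar[, , k] <- 1400 + bump[k]
  tc <- roiTimeCourse(es, matrix(TRUE, 10, 10))
  pk <- detectPeak(tc, eventTime = 30, searchWindow = 10)
  expect_equal(pk$delay, 2.4, tolerance = 0.1)
  expect_equal(pk$pct, 100 * pk$peak / attr(tc, "bslGstar"))
  # monotone ramp: argmax at the window end
  es2 <- trimMargins(makeElastogram(), 5)
  for (k in seq_along(tt)) es2@gstar[, , k] <- 1400 + 2 * tt[k]
  tc2 <- roiTimeCourse(es2, matrix(TRUE, 10, 10))
  pk2 <- detectPeak(tc2, eventTime = 30, searchWindow = 10)
  expect_equal(pk2$delay, 10, tolerance = 0.2)
  # flat zero difference series
  tc3 <- roiTimeCourse(trimMargins(makeElastogram(), 5), matrix(TRUE, 10, 10))
  pk3 <- detectPeak(tc3, eventTime = 30, searchWindow = 10)
  expect_equal(pk3$peak, 0)
  expect_equal(pk3$pct, 0)
  expect_error(detectPeak(tc3, eventTime = 200, searchWindow = 5), "empty")
})

test_that("coefficient of variation matches its definition", {
  es <- trimMargins(makeElastogram(), 5)
  tc <- roiTimeCourse(es, matrix(TRUE, 10, 10))
  expect_equal(coefficientOfVariation(tc), 0)
  # alternating v(1 +/- 0.01) -> CV ~= 1%
  tc$gstar_pa <- 1400 * (1 + c(-0.01, 0.01))
  expect_equal(coefficientOfVariation(tc), 1.0, tolerance = 0.01)
  tc$gstar_pa <- rep(0, nrow(tc))
  expect_error(coefficientOfVariation(tc), "zero")
})

test_that("blind wavelet noise estimate recovers injected noise within 15%", {
  set.seed(21)
  g <- 1370 * exp(0.8i)
  u <- planeWaveField(g, 30.03, c(1, 1) / sqrt(2), 64, 0.002, u0 = 1)
  u <- u / sqrt(mean(Mod(u)^2))          # unit RMS
  for (snrLin in c(5, 12)) {
    sigma <- 1 / snrLin                   # complex-noise SD
    noisy <- u + complex(real = rnorm(64^2, sd = sigma / sqrt(2)),
                         imaginary = rnorm(64^2, sd = sigma / sqrt(2)))
    est <- waveletNoiseSd(matrix(noisy, 64, 64))
    expect_lt(abs(est - sigma) / sigma, 0.15)
    w <- wsnrDb(matrix(noisy, 64, 64))
    expect_lt(abs(w - 20 * log10(sqrt(mean(Mod(noisy)^2)) / sigma)), 1.5)
  }
})

test_that("WSNR endpoints: noise-free warns with Inf; pure noise scores ~0 dB", {
  smooth <- gaussianSmoothComplex(matrix(1 + 0i, 32, 32), 2)
  expect_warning(w <- wsnrDb(smooth), "unbounded")
  expect_identical(w, Inf)
  set.seed(5)
  pure <- matrix(complex(real = rnorm(4096, sd = 1 / sqrt(2)),
                         imaginary = rnorm(4096, sd = 1 / sqrt(2))), 64, 64)
  expect_lt(abs(wsnrDb(pure)), 1)
})

test_that("magnitude SNR follows its definition and gains 6 dB per doubling", {
  mag <- matrix(50, 20, 20)
  roi <- matrix(TRUE, 20, 20)
  bg <- matrix(FALSE, 20, 20); bg[1:3, ] <- TRUE
  set.seed(2)
  mag[bg] <- rnorm(sum(bg), mean = 0, sd = 5)
  roi[bg] <- FALSE
  s1 <- snrDb(mag, roi, background = bg)
  expect_equal(s1, 20 * log10(mean(mag[roi]) / sd(mag[bg])), tolerance = 1e-12)
  mag2 <- mag; mag2[roi] <- 2 * mag2[roi]
  expect_equal(snrDb(mag2, roi, background = bg) - s1, 20 * log10(2),
               tolerance = 1e-9)
  expect_error(snrDb(mag, roi, background = matrix(FALSE, 20, 20)), "background")
})
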