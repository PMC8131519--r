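test_that("five-point Laplacian: linear fields, quadratics, dispersion relation", {
  n <- 24; h <- 0.002
  xx <- matrix((0:(n - 1)) * h, n, n, byrow = TRUE)
  lin <- 3 * xx + 2 * t(xx) + 1
  L <- laplacianField(lin, h)
  v <- attr(L, "validMask")
  expect_true(all(abs(L[v]) < 1e-9))
  expect_false(any(v[1, ]) || any(v[, n]))
  quad <- xx^2
  L2 <- laplacianField(quad, h)
  expect_equal(unname(L2[v]), rep(2, sum(v)), tolerance = 1e-9)
  # complex plane wave: discrete dispersion matches closed form to 1e-12
  k <- c(0.32, 0) / h   # |k| h = 0.32 along rows
  u <- exp(1i * (outer((0:(n - 1)) * h * k[1], rep(0, n), "+")))
  L3 <- laplacianField(u, h)
  kEff2 <- (2 - 2 * cos(k[1] * h)) / h^2
  expect_equal(L3[v], -kEff2 * u[v], tolerance = 1e-12)
  # oblique wavevector
  k2 <- c(0.2, 0.25) / h
  ph <- outer((0:(n - 1)) * h * k2[1], (0:(n - 1)) * h * k2[2], "+")
  u2 <- exp(1i * ph)
  L4 <- laplacianField(u2, h)
  kEff22 <- (2 - 2 * cos(k2[1] * h)) / h^2 + (2 - 2 * cos(k2[2] * h)) / h^2
  expect_equal(L4[v], -kEff22 * u2[v], tolerance = 1e-12)
})

test_that("MDEV inversion recovers |G*| and phi from analytic plane waves", {
  pw <- cachedFixture("planeWaves64", function() planeWaveSet())
  m <- mdevInvert(pw$fields, pw$frequencies, rho = 1000, spacing = 0.002)
  expect_lt(abs(median(m$gstar[m$valid]) - 1370) / 1370, 0.02)
  expect_lt(abs(median(m$phi[m$valid]) - 0.800), 0.02)
  # discrete-dispersion bias bound at ~21 px/wavelength
  expect_lt(abs(median(m$gstar[m$valid]) / 1370 - 1), 0.012)
})

test_that("MDEV is linear in rho and invariant to per-pair complex rescaling", {
  pw <- cachedFixture("planeWaves64", function() planeWaveSet())
  m1 <- mdevInvert(pw$fields, pw$frequencies, rho = 1000, spacing = 0.002)
  m2 <- mdevInvert(pw$fields, pw$frequencies, rho = 2000, spacing = 0.002)
  expect_equal(m2$gstar[m2$valid], 2 * m1$gstar[m1$valid], tolerance = 1e-12)
  expect_equal(m2$phi[m2$valid], m1$phi[m1$valid], tolerance = 1e-12)
  # unit-modulus rescaling leaves the amplitude weights untouched: exact
  set.seed(14)
  phases <- exp(2i * runif(length(pw$fields)))
  m3 <- mdevInvert(Map(`*`, pw$fields, as.list(phases)),
                   pw$frequencies, rho = 1000, spacing = 0.002)
  expect_equal(m3$gstar, m1$gstar, tolerance = 1e-10)
  expect_equal(m3$phi, m1$phi, tolerance = 1e-10)
  # modulus rescaling shifts the amplitude weights between pairs; on
  # near-consistent plane waves the maps move only at the 1e-4 level
  scales <- phases * runif(length(pw$fields), 0.5, 5)
  m4 <- mdevInvert(Map(`*`, pw$fields, as.list(scales)),
                   pw$frequencies, rho = 1000, spacing = 0.002)
  expect_lt(max(abs(m4$gstar - m1$gstar) / m1$gstar, na.rm = TRUE), 1e-3)
  expect_lt(max(abs(m4$phi - m1$phi), na.rm = TRUE), 1e-3)
})

test_that("phi is clipped to [0, pi] for arbitrary complex inputs", {
  set.seed(9)
  flds <- lapply(1:4, function(i)
    matrix(complex(real = rnorm(400), imaginary = rnorm(400)), 20, 20))
  m <- mdevInvert(flds, c(30, 30, 31, 31), rho = 1000, spacing = 0.002)
  expect_true(all(m$phi[m$valid] >= 0 & m$phi[m$valid] <= pi))
})

test_that("degenerate inputs are rejected or masked", {
  expect_error(mdevInvert(list(), 30), "empty")
  expect_error(mdevInvert(list(matrix(0i, 4, 4), matrix(0i, 5, 5)), 30),
               "mismatched")
  z <- mdevInvert(list(matrix(0i, 6, 6)), 30, 1000, 0.002)
  expect_false(any(z$valid))   # zero denominators masked invalid
})

test_that("single-frequency inversion equals MDEV restricted to that frequency", {
  pw <- cachedFixture("planeWaves64", function() planeWaveSet())
  sel <- pw$frequencies == 30.03
  m1 <- singleFreqInvert(pw$fields[sel], 30.03, 1000, 0.002)
  m2 <- mdevInvert(pw$fields[sel], pw$frequencies[sel], 1000, 0.002)
  expect_identical(m1, m2)
})

test_that("series inversion consumes nine images per frame: 4,374 -> 486 maps", {
  cfg <- countConfig(nImages = 1458L)
  flat <- flatFields(8, lapply(1:3, function(f) as.list(rep(4e-6, 3))))
  raw <- sampleAcquisition(flat, cfg, matrix(50, 8, 8), noiseSd = 0, seed = 1)
  wf <- decomposeSeries(preprocessSeries(raw, sigma = 0))
  expect_identical(nWaveImages(wf), 4374L)
  es <- invertSeries(wf)
  expect_identical(nFrames(es), 486L)
  expect_identical(nWaveImages(wf) %/% (3L * 3L), nFrames(es))
  expect_identical(dim(gstarMaps(es)), c(8L, 8L, 486L))
})

test_that("time-constant wave fields give time-constant maps", {
  g <- 1370 * exp(0.8i)
  n <- 20L
  cfg <- acquisitionConfig(scanDuration = 90 * 0.062, matrixSize = c(n, n),
                           voxelSize = c(0.003, 0.003, 0.005))
  u <- lapply(cfg@frequencies, function(f)
    lapply(list(c(1, 0), c(0, 1), c(1, 1) / sqrt(2)), function(d)
      planeWaveField(g, f, d, n, 0.003)))
  spec <- spectralConfig(cfg)
  nFr <- 30L
  fields <- lapply(1:3, function(fi) lapply(1:3, function(ci)
    array(rep(u[[fi]][[ci]], nFr), c(n, n, nFr))))
  wf <- new("DecomposedWavefield", fields = fields,
            frameTimes = (0:(nFr - 1)) * 0.186 + 0.062,
            frequencies = cfg@frequencies, spectral = spec, config = cfg)
  es <- invertSeries(wf, spacing = 0.003)
  gs <- gstarMaps(es)
  perPixelSd <- apply(gs, c(1, 2), sd)
  expect_true(all(perPixelSd[validityMask(es)[, , 1]] == 0))
  expect_lt(abs(median(gs[validityMask(es)]) - 1370) / 1370, 0.02)
})

test_that("frequency-regimen consistency: 42-Hz run matches 31-Hz relative response", {
  # noiseless maneuver pipelines under both narrowband regimens recover the
  # same relative overshoot to within one percentage point
  run <- function(freqs) {
    cfg <- pipelineConfig(
      acquisition = list(matrixSize = c(64L, 64L),
                         voxelSize = c(0.003, 0.003, 0.005),
                         frequencies = freqs),
      simulation = list(noiseSd = 0))
    res <- runPipeline(cfg, seed = 1)
    c(res$summary$early_pct, res$summary$late_pct, res$summary$phi_dip_pct)
  }
  r31 <- run(c(30.03, 30.91, 31.8))
  r42 <- run(c(40.77, 41.67, 42.55))
  expect_lt(abs(r31[1] - r42[1]), 1)
  expect_lt(abs(r31[2] - r42[2]), 1)
  expect_lt(abs(r31[3] - r42[3]), 1)
})
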