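# Shared fixtures: small configurations and cached expensive objects.

# per-component sampling rate of the default protocol
fsDefault <- function() 1 / (3 * 0.062)

# small test grid resolving the 31-Hz shear wavelength (~14 px at 3 mm)
testConfig <- function(nImages = 1458L, n = 64L, h = 0.003, xi = 80000, ...) {
  acquisitionConfig(scanDuration = nImages * 0.062,
                    matrixSize = c(n, n), voxelSize = c(h, h, 0.005),
                    encodingSensitivity = xi, ...)
}

# tiny grid for pure timing/counting tests (fields supplied directly,
# no Helmholtz solve, so wavelength resolution is irrelevant)
countConfig <- function(nImages = 1458L, n = 8L) {
  acquisitionConfig(scanDuration = nImages * 0.062,
                    matrixSize = c(n, n), voxelSize = c(0.002, 0.002, 0.005))
}

# constant-field provider: one complex amplitude per (frequency, component)
flatFields <- function(n, amps) {
  lapply(amps, function(af) lapply(af, function(a) matrix(a, n, n)))
}

# a smooth random 2-D field with bounded gradients, for unwrap properties
smoothRandomField <- function(n, amplitude = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * n), n, n)
  S <- stroboMRE::gaussianSmoothComplex(x, 3)
  amplitude * S / max(abs(S))
}

# cache expensive solver-based objects across test files within one run
.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, build) {
  hit <- get0(key, envir = .fixtureCache, inherits = FALSE)
  if (is.null(hit)) {
    hit <- build()
    assign(key, hit, envir = .fixtureCache)
  }
  hit
}

# nine analytic plane-wave fields (3 frequencies x 3 directions)
planeWaveSet <- function(gstar = 1370 * exp(0.8i), n = 64L, h = 0.002,
                         rho = 1000, freqs = c(30.03, 30.91, 31.8)) {
  dirs <- list(c(1, 0), c(0, 1), c(1, 1) / sqrt(2))
  fields <- list(); fv <- numeric(0)
  for (f in freqs) for (d in dirs) {
    fields <- c(fields, list(planeWaveField(gstar, f, d, n, h, rho = rho)))
    fv <- c(fv, f)
  }
  list(fields = fields, frequencies = fv)
}

# wrap to (-pi, pi] (test-side reference implementation)
wrapToPiTest <- function(x) {
  y <- atan2(sin(x), cos(x))
  y[y == -pi] <- pi
  y
}
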