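#' Stroboscopically sample an acquisition
#'
#' Generates the raw complex single-shot image series of a scan. For image
#' index k (0-based) at timestamp `t_k = k * tr`, encoding component
#' `c = k %% nComponents`, the noiseless encoded phase is
#' \deqn{\phi_k(x) = \xi \sum_f Re[u_{f,c}(x; t_k) e^{i 2\pi f t_k}]}
#' with encoding sensitivity xi (rad/m). The stored image is
#' `M(x) * exp(1i * phi_k(x))` plus i.i.d. complex Gaussian noise of the
#' given per-channel standard deviation; its phase is wrapped to (-pi, pi]
#' by construction. The seed fully determines the output.
#'
#' @param fields a function `(fi, ci, t) -> complex matrix` giving the
#'   displacement field of frequency index fi and component index ci (both
#'   1-based) at slow time t, e.g. from [wavefieldSeries()], or a plain list
#'   `fields[[fi]][[ci]]` of time-constant matrices.
#' @param config an [AcquisitionConfig-class].
#' @param magnitude MR magnitude template matrix `M(x)`.
#' @param noiseSd per-channel standard deviation of the complex noise, in
#'   image units; the default is calibrated to a magnitude SNR near 29 dB
#'   for the default template.
#' @param seed integer random seed.
#' @return a [RawImageSeries-class].
#' @examples
#' cfg <- acquisitionConfig(scanDuration = 30 * 0.062, matrixSize = c(16, 16))
#' flat <- lapply(1:3, function(f) lapply(1:3, function(c) matrix(0i, 16, 16)))
#' s <- sampleAcquisition(flat, cfg, matrix(50, 16, 16), noiseSd = 0, seed = 1)
#' stopifnot(all(Arg(imageData(s)) == 0))
#' @export
sampleAcquisition <- function(fields, config, magnitude,
                              noiseSd = 1.8, seed = 1L) {
  stopifnot(noiseSd >= 0)
  ny <- config@matrixSize[1]; nx <- config@matrixSize[2]
  if (!identical(dim(magnitude), c(ny, nx)))
    stop("magnitude template does not match the configured matrix")
  nImg <- nImages(config)
  tks <- imageTimes(config)
  comps <- imageComponents(config)
  freqs <- config@frequencies
  xi <- config@encodingSensitivity

  fieldAt <- if (is.function(fields)) fields else function(fi, ci, t) {
    fields[[fi]][[ci]]
  }
  set.seed(as.integer(seed))
  images <- array(0i, dim = c(ny, nx, nImg))
  for (k in seq_len(nImg)) {
    tk <- tks[k]
    if (tk >= config@scanDuration + config@tr)
      stop("field slow-time support does not cover the scan duration")
    ci <- comps[k] + 1L
    ph <- matrix(0, ny, nx)
    for (fi in seq_along(freqs)) {
      u <- fieldAt(fi, ci, tk)
      ph <- ph + Re(u * exp(2i * pi * freqs[fi] * tk))
    }
    img <- magnitude * exp(1i * xi * ph)
    if (noiseSd > 0)
      img <- img + complex(real = rnorm(ny * nx, sd = noiseSd),
                           imaginary = rnorm(ny * nx, sd = noiseSd))
    images[, , k] <- img
  }
  new("RawImageSeries", images = images, timestamps = tks,
      componentLabels = comps, config = config,
      seed = as.integer(seed), noiseSd = noiseSd)
}

#' Simulate a full maneuver acquisition
#'
#' Convenience wrapper: builds (or accepts) a phantom, a quasi-static
#' wavefield provider under the maneuver profile, and samples the raw image
#' series. Pass a pre-built `solver` to reuse cached Helmholtz solutions
#' across repeated noise realizations of the same phantom and profile.
#'
#' @param config an [AcquisitionConfig-class].
#' @param profile a [ManeuverProfile-class] or NULL for a steady phantom.
#' @param phantom a [ViscoelasticPhantom-class]; defaults to
#'   [brainPhantom()] at the profile's baseline modulus.
#' @param noiseSd per-channel complex noise standard deviation.
#' @param seed integer random seed.
#' @param solver optional precomputed [wavefieldSeries()] provider.
#' @param u0 drive amplitude in metres.
#' @return a [RawImageSeries-class].
#' @export
simulateAcquisition <- function(config = acquisitionConfig(),
                                profile = maneuverProfile(),
                                phantom = NULL,
                                noiseSd = 1.8,
                                seed = 1L,
                                solver = NULL,
                                u0 = 30e-6) {
  if (is.null(phantom)) {
    g0 <- if (is.null(profile)) 1370 * exp(0.8i) else
      profile@baselineGstar * exp(1i * profile@baselinePhi)
    phantom <- brainPhantom(config, gstar = g0)
  }
  if (is.null(solver))
    solver <- wavefieldSeries(phantom, config, profile, u0 = u0)
  sampleAcquisition(solver, config, phantom@magnitudeMap,
                    noiseSd = noiseSd, seed = seed)
}

setMethod("nFrames", "RawImageSeries", function(x) dim(x@images)[3L])
setMethod("frameTimes", "RawImageSeries", function(x) x@timestamps)
setMethod("imageData", "RawImageSeries", function(x) x@images)
setMethod("componentLabels", "RawImageSeries", function(x) x@componentLabels)
setMethod("seriesConfig", "RawImageSeries", function(x) x@config)

setMethod("show", "RawImageSeries", function(object) {
  d <- dim(object@images)
  cat(sprintf("RawImageSeries: %d complex images of %d x %d px over %.2f s\n",
              d[3], d[1], d[2], object@config@scanDuration))
  cat(sprintf("  %d interleaved components, noise sd %.3g, seed %d\n",
              object@config@nComponents, object@noiseSd, object@seed))
})
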