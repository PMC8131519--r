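#' @import methods
#' @importFrom stats fft mvfft rnorm sd median dnorm approx dist
#' @importFrom utils write.csv read.csv
NULL

#' Acquisition configuration
#'
#' Timing, frequency, geometry, and motion-encoding parameters of a
#' stroboscopic multifrequency MRE scan, real or simulated. Defaults describe
#' a 62-ms TR single-shot acquisition of 1,458 images with three interleaved
#' Cartesian encoding components and three simultaneous vibration frequencies
#' around 31 Hz.
#'
#' @slot tr repetition time in seconds.
#' @slot nComponents number of interleaved motion-encoding components.
#' @slot frequencies vibration frequencies in Hz, strictly increasing.
#' @slot scanDuration total acquisition time in seconds.
#' @slot matrixSize image matrix (rows, columns) in pixels.
#' @slot voxelSize voxel size in metres (in-plane row, in-plane column, slice).
#' @slot megDuration motion-encoding gradient duration in seconds.
#' @slot megAmplitude motion-encoding gradient amplitude in mT/m.
#' @slot encodingSensitivity phase per unit displacement, rad/m.
#' @slot flipAngle recorded flip angle in degrees (metadata only).
#' @slot te recorded echo time in seconds (metadata only).
#'
#' @seealso [acquisitionConfig()]
#' @export
setClass("AcquisitionConfig",
  representation(
    tr = "numeric",
    nComponents = "integer",
    frequencies = "numeric",
    scanDuration = "numeric",
    matrixSize = "integer",
    voxelSize = "numeric",
    megDuration = "numeric",
    megAmplitude = "numeric",
    encodingSensitivity = "numeric",
    flipAngle = "numeric",
    te = "numeric"
  )
)

setValidity("AcquisitionConfig", function(object) {
  msg <- character()
  if (length(object@tr) != 1L || object@tr <= 0) msg <- c(msg, "tr must be a positive scalar")
  if (object@nComponents < 1L) msg <- c(msg, "nComponents must be >= 1")
  f <- object@frequencies
  if (length(f) < 1L || any(f <= 0)) msg <- c(msg, "frequencies must be positive")
  if (is.unsorted(f, strictly = TRUE)) msg <- c(msg, "frequencies must be strictly increasing")
  if (object@scanDuration < object@nComponents * object@tr)
    msg <- c(msg, "scanDuration must cover at least one full component interleave")
  if (any(object@matrixSize <= 0L)) msg <- c(msg, "matrixSize must be positive")
  if (any(object@voxelSize <= 0)) msg <- c(msg, "voxelSize must be positive")
  if (length(msg) == 0L && length(f) >= 1L) {
    fs <- 1 / (object@nComponents * object@tr)
    ali <- vapply(f, function(ff) tryCatch(aliasFrequency(ff, fs)$apparent,
                                           error = function(e) NA_real_), 0)
    if (anyNA(ali)) msg <- c(msg, "a vibration frequency lands on a spectral fold point")
    else if (any(duplicated(round(ali, 9)))) msg <- c(msg, "vibration frequencies must alias to pairwise distinct apparent frequencies")
  }
  if (length(msg)) msg else TRUE
})

#' Valsalva-style maneuver profile
#'
#' Parameters of the slow time course imposed on the phantom's complex shear
#' modulus: a baseline, an early stiffness overshoot after maneuver onset, a
#' ramped plateau during the maneuver, a second overshoot after release with
#' exponential recovery, and a constant relative reduction of the loss angle
#' while the maneuver is held. Defaults reproduce group-mean in vivo values
#' (baseline 1370 Pa / 0.800 rad; overshoots of 6.7% at 2.4 s and 7.4% at
#' 5.5 s; loss-angle dip of about -2.1%).
#'
#' @slot baselineGstar baseline shear-modulus magnitude in Pa.
#' @slot baselinePhi baseline loss angle in rad, within (0, pi).
#' @slot onset,release maneuver onset and release times in seconds.
#' @slot earlyOvershootPct,earlyDelay early overshoot amplitude (% above
#'   baseline) and its delay after onset (s).
#' @slot lateOvershootPct,lateDelay post-release overshoot amplitude (%) and
#'   delay after release (s).
#' @slot plateauRampPct stiffness plateau reached by the end of the maneuver
#'   (% above baseline).
#' @slot rampDelay seconds after onset before the plateau ramp engages; the
#'   early overshoot decays through a short drop before stiffness climbs
#'   again.
#' @slot phiDipPct relative change of the loss angle while the maneuver is
#'   held, in percent (negative for a dip).
#' @slot recoveryTau exponential recovery time constant after release (s).
#' @slot earlySigma,lateSigma Gaussian widths (s) of the two overshoot bumps.
#' @slot leadIn,leadWidth start (s before onset) and width (s) of the
#'   smoothstep window that zeroes the early bump's far tail so the baseline
#'   multiplier is exactly 1.
#' @slot transitionWidth smoothstep width (s) of the loss-angle transitions.
#'
#' @seealso [maneuverProfile()], [maneuverFunctions()]
#' @export
setClass("ManeuverProfile",
  representation(
    baselineGstar = "numeric",
    baselinePhi = "numeric",
    onset = "numeric",
    release = "numeric",
    earlyOvershootPct = "numeric",
    earlyDelay = "numeric",
    lateOvershootPct = "numeric",
    lateDelay = "numeric",
    plateauRampPct = "numeric",
    rampDelay = "numeric",
    phiDipPct = "numeric",
    recoveryTau = "numeric",
    earlySigma = "numeric",
    lateSigma = "numeric",
    leadIn = "numeric",
    leadWidth = "numeric",
    transitionWidth = "numeric"
  )
)

setValidity("ManeuverProfile", function(object) {
  msg <- character()
  if (object@release <= object@onset)
    msg <- c(msg, "overlapping events: release must come after onset")
  if (object@baselineGstar <= 0) msg <- c(msg, "baselineGstar must be positive")
  if (object@baselinePhi <= 0 || object@baselinePhi >= pi)
    msg <- c(msg, "baselinePhi must lie in (0, pi)")
  phiHeld <- object@baselinePhi * (1 + object@phiDipPct / 100)
  if (phiHeld <= 0 || phiHeld >= pi)
    msg <- c(msg, "phiDipPct drives the loss angle outside (0, pi)")
  if (object@recoveryTau <= 0) msg <- c(msg, "recoveryTau must be positive")
  if (object@earlySigma <= 0 || object@lateSigma <= 0)
    msg <- c(msg, "bump widths must be positive")
  if (length(msg)) msg else TRUE
})

#' Viscoelastic phantom
#'
#' A 2-D digital phantom: per-pixel complex shear modulus, an MR magnitude
#' template (brain-like tissue disc with low-magnitude CSF-like holes), the
#' driven source pixels (outer rim and hole interiors), and mass density.
#'
#' @slot gstarMap complex shear modulus per pixel, Pa (magnitude times
#'   `exp(1i*phi)`).
#' @slot magnitudeMap MR magnitude template in arbitrary scanner-like units
#'   (tissue about 50, CSF-like holes about 5).
#' @slot sourceMask logical; pixels with prescribed oscillatory displacement.
#' @slot holeMask logical; CSF-like hole pixels.
#' @slot tissueMask logical; pixels inside the tissue disc.
#' @slot density mass density in kg/m^3.
#' @slot voxelSize in-plane voxel size in metres.
#'
#' @seealso [brainPhantom()]
#' @export
setClass("ViscoelasticPhantom",
  representation(
    gstarMap = "matrix",
    magnitudeMap = "matrix",
    sourceMask = "matrix",
    holeMask = "matrix",
    tissueMask = "matrix",
    density = "numeric",
    voxelSize = "numeric"
  )
)

setValidity("ViscoelasticPhantom", function(object) {
  msg <- character()
  if (!is.complex(object@gstarMap)) msg <- c(msg, "gstarMap must be complex")
  else {
    if (any(Mod(object@gstarMap) <= 0)) msg <- c(msg, "|G*| must be positive everywhere")
    a <- Arg(object@gstarMap)
    if (any(a < 0 | a > pi / 2 + 1e-9))
      msg <- c(msg, "arg(G*) must lie in [0, pi/2] for a dissipative medium")
  }
  if (!identical(dim(object@gstarMap), dim(object@magnitudeMap)))
    msg <- c(msg, "gstarMap and magnitudeMap dimensions differ")
  if (object@density <= 0) msg <- c(msg, "density must be positive")
  if (length(msg)) msg else TRUE
})

#' Raw complex image series
#'
#' Ordered complex single-shot images with per-image timestamps and cyclic
#' motion-encoding component labels, plus the acquisition configuration and
#' the random seed that generated them (for simulated data).
#'
#' @slot images complex array (rows, columns, images).
#' @slot timestamps per-image acquisition times in seconds (`k * tr`).
#' @slot componentLabels integer in `0:(nComponents-1)`, cyclic.
#' @slot config the [AcquisitionConfig-class] of the scan.
#' @slot seed integer seed used for the noise draw (NA for external data).
#' @slot noiseSd complex-noise standard deviation per channel (NA if unknown).
#'
#' @export
setClass("RawImageSeries",
  representation(
    images = "array",
    timestamps = "numeric",
    componentLabels = "integer",
    config = "AcquisitionConfig",
    seed = "integer",
    noiseSd = "numeric"
  )
)

setValidity("RawImageSeries", function(object) {
  msg <- character()
  d <- dim(object@images)
  if (length(d) != 3L) msg <- c(msg, "images must be a 3-D array")
  n <- d[3L]
  if (length(object@timestamps) != n) msg <- c(msg, "one timestamp per image required")
  if (length(object@componentLabels) != n) msg <- c(msg, "one component label per image required")
  nc <- object@config@nComponents
  expected <- as.integer((seq_len(n) - 1L) %% nc)
  if (!identical(object@componentLabels, expected))
    msg <- c(msg, "component labels must follow the interleave cycle exactly")
  nExp <- imageCount(object@config@scanDuration, object@config@tr)
  if (n != nExp)
    msg <- c(msg, sprintf("series length %d != floor(scanDuration/tr) = %d", n, nExp))
  if (length(msg)) msg else TRUE
})

#' Unwrapped phase image series
#'
#' Per-image unwrapped phase after complex-domain Gaussian smoothing, with
#' the ordering, timestamps and component labels of the source series.
#'
#' @slot phase numeric array (rows, columns, images) in rad.
#' @slot timestamps,componentLabels,config as in [RawImageSeries-class].
#' @slot smoothingSigma Gaussian smoothing width applied upstream, in pixels.
#'
#' @export
setClass("PhaseImageSeries",
  representation(
    phase = "array",
    timestamps = "numeric",
    componentLabels = "integer",
    config = "AcquisitionConfig",
    smoothingSigma = "numeric"
  )
)

#' Spectral decomposition configuration
#'
#' Per-component sampling rate, bandpass width, and the aliased (apparent)
#' position plus spectral orientation of each vibration frequency in the
#' undersampled slow-time spectrum.
#'
#' @slot samplingRate per-component sampling rate in Hz
#'   (`1/(nComponents*tr)`).
#' @slot bandpassSigma Gaussian bandpass width in Hz.
#' @slot frequencies vibration frequencies in Hz.
#' @slot apparentFrequencies aliased positions in Hz, within (0, fs/2).
#' @slot reversed logical; TRUE where the aliased tone rotates with opposite
#'   sense and must be conjugated on reconstruction.
#'
#' @seealso [spectralConfig()], [aliasFrequency()]
#' @export
setClass("SpectralConfig",
  representation(
    samplingRate = "numeric",
    bandpassSigma = "numeric",
    frequencies = "numeric",
    apparentFrequencies = "numeric",
    reversed = "logical"
  )
)

setValidity("SpectralConfig", function(object) {
  msg <- character()
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  fa <- object@apparentFrequencies
  if (any(fa <= 0 | fa >= object@samplingRate / 2))
    msg <- c(msg, "apparent frequencies must lie strictly inside (0, fs/2)")
  if (length(msg)) msg else TRUE
})

#' Time-resolved decomposed wavefields
#'
#' Complex shear-displacement fields u[f, c](x, frame) per vibration frequency
#' f and encoding component c, on a common frame time axis with spacing
#' `nComponents * tr`.
#'
#' @slot fields list indexed `[[frequency]][[component]]`, each a complex
#'   array (rows, columns, frames).
#' @slot frameTimes frame timestamps in seconds (middle image of each
#'   interleave).
#' @slot frequencies vibration frequencies in Hz.
#' @slot spectral the [SpectralConfig-class] used (filter settings and
#'   conjugation flags: provenance).
#' @slot config the source [AcquisitionConfig-class].
#'
#' @export
setClass("DecomposedWavefield",
  representation(
    fields = "list",
    frameTimes = "numeric",
    frequencies = "numeric",
    spectral = "SpectralConfig",
    config = "AcquisitionConfig"
  )
)

setValidity("DecomposedWavefield", function(object) {
  msg <- character()
  if (length(object@fields) != length(object@frequencies))
    msg <- c(msg, "one field group per vibration frequency required")
  nF <- length(object@frameTimes)
  for (g in object@fields) for (u in g)
    if (dim(u)[3L] != nF) msg <- c(msg, "all fields must share the frame axis")
  if (length(msg)) unique(msg) else TRUE
})

#' Elastogram series
#'
#' Per-frame stiffness |G*| and loss-angle maps with a common time axis and a
#' per-frame validity mask (pixels with usable Laplacian support and non-zero
#' inversion denominators).
#'
#' @slot gstar numeric array (rows, columns, frames), Pa.
#' @slot phi numeric array (rows, columns, frames), rad.
#' @slot valid logical array (rows, columns, frames).
#' @slot frameTimes frame timestamps in seconds.
#' @slot scanDuration total scan duration in seconds (for margin trimming).
#' @slot settings list recording rho, spacing, stencil and frequencies used.
#'
#' @export
setClass("ElastogramSeries",
  representation(
    gstar = "array",
    phi = "array",
    valid = "array",
    frameTimes = "numeric",
    scanDuration = "numeric",
    settings = "list"
  )
)

setValidity("ElastogramSeries", function(object) {
  msg <- character()
  if (!identical(dim(object@gstar), dim(object@phi)) ||
      !identical(dim(object@gstar), dim(object@valid)))
    msg <- c(msg, "gstar, phi and valid must share dimensions")
  if (dim(object@gstar)[3L] != length(object@frameTimes))
    msg <- c(msg, "one frame time per map required")
  v <- object@valid
  if (any(object@gstar[v] <= 0)) msg <- c(msg, "|G*| must be positive inside the mask")
  ph <- object@phi[v]
  if (length(ph) && (min(ph) < -1e-12 || max(ph) > pi + 1e-12))
    msg <- c(msg, "phi must lie in [0, pi] inside the mask")
  if (length(msg)) msg else TRUE
})
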