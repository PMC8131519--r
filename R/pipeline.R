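#' Assemble a pipeline configuration
#'
#' A plain nested list mirroring the stage parameters, suitable for lossless
#' YAML round-tripping: acquisition timing/geometry, maneuver profile,
#' spectral decomposition, inversion, and analysis settings, plus the global
#' seed. Any subset of values can be overridden through `...` using the same
#' nesting, e.g. `pipelineConfig(acquisition = list(matrixSize = c(64, 64)))`.
#'
#' @param ... named sublists overriding defaults (merged recursively).
#' @return a list of class `"stroboMREConfig"`.
#' @export
pipelineConfig <- function(...) {
  defaults <- list(
    acquisition = list(
      tr = 0.062, nComponents = 3L,
      frequencies = c(30.03, 30.91, 31.8),
      nImages = 1458L,
      matrixSize = c(96L, 96L), voxelSize = c(0.002, 0.002, 0.005),
      megDuration = 0.0175, megAmplitude = 40,
      encodingSensitivity = 80000),
    profile = list(
      baselineGstar = 1370, baselinePhi = 0.800,
      onset = 30, release = 50,
      earlyOvershootPct = 6.7, earlyDelay = 2.4,
      lateOvershootPct = 7.4, lateDelay = 5.5,
      plateauRampPct = 2.5, phiDipPct = -2.1, recoveryTau = 8,
      rampDelay = 8),
    simulation = list(noiseSd = 1.8, u0 = 30e-6),
    spectral = list(bandpassSigma = 0.1),
    inversion = list(rho = 1000),
    analysis = list(
      margin = 5, magnitudeThreshold = 10, gstarThreshold = 950,
      roiMargin = 2L, baseline = c(2.5, 22.5),
      intervals = list(bsl = c(2.5, 22.5), esm = c(32.5, 47.5),
                       lrm = c(52.5, 57.5), rec = c(70, 80)),
      onsetSearchWindow = 10, releaseSearchWindow = 15),
    seed = 1L)
  override <- list(...)
  merge2 <- function(a, b) {
    for (nm in names(b))
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]])) merge2(a[[nm]], b[[nm]])
                 else b[[nm]]
    a
  }
  structure(merge2(defaults, override), class = "stroboMREConfig")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a list from [pipelineConfig()].
#' @param path YAML file path.
#' @return `readPipelineConfig`: the configuration list (revalidated through
#'   [pipelineConfig()]).
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- rapply(raw, unlist, how = "replace")
  do.call(pipelineConfig, raw)
}

## materialize S4 stage objects from the plain config list
.configObjects <- function(config) {
  a <- config$acquisition
  acq <- acquisitionConfig(
    tr = a$tr, nComponents = a$nComponents, frequencies = a$frequencies,
    scanDuration = a$nImages * a$tr, matrixSize = a$matrixSize,
    voxelSize = a$voxelSize, megDuration = a$megDuration,
    megAmplitude = a$megAmplitude, encodingSensitivity = a$encodingSensitivity)
  p <- config$profile
  prof <- maneuverProfile(
    baselineGstar = p$baselineGstar, baselinePhi = p$baselinePhi,
    onset = p$onset, release = p$release,
    earlyOvershootPct = p$earlyOvershootPct, earlyDelay = p$earlyDelay,
    lateOvershootPct = p$lateOvershootPct, lateDelay = p$lateDelay,
    plateauRampPct = p$plateauRampPct, rampDelay = p$rampDelay,
    phiDipPct = p$phiDipPct, recoveryTau = p$recoveryTau)
  list(acq = acq, prof = prof)
}

#' Run the full pipeline on a synthetic acquisition
#'
#' Executes simulate, preprocess, decompose, invert, trim, and analyze in
#' order, entirely determined by the configuration and the seed: identical
#' inputs give bit-identical outputs. The spectral configuration is
#' validated (aliased-frequency separation) before any heavy computation.
#'
#' @param config a list from [pipelineConfig()].
#' @param seed integer seed overriding `config$seed`.
#' @param outDir optional directory; when given, the resolved configuration,
#'   the elastogram NIfTI volumes and the CSV analysis tables are written
#'   there.
#' @param solver optional precomputed [wavefieldSeries()] provider for
#'   repeated noise realizations.
#' @param raw optional pre-simulated [RawImageSeries-class] (skips
#'   simulation; used for external data).
#' @param verbose print stage progress.
#' @return list with elements `raw`, `phase`, `wavefields`, `elastograms`
#'   (trimmed), `roi`, `timecourse`, `phases`, `peaks` and `summary`.
#' @export
runPipeline <- function(config = pipelineConfig(), seed = NULL,
                        outDir = NULL, solver = NULL, raw = NULL,
                        verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  obj <- .configObjects(config)
  acq <- obj$acq; prof <- obj$prof

  spec <- spectralConfig(acq, config$spectral$bandpassSigma)
  fa <- spec@apparentFrequencies
  if (length(fa) > 1L && min(dist(fa)) <= 2 * spec@bandpassSigma)
    stop("configured vibration frequencies collide in the aliased spectrum")

  polygon <- NULL
  if (is.null(raw)) {
    say("simulate: %d images at %d x %d px", nImages(acq),
        acq@matrixSize[1], acq@matrixSize[2])
    phantom <- brainPhantom(acq, gstar = prof@baselineGstar * exp(1i * prof@baselinePhi))
    if (is.null(solver))
      solver <- wavefieldSeries(phantom, acq, prof, u0 = config$simulation$u0)
    raw <- sampleAcquisition(solver, acq, phantom@magnitudeMap,
                             noiseSd = config$simulation$noiseSd,
                             seed = config$seed)
    # stand-in for the manually drawn parenchymal ROI
    polygon <- parenchymaPolygon(phantom, margin = config$analysis$roiMargin)
  }
  say("preprocess: smoothing + unwrapping")
  phase <- preprocessSeries(raw, sigma = 0.65)
  say("decompose: %d -> %d wave images", nFrames(raw), nFrames(raw) * length(acq@frequencies))
  wf <- decomposeSeries(phase, spec)
  say("invert: %d frames", nFrames(wf))
  es <- invertSeries(wf, rho = config$inversion$rho)
  est <- trimMargins(es, margin = config$analysis$margin)

  meanMag <- rowMeans(Mod(raw@images), dims = 2L)
  meanG <- rowMeans(est@gstar, dims = 2L, na.rm = TRUE)
  anyValid <- apply(est@valid, c(1, 2), any)
  roi <- makeROI(meanMag, meanG,
                 magnitudeThreshold = config$analysis$magnitudeThreshold,
                 gstarThreshold = config$analysis$gstarThreshold,
                 polygon = polygon, valid = anyValid)
  tc <- roiTimeCourse(est, roi, baseline = config$analysis$baseline,
                      raw = raw, wavefields = wf)
  phases <- phaseStatistics(tc, do.call(phaseIntervals, config$analysis$intervals))
  pkOn <- detectPeak(tc, prof@onset, config$analysis$onsetSearchWindow)
  pkRel <- detectPeak(tc, prof@release, config$analysis$releaseSearchWindow)
  phiEsm <- phases$mean_phi[phases$phase == "ESM"]
  phiBsl <- phases$mean_phi[phases$phase == "BSL"]
  peaks <- data.frame(
    event = c("onset", "release"),
    event_time_s = c(prof@onset, prof@release),
    peak_pa = c(pkOn$peak, pkRel$peak),
    pct = c(pkOn$pct, pkRel$pct),
    delay_s = c(pkOn$delay, pkRel$delay))
  summary <- list(
    n_images = nFrames(raw),
    n_wave_images = nWaveImages(wf),
    n_maps = nFrames(es),
    n_maps_trimmed = nFrames(est),
    window_s = diff(range(config$analysis$margin,
                          es@scanDuration - config$analysis$margin)),
    early_pct = pkOn$pct, early_delay_s = pkOn$delay,
    late_pct = pkRel$pct, late_delay_s = pkRel$delay,
    phi_dip_pct = 100 * (phiEsm - phiBsl) / phiBsl,
    bsl_gstar_pa = attr(tc, "bslGstar"),
    bsl_phi_rad = attr(tc, "bslPhi"),
    cv_gstar_pct = coefficientOfVariation(tc, config$analysis$baseline, "gstar_pa"),
    cv_phi_pct = coefficientOfVariation(tc, config$analysis$baseline, "phi_rad"),
    snr_db = mean(tc$snr_db, na.rm = TRUE),
    wsnr_db = mean(tc$wsnr_db, na.rm = TRUE))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writePipelineConfig(config, file.path(outDir, "config.yaml"))
    writeElastogramSeries(est, file.path(outDir, "elastograms"),
                          voxelSize = acq@voxelSize)
    writeTimeCourses(tc, phases, peaks, outDir)
    yaml::write_yaml(summary, file.path(outDir, "summary.yaml"))
  }
  list(raw = raw, phase = phase, wavefields = wf, elastograms = est,
       roi = roi, timecourse = tc, phases = phases, peaks = peaks,
       summary = summary)
}
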