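#' Create an acquisition configuration
#'
#' Defaults describe the triple-frequency stroboscopic protocol: TR 62 ms,
#' three interleaved Cartesian motion-encoding components, vibration
#' frequencies 30.03, 30.91 and 31.8 Hz, 1,458 images over 90.396 s on a
#' 96 x 96 matrix with 2 x 2 x 5 mm voxels, and a 17.5-ms single-cycle
#' motion-encoding gradient of 40 mT/m (fractional encoding, summarized by a
#' single phase-per-displacement sensitivity).
#'
#' A matched higher-frequency regimen (40.77, 41.67, 42.55 Hz) aliases to
#' nearly the same apparent frequencies and can be selected by passing those
#' `frequencies`.
#'
#' @param tr repetition time in seconds.
#' @param nComponents number of interleaved motion-encoding components.
#' @param frequencies vibration frequencies in Hz, strictly increasing.
#' @param scanDuration total scan time in seconds; the series length is
#'   `floor(scanDuration/tr)`.
#' @param matrixSize image matrix (rows, columns) in pixels.
#' @param voxelSize voxel size in metres (row, column, slice).
#' @param megDuration motion-encoding gradient duration in seconds.
#' @param megAmplitude motion-encoding gradient amplitude in mT/m.
#' @param encodingSensitivity motion-encoding sensitivity in rad per metre of
#'   displacement. The default is calibrated so that simulator defaults give
#'   a wave-displacement SNR near 36 dB (see the package vignette).
#' @param flipAngle,te recorded metadata (degrees, seconds).
#' @return an [AcquisitionConfig-class] object.
#' @examples
#' cfg <- acquisitionConfig()
#' nImages(cfg)            # 1458
#' frameRate(cfg)          # ~5.4 Hz
#' @export
acquisitionConfig <- function(tr = 0.062,
                              nComponents = 3L,
                              frequencies = c(30.03, 30.91, 31.8),
                              scanDuration = 1458 * tr,
                              matrixSize = c(96L, 96L),
                              voxelSize = c(0.002, 0.002, 0.005),
                              megDuration = 0.0175,
                              megAmplitude = 40,
                              encodingSensitivity = 80000,
                              flipAngle = 20,
                              te = 0.02) {
  new("AcquisitionConfig",
      tr = tr, nComponents = as.integer(nComponents),
      frequencies = as.numeric(frequencies), scanDuration = scanDuration,
      matrixSize = as.integer(rep_len(matrixSize, 2L)),
      voxelSize = as.numeric(voxelSize),
      megDuration = megDuration, megAmplitude = megAmplitude,
      encodingSensitivity = encodingSensitivity,
      flipAngle = flipAngle, te = te)
}

#' Number of single-shot images in a configured scan
#'
#' @param config an [AcquisitionConfig-class].
#' @return integer, `floor(scanDuration/tr)`.
#' @export
nImages <- function(config) imageCount(config@scanDuration, config@tr)

#' Elastogram frame interval and frame rate
#'
#' One viscoelasticity frame consumes `nComponents` consecutive images, so the
#' frame interval is `nComponents * tr` (186 ms for the defaults, about
#' 5.4 Hz).
#'
#' @param config an [AcquisitionConfig-class].
#' @return `frameInterval`: seconds per frame. `frameRate`: frames per second.
#' @export
frameInterval <- function(config) config@nComponents * config@tr

#' @rdname frameInterval
#' @export
frameRate <- function(config) 1 / frameInterval(config)

#' Per-image timestamps and component labels of a configured scan
#'
#' Image k (0-based) is acquired at `k * tr` and encodes component
#' `k %% nComponents`.
#'
#' @param config an [AcquisitionConfig-class].
#' @return `imageTimes`: numeric vector; `imageComponents`: integer vector.
#' @export
imageTimes <- function(config) (seq_len(nImages(config)) - 1L) * config@tr

#' @rdname imageTimes
#' @export
imageComponents <- function(config)
  as.integer((seq_len(nImages(config)) - 1L) %% config@nComponents)

#' Frame time axis of a configured scan
#'
#' Frame n (0-based) collapses images `nComponents*n + (0:(nComponents-1))`;
#' its timestamp is that of the middle image of the interleave.
#'
#' @param config an [AcquisitionConfig-class].
#' @return numeric vector of frame times in seconds.
#' @export
configFrameTimes <- function(config) {
  nFr <- nImages(config) %/% config@nComponents
  mid <- (config@nComponents - 1L) / 2
  ((seq_len(nFr) - 1L) * config@nComponents + mid) * config@tr
}

setMethod("show", "AcquisitionConfig", function(object) {
  cat("AcquisitionConfig\n")
  cat(sprintf("  TR %.1f ms, %d interleaved components, frame rate %.2f Hz\n",
              1000 * object@tr, object@nComponents, frameRate(object)))
  cat(sprintf("  vibration frequencies: %s Hz\n",
              paste(object@frequencies, collapse = ", ")))
  cat(sprintf("  %d images over %.3f s, matrix %d x %d, voxel %s mm\n",
              nImages(object), object@scanDuration,
              object@matrixSize[1], object@matrixSize[2],
              paste(1000 * object@voxelSize, collapse = " x ")))
  cat(sprintf("  encoding sensitivity %.0f rad/m (MEG %.1f ms, %.0f mT/m)\n",
              object@encodingSensitivity, 1000 * object@megDuration,
              object@megAmplitude))
})
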