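#' Aliased position of an undersampled tone
#'
#' A vibration at `fTrue` Hz sampled stroboscopically at `fs` Hz appears in
#' the slow-time spectrum at its aliased position. With `r = fTrue mod fs`:
#' if `r <= fs/2` the tone appears at `r` with preserved rotation sense;
#' otherwise it appears at `fs - r` with reversed sense, and its analytic
#' signal must be conjugated on reconstruction. Tones landing on a fold
#' point (a multiple of `fs/2`) are rejected.
#'
#' @param fTrue true vibration frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param tol rejection margin around fold points, Hz.
#' @return list with `apparent` (Hz) and `reversed` (logical).
#' @examples
#' aliasFrequency(30.03, 1/0.186)  # ~2.23 Hz, reversed
#' @export
aliasFrequency <- function(fTrue, fs, tol = 1e-6) {
  stopifnot(fs > 0, fTrue > 0)
  r <- fTrue %% fs
  dFold <- min(abs(r), abs(r - fs / 2), abs(r - fs))
  if (dFold < tol)
    stop(sprintf("frequency %.4f Hz lands on a spectral fold point (fs = %.4f Hz, fs/2 = %.4f Hz)",
                 fTrue, fs, fs / 2))
  if (r <= fs / 2) list(apparent = r, reversed = FALSE)
  else list(apparent = fs - r, reversed = TRUE)
}

#' Build a spectral decomposition configuration
#'
#' Computes the per-component sampling rate `1/(nComponents * tr)` and the
#' aliased position and orientation of each vibration frequency, and records
#' the Gaussian bandpass width. Warns if two apparent frequencies are closer
#' than four bandpass widths.
#'
#' @param config an [AcquisitionConfig-class].
#' @param bandpassSigma Gaussian bandpass width in Hz.
#' @return a [SpectralConfig-class].
#' @export
spectralConfig <- function(config, bandpassSigma = 0.1) {
  fs <- 1 / (config@nComponents * config@tr)
  ali <- lapply(config@frequencies, aliasFrequency, fs = fs)
  fa <- vapply(ali, `[[`, 0, "apparent")
  rev <- vapply(ali, `[[`, TRUE, "reversed")
  if (length(fa) > 1L) {
    sep <- min(dist(fa))
    if (sep <= 4 * bandpassSigma)
      warning(sprintf("apparent frequencies separated by only %.3f Hz (< 4 sigma = %.3f Hz)",
                      sep, 4 * bandpassSigma))
  }
  new("SpectralConfig", samplingRate = fs, bandpassSigma = bandpassSigma,
      frequencies = config@frequencies, apparentFrequencies = fa,
      reversed = rev)
}

#' Decompose a phase series into time-resolved wavefields
#'
#' Per pixel and per motion-encoding component, the unwrapped phase time
#' series is Fourier transformed over the full series; the positive-frequency
#' half-spectrum is multiplied by `2 * exp(-(f - fApparent)^2 / (2 sigma^2))`
#' and the negative half zeroed (one-sided Gaussian bandpass, i.e. an inverse
#' Hilbert transformation); the inverse FFT yields the analytic signal, which
#' is demodulated by `exp(-1i * 2 pi fApparent t)` using the true per-image
#' timestamps and conjugated where the alias is orientation-reversed. The
#' factor 2 preserves tone amplitude. Each vibration frequency yields one
#' complex field per component and frame, so the output holds
#' `nFrequencies x` (input series length) images.
#'
#' @param series a [PhaseImageSeries-class].
#' @param spectral a [SpectralConfig-class]; defaults to
#'   `spectralConfig(seriesConfig(series))`.
#' @return a [DecomposedWavefield-class].
#' @export
decomposeSeries <- function(series, spectral = NULL) {
  config <- series@config
  if (is.null(spectral)) spectral <- spectralConfig(config)
  fa <- spectral@apparentFrequencies
  if (length(fa) > 1L) {
    dd <- as.matrix(dist(fa))
    diag(dd) <- Inf
    bad <- which(dd <= 2 * spectral@bandpassSigma, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("apparent frequencies collide: %.3f Hz (%.2f Hz) and %.3f Hz (%.2f Hz) separated by <= 2 sigma",
                   fa[bad[1, 1]], spectral@frequencies[bad[1, 1]],
                   fa[bad[1, 2]], spectral@frequencies[bad[1, 2]]))
  }
  nc <- config@nComponents
  phase <- series@phase
  d <- dim(phase)
  nImg <- d[3]
  nFr <- nImg %/% nc
  if (nImg %% nc != 0L) {
    warning(sprintf("series length %d not divisible by %d components; truncating trailing partial interleave",
                    nImg, nc))
    phase <- phase[, , seq_len(nFr * nc), drop = FALSE]
    nImg <- nFr * nc
  }
  npix <- d[1] * d[2]
  sig <- spectral@bandpassSigma
  fsamp <- spectral@samplingRate

  fields <- lapply(seq_along(fa), function(fi) vector("list", nc))
  for (ci in seq_len(nc)) {
    sel <- which(series@componentLabels[seq_len(nImg)] == ci - 1L)
    tn <- series@timestamps[sel]
    X <- t(matrix(phase[, , sel], npix, nFr))   # frames x pixels
    FX <- mvfft(X)
    fr <- (0:(nFr - 1)) / (nFr / fsamp)
    for (fi in seq_along(fa)) {
      W <- numeric(nFr)
      pos <- fr > 0 & fr <= fsamp / 2
      W[pos] <- 2 * exp(-(fr[pos] - fa[fi])^2 / (2 * sig^2))
      A <- mvfft(FX * W, inverse = TRUE) / nFr
      A <- A * exp(-2i * pi * fa[fi] * tn)
      if (spectral@reversed[fi]) A <- Conj(A)
      fields[[fi]][[ci]] <- array(t(A), dim = c(d[1], d[2], nFr))
    }
  }
  mid <- (nc - 1L) / 2
  fTimes <- ((seq_len(nFr) - 1L) * nc + mid) * config@tr
  new("DecomposedWavefield", fields = fields, frameTimes = fTimes,
      frequencies = spectral@frequencies, spectral = spectral,
      config = config)
}

#' Total number of decomposed wave images
#'
#' Fan-out accounting: each of the input phase images contributes one
#' decomposed image per vibration frequency.
#'
#' @param x a [DecomposedWavefield-class].
#' @return integer count (`nFrequencies * nComponents * nFrames`).
#' @export
nWaveImages <- function(x) {
  length(x@frequencies) * length(x@fields[[1]]) * length(x@frameTimes)
}

setMethod("nFrames", "DecomposedWavefield", function(x) length(x@frameTimes))
setMethod("frameTimes", "DecomposedWavefield", function(x) x@frameTimes)
setMethod("imageData", "DecomposedWavefield", function(x) x@fields)
setMethod("seriesConfig", "DecomposedWavefield", function(x) x@config)

setMethod("show", "DecomposedWavefield", function(object) {
  d <- dim(object@fields[[1]][[1]])
  cat(sprintf("DecomposedWavefield: %d frequencies x %d components x %d frames (%d wave images)\n",
              length(object@frequencies), length(object@fields[[1]]),
              length(object@frameTimes), nWaveImages(object)))
  cat(sprintf("  apparent frequencies: %s Hz%s (fs = %.3f Hz, bandpass sigma %.2f Hz)\n",
              paste(sprintf("%.3f", object@spectral@apparentFrequencies), collapse = ", "),
              ifelse(any(object@spectral@reversed), " (reversed aliases conjugated)", ""),
              object@spectral@samplingRate, object@spectral@bandpassSigma))
})
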