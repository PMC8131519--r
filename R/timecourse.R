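#' Discard transient margins of an elastogram series
#'
#' The one-sided spectral filtering of the decomposition assumes periodic
#' boundaries, so the first and last seconds of the map series carry
#' transients. Frames with `t < margin` or `t > scanDuration - margin` are
#' removed; the remaining observation window spans `scanDuration - 2*margin`
#' (80 s for the default 90-s protocol with 5-s margins).
#'
#' @param series an [ElastogramSeries-class].
#' @param margin seconds to discard at each end.
#' @return the trimmed [ElastogramSeries-class].
#' @export
trimMargins <- function(series, margin = 5) {
  stopifnot(margin >= 0)
  dur <- series@scanDuration
  if (2 * margin >= dur) stop("margin too large for the series duration")
  keep <- series@frameTimes >= margin & series@frameTimes <= dur - margin
  new("ElastogramSeries",
      gstar = series@gstar[, , keep, drop = FALSE],
      phi = series@phi[, , keep, drop = FALSE],
      valid = series@valid[, , keep, drop = FALSE],
      frameTimes = series@frameTimes[keep],
      scanDuration = dur, settings = series@settings)
}

#' Threshold-refined region of interest
#'
#' Builds the analysis mask: an optional drawn region intersected with
#' pixels whose time-averaged MRE signal magnitude exceeds
#' `magnitudeThreshold` (default 10, removing CSF-filled ventricles and
#' larger sulci) and whose time-averaged stiffness exceeds `gstarThreshold`
#' (default 950 Pa), restricted to inversion-valid pixels.
#'
#' @param meanMagnitude time-averaged magnitude image.
#' @param meanGstar time-averaged stiffness map (Pa); NA treated as below
#'   threshold.
#' @param magnitudeThreshold magnitude cutoff (scanner units).
#' @param gstarThreshold stiffness cutoff in Pa.
#' @param polygon optional logical matrix of the drawn region.
#' @param valid optional logical matrix of inversion-valid pixels.
#' @return logical matrix; errors if empty.
#' @export
makeROI <- function(meanMagnitude, meanGstar,
                    magnitudeThreshold = 10, gstarThreshold = 950,
                    polygon = NULL, valid = NULL) {
  mask <- meanMagnitude > magnitudeThreshold
  g <- meanGstar
  g[is.na(g)] <- -Inf
  mask <- mask & (g > gstarThreshold)
  if (!is.null(polygon)) mask <- mask & polygon
  if (!is.null(valid)) mask <- mask & valid
  if (!any(mask)) stop("empty ROI after thresholding")
  mask
}

#' Named maneuver phase intervals
#'
#' Default analysis phases of the maneuver protocol: baseline (BSL)
#' 2.5-22.5 s, established maneuver (ESM) 32.5-47.5 s, late response
#' maneuver (LRM) 52.5-57.5 s and recovery (REC) 70-80 s. Transition
#' periods between phases are deliberately excluded.
#'
#' @param bsl,esm,lrm,rec numeric `c(start, end)` in seconds.
#' @return named list of intervals; errors if any two overlap.
#' @export
phaseIntervals <- function(bsl = c(2.5, 22.5), esm = c(32.5, 47.5),
                           lrm = c(52.5, 57.5), rec = c(70, 80)) {
  iv <- list(BSL = bsl, ESM = esm, LRM = lrm, REC = rec)
  ord <- iv[order(vapply(iv, `[`, 0, 1))]
  for (i in seq_len(length(ord) - 1L))
    if (ord[[i]][2] > ord[[i + 1L]][1])
      stop(sprintf("phase intervals %s and %s overlap",
                   names(ord)[i], names(ord)[i + 1L]))
  iv
}

#' ROI-mean parameter time course
#'
#' Averages |G*| and phi over the ROI (per-frame valid pixels only) and
#' forms difference series relative to the baseline-interval mean:
#' `dgstar = gstar(t) - mean(gstar over baseline)`, correspondingly for
#' phi. Optional per-frame SNR and wave-SNR diagnostics are attached when a
#' raw series / decomposed wavefield is supplied.
#'
#' @param series an [ElastogramSeries-class] (usually margin-trimmed).
#' @param roi logical ROI matrix from [makeROI()].
#' @param baseline baseline interval `c(start, end)` in seconds; frames of
#'   the series inside it define the baseline means.
#' @param raw optional [RawImageSeries-class] for magnitude SNR.
#' @param wavefields optional [DecomposedWavefield-class] for wave SNR.
#' @return data.frame with columns `time_s`, `gstar_pa`, `phi_rad`,
#'   `dgstar_pa`, `dphi_rad`, `snr_db`, `wsnr_db`, with baseline means in
#'   attributes `bslGstar` and `bslPhi`.
#' @export
roiTimeCourse <- function(series, roi, baseline = c(2.5, 22.5),
                          raw = NULL, wavefields = NULL) {
  nFr <- length(series@frameTimes)
  gs <- numeric(nFr); ph <- numeric(nFr)
  for (k in seq_len(nFr)) {
    sel <- roi & series@valid[, , k]
    gs[k] <- mean(series@gstar[, , k][sel])
    ph[k] <- mean(series@phi[, , k][sel])
  }
  inBsl <- series@frameTimes >= baseline[1] & series@frameTimes <= baseline[2]
  if (!any(inBsl)) stop("no frames inside the baseline interval")
  bslG <- mean(gs[inBsl]); bslP <- mean(ph[inBsl])

  snr <- rep(NA_real_, nFr); wsnr <- rep(NA_real_, nFr)
  if (!is.null(raw)) {
    mag <- Mod(raw@images)
    meanMag <- rowMeans(mag, dims = 2L)
    bg <- meanMag < 10
    bgMat <- matrix(mag, prod(dim(mag)[1:2]))[bg, , drop = FALSE]
    noise <- sd(bgMat - rowMeans(bgMat))
    nc <- raw@config@nComponents
    tr <- raw@config@tr
    for (k in seq_len(nFr)) {
      # frame timestamps are the middle image of each interleave
      n0 <- round((series@frameTimes[k] / tr - (nc - 1) / 2) / nc)
      imgIdx <- n0 * nc + seq_len(nc)
      snr[k] <- 20 * log10(mean(mag[, , imgIdx][roi]) / noise)
    }
  }
  if (!is.null(wavefields)) {
    kmap <- match(round(series@frameTimes, 9), round(wavefields@frameTimes, 9))
    for (k in seq_len(nFr)) {
      frame <- unlist(lapply(wavefields@fields, function(g)
        lapply(g, function(u) u[, , kmap[k]])), recursive = FALSE)
      wsnr[k] <- suppressWarnings(wsnrDb(frame, roi))
    }
  }
  out <- data.frame(time_s = series@frameTimes, gstar_pa = gs, phi_rad = ph,
                    dgstar_pa = gs - bslG, dphi_rad = ph - bslP,
                    snr_db = snr, wsnr_db = wsnr)
  attr(out, "bslGstar") <- bslG
  attr(out, "bslPhi") <- bslP
  out
}

#' Per-phase interval statistics
#'
#' Temporal mean and standard deviation of the ROI-mean |G*| and phi over
#' each named phase interval, plus their coefficients of variation.
#'
#' @param tc a time course from [roiTimeCourse()].
#' @param intervals named list from [phaseIntervals()].
#' @return data.frame with one row per phase.
#' @export
phaseStatistics <- function(tc, intervals = phaseIntervals()) {
  rows <- lapply(names(intervals), function(nm) {
    iv <- intervals[[nm]]
    sel <- tc$time_s >= iv[1] & tc$time_s <= iv[2]
    if (sum(sel) < 2L) stop(sprintf("phase interval %s contains < 2 frames", nm))
    g <- tc$gstar_pa[sel]; p <- tc$phi_rad[sel]
    data.frame(phase = nm, t_start = iv[1], t_end = iv[2], n_frames = sum(sel),
               mean_gstar = mean(g), sd_gstar = sd(g),
               mean_phi = mean(p), sd_phi = sd(p),
               cv_gstar_pct = 100 * sd(g) / mean(g),
               cv_phi_pct = 100 * sd(p) / mean(p))
  })
  do.call(rbind, rows)
}

#' Detect an overshoot peak and its delay
#'
#' Scans the baseline-difference series in the window
#' `(eventTime, eventTime + searchWindow]` for its maximum; reports the peak
#' value, the delay of the peak after the event, and the peak as a
#' percentage of the baseline mean.
#'
#' @param tc a time course from [roiTimeCourse()].
#' @param eventTime event (maneuver onset or release) time in seconds.
#' @param searchWindow window length after the event in seconds.
#' @param variable difference column to scan (default `dgstar_pa`).
#' @return list with `peak` (series units), `pct` (percent of baseline
#'   mean) and `delay` (s).
#' @export
detectPeak <- function(tc, eventTime, searchWindow = 10,
                       variable = "dgstar_pa") {
  sel <- tc$time_s > eventTime & tc$time_s <= eventTime + searchWindow
  if (!any(sel)) stop("empty peak search window")
  y <- tc[[variable]][sel]; t <- tc$time_s[sel]
  i <- which.max(y)
  bsl <- if (variable == "dphi_rad") attr(tc, "bslPhi") else attr(tc, "bslGstar")
  list(peak = y[i], pct = 100 * y[i] / bsl, delay = t[i] - eventTime)
}

#' Coefficient of variation over an interval
#'
#' `100 * sd / mean` of a time-course column over the frames inside the
#' interval; the baseline-phase CV of |G*| and phi is the stability metric
#' used to compare multifrequency and single-frequency inversion.
#'
#' @param tc a time course from [roiTimeCourse()].
#' @param interval `c(start, end)` in seconds.
#' @param variable column name.
#' @return CV in percent.
#' @export
coefficientOfVariation <- function(tc, interval = c(2.5, 22.5),
                                   variable = "gstar_pa") {
  sel <- tc$time_s >= interval[1] & tc$time_s <= interval[2]
  x <- tc[[variable]][sel]
  m <- mean(x)
  if (m == 0) stop("interval mean is zero; CV undefined")
  100 * sd(x) / m
}

#' Blind noise estimate of a wave image
#'
#' Estimates the noise standard deviation of a (complex) wave image from the
#' median absolute value of its finest-level diagonal wavelet coefficients
#' (Daubechies-4 by default), scaled by 1/0.6745. Shear waves and noise
#' separate well in the wavelet domain: wave energy lives at coarse scales
#' while white noise spreads evenly, so the finest diagonal subband is
#' essentially noise. Real and imaginary channels are estimated separately
#' and combined, returning the standard deviation of the complex noise
#' (`sqrt(E|n|^2)`).
#'
#' @param u complex (or numeric) matrix.
#' @param roi optional logical mask; coefficients are kept where the
#'   corresponding 2x2 pixel block lies inside the mask.
#' @param wavelet `"d4"` (default) or `"haar"`.
#' @return estimated complex-noise standard deviation.
#' @export
waveletNoiseSd <- function(u, roi = NULL, wavelet = c("d4", "haar")) {
  wavelet <- match.arg(wavelet)
  est1 <- function(x) {
    cc <- waveletDiagonal(x, wavelet)
    if (!is.null(roi)) {
      rsel <- roi[seq(1L, 2L * nrow(cc), by = 2L), seq(1L, 2L * ncol(cc), by = 2L)]
      cc <- cc[rsel]
    }
    median(abs(cc)) / 0.6745
  }
  if (is.complex(u)) sqrt(est1(Re(u))^2 + est1(Im(u))^2)
  else sqrt(2) * est1(u)
}

#' Wave-displacement signal-to-noise ratio
#'
#' `WSNR = 20 log10(RMS field amplitude / noise SD)` in dB, with the noise
#' standard deviation estimated blindly per wave image by
#' [waveletNoiseSd()] and pooled (root mean square) over the supplied
#' images. A pure-noise field scores about 0 dB since the RMS of complex
#' Gaussian noise equals its complex standard deviation. A zero noise
#' estimate returns `Inf` with a warning.
#'
#' @param fields a complex matrix, or a list of complex matrices (e.g. the
#'   nine wave images of one frame).
#' @param roi optional logical mask restricting both RMS and noise
#'   estimation.
#' @param wavelet passed to [waveletNoiseSd()].
#' @return WSNR in dB.
#' @export
wsnrDb <- function(fields, roi = NULL, wavelet = "d4") {
  if (!is.list(fields)) fields <- list(fields)
  if (length(fields) == 0L) stop("empty field set")
  rms2 <- mean(vapply(fields, function(u) {
    a2 <- Mod(u)^2
    if (!is.null(roi)) mean(a2[roi]) else mean(a2)
  }, 0))
  sig2 <- mean(vapply(fields, function(u) waveletNoiseSd(u, roi, wavelet)^2, 0))
  if (sig2 <= rms2 * 1e-20) {
    warning("zero blind-noise estimate; WSNR is unbounded")
    return(Inf)
  }
  10 * log10(rms2 / sig2)
}

#' Magnitude signal-to-noise ratio
#'
#' `SNR = 20 log10(mean ROI magnitude / background noise SD)` in dB, the
#' background being pixels outside the magnitude support (time-averaged
#' magnitude below `backgroundThreshold`, the same scanner-unit cutoff that
#' defines the analysis ROI). For a magnitude series the noise SD is the
#' temporal fluctuation of the background magnitudes (per-pixel temporal
#' means removed, pooled); for a single image it is the plain SD over the
#' background pixels. Doubling the signal magnitude adds about 6.02 dB.
#'
#' @param magnitude magnitude image (matrix) or series (3-D array).
#' @param roi logical ROI matrix.
#' @param background logical matrix of background pixels; by default pixels
#'   with time-averaged magnitude below `backgroundThreshold`.
#' @param backgroundThreshold magnitude-support cutoff (scanner units).
#' @return SNR in dB (scalar; magnitude series are pooled over time).
#' @export
snrDb <- function(magnitude, roi, background = NULL,
                  backgroundThreshold = 10) {
  if (!any(roi)) stop("empty ROI")
  series <- length(dim(magnitude)) == 3L
  meanMag <- if (series) rowMeans(magnitude, dims = 2L) else magnitude
  if (is.null(background)) background <- meanMag < backgroundThreshold
  if (!any(background)) stop("no background pixels outside the magnitude support")
  noise <- if (series) {
    bgMat <- matrix(magnitude, prod(dim(magnitude)[1:2]))[background, , drop = FALSE]
    sd(bgMat - rowMeans(bgMat))
  } else sd(magnitude[background])
  20 * log10(mean(meanMag[roi]) / noise)
}
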