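#' Five-point discrete Laplacian
#'
#' `(u_E + u_W + u_N + u_S - 4 u_C) / h^2` applied to a 2-D field or to
#' every slice of a 3-D array. The outermost one-pixel border has no full
#' stencil support and is set to zero and marked invalid in the attached
#' `"validMask"` attribute.
#'
#' On a discrete plane wave `exp(1i k . x)` the operator returns
#' `-kEff^2 * u` with `kEff^2 = sum_d (2 - 2 cos(k_d h)) / h^2`, the
#' closed-form discrete dispersion relation.
#'
#' @param field complex or numeric matrix, or 3-D array.
#' @param spacing grid spacing h in metres.
#' @return array of the same shape with attribute `validMask` (logical
#'   matrix, FALSE on the border).
#' @export
laplacianField <- function(field, spacing) {
  stopifnot(spacing > 0)
  d <- dim(field)
  ny <- d[1]; nx <- d[2]
  out <- array(if (is.complex(field)) 0i else 0, dim = d)
  i <- 2:(ny - 1); j <- 2:(nx - 1)
  if (length(d) == 2L) {
    out[i, j] <- (field[i - 1, j] + field[i + 1, j] +
                  field[i, j - 1] + field[i, j + 1] - 4 * field[i, j]) / spacing^2
  } else {
    out[i, j, ] <- (field[i - 1, j, , drop = FALSE] + field[i + 1, j, , drop = FALSE] +
                    field[i, j - 1, , drop = FALSE] + field[i, j + 1, , drop = FALSE] -
                    4 * field[i, j, , drop = FALSE]) / spacing^2
  }
  valid <- matrix(FALSE, ny, nx); valid[i, j] <- TRUE
  attr(out, "validMask") <- valid
  out
}

#' Multifrequency dual elasto-visco (MDEV) inversion of one frame
#'
#' Pools the wave images of all (frequency, component) pairs of one frame
#' into a stiffness map and a loss-angle map by the amplitude-weighted
#' algebraic Helmholtz estimator:
#' \deqn{|G^*|(x) = \rho \frac{\sum_{f,c} \omega_f^2 |u_{f,c}(x)|}
#'                           {\sum_{f,c} |\Delta u_{f,c}(x)|}}
#' \deqn{\varphi(x) = \arccos\left[- \frac{\sum_{f,c}
#'   Re(\Delta u_{f,c}(x) \overline{u_{f,c}(x)})}
#'   {\sum_{f,c} |\Delta u_{f,c}(x)| |u_{f,c}(x)|}\right]}
#' with the five-point Laplacian, the arccos argument clipped to [-1, 1].
#' Both maps are invariant to any per-pair complex rescaling of the fields,
#' so the motion-encoding sensitivity cancels. Pixels without stencil
#' support or with a zero denominator are masked invalid.
#'
#' @param fields list of complex matrices (the frame's wave images), all the
#'   same size.
#' @param frequencies vibration frequency in Hz of each field (recycled if a
#'   single value is given).
#' @param rho density in kg/m^3.
#' @param spacing pixel spacing in metres.
#' @return list with `gstar` (Pa), `phi` (rad) and logical `valid`.
#' @examples
#' g <- 1370 * exp(0.8i)
#' u <- planeWaveField(g, 30.03, c(0, 1), 48, 0.002)
#' m <- mdevInvert(list(u), 30.03, 1000, 0.002)
#' median(m$gstar[m$valid])   # close to 1370
#' @export
mdevInvert <- function(fields, frequencies, rho = 1000, spacing = 0.002) {
  if (length(fields) == 0L) stop("empty field set")
  d <- dim(fields[[1]])
  if (!all(vapply(fields, function(u) identical(dim(u), d), TRUE)))
    stop("mismatched field shapes")
  frequencies <- rep_len(frequencies, length(fields))
  num <- matrix(0, d[1], d[2]); den <- matrix(0, d[1], d[2])
  cross <- matrix(0, d[1], d[2]); wnorm <- matrix(0, d[1], d[2])
  for (i in seq_along(fields)) {
    u <- fields[[i]]
    lap <- laplacianField(u, spacing)
    om2 <- (2 * pi * frequencies[i])^2
    au <- Mod(u); al <- Mod(lap)
    num <- num + om2 * au
    den <- den + al
    cross <- cross + Re(lap * Conj(u))
    wnorm <- wnorm + al * au
  }
  valid <- attr(laplacianField(fields[[1]], spacing), "validMask") &
    den > 0 & wnorm > 0
  gstar <- matrix(NA_real_, d[1], d[2])
  phi <- matrix(NA_real_, d[1], d[2])
  gstar[valid] <- rho * num[valid] / den[valid]
  phi[valid] <- acos(pmin(pmax(-cross[valid] / wnorm[valid], -1), 1))
  list(gstar = gstar, phi = phi, valid = valid)
}

#' Single-frequency inversion of one frame
#'
#' [mdevInvert()] restricted to the wave images of a single vibration
#' frequency; used to contrast the temporal stability of multifrequency
#' pooling against single-frequency direct inversion.
#'
#' @param fields list of complex matrices (the frame's components at one
#'   frequency).
#' @param frequency the vibration frequency in Hz.
#' @param rho density in kg/m^3.
#' @param spacing pixel spacing in metres.
#' @return as [mdevInvert()].
#' @export
singleFreqInvert <- function(fields, frequency, rho = 1000, spacing = 0.002) {
  stopifnot(length(frequency) == 1L)
  mdevInvert(fields, frequency, rho, spacing)
}

#' Invert a decomposed wavefield series
#'
#' Applies the MDEV inversion frame by frame: each frame consumes exactly
#' `nFrequencies x nComponents` wave images (nine for the default protocol)
#' and yields one stiffness and one loss-angle map, so a 1,458-image
#' acquisition decomposed into 4,374 wave images gives 486 map pairs at the
#' frame rate `1/(nComponents * tr)`.
#'
#' @param wavefields a [DecomposedWavefield-class].
#' @param rho density in kg/m^3.
#' @param spacing pixel spacing in metres; defaults to the configured
#'   in-plane voxel size.
#' @param useFrequencies indices of vibration frequencies to pool (default
#'   all; a single index gives the single-frequency variant).
#' @return an [ElastogramSeries-class].
#' @export
invertSeries <- function(wavefields, rho = 1000, spacing = NULL,
                         useFrequencies = NULL) {
  config <- wavefields@config
  if (is.null(spacing)) spacing <- config@voxelSize[1]
  fsel <- if (is.null(useFrequencies)) seq_along(wavefields@frequencies)
          else useFrequencies
  nFr <- length(wavefields@frameTimes)
  d <- dim(wavefields@fields[[1]][[1]])[1:2]
  h2 <- spacing^2

  num <- array(0, c(d, nFr)); den <- array(0, c(d, nFr))
  cross <- array(0, c(d, nFr)); wnorm <- array(0, c(d, nFr))
  for (fi in fsel) {
    om2 <- (2 * pi * wavefields@frequencies[fi])^2
    for (u in wavefields@fields[[fi]]) {
      lap <- laplacianField(u, spacing)
      au <- Mod(u); al <- Mod(lap)
      num <- num + om2 * au
      den <- den + al
      cross <- cross + Re(lap * Conj(u))
      wnorm <- wnorm + al * au
    }
  }
  interior <- array(FALSE, c(d, nFr))
  interior[2:(d[1] - 1), 2:(d[2] - 1), ] <- TRUE
  valid <- interior & den > 0 & wnorm > 0
  gstar <- array(NA_real_, c(d, nFr)); phi <- array(NA_real_, c(d, nFr))
  gstar[valid] <- rho * num[valid] / den[valid]
  phi[valid] <- acos(pmin(pmax(-cross[valid] / wnorm[valid], -1), 1))
  new("ElastogramSeries", gstar = gstar, phi = phi, valid = valid,
      frameTimes = wavefields@frameTimes,
      scanDuration = config@scanDuration,
      settings = list(rho = rho, spacing = spacing, stencil = "5-point",
                      frequencies = wavefields@frequencies[fsel],
                      nComponents = length(wavefields@fields[[1]])))
}

setMethod("nFrames", "ElastogramSeries", function(x) length(x@frameTimes))
setMethod("frameTimes", "ElastogramSeries", function(x) x@frameTimes)
setMethod("gstarMaps", "ElastogramSeries", function(x) x@gstar)
setMethod("phiMaps", "ElastogramSeries", function(x) x@phi)
setMethod("validityMask", "ElastogramSeries", function(x) x@valid)

setMethod("show", "ElastogramSeries", function(object) {
  d <- dim(object@gstar)
  cat(sprintf("ElastogramSeries: %d frames of %d x %d |G*| and phi maps\n",
              d[3], d[1], d[2]))
  v <- object@valid
  cat(sprintf("  frame times %.3f-%.3f s; |G*| median %.0f Pa, phi median %.3f rad (frequencies %s Hz)\n",
              min(object@frameTimes), max(object@frameTimes),
              median(object@gstar[v]), median(object@phi[v]),
              paste(object@settings$frequencies, collapse = ", ")))
})
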