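#' Analytic plane shear wave on a grid
#'
#' Evaluates the exact damped plane wave `u(x) = u0 * exp(1i * k * (d . x))`
#' with complex wavenumber `k = omega * sqrt(rho / gstar)` (principal branch)
#' on a regular grid. For a lossy medium (`Arg(gstar) > 0`) the amplitude
#' decays along the propagation direction; for a purely elastic medium the
#' magnitude is constant. Used as the closed-form oracle for the Helmholtz
#' solver and the MDEV inversion.
#'
#' @param gstar complex shear modulus in Pa.
#' @param frequency vibration frequency in Hz.
#' @param direction unit vector (row, column components) of propagation.
#' @param n grid size (rows, columns) or a single integer.
#' @param spacing grid spacing in metres.
#' @param rho density in kg/m^3.
#' @param u0 complex amplitude (metres).
#' @return complex matrix of displacements.
#' @examples
#' u <- planeWaveField(1370 * exp(0.8i), 30.03, c(0, 1), 64, 0.002)
#' @export
planeWaveField <- function(gstar, frequency, direction, n, spacing,
                           rho = 1000, u0 = 1) {
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-8)
    stop("direction must be a unit vector")
  n <- rep_len(as.integer(n), 2L)
  k <- shearWavenumber(gstar, frequency, rho)
  y <- (seq_len(n[1]) - 1L) * spacing
  x <- (seq_len(n[2]) - 1L) * spacing
  phase <- outer(direction[1] * y, direction[2] * x, "+")
  u0 * exp(1i * k * phase)
}

#' Complex shear wavenumber
#'
#' `k = omega * sqrt(rho / gstar)` on the principal square-root branch, so
#' `Im(k) <= 0` for a dissipative medium and the wave
#' `exp(1i * k * x)` decays opposite to its propagation direction at rate
#' `|k| * sin(Arg(gstar)/2)` per metre.
#'
#' @param gstar complex shear modulus in Pa.
#' @param frequency vibration frequency in Hz.
#' @param rho density in kg/m^3.
#' @return complex wavenumber in rad/m.
#' @export
shearWavenumber <- function(gstar, frequency, rho = 1000)
  2 * pi * frequency * sqrt(as.complex(rho / gstar))

#' Solve the heterogeneous 2-D Helmholtz equation on a phantom
#'
#' Solves `gstar(x) * Lap(u) + rho * omega^2 * u = 0` with a five-point
#' finite-difference Laplacian over all non-source pixels, with prescribed
#' oscillatory Dirichlet values on the phantom's source pixels (outer rim and
#' hole interiors). The complex sparse system is solved in its equivalent
#' 2N-dimensional real form with a sparse LU factorization; the same
#' factorization serves multiple boundary patterns (right-hand sides) at
#' once.
#'
#' The grid must resolve the shear wavelength: the solver stops if the
#' minimum wavelength over the phantom falls below 8 pixels.
#'
#' @param phantom a [ViscoelasticPhantom-class].
#' @param frequency vibration frequency in Hz.
#' @param sources a complex matrix of prescribed displacements (read at the
#'   phantom's source pixels), or a list of such matrices for several
#'   independent boundary patterns; see [componentSources()].
#' @param gstarScale optional complex scalar multiplying the phantom's
#'   modulus map (used for quasi-static maneuver modulation).
#' @return a complex displacement matrix, or a list of them (one per source
#'   pattern).
#' @seealso [planeWaveField()] for the homogeneous-medium oracle.
#' @export
solveWavefield <- function(phantom, frequency, sources, gstarScale = 1 + 0i) {
  g <- phantom@gstarMap * gstarScale
  h <- phantom@voxelSize
  rho <- phantom@density
  om <- 2 * pi * frequency

  lambdaMin <- 2 * pi / max(Mod(shearWavenumber(g, frequency, rho)))
  if (lambdaMin < 8 * h)
    stop(sprintf(paste0("grid does not resolve the shear wavelength at %.2f Hz: ",
                        "%.1f px/wavelength < 8 (|G*| min %.0f Pa, h %.1f mm)"),
                 frequency, lambdaMin / h, min(Mod(g)), 1000 * h))

  single <- !is.list(sources)
  if (single) sources <- list(sources)

  ny <- nrow(g); nx <- ncol(g)
  interior <- !phantom@sourceMask
  ii <- which(interior)
  ni <- length(ii)
  idx <- matrix(0L, ny, nx); idx[ii] <- seq_len(ni)
  ij <- arrayInd(ii, c(ny, nx))

  coef <- g[ii] / h^2
  rows <- seq_len(ni); cols <- seq_len(ni)
  vals <- -4 * coef + rho * om^2
  bs <- lapply(sources, function(s) complex(ni))
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nb <- cbind(ij[, 1] + d[1], ij[, 2] + d[2])
    stopifnot(all(nb >= 1L), all(nb[, 1] <= ny), all(nb[, 2] <= nx))
    nbl <- idx[nb]
    isInt <- nbl > 0L
    rows <- c(rows, which(isInt)); cols <- c(cols, nbl[isInt])
    vals <- c(vals, coef[isInt])
    for (s in seq_along(bs))
      bs[[s]][!isInt] <- bs[[s]][!isInt] -
        coef[!isInt] * sources[[s]][nb[!isInt, , drop = FALSE]]
  }

  Ar <- Matrix::sparseMatrix(i = rows, j = cols, x = Re(vals), dims = c(ni, ni))
  Ai <- Matrix::sparseMatrix(i = rows, j = cols, x = Im(vals), dims = c(ni, ni))
  M <- rbind(cbind(Ar, -Ai), cbind(Ai, Ar))
  B <- vapply(bs, function(b) c(Re(b), Im(b)), numeric(2 * ni))
  Z <- tryCatch(as.matrix(Matrix::solve(M, B)),
                error = function(e)
                  stop(sprintf(paste0("Helmholtz system singular or ill-conditioned ",
                                      "at %.2f Hz on a %d x %d grid: %s"),
                               frequency, ny, nx, conditionMessage(e))))
  out <- lapply(seq_along(bs), function(s) {
    u <- matrix(0i, ny, nx)
    u[ii] <- Z[seq_len(ni), s] + 1i * Z[ni + seq_len(ni), s]
    u[phantom@sourceMask] <- sources[[s]][phantom@sourceMask]
    u
  })
  if (single) out[[1]] else out
}

#' Component boundary-source patterns
#'
#' Three independent oscillatory source patterns standing in for the three
#' Cartesian motion-encoding components of the scan: damped plane-wave
#' displacement patterns travelling along the image rows, the columns, and
#' the diagonal, evaluated at the phantom's baseline modulus. Because a
#' lossy plane wave spans a huge dynamic range across the grid, the pattern
#' is rescaled per source region so that its peak displacement is `u0` on
#' the outer rim and `holeFactor * u0` on the ventricle-like hole pixels
#' (the CSF transmits the drive into the slice interior largely
#' unattenuated). Each pattern is read by [solveWavefield()] at the source
#' pixels only.
#'
#' @param phantom a [ViscoelasticPhantom-class].
#' @param frequency vibration frequency in Hz.
#' @param u0 drive amplitude in metres.
#' @param holeFactor relative drive amplitude of the hole interiors.
#' @param gstarScale complex scalar applied to the phantom's modulus before
#'   evaluating the pattern wavenumber. Under quasi-static maneuver
#'   modulation the transmitted wave's local wavelength follows the
#'   instantaneous stiffness, so the prescribed pattern must be evaluated in
#'   the modulated medium for the source pixels to stay consistent with the
#'   interior Helmholtz solution.
#' @param rotation angle in radians added to all three pattern directions.
#'   Each vibration frequency is excited through a different driver pair in
#'   the real setup, so different frequencies see rotated wave patterns;
#'   this also keeps the tones' phase gradients from aligning spatially.
#' @return list of three complex matrices.
#' @export
componentSources <- function(phantom, frequency, u0 = 30e-6,
                             holeFactor = 1, gstarScale = 1 + 0i,
                             rotation = 0) {
  n <- dim(phantom@gstarMap)
  g0 <- phantom@gstarMap[which(phantom@tissueMask & !phantom@holeMask)[1]] *
    gstarScale
  baseAngles <- c(0, pi / 2, pi / 4) + rotation
  dirs <- lapply(baseAngles, function(a) c(cos(a), sin(a)))
  border <- phantom@sourceMask & !phantom@holeMask
  lapply(dirs, function(d) {
    w <- planeWaveField(g0, frequency, d, n, phantom@voxelSize,
                        rho = phantom@density, u0 = 1)
    src <- matrix(0i, n[1], n[2])
    src[border] <- w[border] * (u0 / max(Mod(w[border])))
    if (any(phantom@holeMask))
      src[phantom@holeMask] <- w[phantom@holeMask] *
        (holeFactor * u0 / max(Mod(w[phantom@holeMask])))
    src
  })
}

#' Quasi-static time-resolved wavefield provider
#'
#' Returns a function `fields(fi, ci, t)` giving the complex displacement
#' field of vibration frequency index `fi` and component `ci` at slow time
#' `t`, under the maneuver modulation `gstar(t) = m(t) * |G0| * exp(1i *
#' phi(t))`. Stiffness varies slowly compared with the wave period, so
#' fields are re-solved only when the modulation moves to a new quantization
#' bin (default bin width 0.1% in log-magnitude and log-loss-angle); bins are
#' cached and shared across calls, including across repeated noise
#' realizations of the same phantom and profile.
#'
#' @param phantom a [ViscoelasticPhantom-class].
#' @param config an [AcquisitionConfig-class].
#' @param profile a [ManeuverProfile-class], or NULL for a steady phantom.
#' @param u0 drive amplitude in metres.
#' @param quantum relative quantization step of the modulation cache.
#' @return a function `(fi, ci, t) -> complex matrix`, with the cache
#'   environment attached as attribute `cache`.
#' @export
wavefieldSeries <- function(phantom, config, profile = NULL, u0 = 30e-6,
                            quantum = 1e-3) {
  freqs <- config@frequencies
  if (is.null(profile)) {
    mFun <- function(t) rep(1, length(t)); phiFun <- NULL
  } else {
    fns <- maneuverFunctions(profile)
    mFun <- fns$m
    phi0 <- profile@baselinePhi
    phiFun <- fns$phi
  }
  cache <- new.env(parent = emptyenv())
  fields <- function(fi, ci, t) {
    mbin <- round(log(mFun(t)) / quantum)
    pbin <- if (is.null(phiFun)) 0 else round((phiFun(t) - phi0) / (phi0 * quantum))
    key <- sprintf("f%d_m%d_p%d", fi, mbin, pbin)
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (is.null(hit)) {
      m <- exp(mbin * quantum)
      dphi <- if (is.null(phiFun)) 0 else pbin * phi0 * quantum
      scale <- m * exp(1i * dphi)
      src <- componentSources(phantom, freqs[fi], u0, gstarScale = scale,
                              rotation = (fi - 1) * 2 * pi / 3 / length(freqs))
      hit <- solveWavefield(phantom, freqs[fi], src, gstarScale = scale)
      assign(key, hit, envir = cache)
    }
    hit[[ci]]
  }
  attr(fields, "cache") <- cache
  fields
}
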