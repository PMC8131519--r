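#' Build a brain-like viscoelastic phantom
#'
#' Constructs a 2-D phantom on the configured image grid: a tissue disc with
#' complex shear modulus `baselineGstar * exp(1i * baselinePhi)`, an MR
#' magnitude template of about 50 (arbitrary scanner-like units) inside the
#' disc and about 5 inside two elliptical CSF-like ventricle holes near the
#' centre, and zero magnitude outside the disc. The skull-like disc rim and
#' the hole pixels form the driven source set of the wavefield solver: in
#' vivo, shear waves enter the slice both through the skull and via the
#' ventricles, and driving both keeps every tissue pixel within a couple of
#' wave penetration depths of a source despite the strong attenuation of a
#' lossy medium.
#'
#' @param config an [AcquisitionConfig-class]; sets grid size and voxel size.
#' @param gstar baseline complex shear modulus in Pa (scalar), default
#'   `1370 * exp(0.8i)`.
#' @param density mass density in kg/m^3.
#' @param tissueMagnitude,holeMagnitude,outsideMagnitude magnitude template
#'   levels for tissue, CSF-like holes, and the extracranial surround. The
#'   surround default (8) models faint scalp-like signal: it stays below the
#'   analysis magnitude threshold of 10 but keeps the phase noise outside
#'   the disc small and free of wrap residues, which matters because the
#'   least-squares unwrapping integrates gradients globally. Set it to 0
#'   for an air-like pure-noise background.
#' @param discRadiusFrac tissue disc radius as a fraction of the grid size.
#' @param holes logical; carve the two CSF-like ventricle holes.
#' @param inclusion optional list `list(centre = c(row, col), radius = px,
#'   factor = x)` describing a circular inclusion whose |G*| is scaled by
#'   `factor` (loss angle unchanged).
#' @return a [ViscoelasticPhantom-class].
#' @examples
#' ph <- brainPhantom(acquisitionConfig())
#' table(ph@holeMask)
#' @export
brainPhantom <- function(config,
                         gstar = 1370 * exp(0.8i),
                         density = 1000,
                         tissueMagnitude = 50,
                         holeMagnitude = 5,
                         outsideMagnitude = 8,
                         discRadiusFrac = 0.48,
                         holes = TRUE,
                         inclusion = NULL) {
  ny <- config@matrixSize[1]; nx <- config@matrixSize[2]
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  row <- matrix(seq_len(ny), ny, nx)
  col <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  rad <- discRadiusFrac * min(ny, nx)
  tissue <- ((row - cy)^2 + (col - cx)^2) <= rad^2

  hole <- matrix(FALSE, ny, nx)
  if (holes) {
    # two anterior-posterior elliptical ventricle-like holes flanking midline
    for (s in c(-1, 1)) {
      hy <- cy; hx <- cx + s * 0.08 * nx
      hole <- hole | (((row - hy) / (0.14 * ny))^2 +
                      ((col - hx) / (0.045 * nx))^2) <= 1
    }
    # ring of small sulcus-like CSF holes at mid-radius; like the ventricles
    # they transmit the drive into the slice interior and are removed from
    # analysis by the magnitude threshold
    for (a in (0:7) * pi / 4 + pi / 8) {
      hy <- cy + 0.30 * ny * sin(a); hx <- cx + 0.30 * nx * cos(a)
      hole <- hole | ((row - hy)^2 + (col - hx)^2) <= (0.04 * min(ny, nx))^2
    }
    hole <- hole & tissue
  }

  g <- matrix(as.complex(gstar), ny, nx)
  if (!is.null(inclusion)) {
    inside <- ((row - inclusion$centre[1])^2 + (col - inclusion$centre[2])^2) <=
      inclusion$radius^2
    g[inside] <- g[inside] * inclusion$factor
  }

  mag <- matrix(outsideMagnitude, ny, nx)
  mag[tissue] <- tissueMagnitude
  mag[hole] <- holeMagnitude

  # skull-like rim: tissue pixels with a 4-neighbour outside the disc
  inn <- matrix(FALSE, ny, nx)
  inn[2:(ny - 1), 2:(nx - 1)] <-
    tissue[1:(ny - 2), 2:(nx - 1)] & tissue[3:ny, 2:(nx - 1)] &
    tissue[2:(ny - 1), 1:(nx - 2)] & tissue[2:(ny - 1), 3:nx]
  rim <- tissue & !inn
  # the extracranial layer is solved as a passive medium (the scalp vibrates
  # with the skull); displacement is clamped to zero at the FoV border,
  # where the wave has decayed, so the field is smooth across the whole grid
  border <- row == 1L | row == ny | col == 1L | col == nx
  src <- rim | hole | border

  new("ViscoelasticPhantom",
      gstarMap = g, magnitudeMap = mag,
      sourceMask = src, holeMask = hole, tissueMask = tissue,
      density = density, voxelSize = config@voxelSize[1])
}

#' Parenchyma polygon of a phantom
#'
#' A stand-in for the manually drawn region of interest: tissue pixels at
#' least `margin` pixels away from every driven source pixel (skull rim and
#' CSF-like holes). Human raters draw ROIs well inside the parenchyma,
#' avoiding the brain surface and the ventricle walls where partial-volume
#' smoothing mixes tissue with CSF and skull; this mask reproduces that
#' practice for the synthetic phantom.
#'
#' @param phantom a [ViscoelasticPhantom-class].
#' @param margin minimum distance to a source pixel, in pixels.
#' @return logical matrix.
#' @export
parenchymaPolygon <- function(phantom, margin = 2) {
  excl <- phantom@sourceMask
  ny <- nrow(excl); nx <- ncol(excl)
  for (i in seq_len(margin)) {
    d <- excl
    d[2:ny, ] <- d[2:ny, ] | excl[1:(ny - 1), ]
    d[1:(ny - 1), ] <- d[1:(ny - 1), ] | excl[2:ny, ]
    d[, 2:nx] <- d[, 2:nx] | excl[, 1:(nx - 1)]
    d[, 1:(nx - 1)] <- d[, 1:(nx - 1)] | excl[, 2:nx]
    excl <- d
  }
  phantom@tissueMask & !excl
}

setMethod("show", "ViscoelasticPhantom", function(object) {
  d <- dim(object@gstarMap)
  cat("ViscoelasticPhantom\n")
  cat(sprintf("  grid %d x %d, voxel %.1f mm, density %.0f kg/m^3\n",
              d[1], d[2], 1000 * object@voxelSize, object@density))
  g <- object@gstarMap[!object@holeMask]
  cat(sprintf("  tissue |G*| %.0f-%.0f Pa, phi %.3f-%.3f rad; %d hole px, %d source px\n",
              min(Mod(g)), max(Mod(g)), min(Arg(g)), max(Arg(g)),
              sum(object@holeMask), sum(object@sourceMask)))
})
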