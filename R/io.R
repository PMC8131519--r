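#' Write / read a raw image series as NIfTI pair plus YAML sidecar
#'
#' A complex series is stored as paired 4-D magnitude and phase NIfTI
#' volumes (`<prefix>_mag.nii.gz`, `<prefix>_phase.nii.gz`, time as 4th
#' dimension, temporal pixdim = TR) with a `<prefix>.yaml` sidecar carrying
#' TR, component interleave order, vibration frequencies, voxel size, scan
#' duration, encoding sensitivity and the seed/noise record. The round trip
#' is lossless up to float32 NIfTI storage; pass `datatype = "double"` for a
#' bit-exact round trip.
#'
#' @param series a [RawImageSeries-class].
#' @param prefix output path prefix.
#' @param datatype NIfTI datatype (default `"double"`).
#' @return `writeRawSeries`: the prefix, invisibly. `readRawSeries`: a
#'   [RawImageSeries-class].
#' @export
writeRawSeries <- function(series, prefix, datatype = "double") {
  cfg <- series@config
  d <- dim(series@images)
  arr4 <- function(x) array(x, c(d[1], d[2], 1L, d[3]))
  pd <- c(1000 * cfg@voxelSize[1:2], 1000 * cfg@voxelSize[3], cfg@tr)
  img <- RNifti::asNifti(arr4(Mod(series@images)))
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, paste0(prefix, "_mag.nii.gz"), datatype = datatype)
  img <- RNifti::asNifti(arr4(Arg(series@images)))
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, paste0(prefix, "_phase.nii.gz"), datatype = datatype)
  side <- list(
    tr = cfg@tr,
    n_components = cfg@nComponents,
    component_order = as.integer(series@componentLabels[seq_len(cfg@nComponents)]),
    frequencies = cfg@frequencies,
    scan_duration = cfg@scanDuration,
    matrix = cfg@matrixSize,
    voxel_size_m = cfg@voxelSize,
    meg_duration = cfg@megDuration,
    meg_amplitude = cfg@megAmplitude,
    encoding_sensitivity = cfg@encodingSensitivity,
    flip_angle = cfg@flipAngle,
    te = cfg@te,
    seed = series@seed,
    noise_sd = series@noiseSd)
  yaml::write_yaml(side, paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' @rdname writeRawSeries
#' @export
readRawSeries <- function(prefix) {
  yamlPath <- paste0(prefix, ".yaml")
  if (!file.exists(yamlPath)) stop("missing YAML sidecar: ", yamlPath)
  side <- yaml::read_yaml(yamlPath)
  required <- c("tr", "n_components", "frequencies", "scan_duration",
                "voxel_size_m")
  missing <- setdiff(required, names(side))
  if (length(missing))
    stop("sidecar is missing required fields: ", paste(missing, collapse = ", "))
  for (f in c("_mag.nii.gz", "_phase.nii.gz"))
    if (!file.exists(paste0(prefix, f))) stop("missing NIfTI volume: ", prefix, f)
  mag <- as.array(RNifti::readNifti(paste0(prefix, "_mag.nii.gz")))
  ph <- as.array(RNifti::readNifti(paste0(prefix, "_phase.nii.gz")))
  d <- dim(mag)
  imgs <- array(complex(modulus = mag, argument = ph), c(d[1], d[2], d[4]))
  cfg <- acquisitionConfig(
    tr = side$tr, nComponents = side$n_components,
    frequencies = unlist(side$frequencies),
    scanDuration = side$scan_duration,
    matrixSize = c(d[1], d[2]),
    voxelSize = unlist(side$voxel_size_m),
    megDuration = side$meg_duration %||% 0.0175,
    megAmplitude = side$meg_amplitude %||% 40,
    encodingSensitivity = side$encoding_sensitivity %||% 80000,
    flipAngle = side$flip_angle %||% 20,
    te = side$te %||% 0.02)
  new("RawImageSeries", images = imgs, timestamps = imageTimes(cfg),
      componentLabels = imageComponents(cfg), config = cfg,
      seed = as.integer(side$seed %||% NA_integer_),
      noiseSd = as.numeric(side$noise_sd %||% NA_real_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an elastogram series as NIfTI volumes
#'
#' Stores `<prefix>_gstar.nii.gz` (Pa) and `<prefix>_phi.nii.gz` (rad) as
#' 4-D volumes whose temporal pixdim records the frame interval, plus a
#' `<prefix>.yaml` sidecar with the frame origin, scan duration, inversion
#' settings and validity convention (invalid pixels are stored as NaN).
#' Frame times are reconstructed exactly from the temporal pixdim and
#' origin.
#'
#' @param series an [ElastogramSeries-class].
#' @param prefix output path prefix.
#' @param voxelSize in-plane/slice voxel size in metres for the NIfTI
#'   header.
#' @return `writeElastogramSeries`: the prefix, invisibly.
#'   `readElastogramSeries`: an [ElastogramSeries-class].
#' @export
writeElastogramSeries <- function(series, prefix,
                                  voxelSize = c(0.002, 0.002, 0.005)) {
  d <- dim(series@gstar)
  dt <- if (d[3] > 1L) series@frameTimes[2] - series@frameTimes[1] else 1
  arr4 <- function(x) { x[!series@valid] <- NaN; array(x, c(d[1], d[2], 1L, d[3])) }
  pd <- c(1000 * voxelSize[1:2], 1000 * voxelSize[3], dt)
  for (what in c("gstar", "phi")) {
    img <- RNifti::asNifti(arr4(slot(series, what)))
    RNifti::pixdim(img) <- pd
    RNifti::writeNifti(img, paste0(prefix, "_", what, ".nii.gz"),
                       datatype = "double")
  }
  yaml::write_yaml(list(frame_time_origin = series@frameTimes[1],
                        scan_duration = series@scanDuration,
                        settings = series@settings),
                   paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' @rdname writeElastogramSeries
#' @export
readElastogramSeries <- function(prefix) {
  side <- yaml::read_yaml(paste0(prefix, ".yaml"))
  g <- RNifti::readNifti(paste0(prefix, "_gstar.nii.gz"))
  p <- RNifti::readNifti(paste0(prefix, "_phi.nii.gz"))
  dt <- RNifti::pixdim(g)[4]
  ga <- as.array(g); pa <- as.array(p)
  d <- dim(ga)
  ga <- array(ga, c(d[1], d[2], d[4])); pa <- array(pa, c(d[1], d[2], d[4]))
  valid <- !is.na(ga) & !is.na(pa)
  ga[!valid] <- NA_real_; pa[!valid] <- NA_real_
  new("ElastogramSeries", gstar = ga, phi = pa, valid = valid,
      frameTimes = side$frame_time_origin + (seq_len(d[4]) - 1L) * dt,
      scanDuration = side$scan_duration,
      settings = lapply(side$settings, function(x) if (length(x) > 1) unlist(x) else x))
}

#' Write analysis tables as CSV
#'
#' Writes the per-frame time course (`timecourse.csv`), the per-phase
#' summary (`phases.csv`) and the peaks table (`peaks.csv`) into a
#' directory.
#'
#' @param tc time course data.frame from [roiTimeCourse()].
#' @param phases data.frame from [phaseStatistics()].
#' @param peaks data.frame with one row per detected event.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeTimeCourses <- function(tc, phases, peaks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(tc, file.path(dir, "timecourse.csv"), row.names = FALSE)
  write.csv(phases, file.path(dir, "phases.csv"), row.names = FALSE)
  write.csv(peaks, file.path(dir, "peaks.csv"), row.names = FALSE)
  invisible(dir)
}
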