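#' Number of frames or images in a series object
#'
#' For a [RawImageSeries-class] or [PhaseImageSeries-class] this is the number
#' of single-shot images; for a [DecomposedWavefield-class] or
#' [ElastogramSeries-class] it is the number of time-resolved frames.
#'
#' @param x a series object.
#' @return integer count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame or image time axis
#'
#' @param x a series object.
#' @return numeric vector of times in seconds.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Underlying array data of a series object
#'
#' @param x a series object.
#' @return the complex image array (raw series), phase array (phase series)
#'   or field list (decomposed wavefield).
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' Motion-encoding component labels
#'
#' @param x a series object carrying per-image labels.
#' @return integer vector in `0:(nComponents-1)`.
#' @export
setGeneric("componentLabels", function(x) standardGeneric("componentLabels"))

#' Acquisition configuration of a series object
#'
#' @param x a series object.
#' @return the [AcquisitionConfig-class].
#' @export
setGeneric("seriesConfig", function(x) standardGeneric("seriesConfig"))

#' Stiffness maps of an elastogram series
#'
#' @param x an [ElastogramSeries-class].
#' @return numeric array (rows, columns, frames) of |G*| in Pa.
#' @export
setGeneric("gstarMaps", function(x) standardGeneric("gstarMaps"))

#' Loss-angle maps of an elastogram series
#'
#' @param x an [ElastogramSeries-class].
#' @return numeric array (rows, columns, frames) of phi in rad.
#' @export
setGeneric("phiMaps", function(x) standardGeneric("phiMaps"))

#' Validity mask of an elastogram series
#'
#' @param x an [ElastogramSeries-class].
#' @return logical array marking pixels with usable inversion support.
#' @export
setGeneric("validityMask", function(x) standardGeneric("validityMask"))
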