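#' @import methods
#' @importFrom stats median quantile rnorm rpois rexp rgeom runif sd pnorm setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' MovieStack: a multi-dimensional fluorescence movie
#'
#' Container for a time-lapse movie as a 5-D intensity array indexed
#' \code{(t, z, c, y, x)} together with its physical metadata. Intensities
#' are non-negative and in arbitrary units; the z axis may have length 1
#' (e.g. after projection).
#'
#' @slot data numeric array, dimensions \code{(t, z, c, y, x)}, all values >= 0.
#' @slot frameInterval numeric(1), seconds between frames (> 0).
#' @slot zStep numeric(1), micrometres between z slices (> 0).
#' @slot pixelSize numeric(1), micrometres per pixel (> 0).
#' @slot channelNames character, one label per channel (length = c axis).
#'
#' @seealso [movieStack()], [readMovie()], [maxProject()]
#' @export
setClass("MovieStack",
  representation(
    data          = "array",
    frameInterval = "numeric",
    zStep         = "numeric",
    pixelSize     = "numeric",
    channelNames  = "character"
  )
)

setValidity("MovieStack", function(object) {
  d <- object@data
  if (length(dim(d)) != 5L)
    return("data must be a 5-D array (t, z, c, y, x)")
  if (any(d < 0, na.rm = TRUE))
    return("intensities must be >= 0")
  if (length(object@channelNames) != dim(d)[3L])
    return("length(channelNames) must equal the c-axis length")
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    return("frameInterval must be a single positive number (seconds)")
  if (length(object@zStep) != 1L || object@zStep <= 0)
    return("zStep must be a single positive number (micrometres)")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("pixelSize must be a single positive number (micrometres)")
  TRUE
})

#' Projection: a z-collapsed movie
#'
#' A movie reduced over z, indexed \code{(t, c, y, x)}. Produced by
#' [maxProject()]; carries the projection method and a provenance note.
#'
#' @slot data numeric array, dimensions \code{(t, c, y, x)}.
#' @slot method character(1), projection method label (\code{"max"}).
#' @slot provenance character(1), free-text note on the source movie.
#' @slot frameInterval numeric(1), seconds.
#' @slot pixelSize numeric(1), micrometres.
#' @slot channelNames character.
#' @export
setClass("Projection",
  representation(
    data          = "array",
    method        = "character",
    provenance    = "character",
    frameInterval = "numeric",
    pixelSize     = "numeric",
    channelNames  = "character"
  )
)

setValidity("Projection", function(object) {
  d <- object@data
  if (length(dim(d)) != 4L)
    return("data must be a 4-D array (t, c, y, x)")
  if (length(object@channelNames) != dim(d)[2L])
    return("length(channelNames) must equal the c-axis length")
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    return("frameInterval must be positive")
  TRUE
})

#' MaskMovie: per-frame binary masks
#'
#' Boolean chromatin/nuclear masks aligned with a [Projection-class], one
#' mask per frame, plus a record of the parameters used to build them.
#'
#' @slot data logical array, dimensions \code{(t, y, x)}.
#' @slot params list of the clipping / blurring / thresholding parameters.
#' @export
setClass("MaskMovie",
  representation(data = "array", params = "list")
)

setValidity("MaskMovie", function(object) {
  if (length(dim(object@data)) != 3L)
    return("data must be a 3-D array (t, y, x)")
  if (!is.logical(object@data))
    return("mask data must be logical")
  TRUE
})

#' LabelMovie: per-frame labelled nuclear segmentations
#'
#' Integer-labelled nuclei per frame (0 = background) with a per-frame
#' region table. Labels are unique within a frame and, after filtering,
#' no retained label touches an X-Y border.
#'
#' @slot data integer array, dimensions \code{(t, y, x)}; 0 = background.
#' @slot regions data.frame with columns \code{frame, label, area, cy, cx}.
#' @slot params list of segmentation parameters.
#' @export
setClass("LabelMovie",
  representation(data = "array", regions = "data.frame", params = "list")
)

setValidity("LabelMovie", function(object) {
  if (length(dim(object@data)) != 3L)
    return("data must be a 3-D array (t, y, x)")
  if (any(object@data < 0))
    return("labels must be non-negative")
  need <- c("frame", "label", "area", "cy", "cx")
  if (!all(need %in% names(object@regions)))
    return(paste("regions must have columns:", paste(need, collapse = ", ")))
  TRUE
})

#' IntensitySeries: a per-frame masked intensity statistic
#'
#' A single summary statistic (mean or population variance) of the masked
#' pixels of one channel, evaluated at every frame.
#'
#' @slot values numeric, one value per frame (arbitrary units).
#' @slot statistic character(1), \code{"mean"} or \code{"variance"}.
#' @slot channel character(1), channel label.
#' @slot times numeric, frame times in seconds.
#' @export
setClass("IntensitySeries",
  representation(
    values    = "numeric",
    statistic = "character",
    channel   = "character",
    times     = "numeric"
  )
)

setValidity("IntensitySeries", function(object) {
  if (length(object@values) != length(object@times))
    return("values and times must have equal length")
  if (object@statistic == "variance" && any(object@values < -1e-12, na.rm = TRUE))
    return("a variance series must be non-negative")
  TRUE
})

#' StateTraces: per-nucleus ON/OFF transcription states
#'
#' Boolean ON state per retained nucleus track per frame, with the derived
#' first-ON and first-OFF-after-ON transition frames.
#'
#' @slot on logical matrix, rows = nucleus tracks, columns = frames.
#' @slot summary data.frame with columns
#'   \code{track, firstOn, firstOffAfterOn} (frames, NA when undefined).
#' @export
setClass("StateTraces",
  representation(on = "matrix", summary = "data.frame")
)

setValidity("StateTraces", function(object) {
  s <- object@summary
  if (!all(c("track", "firstOn", "firstOffAfterOn") %in% names(s)))
    return("summary must have columns track, firstOn, firstOffAfterOn")
  if (nrow(s) != nrow(object@on))
    return("one summary row per track is required")
  bad <- !is.na(s$firstOffAfterOn) &
    (is.na(s$firstOn) | s$firstOffAfterOn <= s$firstOn)
  if (any(bad))
    return("firstOffAfterOn requires an earlier firstOn")
  TRUE
})

#' GroundTruth: the synthetic movie generator's emitted truth
#'
#' Frame-by-frame truth tables for a simulated embryo movie, used for
#' parameter-recovery testing: nucleus positions and phases, rendered focus
#' positions and amplitudes, per-nucleus transcription states, true 5'/3'
#' spot intensities, and the cycle annotation.
#'
#' @slot nuclei data.frame: \code{frame, track, y, x, radius, phase, cycle}.
#' @slot foci data.frame: \code{frame, track, channel, y, x, amplitude, sigma}.
#' @slot states data.frame: \code{frame, track, on}.
#' @slot stateSummary data.frame:
#'   \code{track, cycle, sStart, firstOn, firstOffAfterOn}.
#' @slot spots data.frame: \code{frame, track, mcp, pcp} (true amplitudes).
#' @slot cycles data.frame: \code{frame, cycle, phase}.
#' @slot sStarts integer, first frame of each S phase (1-based).
#' @export
setClass("GroundTruth",
  representation(
    nuclei       = "data.frame",
    foci         = "data.frame",
    states       = "data.frame",
    stateSummary = "data.frame",
    spots        = "data.frame",
    cycles       = "data.frame",
    sStarts      = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  nFrames <- nrow(object@cycles)
  if (nFrames > 0 && nrow(object@states) > 0) {
    perTrack <- table(object@states$track)
    if (any(perTrack > nFrames))
      return("state series cannot be longer than the movie")
  }
  TRUE
})
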