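#' @name accessors
#' @title Accessors for movie containers
#'
#' @description
#' \code{movieData()} returns the raw intensity array; \code{nFrames()},
#' \code{nChannels()} the axis lengths; \code{channelNames()} the channel
#' labels; \code{frameInterval()} the frame spacing in seconds;
#' \code{channelIndex()} resolves a channel given by name or position;
#' \code{getFrame()} extracts one 2-D \code{(y, x)} frame;
#' \code{regionTable()} the per-frame region table of a [LabelMovie-class].
#'
#' @param x a [MovieStack-class], [Projection-class], [MaskMovie-class]
#'   or [LabelMovie-class].
#' @param channel channel name or 1-based index.
#' @param t 1-based frame index.
#' @return See individual descriptions.
NULL

#' @rdname accessors
#' @export
setGeneric("movieData", function(x) standardGeneric("movieData"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("getFrame", function(x, t, channel = 1L) standardGeneric("getFrame"))
#' @rdname accessors
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @rdname accessors
setMethod("movieData", "MovieStack", function(x) x@data)
#' @rdname accessors
setMethod("movieData", "Projection", function(x) x@data)
#' @rdname accessors
setMethod("movieData", "MaskMovie", function(x) x@data)
#' @rdname accessors
setMethod("movieData", "LabelMovie", function(x) x@data)

#' @rdname accessors
setMethod("nFrames", "MovieStack", function(x) dim(x@data)[1L])
#' @rdname accessors
setMethod("nFrames", "Projection", function(x) dim(x@data)[1L])
#' @rdname accessors
setMethod("nFrames", "MaskMovie", function(x) dim(x@data)[1L])
#' @rdname accessors
setMethod("nFrames", "LabelMovie", function(x) dim(x@data)[1L])

#' @rdname accessors
setMethod("nChannels", "MovieStack", function(x) dim(x@data)[3L])
#' @rdname accessors
setMethod("nChannels", "Projection", function(x) dim(x@data)[2L])

#' @rdname accessors
setMethod("channelNames", "MovieStack", function(x) x@channelNames)
#' @rdname accessors
setMethod("channelNames", "Projection", function(x) x@channelNames)

#' @rdname accessors
setMethod("frameInterval", "MovieStack", function(x) x@frameInterval)
#' @rdname accessors
setMethod("frameInterval", "Projection", function(x) x@frameInterval)

#' @rdname accessors
#' @export
channelIndex <- function(x, channel) {
  nms <- channelNames(x)
  if (is.character(channel)) {
    i <- match(channel, nms)
    if (is.na(i))
      stop("unknown channel '", channel, "'; available: ",
           paste(nms, collapse = ", "))
    return(i)
  }
  channel <- as.integer(channel)
  if (channel < 1L || channel > length(nms))
    stop("channel index out of range")
  channel
}

#' @rdname accessors
setMethod("getFrame", "Projection", function(x, t, channel = 1L) {
  ci <- channelIndex(x, channel)
  if (t < 1L || t > nFrames(x)) stop("frame index out of range")
  x@data[t, ci, , ]
})

#' @rdname accessors
setMethod("getFrame", "MaskMovie", function(x, t, channel = 1L) {
  if (t < 1L || t > nFrames(x)) stop("frame index out of range")
  x@data[t, , ]
})

#' @rdname accessors
setMethod("getFrame", "LabelMovie", function(x, t, channel = 1L) {
  if (t < 1L || t > nFrames(x)) stop("frame index out of range")
  x@data[t, , ]
})

#' @rdname accessors
setMethod("regionTable", "LabelMovie", function(x) x@regions)

setMethod("show", "MovieStack", function(object) {
  d <- dim(object@data)
  cat("MovieStack:", d[1L], "frames x", d[2L], "z x", d[3L],
      "channels x", d[4L], "x", d[5L], "px\n")
  cat("  channels:     ", paste(object@channelNames, collapse = ", "), "\n")
  cat("  frameInterval:", object@frameInterval, "s; zStep:", object@zStep,
      "um; pixelSize:", object@pixelSize, "um\n")
})

setMethod("show", "Projection", function(object) {
  d <- dim(object@data)
  cat("Projection (", object@method, "): ", d[1L], " frames x ", d[2L],
      " channels x ", d[3L], " x ", d[4L], " px\n", sep = "")
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
})

setMethod("show", "MaskMovie", function(object) {
  d <- dim(object@data)
  cat("MaskMovie:", d[1L], "frames x", d[2L], "x", d[3L], "px;",
      "foreground fraction", round(mean(object@data), 3), "\n")
})

setMethod("show", "LabelMovie", function(object) {
  d <- dim(object@data)
  cat("LabelMovie:", d[1L], "frames x", d[2L], "x", d[3L], "px;",
      nrow(object@regions), "regions total\n")
})

setMethod("show", "IntensitySeries", function(object) {
  cat("IntensitySeries (", object@statistic, ", channel ", object@channel,
      "): ", length(object@values), " frames\n", sep = "")
})

setMethod("show", "StateTraces", function(object) {
  s <- object@summary
  cat("StateTraces:", nrow(s), "nucleus tracks x", ncol(object@on), "frames;",
      sum(!is.na(s$firstOn)), "turned ON,",
      sum(!is.na(s$firstOffAfterOn)), "turned OFF\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", paste(object@imageSize, collapse = "x"), "px,",
      length(object@sPhaseMinutes), "cycles,",
      object@initialNuclei, "initial nuclei, dt =", object@frameInterval,
      "s, preset:", object@perturbation, "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@cycles), "frames,",
      length(unique(object@nuclei$track)), "nucleus tracks,",
      nrow(object@foci), "focus renderings\n")
})
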