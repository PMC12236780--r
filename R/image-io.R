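#' Construct a MovieStack
#'
#' @param data numeric array with dimensions \code{(t, z, c, y, x)};
#'   missing leading axes of a 2-D/3-D/4-D array can be supplied by
#'   reshaping before the call.
#' @param frameInterval seconds between frames.
#' @param zStep micrometres between z slices.
#' @param pixelSize micrometres per pixel.
#' @param channelNames character vector, one per channel; defaults to
#'   \code{"ch1"}, \code{"ch2"}, ...
#' @return A validated [MovieStack-class].
#' @examples
#' a <- array(runif(2 * 3 * 1 * 8 * 8), c(2, 3, 1, 8, 8))
#' movieStack(a, frameInterval = 20)
#' @export
movieStack <- function(data, frameInterval = 20, zStep = 0.5, pixelSize = 0.2,
                       channelNames = NULL) {
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(dim(data)[3L]))
  new("MovieStack", data = data, frameInterval = frameInterval,
      zStep = zStep, pixelSize = pixelSize, channelNames = channelNames)
}

.sidecarPath <- function(path) paste0(path, ".json")

#' Write a movie to a multi-page TIFF
#'
#' Pages are written in channel-fastest order (c, then z, then t), the de
#' facto hyperstack page order, as unsigned integers of the requested
#' depth. Intensities must already lie within the integer range; they are
#' rounded, so integer-valued data round-trips exactly through
#' [readMovie()]. Physical metadata and axis lengths are stored in a JSON
#' sidecar next to the TIFF (\code{<path>.json}).
#'
#' @param movie a [MovieStack-class].
#' @param path output TIFF path.
#' @param bitsPerSample 8 or 16.
#' @return \code{path}, invisibly.
#' @seealso [readMovie()]
#' @export
writeMovie <- function(movie, path, bitsPerSample = 16L) {
  stopifnot(is(movie, "MovieStack"))
  if (!bitsPerSample %in% c(8L, 16L))
    stop("bitsPerSample must be 8 or 16")
  maxVal <- 2^bitsPerSample - 1
  d <- movie@data
  if (max(d) > maxVal)
    stop("intensities exceed the ", bitsPerSample, "-bit range [0, ", maxVal, "]")
  dims <- dim(d)  # t z c y x
  pages <- vector("list", dims[1L] * dims[2L] * dims[3L])
  k <- 0L
  for (t in seq_len(dims[1L])) for (z in seq_len(dims[2L]))
    for (ch in seq_len(dims[3L])) {
      k <- k + 1L
      pages[[k]] <- round(d[t, z, ch, , ]) / maxVal
    }
  tiff::writeTIFF(pages, path, bits.per.sample = bitsPerSample)
  meta <- list(
    axes = "tzcyx", dims = as.integer(dims),
    frameInterval = movie@frameInterval, zStep = movie@zStep,
    pixelSize = movie@pixelSize, channelNames = movie@channelNames,
    bitsPerSample = as.integer(bitsPerSample)
  )
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie from a multi-page TIFF
#'
#' Pages are interpreted in channel-fastest order (c, then z, then t). If
#' a JSON sidecar written by [writeMovie()] is present, axis lengths and
#' metadata are taken from it; otherwise \code{nZ} and \code{nC} must be
#' given (the frame count is inferred from the page count) together with
#' the physical metadata. Missing axes are inserted with length 1.
#'
#' @param path TIFF path.
#' @param nZ,nC z-slice and channel counts, ignored when a sidecar exists.
#' @param frameInterval,zStep,pixelSize,channelNames metadata used when no
#'   sidecar exists.
#' @return A [MovieStack-class] with axis order \code{(t, z, c, y, x)}.
#' @export
readMovie <- function(path, nZ = 1L, nC = 1L, frameInterval = 20,
                      zStep = 0.5, pixelSize = 0.2, channelNames = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = FALSE),
                    error = function(e) stop("unreadable TIFF '", path, "': ",
                                             conditionMessage(e)))
  if (is.matrix(pages) || (is.array(pages) && length(dim(pages)) <= 3L))
    pages <- list(pages)
  bits <- 16L
  side <- .sidecarPath(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    dims <- as.integer(meta$dims)
    nZ <- dims[2L]; nC <- dims[3L]
    frameInterval <- meta$frameInterval; zStep <- meta$zStep
    pixelSize <- meta$pixelSize; channelNames <- meta$channelNames
    bits <- as.integer(meta$bitsPerSample)
  }
  nPages <- length(pages)
  if (nPages %% (nZ * nC) != 0L)
    stop("page count (", nPages, ") is not divisible by nZ * nC = ", nZ * nC,
         "; axes are ambiguous, supply nZ and nC")
  nT <- nPages %/% (nZ * nC)
  first <- pages[[1L]]
  if (length(dim(first)) == 3L) first <- first[, , 1L]  # drop extra samples
  ny <- nrow(first); nx <- ncol(first)
  maxVal <- 2^bits - 1
  d <- array(0, c(nT, nZ, nC, ny, nx))
  k <- 0L
  for (t in seq_len(nT)) for (z in seq_len(nZ)) for (ch in seq_len(nC)) {
    k <- k + 1L
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]
    d[t, z, ch, , ] <- round(pg * maxVal)
  }
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(nC))
  movieStack(d, frameInterval = frameInterval, zStep = zStep,
             pixelSize = pixelSize, channelNames = channelNames)
}

#' Maximal-intensity projection over z
#'
#' Collapses the z axis by the per-pixel maximum; the standard first step
#' before any downstream quantification. Idempotent once z has length 1.
#'
#' @param movie a [MovieStack-class].
#' @return A [Projection-class] with data indexed \code{(t, c, y, x)}.
#' @export
maxProject <- function(movie) {
  stopifnot(is(movie, "MovieStack"))
  d <- movie@data
  dims <- dim(d)
  out <- array(d[, 1L, , , , drop = FALSE], dims[-2L])
  if (dims[2L] > 1L)
    for (z in 2L:dims[2L])
      out <- pmax(out, array(d[, z, , , , drop = FALSE], dims[-2L]))
  new("Projection", data = out, method = "max",
      provenance = paste0("maxProject of ", dims[2L], "-slice stack"),
      frameInterval = movie@frameInterval, pixelSize = movie@pixelSize,
      channelNames = movie@channelNames)
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of a single 2-D image as its grayscale
#' morphological opening with a flat disc structuring element of the given
#' radius and subtracts it; output is clipped at zero. The default radius
#' of 50 px matches common practice for these movies.
#'
#' @param image numeric matrix (y, x), non-negative.
#' @param radius ball radius in pixels (> 0).
#' @return Matrix of the same shape, \code{0 <= out <= image} pointwise.
#' @examples
#' img <- matrix(100, 64, 64); img[32, 32] <- 300
#' bg <- rollingBallSubtract(img, radius = 50)
#' bg[32, 32]  # ~200: the spike survives, the flat background is removed
#' @export
rollingBallSubtract <- function(image, radius = 50) {
  if (!is.matrix(image)) stop("image must be a 2-D matrix")
  if (radius <= 0) stop("radius must be positive")
  sc <- max(image)
  if (sc == 0) return(image)
  side <- 2L * as.integer(ceiling(radius)) + 1L
  brush <- EBImage::makeBrush(side, shape = "disc")
  bg <- EBImage::opening(image / sc, brush) * sc
  pmax(image - bg, 0)
}

#' Crop a region from a projection
#'
#' Extracts a sub-movie addressed by closed 1-based index intervals
#' \code{c(first, last)} on the t, y and x axes (all channels retained).
#' Used to restrict analysis to well-sampled central nuclei.
#'
#' @param proj a [Projection-class].
#' @param tRange,yRange,xRange integer pairs \code{c(first, last)}, 1-based
#'   inclusive; \code{NULL} keeps the full axis.
#' @return A [Projection-class] holding a copy of the addressed sub-array.
#' @export
cropRegion <- function(proj, tRange = NULL, yRange = NULL, xRange = NULL) {
  stopifnot(is(proj, "Projection"))
  d <- dim(proj@data)
  rng <- function(r, n, axis) {
    if (is.null(r)) return(seq_len(n))
    r <- as.integer(r)
    if (length(r) != 2L || r[1L] < 1L || r[2L] > n || r[1L] > r[2L])
      stop("interval out of bounds on ", axis, " axis: [", r[1L], ", ", r[2L],
           "] with length ", n)
    r[1L]:r[2L]
  }
  ts <- rng(tRange, d[1L], "t"); ys <- rng(yRange, d[3L], "y")
  xs <- rng(xRange, d[4L], "x")
  sub <- proj@data[ts, , ys, xs, drop = FALSE]
  new("Projection", data = sub, method = proj@method,
      provenance = paste0(proj@provenance, "; cropped"),
      frameInterval = proj@frameInterval, pixelSize = proj@pixelSize,
      channelNames = proj@channelNames)
}
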