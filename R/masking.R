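#' Clip bright intensities before segmentation
#'
#' Replaces every pixel above a threshold with a lower constant value.
#' Bright sub-nuclear foci (histone-locus bodies and other hubs) otherwise
#' dominate a between-class-variance threshold and shrink the nuclear
#' mask; clipping them restores a body-weighted segmentation.
#'
#' @param image numeric matrix.
#' @param clipThreshold intensity above which pixels are replaced.
#' @param replacement the constant to write; must be <= \code{clipThreshold}.
#' @return Matrix of the same shape.
#' @export
clipIntensities <- function(image, clipThreshold, replacement) {
  if (replacement > clipThreshold)
    stop("replacement (", replacement, ") must be <= clipThreshold (",
         clipThreshold, ")")
  image[image > clipThreshold] <- replacement
  image
}

#' Otsu's threshold
#'
#' Histogram threshold maximizing the between-class variance over
#' \code{nBins} equal-width bins spanning the image range. Foreground is
#' defined as pixels strictly greater than the returned value (a bin
#' edge). Ties are broken toward the lowest maximizing cut.
#'
#' @param image numeric matrix with at least two distinct values.
#' @param nBins number of histogram bins (default 256).
#' @return The threshold intensity (a single number).
#' @export
otsuThreshold <- function(image, nBins = 256L) {
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  if (hi - lo <= 1e-10 * max(abs(lo), abs(hi), 1))
    stop("otsuThreshold: image is constant, no threshold exists")
  breaks <- seq(lo, hi, length.out = nBins + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), nBins),
    nbins = nBins)
  mids <- (breaks[-1L] + breaks[-(nBins + 1L)]) / 2
  w <- cumsum(counts)                      # class-0 size up to cut k
  m <- cumsum(counts * mids)               # class-0 intensity sum
  n <- w[nBins]; mTot <- m[nBins]
  k <- seq_len(nBins - 1L)
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  sigmaB <- rep(-Inf, nBins - 1L)
  sigmaB[valid] <- (mTot * w0[valid] - n * m[k][valid])^2 /
    (as.numeric(w0[valid]) * w1[valid])
  best <- which.max(sigmaB)
  breaks[best + 1L]
}

.autoClip <- function(img, clipQuantile, clipThreshold, replacement) {
  thr <- if (is.null(clipThreshold))
    as.numeric(quantile(img, clipQuantile, names = FALSE)) else clipThreshold
  rep <- if (is.null(replacement)) {
    below <- img[img <= thr]
    if (length(below)) median(below) else thr
  } else replacement
  clipIntensities(img, thr, rep)
}

#' Combined chromatin mask from two channels
#'
#' Per frame: sum the two channels, clip bright foci, Gaussian-blur, then
#' binarize at the Otsu threshold. The resulting mask follows chromatin
#' through both interphase (nuclei) and mitosis (condensed chromosomes),
#' which is what makes whole-cycle intensity series possible.
#'
#' @param proj a [Projection-class].
#' @param channels two channel names or indices to sum.
#' @param clipQuantile quantile used for the automatic clip threshold
#'   (default 0.995); ignored when \code{clipThreshold} is given.
#' @param clipThreshold,replacement explicit clip parameters; when
#'   \code{NULL}, the threshold is the \code{clipQuantile} quantile of the
#'   frame and the replacement the median of sub-threshold pixels.
#' @param blurSigma Gaussian blur sigma in pixels (default 2).
#' @return A [MaskMovie-class].
#' @export
combinedChromatinMask <- function(proj, channels = c(1L, 2L),
                                  clipQuantile = 0.995, clipThreshold = NULL,
                                  replacement = NULL, blurSigma = 2) {
  stopifnot(is(proj, "Projection"))
  if (length(channels) != 2L) stop("channels must name exactly two channels")
  i1 <- channelIndex(proj, channels[[1L]])
  i2 <- channelIndex(proj, channels[[2L]])
  nT <- nFrames(proj)
  d <- dim(proj@data)
  mask <- array(FALSE, c(nT, d[3L], d[4L]))
  for (t in seq_len(nT)) {
    s <- proj@data[t, i1, , ] + proj@data[t, i2, , ]
    s <- .autoClip(s, clipQuantile, clipThreshold, replacement)
    b <- .gaussSmooth(s, blurSigma)
    thr <- tryCatch(otsuThreshold(b),
                    error = function(e) stop("frame ", t, ": ",
                                             conditionMessage(e)))
    mask[t, , ] <- b > thr
  }
  new("MaskMovie", data = mask,
      params = list(channels = c(i1, i2), clipQuantile = clipQuantile,
                    clipThreshold = clipThreshold, replacement = replacement,
                    blurSigma = blurSigma))
}

# per-frame region statistics for a label matrix
.regionStats <- function(lab) {
  labs <- sort(unique(lab[lab > 0L]))
  if (!length(labs))
    return(data.frame(label = integer(0), area = integer(0),
                      cy = numeric(0), cx = numeric(0),
                      onBorder = logical(0)))
  ny <- nrow(lab); nx <- ncol(lab)
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[lab > 0L]
  area <- as.integer(table(factor(l, levels = labs)))
  cy <- tapply(idx[, 1L], factor(l, levels = labs), mean)
  cx <- tapply(idx[, 2L], factor(l, levels = labs), mean)
  onB <- tapply(idx[, 1L] == 1L | idx[, 1L] == ny |
                idx[, 2L] == 1L | idx[, 2L] == nx,
                factor(l, levels = labs), any)
  data.frame(label = labs, area = area, cy = as.numeric(cy),
             cx = as.numeric(cx), onBorder = as.logical(onB))
}

#' Segment nuclei in one channel
#'
#' Per frame: clip bright foci, Gaussian-blur, Otsu-binarize, dilate the
#' mask (to capture peripheral transcription foci later), split touching
#' nuclei by a watershed on the Euclidean distance transform, then drop
#' regions smaller than \code{minArea} or touching an X-Y border. Retained
#' labels are relabelled consecutively in raster order.
#'
#' @param proj a [Projection-class].
#' @param channel channel name or index carrying the nuclear signal.
#' @inheritParams combinedChromatinMask
#' @param dilationRadius disc radius in pixels for mask dilation (default 2).
#' @param minArea minimum retained region area in px^2; \code{NULL} (default)
#'   uses 25 percent of the median region area of the frame.
#' @param watershedExt neighbourhood radius for watershed seed detection
#'   (default 3 px); \code{tolerance} is the minimum seed depth.
#' @param tolerance watershed tolerance (default 1).
#' @return A [LabelMovie-class] whose regions carry per-frame label, area
#'   and centroid; no retained label touches an X-Y border.
#' @export
segmentNuclei <- function(proj, channel = 1L, clipQuantile = 0.995,
                          clipThreshold = NULL, replacement = NULL,
                          blurSigma = 2, dilationRadius = 2, minArea = NULL,
                          watershedExt = 3, tolerance = 1) {
  stopifnot(is(proj, "Projection"))
  ci <- channelIndex(proj, channel)
  nT <- nFrames(proj)
  d <- dim(proj@data)
  labArr <- array(0L, c(nT, d[3L], d[4L]))
  regions <- vector("list", nT)
  brush <- EBImage::makeBrush(2L * as.integer(dilationRadius) + 1L, "disc")
  for (t in seq_len(nT)) {
    img <- proj@data[t, ci, , ]
    img <- .autoClip(img, clipQuantile, clipThreshold, replacement)
    b <- .gaussSmooth(img, blurSigma)
    thr <- tryCatch(otsuThreshold(b),
                    error = function(e) stop("frame ", t, ": ",
                                             conditionMessage(e)))
    bin <- b > thr
    if (dilationRadius > 0)
      bin <- EBImage::dilate(bin * 1, brush) > 0
    dm <- EBImage::distmap(bin * 1)
    lab <- EBImage::watershed(dm, tolerance = tolerance, ext = watershedExt)
    lab <- array(as.integer(lab), dim(lab))
    st <- .regionStats(lab)
    if (nrow(st)) {
      cut <- if (is.null(minArea)) 0.25 * median(st$area) else minArea
      keep <- st$label[st$area >= cut & !st$onBorder]
      relab <- integer(max(st$label) + 1L)
      relab[keep + 1L] <- seq_along(keep)
      lab <- array(relab[lab + 1L], dim(lab))
      st <- .regionStats(lab)
    }
    labArr[t, , ] <- lab
    if (nrow(st))
      regions[[t]] <- cbind(frame = t, st[, c("label", "area", "cy", "cx")])
  }
  regions <- do.call(rbind, regions[!vapply(regions, is.null, logical(1))])
  if (is.null(regions))
    regions <- data.frame(frame = integer(0), label = integer(0),
                          area = integer(0), cy = numeric(0), cx = numeric(0))
  new("LabelMovie", data = labArr, regions = regions,
      params = list(channel = ci, clipQuantile = clipQuantile,
                    blurSigma = blurSigma, dilationRadius = dilationRadius,
                    minArea = minArea, watershedExt = watershedExt,
                    tolerance = tolerance))
}
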