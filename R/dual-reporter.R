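#' Detect transcription spots by Difference of Gaussians
#'
#' Per frame: sum the two reporter channels (so a spot visible in either
#' channel is found), Gaussian-blur, compute the DoG response
#' (narrow-sigma smooth minus wide-sigma smooth) and keep strict local
#' maxima above \code{threshold}.
#'
#' @param proj a [Projection-class].
#' @param channels the two reporter channels (names or indices).
#' @param blurSigma pre-blur sigma in pixels (default 1).
#' @param dogSigmas increasing pair of DoG sigmas in pixels (default 1.5, 3).
#' @param threshold minimum DoG response.
#' @return data.frame with columns \code{frame, y, x, response}.
#' @export
detectSpotsDog <- function(proj, channels = c(1L, 2L), blurSigma = 1,
                           dogSigmas = c(1.5, 3), threshold = 0.5) {
  stopifnot(is(proj, "Projection"))
  if (length(dogSigmas) != 2L || dogSigmas[1L] >= dogSigmas[2L])
    stop("dogSigmas must be an increasing pair")
  i1 <- channelIndex(proj, channels[[1L]])
  i2 <- channelIndex(proj, channels[[2L]])
  out <- vector("list", nFrames(proj))
  for (t in seq_len(nFrames(proj))) {
    s <- proj@data[t, i1, , ] + proj@data[t, i2, , ]
    s <- .gaussSmooth(s, blurSigma)
    dog <- .gaussSmooth(s, dogSigmas[1L]) - .gaussSmooth(s, dogSigmas[2L])
    pk <- .localMaxima(dog, threshold)
    if (nrow(pk))
      out[[t]] <- data.frame(frame = t, y = as.integer(pk[, "y"]),
                             x = as.integer(pk[, "x"]), response = dog[pk])
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(frame = integer(0), y = integer(0), x = integer(0),
                      response = numeric(0))
  rownames(out) <- NULL
  out
}

#' Quantify a spot with local background correction
#'
#' Raw intensity is the mean of the \code{inner} x \code{inner} square
#' centred on the spot. Background is the mean of the surrounding
#' \code{outer} x \code{outer} square, by default excluding the inner
#' square (annulus policy, so spot signal does not contaminate its own
#' background); \code{policy = "full"} uses the whole outer square.
#' Corrected = raw - background (may be negative). When the outer window
#' does not fit inside the image, the spot is flagged border-touching and
#' intensities are NA.
#'
#' @param image numeric matrix (y, x).
#' @param y,x spot centre (1-based pixel indices).
#' @param inner,outer odd window sides in pixels (defaults 17 and 31).
#' @param policy \code{"annulus"} (default) or \code{"full"}.
#' @return A one-row data.frame:
#'   \code{raw, background, corrected, border} (logical).
#' @export
quantifySpot <- function(image, y, x, inner = 17L, outer = 31L,
                         policy = c("annulus", "full")) {
  policy <- match.arg(policy)
  if (inner %% 2L != 1L || outer %% 2L != 1L || outer <= inner)
    stop("inner and outer must be odd with outer > inner")
  hI <- (inner - 1L) %/% 2L; hO <- (outer - 1L) %/% 2L
  ny <- nrow(image); nx <- ncol(image)
  y <- as.integer(round(y)); x <- as.integer(round(x))
  if (y - hO < 1L || y + hO > ny || x - hO < 1L || x + hO > nx)
    return(data.frame(raw = NA_real_, background = NA_real_,
                      corrected = NA_real_, border = TRUE))
  innerPx <- image[(y - hI):(y + hI), (x - hI):(x + hI)]
  outerPx <- image[(y - hO):(y + hO), (x - hO):(x + hO)]
  raw <- mean(innerPx)
  bg <- if (policy == "annulus")
    (sum(outerPx) - sum(innerPx)) / (length(outerPx) - length(innerPx))
  else mean(outerPx)
  data.frame(raw = raw, background = bg, corrected = raw - bg, border = FALSE)
}

#' Link spot detections into tracks with gap closing
#'
#' Greedy nearest-neighbour linking: at each frame, detections are matched
#' to the nearest live track end within \code{maxDisplacement} pixels; a
#' track stays alive through up to \code{maxGap} consecutive frames with
#' no detection (a gap of exactly \code{maxGap} is bridged, one more
#' splits the track). Positions during gaps are not interpolated.
#' Unmatched detections start new tracks.
#'
#' @param detections data.frame with columns \code{frame, y, x} (sorted or
#'   not; sorted internally by frame).
#' @param maxDisplacement maximum link distance in pixels.
#' @param maxGap maximum bridged gap in frames (default 5).
#' @return \code{detections} with an added integer \code{track} column,
#'   ordered by track then frame.
#' @export
linkSpots <- function(detections, maxDisplacement, maxGap = 5L) {
  det <- detections[order(detections$frame), , drop = FALSE]
  n <- nrow(det)
  det$track <- rep(NA_integer_, n)
  if (!n) return(det)
  lastFrame <- integer(0); lastY <- numeric(0); lastX <- numeric(0)
  rowOfTrack <- list()
  nTracks <- 0L
  for (f in sort(unique(det$frame))) {
    idx <- which(det$frame == f)
    live <- which(lastFrame >= f - maxGap - 1L & lastFrame < f)
    m <- .greedyMatch(lastY[live], lastX[live], det$y[idx], det$x[idx],
                      maxDisplacement)
    for (k in seq_along(live)) {
      if (is.na(m[k])) next
      tr <- live[k]; row <- idx[m[k]]
      det$track[row] <- tr
      lastFrame[tr] <- f; lastY[tr] <- det$y[row]; lastX[tr] <- det$x[row]
    }
    for (row in idx[is.na(det$track[idx])]) {
      nTracks <- nTracks + 1L
      det$track[row] <- nTracks
      lastFrame[nTracks] <- f
      lastY[nTracks] <- det$y[row]; lastX[nTracks] <- det$x[row]
    }
  }
  det <- det[order(det$track, det$frame), , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Quantify every detection of every track in both channels
#'
#' Applies [quantifySpot()] at each tracked detection in each of the two
#' reporter channels and summarises tracks: first appearance and the total
#' (summed) corrected 3'-channel intensity.
#'
#' @param proj a [Projection-class].
#' @param tracks output of [linkSpots()].
#' @param channels the two reporter channels, 5' first, 3' second.
#' @inheritParams quantifySpot
#' @return A list: \code{perFrame} (track, frame, y, x, per-channel raw /
#'   background / corrected, border flag) and \code{summary} (track,
#'   firstAppearance, nFrames, anyBorder, totalPcp).
#' @export
quantifyTracks <- function(proj, tracks, channels = c("mcp", "pcp"),
                           inner = 17L, outer = 31L,
                           policy = c("annulus", "full")) {
  policy <- match.arg(policy)
  i5 <- channelIndex(proj, channels[[1L]])
  i3 <- channelIndex(proj, channels[[2L]])
  n <- nrow(tracks)
  pf <- data.frame(track = tracks$track, frame = tracks$frame,
                   y = tracks$y, x = tracks$x,
                   raw5 = NA_real_, bg5 = NA_real_, corr5 = NA_real_,
                   raw3 = NA_real_, bg3 = NA_real_, corr3 = NA_real_,
                   border = FALSE)
  for (k in seq_len(n)) {
    img5 <- proj@data[pf$frame[k], i5, , ]
    img3 <- proj@data[pf$frame[k], i3, , ]
    q5 <- quantifySpot(img5, pf$y[k], pf$x[k], inner, outer, policy)
    q3 <- quantifySpot(img3, pf$y[k], pf$x[k], inner, outer, policy)
    pf$raw5[k] <- q5$raw; pf$bg5[k] <- q5$background; pf$corr5[k] <- q5$corrected
    pf$raw3[k] <- q3$raw; pf$bg3[k] <- q3$background; pf$corr3[k] <- q3$corrected
    pf$border[k] <- q5$border || q3$border
  }
  summ <- do.call(rbind, lapply(split(pf, pf$track), function(g)
    data.frame(track = g$track[1L], firstAppearance = min(g$frame),
               nFrames = nrow(g), anyBorder = any(g$border),
               totalPcp = sum(g$corr3, na.rm = TRUE))))
  rownames(summ) <- NULL
  list(perFrame = pf, summary = summ)
}

#' Filter spot tracks
#'
#' Drops tracks that appear in only a single frame and tracks with any
#' border-touching quantification window.
#'
#' @param quant output of [quantifyTracks()].
#' @return The same structure with offending tracks removed.
#' @export
filterTracks <- function(quant) {
  keep <- quant$summary$track[quant$summary$nFrames > 1L &
                              !quant$summary$anyBorder]
  list(perFrame = quant$perFrame[quant$perFrame$track %in% keep, ,
                                 drop = FALSE],
       summary = quant$summary[quant$summary$track %in% keep, , drop = FALSE])
}

#' Sort spot tracks
#'
#' Stable sort by time of first appearance (ascending), breaking ties by
#' total corrected 3'-channel intensity (descending, brightest first).
#'
#' @param summary the \code{summary} element of [quantifyTracks()] output.
#' @return The summary reordered; row order defines montage row order.
#' @export
sortTracks <- function(summary) {
  out <- summary[order(summary$firstAppearance, -summary$totalPcp), ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a track-by-time montage for one channel
#'
#' For the first \code{nTracks} sorted tracks, a \code{tile} x \code{tile}
#' crop is placed at (row = track, column = frame); the crop is centred on
#' the track's position at that frame, or its last known position during
#' gaps and after the last detection. Tiles before a track's first
#' appearance are blank. Column 1 is anchored at the earliest first
#' appearance over all supplied tracks.
#'
#' @param proj a [Projection-class].
#' @param perFrame the \code{perFrame} element of [quantifyTracks()] output.
#' @param sortedSummary output of [sortTracks()].
#' @param channel channel name or index to render.
#' @param nTracks number of top tracks (default 50, clamped to available).
#' @param frames frames to render as columns; default: anchor to movie end.
#' @param tile odd tile side in pixels (default 17).
#' @return Numeric matrix of size \code{(nTracks * tile) x (nFrames * tile)}.
#' @export
buildMontage <- function(proj, perFrame, sortedSummary, channel,
                         nTracks = 50L, frames = NULL, tile = 17L) {
  stopifnot(is(proj, "Projection"))
  ci <- channelIndex(proj, channel)
  nTracks <- min(nTracks, nrow(sortedSummary))
  ids <- sortedSummary$track[seq_len(nTracks)]
  if (is.null(frames)) {
    anchor <- min(sortedSummary$firstAppearance)
    frames <- anchor:nFrames(proj)
  }
  h <- (tile - 1L) %/% 2L
  M <- matrix(0, nTracks * tile, length(frames) * tile)
  for (r in seq_len(nTracks)) {
    g <- perFrame[perFrame$track == ids[r], , drop = FALSE]
    g <- g[order(g$frame), ]
    for (j in seq_along(frames)) {
      f <- frames[j]
      known <- g[g$frame <= f, , drop = FALSE]
      if (!nrow(known)) next  # blank before first appearance
      y <- as.integer(round(known$y[nrow(known)]))
      x <- as.integer(round(known$x[nrow(known)]))
      img <- proj@data[f, ci, , ]
      if (y - h < 1L || y + h > nrow(img) || x - h < 1L || x + h > ncol(img))
        next
      crop <- img[(y - h):(y + h), (x - h):(x + h)]
      M[((r - 1L) * tile + 1L):(r * tile),
        ((j - 1L) * tile + 1L):(j * tile)] <- crop
    }
  }
  M
}
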