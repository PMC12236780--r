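# greedy one-to-one assignment between two point sets by increasing
# distance, capped at maxDist; returns integer index into (yB, xB) per A
# point, NA when unmatched
.greedyMatch <- function(yA, xA, yB, xB, maxDist) {
  nA <- length(yA); nB <- length(yB)
  out <- rep(NA_integer_, nA)
  if (nA == 0L || nB == 0L) return(out)
  dd <- sqrt(outer(yA, yB, "-")^2 + outer(xA, xB, "-")^2)
  dd[dd > maxDist] <- NA
  repeat {
    if (all(is.na(dd))) break
    k <- arrayInd(which.min(dd), dim(dd))
    out[k[1L]] <- k[2L]
    dd[k[1L], ] <- NA
    dd[, k[2L]] <- NA
  }
  out
}

#' Track nuclei across frames
#'
#' Frame-to-frame greedy nearest-centroid linking of the regions of a
#' [LabelMovie-class], capped at \code{maxDisplacement} pixels per frame.
#' Only tracks present in every frame are retained; nuclei that appear,
#' disappear or are born mid-movie are discarded so that every retained
#' state series covers the full movie.
#'
#' @param labels a [LabelMovie-class].
#' @param maxDisplacement maximum centroid displacement per frame (px).
#' @return data.frame with columns \code{track, frame, label, y, x}, one
#'   row per retained track per frame (possibly zero rows).
#' @export
linkNuclei <- function(labels, maxDisplacement) {
  stopifnot(is(labels, "LabelMovie"))
  nT <- nFrames(labels)
  reg <- labels@regions
  if (!nrow(reg))
    return(data.frame(track = integer(0), frame = integer(0),
                      label = integer(0), y = numeric(0), x = numeric(0)))
  rows <- vector("list", nT)
  r1 <- reg[reg$frame == 1L, ]
  nTracks <- nrow(r1)
  if (nTracks == 0L)
    return(data.frame(track = integer(0), frame = integer(0),
                      label = integer(0), y = numeric(0), x = numeric(0)))
  cur <- data.frame(track = seq_len(nTracks), label = r1$label,
                    y = r1$cy, x = r1$cx)
  rows[[1L]] <- cbind(frame = 1L, cur)
  alive <- cur
  for (t in seq_len(nT)[-1L]) {
    rt <- reg[reg$frame == t, ]
    m <- .greedyMatch(alive$y, alive$x, rt$cy, rt$cx, maxDisplacement)
    matched <- !is.na(m)
    nxt <- data.frame(track = alive$track[matched],
                      label = rt$label[m[matched]],
                      y = rt$cy[m[matched]], x = rt$cx[m[matched]])
    # unmatched detections start new (necessarily incomplete) tracks
    newIdx <- setdiff(seq_len(nrow(rt)), m[matched])
    if (length(newIdx)) {
      newTr <- data.frame(track = nTracks + seq_along(newIdx),
                          label = rt$label[newIdx],
                          y = rt$cy[newIdx], x = rt$cx[newIdx])
      nTracks <- nTracks + length(newIdx)
      nxt <- rbind(nxt, newTr)
    }
    rows[[t]] <- cbind(frame = t, nxt)
    alive <- nxt
  }
  all <- do.call(rbind, rows)
  counts <- table(all$track)
  complete <- as.integer(names(counts)[counts == nT])
  out <- all[all$track %in% complete, c("track", "frame", "label", "y", "x")]
  out <- out[order(out$track, out$frame), ]
  rownames(out) <- NULL
  out
}

#' Detect foci by Laplacian of Gaussian
#'
#' Scale-normalized LoG blob detection on a single 2-D image: the
#' response is computed at each sigma in \code{sigmas}, the per-pixel best
#' scale is kept, and strict 8-neighbour local maxima of the best-scale
#' response above \code{threshold} become detections.
#'
#' @param image numeric matrix (y, x).
#' @param sigmas blob scales (pixels) to probe; default \code{seq(1.5, 4, 0.5)}.
#' @param threshold minimum detector response (same units as intensity;
#'   for a Gaussian blob of matched scale the peak response is about half
#'   the blob's peak amplitude).
#' @return data.frame with columns \code{y, x, sigma, response}.
#' @export
detectFociLog <- function(image, sigmas = seq(1.5, 4, by = 0.5),
                          threshold = 0.5) {
  if (!length(sigmas)) stop("sigmas must be non-empty")
  best <- matrix(-Inf, nrow(image), ncol(image))
  bestS <- matrix(sigmas[1L], nrow(image), ncol(image))
  for (s in sigmas) {
    r <- .convolve2(image, .logKernel(s))
    upd <- r > best
    best[upd] <- r[upd]
    bestS[upd] <- s
  }
  pk <- .localMaxima(best, threshold)
  data.frame(y = as.integer(pk[, "y"]), x = as.integer(pk[, "x"]),
             sigma = bestS[pk], response = best[pk])
}

#' Assign foci to nuclei
#'
#' Each focus takes the label of the (pre-dilated) nucleus containing its
#' coordinates; foci on background get \code{NA}.
#'
#' @param foci data.frame with columns \code{frame, y, x} (e.g. pooled
#'   [detectFociLog()] output with a \code{frame} column added).
#' @param labels a [LabelMovie-class].
#' @return \code{foci} with an added integer \code{nucleus} column
#'   (NA = unassigned).
#' @export
assignFoci <- function(foci, labels) {
  stopifnot(is(labels, "LabelMovie"))
  if (!nrow(foci)) {
    foci$nucleus <- integer(0)
    return(foci)
  }
  d <- dim(labels@data)
  yy <- pmin(pmax(as.integer(round(foci$y)), 1L), d[2L])
  xx <- pmin(pmax(as.integer(round(foci$x)), 1L), d[3L])
  lab <- labels@data[cbind(foci$frame, yy, xx)]
  foci$nucleus <- ifelse(lab > 0L, lab, NA_integer_)
  foci
}

#' Call per-nucleus ON/OFF transcription states
#'
#' A nucleus is ON at a frame when at least one focus is assigned to it.
#' \code{firstOn} is the first ON frame; \code{firstOffAfterOn} is the
#' first frame of the first run of at least \code{debounce} consecutive
#' OFF frames after \code{firstOn}. With the default \code{debounce = 1}
#' any single dark frame after activation counts as an OFF transition.
#'
#' @param tracks complete nucleus tracks from [linkNuclei()].
#' @param assignedFoci output of [assignFoci()] (only rows with a
#'   non-NA nucleus are used).
#' @param nFrames total frame count of the movie.
#' @param debounce minimum OFF run length in frames (default 1).
#' @return A [StateTraces-class].
#' @export
callStates <- function(tracks, assignedFoci, nFrames, debounce = 1L) {
  trackIds <- sort(unique(tracks$track))
  on <- matrix(FALSE, length(trackIds), nFrames,
               dimnames = list(trackIds, NULL))
  af <- assignedFoci[!is.na(assignedFoci$nucleus), , drop = FALSE]
  if (nrow(af)) {
    key <- paste(tracks$frame, tracks$label)
    trackOfKey <- setNames(tracks$track, key)
    hit <- trackOfKey[paste(af$frame, af$nucleus)]
    ok <- !is.na(hit)
    if (any(ok))
      on[cbind(match(hit[ok], trackIds), af$frame[ok])] <- TRUE
  }
  summ <- data.frame(track = trackIds, firstOn = NA_integer_,
                     firstOffAfterOn = NA_integer_)
  for (i in seq_along(trackIds)) {
    v <- on[i, ]
    fo <- which(v)[1L]
    if (is.na(fo)) next
    summ$firstOn[i] <- fo
    if (fo < nFrames) {
      run <- 0L
      for (t in (fo + 1L):nFrames) {
        if (!v[t]) {
          run <- run + 1L
          if (run >= debounce) {
            summ$firstOffAfterOn[i] <- t - run + 1L
            break
          }
        } else run <- 0L
      }
    }
  }
  new("StateTraces", on = on, summary = summ)
}

#' Cumulative ON / OFF transition curves
#'
#' For each frame from \code{sStart} to \code{endFrame}, the percentage of
#' retained nuclei whose first ON (respectively first OFF-after-ON)
#' transition has occurred by that frame. Denominators are all retained
#' nuclei, so both curves are nondecreasing, bounded by 100, and the OFF
#' curve never exceeds the ON curve.
#'
#' @param traces a [StateTraces-class].
#' @param sStart 1-based frame of S-phase entry (time origin).
#' @param endFrame last frame of the curve (default: last state frame).
#' @param frameInterval seconds per frame, for the time column (default 20).
#' @return data.frame with columns \code{frame, timeSec, onPct, offPct}.
#' @export
cumulativeTransitions <- function(traces, sStart, endFrame = NULL,
                                  frameInterval = 20) {
  stopifnot(is(traces, "StateTraces"))
  s <- traces@summary
  if (!nrow(s)) stop("no nucleus traces")
  nF <- ncol(traces@on)
  if (is.null(endFrame)) endFrame <- nF
  frames <- sStart:endFrame
  onPct <- vapply(frames, function(t)
    100 * mean(!is.na(s$firstOn) & s$firstOn <= t), numeric(1))
  offPct <- vapply(frames, function(t)
    100 * mean(!is.na(s$firstOffAfterOn) & s$firstOffAfterOn <= t), numeric(1))
  data.frame(frame = frames, timeSec = (frames - sStart) * frameInterval,
             onPct = onPct, offPct = offPct)
}
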