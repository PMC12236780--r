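#' Per-frame statistic of masked intensities
#'
#' For each frame, the mean or population variance (divide by N) of the
#' pixels of one channel lying inside the frame's mask. Pixels outside the
#' mask never influence the result.
#'
#' @param proj a [Projection-class].
#' @param masks a [MaskMovie-class] aligned with \code{proj}.
#' @param channel channel name or index.
#' @param statistic \code{"mean"} or \code{"variance"}.
#' @return An [IntensitySeries-class].
#' @export
maskedStats <- function(proj, masks, channel = 1L,
                        statistic = c("mean", "variance")) {
  statistic <- match.arg(statistic)
  stopifnot(is(proj, "Projection"), is(masks, "MaskMovie"))
  ci <- channelIndex(proj, channel)
  nT <- nFrames(proj)
  if (nFrames(masks) != nT) stop("mask and projection frame counts differ")
  vals <- numeric(nT)
  for (t in seq_len(nT)) {
    px <- proj@data[t, ci, , ][masks@data[t, , ]]
    if (!length(px)) stop("frame ", t, ": empty mask")
    vals[t] <- if (statistic == "mean") mean(px) else mean((px - mean(px))^2)
  }
  new("IntensitySeries", values = vals, statistic = statistic,
      channel = as.character(channelNames(proj)[ci]),
      times = (seq_len(nT) - 1L) * proj@frameInterval)
}

#' Detect the recruitment onset of an intensity series
#'
#' First frame at which the series reaches
#' \code{min + riseFraction * (max - min)}: a deterministic surrogate for
#' the visually scored start of kinase recruitment at mitotic exit. A
#' manual frame override is accepted wherever an onset is consumed.
#'
#' @param series an [IntensitySeries-class] or numeric vector.
#' @param riseFraction fraction of the dynamic range (default 0.2).
#' @return 1-based frame index.
#' @export
detectRecruitmentOnset <- function(series, riseFraction = 0.2) {
  v <- if (is(series, "IntensitySeries")) series@values else series
  if (max(v) <= min(v))
    stop("series is constant; onset is undefined")
  thr <- min(v) + riseFraction * (max(v) - min(v))
  which(v >= thr)[1L]
}

#' Peak of a series in a fixed window after onset
#'
#' Maximum of the series over \code{floor(windowSeconds / frameInterval)}
#' frames starting at \code{onset} (window clipped to the series end). The
#' default 120 s window captures the burst of hub intensity at S-phase
#' entry.
#'
#' @param series an [IntensitySeries-class] or numeric vector.
#' @param onset 1-based onset frame.
#' @param windowSeconds window length in seconds (default 120).
#' @param frameInterval frame spacing in seconds; taken from the series
#'   when it is an [IntensitySeries-class].
#' @return A one-row data.frame: \code{peak, start, end, statistic, channel}.
#' @export
peakInWindow <- function(series, onset, windowSeconds = 120,
                         frameInterval = NULL) {
  if (is(series, "IntensitySeries")) {
    v <- series@values
    if (is.null(frameInterval))
      frameInterval <- diff(series@times[1:2])
    stat <- series@statistic; chan <- series@channel
  } else {
    v <- series
    if (is.null(frameInterval)) stop("frameInterval required for a bare vector")
    stat <- NA_character_; chan <- NA_character_
  }
  n <- length(v)
  if (onset < 1L || onset > n) stop("onset out of range")
  nw <- max(1L, as.integer(floor(windowSeconds / frameInterval)))
  end <- min(n, onset + nw - 1L)
  data.frame(peak = max(v[onset:end]), start = as.integer(onset),
             end = as.integer(end), statistic = stat, channel = chan)
}

#' Per-nucleus intensities from a labelled segmentation
#'
#' One row per (frame, nucleus label): the mean or the brightest pixel of
#' the channel inside that label. The per-nucleus maximum serves as a
#' proxy for protein clustering; values are pooled across embryos by the
#' caller.
#'
#' @param proj a [Projection-class].
#' @param labels a [LabelMovie-class] aligned with \code{proj}.
#' @param channel channel name or index.
#' @param statistic \code{"mean"} or \code{"max"}.
#' @return data.frame with columns \code{frame, nucleus, value}.
#' @export
perNucleusIntensities <- function(proj, labels, channel = 1L,
                                  statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  stopifnot(is(proj, "Projection"), is(labels, "LabelMovie"))
  ci <- channelIndex(proj, channel)
  dP <- dim(proj@data); dL <- dim(labels@data)
  if (!identical(dP[c(1L, 3L, 4L)], dL))
    stop("label and projection shapes differ")
  out <- vector("list", dP[1L])
  for (t in seq_len(dP[1L])) {
    lab <- labels@data[t, , ]
    labs <- sort(unique(lab[lab > 0L]))
    if (!length(labs)) next
    img <- proj@data[t, ci, , ]
    f <- factor(lab[lab > 0L], levels = labs)
    v <- if (statistic == "mean") tapply(img[lab > 0L], f, mean)
         else tapply(img[lab > 0L], f, max)
    out[[t]] <- data.frame(frame = t, nucleus = labs, value = as.numeric(v))
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(frame = integer(0), nucleus = integer(0),
                      value = numeric(0))
  rownames(out) <- NULL
  out
}
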