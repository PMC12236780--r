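# Shared fixtures and independent oracles, all built in code.

# small noiseless two-nucleus single-frame projection with known geometry
twoDiskProjection <- function(centers = rbind(c(20, 20), c(20, 44)),
                              r = 8, amp = 2, baseline = 0.2,
                              ny = 64, nx = 64, nChan = 1,
                              channelNames = paste0("ch", seq_len(nChan)),
                              focus = NULL) {
  img <- matrix(baseline, ny, nx)
  for (k in seq_len(nrow(centers))) {
    d <- sqrt(outer((seq_len(ny) - centers[k, 1])^2,
                    (seq_len(nx) - centers[k, 2])^2, "+"))
    img <- img + amp / (1 + exp(-(r - d)))
  }
  if (!is.null(focus))
    img <- img + focus$amp * exp(-(outer((seq_len(ny) - focus$y)^2,
                                         (seq_len(nx) - focus$x)^2,
                                         "+")) / (2 * focus$sigma^2))
  d <- array(0, c(1, nChan, ny, nx))
  for (ci in seq_len(nChan)) d[1, ci, , ] <- img
  new("Projection", data = d, method = "max", provenance = "fixture",
      frameInterval = 20, pixelSize = 0.2, channelNames = channelNames)
}

# ground-truth pixel mask of ideal disks (no smoothing), for coverage checks
diskTruthMask <- function(centers, r, ny = 64, nx = 64) {
  m <- matrix(FALSE, ny, nx)
  for (k in seq_len(nrow(centers))) {
    d <- sqrt(outer((seq_len(ny) - centers[k, 1])^2,
                    (seq_len(nx) - centers[k, 2])^2, "+"))
    m <- m | (d <= r)
  }
  m
}

# brute-force Otsu: try every histogram cut, compute the two class
# variances from the binned values directly
otsuOracle <- function(image, nBins = 256L) {
  v <- as.numeric(image)
  breaks <- seq(min(v), max(v), length.out = nBins + 1L)
  bin <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L),
              nBins)
  mids <- (breaks[-1L] + breaks[-(nBins + 1L)]) / 2
  best <- -Inf; bestK <- NA
  for (k in seq_len(nBins - 1L)) {
    in0 <- bin <= k
    n0 <- sum(in0); n1 <- length(v) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- mean(mids[bin[in0]]); mu1 <- mean(mids[bin[!in0]])
    sB <- n0 * n1 * (mu0 - mu1)^2 / length(v)^2
    if (sB > best) { best <- sB; bestK <- k }
  }
  breaks[bestK + 1L]
}

# direct kernel sum at one pixel with index clamping (replicate border),
# the boundary rule used by the package's convolutions
directConvAt <- function(image, kernel, y, x) {
  r <- (nrow(kernel) - 1L) %/% 2L
  acc <- 0
  for (dy in -r:r) for (dx in -r:r) {
    yy <- min(max(y + dy, 1L), nrow(image))
    xx <- min(max(x + dx, 1L), ncol(image))
    acc <- acc + image[yy, xx] * kernel[dy + r + 1L, dx + r + 1L]
  }
  acc
}

# truncated normalized Gaussian kernel identical in spec to the package's
gaussKernelOracle <- function(sigma) {
  radius <- ceiling(3 * sigma)
  ax <- -radius:radius
  k <- outer(exp(-ax^2 / (2 * sigma^2)), exp(-ax^2 / (2 * sigma^2)))
  k / sum(k)
}

# brute-force grayscale opening (erosion then dilation) with a disc SE,
# ignoring out-of-image positions
openingOracle <- function(img, radius) {
  side <- 2L * as.integer(ceiling(radius)) + 1L
  brush <- EBImage::makeBrush(side, "disc")
  r <- (side - 1L) %/% 2L
  se <- which(brush == 1, arr.ind = TRUE) - (r + 1L)
  ny <- nrow(img); nx <- ncol(img)
  ero <- matrix(NA_real_, ny, nx); dil <- matrix(NA_real_, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    ys <- i + se[, 1L]; xs <- j + se[, 2L]
    ok <- ys >= 1 & ys <= ny & xs >= 1 & xs <= nx
    ero[i, j] <- min(img[cbind(ys[ok], xs[ok])])
  }
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    ys <- i + se[, 1L]; xs <- j + se[, 2L]
    ok <- ys >= 1 & ys <= ny & xs >= 1 & xs <= nx
    dil[i, j] <- max(ero[cbind(ys[ok], xs[ok])])
  }
  dil
}

# exact two-sided Mann-Whitney p by direct enumeration: U computed by
# pair counting (greater + half ties), not by ranks
mwuEnumOracle <- function(x, y) {
  uPairs <- function(a, b) {
    u <- 0
    for (ai in a) for (bj in b) u <- u + (ai > bj) + 0.5 * (ai == bj)
    u
  }
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  u <- uPairs(x, y)
  sets <- utils::combn(n, nx)
  uAll <- apply(sets, 2, function(ix) uPairs(pooled[ix], pooled[-ix]))
  eps <- 1e-9
  min(1, 2 * min(mean(uAll <= u + eps), mean(uAll >= u - eps)))
}

# hand-built LabelMovie from a list of per-frame label matrices
labelMovieFromList <- function(mats) {
  nT <- length(mats)
  arr <- array(0L, c(nT, nrow(mats[[1]]), ncol(mats[[1]])))
  regions <- list()
  for (t in seq_len(nT)) {
    arr[t, , ] <- mats[[t]]
    labs <- sort(unique(mats[[t]][mats[[t]] > 0]))
    for (l in labs) {
      idx <- which(mats[[t]] == l, arr.ind = TRUE)
      regions[[length(regions) + 1]] <- data.frame(
        frame = t, label = l, area = nrow(idx),
        cy = mean(idx[, 1]), cx = mean(idx[, 2]))
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions)
    else data.frame(frame = integer(0), label = integer(0),
                    area = integer(0), cy = numeric(0), cx = numeric(0))
  new("LabelMovie", data = arr, regions = regions, params = list())
}

# per-track 3'-minus-5' onset lag in frames: the 5' onset is the track's
# first appearance (tracks are seeded by the 5' spot); the 3' onset is the
# first mid-range crossing of the corrected 3' intensity. Tracks whose 3'
# signal never develops (range below minRange) give NA.
recoveredLags <- function(perFrame, minRange = 0.08) {
  vapply(split(perFrame, perFrame$track), function(g) {
    g <- g[order(g$frame), ]
    v <- g$corr3
    if (max(v) - min(v) < minRange) return(NA_real_)
    thr <- (max(v) + min(v)) / 2
    g$frame[which(v >= thr)[1]] - g$frame[1]
  }, numeric(1))
}

# StateTraces built directly from transition frames
tracesFromSummary <- function(firstOn, firstOff, nFrames) {
  n <- length(firstOn)
  on <- matrix(FALSE, n, nFrames)
  for (i in seq_len(n)) {
    if (is.na(firstOn[i])) next
    end <- if (is.na(firstOff[i])) nFrames else firstOff[i] - 1L
    on[i, firstOn[i]:end] <- TRUE
  }
  new("StateTraces", on = on,
      summary = data.frame(track = seq_len(n),
                           firstOn = as.integer(firstOn),
                           firstOffAfterOn = as.integer(firstOff)))
}
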