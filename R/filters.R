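# Shared convolution helpers. All spot detectors in the package go through
# these so that test oracles (direct kernel sums with replicated borders)
# see exactly the same boundary handling.

.gaussKernel <- function(sigma, radius = ceiling(3 * sigma)) {
  ax <- -radius:radius
  g <- exp(-ax^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# scale-normalized negative Laplacian-of-Gaussian: positive response on
# bright blobs, peak response at sigma matching the blob scale
.logKernel <- function(sigma, radius = ceiling(4 * sigma)) {
  ax <- -radius:radius
  r2 <- outer(ax^2, ax^2, "+")
  g <- exp(-r2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- -sigma^2 * (r2 - 2 * sigma^2) / sigma^4 * g
  k - mean(k)  # zero net response on flat regions
}

.convolve2 <- function(image, kernel) {
  # filter2 requires the kernel to fit inside the image; crop centrally
  # (kernel tails are negligible at these scales)
  kr <- (nrow(kernel) - 1L) %/% 2L
  maxR <- (min(dim(image)) - 1L) %/% 2L
  if (kr > maxR) {
    keep <- (kr + 1L - maxR):(kr + 1L + maxR)
    kernel <- kernel[keep, keep]
  }
  EBImage::filter2(image, kernel, boundary = "replicate")
}

.gaussSmooth <- function(image, sigma) {
  if (sigma <= 0) return(image)
  .convolve2(image, .gaussKernel(sigma))
}

# strict 8-neighbour local maxima of a response image, returned as a
# two-column (y, x) index matrix; border pixels are never maxima
.localMaxima <- function(resp, threshold) {
  ny <- nrow(resp); nx <- ncol(resp)
  if (ny < 3L || nx < 3L) return(cbind(y = integer(0), x = integer(0)))
  ci <- 2L:(ny - 1L); cj <- 2L:(nx - 1L)
  c0 <- resp[ci, cj]
  isMax <- c0 > threshold &
    c0 > resp[ci - 1L, cj - 1L] & c0 > resp[ci - 1L, cj] &
    c0 > resp[ci - 1L, cj + 1L] & c0 > resp[ci, cj - 1L] &
    c0 > resp[ci, cj + 1L] & c0 > resp[ci + 1L, cj - 1L] &
    c0 > resp[ci + 1L, cj] & c0 > resp[ci + 1L, cj + 1L]
  w <- which(isMax, arr.ind = TRUE)
  cbind(y = w[, 1L] + 1L, x = w[, 2L] + 1L)
}
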