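spotProjection <- function(spots5 = NULL, spots3 = NULL, nT = 1,
                           ny = 64, nx = 64, baseline = 0) {
  d <- array(baseline, c(nT, 2, ny, nx))
  addTo <- function(ci, sp) {
    for (k in seq_len(nrow(sp))) {
      d2 <- outer((seq_len(ny) - sp$y[k])^2, (seq_len(nx) - sp$x[k])^2, "+")
      d[sp$t[k], ci, , ] <<- d[sp$t[k], ci, , ] +
        sp$amp[k] * exp(-d2 / (2 * sp$sigma[k]^2))
    }
  }
  if (!is.null(spots5)) addTo(1, spots5)
  if (!is.null(spots3)) addTo(2, spots3)
  new("Projection", data = d, method = "max", provenance = "fixture",
      frameInterval = 20, pixelSize = 0.2, channelNames = c("mcp", "pcp"))
}

test_that("DoG detection works on the summed channels", {
  # a spot in the 5' channel only is still found (summation rule)
  p <- spotProjection(spots5 = data.frame(t = 1, y = 30, x = 35, amp = 5,
                                          sigma = 2))
  det <- detectSpotsDog(p, c("mcp", "pcp"), threshold = 0.5)
  expect_equal(nrow(det), 1L)
  expect_lte(abs(det$y - 30) + abs(det$x - 35), 2)

  blank <- spotProjection()
  expect_equal(nrow(detectSpotsDog(blank, 1:2, threshold = 0.1)), 0L)
  expect_error(detectSpotsDog(p, 1:2, dogSigmas = c(3, 1.5)), "increasing")
})

test_that("spot quantification matches brute-force window means", {
  flat <- matrix(100, 40, 40)
  q <- quantifySpot(flat, 20, 20)
  expect_equal(q$raw, 100); expect_equal(q$background, 100)
  expect_equal(q$corrected, 0)

  # +50 confined to the inner square leaves the annulus untouched
  boxed <- flat
  boxed[12:28, 12:28] <- 150
  expect_equal(quantifySpot(boxed, 20, 20)$corrected, 50)

  # random image against an explicit double loop
  set.seed(14)
  img <- matrix(runif(40 * 40, 0, 1000), 40, 40)
  q <- quantifySpot(img, 20, 20)
  inner <- 0; outer <- 0
  for (dy in -8:8) for (dx in -8:8) inner <- inner + img[20 + dy, 20 + dx]
  for (dy in -15:15) for (dx in -15:15) outer <- outer + img[20 + dy, 20 + dx]
  expect_equal(q$raw, inner / 289)
  expect_equal(q$background, (outer - inner) / (961 - 289))
  expect_equal(q$corrected, inner / 289 - (outer - inner) / 672)
  qf <- quantifySpot(img, 20, 20, policy = "full")
  expect_equal(qf$background, outer / 961)

  # constant image is zero-corrected under both policies
  expect_equal(quantifySpot(flat, 20, 20, policy = "full")$corrected, 0)

  # window hanging over the edge flags the spot
  expect_true(quantifySpot(img, 5, 20)$border)
  expect_true(is.na(quantifySpot(img, 5, 20)$corrected))
})

test_that("spot linking bridges gaps up to maxGap frames", {
  det <- data.frame(frame = c(1:3, 9:10), y = 20, x = 20)
  one <- linkSpots(det, maxDisplacement = 4, maxGap = 5)
  expect_equal(length(unique(one$track)), 1L)

  det2 <- data.frame(frame = c(1:3, 10), y = 20, x = 20)
  two <- linkSpots(det2, maxDisplacement = 4, maxGap = 5)
  expect_equal(length(unique(two$track)), 2L)
})

test_that("parallel nearby tracks keep their identities", {
  frames <- 1:10
  det <- rbind(
    data.frame(frame = frames, y = 20, x = 10 + frames),
    data.frame(frame = frames, y = 50, x = 10 + frames))
  det <- det[sample(nrow(det)), ]
  linked <- linkSpots(det, maxDisplacement = 10, maxGap = 5)
  expect_equal(length(unique(linked$track)), 2L)
  for (id in unique(linked$track))
    expect_equal(length(unique(linked$y[linked$track == id])), 1L)
  # partition property: every detection belongs to exactly one track
  expect_equal(nrow(linked), 20L)
  expect_false(any(duplicated(linked[, c("frame", "y", "x")])))
})

test_that("track filtering drops singletons and border-touchers", {
  p <- spotProjection(
    spots5 = data.frame(t = c(1, 2, 1, 1, 2), y = c(30, 30, 5, 40, 40),
                        x = c(30, 30, 30, 45, 45), amp = 5, sigma = 2),
    nT = 2)
  det <- detectSpotsDog(p, 1:2, threshold = 0.5)
  linked <- linkSpots(det, 4, 5)
  quant <- quantifyTracks(p, linked)
  filt <- filterTracks(quant)
  # the (5, 30) spot touches the border; (40, 45) appears twice and stays;
  # (30, 30) appears twice and stays
  expect_equal(nrow(filt$summary), 2L)
  expect_true(all(filt$summary$nFrames == 2L))
})

test_that("track sorting is stable with the composite key", {
  s <- data.frame(track = 1:3, firstAppearance = c(2, 1, 1),
                  totalPcp = c(10, 0, 99))
  expect_equal(sortTracks(s)$track, c(3, 2, 1))

  tied <- data.frame(track = 1:4, firstAppearance = 1, totalPcp = 5)
  expect_equal(sortTracks(tied)$track, 1:4)

  set.seed(15)
  r <- data.frame(track = 1:50,
                  firstAppearance = sample(5, 50, replace = TRUE),
                  totalPcp = sample(c(1, 2, 3), 50, replace = TRUE))
  got <- sortTracks(r)$track
  # brute-force comparison sort on the composite key
  key <- order(r$firstAppearance, -r$totalPcp)
  expect_equal(got, r$track[key])
})

test_that("montages tile tracks by rows and time by columns", {
  p <- spotProjection(
    spots5 = data.frame(t = rep(1:3, 2), y = rep(c(25, 45), each = 3),
                        x = rep(c(25, 45), each = 3), amp = 5, sigma = 2),
    nT = 3)
  det <- detectSpotsDog(p, 1:2, threshold = 0.5)
  linked <- linkSpots(det, 4, 5)
  quant <- quantifyTracks(p, linked)
  sorted <- sortTracks(quant$summary)
  m <- buildMontage(p, quant$perFrame, sorted, "mcp", nTracks = 10)
  expect_equal(dim(m), c(2L * 17L, 3L * 17L))   # clamped to 2 tracks

  # each tile equals the direct crop around the track position
  g <- quant$perFrame[quant$perFrame$track == sorted$track[1], ]
  y <- round(g$y[1]); x <- round(g$x[1])
  tile <- m[1:17, 18:34]
  expect_equal(tile, p@data[2, 1, (y - 8):(y + 8), (x - 8):(x + 8)])
})
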