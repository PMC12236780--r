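diskLabel <- function(centers, r = 5, ny = 48, nx = 48) {
  lab <- matrix(0L, ny, nx)
  for (k in seq_len(nrow(centers))) {
    d <- sqrt(outer((seq_len(ny) - centers[k, 1])^2,
                    (seq_len(nx) - centers[k, 2])^2, "+"))
    lab[d <= r] <- k
  }
  lab
}

test_that("stationary nuclei yield complete tracks", {
  lab <- diskLabel(rbind(c(12, 12), c(30, 34)))
  lm <- labelMovieFromList(rep(list(lab), 5))
  tr <- linkNuclei(lm, maxDisplacement = 5)
  expect_equal(length(unique(tr$track)), 2L)
  expect_equal(nrow(tr), 10L)
})

test_that("a nucleus missing in one frame loses its whole track", {
  full <- diskLabel(rbind(c(12, 12), c(30, 34)))
  one <- diskLabel(rbind(c(12, 12)))
  lm <- labelMovieFromList(list(full, full, one, full, full))
  tr <- linkNuclei(lm, maxDisplacement = 5)
  expect_equal(length(unique(tr$track)), 1L)
  expect_lt(max(abs(tr$y - 12)), 1)
})

test_that("tracking follows drifting nuclei and recovers identities", {
  sim <- simulateEmbryoMovie(simConfig(
    imageSize = c(192, 192), initialNuclei = 10, sPhaseMinutes = 8,
    mitosisMinutes = numeric(0), channels = c("polymerase", "mcp"),
    driftSd = 0.6, rngSeed = 9))
  proj <- maxProject(sim$movie)
  labels <- segmentNuclei(proj, "polymerase")
  tr <- linkNuclei(labels, maxDisplacement = 8)
  tru <- sim$truth@nuclei
  nGood <- 0L
  for (id in unique(tr$track)) {
    g <- tr[tr$track == id, ]
    # nearest truth nucleus at frame 1 must stay nearest in every frame
    t1 <- tru[tru$frame == 1, ]
    truthId <- t1$track[which.min((t1$y - g$y[1])^2 + (t1$x - g$x[1])^2)]
    gt <- tru[tru$track == truthId, ]
    gt <- gt[order(gt$frame), ]
    if (max(abs(gt$y - g$y) + abs(gt$x - g$x)) < 5) nGood <- nGood + 1L
  }
  expect_gte(nGood / length(unique(tr$track)), 0.95)
  expect_gte(length(unique(tr$track)), 8L)
})

test_that("LoG detection finds isolated Gaussian blobs precisely", {
  img <- matrix(0, 64, 64)
  d2 <- outer((1:64 - 30)^2, (1:64 - 35)^2, "+")
  img <- img + 5 * exp(-d2 / (2 * 2^2))
  det <- detectFociLog(img, threshold = 0.5)
  expect_equal(nrow(det), 1L)
  expect_lte(abs(det$y - 30) + abs(det$x - 35), 2)

  expect_equal(nrow(detectFociLog(matrix(0, 32, 32), threshold = 0.1)), 0L)

  two <- img + 5 * exp(-outer((1:64 - 30)^2, (1:64 - 15)^2, "+") / (2 * 2^2))
  expect_equal(nrow(detectFociLog(two, threshold = 0.5)), 2L)
})

test_that("foci are assigned through the dilated nuclear mask", {
  lab <- diskLabel(rbind(c(20, 20)), r = 6)
  lm <- labelMovieFromList(list(lab))
  foci <- data.frame(frame = 1L, y = c(20, 40, 20), x = c(21, 40, 27))
  out <- assignFoci(foci, lm)
  expect_equal(out$nucleus, c(1L, NA_integer_, NA_integer_))
  # a focus 1 px outside the bare nucleus is captured after 2-px dilation
  dil <- diskLabel(rbind(c(20, 20)), r = 8)  # stands for the dilated label
  out2 <- assignFoci(data.frame(frame = 1L, y = 20, x = 27),
                     labelMovieFromList(list(dil)))
  expect_equal(out2$nucleus, 1L)
})

test_that("state calling derives ON/OFF transitions with debounce", {
  lab <- diskLabel(rbind(c(10, 10)), r = 4, ny = 24, nx = 24)
  lm <- labelMovieFromList(rep(list(lab), 6))
  tracks <- linkNuclei(lm, 3)
  mkFoci <- function(frames) data.frame(frame = frames,
                                        y = rep(10, length(frames)),
                                        x = rep(10, length(frames)),
                                        nucleus = rep(1L, length(frames)))
  tr <- callStates(tracks, mkFoci(c(3, 4)), nFrames = 6)
  expect_equal(tr@summary$firstOn, 3L)
  expect_equal(tr@summary$firstOffAfterOn, 5L)

  trNone <- callStates(tracks, mkFoci(integer(0)), nFrames = 6)
  expect_true(is.na(trNone@summary$firstOn))

  # flicker 0,1,0,1 with debounce 2 never counts as OFF
  trFlick <- callStates(tracks, mkFoci(c(2, 4)), nFrames = 4, debounce = 2)
  expect_equal(trFlick@summary$firstOn, 2L)
  expect_true(is.na(trFlick@summary$firstOffAfterOn))
})

test_that("cumulative curves match the counting definition", {
  traces <- tracesFromSummary(firstOn = c(2, 2, 3, NA),
                              firstOff = c(4, NA, NA, NA), nFrames = 6)
  cv <- cumulativeTransitions(traces, sStart = 1, frameInterval = 20)
  expect_equal(cv$onPct, c(0, 50, 75, 75, 75, 75))
  expect_equal(cv$offPct, c(0, 0, 0, 25, 25, 25))
  expect_equal(cv$timeSec, (0:5) * 20)

  allOn <- tracesFromSummary(rep(1, 3), rep(NA, 3), nFrames = 4)
  expect_equal(cumulativeTransitions(allOn, 1)$onPct, rep(100, 4))
})

test_that("cumulative curves are monotone, bounded and ordered", {
  set.seed(12)
  for (i in 1:10) {
    n <- 15L; nF <- 30L
    fOn <- ifelse(runif(n) < 0.8, sample(nF - 2L, n, replace = TRUE), NA)
    fOff <- ifelse(!is.na(fOn) & runif(n) < 0.5,
                   fOn + sample(3L, n, replace = TRUE), NA)
    fOff[!is.na(fOff) & fOff > nF] <- NA
    cv <- cumulativeTransitions(tracesFromSummary(fOn, fOff, nF), 1)
    expect_true(all(diff(cv$onPct) >= 0))
    expect_true(all(diff(cv$offPct) >= 0))
    expect_true(all(cv$offPct <= cv$onPct + 1e-9))
    expect_true(all(cv$onPct <= 100 & cv$offPct <= 100))
  }
})
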