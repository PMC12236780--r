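test_that("intensity clipping replaces only supra-threshold pixels", {
  img <- matrix(c(10, 200), 1, 2)
  expect_equal(clipIntensities(img, 100, 50), matrix(c(10, 50), 1, 2))
  low <- matrix(c(1, 2, 3), 1)
  expect_equal(clipIntensities(low, 100, 50), low)
  expect_error(clipIntensities(img, 100, 150), "must be <=")
})

test_that("Otsu threshold separates classes and matches exhaustive search", {
  half <- matrix(rep(c(0, 10), each = 50), 10, 10)
  thr <- otsuThreshold(half)
  expect_gte(thr, 0)
  expect_lt(thr, 10)
  expect_equal(sum(half > thr), 50)

  expect_error(otsuThreshold(matrix(5, 4, 4)), "constant")

  set.seed(42)
  bimodal <- matrix(c(rnorm(600, 20, 3), rnorm(400, 200, 12)), 25, 40)
  expect_equal(otsuThreshold(bimodal), otsuOracle(bimodal))

  # random images, including skewed and near-uniform ones
  for (i in 1:10) {
    set.seed(100 + i)
    img <- matrix(rexp(64 * 64, 1 / (10 * i)), 64, 64)
    expect_equal(otsuThreshold(img), otsuOracle(img))
  }
})

test_that("combined chromatin mask covers nuclei and excludes background", {
  centers <- rbind(c(20, 20), c(40, 44))
  proj <- twoDiskProjection(centers, r = 8, amp = 2, nChan = 2,
                            channelNames = c("bookmark", "kinase"))
  mask <- combinedChromatinMask(proj, c("bookmark", "kinase"))
  truth <- diskTruthMask(centers, r = 8)
  expect_gte(mean(getFrame(mask, 1)[truth]), 0.95)     # nucleus coverage
  expect_lte(mean(getFrame(mask, 1)[!truth]), 0.05)    # background leak
})

test_that("clipping rescues segmentation from a saturated focus", {
  centers <- rbind(c(24, 24), c(40, 44))
  proj <- twoDiskProjection(centers, r = 8, amp = 2, nChan = 2,
                            channelNames = c("bookmark", "kinase"),
                            focus = list(y = 24, x = 24, sigma = 2,
                                         amp = 400))
  # manual clip just above the nucleus body level, as in practice
  withClip <- combinedChromatinMask(proj, 1:2, clipThreshold = 8,
                                    replacement = 4.4)
  noClip <- combinedChromatinMask(proj, 1:2, clipThreshold = Inf,
                                  replacement = Inf)
  expect_gt(sum(getFrame(withClip, 1)), sum(getFrame(noClip, 1)))
  truth <- diskTruthMask(centers, r = 8)
  expect_gte(mean(getFrame(withClip, 1)[truth]), 0.9)
})

test_that("blank frames raise an error naming the frame", {
  d <- array(0.5, c(2, 2, 32, 32))
  d[1, , , ] <- d[1, , , ] + array(rep(c(0, 1), each = 32 * 16), c(2, 32, 32))
  proj <- new("Projection", data = d, method = "max", provenance = "fixture",
              frameInterval = 20, pixelSize = 0.2, channelNames = c("a", "b"))
  expect_error(combinedChromatinMask(proj, 1:2), "frame 2")
})

test_that("nucleus segmentation recovers separated and touching disks", {
  centers <- rbind(c(20, 20), c(40, 44))
  proj <- twoDiskProjection(centers, r = 8, amp = 2)
  lab <- segmentNuclei(proj, 1)
  reg <- regionTable(lab)
  expect_equal(nrow(reg), 2L)
  ord <- order(reg$cy)
  expect_lt(max(abs(reg$cy[ord] - centers[, 1])), 1)
  expect_lt(max(abs(reg$cx[ord] - centers[, 2])), 1)

  # overlap of ~20% of the radius: watershed must split the pair
  centers2 <- rbind(c(32, 24), c(32, 24 + 14.4))
  proj2 <- twoDiskProjection(centers2, r = 8, amp = 2)
  reg2 <- regionTable(segmentNuclei(proj2, 1))
  expect_equal(nrow(reg2), 2L)
  ord2 <- order(reg2$cx)
  expect_lt(max(abs(reg2$cx[ord2] - centers2[, 2])), 2)
  expect_lt(max(abs(reg2$cy[ord2] - centers2[, 1])), 2)
})

test_that("border-touching nuclei are removed", {
  proj <- twoDiskProjection(rbind(c(32, 1), c(32, 40)), r = 8, amp = 2)
  reg <- regionTable(segmentNuclei(proj, 1))
  expect_equal(nrow(reg), 1L)
  expect_gt(reg$cx, 30)
})

test_that("masks are invariant to a constant offset with a shifted clip", {
  centers <- rbind(c(20, 20), c(40, 44))
  proj <- twoDiskProjection(centers, r = 8, amp = 2, nChan = 2,
                            channelNames = c("a", "b"))
  shifted <- proj
  shifted@data <- proj@data + 5
  m1 <- combinedChromatinMask(proj, 1:2, clipThreshold = 3, replacement = 3)
  m2 <- combinedChromatinMask(shifted, 1:2, clipThreshold = 13,
                              replacement = 13)
  expect_equal(movieData(m1), movieData(m2))
})

test_that("raising the area cutoff never increases retained label count", {
  centers <- rbind(c(16, 16), c(44, 40), c(50, 14))
  proj <- twoDiskProjection(centers, r = 6, amp = 2)
  counts <- vapply(c(10, 80, 120, 200, 1000), function(a)
    nrow(regionTable(segmentNuclei(proj, 1, minArea = a))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})
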