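test_that("cycle schedules alternate S and M with doubling", {
  cfg <- simConfig(sPhaseMinutes = c(3, 3), mitosisMinutes = c(1, 1),
                   initialNuclei = 4L, imageSize = c(96, 96))
  sc <- scheduleCycles(cfg)
  expect_equal(paste(sc$phase, collapse = ""),
               paste(rep(c(rep("S", 9), rep("M", 3)), 2), collapse = ""))
  expect_equal(sc$sStarts, c(1L, 13L))
  expect_equal(sc$nucleiPerCycle, c(4L, 8L))

  one <- scheduleCycles(simConfig(sPhaseMinutes = 3,
                                  mitosisMinutes = numeric(0)))
  expect_equal(unique(one$phase), "S")

  expect_error(scheduleCycles(cfg, nFrames = 10), "exceeds movie length")
})

test_that("the simulation is bit-identical under a fixed seed", {
  cfg <- simConfig(imageSize = c(96, 96), initialNuclei = 4,
                   sPhaseMinutes = 2, mitosisMinutes = 1, rngSeed = 31)
  a <- simulateEmbryoMovie(cfg)
  b <- simulateEmbryoMovie(cfg)
  expect_identical(movieData(a$movie), movieData(b$movie))
  expect_identical(a$truth@nuclei, b$truth@nuclei)
  expect_identical(a$truth@stateSummary, b$truth@stateSummary)
})

test_that("a noiseless static nucleus renders the analytic disk", {
  cfg <- simConfig(imageSize = c(64, 64), initialNuclei = 1,
                   sPhaseMinutes = 1, mitosisMinutes = numeric(0),
                   channels = "histone", photonScale = 0, readNoiseSd = 0,
                   driftSd = 0, rngSeed = 5)
  sim <- simulateEmbryoMovie(cfg)
  d <- movieData(sim$movie)
  # every frame identical
  for (t in 2:dim(d)[1]) expect_identical(d[t, , , , ], d[1, , , , ])
  # pixel values equal the analytic smoothed-disk model
  nuc <- sim$truth@nuclei[1, ]
  dist <- sqrt(outer((1:64 - nuc$y)^2, (1:64 - nuc$x)^2, "+"))
  analytic <- 0.2 + 4.0 / (1 + exp(-(11 - dist) / 1))
  # rendering truncates the logistic tail outside its bounding box
  expect_lt(max(abs(d[1, 1, 1, , ] - analytic)), 1e-4)
})

test_that("noise is unbiased: sample mean tracks the noiseless frame", {
  base <- list(imageSize = c(64, 64), initialNuclei = 1,
               sPhaseMinutes = 200 * 20 / 60, mitosisMinutes = numeric(0),
               channels = "histone", driftSd = 0, rngSeed = 6)
  clean <- simulateEmbryoMovie(do.call(simConfig,
    c(base, list(photonScale = 0, readNoiseSd = 0))))
  noisy <- simulateEmbryoMovie(do.call(simConfig,
    c(base, list(photonScale = 100, readNoiseSd = 0.02))))
  truthImg <- movieData(clean$movie)[1, 1, 1, , ]
  stack <- movieData(noisy$movie)[, 1, 1, , ]   # 200 replicate frames
  mu <- apply(stack, c(2, 3), mean)
  se <- apply(stack, c(2, 3), sd) / sqrt(dim(stack)[1])
  within <- abs(mu - truthImg) <= 3 * se
  expect_gte(mean(within), 0.99)   # ~0.3% of pixels expected outside 3 SE
})

test_that("nucleus counts are conserved within phases and double at mitosis", {
  cfg <- simConfig(imageSize = c(160, 160), initialNuclei = 5,
                   sPhaseMinutes = c(2, 2), mitosisMinutes = c(1, 1),
                   rngSeed = 8)
  sim <- simulateEmbryoMovie(cfg)
  nuc <- sim$truth@nuclei
  perFrame <- tapply(nuc$track, nuc$frame, function(x) length(unique(x)))
  cyc <- sim$truth@cycles
  expect_true(all(perFrame[cyc$cycle == 1] == 5))
  expect_true(all(perFrame[cyc$cycle == 2] == 10))
})

test_that("rendered foci peak within 1 px of their ground-truth position", {
  cfg <- simConfig(imageSize = c(128, 128), initialNuclei = 3,
                   sPhaseMinutes = 6, mitosisMinutes = numeric(0),
                   channels = c("polymerase", "mcp"), photonScale = 0,
                   readNoiseSd = 0, rngSeed = 10)
  sim <- simulateEmbryoMovie(cfg)
  proj <- maxProject(sim$movie)
  tru <- sim$truth@foci
  mcpFoci <- tru[tru$channel == "mcp", ]
  expect_gt(nrow(mcpFoci), 0)
  for (k in seq_len(min(10, nrow(mcpFoci)))) {
    f <- mcpFoci[k, ]
    img <- proj@data[f$frame, 2, , ]
    win <- img[(round(f$y) - 4):(round(f$y) + 4),
               (round(f$x) - 4):(round(f$x) + 4)]
    pk <- which(win == max(win), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(pk - 5 + c(round(f$y), round(f$x)) -
                         c(f$y, f$x))), 1)
  }
})

test_that("transcription onsets respect S-phase boundaries", {
  cfg <- simConfig(imageSize = c(160, 160), initialNuclei = 6,
                   sPhaseMinutes = c(4, 6), mitosisMinutes = c(1, 1),
                   rngSeed = 11)
  sim <- simulateEmbryoMovie(cfg)
  ss <- sim$truth@stateSummary
  on <- ss[!is.na(ss$firstOn), ]
  expect_true(all(on$firstOn >= on$sStart))
  # every ON frame in the states table has an mcp focus rendered
  st <- sim$truth@states
  foci <- sim$truth@foci
  onRows <- st[st$on, ]
  key <- paste(foci$frame[foci$channel == "mcp"],
               foci$track[foci$channel == "mcp"])
  expect_true(all(paste(onRows$frame, onRows$track) %in% key))
})

test_that("ground truth round-trips through CSV", {
  cfg <- simConfig(imageSize = c(96, 96), initialNuclei = 2,
                   sPhaseMinutes = 2, mitosisMinutes = 1, rngSeed = 12)
  sim <- simulateEmbryoMovie(cfg)
  dir <- tempfile()
  writeGroundTruth(sim$truth, dir)
  back <- readGroundTruth(dir)
  expect_equal(back@nuclei, sim$truth@nuclei)
  expect_equal(back@foci, sim$truth@foci)
  expect_equal(back@stateSummary, sim$truth@stateSummary)
  expect_equal(back@sStarts, sim$truth@sStarts)
  # nucleus table has one row per nucleus per live frame
  expect_equal(nrow(sim$truth@nuclei),
               sum(c(2, 4)[sim$truth@cycles$cycle]))

  # an empty focus table still writes a valid header-only CSV
  empty <- sim$truth
  empty@foci <- empty@foci[0, ]
  dir2 <- tempfile()
  writeGroundTruth(empty, dir2)
  expect_equal(nrow(readGroundTruth(dir2)@foci), 0L)
})
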