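# Pipeline drivers. Each run resolves a nested config list against
# defaults, executes the stage composition, and writes CSV outputs plus
# the resolved config (with package version and seed) to the output
# directory. Outputs contain no timestamps, so a rerun with the same
# config and seed is byte-identical.

.mergeConfig <- function(defaults, config, pipeline) {
  bad <- setdiff(names(config), names(defaults))
  if (length(bad))
    stop(pipeline, ": unknown config field(s): ", paste(bad, collapse = ", "))
  utils::modifyList(defaults, config)
}

.requireField <- function(cfg, field, pipeline) {
  if (is.null(cfg[[field]]))
    stop(pipeline, ": required config field '", field, "' is missing")
  cfg[[field]]
}

# simulate or read the input movie; returns list(movie, truth or NULL)
.loadInput <- function(cfg, seedOffset = 0L) {
  if (!is.null(cfg$movie)) {
    return(list(movie = readMovie(cfg$movie), truth = NULL))
  }
  simArgs <- cfg$sim
  if (is.null(simArgs)) simArgs <- list()
  simArgs$rngSeed <- cfg$seed + seedOffset
  sim <- simulateEmbryoMovie(do.call(simConfig, simArgs))
  sim
}

.applyRollingBall <- function(proj, radius) {
  if (is.null(radius)) return(proj)
  d <- proj@data
  for (t in seq_len(dim(d)[1L])) for (ci in seq_len(dim(d)[2L]))
    d[t, ci, , ] <- rollingBallSubtract(d[t, ci, , ], radius)
  proj@data <- d
  proj
}

.writeResolved <- function(cfg, outDir, pipeline) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfg$pipeline <- pipeline
  cfg$packageVersion <- as.character(utils::packageVersion("embryohub"))
  yaml::write_yaml(cfg, file.path(outDir, "config.yaml"))
}

.writeLog <- function(lines, outDir) {
  writeLines(lines, file.path(outDir, "log.txt"))
}

#' Run the hub-dynamics pipeline
#'
#' Stage composition: simulate or read the movie, max-project, optional
#' rolling-ball subtraction, combined chromatin mask from the bookmark and
#' kinase channels, masked mean/variance series per channel, recruitment
#' onset on the kinase mean series (or a manual override), peak extraction
#' in a fixed window after onset, and a per-nucleus branch (segmentation
#' plus per-nucleus maxima).
#'
#' @param config a nested list; recognised fields (all defaulted except
#'   the input): \code{sim} (list of [simConfig()] arguments) or
#'   \code{movie} (TIFF path), \code{seed}, \code{out} (output directory),
#'   \code{bookmarkChannel}, \code{kinaseChannel}, \code{rollingBall}
#'   (radius or NULL), \code{blurSigma}, \code{clipQuantile},
#'   \code{windowSeconds}, \code{riseFraction}, \code{onsetFrame}
#'   (manual override), \code{segmentChannel}.
#' @return Invisibly, a list with \code{series} (tidy per-frame statistic
#'   table), \code{peaks}, \code{perNucleus}, \code{onset}.
#' @export
runHubdyn <- function(config = list()) {
  defaults <- list(sim = NULL, movie = NULL, seed = 1L, out = NULL,
                   bookmarkChannel = "bookmark", kinaseChannel = "kinase",
                   rollingBall = NULL, blurSigma = 2, clipQuantile = 0.995,
                   windowSeconds = 120, riseFraction = 0.2, onsetFrame = NULL,
                   segmentChannel = NULL)
  cfg <- .mergeConfig(defaults, config, "runHubdyn")
  if (is.null(cfg$sim) && is.null(cfg$movie))
    stop("runHubdyn: required config field 'sim' or 'movie' is missing")
  input <- .loadInput(cfg)
  proj <- maxProject(input$movie)
  for (f in c("bookmarkChannel", "kinaseChannel"))
    if (!cfg[[f]] %in% channelNames(proj))
      stop("runHubdyn: config field '", f, "' (", cfg[[f]],
           ") is not a channel of the movie")
  proj <- .applyRollingBall(proj, cfg$rollingBall)
  masks <- combinedChromatinMask(proj,
    channels = c(cfg$bookmarkChannel, cfg$kinaseChannel),
    clipQuantile = cfg$clipQuantile, blurSigma = cfg$blurSigma)
  chans <- c(cfg$bookmarkChannel, cfg$kinaseChannel)
  series <- list(); peaks <- list()
  kinaseMean <- maskedStats(proj, masks, cfg$kinaseChannel, "mean")
  onset <- if (!is.null(cfg$onsetFrame)) as.integer(cfg$onsetFrame)
           else detectRecruitmentOnset(kinaseMean, cfg$riseFraction)
  for (ch in chans) for (st in c("mean", "variance")) {
    s <- maskedStats(proj, masks, ch, st)
    series[[paste(ch, st)]] <- data.frame(
      frame = seq_along(s@values), timeSec = s@times, channel = ch,
      statistic = st, value = s@values)
    pk <- peakInWindow(s, onset, cfg$windowSeconds)
    peaks[[paste(ch, st)]] <- pk
  }
  seriesTab <- do.call(rbind, series); rownames(seriesTab) <- NULL
  peaksTab <- do.call(rbind, peaks); rownames(peaksTab) <- NULL
  segCh <- if (is.null(cfg$segmentChannel)) cfg$kinaseChannel
           else cfg$segmentChannel
  labels <- segmentNuclei(proj, segCh, clipQuantile = cfg$clipQuantile,
                          blurSigma = cfg$blurSigma)
  perNuc <- do.call(rbind, lapply(chans, function(ch) {
    tab <- perNucleusIntensities(proj, labels, ch, "max")
    if (nrow(tab)) cbind(channel = ch, tab) else NULL
  }))
  if (is.null(perNuc))
    perNuc <- data.frame(channel = character(0), frame = integer(0),
                         nucleus = integer(0), value = numeric(0))
  if (!is.null(cfg$out)) {
    .writeResolved(cfg[setdiff(names(cfg), "out")], cfg$out, "hubdyn")
    write.csv(seriesTab, file.path(cfg$out, "series.csv"), row.names = FALSE)
    write.csv(peaksTab, file.path(cfg$out, "peaks.csv"), row.names = FALSE)
    write.csv(perNuc, file.path(cfg$out, "per_nucleus.csv"),
              row.names = FALSE)
    .writeLog(c(paste("onset frame:", onset),
                paste("mask foreground fraction:",
                      round(mean(masks@data), 4)),
                paste("segmented regions:", nrow(regionTable(labels)))),
              cfg$out)
  }
  invisible(list(series = seriesTab, peaks = peaksTab, perNucleus = perNuc,
                 onset = onset, masks = masks, labels = labels))
}

#' Run the transcription ON/OFF state pipeline
#'
#' Stage composition per embryo: simulate or read, max-project, segment
#' nuclei on the polymerase channel, track nuclei (complete tracks only),
#' detect transcription foci by LoG on the reporter channel, assign foci
#' to (pre-dilated) nuclei, call ON/OFF states, and compute cumulative
#' ON/OFF transition curves from S-phase entry. With several embryos
#' (\code{seeds}), curves are aggregated as pointwise mean and SEM.
#'
#' @param config nested list; fields: \code{sim}/\code{movie}, \code{seed},
#'   \code{seeds} (replicate embryo seeds; default \code{seed}),
#'   \code{out}, \code{nucleusChannel}, \code{fociChannel},
#'   \code{maxDisplacement}, \code{logSigmas}, \code{logThreshold},
#'   \code{debounce}, \code{sStart} (S-phase entry frame; default: last
#'   S start of the simulated schedule), \code{endFrame},
#'   \code{blurSigma}, \code{clipQuantile}.
#' @return Invisibly, a list with \code{states} (per-embryo track
#'   summaries), \code{curves} (per-embryo), \code{curvesSem}
#'   (mean +/- SEM, NULL for one embryo).
#' @export
runMcp <- function(config = list()) {
  defaults <- list(sim = NULL, movie = NULL, seed = 1L, seeds = NULL,
                   out = NULL, nucleusChannel = "polymerase",
                   fociChannel = "mcp", maxDisplacement = NULL,
                   logSigmas = seq(1.5, 4, by = 0.5), logThreshold = 0.5,
                   debounce = 1L, sStart = NULL, endFrame = NULL,
                   blurSigma = 2, clipQuantile = 0.995)
  cfg <- .mergeConfig(defaults, config, "runMcp")
  if (is.null(cfg$sim) && is.null(cfg$movie))
    stop("runMcp: required config field 'sim' or 'movie' is missing")
  if (is.null(cfg$sim$channels) && is.null(cfg$movie))
    cfg$sim$channels <- c("polymerase", "mcp")
  seeds <- if (is.null(cfg$seeds)) cfg$seed else cfg$seeds
  allStates <- list(); allCurves <- list(); logLines <- character(0)
  for (e in seq_along(seeds)) {
    input <- .loadInput(cfg, seedOffset = seeds[e] - cfg$seed)
    proj <- maxProject(input$movie)
    labels <- segmentNuclei(proj, cfg$nucleusChannel,
                            clipQuantile = cfg$clipQuantile,
                            blurSigma = cfg$blurSigma)
    maxDisp <- cfg$maxDisplacement
    if (is.null(maxDisp)) {
      areas <- regionTable(labels)$area
      maxDisp <- if (length(areas)) sqrt(median(areas) / pi) else 10
    }
    tracks <- linkNuclei(labels, maxDisp)
    if (!nrow(tracks))
      stop("runMcp: no complete nucleus tracks retained (embryo ", e, ")")
    fi <- channelIndex(proj, cfg$fociChannel)
    foci <- do.call(rbind, lapply(seq_len(nFrames(proj)), function(t) {
      d <- detectFociLog(proj@data[t, fi, , ], cfg$logSigmas,
                         cfg$logThreshold)
      if (nrow(d)) cbind(frame = t, d) else NULL
    }))
    if (is.null(foci))
      foci <- data.frame(frame = integer(0), y = integer(0), x = integer(0),
                         sigma = numeric(0), response = numeric(0))
    foci <- assignFoci(foci, labels)
    traces <- callStates(tracks, foci, nFrames(proj), cfg$debounce)
    sStart <- cfg$sStart
    endFrame <- cfg$endFrame
    if (!is.null(input$truth)) {
      cyc <- input$truth@cycles
      if (is.null(sStart)) sStart <- max(input$truth@sStarts)
      if (is.null(endFrame))
        endFrame <- max(cyc$frame[cyc$phase == "S" &
                                  cyc$cycle == cyc$cycle[sStart]])
    }
    if (is.null(sStart))
      stop("runMcp: required config field 'sStart' is missing for a real movie")
    curves <- cumulativeTransitions(traces, sStart, endFrame,
                                    frameInterval(proj))
    allStates[[e]] <- cbind(embryo = e, traces@summary)
    allCurves[[e]] <- cbind(embryo = e, curves)
    logLines <- c(logLines, paste0("embryo ", e, ": ",
      length(unique(tracks$track)), " tracks, ", nrow(foci), " foci, ",
      sum(!is.na(traces@summary$firstOn)), " ON"))
  }
  states <- do.call(rbind, allStates)
  curves <- do.call(rbind, allCurves)
  curvesSem <- NULL
  if (length(seeds) >= 2L) {
    onM <- semCurves(lapply(allCurves, function(cv) cv$onPct))
    offM <- semCurves(lapply(allCurves, function(cv) cv$offPct))
    curvesSem <- data.frame(timeSec = allCurves[[1L]]$timeSec,
                            onMean = onM$mean, onSem = onM$sem,
                            offMean = offM$mean, offSem = offM$sem)
  }
  if (!is.null(cfg$out)) {
    .writeResolved(cfg[setdiff(names(cfg), "out")], cfg$out, "mcp")
    write.csv(states, file.path(cfg$out, "states.csv"), row.names = FALSE)
    write.csv(curves, file.path(cfg$out, "curves.csv"), row.names = FALSE)
    if (!is.null(curvesSem))
      write.csv(curvesSem, file.path(cfg$out, "curves_sem.csv"),
                row.names = FALSE)
    .writeLog(logLines, cfg$out)
  }
  invisible(list(states = states, curves = curves, curvesSem = curvesSem))
}

#' Run the dual 5'/3' reporter pipeline
#'
#' Stage composition: simulate or read, max-project, detect spots by DoG
#' on the summed reporter channels, link detections into gap-closing
#' tracks, quantify every detection in both channels with local background
#' correction, drop single-frame and border-touching tracks, sort by first
#' appearance then total 3' intensity, and render track-by-time montages
#' for both channels.
#'
#' @param config nested list; fields: \code{sim}/\code{movie}, \code{seed},
#'   \code{out}, \code{fivePrimeChannel}, \code{threePrimeChannel},
#'   \code{blurSigma}, \code{dogSigmas}, \code{dogThreshold},
#'   \code{maxDisplacement}, \code{maxGap}, \code{nTracks},
#'   \code{backgroundPolicy} (\code{"annulus"} or \code{"full"}).
#' @return Invisibly, a list with \code{tracks} (per-frame quantified),
#'   \code{summary} (sorted track summary), \code{montages} (list of
#'   matrices per channel).
#' @export
runDual <- function(config = list()) {
  defaults <- list(sim = NULL, movie = NULL, seed = 1L, out = NULL,
                   fivePrimeChannel = "mcp", threePrimeChannel = "pcp",
                   blurSigma = 1, dogSigmas = c(1.5, 3), dogThreshold = 0.5,
                   maxDisplacement = 5, maxGap = 5L, nTracks = 50L,
                   backgroundPolicy = "annulus")
  cfg <- .mergeConfig(defaults, config, "runDual")
  if (is.null(cfg$sim) && is.null(cfg$movie))
    stop("runDual: required config field 'sim' or 'movie' is missing")
  if (is.null(cfg$sim$channels) && is.null(cfg$movie))
    cfg$sim$channels <- c("mcp", "pcp")
  input <- .loadInput(cfg)
  proj <- maxProject(input$movie)
  chans <- c(cfg$fivePrimeChannel, cfg$threePrimeChannel)
  det <- detectSpotsDog(proj, chans, cfg$blurSigma, cfg$dogSigmas,
                        cfg$dogThreshold)
  linked <- linkSpots(det, cfg$maxDisplacement, cfg$maxGap)
  quant <- quantifyTracks(proj, linked, chans,
                          policy = cfg$backgroundPolicy)
  filt <- filterTracks(quant)
  sorted <- sortTracks(filt$summary)
  montages <- lapply(setNames(chans, chans), function(ch)
    buildMontage(proj, filt$perFrame, sorted, ch, cfg$nTracks))
  if (!is.null(cfg$out)) {
    .writeResolved(cfg[setdiff(names(cfg), "out")], cfg$out, "dual")
    write.csv(filt$perFrame, file.path(cfg$out, "tracks.csv"),
              row.names = FALSE)
    write.csv(sorted, file.path(cfg$out, "track_summary.csv"),
              row.names = FALSE)
    for (ch in chans) {
      m <- montages[[ch]]
      sc <- max(m, 1e-9)
      tiff::writeTIFF(m / sc, file.path(cfg$out,
                                        paste0("montage_", ch, ".tif")),
                      bits.per.sample = 16L)
    }
    .writeLog(c(paste("detections:", nrow(det)),
                paste("tracks linked:", length(unique(linked$track))),
                paste("tracks kept:", nrow(sorted))),
              cfg$out)
  }
  invisible(list(tracks = filt$perFrame, summary = sorted,
                 montages = montages, detections = det))
}
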