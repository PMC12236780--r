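# rendering primitives ------------------------------------------------------

# smoothed disk: adds amp / (1 + exp(-(r - d)/edge)) inside a local
# bounding box; this closed form is the package's analytic nucleus model
.addDisk <- function(img, cy, cx, r, amp, edge = 1) {
  ny <- nrow(img); nx <- ncol(img)
  ext <- ceiling(r + 12 * edge)
  ys <- max(1L, floor(cy - ext)):min(ny, ceiling(cy + ext))
  xs <- max(1L, floor(cx - ext)):min(nx, ceiling(cx + ext))
  if (!length(ys) || !length(xs)) return(img)
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  img[ys, xs] <- img[ys, xs] + amp / (1 + exp(-(r - d) / edge))
  img
}

# isotropic 2-D Gaussian focus of peak amplitude amp
.addGaussian <- function(img, cy, cx, sigma, amp) {
  ny <- nrow(img); nx <- ncol(img)
  ext <- ceiling(4 * sigma)
  ys <- max(1L, floor(cy - ext)):min(ny, ceiling(cy + ext))
  xs <- max(1L, floor(cx - ext)):min(nx, ceiling(cx + ext))
  if (!length(ys) || !length(xs)) return(img)
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  img[ys, xs] <- img[ys, xs] + amp * exp(-d2 / (2 * sigma^2))
  img
}

# jittered hexagonal lattice of n points within [margin, ny-margin] x
# [margin, nx-margin]; consumes the RNG (jitter + selection order)
.hexPlace <- function(n, ny, nx, margin) {
  H <- ny - 2 * margin; W <- nx - 2 * margin
  d <- sqrt(2 * H * W / (sqrt(3) * n)) # hex spacing for ~n points
  rowStep <- d * sqrt(3) / 2
  pts <- NULL
  i <- 0L
  while (margin + i * rowStep <= ny - margin) {
    y <- margin + i * rowStep
    off <- if (i %% 2L == 0L) 0 else d / 2
    xs <- seq(margin + off, nx - margin, by = d)
    if (length(xs)) pts <- rbind(pts, cbind(y = y, x = xs))
    i <- i + 1L
  }
  jit <- matrix(runif(2L * nrow(pts), -0.15 * d, 0.15 * d), ncol = 2L)
  pts <- pts + jit
  pts[, 1L] <- pmin(pmax(pts[, 1L], margin), ny - margin)
  pts[, 2L] <- pmin(pmax(pts[, 2L], margin), nx - margin)
  if (nrow(pts) < n)
    stop("field too small for ", n, " nuclei at this radius")
  pts[sample(nrow(pts), n), , drop = FALSE]
}

# mitotic chromatin rendering constants (condensation)
.CONDENSED_RADIUS <- 0.55
.CONDENSED_AMP <- 1.6

#' Simulate a ground-truthed syncytial-embryo movie
#'
#' Renders a single-z, multi-channel movie following a [SimConfig-class]:
#' nuclei as smoothed disks on a jittered hexagonal lattice that drift by
#' a small random walk, condense during mitosis and split into two
#' daughters at each mitosis-to-S boundary; channel-specific Gaussian
#' foci implement bookmark persistence/dispersal, transient kinase
#' co-clusters at S-phase entry, polymerase foci appearing ~2 min into S
#' phase, and telegraph (ON/OFF) transcription whose 3' (pcp) focus lags
#' the 5' (mcp) focus by the configured elongation delay. Poisson shot
#' noise and Gaussian read noise are applied last. All stochastic draws
#' consume one stream seeded from \code{rngSeed}, in a fixed order
#' (placement, then per-cycle division/offset/kinetics draws, then drift,
#' then noise), so identical configs give bit-identical output.
#'
#' @param config a [SimConfig-class].
#' @return A list with elements \code{movie} ([MovieStack-class], z = 1)
#'   and \code{truth} ([GroundTruth-class]).
#' @examples
#' sim <- simulateEmbryoMovie(simConfig(imageSize = c(96, 96),
#'   initialNuclei = 4, sPhaseMinutes = 2, mitosisMinutes = 1,
#'   photonScale = 0, readNoiseSd = 0, rngSeed = 1))
#' sim$movie
#' @export
simulateEmbryoMovie <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@rngSeed)
  sc <- scheduleCycles(config)
  nF <- sc$nFrames
  ny <- config@imageSize[1L]; nx <- config@imageSize[2L]
  dt <- config@frameInterval; dtMin <- dt / 60
  chans <- config@channels
  nC <- length(chans)
  nCycles <- length(sc$sStarts)
  # emulate the cropped central field: keep whole nuclei (incl. blur
  # tails) away from the X-Y borders
  margin <- config@nuclearRadius + 8

  # cycle frame windows
  cyc <- lapply(seq_len(nCycles), function(g) {
    fr <- which(sc$cycle == g)
    list(frames = fr, sStart = sc$sStarts[g],
         sEnd = max(fr[sc$phase[fr] == "S"]),
         mFrames = fr[sc$phase[fr] == "M"])
  })

  shiftF <- round(config@onTimeShiftMin * 60 / dt)
  meanF <- config@onTimeMeanMin * 60 / dt
  delayF <- config@elongationDelayFrames

  # --- genealogy, offsets and kinetics (RNG order documented above) ---
  nextId <- 0L
  cycleTracks <- vector("list", nCycles)
  for (g in seq_len(nCycles)) {
    rG <- config@nuclearRadius * config@radiusDecay^(g - 1L)
    if (g == 1L) {
      p0 <- .hexPlace(config@initialNuclei, ny, nx, margin)
      ids <- nextId + seq_len(nrow(p0)); nextId <- nextId + nrow(p0)
      tr <- data.frame(id = ids, y0 = p0[, "y"], x0 = p0[, "x"])
    } else {
      par <- cycleTracks[[g - 1L]]
      lastF <- max(cyc[[g - 1L]]$frames)
      sep <- 2.2 * rG
      rows <- vector("list", nrow(par$info))
      for (i in seq_len(nrow(par$info))) {
        th <- runif(1, 0, pi)
        py <- par$pos[i, length(par$frames), 1L]
        px <- par$pos[i, length(par$frames), 2L]
        dy <- sep / 2 * sin(th); dx <- sep / 2 * cos(th)
        rows[[i]] <- data.frame(
          id = nextId + c(1L, 2L),
          y0 = pmin(pmax(py + c(dy, -dy), margin), ny - margin),
          x0 = pmin(pmax(px + c(dx, -dx), margin), nx - margin))
        nextId <- nextId + 2L
      }
      tr <- do.call(rbind, rows)
    }
    nTr <- nrow(tr)
    # per-track hub focus offsets (polar, within half the radius)
    fociOff <- array(0, c(nTr, config@fociPerNucleus, 2L))
    for (i in seq_len(nTr)) for (k in seq_len(config@fociPerNucleus)) {
      a <- runif(1, 0, 2 * pi); rr <- runif(1, 0.15, 0.5) * rG
      fociOff[i, k, ] <- c(rr * sin(a), rr * cos(a))
    }
    # per-track transcription spot offset
    spotOff <- matrix(0, nTr, 2L)
    for (i in seq_len(nTr)) {
      a <- runif(1, 0, 2 * pi); rr <- runif(1, 0, 0.4) * rG
      spotOff[i, ] <- c(rr * sin(a), rr * cos(a))
    }
    # telegraph kinetics
    sS <- cyc[[g]]$sStart; sE <- cyc[[g]]$sEnd
    onF <- sS + shiftF + floor(rexp(nTr, rate = 1 / meanF))
    durF <- if (config@offProbPerFrame > 0)
      rgeom(nTr, config@offProbPerFrame) + 1L else rep(Inf, nTr)
    elongFail <- runif(nTr) < config@elongationFailureProb
    onF[onF > sE] <- NA
    offF <- onF + durF                       # first spontaneous OFF frame
    offF[!is.na(offF) & offF > sE] <- NA     # mitosis aborts, not an OFF event
    # drift random walk over this cycle's frames
    frames <- cyc[[g]]$frames
    pos <- array(0, c(nTr, length(frames), 2L))
    pos[, 1L, 1L] <- tr$y0; pos[, 1L, 2L] <- tr$x0
    if (length(frames) > 1L) for (j in 2L:length(frames)) {
      step <- matrix(rnorm(2L * nTr, 0, config@driftSd), ncol = 2L)
      pos[, j, ] <- pos[, j - 1L, ] + step
      pos[, j, 1L] <- pmin(pmax(pos[, j, 1L], margin), ny - margin)
      pos[, j, 2L] <- pmin(pmax(pos[, j, 2L], margin), nx - margin)
    }
    cycleTracks[[g]] <- list(info = tr, fociOff = fociOff, spotOff = spotOff,
                             onF = onF, offF = offF, elongFail = elongFail,
                             radius = rG, frames = frames, pos = pos)
  }

  # --- render ---
  data <- array(0, c(nF, 1L, nC, ny, nx))
  nucleiRows <- list(); fociRows <- list(); stateRows <- list()
  spotRows <- list()
  for (g in seq_len(nCycles)) {
    ct <- cycleTracks[[g]]
    sS <- cyc[[g]]$sStart; sE <- cyc[[g]]$sEnd
    mEnd <- if (length(cyc[[g]]$mFrames)) max(cyc[[g]]$mFrames) else NA
    for (j in seq_along(ct$frames)) {
      t <- ct$frames[j]
      phase <- sc$phase[t]
      tS <- (t - sS) * dtMin
      toNextS <- if (!is.na(mEnd)) (mEnd - t + 1L) * dtMin else Inf
      mitotic <- phase == "M"
      rEff <- if (mitotic) .CONDENSED_RADIUS * ct$radius else ct$radius
      offScale <- if (mitotic) 0.5 else 1
      imgs <- lapply(seq_len(nC), function(ci) data[t, 1L, ci, , ])
      for (i in seq_len(nrow(ct$info))) {
        yC <- ct$pos[i, j, 1L]; xC <- ct$pos[i, j, 2L]
        id <- ct$info$id[i]
        nucleiRows[[length(nucleiRows) + 1L]] <- data.frame(
          frame = t, track = id, y = yC, x = xC, radius = rEff,
          phase = if (mitotic) "mitosis" else "interphase", cycle = g)
        on <- !is.na(ct$onF[i]) && !mitotic && t >= ct$onF[i] &&
          (is.na(ct$offF[i]) || t < ct$offF[i]) && t <= sE
        stateRows[[length(stateRows) + 1L]] <- data.frame(
          frame = t, track = id, on = on)
        for (ci in seq_len(nC)) {
          ch <- chans[ci]
          ampB <- config@bodyAmplitudes[[ch]] *
            (if (mitotic) .CONDENSED_AMP else 1)
          img <- .addDisk(imgs[[ci]], yC, xC, rEff, ampB)
          # channel-specific focus presence rules
          present <- switch(ch,
            bookmark = mitotic ||
              (tS < config@bookmarkDispersalMin) ||
              (tS >= config@bookmarkAppearMin && t <= sE),
            kinase = (mitotic && toNextS <= config@kinaseLeadMin) ||
              (!mitotic && tS >= config@kinaseDelayMin &&
                 tS < config@kinaseDelayMin + config@kinaseDispersalMin),
            polymerase = !mitotic && tS >= config@polAppearMin && t <= sE,
            mcp = on,
            pcp = on && !ct$elongFail[i] && t >= ct$onF[i] + delayF,
            histone = FALSE)
          if (present && ch %in% c("mcp", "pcp")) {
            fy <- yC + ct$spotOff[i, 1L]; fx <- xC + ct$spotOff[i, 2L]
            amp <- config@focusAmplitudes[[ch]]
            img <- .addGaussian(img, fy, fx, config@focusSigma, amp)
            fociRows[[length(fociRows) + 1L]] <- data.frame(
              frame = t, track = id, channel = ch, y = fy, x = fx,
              amplitude = amp, sigma = config@focusSigma)
          } else if (present) {
            amp <- config@focusAmplitudes[[ch]]
            for (k in seq_len(config@fociPerNucleus)) {
              fy <- yC + offScale * ct$fociOff[i, k, 1L]
              fx <- xC + offScale * ct$fociOff[i, k, 2L]
              img <- .addGaussian(img, fy, fx, config@focusSigma, amp)
              fociRows[[length(fociRows) + 1L]] <- data.frame(
                frame = t, track = id, channel = ch, y = fy, x = fx,
                amplitude = amp, sigma = config@focusSigma)
            }
          }
          imgs[[ci]] <- img
        }
        if (all(c("mcp", "pcp") %in% chans) && on)
          spotRows[[length(spotRows) + 1L]] <- data.frame(
            frame = t, track = id,
            mcp = config@focusAmplitudes[["mcp"]],
            pcp = if (!ct$elongFail[i] && t >= ct$onF[i] + delayF)
              config@focusAmplitudes[["pcp"]] else 0)
      }
      for (ci in seq_len(nC)) data[t, 1L, ci, , ] <- imgs[[ci]]
    }
  }
  data <- data + config@baseline

  # --- noise, applied last ---
  if (config@photonScale > 0) {
    lam <- data * config@photonScale
    data <- array(rpois(length(lam), lam), dim(lam)) / config@photonScale
  }
  if (config@readNoiseSd > 0)
    data <- pmax(data + array(rnorm(length(data), 0, config@readNoiseSd),
                              dim(data)), 0)

  movie <- movieStack(data, frameInterval = dt, zStep = 0.5, pixelSize = 0.2,
                      channelNames = chans)
  summ <- do.call(rbind, lapply(seq_len(nCycles), function(g) {
    ct <- cycleTracks[[g]]
    data.frame(track = ct$info$id, cycle = g, sStart = cyc[[g]]$sStart,
               firstOn = ct$onF, firstOffAfterOn = ct$offF)
  }))
  bindOr <- function(rows, proto) {
    if (length(rows)) do.call(rbind, rows) else proto
  }
  truth <- new("GroundTruth",
    nuclei = bindOr(nucleiRows, data.frame(frame = integer(0),
      track = integer(0), y = numeric(0), x = numeric(0),
      radius = numeric(0), phase = character(0), cycle = integer(0))),
    foci = bindOr(fociRows, data.frame(frame = integer(0),
      track = integer(0), channel = character(0), y = numeric(0),
      x = numeric(0), amplitude = numeric(0), sigma = numeric(0))),
    states = bindOr(stateRows, data.frame(frame = integer(0),
      track = integer(0), on = logical(0))),
    stateSummary = summ,
    spots = bindOr(spotRows, data.frame(frame = integer(0),
      track = integer(0), mcp = numeric(0), pcp = numeric(0))),
    cycles = data.frame(frame = seq_len(nF), cycle = sc$cycle,
                        phase = sc$phase),
    sStarts = as.integer(sc$sStarts))
  list(movie = movie, truth = truth)
}
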