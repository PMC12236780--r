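#' SimConfig: parameters of the synthetic embryo movie generator
#'
#' Full parameterisation of a simulated syncytial-embryo movie. Defaults
#' emulate the nuclear-cycle 12 to 13 transition at a 20 s frame interval:
#' alternating S and M phases with nuclear doubling at each mitosis,
#' mitotically persistent bookmark foci that disperse shortly after
#' S-phase onset, transient kinase co-clusters at S-phase entry,
#' polymerase foci appearing about 2 min into S phase, and telegraph
#' (ON/OFF) transcription whose 5' (mcp) signal is joined by the 3' (pcp)
#' signal after a fixed elongation delay. See [simConfig()] for the
#' meaning, unit and default of every slot.
#'
#' @seealso [simConfig()], [simulateEmbryoMovie()], [scheduleCycles()]
#' @export
setClass("SimConfig",
  representation(
    imageSize             = "integer",   # (y, x) pixels
    frameInterval         = "numeric",   # seconds
    sPhaseMinutes         = "numeric",   # per-cycle S durations
    mitosisMinutes        = "numeric",   # per-cycle M durations
    initialNuclei         = "integer",
    nuclearRadius         = "numeric",   # pixels, first cycle
    radiusDecay           = "numeric",   # radius factor per cycle
    channels              = "character",
    bodyAmplitudes        = "numeric",   # named, nucleoplasmic level
    focusAmplitudes       = "numeric",   # named, focus peak over body
    fociPerNucleus        = "integer",
    focusSigma            = "numeric",   # pixels
    bookmarkAppearMin     = "numeric",   # min into S when bookmarks form
    bookmarkDispersalMin  = "numeric",   # min into S until dispersal
    kinaseLeadMin         = "numeric",   # min before S onset (late M)
    kinaseDelayMin        = "numeric",   # min after S onset (perturbed)
    kinaseDispersalMin    = "numeric",   # min into S until dispersal
    polAppearMin          = "numeric",   # min into S
    onTimeShiftMin        = "numeric",   # telegraph onset shift
    onTimeMeanMin         = "numeric",   # exponential mean beyond shift
    offProbPerFrame       = "numeric",
    elongationDelayFrames = "integer",
    elongationFailureProb = "numeric",
    baseline              = "numeric",   # camera offset, intensity units
    photonScale           = "numeric",   # photons per intensity unit
    readNoiseSd           = "numeric",   # intensity units
    driftSd               = "numeric",   # px / frame random walk
    rngSeed               = "integer",
    perturbation          = "character"  # "none" or "cdc7i"
  )
)

setValidity("SimConfig", function(object) {
  if (length(object@imageSize) != 2L || any(object@imageSize < 32L))
    return("imageSize must be two integers >= 32")
  if (object@frameInterval <= 0)
    return("frameInterval must be positive")
  if (any(object@sPhaseMinutes <= 0) || any(object@mitosisMinutes <= 0))
    return("phase durations must be positive")
  nS <- length(object@sPhaseMinutes); nM <- length(object@mitosisMinutes)
  if (!(nM == nS || nM == nS - 1L))
    return("mitosisMinutes must have length equal to, or one less than, sPhaseMinutes")
  if (object@initialNuclei < 1L)
    return("initialNuclei must be >= 1")
  if (object@nuclearRadius <= 0 || object@focusSigma <= 0)
    return("nuclearRadius and focusSigma must be positive")
  known <- c("bookmark", "kinase", "polymerase", "mcp", "pcp", "histone")
  if (!all(object@channels %in% known))
    return(paste("channels must be among:", paste(known, collapse = ", ")))
  if (!all(object@channels %in% names(object@bodyAmplitudes)) ||
      !all(object@channels %in% names(object@focusAmplitudes)))
    return("bodyAmplitudes and focusAmplitudes must name every rendered channel")
  probs <- c(object@offProbPerFrame, object@elongationFailureProb)
  if (any(probs < 0 | probs > 1))
    return("probabilities must lie in [0, 1]")
  if (any(c(object@bodyAmplitudes, object@focusAmplitudes) < 0))
    return("amplitudes must be non-negative")
  if (object@photonScale < 0 || object@readNoiseSd < 0 || object@baseline < 0)
    return("noise parameters must be non-negative")
  if (!object@perturbation %in% c("none", "cdc7i"))
    return("perturbation must be 'none' or 'cdc7i'")
  if (object@elongationDelayFrames < 0L)
    return("elongationDelayFrames must be >= 0")
  TRUE
})

#' Build a synthetic-movie configuration
#'
#' Returns a validated [SimConfig-class]. Defaults describe a two-cycle
#' movie (an 8.5 min then a 15.5 min S phase, 3 min mitoses) imaged at a
#' 20 s frame interval on a 256 x 256 field starting from 15 nuclei.
#' Transcription onset times follow a shifted exponential after S-phase
#' entry (shift 1.5 min + exponential mean 1.5 min, i.e. mean onset 3 min
#' into S phase); the 3' reporter signal lags the 5' signal by
#' \code{elongationDelayFrames} (default 10 frames = 200 s).
#'
#' The \code{"cdc7i"} perturbation preset (kinase-inhibited embryos)
#' delays kinase recruitment into S phase, prolongs bookmark persistence,
#' delays transcription onset, raises the per-frame OFF probability and
#' makes half of the transcribing spots fail to acquire a 3' signal.
#' Explicit arguments always override the preset.
#'
#' @param perturbation \code{"none"} or \code{"cdc7i"}.
#' @param rngSeed integer seed; identical config + seed gives bit-identical
#'   output from [simulateEmbryoMovie()].
#' @param ... any slot of [SimConfig-class] by name.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(imageSize = c(96, 96), initialNuclei = 4, rngSeed = 1)
#' @export
simConfig <- function(perturbation = c("none", "cdc7i"), rngSeed = 1L, ...) {
  perturbation <- match.arg(perturbation)
  defaults <- list(
    imageSize             = c(256L, 256L),
    frameInterval         = 20,
    sPhaseMinutes         = c(8.5, 15.5),
    mitosisMinutes        = c(3, 3),
    initialNuclei         = 15L,
    nuclearRadius         = 11,
    radiusDecay           = 0.8,
    channels              = c("bookmark", "kinase", "mcp", "pcp"),
    bodyAmplitudes        = c(bookmark = 1.5, kinase = 1.2, polymerase = 1.5,
                              mcp = 1.0, pcp = 1.0, histone = 4.0),
    focusAmplitudes       = c(bookmark = 3.0, kinase = 2.5, polymerase = 2.0,
                              mcp = 3.0, pcp = 2.5, histone = 0),
    fociPerNucleus        = 2L,
    focusSigma            = 1.8,
    bookmarkAppearMin     = 2,
    bookmarkDispersalMin  = 1,
    kinaseLeadMin         = 1,
    kinaseDelayMin        = 0,
    kinaseDispersalMin    = 1,
    polAppearMin          = 2,
    onTimeShiftMin        = 1.5,
    onTimeMeanMin         = 1.5,
    offProbPerFrame       = 0.01,
    elongationDelayFrames = 10L,
    elongationFailureProb = 0,
    baseline              = 0.2,
    photonScale           = 100,
    readNoiseSd           = 0.02,
    driftSd               = 0.2,
    rngSeed               = 1L,
    perturbation          = "none"
  )
  preset <- switch(perturbation,
    none  = list(),
    cdc7i = list(
      bookmarkDispersalMin  = 3,
      kinaseLeadMin         = 0,
      kinaseDelayMin        = 1,
      onTimeShiftMin        = 3,
      onTimeMeanMin         = 3,
      offProbPerFrame       = 0.06,
      elongationFailureProb = 0.5
    )
  )
  user <- list(...)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown SimConfig parameter(s): ", paste(bad, collapse = ", "))
  args <- utils::modifyList(utils::modifyList(defaults, preset), user)
  args$perturbation <- perturbation
  args$rngSeed <- as.integer(rngSeed)
  ints <- c("imageSize", "initialNuclei", "fociPerNucleus",
            "elongationDelayFrames", "rngSeed")
  for (nm in ints) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list(Class = "SimConfig"), args))
}

#' Partition a movie into nuclear-cycle phases
#'
#' Alternating S and M blocks (S first), each lasting its configured
#' duration rounded to whole frames at the configured frame interval.
#' The nucleus count doubles at each M-to-S boundary.
#'
#' @param config a [SimConfig-class].
#' @param nFrames optional total frame count; defaults to the summed block
#'   lengths. An error is raised if the schedule exceeds \code{nFrames}.
#' @return A list with \code{phase} (character per frame, \code{"S"}/\code{"M"}),
#'   \code{cycle} (integer per frame, 1-based), \code{sStarts} (1-based first
#'   frame of each S block), \code{nFrames}, and \code{nucleiPerCycle}
#'   (count alive during each cycle).
#' @examples
#' cfg <- simConfig(sPhaseMinutes = c(3, 3), mitosisMinutes = c(1, 1),
#'                  initialNuclei = 4)
#' sc <- scheduleCycles(cfg)
#' table(sc$phase)
#' @export
scheduleCycles <- function(config, nFrames = NULL) {
  stopifnot(is(config, "SimConfig"))
  dt <- config@frameInterval
  sFrames <- pmax(1L, as.integer(round(config@sPhaseMinutes * 60 / dt)))
  mFrames <- pmax(1L, as.integer(round(config@mitosisMinutes * 60 / dt)))
  nCycles <- length(sFrames)
  phase <- character(0); cycle <- integer(0); sStarts <- integer(0)
  for (i in seq_len(nCycles)) {
    sStarts <- c(sStarts, length(phase) + 1L)
    phase <- c(phase, rep("S", sFrames[i]))
    cycle <- c(cycle, rep(i, sFrames[i]))
    if (i <= length(mFrames)) {
      phase <- c(phase, rep("M", mFrames[i]))
      cycle <- c(cycle, rep(i, mFrames[i]))
    }
  }
  total <- length(phase)
  if (is.null(nFrames)) nFrames <- total
  if (total > nFrames)
    stop("cycle schedule (", total, " frames) exceeds movie length (",
         nFrames, " frames)")
  list(
    phase = phase, cycle = cycle, sStarts = sStarts, nFrames = total,
    nucleiPerCycle = config@initialNuclei * 2L^(seq_len(nCycles) - 1L)
  )
}
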