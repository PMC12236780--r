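#' Write ground truth to CSV tables
#'
#' Serialises a [GroundTruth-class] as six CSV files
#' (\code{nuclei.csv}, \code{foci.csv}, \code{states.csv},
#' \code{state_summary.csv}, \code{spots.csv}, \code{cycles.csv}) under
#' \code{dir}; round-trips losslessly through [readGroundTruth()].
#' Empty tables are written as a header-only CSV.
#'
#' @param gt a [GroundTruth-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeGroundTruth <- function(gt, dir) {
  stopifnot(is(gt, "GroundTruth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(gt@nuclei, file.path(dir, "nuclei.csv"), row.names = FALSE)
  write.csv(gt@foci, file.path(dir, "foci.csv"), row.names = FALSE)
  write.csv(gt@states, file.path(dir, "states.csv"), row.names = FALSE)
  write.csv(gt@stateSummary, file.path(dir, "state_summary.csv"),
            row.names = FALSE)
  write.csv(gt@spots, file.path(dir, "spots.csv"), row.names = FALSE)
  cyc <- gt@cycles
  cyc$sStart <- cyc$frame %in% gt@sStarts
  write.csv(cyc, file.path(dir, "cycles.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read ground truth written by [writeGroundTruth()]
#'
#' @param dir directory containing the CSV tables.
#' @return A [GroundTruth-class].
#' @export
readGroundTruth <- function(dir) {
  rd <- function(f, colClasses = NA)
    read.csv(file.path(dir, f), colClasses = colClasses)
  cyc <- rd("cycles.csv")
  sStarts <- as.integer(cyc$frame[cyc$sStart])
  summ <- rd("state_summary.csv")
  for (nm in c("firstOn", "firstOffAfterOn"))   # all-NA columns read as logical
    summ[[nm]] <- as.numeric(summ[[nm]])
  new("GroundTruth",
      nuclei = rd("nuclei.csv"),
      foci = rd("foci.csv"),
      states = rd("states.csv"),
      stateSummary = summ,
      spots = rd("spots.csv"),
      cycles = cyc[, c("frame", "cycle", "phase")],
      sStarts = sStarts)
}
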