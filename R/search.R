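#' Search a proteome for opsin-domain homologs
#'
#' Aligns every proteome sequence to every reference (semi-global,
#' BLOSUM62/affine by default), picks the best-scoring reference (ties go to
#' the lexicographically smallest reference id), and retains a hit iff
#' identity >= \code{minIdentity}, query coverage >= \code{minCoverage}, and
#' the profile-gate score reaches the decoy-calibrated cutoff ("standard"
#' preset: decoy mean + 4 SD; "strict": + 6 SD). The profile gate stands in
#' for a rhodopsin-domain scan.
#'
#' @param proteome \code{AAStringSet} of query proteins (possibly empty).
#' @param references named \code{AAStringSet} reference panel.
#' @param params \code{\link{alignmentParams}}.
#' @param config \code{\link{screenConfig}} list (identity/coverage
#'   thresholds, preset, calibration settings).
#' @param referenceAlignment gapped alignment used to build the profile gate
#'   (default: packaged panel alignment).
#' @param gate optional precomputed result of
#'   \code{\link{calibrateProfileGate}} to avoid re-calibration.
#' @return \code{DataFrame} with one row per retained hit: \code{query},
#'   \code{bestRef}, \code{score}, \code{identity}, \code{coverage},
#'   \code{profileScore}, \code{passesDomainGate}.
#' @export
searchProteome <- function(proteome, references,
                           params = alignmentParams(),
                           config = screenConfig(),
                           referenceAlignment = referencePanelAlignment(),
                           gate = NULL) {
  if (length(references) == 0) stop("reference panel is empty", call. = FALSE)
  emptyHits <- S4Vectors::DataFrame(
    query = character(0), bestRef = character(0), score = numeric(0),
    identity = numeric(0), coverage = numeric(0),
    profileScore = numeric(0), passesDomainGate = logical(0))
  if (length(proteome) == 0) return(emptyHits)
  if (is.null(names(proteome)) || anyDuplicated(names(proteome)))
    stop("proteome sequences must carry unique names", call. = FALSE)
  kSd <- if (identical(config$preset, "strict")) config$sdStrict else config$sdStandard
  if (is.null(gate)) {
    profile <- buildProfile(referenceAlignment)
    gate <- calibrateProfileGate(profile, references, n = config$calibrationN,
                                 kSd = kSd, seed = config$calibrationSeed,
                                 gapOpen = config$gapOpen,
                                 gapExtend = config$gapExtend)
    gate$profile <- profile
  }
  refIds <- sort(names(references))
  scoreMat <- vapply(refIds, function(r)
    .batchScores(proteome, references[[r]], params), numeric(length(proteome)))
  scoreMat <- matrix(scoreMat, nrow = length(proteome),
                     dimnames = list(names(proteome), refIds))
  # ties resolved toward the lexicographically smallest id (column order)
  bestIdx <- apply(scoreMat, 1, which.max)
  bestRef <- refIds[bestIdx]
  rows <- lapply(seq_along(proteome), function(i) {
    q <- names(proteome)[i]
    al <- semiGlobalAlign(proteome[[i]], references[[bestRef[i]]], params,
                          queryId = q, subjectId = bestRef[i])
    ps <- profileScore(proteome[[i]], gate$profile,
                       gapOpen = config$gapOpen, gapExtend = config$gapExtend)
    passes <- ps >= gate$cutoff
    if (al@identity >= config$minIdentity &&
        al@coverage >= config$minCoverage && passes)
      S4Vectors::DataFrame(query = q, bestRef = bestRef[i], score = al@score,
                           identity = al@identity, coverage = al@coverage,
                           profileScore = ps, passesDomainGate = passes)
    else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(emptyHits)
  do.call(rbind, rows)
}
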