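#' Detect the retinal-biosynthesis gene complement of a proteome
#'
#' For each packaged exemplar (crtY, brp, crtE, crtB, crtI), a gene is
#' present iff any proteome sequence passes a decoy-calibrated semi-global
#' alignment-score gate against that exemplar (the "strict" preset,
#' decoy mean + 6 SD, mirrors a conservative homology cutoff).
#' Retinal capability is the conjunction crtY AND brp — the terminal steps
#' of retinal biosynthesis; all five flags are reported so the implication
#' "capable genomes carry the full crtE/crtB/crtI complement" stays checkable.
#'
#' @param proteome \code{AAStringSet}.
#' @param crtReferences named \code{AAStringSet} exemplar panel.
#' @param params \code{\link{alignmentParams}}.
#' @param config \code{\link{screenConfig}} (preset, calibration settings).
#' @param gates optional precomputed per-gene gates (named list from
#'   \code{\link{calibrateScoreGate}}).
#' @return \code{DataFrame} row with logical columns \code{crtY}, \code{brp},
#'   \code{crtE}, \code{crtB}, \code{crtI}, \code{retinalCapable},
#'   \code{partialComplement}.
#' @export
detectPathway <- function(proteome, crtReferences = crtPanel(),
                          params = alignmentParams(),
                          config = screenConfig(preset = "strict"),
                          gates = NULL) {
  kSd <- if (identical(config$preset, "strict")) config$sdStrict else config$sdStandard
  genes <- names(crtReferences)
  if (is.null(gates))
    gates <- lapply(stats::setNames(genes, genes), function(g)
      calibrateScoreGate(crtReferences[[g]], params, n = config$calibrationN,
                         kSd = kSd, seed = config$calibrationSeed))
  flags <- vapply(genes, function(g) {
    if (length(proteome) == 0) return(FALSE)
    any(.batchScores(proteome, crtReferences[[g]], params) >= gates[[g]]$cutoff)
  }, logical(1))
  need <- c("crtY", "brp")
  if (!all(need %in% genes))
    stop("crt panel must contain crtY and brp", call. = FALSE)
  capable <- unname(flags["crtY"] && flags["brp"])
  out <- S4Vectors::DataFrame(as.list(flags))
  out$retinalCapable <- capable
  out$partialComplement <- any(flags) && !capable
  out
}

#' Cross-tabulate opsin complements with retinal-biosynthesis genes
#'
#' Builds the genomes-by-classes presence/absence count matrix (opsin
#' families, ORP groups, crtY, brp) and the summary of genomes whose opsin
#' complement consists solely of ORPs — among which the count lacking
#' retinal capability is the quantity of interest: ORP-only genomes that
#' cannot make retinal corroborate a retinal-independent role.
#'
#' @param calls \code{DataFrame} of classified hits with a \code{genome}
#'   column (as produced by \code{\link{runScreen}}).
#' @param complements \code{DataFrame} of per-genome
#'   \code{\link{detectPathway}} rows with a \code{genome} column.
#' @return list with \code{matrix} (integer counts) and \code{summary}
#'   (\code{orpOnlyGenomes}, \code{orpOnlyLackingPathway} ids and count).
#' @export
cooccurrenceTable <- function(calls, complements) {
  classes <- c("BR", "BR2", "HR", "SRI", "SRII", "SR3", "MR",
               "ORP_A", "ORP_B", "crtY", "brp")
  genomes <- unique(c(calls$genome, complements$genome))
  mat <- matrix(0L, length(genomes), length(classes),
                dimnames = list(genomes, classes))
  if (nrow(calls)) {
    lab <- .classLabel(calls$family, calls$orpGroup)
    for (i in seq_len(nrow(calls)))
      if (lab[i] %in% classes)
        mat[calls$genome[i], lab[i]] <- mat[calls$genome[i], lab[i]] + 1L
  }
  for (i in seq_len(nrow(complements))) {
    g <- complements$genome[i]
    mat[g, "crtY"] <- as.integer(complements$crtY[i])
    mat[g, "brp"] <- as.integer(complements$brp[i])
  }
  canonical <- c("BR", "BR2", "HR", "SRI", "SRII", "SR3", "MR")
  hasOrp <- rowSums(mat[, c("ORP_A", "ORP_B"), drop = FALSE]) > 0
  # ORP_unassigned calls also count as ORPs for the ORP-only census
  if (nrow(calls)) {
    lab <- .classLabel(calls$family, calls$orpGroup)
    for (g in unique(calls$genome[lab == "ORP_unassigned"])) hasOrp[g] <- TRUE
  }
  noCanon <- rowSums(mat[, canonical, drop = FALSE]) == 0
  orpOnly <- rownames(mat)[hasOrp & noCanon]
  lacking <- orpOnly[mat[orpOnly, "crtY"] + mat[orpOnly, "brp"] == 0]
  list(matrix = mat,
       summary = list(orpOnlyGenomes = orpOnly,
                      orpOnlyLackingPathway = lacking,
                      orpOnlyLackingPathwayCount = length(lacking)))
}
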