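#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Alignment parameters
#'
#' Scoring parameters for pairwise protein alignment: a symmetric substitution
#' matrix plus affine gap costs under the convention that a gap of length k
#' costs \code{gapOpen + k * gapExtend}.
#'
#' @slot substMatrix symmetric integer substitution matrix (default BLOSUM62).
#' @slot gapOpen positive gap-opening cost (default 11).
#' @slot gapExtend positive per-residue gap-extension cost (default 1);
#'   must not exceed \code{gapOpen}.
#' @export
setClass("AlignmentParams",
  representation(substMatrix = "matrix", gapOpen = "numeric", gapExtend = "numeric"),
  validity = function(object) {
    m <- object@substMatrix
    if (!isTRUE(all.equal(m, t(m)))) return("substitution matrix must be symmetric")
    if (object@gapOpen <= 0 || object@gapExtend <= 0)
      return("gap costs must be positive")
    if (object@gapExtend > object@gapOpen)
      return("gapExtend must not exceed gapOpen")
    TRUE
  })

#' Pairwise alignment result
#'
#' A scored global or semi-global alignment of a query against a subject.
#' Identity is the fraction of identical residues over aligned columns
#' (gap columns count in the denominator); coverage is the fraction of the
#' query inside the aligned region.
#'
#' @slot queryId,subjectId sequence identifiers.
#' @slot score optimal alignment score.
#' @slot alignedQuery,alignedSubject equal-length gapped strings.
#' @slot queryStart,subjectStart 1-based positions of the first aligned
#'   residue within the original sequences (semi-global alignments clip ends).
#' @slot identity,coverage fractions in [0, 1].
#' @export
setClass("PairwiseAln",
  representation(queryId = "character", subjectId = "character",
                 score = "numeric", alignedQuery = "character",
                 alignedSubject = "character", queryStart = "integer",
                 subjectStart = "integer", identity = "numeric",
                 coverage = "numeric"),
  validity = function(object) {
    if (nchar(object@alignedQuery) != nchar(object@alignedSubject))
      return("aligned strings must have equal length")
    if (object@identity < 0 || object@identity > 1 ||
        object@coverage < 0 || object@coverage > 1)
      return("identity and coverage must lie in [0, 1]")
    TRUE
  })

#' Fingerprint position schema
#'
#' The set of functionally important residues read out of every query, in the
#' residue numbering of the packaged sensory rhodopsin II (SRII) reference:
#' signal-transduction positions (Y51, R72, D189, Y199), retinal-binding-pocket
#' positions (W76, V108, F127, W171, Y174, W178), and the Schiff-base lysine
#' column reported under the conventional label 216. The Schiff column is
#' defined structurally as the lysine column of the packaged reference
#' alignment; the numeric label is kept for continuity with bacteriorhodopsin
#' K216 usage.
#'
#' @slot referenceId id of the numbering reference in the packaged panel.
#' @slot positions named integer vector, names are position labels, strictly
#'   increasing.
#' @slot roles named character vector: "signaling", "retinal_pocket" or
#'   "schiff_base" per position.
#' @slot expected named character vector of canonical residues per position.
#' @export
setClass("FingerprintSchema",
  representation(referenceId = "character", positions = "integer",
                 roles = "character", expected = "character"),
  validity = function(object) {
    p <- object@positions
    if (is.unsorted(p, strictly = TRUE)) return("positions must be strictly increasing")
    if (anyDuplicated(names(p))) return("position labels must be unique")
    if (!identical(names(p), names(object@roles)) ||
        !identical(names(p), names(object@expected)))
      return("positions, roles and expected must share names")
    if (sum(object@roles == "schiff_base") != 1)
      return("exactly one schiff_base position required")
    TRUE
  })

#' Reference-to-query residue map
#'
#' For each schema position (in reference numbering), the corresponding
#' query position, or NA where the query has a gap at that column.
#'
#' @slot queryId,referenceId sequence identifiers.
#' @slot positions named integer vector (NA = gap), monotone increasing over
#'   non-gap entries.
#' @export
setClass("ResidueMap",
  representation(queryId = "character", referenceId = "character",
                 positions = "integer"),
  validity = function(object) {
    p <- object@positions[!is.na(object@positions)]
    if (length(p) > 1 && is.unsorted(p, strictly = TRUE))
      return("mapped query positions must be strictly increasing")
    TRUE
  })

#' Residue fingerprint
#'
#' Observed residues of one query at the schema positions; "-" marks a gap.
#'
#' @slot queryId sequence identifier.
#' @slot residues named character vector, one single-letter entry per schema
#'   position label.
#' @export
setClass("Fingerprint",
  representation(queryId = "character", residues = "character"),
  validity = function(object) {
    if (any(nchar(object@residues) != 1))
      return("residues must be single letters or '-'")
    if (is.null(names(object@residues)) || anyDuplicated(names(object@residues)))
      return("residues must be uniquely named by position label")
    TRUE
  })

#' Position-specific score profile
#'
#' Log-odds profile built from a gapped reference alignment; used as the
#' opsin-domain gate replacing a Pfam domain scan.
#'
#' @slot scores numeric matrix, 20 amino-acid rows by kept-column columns.
#' @slot columns integer indices of the kept source alignment columns.
#' @export
setClass("ScoreProfile",
  representation(scores = "matrix", columns = "integer"),
  validity = function(object) {
    if (nrow(object@scores) != 20) return("profile must have 20 amino-acid rows")
    if (ncol(object@scores) != length(object@columns))
      return("columns must index every profile column")
    TRUE
  })

#' Absorbance spectrum
#'
#' A wavelength/absorbance trace, wavelengths strictly increasing.
#'
#' @slot wavelength wavelengths in nm.
#' @slot absorbance matched absorbance values (AU).
#' @export
setClass("SpectrumRecord",
  representation(wavelength = "numeric", absorbance = "numeric"),
  validity = function(object) {
    if (length(object@wavelength) != length(object@absorbance))
      return("wavelength and absorbance must have equal length")
    if (length(object@wavelength) == 0) return("spectrum must be non-empty")
    if (is.unsorted(object@wavelength, strictly = TRUE))
      return("wavelengths must be strictly increasing")
    TRUE
  })

#' Screen result container
#'
#' Aggregated output of \code{\link{runScreen}}: per-query opsin calls,
#' fingerprints, per-class conservation, genomic context of ORP loci,
#' the species-by-class presence/absence matrix, per-genome retinal-pathway
#' complements, the optional NJ tree, and the summary counts.
#'
#' @slot calls \code{DataFrame} of classified hits, one row per query.
#' @slot fingerprints \code{DataFrame}, one row per query, one column per
#'   schema position.
#' @slot conservation data.frame of per-class, per-position modal residues.
#' @slot context \code{DataFrame} of neighborhood categories for ORP loci.
#' @slot pam integer presence/absence count matrix (genomes x classes).
#' @slot pathways \code{DataFrame} of per-genome crt/brp flags.
#' @slot tree \code{phylo} tree of hits, or NULL.
#' @slot summary list of headline counts.
#' @slot config list of thresholds used (logged verbatim into output bundles).
#' @export
setClass("OpsinScreen",
  representation(calls = "DataFrame", fingerprints = "DataFrame",
                 conservation = "data.frame", context = "DataFrame",
                 pam = "matrix", pathways = "DataFrame", tree = "ANY",
                 summary = "list", config = "list"),
  validity = function(object) {
    s <- object@summary
    need <- c("totalOpsins", "orps", "groupA", "groupB", "orpUnassigned")
    if (!all(need %in% names(s))) return("summary is missing required counts")
    if (s$orps != s$groupA + s$groupB + s$orpUnassigned)
      return("ORP count must equal group A + group B + unassigned")
    TRUE
  })
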