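#' @rdname OpsinScreen-class
#' @param object,x an \code{OpsinScreen} object.
#' @export
setGeneric("opsinCalls", function(x) standardGeneric("opsinCalls"))

#' @rdname OpsinScreen-class
#' @export
setGeneric("fingerprintTable", function(x) standardGeneric("fingerprintTable"))

#' @rdname OpsinScreen-class
#' @export
setGeneric("conservationTable", function(x) standardGeneric("conservationTable"))

#' @rdname OpsinScreen-class
#' @export
setGeneric("contextTable", function(x) standardGeneric("contextTable"))

#' @rdname OpsinScreen-class
#' @export
setGeneric("presenceAbsence", function(x) standardGeneric("presenceAbsence"))

#' @rdname OpsinScreen-class
#' @export
setGeneric("pathwayTable", function(x) standardGeneric("pathwayTable"))

#' @rdname OpsinScreen-class
#' @export
setGeneric("opsinTree", function(x) standardGeneric("opsinTree"))

#' @rdname OpsinScreen-class
#' @export
setGeneric("screenSummary", function(x) standardGeneric("screenSummary"))

#' @rdname OpsinScreen-class
#' @export
setMethod("opsinCalls", "OpsinScreen", function(x) x@calls)

#' @rdname OpsinScreen-class
#' @export
setMethod("fingerprintTable", "OpsinScreen", function(x) x@fingerprints)

#' @rdname OpsinScreen-class
#' @export
setMethod("conservationTable", "OpsinScreen", function(x) x@conservation)

#' @rdname OpsinScreen-class
#' @export
setMethod("contextTable", "OpsinScreen", function(x) x@context)

#' @rdname OpsinScreen-class
#' @export
setMethod("presenceAbsence", "OpsinScreen", function(x) x@pam)

#' @rdname OpsinScreen-class
#' @export
setMethod("pathwayTable", "OpsinScreen", function(x) x@pathways)

#' @rdname OpsinScreen-class
#' @export
setMethod("opsinTree", "OpsinScreen", function(x) x@tree)

#' @rdname OpsinScreen-class
#' @export
setMethod("screenSummary", "OpsinScreen", function(x) x@summary)

#' @rdname OpsinScreen-class
#' @export
setMethod("show", "OpsinScreen", function(object) {
  s <- object@summary
  cat("OpsinScreen:", nrow(object@pam), "genome(s),", s$totalOpsins,
      "opsin homolog(s)\n")
  cat("  ORPs:", s$orps, "(group A:", s$groupA, ", group B:", s$groupB,
      ", unassigned:", s$orpUnassigned, ")\n")
  if (!is.null(s$transducerAdjacentA))
    cat("  transducer-adjacent: A =", s$transducerAdjacentA,
        ", B =", s$transducerAdjacentB, "\n")
  if (!is.null(s$orpOnlyGenomesLackingPathway))
    cat("  ORP-only genomes lacking crtY+brp:",
        s$orpOnlyGenomesLackingPathway, "\n")
  invisible(object)
})

#' @rdname PairwiseAln-class
#' @param object a \code{PairwiseAln} object.
#' @export
setMethod("show", "PairwiseAln", function(object) {
  cat(sprintf("PairwiseAln %s vs %s: score %g, identity %.3f, coverage %.3f\n",
              object@queryId, object@subjectId, object@score,
              object@identity, object@coverage))
  invisible(object)
})

#' @rdname Fingerprint-class
#' @param object a \code{Fingerprint} object.
#' @export
setMethod("show", "Fingerprint", function(object) {
  cat("Fingerprint for", object@queryId, "\n")
  print(object@residues)
  invisible(object)
})

#' @rdname SpectrumRecord-class
#' @param object a \code{SpectrumRecord} object.
#' @export
setMethod("show", "SpectrumRecord", function(object) {
  cat(sprintf("SpectrumRecord: %d points, %g-%g nm\n",
              length(object@wavelength), min(object@wavelength),
              max(object@wavelength)))
  invisible(object)
})
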