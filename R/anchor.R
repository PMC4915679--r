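# full reference-position -> query-position mapping from a semi-global
# alignment of query vs reference; NA where the query has a gap or the
# reference position lies outside the aligned span
.referenceMapping <- function(query, reference, params,
                              queryId = "query", referenceId = "reference") {
  al <- semiGlobalAlign(query, reference, params, queryId, referenceId)
  qc <- strsplit(al@alignedQuery, "")[[1]]
  sc <- strsplit(al@alignedSubject, "")[[1]]
  refLen <- nchar(asCharacterSeq(reference))
  map <- rep(NA_integer_, refLen)
  if (length(sc)) {
    # start offsets of the clipped (aligned) regions within the originals
    qStart <- al@queryStart
    sStart <- al@subjectStart
    cumQ <- cumsum(qc != "-")
    cumS <- cumsum(sc != "-")
    cols <- which(sc != "-")
    refPos <- sStart - 1L + cumS[cols]
    qPos <- ifelse(qc[cols] == "-", NA_integer_, qStart - 1L + cumQ[cols])
    map[refPos] <- qPos
  }
  list(map = map, alignment = al)
}

#' Anchor a query to the numbering reference
#'
#' Semi-globally aligns a query to the schema's numbering reference (the
#' packaged SRII exemplar by default) and maps each schema position to the
#' corresponding query position, or NA where the query has a gap at that
#' column. Queries whose alignment identity falls below
#' \code{minIdentity} cannot be trusted to carry reference numbering and
#' raise an "unanchorable" error.
#'
#' @param query amino-acid sequence (character or \code{AAString}).
#' @param schema \code{\link{fingerprintSchema}}.
#' @param references named \code{AAStringSet} containing the schema
#'   reference.
#' @param params \code{\link{alignmentParams}}.
#' @param minIdentity anchoring identity floor (default 0.15).
#' @param queryId identifier recorded in the map.
#' @return \code{\link{ResidueMap-class}} object.
#' @export
anchorToReference <- function(query, schema = fingerprintSchema(),
                              references = referencePanel(),
                              params = alignmentParams(),
                              minIdentity = 0.15, queryId = "query") {
  ref <- references[[schema@referenceId]]
  if (is.null(ref)) stop("schema reference '", schema@referenceId,
                         "' not in panel", call. = FALSE)
  res <- .referenceMapping(query, ref, params, queryId, schema@referenceId)
  if (res$alignment@identity < minIdentity)
    stop("unanchorable: identity ", sprintf("%.3f", res$alignment@identity),
         " below ", minIdentity, " for '", queryId, "'", call. = FALSE)
  pos <- res$map[schema@positions]
  names(pos) <- names(schema@positions)
  new("ResidueMap", queryId = queryId, referenceId = schema@referenceId,
      positions = pos)
}

#' Extract the residue fingerprint of a query
#'
#' Reads the query residues at the positions given by a
#' \code{\link{ResidueMap-class}}; positions mapping to a gap yield "-".
#'
#' @param query amino-acid sequence the map refers to.
#' @param map \code{\link{ResidueMap-class}} from
#'   \code{\link{anchorToReference}}.
#' @param schema \code{\link{fingerprintSchema}} (defines the position set).
#' @return \code{\link{Fingerprint-class}} object.
#' @export
extractFingerprint <- function(query, map, schema = fingerprintSchema()) {
  s <- asCharacterSeq(query)
  pos <- map@positions[names(schema@positions)]
  res <- vapply(pos, function(p)
    if (is.na(p)) "-" else substr(s, p, p), character(1))
  names(res) <- names(schema@positions)
  new("Fingerprint", queryId = map@queryId, residues = res)
}

#' Fingerprint residues accessor
#'
#' @param fp \code{\link{Fingerprint-class}} object.
#' @return named character vector of residues ("-" = gap).
#' @export
fingerprintResidues <- function(fp) fp@residues
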