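#' Construct alignment parameters
#'
#' @param substMatrix substitution matrix name or matrix (default BLOSUM62).
#' @param gapOpen gap-opening cost; a gap of length k costs
#'   \code{gapOpen + k * gapExtend}.
#' @param gapExtend per-residue gap-extension cost.
#' @return \code{\link{AlignmentParams-class}} object.
#' @export
alignmentParams <- function(substMatrix = "BLOSUM62", gapOpen = 11,
                            gapExtend = 1) {
  if (is.character(substMatrix)) {
    e <- new.env()
    utils::data(list = substMatrix, package = "Biostrings", envir = e)
    substMatrix <- get(substMatrix, envir = e)
  }
  keep <- intersect(rownames(substMatrix), c(AA20, "X"))
  new("AlignmentParams", substMatrix = substMatrix[keep, keep],
      gapOpen = gapOpen, gapExtend = gapExtend)
}

# shared driver over Biostrings; type "global" (Needleman-Wunsch) or
# "overlap" (semi-global: free end gaps on both sequences)
.pairAlign <- function(a, b, params, type, queryId = "query",
                       subjectId = "subject") {
  a <- asCharacterSeq(a); b <- asCharacterSeq(b)
  checkAlphabet(a, "query"); checkAlphabet(b, "subject")
  if (nchar(a) == 0 && nchar(b) == 0)
    return(new("PairwiseAln", queryId = queryId, subjectId = subjectId,
               score = 0, alignedQuery = "", alignedSubject = "",
               queryStart = 1L, subjectStart = 1L,
               identity = 0, coverage = 0))
  if (nchar(a) == 0 || nchar(b) == 0) {
    k <- max(nchar(a), nchar(b))
    gapcost <- if (type == "global") -(params@gapOpen + k * params@gapExtend) else 0
    return(new("PairwiseAln", queryId = queryId, subjectId = subjectId,
               score = gapcost,
               alignedQuery = if (nchar(a)) a else strrep("-", k),
               alignedSubject = if (nchar(b)) b else strrep("-", k),
               queryStart = 1L, subjectStart = 1L,
               identity = 0, coverage = if (nchar(a)) 1 else 0))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = params@substMatrix,
    gapOpening = params@gapOpen, gapExtension = params@gapExtend, type = type)
  aq <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  qc <- strsplit(aq, "")[[1]]; sc <- strsplit(as_, "")[[1]]
  ident <- if (length(qc)) sum(qc == sc & qc != "-") / length(qc) else 0
  cov <- sum(qc != "-") / nchar(a)
  new("PairwiseAln", queryId = queryId, subjectId = subjectId,
      score = Biostrings::score(pa), alignedQuery = aq, alignedSubject = as_,
      queryStart = as.integer(Biostrings::start(Biostrings::pattern(pa))),
      subjectStart = as.integer(Biostrings::start(Biostrings::subject(pa))),
      identity = ident, coverage = cov)
}

#' Global pairwise alignment
#'
#' Optimal Needleman-Wunsch alignment under affine gap costs
#' (a gap of length k costs \code{gapOpen + k * gapExtend}; end gaps are
#' penalized).
#'
#' @param a,b amino-acid sequences (character or \code{AAString}).
#' @param params \code{\link{alignmentParams}}.
#' @param queryId,subjectId identifiers recorded in the result.
#' @return \code{\link{PairwiseAln-class}} object.
#' @examples
#' score(globalAlign("AAA", "AAA"))  # 12: three A:A matches
#' @export
globalAlign <- function(a, b, params = alignmentParams(), queryId = "query",
                        subjectId = "subject") {
  .pairAlign(a, b, params, "global", queryId, subjectId)
}

#' Semi-global pairwise alignment
#'
#' Like \code{\link{globalAlign}} but with free end gaps on both sequences
#' (overlap alignment), the mode used for proteome searching: the opsin
#' domain spans most of these short proteins, so terminal overhangs are not
#' penalized.
#'
#' @inheritParams globalAlign
#' @return \code{\link{PairwiseAln-class}} object.
#' @export
semiGlobalAlign <- function(a, b, params = alignmentParams(),
                            queryId = "query", subjectId = "subject") {
  .pairAlign(a, b, params, "overlap", queryId, subjectId)
}

#' @rdname PairwiseAln-class
#' @param x a \code{PairwiseAln} object.
#' @importFrom BiocGenerics score
#' @export
setMethod("score", "PairwiseAln", function(x, ...) x@score)

# vectorized semi-global scores of many queries against one subject
.batchScores <- function(queries, subject, params) {
  if (length(queries) == 0) return(numeric(0))
  if (!is.null(S4Vectors::mcols(queries)))
    S4Vectors::mcols(queries) <- NULL   # silence the drop notice
  Biostrings::pairwiseAlignment(
    queries, Biostrings::AAString(asCharacterSeq(subject)),
    substitutionMatrix = params@substMatrix,
    gapOpening = params@gapOpen, gapExtension = params@gapExtend,
    type = "overlap", scoreOnly = TRUE)
}
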