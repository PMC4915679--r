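#' Gene neighborhood of a target locus
#'
#' Up to \code{windowGenes} features on each side of the target, on the same
#' genome and contig, with signed gene-rank distances (-1 = immediately
#' upstream in coordinate order, +1 = immediately downstream).
#'
#' @param features sorted \code{GRanges} from \code{\link{readGff}} or
#'   \code{\link{generateGenomeAnnotation}}.
#' @param locusId target locus identifier.
#' @param windowGenes neighborhood half-width in genes; 0 gives an empty
#'   neighborhood.
#' @return \code{DataFrame} with columns \code{rank}, \code{locus_id},
#'   \code{product}, \code{strand}.
#' @export
neighborhood <- function(features, locusId, windowGenes = 10) {
  hit <- which(features$locus_id == locusId)
  if (length(hit) != 1)
    stop("target locus '", locusId, "' not found", call. = FALSE)
  g <- features$genome_id[hit]
  ctg <- as.character(GenomicRanges::seqnames(features))[hit]
  same <- which(features$genome_id == g &
                as.character(GenomicRanges::seqnames(features)) == ctg)
  ord <- same[order(GenomicRanges::start(features)[same])]
  center <- match(hit, ord)
  idx <- seq(max(1, center - windowGenes), min(length(ord), center + windowGenes))
  idx <- idx[idx != center]
  nb <- ord[idx]
  S4Vectors::DataFrame(
    rank = idx - center,
    locus_id = features$locus_id[nb],
    product = features$product[nb],
    strand = as.character(GenomicRanges::strand(features))[nb])
}

# category of one product string under the vocabulary (first match in
# priority order), or NA
.productCategory <- function(product, vocab) {
  for (i in seq_len(nrow(vocab)))
    if (grepl(vocab$keyword[i], product, ignore.case = TRUE, fixed = FALSE))
      return(vocab$category[i])
  NA_character_
}

#' Classify the genomic context of a locus
#'
#' Applies the neighborhood rules: \code{transducer_adjacent} iff a
#' transducer-category neighbor (HAMP/MCP signal transducer) lies within
#' |rank| <= \code{adjacencyRank}; else \code{taxis_operon_proximal} iff at
#' least two taxis-operon-category neighbors (chemotaxis/flagellar genes)
#' lie within |rank| <= \code{proximityRank}; else \code{stress_proximal}
#' iff at least one stress-category neighbor lies within
#' \code{proximityRank}; else \code{unlinked}.
#'
#' @param neighbors \code{DataFrame} from \code{\link{neighborhood}}.
#' @param vocab vocabulary data.frame from \code{\link{contextVocabulary}}.
#' @param adjacencyRank gene-rank distance defining "adjacent" (default 1,
#'   i.e. no intervening gene, either strand).
#' @param proximityRank gene-rank distance defining "proximal" (default 10).
#' @return list with \code{category}, supporting \code{loci} and their
#'   \code{ranks}.
#' @export
classifyContext <- function(neighbors, vocab = contextVocabulary(),
                            adjacencyRank = 1, proximityRank = 10) {
  n <- nrow(neighbors)
  cats <- if (n) vapply(neighbors$product, .productCategory, character(1),
                        vocab = vocab, USE.NAMES = FALSE)
          else character(0)
  absRank <- abs(neighbors$rank)
  pick <- function(sel) list(loci = neighbors$locus_id[sel],
                             ranks = neighbors$rank[sel])
  sel <- !is.na(cats) & cats == "transducer" & absRank <= adjacencyRank
  if (any(sel)) return(c(list(category = "transducer_adjacent"), pick(sel)))
  sel <- !is.na(cats) & cats == "taxis_operon" & absRank <= proximityRank
  if (sum(sel) >= 2) return(c(list(category = "taxis_operon_proximal"), pick(sel)))
  sel <- !is.na(cats) & cats == "stress" & absRank <= proximityRank
  if (any(sel)) return(c(list(category = "stress_proximal"), pick(sel)))
  list(category = "unlinked", loci = character(0), ranks = integer(0))
}
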