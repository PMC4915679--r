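#' Packaged opsin reference panel
#'
#' One synthetic exemplar per haloarchaeal opsin family (BR, BR2, HR, SRI,
#' SRII, SR3, MR), built so that the SRII exemplar carries the canonical
#' fingerprint residues at their literal sensory-rhodopsin-II positions
#' (Y51, R72, W76, V108, F127, W171, Y174, W178, D189, Y199 and the
#' Schiff-base K216 column). Real deposited opsin sequences can be swapped in
#' by pointing \code{path} at any FASTA whose ids are family labels.
#'
#' @param path FASTA path; defaults to the packaged synthetic panel.
#' @return named \code{AAStringSet}.
#' @export
referencePanel <- function(path = orpscanExtdata("opsin_panel_synthetic.faa")) {
  readFasta(path)
}

#' Packaged gapped reference alignment
#'
#' Equal-length gapped alignment of the reference panel, used to build the
#' profile score gate and to define the Schiff-base column structurally.
#'
#' @param path FASTA path; defaults to the packaged synthetic alignment.
#' @return named \code{AAStringSet} of equal widths.
#' @export
referencePanelAlignment <- function(
    path = orpscanExtdata("opsin_panel_alignment_synthetic.faa")) {
  aln <- readFasta(path)
  if (length(unique(Biostrings::width(aln))) != 1)
    stop("reference alignment is ragged", call. = FALSE)
  aln
}

#' Packaged retinal-biosynthesis reference panel
#'
#' One synthetic exemplar each for crtY (lycopene cyclase), brp, crtE, crtB
#' and crtI, used by \code{\link{detectPathway}}.
#'
#' @param path FASTA path; defaults to the packaged synthetic panel.
#' @return named \code{AAStringSet}.
#' @export
crtPanel <- function(path = orpscanExtdata("crt_panel_synthetic.faa")) {
  readFasta(path)
}

#' Default fingerprint schema
#'
#' The position set read out of every anchored query, in SRII numbering:
#' signaling Y51, R72, D189, Y199; retinal pocket W76, V108, F127, W171,
#' Y174, W178; Schiff base K216 (column label kept for continuity with
#' bacteriorhodopsin numbering).
#'
#' @param referenceId id of the numbering reference within the panel.
#' @return \code{\link{FingerprintSchema-class}} object.
#' @export
fingerprintSchema <- function(referenceId = "SRII") {
  pos <- c(`51` = 51L, `72` = 72L, `76` = 76L, `108` = 108L, `127` = 127L,
           `171` = 171L, `174` = 174L, `178` = 178L, `189` = 189L,
           `199` = 199L, `216` = 216L)
  roles <- c(`51` = "signaling", `72` = "signaling", `76` = "retinal_pocket",
             `108` = "retinal_pocket", `127` = "retinal_pocket",
             `171` = "retinal_pocket", `174` = "retinal_pocket",
             `178` = "retinal_pocket", `189` = "signaling",
             `199` = "signaling", `216` = "schiff_base")
  expected <- c(`51` = "Y", `72` = "R", `76` = "W", `108` = "V", `127` = "F",
                `171` = "W", `174` = "Y", `178` = "W", `189` = "D",
                `199` = "Y", `216` = "K")
  new("FingerprintSchema", referenceId = referenceId, positions = pos,
      roles = roles, expected = expected)
}

#' Gene-neighborhood keyword vocabulary
#'
#' Maps product annotation strings to context categories by case-insensitive
#' substring match, first category wins in priority order
#' transducer > taxis_operon > stress. Shipped as an editable TSV.
#'
#' @param path vocabulary TSV (columns \code{category}, \code{keyword});
#'   defaults to the packaged file.
#' @return data.frame with columns \code{category} and \code{keyword},
#'   ordered by category priority.
#' @export
contextVocabulary <- function(path = orpscanExtdata("context_vocabulary.tsv")) {
  v <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("category", "keyword") %in% names(v)))
  order_ <- c("transducer", "taxis_operon", "stress")
  bad <- setdiff(v$category, order_)
  if (length(bad)) stop("unknown vocabulary category: ",
                        paste(unique(bad), collapse = ", "), call. = FALSE)
  v[order(match(v$category, order_)), , drop = FALSE]
}
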