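#' Schiff-base lysine test
#'
#' Classifies a fingerprint by its Schiff-base column: the conserved lysine
#' gives "canonical", a gap (truncation rather than substitution) gives
#' "unassigned", and any other residue marks an opsin-related protein (ORP).
#'
#' @param fp \code{\link{Fingerprint-class}} object.
#' @return one of "canonical", "ORP", "unassigned".
#' @export
schiffBaseTest <- function(fp) {
  labels <- names(fp@residues)
  if (!"216" %in% labels) stop("fingerprint lacks the Schiff-base entry",
                               call. = FALSE)
  r <- fp@residues[["216"]]
  if (r == "K") "canonical" else if (r == "-") "unassigned" else "ORP"
}

#' ORP group assignment
#'
#' Splits ORPs by the residue replacing the Schiff-base lysine: arginine
#' defines group A; a hydrophobic residue (leucine or another member of the
#' configured hydrophobic set) defines group B; anything else is unassigned.
#' Glycine and tryptophan are deliberately excluded from the hydrophobic set
#' (glycine appears at other fingerprint columns; tryptophan is
#' aromatic-bulky).
#'
#' @param fp \code{\link{Fingerprint-class}} object for which
#'   \code{\link{schiffBaseTest}} returned "ORP".
#' @param hydrophobicSet residues defining group B, as a string.
#' @return one of "A", "B", "unassigned".
#' @export
orpGroup <- function(fp, hydrophobicSet = "LIVMFA") {
  if (schiffBaseTest(fp) != "ORP")
    stop("orpGroup() called on a non-ORP fingerprint", call. = FALSE)
  r <- fp@residues[["216"]]
  hyd <- strsplit(hydrophobicSet, "")[[1]]
  if (r == "R") "A" else if (r %in% hyd) "B" else "unassigned"
}

#' Assign an opsin family to one hit
#'
#' ORPs (by the Schiff-base test) get family "ORP" with a group from
#' \code{\link{orpGroup}}; hits with a gap at the Schiff column are
#' "unassigned"; all other hits inherit the family label of their nearest
#' reference by alignment score, a desk-scale stand-in for tree-clade
#' affiliation (the NJ monophyly check in \code{\link{runScreen}}
#' corroborates it).
#'
#' @param hit one row of the \code{\link{searchProteome}} result.
#' @param fp \code{\link{Fingerprint-class}} for the same query.
#' @param hydrophobicSet residues defining ORP group B.
#' @return \code{DataFrame} row: \code{query}, \code{family},
#'   \code{orpGroup}, \code{nearestRef}, \code{score}.
#' @export
assignFamily <- function(hit, fp, hydrophobicSet = "LIVMFA") {
  stopifnot(identical(hit$query, fp@queryId))
  verdict <- schiffBaseTest(fp)
  if (verdict == "ORP") {
    fam <- "ORP"; grp <- orpGroup(fp, hydrophobicSet)
  } else if (verdict == "unassigned") {
    fam <- "unassigned"; grp <- "n/a"
  } else {
    fam <- hit$bestRef; grp <- "n/a"
  }
  S4Vectors::DataFrame(query = hit$query, family = fam, orpGroup = grp,
                       nearestRef = hit$bestRef, score = hit$score)
}

# class label used in conservation and presence/absence tables
.classLabel <- function(family, group) {
  ifelse(family == "ORP",
         ifelse(group == "A", "ORP_A",
                ifelse(group == "B", "ORP_B", "ORP_unassigned")),
         family)
}

#' Per-class residue conservation report
#'
#' For every class label (opsin family or ORP group) and every schema
#' position, the modal residue, the fraction of sequences carrying it, and
#' the class size. Classes with no members are omitted.
#'
#' @param calls \code{DataFrame} of classified hits (columns \code{query},
#'   \code{family}, \code{orpGroup}).
#' @param fingerprints named list of \code{\link{Fingerprint-class}} objects
#'   keyed by query id.
#' @return data.frame with columns \code{class}, \code{position},
#'   \code{modal}, \code{fraction}, \code{n}.
#' @export
conservationReport <- function(calls, fingerprints) {
  if (nrow(calls) == 0) stop("no calls to summarize", call. = FALSE)
  labels <- .classLabel(calls$family, calls$orpGroup)
  posNames <- names(fingerprints[[calls$query[1]]]@residues)
  out <- list()
  for (cl in unique(labels)) {
    qs <- calls$query[labels == cl]
    mat <- do.call(rbind, lapply(qs, function(q) fingerprints[[q]]@residues))
    for (p in posNames) {
      tab <- sort(table(mat[, p]), decreasing = TRUE)
      out[[length(out) + 1]] <- data.frame(
        class = cl, position = p, modal = names(tab)[1],
        fraction = as.numeric(tab[1]) / length(qs), n = length(qs))
    }
  }
  do.call(rbind, out)
}
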