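#' Pairwise distance matrix from a gapped alignment
#'
#' p-distance over columns where neither sequence has a gap (pairwise
#' deletion, suited to fragmentary queries), optionally Poisson-corrected
#' (\code{-ln(1 - p)}).
#'
#' @param alignment \code{AAStringSet} or character vector of equal-length
#'   gapped sequences (>= 2, uniquely named).
#' @param correction "p" (raw proportion) or "poisson".
#' @return symmetric numeric matrix with zero diagonal, labelled by sequence
#'   names.
#' @export
distanceMatrix <- function(alignment, correction = c("p", "poisson")) {
  correction <- match.arg(correction)
  seqs <- toupper(asCharacterSeq(alignment))
  if (length(seqs) < 2) stop("at least 2 sequences required", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1)
    stop("ragged alignment", call. = FALSE)
  labs <- names(seqs)
  if (is.null(labs) || anyDuplicated(labs))
    stop("sequences must carry unique names", call. = FALSE)
  m <- do.call(rbind, strsplit(seqs, ""))
  isGap <- m == "-" | m == "."
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !isGap[i, ] & !isGap[j, ]
    if (!any(ok))
      stop("no comparable columns between '", labs[i], "' and '", labs[j],
           "'", call. = FALSE)
    p <- mean(m[i, ok] != m[j, ok])
    if (correction == "poisson") {
      if (p >= 1) stop("saturated: p >= 1 between '", labs[i], "' and '",
                       labs[j], "'", call. = FALSE)
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a symmetric distance matrix (delegated to
#' \code{ape::nj}), with validation, a two-taxon special case (the single
#' edge of total length d is represented as two half-length pendant edges),
#' and clamping of negative branch-length estimates to zero — the clamped
#' amount is transferred to the sibling edge, with a warning.
#'
#' @param d symmetric numeric matrix with zero diagonal and labels.
#' @return \code{ape} \code{phylo} tree.
#' @export
neighborJoining <- function(d) {
  if (is.null(dim(d)) || nrow(d) != ncol(d))
    stop("distance matrix must be square", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(diag(d) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (any(!is.finite(d))) stop("distances must be finite", call. = FALSE)
  labs <- rownames(d)
  if (is.null(labs)) stop("distance matrix must be labelled", call. = FALSE)
  n <- nrow(d)
  if (n < 2) stop("at least 2 labels required", call. = FALSE)
  if (n == 2) {
    tr <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
               edge.length = rep(d[1, 2] / 2, 2),
               tip.label = labs, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  if (length(neg)) {
    warning(length(neg), " negative branch length(s) clamped to zero",
            call. = FALSE)
    for (e in neg) {
      parent <- tr$edge[e, 1]
      sib <- setdiff(which(tr$edge[, 1] == parent), e)
      if (length(sib))
        tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + tr$edge.length[e]
      tr$edge.length[e] <- 0
    }
  }
  tr
}

#' Test a label set for monophyly
#'
#' TRUE iff some edge of the (unrooted) tree bipartitions the leaves into
#' the label set versus its complement. Trivial sets (a single leaf, or all
#' leaves) are monophyletic by convention.
#'
#' @param tree \code{phylo} tree.
#' @param labels character vector of leaf labels.
#' @return logical flag.
#' @export
isMonophyletic <- function(tree, labels) {
  tips <- tree$tip.label
  unknown <- setdiff(labels, tips)
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  labels <- unique(labels)
  rest <- setdiff(tips, labels)
  if (length(rest) == 0 || length(labels) == 1) return(TRUE)
  # root at a leaf outside the set; the set is then an unrooted bipartition
  # iff it is a rooted clade
  rooted <- ape::root(tree, outgroup = rest[1], resolve.root = TRUE)
  ape::is.monophyletic(rooted, labels)
}

#' Write a tree in Newick format
#'
#' @param tree \code{phylo} tree.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
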