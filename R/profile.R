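#' Build a position score profile from a reference alignment
#'
#' Per-column log-odds scores (log2) of each amino acid against a background
#' distribution, from a gapped alignment of reference sequences. Columns with
#' more than \code{maxGapFrac} gaps are dropped. The profile plays the role of
#' a domain model: queries are scored against it and gated on a
#' decoy-calibrated cutoff (see \code{\link{calibrateProfileGate}}).
#'
#' @param alignment \code{AAStringSet} or character vector of equal-length
#'   gapped sequences (at least 2).
#' @param background amino-acid background frequencies (default uniform 1/20).
#' @param pseudocount added to each residue count per column.
#' @param maxGapFrac columns with a gap fraction above this are dropped.
#' @return \code{\link{ScoreProfile-class}} object.
#' @export
buildProfile <- function(alignment, background = rep(1/20, 20),
                         pseudocount = 0.5, maxGapFrac = 0.5) {
  seqs <- toupper(asCharacterSeq(alignment))
  if (length(seqs) < 2) stop("at least 2 sequences required", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1)
    stop("ragged alignment: sequences differ in length", call. = FALSE)
  background <- background / sum(background)
  names(background) <- AA20
  m <- do.call(rbind, strsplit(seqs, ""))
  gapFrac <- colMeans(m == "-" | m == ".")
  keep <- which(gapFrac <= maxGapFrac)
  if (length(keep) == 0) stop("no columns survive the gap filter", call. = FALSE)
  scores <- vapply(keep, function(j) {
    col <- m[, j]
    cnt <- table(factor(col[col %in% AA20], levels = AA20))
    n <- sum(cnt)
    p <- (as.numeric(cnt) + pseudocount) / (n + 20 * pseudocount)
    log2(p / background)
  }, numeric(20))
  rownames(scores) <- AA20
  new("ScoreProfile", scores = scores, columns = as.integer(keep))
}

#' Score a sequence against a profile
#'
#' Best semi-global alignment score of a query against the profile: the whole
#' profile must be traversed (column deletions pay affine gap costs), while
#' query residues before the first and after the last matched column are free.
#' Internal query insertions pay affine gap costs. Gap convention matches
#' \code{\link{alignmentParams}}: a gap of length k costs
#' \code{gapOpen + k * gapExtend}.
#'
#' @param seq amino-acid sequence.
#' @param profile \code{\link{ScoreProfile-class}} object.
#' @param gapOpen,gapExtend affine gap costs.
#' @return numeric alignment score (log2 odds units).
#' @export
profileScore <- function(seq, profile, gapOpen = 11, gapExtend = 1) {
  s <- toupper(asCharacterSeq(seq))
  checkAlphabet(s)
  q <- strsplit(s, "")[[1]]
  m <- length(q)
  S <- profile@scores
  n <- ncol(S)
  xScore <- rep(0, 20)  # X matches any column at score 0 (uninformative)
  emit <- function(j) {
    v <- S[, j][q]
    v[is.na(v)] <- 0
    v
  }
  if (m == 0) return(-(gapOpen + n * gapExtend))
  open1 <- gapOpen + gapExtend
  NEG <- -1e9
  # H[i, j] = best score with first j profile columns consumed and query
  # prefix i consumed; insertions (extra query residues) handled by a
  # cummax running-max trick, deletions (skipped columns) chain along j.
  Hprev <- rep(0, m + 1)     # j = 0: any query prefix is free
  Dprev <- rep(NEG, m + 1)
  for (j in seq_len(n)) {
    e <- emit(j)
    # insertion state entering column j: best over k < i of Hprev[k] minus
    # affine cost of inserting (i - k) query residues after column j-1
    best <- cummax(Hprev[seq_len(m)] + (seq_len(m) - 1) * gapExtend)
    ins <- c(NEG, best - open1 - (seq_len(m) - 1) * gapExtend)
    diagIn <- pmax(Hprev, ins)              # entering (i-1, j-1)
    M <- c(NEG, diagIn[seq_len(m)] + e)     # column j matched to residue i
    D <- pmax(Hprev - open1, Dprev - gapExtend)  # column j deleted
    Hprev <- pmax(M, D)
    Dprev <- D
  }
  max(Hprev)  # trailing query residues are free
}

#' Dipeptide-preserving shuffle
#'
#' Shuffles a sequence as non-overlapping dipeptide blocks, preserving local
#' composition biases; \code{mode = "residue"} gives a plain residue shuffle.
#' Used to generate decoys for gate calibration and synthetic proteomes.
#'
#' @param seq amino-acid sequence.
#' @param mode "dipeptide" (default) or "residue".
#' @return shuffled character string of the same length and composition.
#' @export
shuffleSequence <- function(seq, mode = c("dipeptide", "residue")) {
  mode <- match.arg(mode)
  q <- strsplit(toupper(asCharacterSeq(seq)), "")[[1]]
  if (mode == "residue") return(paste(sample(q), collapse = ""))
  n <- length(q)
  starts <- seq(1, n, by = 2)
  blocks <- lapply(starts, function(i) q[i:min(i + 1, n)])
  paste(unlist(blocks[sample(length(blocks))]), collapse = "")
}

#' Calibrate the profile-score gate from shuffled decoys
#'
#' Scores seed-fixed shuffled decoys (dipeptide shuffles of the reference
#' sequences, cycled) against the profile and returns the cutoff
#' mean + k SD. The "standard" preset uses k = 4 and plays the role of a
#' permissive homology cutoff; "strict" uses k = 6 for the conservative
#' screen used on biosynthesis genes.
#'
#' @param profile \code{\link{ScoreProfile-class}}.
#' @param references \code{AAStringSet} of reference sequences to shuffle.
#' @param n number of decoys.
#' @param kSd number of decoy standard deviations above the decoy mean.
#' @param seed RNG seed fixing the decoy set.
#' @param gapOpen,gapExtend affine gap costs for profile scoring.
#' @return list with \code{cutoff}, \code{mean}, \code{sd} and the decoy
#'   \code{scores}.
#' @export
calibrateProfileGate <- function(profile, references, n = 200, kSd = 4,
                                 seed = 101, gapOpen = 11, gapExtend = 1) {
  refs <- asCharacterSeq(references)
  refs <- gsub("-", "", refs)
  scores <- withSeed(seed, {
    vapply(seq_len(n), function(i) {
      d <- shuffleSequence(refs[[(i - 1) %% length(refs) + 1]])
      profileScore(d, profile, gapOpen, gapExtend)
    }, numeric(1))
  })
  list(cutoff = mean(scores) + kSd * stats::sd(scores),
       mean = mean(scores), sd = stats::sd(scores), scores = scores)
}

#' Calibrate a pairwise-score gate for a single reference
#'
#' For references without an alignment (single exemplars, e.g. the crt/brp
#' panel), the gate is calibrated on semi-global alignment scores of shuffled
#' decoys against the reference itself.
#'
#' @param reference a single amino-acid sequence.
#' @param params \code{\link{alignmentParams}}.
#' @inheritParams calibrateProfileGate
#' @return list with \code{cutoff}, \code{mean}, \code{sd}.
#' @export
calibrateScoreGate <- function(reference, params = alignmentParams(),
                               n = 200, kSd = 6, seed = 101) {
  ref <- asCharacterSeq(reference)
  decoys <- withSeed(seed, {
    Biostrings::AAStringSet(vapply(seq_len(n), function(i)
      shuffleSequence(ref), character(1)))
  })
  scores <- .batchScores(decoys, ref, params)
  list(cutoff = mean(scores) + kSd * stats::sd(scores),
       mean = mean(scores), sd = stats::sd(scores))
}
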