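# Independent exhaustive-enumeration oracle for global affine-gap alignment.
# All move sequences (M = match column, X = query-only column, Y =
# subject-only column, no gap-gap columns) are enumerated once per sequence
# shape; each complete alignment is scored as sum of substitution scores
# minus, per maximal gap run of length k, (open + k * ext). The oracle never
# uses dynamic programming and is independent of the implementation it checks.

.enumMoves <- function(n, m) {
  out <- list()
  rec <- function(i, j, acc) {
    if (i == n && j == m) {
      out[[length(out) + 1]] <<- acc
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1, j + 1, c(acc, "M"))
    if (i < n) rec(i + 1, j, c(acc, "X"))
    if (j < m) rec(i, j + 1, c(acc, "Y"))
  }
  rec(0, 0, character(0))
  out
}

# per-shape tables: padded query/subject index matrices over match columns
# and the total affine gap penalty of each enumerated alignment
makeShapeCache <- function(maxLen = 4, open = 11, ext = 1) {
  cache <- list()
  for (n in 0:maxLen) for (m in 0:maxLen) {
    moves <- .enumMoves(n, m)
    if (length(moves) == 0) {       # n == 0 && m == 0
      cache[[paste(n, m)]] <- list(QI = matrix(0L, 1, 1),
                                   SI = matrix(0L, 1, 1), gapPen = 0)
      next
    }
    K <- max(1, max(vapply(moves, function(mv) sum(mv == "M"), integer(1))))
    QI <- matrix(0L, length(moves), K)
    SI <- matrix(0L, length(moves), K)
    gapPen <- numeric(length(moves))
    for (a in seq_along(moves)) {
      mv <- moves[[a]]
      qi <- cumsum(mv != "Y"); si <- cumsum(mv != "X")
      sel <- mv == "M"
      k <- sum(sel)
      if (k > 0) { QI[a, seq_len(k)] <- qi[sel]; SI[a, seq_len(k)] <- si[sel] }
      r <- rle(mv)
      runs <- r$lengths[r$values != "M"]
      gapPen[a] <- sum(open + runs * ext)
    }
    cache[[paste(n, m)]] <- list(QI = QI, SI = SI, gapPen = gapPen)
  }
  cache
}

# optimal global affine-gap score of a vs b by exhaustive enumeration
alignOracle <- function(a, b, S, cache, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  if (length(A) == 0 && length(B) == 0) return(0)
  if (length(A) == 0 || length(B) == 0)  # forced single gap
    return(-(open + ext * max(length(A), length(B))))
  sh <- cache[[paste(length(A), length(B))]]
  # sentinel index 0 -> score 0 (padding)
  A2 <- c("!", A); B2 <- c("!", B)
  S2 <- rbind(0, cbind(0, S[A, B, drop = FALSE]))
  # S2[i+1, j+1] = S[A[i], B[j]]; padded entries hit row/col 1 (zero)
  sub <- matrix(S2[cbind(as.vector(sh$QI) + 1L, as.vector(sh$SI) + 1L)],
                nrow = nrow(sh$QI))
  max(rowSums(sub) - sh$gapPen)
}
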