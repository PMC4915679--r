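AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# membrane-protein flavored amino-acid background used by the synthetic
# generator (fractions sum to 1)
AA_BACKGROUND <- local({
  w <- c(A = 8.9, C = 1.2, D = 4.5, E = 4.7, F = 5.2, G = 7.8, H = 2.0,
         I = 6.5, K = 3.5, L = 10.8, M = 2.6, N = 3.6, P = 4.4, Q = 3.2,
         R = 4.4, S = 6.3, T = 5.8, V = 7.8, W = 2.4, Y = 4.4)
  w / sum(w)
})

# evaluate expr under a fixed RNG state without disturbing the caller's stream
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# uppercase, strip terminal stop symbols, map non-canonical residues to X
sanitizeSequence <- function(s, id = "?") {
  s <- toupper(s)
  s <- gsub("^\\*+|\\*+$", "", s)
  if (grepl("[BZUJ]", s)) {
    warning("non-canonical residues (B/Z/U/J) in '", id, "' mapped to X",
            call. = FALSE)
    s <- chartr("BZUJ", "XXXX", s)
  }
  bad <- gsub(paste0("[", paste(c(AA20, "X"), collapse = ""), "]"), "", s)
  if (nchar(bad) > 0)
    stop("sequence '", id, "' contains invalid characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""), call. = FALSE)
  s
}

checkAlphabet <- function(s, what = "sequence") {
  bad <- gsub(paste0("[", paste(c(AA20, "X"), collapse = ""), "]"), "", toupper(s))
  if (nchar(bad) > 0)
    stop(what, " contains residues outside the amino-acid alphabet: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""), call. = FALSE)
  invisible(TRUE)
}

asCharacterSeq <- function(x) {
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Path to a packaged data file
#'
#' @param file file name under the package's extdata directory.
#' @return absolute path.
#' @export
orpscanExtdata <- function(file) {
  p <- system.file("extdata", file, package = "orpscan", mustWork = TRUE)
  p
}
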