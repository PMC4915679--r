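#' Read an amino-acid FASTA file
#'
#' Reads protein records into an \code{AAStringSet}. Sequence names are the
#' first whitespace-delimited token of each header; the remainder of the
#' header is kept as a \code{description} metadata column. Sequences are
#' uppercased, terminal stop symbols (\code{*}) are stripped, and the
#' non-canonical residues B, Z, U and J are mapped to X with a warning.
#'
#' @param path path to a FASTA file.
#' @return \code{AAStringSet} with ids as names and a \code{description}
#'   metadata column. A file with zero records gives an empty set.
#' @export
#' @importFrom Biostrings readBStringSet AAStringSet
#' @importFrom S4Vectors mcols<- mcols
readFasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) {
    out <- Biostrings::AAStringSet()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = character(0))
    return(out)
  }
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- vapply(seq_along(raw), function(i)
    sanitizeSequence(as.character(raw[[i]]), ids[i]), character(1))
  if (any(nchar(seqs) == 0))
    stop("empty sequence for id(s): ",
         paste(ids[nchar(seqs) == 0], collapse = ", "), call. = FALSE)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Write an amino-acid FASTA file
#'
#' @param x \code{AAStringSet}, optionally with a \code{description} metadata
#'   column that is appended to each header.
#' @param path output path.
#' @param width line-wrap width.
#' @return \code{path}, invisibly.
#' @export
#' @importFrom Biostrings writeXStringSet
writeFasta <- function(x, path, width = 60) {
  y <- x
  desc <- S4Vectors::mcols(x)$description
  if (!is.null(desc)) {
    has <- !is.na(desc) & nzchar(desc)
    names(y) <- ifelse(has, paste(names(x), desc), names(x))
  }
  Biostrings::writeXStringSet(y, path, width = width)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Parses CDS/gene rows into a \code{GRanges} (1-based inclusive coordinates,
#' the GFF convention), sorted by (contig, start). The locus identifier is
#' taken from the \code{ID} attribute, falling back to \code{locus_tag}; the
#' product annotation from the \code{product} attribute, else empty string.
#'
#' @param path path to a GFF3 file.
#' @param genomeId genome identifier stored in the \code{genome_id} metadata
#'   column (default: file base name).
#' @return sorted \code{GRanges} with metadata columns \code{genome_id},
#'   \code{locus_id} and \code{product}.
#' @export
#' @importFrom rtracklayer import
#' @importFrom GenomicRanges GRanges start end strand
#' @importFrom S4Vectors mcols
readGff <- function(path, genomeId = sub("\\.gff3?$", "", basename(path))) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) stop("malformed GFF row at line ", i, call. = FALSE)
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || s > e)
      stop("start > end (or non-numeric) at line ", i, call. = FALSE)
    if (!f[7] %in% c("+", "-"))
      stop("unknown strand '", f[7], "' at line ", i, call. = FALSE)
  }
  if (length(body) == 0) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      genome_id = character(0), locus_id = character(0), product = character(0))
    return(gr)
  }
  gr <- rtracklayer::import(path)
  gr <- gr[as.character(gr$type) %in% c("CDS", "gene")]
  mc <- S4Vectors::mcols(gr)
  locus <- if (!is.null(mc$ID)) mc$ID else rep(NA_character_, length(gr))
  if (!is.null(mc$locus_tag))
    locus <- ifelse(is.na(locus) | !nzchar(locus), mc$locus_tag, locus)
  if (any(is.na(locus) | !nzchar(locus)))
    stop("feature without ID or locus_tag attribute", call. = FALSE)
  prod <- if (!is.null(mc$product)) ifelse(is.na(mc$product), "", mc$product)
          else rep("", length(gr))
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::ranges(gr),
                                strand = GenomicRanges::strand(gr))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    genome_id = rep(genomeId, length(gr)),
    locus_id = as.character(locus), product = as.character(prod))
  if (anyDuplicated(out$locus_id))
    stop("duplicate locus id(s) in ", path, call. = FALSE)
  out[order(as.character(GenomicRanges::seqnames(out)),
            GenomicRanges::start(out))]
}

#' Write gene features to a GFF3 file
#'
#' @param features \code{GRanges} as produced by \code{\link{readGff}} or
#'   \code{\link{generateGenomeAnnotation}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGff <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(features)) {
    prod <- features$product
    attr <- ifelse(nzchar(prod),
                   sprintf("ID=%s;product=%s", features$locus_id, prod),
                   sprintf("ID=%s", features$locus_id))
    rows <- sprintf("%s\torpscan\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                    as.character(GenomicRanges::seqnames(features)),
                    GenomicRanges::start(features),
                    GenomicRanges::end(features),
                    as.character(GenomicRanges::strand(features)), attr)
    writeLines(rows, con)
  }
  invisible(path)
}

#' Write an iTOL binary-dataset annotation file
#'
#' Serializes a presence/absence count matrix as an iTOL \code{DATASET_BINARY}
#' annotation, one field per matrix column; counts greater than zero are
#' encoded as presence (1), zero counts as absence (0).
#'
#' @param mat non-negative integer matrix, rows = species/genomes,
#'   columns = classes.
#' @param path output path.
#' @param label dataset label.
#' @return \code{path}, invisibly.
#' @export
writeItolBinary <- function(mat, path, label = "orpscan presence/absence") {
  if (is.null(dim(mat)) || nrow(mat) == 0 || ncol(mat) == 0)
    stop("empty matrix", call. = FALSE)
  if (any(mat < 0)) stop("counts must be non-negative", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  nf <- ncol(mat)
  writeLines(c(
    "DATASET_BINARY",
    "SEPARATOR TAB",
    paste0("DATASET_LABEL\t", label),
    "COLOR\t#3b6ea5",
    paste(c("FIELD_LABELS", colnames(mat)), collapse = "\t"),
    paste(c("FIELD_SHAPES", rep("2", nf)), collapse = "\t"),
    paste(c("FIELD_COLORS", rep("#3b6ea5", nf)), collapse = "\t"),
    "DATA"), con)
  for (i in seq_len(nrow(mat)))
    writeLines(paste(c(rownames(mat)[i], ifelse(mat[i, ] > 0, "1", "0")),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a two-column wavelength/absorbance spectrum
#'
#' @param path TSV with wavelength (nm) and absorbance (AU) columns; a header
#'   line is detected automatically.
#' @return \code{\link{SpectrumRecord-class}} object.
#' @export
readSpectrumTsv <- function(path) {
  first <- readLines(path, n = 1)
  header <- !grepl("^\\s*-?[0-9]", first)
  df <- utils::read.table(path, header = header, sep = "\t")
  spectrumRecord(df[[1]], df[[2]])
}

#' Write a spectrum as two-column TSV
#'
#' @param s \code{SpectrumRecord}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSpectrumTsv <- function(s, path) {
  utils::write.table(
    data.frame(wavelength = s@wavelength, absorbance = s@absorbance),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Screen configuration
#'
#' All tunable thresholds of the pipeline as one flat named list. Values can
#' be overridden individually or loaded from a flat YAML file with
#' \code{\link{readScreenConfig}}.
#'
#' @param ... named overrides of the defaults.
#' @return named list of configuration values.
#' @details Defaults: \code{preset} "standard" (decoy-calibrated profile gate
#'   at mean + 4 SD; "strict" uses 6 SD), \code{minIdentity} 0.25,
#'   \code{minCoverage} 0.5, \code{calibrationN} 200 decoys,
#'   \code{calibrationSeed} 101, \code{anchorMinIdentity} 0.15,
#'   \code{adjacencyRank} 1, \code{proximityRank} 10, \code{windowGenes} 10,
#'   \code{hydrophobicSet} "LIVMFA", \code{gapOpen} 11, \code{gapExtend} 1,
#'   \code{spectraWindow} 480-580 nm, \code{noiseRegion} 600-800 nm,
#'   \code{minProminenceSD} 3, \code{smoothNm} 30, \code{phylo} TRUE,
#'   \code{distCorrection} "p".
#' @export
screenConfig <- function(...) {
  cfg <- list(
    preset = "standard",
    minIdentity = 0.25,
    minCoverage = 0.5,
    calibrationN = 200,
    sdStandard = 4,
    sdStrict = 6,
    calibrationSeed = 101,
    anchorMinIdentity = 0.15,
    adjacencyRank = 1,
    proximityRank = 10,
    windowGenes = 10,
    hydrophobicSet = "LIVMFA",
    gapOpen = 11,
    gapExtend = 1,
    spectraWindow = c(480, 580),
    noiseRegion = c(600, 800),
    minProminenceSD = 3,
    smoothNm = 30,
    phylo = TRUE,
    distCorrection = "p")
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    cfg[names(over)] <- over
  }
  cfg
}

#' Read a flat YAML screen configuration
#'
#' @param path YAML file of named thresholds; keys not present fall back to
#'   the \code{\link{screenConfig}} defaults.
#' @return named configuration list.
#' @export
readScreenConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(screenConfig, y)
}
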