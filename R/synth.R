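#' Synthetic-study configuration
#'
#' Defines the conditions of the default synthetic study: per-class sequence
#' counts, the background substitution rate applied to family backbones, the
#' genome layout, which genomes are ORP-only and lack the retinal pathway,
#' and the spectra plan. Defaults give the 25-opsin / 10-decoy / 10-genome
#' bundle used throughout the package's validation.
#'
#' @param seed master RNG seed; every downstream draw derives from it.
#' @param counts named per-class sequence counts (families, ORP_A, ORP_B,
#'   decoy).
#' @param backgroundRate per-residue background substitution rate applied to
#'   class backbones (default 0.05).
#' @param nGenomes number of genomes.
#' @param nOrpOnly trailing genomes that carry ORPs but no canonical opsin
#'   and no retinal-biosynthesis genes.
#' @param blockSize genes allocated around each planted locus; blocks are
#'   wide enough that planted neighborhoods cannot bleed into each other.
#' @param crtNoiseRate substitution rate applied to planted crt/brp genes.
#' @param contextPlanA,contextPlanB context categories cycled over ORP
#'   group A / group B loci.
#' @param spectraNoiseSd Gaussian noise SD of generated spectra.
#' @param spectraAmplitude retinal-peak amplitude of the bound control.
#' @return named list.
#' @export
synthConfig <- function(seed = 7,
                        counts = c(BR = 3, BR2 = 2, HR = 3, SRI = 3,
                                   SRII = 3, SR3 = 2, MR = 1,
                                   ORP_A = 4, ORP_B = 4, decoy = 10),
                        backgroundRate = 0.05,
                        nGenomes = 10,
                        nOrpOnly = 3,
                        blockSize = 25,
                        crtNoiseRate = 0.02,
                        contextPlanA = c("transducer_adjacent",
                                         "transducer_adjacent",
                                         "transducer_adjacent", "unlinked"),
                        contextPlanB = c("transducer_adjacent",
                                         "taxis_operon_proximal",
                                         "stress_proximal", "unlinked"),
                        spectraNoiseSd = 0.005,
                        spectraAmplitude = 0.3) {
  stopifnot(all(counts >= 0), backgroundRate >= 0, backgroundRate < 1,
            nOrpOnly < nGenomes)
  list(seed = seed, counts = counts, backgroundRate = backgroundRate,
       nGenomes = nGenomes, nOrpOnly = nOrpOnly, blockSize = blockSize,
       crtNoiseRate = crtNoiseRate, contextPlanA = contextPlanA,
       contextPlanB = contextPlanB, spectraNoiseSd = spectraNoiseSd,
       spectraAmplitude = spectraAmplitude)
}

# fingerprint edit plans: which backbone each ORP group is planted from,
# which schema positions are rewritten, and which are protected from
# background mutation (unprotected signaling positions in group A mirror
# the observed loss of the Y51/R72 hydrogen-bond pair in that group)
.orpPlans <- list(
  ORP_A = list(backbone = "SRII",
               edits = c(`216` = "R", `76` = "D", `174` = "L", `178` = "A"),
               protect = c("76", "108", "127", "171", "174", "178",
                           "189", "199", "216")),
  ORP_B = list(backbone = "SRII",
               edits = c(`216` = "L", `174` = "L", `178` = "G", `127` = "T"),
               protect = c("51", "72", "76", "108", "127", "171", "174",
                           "178", "189", "199", "216")))

.mutateChars <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    alt <- setdiff(AA20, chars[i])
    chars[i] <- sample(alt, 1, prob = AA_BACKGROUND[alt])
  }
  chars
}

#' Generate a synthetic proteome with planted truth
#'
#' Each opsin-class sequence is its family's reference backbone with
#' background substitutions at \code{cfg$backgroundRate}; fingerprint
#' positions are protected (restored after mutation, so planted signals are
#' exact) except where the class plan rewrites them. ORPs are planted from a
#' shared ancestor backbone, itself derived once from the SRII backbone with
#' 10 percent extra divergence (fingerprint positions intact), emulating a
#' distinct ORP lineage sister to the sensory opsins: group A ORPs get
#' Schiff-K to R, W76 to D, Y174 to L, W178 to A (Y51/R72 left unprotected);
#' group B ORPs get Schiff-K to L, Y174 to L, W178 to G, F127 to T with all
#' signaling positions preserved. Decoys are dipeptide-shuffled references.
#'
#' @param cfg \code{\link{synthConfig}} list.
#' @param references named \code{AAStringSet} reference panel.
#' @param schema \code{\link{fingerprintSchema}}.
#' @return list with \code{proteome} (\code{AAStringSet}) and \code{truth}
#'   (\code{DataFrame}: id, class, family, group).
#' @export
generateProteome <- function(cfg = synthConfig(),
                             references = referencePanel(),
                             schema = fingerprintSchema()) {
  withSeed(cfg$seed, {
    refChars <- lapply(asCharacterSeq(references), function(s)
      strsplit(s, "")[[1]])
    pos <- schema@positions
    # shared ORP ancestor: a distinct lineage sister to the sensory opsins,
    # derived once from the SRII backbone with fingerprint positions intact,
    # so planted ORPs form their own clade rather than scattering among
    # SRII-derived sequences
    orpAncestor <- local({
      bb <- refChars[["SRII"]]
      ch <- .mutateChars(bb, 0.10)
      ch[pos] <- bb[pos]
      ch
    })
    seqs <- character(0); ids <- character(0)
    cls <- character(0); fam <- character(0); grp <- character(0)
    for (class_ in names(cfg$counts)) {
      n <- cfg$counts[[class_]]
      if (n == 0) next
      for (k in seq_len(n)) {
        id <- sprintf("%s_%d", class_, k)
        if (class_ == "decoy") {
          ref <- references[[(k - 1) %% length(references) + 1]]
          s <- shuffleSequence(ref)
          cls <- c(cls, "decoy"); fam <- c(fam, NA); grp <- c(grp, NA)
        } else if (class_ %in% names(.orpPlans)) {
          plan <- .orpPlans[[class_]]
          bb <- orpAncestor
          ch <- .mutateChars(bb, cfg$backgroundRate)
          prot <- plan$protect
          ch[pos[prot]] <- bb[pos[prot]]
          ch[pos[names(plan$edits)]] <- unname(plan$edits)
          s <- paste(ch, collapse = "")
          cls <- c(cls, class_); fam <- c(fam, "ORP")
          grp <- c(grp, sub("ORP_", "", class_))
        } else {
          bb <- refChars[[class_]]
          if (is.null(bb)) stop("no reference for class ", class_, call. = FALSE)
          ch <- .mutateChars(bb, cfg$backgroundRate)
          ch[pos] <- bb[pos]
          s <- paste(ch, collapse = "")
          cls <- c(cls, class_); fam <- c(fam, class_); grp <- c(grp, NA)
        }
        seqs <- c(seqs, s); ids <- c(ids, id)
      }
    }
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- ids
    list(proteome = out,
         truth = S4Vectors::DataFrame(id = ids, class = cls, family = fam,
                                      group = grp))
  })
}

.fillerProducts <- c("hypothetical protein", "ABC transporter permease",
                     "DNA polymerase subunit", "ribosomal protein L2",
                     "glycosyltransferase", "aminotransferase",
                     "cation efflux pump", "DNA gyrase subunit B")

# neighbor products planted per context category, at signed gene-rank offsets
.contextNeighbors <- list(
  transducer_adjacent = list(offsets = 1L,
                             products = "methyl-accepting chemotaxis protein"),
  taxis_operon_proximal = list(offsets = c(4L, 6L),
                               products = c("chemotaxis protein CheW",
                                            "flagellin")),
  stress_proximal = list(offsets = 3L,
                         products = "heat shock protein Hsp20"),
  unlinked = list(offsets = integer(0), products = character(0)),
  none = list(offsets = integer(0), products = character(0)))

#' Generate genome annotations with planted neighborhoods
#'
#' Lays each planned protein locus at the center of its own block of
#' \code{cfg$blockSize} genes on a single contig per genome, planting the
#' category-defining neighbors (an MCP transducer at rank +1, a CheW +
#' flagellin pair within rank 10, a heat-shock gene, or nothing) and filling
#' the rest with neutral products. Blocks are wide enough that no planted
#' neighbor lies within the proximity window of another block's target.
#'
#' @param cfg \code{\link{synthConfig}} list.
#' @param plan \code{DataFrame} with columns \code{id}, \code{genome} and
#'   \code{context} (a category name, or "none").
#' @return list with \code{features} (sorted \code{GRanges}) and
#'   \code{truth} (\code{DataFrame}: id, genome, locus, context).
#' @export
generateGenomeAnnotation <- function(cfg = synthConfig(), plan) {
  stopifnot(all(c("id", "genome", "context") %in% colnames(plan)))
  withSeed(cfg$seed + 1L, {
    rows <- list(); truth <- list()
    half <- ceiling(cfg$blockSize / 2)
    for (g in unique(plan$genome)) {
      sub <- plan[plan$genome == g, , drop = FALSE]
      geneIdx <- 0L
      for (r in seq_len(nrow(sub))) {
        spec_ <- .contextNeighbors[[sub$context[r]]]
        if (is.null(spec_)) stop("unknown context '", sub$context[r], "'",
                                 call. = FALSE)
        prods <- sample(.fillerProducts, cfg$blockSize, replace = TRUE)
        prods[half] <- "opsin family protein"
        prods[half + spec_$offsets] <- spec_$products
        for (j in seq_len(cfg$blockSize)) {
          geneIdx <- geneIdx + 1L
          start <- (geneIdx - 1L) * 1200L + 1L
          locus <- sprintf("%s_g%03d", g, geneIdx)
          rows[[length(rows) + 1]] <- data.frame(
            genome = g, contig = paste0(g, "_c1"), start = start,
            end = start + 899L, strand = sample(c("+", "-"), 1),
            locus = locus, product = prods[j])
          if (j == half)
            truth[[length(truth) + 1]] <- data.frame(
              id = sub$id[r], genome = g, locus = locus,
              context = sub$context[r])
        }
      }
    }
    rowdf <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(
      rowdf$contig,
      IRanges::IRanges(rowdf$start, rowdf$end),
      strand = rowdf$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      genome_id = rowdf$genome, locus_id = rowdf$locus,
      product = rowdf$product)
    gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr))]
    list(features = gr,
         truth = S4Vectors::DataFrame(do.call(rbind, truth)))
  })
}

#' Generate a synthetic absorbance spectrum
#'
#' 250-800 nm grid in 2 nm steps (276 points): a protein band at 280 nm, an
#' optional Gaussian retinal peak, and i.i.d. Gaussian noise.
#'
#' @param peakNm peak center (nm); ignored when \code{amplitude} is 0.
#' @param peakSd peak width (nm).
#' @param amplitude peak amplitude (AU); 0 gives an apo (flat) spectrum.
#' @param noiseSd noise standard deviation (AU).
#' @param a280 protein-band amplitude at 280 nm.
#' @param seed RNG seed.
#' @return \code{\link{SpectrumRecord-class}} object.
#' @export
generateSpectrum <- function(peakNm = 550, peakSd = 30, amplitude = 0.3,
                             noiseSd = 0.005, a280 = 1.0, seed = 1) {
  stopifnot(amplitude >= 0)
  wl <- seq(250, 800, by = 2)
  withSeed(seed, {
    ab <- a280 * exp(-(wl - 280)^2 / (2 * 20^2))
    if (amplitude > 0) ab <- ab + amplitude * exp(-(wl - peakNm)^2 / (2 * peakSd^2))
    ab <- ab + stats::rnorm(length(wl), 0, noiseSd)
    spectrumRecord(wl, ab)
  })
}

#' Generate the full synthetic study bundle
#'
#' Assembles proteomes (opsins, decoys, crt/brp genes), genome annotations
#' with planted neighborhoods, pathway complements, and spectra, all tied
#' together by locus identifiers, with a complete planted-truth table.
#' The trailing \code{cfg$nOrpOnly} genomes carry ORPs but no canonical
#' opsin and none of the retinal-biosynthesis genes; the last
#' canonical-opsin genome carries brp but not crtY (a partial complement);
#' all other canonical genomes carry the full five-gene complement.
#'
#' @param cfg \code{\link{synthConfig}} list.
#' @param references,crtReferences packaged reference panels.
#' @param schema \code{\link{fingerprintSchema}}.
#' @return list with \code{proteomes} (named list of \code{AAStringSet} per
#'   genome), \code{features} (\code{GRanges}), \code{spectra} (named list
#'   of \code{SpectrumRecord}), \code{truth} (list of \code{proteins},
#'   \code{genomes}, \code{spectra} tables) and \code{config}.
#' @export
generateBundle <- function(cfg = synthConfig(),
                           references = referencePanel(),
                           crtReferences = crtPanel(),
                           schema = fingerprintSchema()) {
  prot <- generateProteome(cfg, references, schema)
  genomes <- sprintf("g%02d", seq_len(cfg$nGenomes))
  orpOnly <- if (cfg$nOrpOnly > 0) utils::tail(genomes, cfg$nOrpOnly) else character(0)
  canonicalGenomes <- setdiff(genomes, orpOnly)

  tt <- prot$truth
  isOrp <- !is.na(tt$family) & tt$family == "ORP"
  isCanon <- !is.na(tt$family) & tt$family != "ORP"
  isDecoy <- tt$class == "decoy"

  assign_ <- rep(NA_character_, nrow(tt))
  orpIdx <- which(isOrp)
  # every ORP-only genome gets at least one ORP; the rest cycle over the
  # canonical genomes
  nHead <- min(length(orpIdx), length(orpOnly))
  if (nHead > 0) assign_[orpIdx[seq_len(nHead)]] <- orpOnly[seq_len(nHead)]
  restOrp <- if (nHead > 0) orpIdx[-seq_len(nHead)] else orpIdx
  if (length(restOrp))
    assign_[restOrp] <- rep(canonicalGenomes, length.out = length(restOrp))
  assign_[isCanon] <- rep(canonicalGenomes, length.out = sum(isCanon))
  assign_[isDecoy] <- rep(genomes, length.out = sum(isDecoy))

  context <- rep("none", nrow(tt))
  aIdx <- which(tt$class == "ORP_A"); bIdx <- which(tt$class == "ORP_B")
  context[aIdx] <- rep(cfg$contextPlanA, length.out = length(aIdx))
  context[bIdx] <- rep(cfg$contextPlanB, length.out = length(bIdx))

  # per-genome pathway plan
  partial <- if (length(canonicalGenomes)) utils::tail(canonicalGenomes, 1) else character(0)
  crtGenes <- names(crtReferences)
  pathway <- S4Vectors::DataFrame(genome = genomes)
  for (g in crtGenes)
    pathway[[g]] <- genomes %in% canonicalGenomes &
      !(g == "crtY" & genomes %in% partial)
  pathway$retinalCapable <- pathway$crtY & pathway$brp
  pathway$orpOnly <- genomes %in% orpOnly

  # planted crt sequences, one per present gene per genome
  crtIds <- character(0); crtSeqs <- character(0)
  crtGenome <- character(0); crtGene <- character(0)
  withSeed(cfg$seed + 2L, {
    for (gi in seq_along(genomes)) {
      for (g in crtGenes) {
        if (!pathway[[g]][gi]) next
        ch <- strsplit(asCharacterSeq(crtReferences[[g]]), "")[[1]]
        s <- paste(.mutateChars(ch, cfg$crtNoiseRate), collapse = "")
        crtIds <- c(crtIds, sprintf("%s_%s", g, genomes[gi]))
        crtSeqs <- c(crtSeqs, s)
        crtGenome <- c(crtGenome, genomes[gi]); crtGene <- c(crtGene, g)
      }
    }
  })

  plan <- S4Vectors::DataFrame(
    id = c(tt$id, crtIds),
    genome = c(assign_, crtGenome),
    context = c(context, rep("none", length(crtIds))))
  ann <- generateGenomeAnnotation(cfg, plan)

  # rename every protein to its locus id, tying FASTA to GFF
  locusOf <- stats::setNames(ann$truth$locus, ann$truth$id)
  allSeqs <- c(prot$proteome, stats::setNames(Biostrings::AAStringSet(crtSeqs),
                                              crtIds))
  names(allSeqs) <- unname(locusOf[names(allSeqs)])
  genomeOf <- stats::setNames(ann$truth$genome, ann$truth$locus)

  proteins <- S4Vectors::DataFrame(
    id = unname(locusOf[tt$id]), sourceId = tt$id, class = tt$class,
    family = tt$family, group = tt$group, genome = assign_,
    context = context)
  crtTruth <- S4Vectors::DataFrame(
    id = unname(locusOf[crtIds]), gene = crtGene, genome = crtGenome)

  proteomes <- lapply(stats::setNames(genomes, genomes), function(g)
    allSeqs[names(allSeqs) %in% ann$truth$locus[ann$truth$genome == g]])

  spectra <- list(
    BR2_control = generateSpectrum(550, 30, cfg$spectraAmplitude,
                                   cfg$spectraNoiseSd, seed = cfg$seed + 11L),
    ORP_apo_1 = generateSpectrum(amplitude = 0, noiseSd = cfg$spectraNoiseSd,
                                 seed = cfg$seed + 12L),
    ORP_apo_2 = generateSpectrum(amplitude = 0, noiseSd = cfg$spectraNoiseSd,
                                 seed = cfg$seed + 13L))
  spectraTruth <- S4Vectors::DataFrame(
    id = names(spectra), bound = c(TRUE, FALSE, FALSE))

  list(proteomes = proteomes, features = ann$features, spectra = spectra,
       truth = list(proteins = proteins, crt = crtTruth, genomes = pathway,
                    spectra = spectraTruth),
       config = cfg)
}
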