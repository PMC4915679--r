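#' Run the full opsin / ORP screen
#'
#' Orchestrates the pipeline over one or more proteomes: homology search
#' against the opsin reference panel (decoy-calibrated domain gate),
#' reference anchoring and fingerprint extraction, Schiff-base and family
#' classification, optional gene-neighborhood context (when annotations are
#' supplied), retinal-biosynthesis pathway detection, cross-tabulation, a
#' per-class conservation report, and an optional NJ tree of all hits
#' (projected onto reference coordinates) with an ORP monophyly check.
#' Per-genome failures are isolated and reported in the summary; the run
#' continues.
#'
#' @param proteomes named list of \code{AAStringSet} (one per genome), or a
#'   single \code{AAStringSet}.
#' @param features optional \code{GRanges} of gene annotations covering the
#'   proteome loci (context stage skipped when NULL).
#' @param references,referenceAlignment,crtReferences packaged panels (see
#'   \code{\link{referencePanel}}).
#' @param schema \code{\link{fingerprintSchema}}.
#' @param config \code{\link{screenConfig}} list; every threshold used is
#'   logged into the result.
#' @param outDir optional directory: when given, the report bundle (TSV
#'   tables, iTOL annotation, Newick tree, JSON summary) is written there.
#' @return \code{\link{OpsinScreen-class}} object.
#' @export
runScreen <- function(proteomes, features = NULL,
                      references = referencePanel(),
                      referenceAlignment = referencePanelAlignment(),
                      crtReferences = crtPanel(),
                      schema = fingerprintSchema(),
                      config = screenConfig(), outDir = NULL) {
  if (is(proteomes, "XStringSet")) proteomes <- list(genome1 = proteomes)
  if (!is.list(proteomes) || length(proteomes) == 0)
    stop("at least one proteome is required", call. = FALSE)
  if (is.null(names(proteomes)) || anyDuplicated(names(proteomes)))
    stop("proteomes must be a uniquely named list", call. = FALSE)
  if (length(references) == 0) stop("missing reference panel", call. = FALSE)
  params <- alignmentParams(gapOpen = config$gapOpen,
                            gapExtend = config$gapExtend)

  # shared calibrations, computed once
  profile <- buildProfile(referenceAlignment)
  kSd <- if (identical(config$preset, "strict")) config$sdStrict else config$sdStandard
  gate <- calibrateProfileGate(profile, references, n = config$calibrationN,
                               kSd = kSd, seed = config$calibrationSeed,
                               gapOpen = config$gapOpen,
                               gapExtend = config$gapExtend)
  gate$profile <- profile
  crtGates <- lapply(stats::setNames(names(crtReferences), names(crtReferences)),
                     function(g) calibrateScoreGate(
                       crtReferences[[g]], params, n = config$calibrationN,
                       kSd = config$sdStrict, seed = config$calibrationSeed))

  callRows <- list(); fingerprints <- list(); projections <- character(0)
  ctxRows <- list(); pathRows <- list(); failures <- list()
  vocab <- tryCatch(contextVocabulary(), error = function(e) NULL)
  refSeq <- references[[schema@referenceId]]

  for (g in names(proteomes)) {
    res <- tryCatch({
      prt <- proteomes[[g]]
      hits <- searchProteome(prt, references, params, config,
                             referenceAlignment, gate = gate)
      rows <- list()
      for (i in seq_len(nrow(hits))) {
        q <- hits$query[i]
        mapping <- .referenceMapping(prt[[q]], refSeq, params, q,
                                     schema@referenceId)
        if (mapping$alignment@identity < config$anchorMinIdentity) {
          call_ <- S4Vectors::DataFrame(query = q, family = "unassigned",
                                        orpGroup = "n/a",
                                        nearestRef = hits$bestRef[i],
                                        score = hits$score[i])
        } else {
          rmap <- new("ResidueMap", queryId = q,
                      referenceId = schema@referenceId,
                      positions = stats::setNames(
                        mapping$map[schema@positions],
                        names(schema@positions)))
          fp <- extractFingerprint(prt[[q]], rmap, schema)
          fingerprints[[q]] <- fp
          qc <- strsplit(asCharacterSeq(prt[[q]]), "")[[1]]
          proj <- ifelse(is.na(mapping$map), "-", qc[mapping$map])
          projections[q] <- paste(proj, collapse = "")
          call_ <- assignFamily(hits[i, ], fp,
                                hydrophobicSet = config$hydrophobicSet)
        }
        call_$genome <- g
        call_$identity <- hits$identity[i]
        call_$coverage <- hits$coverage[i]
        call_$profileScore <- hits$profileScore[i]
        rows[[length(rows) + 1]] <- call_
      }
      pw <- detectPathway(prt, crtReferences, params,
                          config = utils::modifyList(config,
                                                     list(preset = "strict")),
                          gates = crtGates)
      pw$genome <- g
      list(rows = rows, pw = pw)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[g]] <- conditionMessage(res)
      next
    }
    callRows <- c(callRows, res$rows)
    pathRows[[g]] <- res$pw
  }

  calls <- if (length(callRows)) do.call(rbind, callRows) else
    S4Vectors::DataFrame(query = character(0), family = character(0),
                         orpGroup = character(0), nearestRef = character(0),
                         score = numeric(0), genome = character(0),
                         identity = numeric(0), coverage = numeric(0),
                         profileScore = numeric(0))
  pathways <- if (length(pathRows)) do.call(rbind, pathRows) else
    S4Vectors::DataFrame(genome = character(0))

  # genomic context of ORP loci
  if (!is.null(features) && !is.null(vocab)) {
    orpQ <- calls$query[calls$family == "ORP"]
    for (q in orpQ) {
      ctx <- tryCatch({
        nb <- neighborhood(features, q, windowGenes = config$windowGenes)
        classifyContext(nb, vocab, adjacencyRank = config$adjacencyRank,
                        proximityRank = config$proximityRank)
      }, error = function(e) NULL)
      if (is.null(ctx)) next
      ctxRows[[q]] <- S4Vectors::DataFrame(
        query = q, genome = calls$genome[calls$query == q],
        category = ctx$category,
        support = paste(ctx$loci, collapse = ","),
        ranks = paste(ctx$ranks, collapse = ","))
    }
  }
  context <- if (length(ctxRows)) do.call(rbind, ctxRows) else
    S4Vectors::DataFrame(query = character(0), genome = character(0),
                         category = character(0), support = character(0),
                         ranks = character(0))

  cooc <- cooccurrenceTable(calls, pathways)
  conservation <- if (nrow(calls[calls$query %in% names(fingerprints), ]) > 0)
    conservationReport(calls[calls$query %in% names(fingerprints), ],
                       fingerprints)
  else data.frame(class = character(0), position = character(0),
                  modal = character(0), fraction = numeric(0), n = integer(0))

  tree <- NULL; orpMono <- NA
  if (isTRUE(config$phylo) && length(projections) >= 3) {
    tree <- tryCatch({
      d <- distanceMatrix(projections, config$distCorrection)
      neighborJoining(d)
    }, error = function(e) NULL)
    orpIds <- calls$query[calls$family == "ORP"]
    if (!is.null(tree) && length(orpIds) >= 1 &&
        all(orpIds %in% tree$tip.label))
      orpMono <- isMonophyletic(tree, orpIds)
  }

  ctxCountFor <- function(grp) {
    q <- calls$query[calls$family == "ORP" & calls$orpGroup == grp]
    sum(context$category[context$query %in% q] == "transducer_adjacent")
  }
  summary_ <- list(
    totalOpsins = sum(calls$family != "unassigned"),
    orps = sum(calls$family == "ORP"),
    groupA = sum(calls$family == "ORP" & calls$orpGroup == "A"),
    groupB = sum(calls$family == "ORP" & calls$orpGroup == "B"),
    orpUnassigned = sum(calls$family == "ORP" & calls$orpGroup == "unassigned"),
    transducerAdjacentA = ctxCountFor("A"),
    transducerAdjacentB = ctxCountFor("B"),
    orpOnlyGenomes = cooc$summary$orpOnlyGenomes,
    orpOnlyGenomesLackingPathway = cooc$summary$orpOnlyLackingPathwayCount,
    orpMonophyletic = orpMono,
    failures = failures)

  fpTab <- if (length(fingerprints)) {
    mat <- do.call(rbind, lapply(fingerprints, function(f) f@residues))
    S4Vectors::DataFrame(query = names(fingerprints), mat,
                         check.names = FALSE)
  } else S4Vectors::DataFrame(query = character(0))

  screen <- new("OpsinScreen", calls = calls, fingerprints = fpTab,
                conservation = conservation, context = context,
                pam = cooc$matrix, pathways = pathways, tree = tree,
                summary = summary_, config = config)
  if (!is.null(outDir)) writeScreenBundle(screen, outDir)
  screen
}

#' Write the report bundle of a screen
#'
#' Emits calls, fingerprint, conservation, context and presence/absence
#' tables as TSV, the iTOL binary annotation, the Newick tree (when built)
#' and a JSON summary that logs every threshold used.
#'
#' @param screen \code{\link{OpsinScreen-class}} object.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeScreenBundle <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(x, f) utils::write.table(
    as.data.frame(x), file.path(dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wtsv(screen@calls, "calls.tsv")
  wtsv(screen@fingerprints, "fingerprints.tsv")
  wtsv(screen@conservation, "conservation.tsv")
  wtsv(screen@context, "context.tsv")
  pam <- data.frame(genome = rownames(screen@pam), screen@pam,
                    check.names = FALSE)
  wtsv(pam, "presence_absence.tsv")
  wtsv(screen@pathways, "pathways.tsv")
  if (nrow(screen@pam) > 0)
    writeItolBinary(screen@pam, file.path(dir, "itol_binary.txt"))
  if (!is.null(screen@tree))
    writeNewick(screen@tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(
    list(summary = screen@summary, thresholds = screen@config),
    file.path(dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA, null = "null")
  invisible(dir)
}

#' Planted-truth recovery of a screen
#'
#' Compares a screen of a \code{\link{generateBundle}} output against its
#' truth tables and returns the recovered fraction per aspect: family labels
#' (decoys count as recovered when absent from the calls), ORP groups,
#' context categories of ORP loci, and per-genome pathway flags.
#'
#' @param screen \code{\link{OpsinScreen-class}}.
#' @param truth the \code{truth} element of a \code{\link{generateBundle}}.
#' @return named list of fractions in [0, 1].
#' @export
plantedRecovery <- function(screen, truth) {
  calls <- screen@calls
  tp <- truth$proteins
  famOK <- vapply(seq_len(nrow(tp)), function(i) {
    id <- tp$id[i]
    inCalls <- id %in% calls$query
    if (tp$class[i] == "decoy") return(!inCalls)
    if (!inCalls) return(FALSE)
    identical(calls$family[calls$query == id], tp$family[i])
  }, logical(1))
  orp <- which(!is.na(tp$family) & tp$family == "ORP")
  grpOK <- vapply(orp, function(i) {
    id <- tp$id[i]
    id %in% calls$query &&
      identical(calls$orpGroup[calls$query == id], tp$group[i])
  }, logical(1))
  planted <- which(!is.na(tp$context) & tp$context != "none")
  ctxOK <- vapply(planted, function(i) {
    id <- tp$id[i]
    id %in% screen@context$query &&
      identical(screen@context$category[screen@context$query == id],
                tp$context[i])
  }, logical(1))
  tg <- truth$genomes
  crtGenes <- intersect(c("crtY", "brp", "crtE", "crtB", "crtI"),
                        colnames(tg))
  pwOK <- vapply(seq_len(nrow(tg)), function(i) {
    g <- tg$genome[i]
    row <- screen@pathways[screen@pathways$genome == g, , drop = FALSE]
    if (nrow(row) != 1) return(FALSE)
    all(vapply(crtGenes, function(x) identical(row[[x]], tg[[x]][i]),
               logical(1)))
  }, logical(1))
  list(family = mean(famOK), group = mean(grpOK), context = mean(ctxOK),
       pathway = mean(pwOK))
}
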