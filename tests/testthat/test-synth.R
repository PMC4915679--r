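test_that("generation is bit-identical under a fixed seed", {
  cfg <- synthConfig(seed = 7)
  p1 <- generateProteome(cfg); p2 <- generateProteome(cfg)
  expect_identical(as.character(p1$proteome), as.character(p2$proteome))
  plan <- S4Vectors::DataFrame(id = p1$truth$id[1:4], genome = "g01",
                               context = c("transducer_adjacent", "none",
                                           "unlinked", "stress_proximal"))
  a1 <- generateGenomeAnnotation(cfg, plan)
  a2 <- generateGenomeAnnotation(cfg, plan)
  expect_identical(a1$features$product, a2$features$product)
  expect_identical(GenomicRanges::start(a1$features),
                   GenomicRanges::start(a2$features))
  s1 <- generateSpectrum(seed = 5); s2 <- generateSpectrum(seed = 5)
  expect_identical(s1@absorbance, s2@absorbance)
  # and a different seed changes the draw
  expect_false(identical(as.character(generateProteome(synthConfig(seed = 8))$proteome),
                         as.character(p1$proteome)))
})

test_that("truth tables mirror the configured class counts", {
  cfg <- synthConfig(seed = 3, counts = c(BR = 2, SRII = 1, ORP_A = 5,
                                          ORP_B = 2, decoy = 4))
  p <- generateProteome(cfg)
  expect_equal(sum(p$truth$class == "ORP_A"), 5)
  expect_equal(sum(p$truth$group %in% "A"), 5)
  expect_equal(sum(p$truth$class == "decoy"), 4)
  expect_equal(length(p$proteome), 14)
  expect_equal(anyDuplicated(p$truth$id), 0)
})

test_that("planted fingerprint edits land exactly on schema positions", {
  cfg <- synthConfig(seed = 7)
  p <- generateProteome(cfg)
  schema <- fingerprintSchema()
  refs <- referencePanel()
  for (i in which(p$truth$class == "ORP_A")) {
    ch <- strsplit(as.character(p$proteome[[p$truth$id[i]]]), "")[[1]]
    expect_equal(ch[216], "R")
    expect_equal(ch[76], "D")
    expect_equal(ch[174], "L")
    expect_equal(ch[178], "A")
    expect_equal(ch[199], "Y")
  }
  for (i in which(p$truth$class == "ORP_B")) {
    ch <- strsplit(as.character(p$proteome[[p$truth$id[i]]]), "")[[1]]
    expect_equal(ch[216], "L")
    expect_equal(ch[178], "G")
    expect_equal(ch[127], "T")
    expect_equal(ch[51], "Y")   # signaling pair preserved in group B
    expect_equal(ch[72], "R")
  }
  for (i in which(p$truth$class == "BR")) {
    ch <- strsplit(as.character(p$proteome[[p$truth$id[i]]]), "")[[1]]
    expect_equal(ch[216], "K")
  }
})

test_that("planted neighborhoods classify as planted", {
  cfg <- synthConfig(seed = 11)
  plan <- S4Vectors::DataFrame(
    id = c("x1", "x2", "x3", "x4"), genome = "g01",
    context = c("transducer_adjacent", "taxis_operon_proximal",
                "stress_proximal", "unlinked"))
  ann <- generateGenomeAnnotation(cfg, plan)
  vocab <- contextVocabulary()
  for (r in seq_len(nrow(ann$truth))) {
    nb <- neighborhood(ann$features, ann$truth$locus[r])
    expect_equal(classifyContext(nb, vocab)$category, ann$truth$context[r],
                 info = ann$truth$context[r])
  }
})

test_that("a context planted beyond the window appears when it widens", {
  # taxis pair at ranks +11/+12: unlinked at the default window, taxis-linked
  # once the proximity rank covers it
  prods <- rep("hypothetical protein", 30)
  prods[15 + 11] <- "chemotaxis protein CheW"
  prods[15 + 12] <- "flagellin"
  starts <- (seq_along(prods) - 1L) * 1200L + 1L
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(starts, starts + 899L),
                               strand = "+")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    genome_id = "g1", locus_id = sprintf("L%02d", seq_along(prods)),
    product = prods)
  vocab <- contextVocabulary()
  nb10 <- neighborhood(gr, "L15", windowGenes = 10)
  expect_equal(classifyContext(nb10, vocab, proximityRank = 10)$category,
               "unlinked")
  nb12 <- neighborhood(gr, "L15", windowGenes = 12)
  expect_equal(classifyContext(nb12, vocab, proximityRank = 12)$category,
               "taxis_operon_proximal")
})

test_that("spectra use the stated measurement grid", {
  s <- generateSpectrum(seed = 1)
  expect_length(s@wavelength, 276)
  expect_equal(range(s@wavelength), c(250, 800))
  expect_equal(unique(diff(s@wavelength)), 2)
})

test_that("label recovery degrades monotonically with mutation load", {
  refs <- referencePanel()
  refAln <- referencePanelAlignment()
  params <- alignmentParams()
  prof <- buildProfile(refAln)
  gate <- calibrateProfileGate(prof, refs)
  gate$profile <- prof
  schema <- fingerprintSchema()
  smallCounts <- c(BR = 2, HR = 2, SRII = 2, ORP_A = 2, ORP_B = 2, decoy = 4)

  recovery <- function(rate, seed) {
    cfg <- synthConfig(seed = seed, counts = smallCounts,
                       backgroundRate = rate)
    p <- generateProteome(cfg)
    hits <- searchProteome(p$proteome, refs, params, gate = gate)
    ok <- vapply(seq_len(nrow(p$truth)), function(i) {
      id <- p$truth$id[i]
      inHits <- id %in% hits$query
      if (p$truth$class[i] == "decoy") return(!inHits)
      if (!inHits) return(FALSE)
      m <- tryCatch(anchorToReference(p$proteome[[id]], schema, refs,
                                      queryId = id),
                    error = function(e) NULL)
      if (is.null(m)) return(FALSE)
      fp <- extractFingerprint(p$proteome[[id]], m, schema)
      call_ <- assignFamily(hits[hits$query == id, ], fp)
      identical(call_$family, p$truth$family[i]) &&
        (p$truth$class[i] %in% c("ORP_A", "ORP_B") == (call_$family == "ORP"))
    }, logical(1))
    mean(ok)
  }
  rates <- c(0.05, 0.15, 0.30)
  curves <- sapply(c(101, 202), function(s)
    vapply(rates, recovery, numeric(1), seed = s))
  avg <- rowMeans(curves)
  expect_equal(avg[1], 1)                 # full recovery at the study rate
  expect_true(all(diff(avg) <= 1e-9))     # non-strict decline with load
})
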