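vocab <- contextVocabulary()

mkFeatures <- function(products, genome = "g1", contig = "c1",
                       start0 = 0L, flip = FALSE) {
  n <- length(products)
  starts <- start0 + (seq_len(n) - 1L) * 1200L + 1L
  gr <- GenomicRanges::GRanges(
    contig, IRanges::IRanges(starts, starts + 899L),
    strand = rep("+", n))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    genome_id = genome, locus_id = sprintf("%s_%03d", genome, seq_len(n)),
    product = products)
  if (flip) {
    L <- max(GenomicRanges::end(gr)) + 1000L
    gr2 <- GenomicRanges::GRanges(
      contig,
      IRanges::IRanges(L - GenomicRanges::end(gr),
                       L - GenomicRanges::start(gr)),
      strand = rep("-", n))
    S4Vectors::mcols(gr2) <- S4Vectors::mcols(gr)
    gr <- gr2
  }
  gr[order(GenomicRanges::start(gr))]
}

test_that("neighborhood windows honor boundaries and ranks", {
  f <- mkFeatures(rep("hypothetical protein", 5))
  # target mid-contig, window 2: four neighbors at ranks -2..2, excluding 0
  nb <- neighborhood(f, "g1_003", windowGenes = 2)
  expect_equal(nb$rank, c(-2L, -1L, 1L, 2L))
  # target at contig start: only downstream neighbors
  nb2 <- neighborhood(f, "g1_001", windowGenes = 2)
  expect_equal(nb2$rank, c(1L, 2L))
  # window 0: empty
  expect_equal(nrow(neighborhood(f, "g1_003", windowGenes = 0)), 0)
  expect_error(neighborhood(f, "nope"), "not found")
})

test_that("context rules fire in priority order", {
  # MCP at rank +1 -> transducer_adjacent
  prods <- rep("hypothetical protein", 11)
  prods[7] <- "methyl-accepting chemotaxis protein"
  f <- mkFeatures(prods)
  ctx <- classifyContext(neighborhood(f, "g1_006"), vocab)
  expect_equal(ctx$category, "transducer_adjacent")
  expect_equal(ctx$ranks, 1L)

  # CheW at +4 and flagellin at +6, no transducer within 1 -> taxis operon
  prods2 <- rep("hypothetical protein", 15)
  prods2[10] <- "chemotaxis protein CheW"; prods2[12] <- "flagellin"
  f2 <- mkFeatures(prods2)
  ctx2 <- classifyContext(neighborhood(f2, "g1_006"), vocab)
  expect_equal(ctx2$category, "taxis_operon_proximal")
  expect_equal(sort(ctx2$ranks), c(4L, 6L))

  # a single taxis gene is not enough; a stress gene is
  prods3 <- rep("hypothetical protein", 15)
  prods3[10] <- "flagellin"; prods3[4] <- "heat shock protein"
  f3 <- mkFeatures(prods3)
  expect_equal(classifyContext(neighborhood(f3, "g1_006"), vocab)$category,
               "stress_proximal")

  # nothing categorized within the window -> unlinked
  f4 <- mkFeatures(rep("hypothetical protein", 11))
  expect_equal(classifyContext(neighborhood(f4, "g1_006"), vocab)$category,
               "unlinked")
})

test_that("labels are invariant under translation and contig flip", {
  prods <- rep("hypothetical protein", 11)
  prods[7] <- "methyl-accepting chemotaxis protein"
  for (variant in list(mkFeatures(prods),
                       mkFeatures(prods, start0 = 50000L),
                       mkFeatures(prods, flip = TRUE))) {
    ctx <- classifyContext(neighborhood(variant, "g1_006"), vocab)
    expect_equal(ctx$category, "transducer_adjacent")
  }
})

test_that("widening the proximity window never unlinks a locus", {
  prods <- rep("hypothetical protein", 21)
  prods[14] <- "chemotaxis protein CheW"; prods[17] <- "flagellin"
  f <- mkFeatures(prods)
  cats <- vapply(c(2, 6, 10, 15), function(pr) {
    nb <- neighborhood(f, "g1_011", windowGenes = 20)
    classifyContext(nb, vocab, proximityRank = pr)$category
  }, character(1))
  linked <- cats != "unlinked"
  # once linked, staying linked as the window grows
  expect_true(all(diff(as.integer(linked)) >= 0))
  expect_equal(cats[4], "taxis_operon_proximal")
})
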