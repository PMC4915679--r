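refs <- referencePanel()
refAln <- referencePanelAlignment()
params <- alignmentParams()

test_that("profile columns score observed residues above alternatives", {
  # two identical sequences: every kept column's top residue is the shared one
  p <- buildProfile(c(a = "KWLM", b = "KWLM"))
  top <- rownames(p@scores)[apply(p@scores, 2, which.max)]
  expect_equal(top, c("K", "W", "L", "M"))
  # an all-K column scores K above R (monotone in counts)
  p2 <- buildProfile(c("KA", "KA", "KC", "KD"))
  expect_gt(p2@scores["K", 1], p2@scores["R", 1])
  expect_error(buildProfile(c("KW", "KWL")), "ragged")
  # >50% gap columns are dropped
  p3 <- buildProfile(c("K-A", "K-A", "KWA"))
  expect_equal(ncol(p3@scores), 2)
})

test_that("member sequences outscore their shuffled permutations", {
  prof <- buildProfile(refAln)
  member <- profileScore(refs[["BR"]], prof)
  set.seed(42)
  shuffled <- replicate(20, profileScore(shuffleSequence(refs[["BR"]]), prof))
  expect_true(all(member >= shuffled))
})

test_that("proteome search recovers references and rejects decoys", {
  prof <- buildProfile(refAln)
  gate <- calibrateProfileGate(prof, refs)
  gate$profile <- prof
  # a verbatim reference is a perfect hit
  prt <- Biostrings::AAStringSet(c(q1 = as.character(refs[["SRII"]])))
  hits <- searchProteome(prt, refs, params, gate = gate)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$identity, 1)
  expect_equal(hits$coverage, 1)
  expect_true(hits$passesDomainGate)
  # 50 seed-fixed shuffled references produce zero hits
  set.seed(7)
  dec <- Biostrings::AAStringSet(vapply(1:50, function(i)
    shuffleSequence(refs[[(i - 1) %% 7 + 1]]), character(1)))
  names(dec) <- paste0("d", 1:50)
  expect_equal(nrow(searchProteome(dec, refs, params, gate = gate)), 0)
  # empty proteome is an empty result, not an error
  expect_equal(nrow(searchProteome(Biostrings::AAStringSet(), refs, params,
                                   gate = gate)), 0)
})

test_that("a diverged synthetic opsin is still recovered exactly once", {
  prof <- buildProfile(refAln)
  gate <- calibrateProfileGate(prof, refs)
  gate$profile <- prof
  # ~40% identity to the SRI reference: mutate 60% of positions
  set.seed(13)
  ch <- strsplit(as.character(refs[["SRI"]]), "")[[1]]
  idx <- sample(length(ch), round(0.6 * length(ch)))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in idx) ch[i] <- sample(setdiff(aa, ch[i]), 1)
  prt <- Biostrings::AAStringSet(c(div1 = paste(ch, collapse = "")))
  hits <- searchProteome(prt, refs, params, gate = gate)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$query, "div1")
})

test_that("raising the identity threshold never adds hits", {
  prof <- buildProfile(refAln)
  gate <- calibrateProfileGate(prof, refs)
  gate$profile <- prof
  set.seed(5)
  ch <- strsplit(as.character(refs[["HR"]]), "")[[1]]
  idx <- sample(length(ch), round(0.5 * length(ch)))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in idx) ch[i] <- sample(setdiff(aa, ch[i]), 1)
  prt <- c(refs, Biostrings::AAStringSet(c(mid = paste(ch, collapse = ""))))
  lo <- searchProteome(prt, refs, params, screenConfig(minIdentity = 0.25),
                       gate = gate)
  hi <- searchProteome(prt, refs, params, screenConfig(minIdentity = 0.6),
                       gate = gate)
  expect_true(all(hi$query %in% lo$query))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("tied best references resolve to the smallest id", {
  # a query equidistant from two identical references
  twin <- Biostrings::AAStringSet(c(zz = as.character(refs[["BR"]]),
                                    aa = as.character(refs[["BR"]])))
  prof <- buildProfile(refAln)
  gate <- calibrateProfileGate(prof, refs)
  gate$profile <- prof
  prt <- Biostrings::AAStringSet(c(q = as.character(refs[["BR"]])))
  hits <- searchProteome(prt, twin, params, gate = gate)
  expect_equal(hits$bestRef, "aa")
})
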