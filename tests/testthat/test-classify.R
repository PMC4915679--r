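refs <- referencePanel()
schema <- fingerprintSchema()

fpWith <- function(schiff, queryId = "q") {
  res <- schema@expected
  res[["216"]] <- schiff
  new("Fingerprint", queryId = queryId, residues = res)
}

test_that("the Schiff-base rule partitions fingerprints", {
  expect_equal(schiffBaseTest(fpWith("K")), "canonical")
  expect_equal(schiffBaseTest(fpWith("R")), "ORP")
  expect_equal(schiffBaseTest(fpWith("L")), "ORP")
  expect_equal(schiffBaseTest(fpWith("-")), "unassigned")
  # exhaustive partition: every residue gets exactly one verdict
  verdicts <- vapply(c(strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]], "-"),
                     function(r) schiffBaseTest(fpWith(r)), character(1))
  expect_true(all(verdicts %in% c("canonical", "ORP", "unassigned")))
  expect_equal(sum(verdicts == "canonical"), 1)  # only K
  expect_equal(sum(verdicts == "unassigned"), 1) # only the gap
})

test_that("ORP groups follow the Schiff-replacement residue", {
  expect_equal(orpGroup(fpWith("R")), "A")
  for (r in strsplit("LIVMFA", "")[[1]])
    expect_equal(orpGroup(fpWith(r)), "B")
  expect_equal(orpGroup(fpWith("S")), "unassigned")
  expect_equal(orpGroup(fpWith("G")), "unassigned")  # G excluded from set
  expect_error(orpGroup(fpWith("K")), "non-ORP")
})

test_that("family assignment follows the nearest reference or the ORP rule", {
  params <- alignmentParams()
  prof <- buildProfile(referencePanelAlignment())
  gate <- calibrateProfileGate(prof, refs)
  gate$profile <- prof

  # verbatim BR reference -> family BR, group n/a
  prt <- Biostrings::AAStringSet(c(q1 = as.character(refs[["BR"]])))
  hit <- searchProteome(prt, refs, params, gate = gate)
  m <- anchorToReference(prt[["q1"]], schema, refs, queryId = "q1")
  fp <- extractFingerprint(prt[["q1"]], m, schema)
  call_ <- assignFamily(hit[1, ], fp)
  expect_equal(call_$family, "BR")
  expect_equal(call_$orpGroup, "n/a")

  # SRII backbone with K->R at the Schiff column -> ORP group A
  ch <- strsplit(as.character(refs[["SRII"]]), "")[[1]]
  ch[216] <- "R"
  prt2 <- Biostrings::AAStringSet(c(q2 = paste(ch, collapse = "")))
  hit2 <- searchProteome(prt2, refs, params, gate = gate)
  m2 <- anchorToReference(prt2[["q2"]], schema, refs, queryId = "q2")
  fp2 <- extractFingerprint(prt2[["q2"]], m2, schema)
  call2 <- assignFamily(hit2[1, ], fp2)
  expect_equal(call2$family, "ORP")
  expect_equal(call2$orpGroup, "A")

  # HR-like sequence at ~60% identity, lysine intact -> family HR
  set.seed(21)
  ch3 <- strsplit(as.character(refs[["HR"]]), "")[[1]]
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  idx <- setdiff(sample(length(ch3), round(0.4 * length(ch3))),
                 schema@positions)
  for (i in idx) ch3[i] <- sample(setdiff(aa, ch3[i]), 1)
  prt3 <- Biostrings::AAStringSet(c(q3 = paste(ch3, collapse = "")))
  hit3 <- searchProteome(prt3, refs, params, gate = gate)
  m3 <- anchorToReference(prt3[["q3"]], schema, refs, queryId = "q3")
  fp3 <- extractFingerprint(prt3[["q3"]], m3, schema)
  call3 <- assignFamily(hit3[1, ], fp3)
  expect_equal(call3$family, "HR")
})

test_that("conservation report counts planted modal residues", {
  # 10 group-A fingerprints, D at position 76 in 9 of them
  fps <- list(); rows <- list()
  for (i in 1:10) {
    res <- schema@expected
    res[["216"]] <- "R"
    res[["76"]] <- if (i <= 9) "D" else "E"
    id <- paste0("a", i)
    fps[[id]] <- new("Fingerprint", queryId = id, residues = res)
    rows[[i]] <- S4Vectors::DataFrame(query = id, family = "ORP",
                                      orpGroup = "A")
  }
  calls <- do.call(rbind, rows)
  rep_ <- conservationReport(calls, fps)
  row76 <- rep_[rep_$class == "ORP_A" & rep_$position == "76", ]
  expect_equal(row76$modal, "D")
  expect_equal(row76$fraction, 0.9)
  expect_equal(row76$n, 10)
  # universally conserved position: fraction 1.0
  row199 <- rep_[rep_$class == "ORP_A" & rep_$position == "199", ]
  expect_equal(row199$fraction, 1.0)

  # single-sequence class: fraction 1.0 everywhere
  one <- conservationReport(
    S4Vectors::DataFrame(query = "a1", family = "ORP", orpGroup = "A"),
    fps["a1"])
  expect_true(all(one$fraction == 1.0))
  expect_error(conservationReport(calls[0, ], fps), "no calls")
})
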