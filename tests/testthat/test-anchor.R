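refs <- referencePanel()
schema <- fingerprintSchema()
srii <- as.character(refs[["SRII"]])

test_that("self-anchoring is the identity map with lysine at the Schiff column", {
  m <- anchorToReference(srii, schema, refs, queryId = "self")
  expect_equal(unname(m@positions), unname(schema@positions))
  fp <- extractFingerprint(srii, m, schema)
  expect_equal(unname(fingerprintResidues(fp)), unname(schema@expected))
  expect_equal(fingerprintResidues(fp)[["216"]], "K")
})

test_that("an N-terminal deletion shifts every schema position by one", {
  q <- paste0(substr(srii, 1, 9), substr(srii, 11, nchar(srii)))  # drop pos 10
  m <- anchorToReference(q, schema, refs, queryId = "del10")
  expect_equal(unname(m@positions), unname(schema@positions) - 1L)
})

test_that("a Schiff-column substitution leaves the map unchanged", {
  ch <- strsplit(srii, "")[[1]]
  ch[216] <- "R"
  q <- paste(ch, collapse = "")
  m <- anchorToReference(q, schema, refs, queryId = "k2r")
  expect_equal(unname(m@positions), unname(schema@positions))
  fp <- extractFingerprint(q, m, schema)
  expect_equal(fingerprintResidues(fp)[["216"]], "R")
})

test_that("an internal deletion spanning a pocket position reads as GAP", {
  # remove residues 173-175; position 174 must read "-", flanks intact
  q <- paste0(substr(srii, 1, 172), substr(srii, 176, nchar(srii)))
  m <- anchorToReference(q, schema, refs, queryId = "del174")
  fp <- extractFingerprint(q, m, schema)
  expect_equal(fingerprintResidues(fp)[["174"]], "-")
  expect_equal(fingerprintResidues(fp)[["171"]], schema@expected[["171"]])
  expect_equal(fingerprintResidues(fp)[["178"]], schema@expected[["178"]])
  expect_equal(fingerprintResidues(fp)[["216"]], "K")
})

test_that("anchoring is deterministic and repeatable", {
  set.seed(3)
  ch <- strsplit(srii, "")[[1]]
  idx <- sample(length(ch), 40)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in idx) ch[i] <- sample(setdiff(aa, ch[i]), 1)
  q <- paste(ch, collapse = "")
  m1 <- anchorToReference(q, schema, refs, queryId = "q")
  m2 <- anchorToReference(q, schema, refs, queryId = "q")
  expect_identical(m1@positions, m2@positions)
})

test_that("insertions between schema positions leave other residues intact", {
  base <- anchorToReference(srii, schema, refs, queryId = "base")
  fpBase <- fingerprintResidues(extractFingerprint(srii, base, schema))
  # insert 5 residues between positions 180 and 189 (strictly between the
  # 178 and 189 schema positions)
  q <- paste0(substr(srii, 1, 183), "GGGGG", substr(srii, 184, nchar(srii)))
  m <- anchorToReference(q, schema, refs, queryId = "ins")
  fp <- fingerprintResidues(extractFingerprint(q, m, schema))
  expect_equal(fp, fpBase)
})

test_that("unanchorable queries raise an error", {
  set.seed(9)
  junk <- paste(sample(c("G", "P", "S", "T"), 80, TRUE), collapse = "")
  expect_error(anchorToReference(junk, schema, refs, queryId = "junk"),
               "unanchorable")
})
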