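# Window-sample assembly: Atchley factors, labeling, windowing with
# X-padding, subsite-major layout, dedup.

test_that("Atchley factor table is the standardized 20 x 5 solution", {
  expect_equal(unname(atchleyFactors("X")), rep(0, 5))
  expect_error(atchleyFactors("B"), "unknown")
  tab <- atchleyFactors(sort(setdiff(strsplit(
    "ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")))
  expect_equal(dim(tab), c(20L, 5L))
  ## standardized scores: every factor column has mean ~0 over the 20 aa
  expect_true(all(abs(colMeans(tab)) < 0.2))
  expect_equal(unname(atchleyFactors("G"))[5], 2.064)
})

test_that("residues are labeled positive iff covered by a domain", {
  ps <- ProteinSet(c(p1 = "ACDE"), list(p1 = cbind(2, 3)))
  expect_equal(labelResidues(ps)$p1,
               c("negative", "positive", "positive", "negative"))
  expect_equal(labelResidues(ProteinSet(c(p = "ACDE")))$p,
               rep("negative", 4))
  full <- ProteinSet(c(p = "ACDE"), list(p = cbind(1, 4)))
  expect_equal(labelResidues(full)$p, rep("positive", 4))
})

test_that("window dimensionality is 31 * w and padding blocks are zero", {
  ps1 <- ProteinSet(c(p = "A"), list(p = cbind(1, 1)))
  blocks <- tinyBlocks(ps1)
  ws <- makeWindows(ps1, blocks, 13L)
  expect_equal(nrow(featureMatrix(ws)), 1L)
  expect_equal(ncol(featureMatrix(ws)), 403L)
  v <- featureMatrix(ws)[1, ]
  ## only the center subsite (7 of 13) can be nonzero for a 1-residue chain
  centerCols <- 31L * 6L + seq_len(31L)
  expect_true(all(v[-centerCols] == 0))
  expect_true(all(v[centerCols] != 0))
  expect_equal(as.character(sampleLabels(ws)), "positive")

  ps20 <- ProteinSet(c(p = strrep("AC", 10)))
  ws20 <- makeWindows(ps20, tinyBlocks(ps20), 13L)
  expect_equal(nrow(featureMatrix(ws20)), 20L)
  expect_equal(ncol(featureMatrix(makeWindows(ps20, tinyBlocks(ps20),
                                              15L))), 465L)
  expect_equal(ncol(featureMatrix(makeWindows(ps20, tinyBlocks(ps20),
                                              17L))), 527L)
  expect_error(makeWindows(ps20, tinyBlocks(ps20), 12L), "odd")
})

test_that("layout is subsite-major: a residue occupies one 31-wide block", {
  ps <- ProteinSet(c(p = "ACDEFGH"))
  blocks <- tinyBlocks(ps)
  w <- 5L
  ws <- makeWindows(ps, blocks, w)
  zeroed <- blocks
  zeroed$p[4, ] <- 0
  wsz <- makeWindows(ps, zeroed, w)
  diffs <- featureMatrix(ws) != featureMatrix(wsz)
  for (s in seq_len(nrow(diffs))) {
    hit <- which(diffs[s, ])
    subsite <- 4 - s + (w + 1) / 2       # where residue 4 sits in window s
    if (subsite >= 1 && subsite <= w) {
      expect_equal(unname(hit), (subsite - 1) * 31 + seq_len(31))
    } else {
      expect_length(hit, 0)
    }
  }
})

test_that("window feature names follow the AA<subsite>_<type>_<i> scheme", {
  nm <- windowFeatureNames(13L)
  expect_length(nm, 403L)
  expect_false(anyDuplicated(nm) > 0)
  expect_equal(nm[1], "AA1_pssm_1")
  expect_equal(nm[13], "AA1_pssm_13")
  expect_equal(nm[31 * 12 + 26], "AA13_aaf_5")
  expect_true(all(grepl("^AA[0-9]+_(pssm|disorder|aaf|ss|sa)_[0-9]+$", nm)))
})

test_that("labels partition the residues and counts match lengths", {
  sim <- plantedSim(seed = 7L, nProteins = 3L, lengthRange = c(30L, 50L))
  ws <- sim$windows
  lens <- Biostrings::width(sequences(sim$proteins))
  expect_equal(nrow(featureMatrix(ws)), sum(lens))
  expect_equal(sum(sampleLabels(ws) == "positive") +
                 sum(sampleLabels(ws) == "negative"), sum(lens))
})

test_that("dedup drops near-identical windows greedily, X never matching", {
  ps <- ProteinSet(c(p = strrep("ACDEF", 6)))          # period-5 repeat
  ws <- makeWindows(ps, tinyBlocks(ps), 5L)
  ## interior windows repeat every 5 residues -> exact duplicates exist
  dd <- dedupeSamples(ws, 1.0)
  expect_lt(nrow(featureMatrix(dd)), nrow(featureMatrix(ws)))
  xfree <- !grepl("X", dedupeSamples(ws, 1.0)@windowSeq)
  expect_false(anyDuplicated(dedupeSamples(ws, 1.0)@windowSeq[xfree]) > 0)
  ## terminal windows contain X padding; identical-looking ones with X
  ## are never merged because X matches nothing
  psx <- ProteinSet(c(a = "AC", b = "AC"))
  wsx <- makeWindows(psx, tinyBlocks(psx), 5L)
  expect_equal(nrow(featureMatrix(dedupeSamples(wsx, 1.0))), 4L)

  ## 13-mers differing at one position: identity 12/13 > 0.9 -> dropped
  ps2 <- ProteinSet(c(a = "ACDEFGHIKLMNP", b = "ACDEFGYIKLMNP"))
  ws2 <- makeWindows(ps2, tinyBlocks(ps2), 13L)
  mid <- which(ws2@center == 7L)
  two <- ws2[mid]
  expect_equal(nrow(featureMatrix(dedupeSamples(two, 0.9))), 1L)
  expect_equal(nrow(featureMatrix(dedupeSamples(two, 0.95))), 2L)

  ## all-distinct windows unchanged
  ps3 <- ProteinSet(c(p = "ACDEFGHIKLMNPQRSTVWY"))
  ws3 <- makeWindows(ps3, tinyBlocks(ps3), 5L)
  expect_equal(nrow(featureMatrix(dedupeSamples(ws3, 0.5))),
               nrow(featureMatrix(ws3)))
})

test_that("sample TSV writer round-trips windows, labels and provenance", {
  sim <- plantedSim(seed = 3L, nProteins = 2L, lengthRange = c(20L, 30L))
  ws <- sim$windows
  path <- tempfile(fileext = ".tsv")
  writeSamples(ws, path)
  back <- readSamples(path)
  expect_equal(featureMatrix(back), featureMatrix(ws))
  expect_equal(sampleLabels(back), sampleLabels(ws))
  expect_equal(back@center, ws@center)
  expect_equal(back@windowSeq, ws@windowSeq)
})
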