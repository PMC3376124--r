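# Metrics, cross-validation, the IFS scan, optimal-set pick, final
# winnowing and feature summaries.

test_that("metrics compute Sn, Sp, Ac, MCC with the zero-denominator rule", {
  expect_equal(unname(metrics(c(TP = 5, TN = 5, FP = 0, FN = 0))),
               c(1, 1, 1, 1))
  m2 <- metrics(c(TP = 0, TN = 0, FP = 5, FN = 5))
  expect_equal(unname(m2), c(0, 0, 0, -1))
  m3 <- metrics(c(TP = 3, TN = 4, FP = 1, FN = 2))
  expect_equal(m3[["MCC"]], 10 / sqrt(4 * 5 * 5 * 6), tolerance = 1e-12)
  expect_equal(m3[["Sn"]], 0.6)
  expect_equal(m3[["Sp"]], 0.8)
  expect_equal(m3[["Ac"]], 0.7)
  ## all-negative predictions: TP + FP = 0 zeroes a sqrt factor -> MCC 0
  expect_equal(metrics(c(TP = 0, TN = 6, FP = 0, FN = 4))[["MCC"]], 0)
  expect_error(metrics(c(TP = 0, TN = 0, FP = 0, FN = 0)), "no evaluated")
})

test_that("confusion counts agree with direct per-sample recomputation", {
  set.seed(14)
  pred <- sample(c("positive", "negative"), 200, replace = TRUE)
  truth <- sample(c("positive", "negative"), 200, replace = TRUE)
  cc <- confusionCounts(pred, truth)
  expect_equal(unname(cc["TP"]),
               sum(pred == "positive" & truth == "positive"))
  expect_equal(unname(cc["FN"]),
               sum(pred == "negative" & truth == "positive"))
  expect_equal(sum(cc), 200L)
})

test_that("5-fold CV partitions evenly, pools all samples, reports truly", {
  sim <- plantedSim(seed = 23L, nProteins = 3L, lengthRange = c(30L, 40L))
  ws <- sim$windows
  cv <- fiveFoldCV(ws, seed = 2L)
  expect_equal(sum(cv$counts), nrow(featureMatrix(ws)))
  expect_true(all(abs(diff(range(table(cv$fold)))) <= 1))
  ## pooled counts agree with recomputation from per-sample predictions
  expect_equal(cv$counts, confusionCounts(cv$predictions,
                                          sampleLabels(ws)))
  expect_equal(cv$metrics, metrics(cv$counts))
})

test_that("ten samples split into folds of size two", {
  x <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  ws <- domainsweep:::WindowSet(
    features = matrix(rnorm(10 * 31 * 1), 10, 31,
                      dimnames = list(NULL, windowFeatureNames(1L))),
    labels = rep(c("negative", "positive"), 5),
    proteinId = rep("p", 10), center = 1:10, window = 1L,
    windowSeq = rep("A", 10))
  cv <- fiveFoldCV(ws, seed = 1L)
  expect_equal(as.vector(table(cv$fold)), rep(2L, 5))
})

test_that("near-separable synthetic data reach MCC ~ 1 under CV", {
  sim <- plantedSim(seed = 31L, nProteins = 6L,
                    lengthRange = c(80L, 100L))
  ws <- sim$windows
  cv <- fiveFoldCV(ws, features = plantedFeatures(sim$config, 13L),
                   seed = 5L)
  expect_gt(cv$metrics[["MCC"]], 0.9)
})

test_that("a single-class training fold warns but still evaluates", {
  feats <- matrix(rnorm(20 * 31), 20, 31,
                  dimnames = list(NULL, windowFeatureNames(1L)))
  ws <- domainsweep:::WindowSet(
    features = feats,
    labels = c("positive", rep("negative", 19)),
    proteinId = rep("p", 20), center = 1:20, window = 1L,
    windowSeq = rep("A", 20))
  expect_warning(cv <- fiveFoldCV(ws, seed = 3L), "single class")
  expect_equal(sum(cv$counts), 20L)
})

test_that("IFS subsets are nested prefixes, floor(N / step) of them", {
  feats <- paste0("f", 1:403)
  subs <- ifsSubsets(feats, 5L)
  expect_length(subs, 80L)
  expect_equal(subs[[1]], feats[1:5])
  expect_equal(subs[[80]], feats[1:400])
  for (i in 2:10) expect_true(all(subs[[i - 1]] %in% subs[[i]]))

  subs10 <- ifsSubsets(paste0("f", 1:10), 5L)
  expect_length(subs10, 2L)
  expect_equal(lengths(subs10), c(5L, 10L))
})

test_that("IFS curve rows mirror per-subset CV and pick rules hold", {
  sim <- plantedSim(seed = 47L, nProteins = 3L, lengthRange = c(40L, 60L))
  ws <- sim$windows
  rk <- mrmrRank(ws)
  curve <- ifsCurve(ws, rk, step = 100L, seed = 6L)
  expect_equal(nrow(curve), 4L)
  expect_equal(curve$n_features, c(100L, 200L, 300L, 400L))
  expect_true(all(curve$MCC >= -1 & curve$MCC <= 1))
  expect_true(all(curve$Ac >= 0 & curve$Ac <= 1))

  ## optimal pick: max MCC, plateau broken toward the smaller subset
  fake <- data.frame(i = 1:4, n_features = c(5L, 10L, 15L, 20L),
                     MCC = c(0.1, 0.4, 0.4, 0.2))
  expect_length(optimalSet(fake, paste0("f", 1:20)), 10L)
  rising <- transform(fake, MCC = c(0.1, 0.2, 0.3, 0.4))
  expect_length(optimalSet(rising, paste0("f", 1:20)), 20L)
  expect_length(optimalSet(fake[1, ], paste0("f", 1:20)), 5L)
})

test_that("winnowing keeps block 1 plus blocks that raise the MCC", {
  feats <- paste0("f", 1:20)
  curve <- data.frame(i = 1:4, n_features = c(5L, 10L, 15L, 20L),
                      MCC = c(0.2, 0.3, 0.25, 0.4))
  kept <- winnowFinal(curve, feats, gap = 5L)
  expect_equal(kept, feats[c(1:5, 6:10, 16:20)])   # blocks 1, 2, 4

  rising <- transform(curve, MCC = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(winnowFinal(rising, feats), feats)
  falling <- transform(curve, MCC = c(0.4, 0.3, 0.2, 0.1))
  expect_equal(winnowFinal(falling, feats), feats[1:5])
  expect_equal(winnowFinal(curve[1, ], feats), feats[1:5])
  ## never empty, always a subset of the scanned features
  expect_true(length(kept) > 0 && all(kept %in% feats))
})

test_that("feature summaries count types, subsites and PSSM residues", {
  s <- summarizeFeatures(c("AA1_pssm_13", "AA13_aaf_5"), w = 13L)
  expect_equal(s$typeCounts[["pssm"]], 1L)
  expect_equal(s$typeCounts[["aafactor"]], 1L)
  expect_equal(unname(s$subsiteCounts[c("1", "13")]), c(1L, 1L))
  expect_equal(s$pssmResidueCounts[["M"]], 1L)   # pssm_13 = methionine

  full <- summarizeFeatures(windowFeatureNames(13L), w = 13L)
  expect_equal(unname(full$typeCounts),
               c(260L, 13L, 65L, 39L, 26L))
  expect_equal(sum(full$typeCounts), 403L)
  expect_true(all(full$subsiteCounts == 31L))
  expect_true(all(full$pssmResidueCounts == 13L))

  zero <- summarizeFeatures(character(0), w = 13L)
  expect_true(all(zero$typeCounts == 0L))
  expect_true(all(zero$subsiteCounts == 0L))
})
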