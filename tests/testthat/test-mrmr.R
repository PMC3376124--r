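# Mutual information, discretization and the greedy mRMR ranking,
# cross-checked against brute-force oracles.

test_that("discretization: 3 sigma-states, arity preserved for discrete", {
  expect_equal(discretize(rep(2.5, 10))$arity, 1L)
  expect_equal(discretize(c(0, 1, 0, 1, 1))$arity, 2L)

  set.seed(101)
  v <- rnorm(10000)
  d <- discretize(v, kSigma = 1)
  expect_equal(d$arity, 3L)
  frac <- tabulate(d$states, 3) / 10000
  ## N(0,1) mass below/above mean +/- sd is ~15.9% each side
  expect_equal(frac, c(0.159, 0.683, 0.159), tolerance = 0.05)
})

test_that("MI matches direct summation and basic identities", {
  ## 2x2 joint counts ((2,1),(1,2)) over 6 samples
  x <- c(1, 1, 1, 2, 2, 2)
  y <- c(1, 1, 2, 1, 2, 2)
  expect_equal(mutualInformation(x, y), bruteMI(x, y), tolerance = 1e-12)

  u <- rep(c(0, 1), 50)
  expect_equal(mutualInformation(u, u), log(2), tolerance = 1e-12)

  set.seed(7)
  a <- sample(0:1, 20000, replace = TRUE)
  b <- sample(0:2, 20000, replace = TRUE)
  expect_lt(mutualInformation(a, b), 0.001)
})

test_that("MI is symmetric, non-negative, and MI(x,x) = H(x)", {
  set.seed(11)
  for (rep in 1:25) {
    x <- sample.int(sample(2:4, 1), 60, replace = TRUE)
    y <- sample.int(sample(2:4, 1), 60, replace = TRUE)
    expect_equal(mutualInformation(x, y), mutualInformation(y, x),
                 tolerance = 1e-12)
    expect_gte(mutualInformation(x, y), 0)
    expect_equal(mutualInformation(x, x), bruteEntropy(x),
                 tolerance = 1e-12)
  }
})

test_that("relevance is MI to the label; noise has none, planted more", {
  lab <- rep(c("negative", "positive"), 300)
  feat <- as.integer(lab == "positive")
  expect_equal(relevance(feat, lab), bruteEntropy(lab), tolerance = 1e-12)

  set.seed(5)
  noise <- rnorm(600)
  expect_lt(relevance(noise, lab), 0.01)

  planted <- rnorm(600, mean = 3 * (lab == "positive"))
  expect_gt(relevance(planted, lab), 10 * relevance(noise, lab))
})

test_that("redundancy is the mean pairwise MI to the selected set", {
  f <- rep(c(0, 1, 2), 30)
  expect_equal(redundancy(f, list()), 0)
  expect_equal(redundancy(f, list(f)), bruteEntropy(f), tolerance = 1e-12)
  g <- rep(c(0, 1), 45)
  expect_equal(redundancy(f, list(f, g)),
               mean(c(bruteMI(f, f), bruteMI(f, g))), tolerance = 1e-12)
})

test_that("mRMR ordering: first pick by relevance, duplicates demoted", {
  ## 2 features: order decided by D alone
  set.seed(9)
  lab <- rep(c("negative", "positive"), each = 100)
  strong <- as.numeric(lab == "positive")
  weak <- strong; weak[1:60] <- 1 - weak[1:60]
  X <- cbind(s = strong, w = weak)
  rk <- mrmrRank(X, lab)
  expect_equal(mrmrOrder(rk), c("s", "w"))
  expect_equal(mrmrTable(rk)$feature[1], maxrelTable(rk)$feature[1])

  ## an exact duplicate of the informative feature ranks below an
  ## independently noised weaker feature once the original is selected:
  ## the duplicate scores D - H < 0 while the weaker feature keeps
  ## D - R > 0 (its MI to the selected feature is capped by its MI to
  ## the label)
  flip <- function(v, rate) ifelse(runif(length(v)) < rate, 1 - v, v)
  truth <- as.numeric(lab == "positive")
  a <- flip(truth, 0.1)
  b <- flip(truth, 0.3)
  X2 <- cbind(a = a, dup = a, b = b)
  rk2 <- mrmrRank(X2, lab)
  expect_equal(mrmrOrder(rk2), c("a", "b", "dup"))
})

test_that("mRMR equals exhaustive greedy recomputation on small sets", {
  set.seed(33)
  for (rep in 1:20) {
    n <- 80L
    p <- sample(3:5, 1)
    lab <- sample(c("negative", "positive"), n, replace = TRUE)
    X <- matrix(rnorm(n * p), n, p)
    ## give some features signal so D values differ
    for (j in seq_len(p)) if (runif(1) < 0.5)
      X[, j] <- X[, j] + runif(1, 0, 2) * (lab == "positive")
    colnames(X) <- paste0("f", seq_len(p))
    rk <- mrmrRank(X, lab)
    oracle <- bruteGreedyMrmr(X, lab)
    expect_equal(mrmrOrder(rk), colnames(X)[oracle])
  }
})

test_that("log base scales D and R jointly without reordering", {
  set.seed(21)
  n <- 120L
  lab <- sample(c("negative", "positive"), n, replace = TRUE)
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  X[, 1] <- X[, 1] + 1.5 * (lab == "positive")
  X[, 2] <- X[, 2] + 0.7 * (lab == "positive")
  nat <- mrmrRank(X, lab, base = exp(1))
  bit <- mrmrRank(X, lab, base = 2)
  expect_equal(mrmrOrder(nat), mrmrOrder(bit))
  expect_equal(maxrelTable(bit)$relevance * log(2),
               maxrelTable(nat)$relevance, tolerance = 1e-12)
})

test_that("planted generator features out-rank noise in relevance", {
  sim <- plantedSim(seed = 19L, nProteins = 4L, lengthRange = c(40L, 60L),
                    plantChannels = 3L)
  ws <- sim$windows
  lab <- sampleLabels(ws)
  dPlanted <- relevance(featureMatrix(ws)[, "AA7_pssm_3"], lab)
  ## pssm channels 11..20 carry no configured effect
  noiseD <- vapply(paste0("AA7_pssm_", 11:20), function(f)
    relevance(featureMatrix(ws)[, f], lab), numeric(1))
  expect_gt(dPlanted, max(noiseD))
})
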