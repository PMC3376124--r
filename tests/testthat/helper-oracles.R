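# Independent oracles used to cross-check the package's implementations.
# These deliberately share no code with the package internals.

## mutual information by direct summation over the joint contingency table
bruteMI <- function(x, y, base = exp(1)) {
  tab <- table(x, y)
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  mi <- 0
  for (i in seq_len(nrow(tab)))
    for (j in seq_len(ncol(tab))) {
      p <- tab[i, j] / n
      if (p > 0) mi <- mi + p * log(p / (px[i] * py[j]))
    }
  as.numeric(mi) / log(base)
}

## three-state cut at mean +/- k*sd, written independently of the package
bruteCut <- function(v, k = 1) {
  if (length(unique(v)) <= 3L) return(as.integer(factor(v)))
  lo <- mean(v) - k * sd(v)
  hi <- mean(v) + k * sd(v)
  ifelse(v < lo, 1L, ifelse(v <= hi, 2L, 3L))
}

## exhaustive greedy mRMR recomputation: each round scores every
## to-be-selected feature as D - mean(MI to selected) from scratch
bruteGreedyMrmr <- function(X, labels, k = 1) {
  p <- ncol(X)
  disc <- lapply(seq_len(p), function(j) bruteCut(X[, j], k))
  D <- vapply(disc, function(s) bruteMI(s, labels), numeric(1))
  selected <- integer(0)
  remaining <- seq_len(p)
  for (round in seq_len(p)) {
    scores <- vapply(remaining, function(j) {
      R <- if (length(selected) == 0L) 0 else
        mean(vapply(selected, function(s) bruteMI(disc[[j]], disc[[s]]),
                    numeric(1)))
      D[j] - R
    }, numeric(1))
    pick <- remaining[which.max(scores)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

## entropy of a discrete variable, in nats
bruteEntropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

## hand-applied single left-to-right scan of the refinement rules:
## rule (i):  '2' after >=5 continuous '1', followed by <=3 '2' -> '1'
## rule (ii): '1' after >=5 continuous '2', followed by <=2 '1' -> '2'
goldenTracks <- list(
  c("1111121111",            "1111111111"),  # lone '2' healed
  c("2222212222",            "2222222222"),  # lone '1' removed
  c("12121212",              "12121212"),    # no qualifying runs
  c("1111111111",            "1111111111"),  # fixpoint
  c("2222222222",            "2222222222"),  # fixpoint
  c("111112",                "111111"),
  c("222221",                "222222"),
  c("11111221111",           "11111111111"), # cascade through '22'
  c("111112222111",          "111111111111"),# 3 trailing '2's absorbed
  c("1111122221111",         "1111111111111"),
  c("111112222211111",       "111112222211111"), # 4 following '2's: keep
  c("22222122222",           "22222222222"),
  c("2222211222",            "2222222222"),
  c("22222111222",           "22222222222"),
  c("222221111222",          "222221111222"), # 3 following '1's: keep
  c("111122111",             "111122111"),    # preceding run too short
  c("11111211112111111",     "11111111111111111"),
  c("21111121111",           "21111111111"),
  c("1211112",               "1211112"),
  c("111111222221111112222", "111111222221111111111"),
  c("1",                     "1"),
  c("2",                     "2"),
  c("21",                    "21"),
  c("111112111112",          "111111111111"),
  c("22222111112222",        "22222111111111")
)

## per-residue accuracy of a code track against a truth code track
trackAccuracy <- function(pred, truth)
  mean(strsplit(pred, "")[[1]] == strsplit(truth, "")[[1]])

## random truth track with alternating segments of length >= minSeg,
## plus an independently flipped prediction
randomFlippedTrack <- function(len = 150L, minSeg = 8L, meanSeg = 20,
                               flipRate = 0.1) {
  segs <- minSeg + rgeom(2L * len %/% minSeg, 1 / (meanSeg - minSeg + 1))
  states <- rep(c("1", "2"), length.out = length(segs))
  if (runif(1) < 0.5) states <- rev(states)
  truth <- head(unlist(mapply(rep, states, segs, SIMPLIFY = FALSE),
                       use.names = FALSE), len)
  pred <- truth
  flip <- runif(length(pred)) < flipRate
  pred[flip] <- ifelse(pred[flip] == "1", "2", "1")
  list(truth = paste(truth, collapse = ""),
       pred = paste(pred, collapse = ""))
}
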