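# Cross-validated incremental feature selection (IFS) over the mRMR
# ordering, the standard binary classification metrics, the final
# MCC-based winnowing of 5-feature blocks, and feature-set summaries.

#' Confusion counts from predictions and truth
#'
#' @param predicted,truth vectors of \code{"positive"}/\code{"negative"}
#'   calls (factors or characters) over the same samples.
#' @return Named integer vector \code{c(TP, TN, FP, FN)}.
#' @export
confusionCounts <- function(predicted, truth) {
  p <- as.character(predicted) == "positive"
  t <- as.character(truth) == "positive"
  if (length(p) != length(t)) stop("predicted and truth lengths differ")
  c(TP = sum(p & t), TN = sum(!p & !t), FP = sum(p & !t), FN = sum(!p & t))
}

#' Sensitivity, specificity, accuracy and MCC
#'
#' Computes the four standard binary metrics from confusion counts:
#' sensitivity \code{TP / (TP + FN)}, specificity \code{TN / (TN + FP)},
#' accuracy \code{(TP + TN) / total} and the Matthews correlation
#' coefficient \code{(TP * TN - FP * FN) / sqrt((TP + FP)(TP + FN)(TN +
#' FP)(TN + FN))}. If any factor under the square root is zero the MCC is
#' defined as 0.
#'
#' @param counts named vector with \code{TP}, \code{TN}, \code{FP},
#'   \code{FN} (as from \code{\link{confusionCounts}}).
#' @return Named numeric vector \code{c(Sn, Sp, Ac, MCC)}.
#' @examples
#' metrics(c(TP = 5, TN = 5, FP = 0, FN = 0))
#' @export
metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]]); fn <- as.numeric(counts[["FN"]])
  total <- tp + tn + fp + fn
  if (total <= 0) stop("no evaluated samples")
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  c(Sn = tp / (tp + fn), Sp = tn / (tn + fp),
    Ac = (tp + tn) / total, MCC = mcc)
}

#' 5-fold cross-validation of the forest on a feature subset
#'
#' Randomly partitions the samples into \code{folds} subsets whose sizes
#' differ by at most one; each subset is tested once with a forest trained
#' on the others, and confusion counts are pooled over the folds.
#'
#' Windows centered on neighbouring residues share most of their feature
#' values, so when both land in different folds of a sample-level
#' partition the classifier can recognise a test window through its
#' overlap with training windows. The default (unstratified, sample-level
#' partition) follows the reference protocol; \code{groups} switches to
#' grouped folds (e.g. by protein), which removes that leakage and is the
#' appropriate mode for no-signal controls.
#'
#' @param ws a \linkS4class{WindowSet}.
#' @param features character vector of feature names to use (default all).
#' @param seed integer seed driving both the partition and the per-fold
#'   forests.
#' @param folds number of folds (default 5).
#' @param groups optional per-sample grouping vector (e.g. the protein
#'   ids); when given, whole groups are assigned to folds so no group is
#'   split across training and testing.
#' @param nTrees,m,criterion forest parameters (see
#'   \code{\link{fitForest}}).
#' @return List with \code{counts} (pooled \code{TP/TN/FP/FN}),
#'   \code{metrics}, per-sample out-of-fold \code{predictions} (in input
#'   order), the \code{fold} assignment and the \code{seed}.
#' @export
fiveFoldCV <- function(ws, features = NULL, seed = 1L, folds = 5L,
                       groups = NULL, nTrees = 10L, m = NULL,
                       criterion = c("entropy", "gini")) {
  criterion <- match.arg(criterion)
  x <- featureMatrix(ws)
  if (!is.null(features)) {
    miss <- setdiff(features, colnames(x))
    if (length(miss))
      stop("unknown feature(s): ", paste(utils::head(miss, 5L),
                                         collapse = ", "))
    x <- x[, features, drop = FALSE]
  }
  y <- sampleLabels(ws)
  n <- nrow(x)
  if (n < folds) stop("need at least ", folds, " samples")
  seeds <- localSeed(seed, {
    if (is.null(groups)) {
      fold <- sample(rep(seq_len(folds), length.out = n))
    } else {
      stopifnot(length(groups) == n)
      g <- unique(groups)
      if (length(g) < folds)
        stop("need at least ", folds, " groups for grouped folds")
      gFold <- sample(rep(seq_len(folds), length.out = length(g)))
      fold <- gFold[match(groups, g)]
    }
    sample.int(.Machine$integer.max, folds)
  })
  pred <- factor(rep(NA_character_, n),
                 levels = c("negative", "positive"))
  for (k in seq_len(folds)) {
    test <- fold == k
    if (length(unique(y[!test])) < 2L)
      warning("fold ", k, ": training data contain a single class")
    fit <- fitForest(x[!test, , drop = FALSE], y[!test], nTrees = nTrees,
                     m = m, seed = seeds[k], criterion = criterion)
    pred[test] <- predict(fit, x[test, , drop = FALSE])
  }
  counts <- confusionCounts(pred, y)
  list(counts = counts, metrics = metrics(counts), predictions = pred,
       fold = fold, seed = as.integer(seed))
}

#' Nested feature subsets for the IFS scan
#'
#' Subset i is the first \code{i * step} features of the mRMR ordering,
#' for i = 1 .. \code{floor(N / step)}; the trailing \code{N mod step}
#' features are never scanned. N = 403 with step 5 gives 80 subsets.
#'
#' @param mrmrFeatures the mRMR-ordered feature names (or a
#'   \linkS4class{RankedFeatures}).
#' @param step features added per subset (default 5).
#' @return List of character vectors, one per subset.
#' @export
ifsSubsets <- function(mrmrFeatures, step = 5L) {
  if (is(mrmrFeatures, "RankedFeatures"))
    mrmrFeatures <- mrmrOrder(mrmrFeatures)
  step <- as.integer(step)
  if (step < 1L) stop("step must be >= 1")
  nSub <- length(mrmrFeatures) %/% step
  lapply(seq_len(nSub), function(i) mrmrFeatures[seq_len(i * step)])
}

#' The IFS curve: cross-validated metrics per nested subset
#'
#' Evaluates every nested mRMR prefix subset with a 5-fold
#' cross-validated forest and tabulates sensitivity, specificity,
#' accuracy and MCC against subset size. The fold partition (driven by
#' \code{seed}) is shared across subsets so rows are comparable.
#'
#' @param ws a \linkS4class{WindowSet}.
#' @param mrmrFeatures mRMR-ordered feature names or a
#'   \linkS4class{RankedFeatures}.
#' @param step features added per subset.
#' @param seed,folds,groups,nTrees,m,criterion passed to
#'   \code{\link{fiveFoldCV}}.
#' @return data.frame with columns \code{i}, \code{n_features},
#'   \code{Sn}, \code{Sp}, \code{Ac}, \code{MCC}.
#' @export
ifsCurve <- function(ws, mrmrFeatures, step = 5L, seed = 1L, folds = 5L,
                     groups = NULL, nTrees = 10L, m = NULL,
                     criterion = c("entropy", "gini")) {
  criterion <- match.arg(criterion)
  subsets <- ifsSubsets(mrmrFeatures, step)
  rows <- lapply(seq_along(subsets), function(i) {
    cv <- fiveFoldCV(ws, subsets[[i]], seed = seed, folds = folds,
                     groups = groups, nTrees = nTrees, m = m,
                     criterion = criterion)
    data.frame(i = i, n_features = length(subsets[[i]]),
               Sn = cv$metrics[["Sn"]], Sp = cv$metrics[["Sp"]],
               Ac = cv$metrics[["Ac"]], MCC = cv$metrics[["MCC"]])
  })
  do.call(rbind, rows)
}

#' Optimal feature subset from an IFS curve
#'
#' The nested subset with the maximal MCC; on a plateau the smallest such
#' subset wins.
#'
#' @param curve data.frame from \code{\link{ifsCurve}}.
#' @param mrmrFeatures the mRMR ordering the curve scanned.
#' @return Character vector of the optimal subset's feature names.
#' @export
optimalSet <- function(curve, mrmrFeatures) {
  if (is(mrmrFeatures, "RankedFeatures"))
    mrmrFeatures <- mrmrOrder(mrmrFeatures)
  if (nrow(curve) == 0L) stop("empty IFS curve")
  best <- which.max(curve$MCC)          # first maximum = smallest subset
  mrmrFeatures[seq_len(curve$n_features[best])]
}

#' Final winnowing of the IFS curve into kept feature blocks
#'
#' Walks the IFS curve comparing neighbouring MCC values at the
#' 5-feature gap: block i (features \code{(i-1)*gap + 1 .. i*gap} of the
#' mRMR ordering) is kept iff its MCC exceeds the previous subset's MCC.
#' The first block is always kept as the baseline (the rule only defines
#' keep/discard for blocks with a predecessor). The result is the union
#' of kept blocks, in mRMR order.
#'
#' @param curve data.frame from \code{\link{ifsCurve}} (scanned at the
#'   same gap).
#' @param mrmrFeatures the mRMR ordering.
#' @param gap block size (default 5, matching the curve step).
#' @return Character vector of the final feature set.
#' @export
winnowFinal <- function(curve, mrmrFeatures, gap = 5L) {
  if (is(mrmrFeatures, "RankedFeatures"))
    mrmrFeatures <- mrmrOrder(mrmrFeatures)
  gap <- as.integer(gap)
  if (nrow(curve) == 0L) stop("empty IFS curve")
  keep <- rep(FALSE, nrow(curve))
  keep[1L] <- TRUE
  if (nrow(curve) >= 2L)
    for (i in 2:nrow(curve)) keep[i] <- curve$MCC[i] > curve$MCC[i - 1L]
  blocks <- lapply(which(keep), function(i)
    mrmrFeatures[((i - 1L) * gap + 1L):(i * gap)])
  unlist(blocks, use.names = FALSE)
}

#' Summarize a feature set by type, subsite and PSSM residue
#'
#' Parses \code{"AA<subsite>_<type>_<index>"} feature names and counts
#' them by feature type (pssm, disorder, aafactor, ss, sa), by subsite
#' 1..w, and - for the PSSM channels - by the amino acid the conservation
#' score refers to.
#'
#' @param subset character vector of feature names.
#' @param w window size (subsite count).
#' @return List with \code{typeCounts}, \code{subsiteCounts} and
#'   \code{pssmResidueCounts} (named integer vectors).
#' @export
summarizeFeatures <- function(subset, w = 13L) {
  w <- checkWindowSize(w)
  typeLevels <- c(pssm = "pssm", disorder = "disorder", aaf = "aafactor",
                  ss = "ss", sa = "sa")
  typeCounts <- stats::setNames(integer(length(typeLevels)),
                                unname(typeLevels))
  subsiteCounts <- stats::setNames(integer(w), as.character(seq_len(w)))
  pssmCounts <- stats::setNames(integer(20L), PSSM_AA_ORDER)
  if (length(subset)) {
    parts <- parseFeatureNames(subset)
    if (any(parts$subsite < 1L | parts$subsite > w))
      stop("subsite outside 1..", w)
    bad <- setdiff(unique(parts$type), names(typeLevels))
    if (length(bad))
      stop("unknown feature type(s): ", paste(bad, collapse = ", "))
    tt <- table(typeLevels[parts$type])
    typeCounts[names(tt)] <- as.integer(tt)
    st <- table(parts$subsite)
    subsiteCounts[names(st)] <- as.integer(st)
    isPssm <- parts$type == "pssm"
    if (any(isPssm)) {
      pt <- table(PSSM_AA_ORDER[parts$index[isPssm]])
      pssmCounts[names(pt)] <- as.integer(pt)
    }
  }
  list(typeCounts = typeCounts, subsiteCounts = subsiteCounts,
       pssmResidueCounts = pssmCounts)
}
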