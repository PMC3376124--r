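# Minimum-redundancy maximum-relevance feature ranking. Relevance of a
# feature is its mutual information with the class label; redundancy is
# its mean mutual information with the already-selected features; the
# greedy ranking repeatedly picks the feature maximizing
# relevance - redundancy. Continuous features are discretized to three
# states at mean +/- k_sigma standard deviations (the convention of the
# published mRMR program); features that are already discrete (at most
# three distinct values, e.g. one-hot channels) are used as they are.

#' Discretize a feature for mutual-information estimation
#'
#' Features with more than three distinct values are cut into three states
#' at \code{mean(x) - kSigma * sd(x)} and \code{mean(x) + kSigma * sd(x)}.
#' Features with at most three distinct values (constants, binaries,
#' 3-state codes) keep one state per distinct value, so one-hot channels
#' retain arity 2 and a constant has arity 1.
#'
#' @param x numeric vector (at least 2 samples).
#' @param kSigma width of the central state in standard deviations.
#' @return A discrete variable: list with integer \code{states} (codes
#'   1..arity), \code{arity}, and the threshold \code{edges} (NULL when no
#'   thresholding was applied).
#' @export
discretize <- function(x, kSigma = 1) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 samples to discretize")
  ux <- sort(unique(x))
  if (length(ux) <= 3L) {
    states <- match(x, ux)
    return(list(states = states, arity = length(ux), edges = NULL))
  }
  mu <- mean(x); sdev <- stats::sd(x)
  lo <- mu - kSigma * sdev
  hi <- mu + kSigma * sdev
  raw <- 1L + (x >= lo) + (x > hi)
  occ <- sort(unique(raw))
  list(states = match(raw, occ), arity = length(occ), edges = c(lo, hi))
}

asDiscrete <- function(x, kSigma = 1) {
  if (is.list(x) && !is.null(x$states)) return(x)
  if (is.factor(x) || is.character(x) || is.logical(x)) {
    f <- factor(x)
    return(list(states = as.integer(f), arity = nlevels(f), edges = NULL))
  }
  ## integer-valued vectors are state codes already; only genuinely
  ## continuous input goes through the sigma-threshold discretization
  if (all(x == round(x))) {
    ux <- sort(unique(x))
    return(list(states = match(x, ux), arity = length(ux), edges = NULL))
  }
  discretize(x, kSigma)
}

## Core plug-in MI between two integer state vectors (codes 1..a).
miStates <- function(sx, ax, sy, ay, base = exp(1)) {
  n <- length(sx)
  joint <- tabulate((sx - 1L) * ay + sy, nbins = ax * ay)
  px <- tabulate(sx, nbins = ax) / n
  py <- tabulate(sy, nbins = ay) / n
  pj <- joint / n
  prod <- rep(px, each = ay) * py        # matches the joint's indexing
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / prod[nz])) / log(base)
}

#' Mutual information between two discrete variables
#'
#' Plug-in estimate \eqn{\sum_{x,y} p(x,y) \log(p(x,y) / (p(x) p(y)))} in
#' nats (or another base via \code{base}). Inputs may be discrete
#' variables from \code{\link{discretize}}, factors/character vectors, or
#' numeric vectors (continuous ones are discretized with the default
#' \code{kSigma = 1}).
#'
#' @param x,y variables over the same samples.
#' @param base logarithm base; the default natural log gives nats.
#' @return Non-negative, symmetric mutual-information estimate.
#' @examples
#' mutualInformation(c(0, 0, 1, 1), c(0, 0, 1, 1))  # = log 2
#' @export
mutualInformation <- function(x, y, base = exp(1)) {
  dx <- asDiscrete(x); dy <- asDiscrete(y)
  if (length(dx$states) != length(dy$states))
    stop("x and y must have the same number of samples")
  if (length(dx$states) == 0L) stop("zero samples")
  miStates(dx$states, dx$arity, dy$states, dy$arity, base)
}

#' Relevance of a feature to the target
#'
#' The mutual information between a feature and the class label.
#'
#' @param feature feature values (see \code{\link{mutualInformation}} for
#'   accepted forms).
#' @param target class labels.
#' @param base logarithm base.
#' @return The relevance D.
#' @export
relevance <- function(feature, target, base = exp(1))
  mutualInformation(feature, target, base)

#' Redundancy of a feature against a selected set
#'
#' Mean mutual information between a feature and each member of the
#' already-selected feature set; zero for an empty set.
#'
#' @param feature feature values.
#' @param selected list of already-selected features (possibly empty).
#' @param base logarithm base.
#' @return The redundancy R.
#' @export
redundancy <- function(feature, selected, base = exp(1)) {
  if (length(selected) == 0L) return(0)
  mean(vapply(selected, function(g)
    mutualInformation(feature, g, base), numeric(1L)))
}

#' Rank features by MaxRel and mRMR
#'
#' Computes the MaxRel list (all features sorted by decreasing relevance
#' to the label) and the greedy mRMR ordering: round 1 picks the feature
#' with maximal relevance D; every later round picks the to-be-selected
#' feature maximizing D - R, where R is the mean mutual information to
#' the already-selected set. An earlier round means a better
#' relevance/redundancy trade-off. Ties are broken toward the lower
#' feature index, so the ordering is deterministic.
#'
#' @param x a \linkS4class{WindowSet}, or a numeric matrix (samples x
#'   features, named columns).
#' @param labels class labels (ignored when \code{x} is a WindowSet).
#' @param kSigma discretization width for continuous features.
#' @param base logarithm base for the mutual information.
#' @return A \linkS4class{RankedFeatures}.
#' @export
mrmrRank <- function(x, labels = NULL, kSigma = 1, base = exp(1)) {
  if (is(x, "WindowSet")) {
    labels <- sampleLabels(x)
    x <- featureMatrix(x)
  }
  if (is.null(colnames(x)))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  p <- ncol(x)
  if (p < 2L) stop("need at least 2 features to rank")
  disc <- lapply(seq_len(p), function(j) discretize(x[, j], kSigma))
  lab <- asDiscrete(labels)
  D <- vapply(disc, function(d)
    miStates(d$states, d$arity, lab$states, lab$arity, base), numeric(1L))
  maxrelIdx <- order(-D, seq_len(p))
  maxrel <- data.frame(feature = colnames(x)[maxrelIdx],
                       relevance = D[maxrelIdx],
                       stringsAsFactors = FALSE)
  selected <- integer(p)
  score <- numeric(p)
  Rsum <- numeric(p)
  remaining <- seq_len(p)
  for (round in seq_len(p)) {
    if (round == 1L) {
      sc <- D[remaining]
    } else {
      sc <- D[remaining] - Rsum[remaining] / (round - 1L)
    }
    pick <- remaining[which.max(sc)]   # which.max takes the first maximum
    selected[round] <- pick
    score[round] <- max(sc)
    remaining <- remaining[remaining != pick]
    if (length(remaining)) {
      dp <- disc[[pick]]
      Rsum[remaining] <- Rsum[remaining] +
        vapply(remaining, function(j)
          miStates(disc[[j]]$states, disc[[j]]$arity,
                   dp$states, dp$arity, base), numeric(1L))
    }
  }
  mrmr <- data.frame(feature = colnames(x)[selected],
                     round = seq_len(p), score = score,
                     stringsAsFactors = FALSE)
  edges <- lapply(disc, `[[`, "edges")
  names(edges) <- colnames(x)
  new("RankedFeatures", maxrel = maxrel, mrmr = mrmr,
      discretization = list(kSigma = kSigma, edges = edges))
}

#' Write MaxRel and mRMR rankings to TSV
#'
#' @param ranked a \linkS4class{RankedFeatures}.
#' @param maxrelPath,mrmrPath output files (either may be NULL to skip).
#' @return Invisibly, a list of the written paths.
#' @export
writeRankedFeatures <- function(ranked, maxrelPath = NULL, mrmrPath = NULL) {
  if (!is.null(maxrelPath))
    utils::write.table(maxrelTable(ranked), maxrelPath, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  if (!is.null(mrmrPath))
    utils::write.table(mrmrTable(ranked), mrmrPath, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  invisible(list(maxrel = maxrelPath, mrmr = mrmrPath))
}
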