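# The classification engine: bagging of fully grown decision trees.
# Each tree is grown on a bootstrap replicate (N draws with replacement
# from the N training cases); at every node m features are drawn at
# random from the M available and the best split on them is taken; trees
# are never pruned; prediction is by majority vote over the (default 10)
# trees, with ties going to the negative class.

## evaluate expr under a temporary RNG seed, restoring the caller's stream
localSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Bootstrap replicate of sample indices
#'
#' Draws exactly \code{n} indices from \code{1..n} with replacement:
#' duplicates are expected (about a fraction 1 - 1/e of the indices are
#' distinct at large n) and the draw is reproducible given the seed.
#'
#' @param n number of training cases.
#' @param seed integer seed.
#' @return Integer vector of length \code{n}.
#' @export
bootstrapSample <- function(n, seed)
  localSeed(seed, sample.int(n, n, replace = TRUE))

#' Default per-node feature-subset size
#'
#' \code{floor(log2(M)) + 1}: 9 features per node for M = 403, 5 for
#' M = 31.
#'
#' @param M total number of features.
#' @return Integer m.
#' @export
defaultFeatureSubsetSize <- function(M) as.integer(floor(log2(M)) + 1)

normalizeLabels <- function(labels, classLevels = c("negative", "positive")) {
  f <- factor(as.character(labels), levels = classLevels)
  if (anyNA(f))
    stop("labels must be in {", paste(classLevels, collapse = ", "), "}")
  as.integer(f) - 1L     # 0 = negative, 1 = positive
}

#' Grow a single unpruned decision tree
#'
#' Recursive growth on the given samples: at each node \code{m} features
#' are drawn without replacement, candidate thresholds are the midpoints
#' between consecutive distinct sorted values, and the split maximizing
#' the impurity decrease (information gain by default) is taken. Trees
#' are fully grown: a node becomes a leaf only when it is class-pure or
#' none of its sampled features can separate its samples; impure nodes
#' split even at zero gain, which is what lets a tree represent
#' parity-style interactions (XOR) whose first split is uninformative on
#' its own.
#'
#' @param x numeric feature matrix (samples x features).
#' @param labels class labels (\code{negative}/\code{positive}).
#' @param m features drawn per node; default \code{floor(log2(M)) + 1}.
#' @param seed integer seed for the per-node feature draws.
#' @param criterion split criterion: information gain (\code{"entropy"},
#'   default) or \code{"gini"}.
#' @param rows training-case indices (a bootstrap multiset); defaults to
#'   all rows once each.
#' @return A tree structure (list of parallel node vectors) as used
#'   inside \linkS4class{DomainForest}.
#' @export
growTree <- function(x, labels, m = defaultFeatureSubsetSize(ncol(x)),
                     seed = 1L, criterion = c("entropy", "gini"),
                     rows = seq_len(nrow(x))) {
  criterion <- match.arg(criterion)
  y <- normalizeLabels(labels)
  stopifnot(length(y) == nrow(x))
  tree <- .cppGrowTree(as.matrix(x), y, as.integer(rows) - 1L,
                       as.integer(m), as.integer(seed),
                       if (criterion == "gini") 1L else 0L)
  tree$seed <- as.integer(seed)
  tree$rows <- as.integer(rows)
  tree
}

#' Fit a random forest of fully grown trees
#'
#' Grows \code{nTrees} unpruned decision trees, each on an independent
#' bootstrap replicate of the training cases, with \code{m} random
#' features considered at every node. Per-tree seeds are derived from the
#' master seed, so refitting with the same seed reproduces identical
#' trees and predictions.
#'
#' @param x a \linkS4class{WindowSet} or numeric feature matrix.
#' @param labels class labels (ignored when \code{x} is a WindowSet).
#' @param nTrees number of trees (default 10).
#' @param m features per node; default \code{floor(log2(M)) + 1}.
#' @param seed integer master seed.
#' @param bootstrap set \code{FALSE} to train every tree on the full
#'   sample (test hook; a 1-tree forest then reduces to
#'   \code{\link{growTree}}).
#' @param criterion split criterion, \code{"entropy"} or \code{"gini"}.
#' @return A \linkS4class{DomainForest}.
#' @export
fitForest <- function(x, labels = NULL, nTrees = 10L, m = NULL, seed = 1L,
                      bootstrap = TRUE, criterion = c("entropy", "gini")) {
  criterion <- match.arg(criterion)
  if (is(x, "WindowSet")) {
    labels <- sampleLabels(x)
    x <- featureMatrix(x)
  }
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  n <- nrow(x); M <- ncol(x)
  if (n < 1L) stop("need at least one training sample")
  if (is.null(m)) m <- defaultFeatureSubsetSize(M)
  m <- as.integer(m)
  if (m < 1L || m > M) stop("m must be in 1..M")
  nTrees <- as.integer(nTrees)
  y <- normalizeLabels(labels)
  treeSeeds <- localSeed(seed, sample.int(.Machine$integer.max, nTrees))
  trees <- lapply(seq_len(nTrees), function(t) {
    rows <- if (bootstrap) bootstrapSample(n, treeSeeds[t]) else seq_len(n)
    tree <- .cppGrowTree(x, y, rows - 1L, m, treeSeeds[t],
                         if (criterion == "gini") 1L else 0L)
    tree$seed <- treeSeeds[t]
    tree$rows <- rows
    tree
  })
  new("DomainForest", trees = trees, featureNames = colnames(x), m = m,
      nTrees = nTrees, seed = as.integer(seed),
      classLevels = c("negative", "positive"))
}

#' @describeIn fitForest majority-vote prediction. Returns the predicted
#'   class factor, or the positive-vote count per sample with
#'   \code{type = "votes"}. A tied vote (even tree count) yields the
#'   negative class.
#' @param object a \linkS4class{DomainForest}.
#' @param newdata \linkS4class{WindowSet} or matrix with the training
#'   feature columns.
#' @param type \code{"class"} or \code{"votes"}.
#' @export
setMethod("predict", "DomainForest",
          function(object, newdata, type = c("class", "votes")) {
  type <- match.arg(type)
  if (is(newdata, "WindowSet")) newdata <- featureMatrix(newdata)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    miss <- setdiff(object@featureNames, colnames(newdata))
    if (length(miss))
      stop("newdata lacks feature(s): ",
           paste(utils::head(miss, 5L), collapse = ", "))
    newdata <- newdata[, object@featureNames, drop = FALSE]
  } else if (ncol(newdata) != length(object@featureNames)) {
    stop("newdata must have ", length(object@featureNames), " columns")
  }
  votes <- Reduce(`+`, lapply(object@trees, function(tr)
    as.numeric(.cppPredictTree(tr, newdata))))
  if (type == "votes") return(votes)
  pos <- 2 * votes > object@nTrees      # strict majority; ties -> negative
  factor(object@classLevels[pos + 1L], levels = object@classLevels)
})

#' Serialize a forest to versioned JSON
#'
#' Writes every tree (node vectors, per-tree seed and bootstrap indices),
#' the feature names and the forest parameters, so a model file is
#' self-contained and reloadable with \code{\link{readForestJSON}}.
#'
#' @param forest a \linkS4class{DomainForest}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeForestJSON <- function(forest, path) {
  obj <- list(format = "domainsweep-forest", version = 1L,
              m = forest@m, nTrees = forest@nTrees, seed = forest@seed,
              classLevels = forest@classLevels,
              featureNames = forest@featureNames,
              trees = forest@trees)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a forest from JSON
#'
#' @param path a file written by \code{\link{writeForestJSON}}.
#' @return A \linkS4class{DomainForest}.
#' @export
readForestJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "domainsweep-forest"))
    stop(path, " is not a domainsweep forest model file")
  num <- function(v)            # leaf thresholds are stored as JSON null
    vapply(v, function(e) if (is.null(e)) NA_real_ else as.numeric(e),
           numeric(1L))
  int <- function(v) as.integer(unlist(v))
  trees <- lapply(obj$trees, function(tr)
    list(feature = int(tr$feature), threshold = num(tr$threshold),
         left = int(tr$left), right = int(tr$right), pred = int(tr$pred),
         n_node = int(tr$n_node), seed = int(tr$seed),
         rows = int(tr$rows)))
  new("DomainForest", trees = trees,
      featureNames = as.character(unlist(obj$featureNames)),
      m = as.integer(obj$m), nTrees = as.integer(obj$nTrees),
      seed = as.integer(obj$seed),
      classLevels = as.character(unlist(obj$classLevels)))
}
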