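#' @import methods
#' @importFrom Biostrings AAStringSet
#' @importFrom IRanges IRanges IRangesList
#' @importFrom S4Vectors metadata metadata<-
NULL

#' ProteinSet: sequences with domain annotations
#'
#' A set of protein sequences together with their annotated domain
#' intervals. Sequences are held as a \linkS4class{AAStringSet} over the
#' 20-letter amino-acid alphabet plus the nominal residue \code{X};
#' domains are an \code{IRangesList} parallel to the sequences, with
#' 1-based inclusive residue coordinates, kept sorted and non-overlapping.
#'
#' @slot sequences \code{AAStringSet}, one entry per protein, unique names.
#' @slot domains \code{IRangesList} parallel to \code{sequences}.
#' @exportClass ProteinSet
setClass("ProteinSet",
         representation(sequences = "AAStringSet", domains = "IRangesList"))

setValidity("ProteinSet", function(object) {
  seqs <- object@sequences
  doms <- object@domains
  msg <- character()
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msg <- c(msg, "every sequence needs a non-empty id")
  else if (anyDuplicated(ids))
    msg <- c(msg, "duplicate protein ids")
  if (length(doms) != length(seqs))
    msg <- c(msg, "domains must be parallel to sequences")
  else if (!identical(names(doms), ids))
    msg <- c(msg, "domain list names must match sequence names")
  if (any(Biostrings::width(seqs) == 0L))
    msg <- c(msg, "empty sequence")
  lett <- unique(unlist(strsplit(as.character(seqs), "", fixed = TRUE)))
  bad <- setdiff(lett, AA_ALPHABET_X)
  if (length(bad))
    msg <- c(msg, paste0("sequence characters outside alphabet: ",
                         paste(bad, collapse = ", ")))
  if (length(doms) == length(seqs)) {
    for (i in seq_along(doms)) {
      r <- doms[[i]]
      if (length(r) == 0L) next
      if (any(IRanges::start(r) < 1L) ||
          any(IRanges::end(r) > Biostrings::width(seqs)[i]))
        msg <- c(msg, paste0("domain interval out of bounds for ", ids[i]))
      if (is.unsorted(IRanges::start(r)) ||
          any(IRanges::start(r)[-1L] <= IRanges::end(r)[-length(r)]))
        msg <- c(msg, paste0("domain intervals not sorted/disjoint for ",
                             ids[i]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinSet
#'
#' @param sequences named character vector or \code{AAStringSet}; sequences
#'   are uppercased and characters outside the alphabet are replaced by
#'   \code{X} with a warning.
#' @param domains optional named list of two-column matrices /
#'   \code{data.frame}s with columns start, end (1-based inclusive), or an
#'   \code{IRangesList}; missing proteins get no domains. Overlapping or
#'   adjacent intervals are merged.
#' @return A \linkS4class{ProteinSet}.
#' @examples
#' ProteinSet(c(p1 = "ACDE"), list(p1 = cbind(start = 2, end = 3)))
#' @export
ProteinSet <- function(sequences, domains = NULL) {
  if (is(sequences, "AAStringSet")) {
    ids <- names(sequences)
    seqchr <- as.character(sequences)
  } else {
    ids <- names(sequences)
    seqchr <- toupper(as.character(sequences))
  }
  if (is.null(ids)) stop("sequences must be named by protein id")
  names(seqchr) <- ids
  seqchr <- sanitizeSequences(seqchr)
  dom <- emptyDomains(ids)
  if (!is.null(domains)) {
    if (is(domains, "IRangesList")) {
      for (id in names(domains)) dom[[id]] <- IRanges::reduce(domains[[id]])
    } else {
      for (id in names(domains)) {
        d <- domains[[id]]
        if (is.null(d) || NROW(d) == 0L) next
        d <- as.data.frame(d)
        dom[[id]] <- IRanges::reduce(
          IRanges(start = as.integer(d[[1L]]), end = as.integer(d[[2L]])))
      }
    }
  }
  new("ProteinSet", sequences = AAStringSet(seqchr),
      domains = dom[ids])
}

emptyDomains <- function(ids) {
  dom <- IRangesList(lapply(ids, function(i) IRanges()))
  names(dom) <- ids
  dom
}

sanitizeSequences <- function(seqchr) {
  pat <- paste0("[^", paste(AA_ALPHABET_X, collapse = ""), "]")
  nbad <- sum(vapply(gregexpr(pat, seqchr),
                     function(g) sum(g > 0L), 1L))
  if (nbad > 0L) {
    warning(nbad, " character(s) outside the amino-acid alphabet ",
            "replaced by 'X'")
    seqchr <- gsub(pat, "X", seqchr)
  }
  seqchr
}

#' @describeIn ProteinSet protein accessions
#' @param x a \code{ProteinSet}
#' @export
proteinIds <- function(x) names(x@sequences)

#' @describeIn ProteinSet the sequences as an \code{AAStringSet}
#' @export
sequences <- function(x) x@sequences

#' @describeIn ProteinSet the domain intervals as an \code{IRangesList}
#' @export
domains <- function(x) x@domains

#' @describeIn ProteinSet number of proteins
#' @export
setMethod("length", "ProteinSet", function(x) length(x@sequences))

setMethod("show", "ProteinSet", function(object) {
  n <- length(object)
  nd <- sum(lengths(object@domains))
  cat("ProteinSet with", n, "protein(s),", nd, "domain interval(s)\n")
  if (n) {
    shown <- utils::head(seq_len(n), 5L)
    for (i in shown)
      cat(sprintf("  %s: %d aa, %d domain(s)\n",
                  proteinIds(object)[i],
                  Biostrings::width(object@sequences)[i],
                  length(object@domains[[i]])))
    if (n > 5L) cat("  ...\n")
  }
})

#' @describeIn ProteinSet subset by index or id
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "ProteinSet", function(x, i, j, ..., drop = FALSE) {
  new("ProteinSet", sequences = x@sequences[i], domains = x@domains[i])
})

#' WindowSet: labeled sliding-window samples
#'
#' One row per classified residue: the flattened subsite-major feature
#' vector of its window (\code{31 * w} values) plus the residue's
#' positive/negative domain label and provenance (protein id, center
#' position).
#'
#' @slot features numeric matrix, samples x (31*w), columns named by
#'   \code{windowFeatureNames(w)}.
#' @slot labels factor with levels \code{negative}, \code{positive}.
#' @slot proteinId character vector, one per sample.
#' @slot center integer vector of 1-based center positions.
#' @slot window the (odd) window size.
#' @slot windowSeq character, the window's w-mer residue string
#'   (\code{X}-padded at the termini); used by the identity-based dedup.
#' @exportClass WindowSet
setClass("WindowSet",
         representation(features = "matrix", labels = "factor",
                        proteinId = "character", center = "integer",
                        window = "integer", windowSeq = "character"))

setValidity("WindowSet", function(object) {
  msg <- character()
  w <- object@window
  if (length(w) != 1L || w < 1L || w %% 2L == 0L)
    msg <- c(msg, "window must be a single odd integer")
  else {
    if (ncol(object@features) != N_BLOCK_CHANNELS * w)
      msg <- c(msg, sprintf("feature matrix must have %d columns",
                            N_BLOCK_CHANNELS * w))
    else if (!identical(colnames(object@features), windowFeatureNames(w)))
      msg <- c(msg, "feature column names must be windowFeatureNames(w)")
  }
  n <- nrow(object@features)
  if (length(object@labels) != n || length(object@proteinId) != n ||
      length(object@center) != n || length(object@windowSeq) != n)
    msg <- c(msg, "labels/proteinId/center/windowSeq must be parallel to features")
  if (!identical(levels(object@labels), c("negative", "positive")))
    msg <- c(msg, "labels must have levels negative, positive")
  if (length(msg)) msg else TRUE
})

WindowSet <- function(features, labels, proteinId, center, window,
                      windowSeq) {
  new("WindowSet", features = features,
      labels = factor(labels, levels = c("negative", "positive")),
      proteinId = as.character(proteinId), center = as.integer(center),
      window = as.integer(window), windowSeq = as.character(windowSeq))
}

#' @describeIn WindowSet number of samples
#' @param x a \code{WindowSet}
#' @export
setMethod("nrow", "WindowSet", function(x) nrow(x@features))

#' @describeIn WindowSet the feature matrix
#' @export
featureMatrix <- function(x) x@features

#' @describeIn WindowSet per-sample labels
#' @export
sampleLabels <- function(x) x@labels

#' @describeIn WindowSet the window size
#' @export
windowSize <- function(x) x@window

#' @describeIn WindowSet feature (column) names
#' @export
setMethod("colnames", "WindowSet", function(x) colnames(x@features))

#' @describeIn WindowSet subset samples
#' @param i row index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "WindowSet", function(x, i, j, ..., drop = FALSE) {
  WindowSet(x@features[i, , drop = FALSE], x@labels[i], x@proteinId[i],
            x@center[i], x@window, x@windowSeq[i])
})

setMethod("show", "WindowSet", function(object) {
  cat(sprintf("WindowSet: %d sample(s) x %d features (w = %d)\n",
              nrow(object@features), ncol(object@features), object@window))
  cat(sprintf("  positives: %d, negatives: %d, proteins: %d\n",
              sum(object@labels == "positive"),
              sum(object@labels == "negative"),
              length(unique(object@proteinId))))
})

#' RankedFeatures: MaxRel and mRMR orderings
#'
#' Output of \code{\link{mrmrRank}}: the MaxRel list (all features sorted
#' by relevance to the class label) and the mRMR list (greedy
#' relevance-minus-redundancy ordering), plus the discretization used for
#' the mutual-information estimates.
#'
#' @slot maxrel data.frame(feature, relevance) sorted by decreasing
#'   relevance.
#' @slot mrmr data.frame(feature, round, score): \code{round} is the greedy
#'   selection round (1 = best), \code{score} the relevance-minus-redundancy
#'   value at selection.
#' @slot discretization list: per-feature bin edges and \code{k_sigma}.
#' @exportClass RankedFeatures
setClass("RankedFeatures",
         representation(maxrel = "data.frame", mrmr = "data.frame",
                        discretization = "list"))

setValidity("RankedFeatures", function(object) {
  msg <- character()
  if (!setequal(object@maxrel$feature, object@mrmr$feature))
    msg <- c(msg, "maxrel and mrmr must rank the same feature set")
  if (nrow(object@mrmr) && nrow(object@maxrel) &&
      object@mrmr$feature[1L] != object@maxrel$feature[1L])
    msg <- c(msg, "first mRMR pick must equal the MaxRel top feature")
  if (length(msg)) msg else TRUE
})

#' @describeIn RankedFeatures the mRMR-ordered feature names
#' @param x a \code{RankedFeatures}
#' @export
mrmrOrder <- function(x) x@mrmr$feature

#' @describeIn RankedFeatures the MaxRel table (feature, relevance)
#' @export
maxrelTable <- function(x) x@maxrel

#' @describeIn RankedFeatures the mRMR table (feature, round, score)
#' @export
mrmrTable <- function(x) x@mrmr

setMethod("show", "RankedFeatures", function(object) {
  cat("RankedFeatures over", nrow(object@mrmr), "features\n")
  top <- utils::head(object@mrmr, 5L)
  cat("  mRMR top:", paste(top$feature, collapse = ", "), "\n")
  cat("  MaxRel top:", paste(utils::head(object@maxrel$feature, 5L),
                             collapse = ", "), "\n")
})

#' DomainForest: an ensemble of fully grown decision trees
#'
#' A random forest in the original bagging formulation: each tree is grown
#' on a bootstrap replicate of the training samples, considering a fixed
#' random subset of \code{m} features at every node, fully grown (no
#' pruning), and prediction is by majority vote with ties resolved to the
#' negative class.
#'
#' @slot trees list of tree structures (parallel integer/numeric vectors).
#' @slot featureNames character, the M feature names in training order.
#' @slot m integer, features drawn at each node.
#' @slot nTrees integer.
#' @slot seed integer master seed.
#' @slot classLevels character(2): negative then positive class.
#' @exportClass DomainForest
setClass("DomainForest",
         representation(trees = "list", featureNames = "character",
                        m = "integer", nTrees = "integer", seed = "integer",
                        classLevels = "character"))

setMethod("show", "DomainForest", function(object) {
  cat(sprintf("DomainForest: %d tree(s), M = %d features, m = %d per node\n",
              object@nTrees, length(object@featureNames), object@m))
  cat("  classes:", paste(object@classLevels, collapse = " / "),
      " seed:", object@seed, "\n")
})
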