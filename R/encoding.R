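# Residue labeling, per-residue feature-block assembly and sliding-window
# sample construction. A residue is a positive sample iff it lies inside
# an annotated domain interval; its feature vector concatenates the 31
# feature channels of the w residues centered on it (subsite-major), with
# all-zero blocks for positions beyond the sequence ends ("X" padding).

#' Label every residue as domain or non-domain
#'
#' @param proteins a \linkS4class{ProteinSet}.
#' @return Named list with one character vector per protein, values
#'   \code{"positive"} (inside some domain interval) or
#'   \code{"negative"}.
#' @examples
#' ps <- ProteinSet(c(p1 = "ACDE"), list(p1 = cbind(2, 3)))
#' labelResidues(ps)
#' @export
labelResidues <- function(proteins) {
  ids <- proteinIds(proteins)
  lens <- Biostrings::width(sequences(proteins))
  out <- lapply(seq_along(ids), function(i) {
    lab <- rep("negative", lens[i])
    r <- domains(proteins)[[i]]
    for (k in seq_along(r))
      lab[IRanges::start(r)[k]:IRanges::end(r)[k]] <- "positive"
    lab
  })
  names(out) <- ids
  out
}

#' Assemble per-residue feature blocks from feature tracks
#'
#' Combines the external per-residue tracks (PSSM, disorder, secondary
#' structure, solvent accessibility) with the sequence-derived Atchley
#' factors into one L x 31 matrix per protein, columns in the canonical
#' \code{\link{blockChannels}} order. Secondary structure is one-hot coded
#' H/E/O as 100/010/001 and solvent accessibility B/E as 10/01. Rows of
#' nominal \code{X} residues are all zero.
#'
#' @param proteins a \linkS4class{ProteinSet}.
#' @param pssm named list of L x 20 matrices in canonical column order
#'   (as from \code{\link{readPssmAscii}}).
#' @param disorder named list of numeric vectors in [0, 1].
#' @param ss named list of character vectors over \code{H, E, O}.
#' @param sa named list of character vectors over \code{B, E}.
#' @return Named list of L x 31 numeric matrices.
#' @export
buildFeatureBlocks <- function(proteins, pssm, disorder, ss, sa) {
  ids <- proteinIds(proteins)
  seqs <- as.character(sequences(proteins))
  out <- vector("list", length(ids)); names(out) <- ids
  for (id in ids) {
    res <- strsplit(seqs[[id]], "")[[1L]]
    L <- length(res)
    for (trk in list(pssm, disorder, ss, sa))
      if (is.null(trk[[id]])) stop("missing feature track for ", id)
    if (nrow(pssm[[id]]) != L || length(disorder[[id]]) != L ||
        length(ss[[id]]) != L || length(sa[[id]]) != L)
      stop("feature track length mismatch for ", id)
    B <- matrix(0, nrow = L, ncol = N_BLOCK_CHANNELS,
                dimnames = list(NULL, BLOCK_CHANNELS))
    B[, 1:20] <- as.matrix(pssm[[id]][, PSSM_AA_ORDER, drop = FALSE])
    B[, 21L] <- as.numeric(disorder[[id]])
    B[, 22:26] <- atchleyFactors(res)
    ssIdx <- match(ss[[id]], SS_STATES)
    saIdx <- match(sa[[id]], SA_STATES)
    if (anyNA(ssIdx)) stop("unknown secondary-structure symbol for ", id)
    if (anyNA(saIdx)) stop("unknown solvent-accessibility symbol for ", id)
    B[cbind(seq_len(L), 26L + ssIdx)] <- 1
    B[cbind(seq_len(L), 29L + saIdx)] <- 1
    B[res == "X", ] <- 0   # the nominal residue carries no information
    out[[id]] <- B
  }
  out
}

#' Build sliding-window samples for every residue
#'
#' Extracts one sample per residue: the residue's domain label and the
#' flattened subsite-major feature vector of the w-residue window centered
#' on it. Window positions beyond the sequence ends are padded with the
#' nominal residue \code{X}, whose feature block is all zeros.
#'
#' @param proteins a \linkS4class{ProteinSet}.
#' @param blocks named list of L x 31 feature-block matrices
#'   (\code{\link{buildFeatureBlocks}}).
#' @param w odd window size; 13 gives 403 features per sample, 15 gives
#'   465 and 17 gives 527.
#' @return A \linkS4class{WindowSet} with one sample per residue of every
#'   protein, in protein then position order.
#' @export
makeWindows <- function(proteins, blocks, w = 13L) {
  w <- checkWindowSize(w)
  h <- (w - 1L) %/% 2L
  ids <- proteinIds(proteins)
  labs <- labelResidues(proteins)
  seqs <- as.character(sequences(proteins))
  featNames <- windowFeatureNames(w)
  perProt <- lapply(ids, function(id) {
    B <- blocks[[id]]
    if (is.null(B)) stop("no feature blocks for ", id)
    L <- nrow(B)
    if (L != nchar(seqs[[id]]))
      stop("feature blocks and sequence length differ for ", id)
    pad <- matrix(0, nrow = h, ncol = N_BLOCK_CHANNELS)
    padded <- rbind(pad, as.matrix(B), pad)
    idx <- outer(seq_len(L), 0:(w - 1L), `+`)     # rows of padded per sample
    flat <- t(padded[as.vector(t(idx)), , drop = FALSE])
    dim(flat) <- c(N_BLOCK_CHANNELS * w, L)
    paddedSeq <- paste0(strrep("X", h), seqs[[id]], strrep("X", h))
    wseq <- substring(paddedSeq, seq_len(L), seq_len(L) + w - 1L)
    list(features = t(flat), center = seq_len(L), wseq = wseq)
  })
  features <- do.call(rbind, lapply(perProt, `[[`, "features"))
  colnames(features) <- featNames
  WindowSet(features,
            labels = unlist(labs, use.names = FALSE),
            proteinId = rep(ids, vapply(perProt, function(p)
              length(p$center), 1L)),
            center = unlist(lapply(perProt, `[[`, "center")),
            window = w,
            windowSeq = unlist(lapply(perProt, `[[`, "wseq")))
}

#' Remove near-identical window samples
#'
#' A greedy, order-dependent stand-in for CD-HIT clustering of the w-mer
#' segments: samples are scanned in input order and a sample is dropped if
#' its window residue string has at least \code{identityThreshold}
#' identity (matching positions / w; the padding residue \code{X} never
#' matches anything) to any already-retained sample of the same label.
#' The default threshold 1.0 removes exact duplicates only.
#'
#' @param ws a \linkS4class{WindowSet}.
#' @param identityThreshold fraction in (0, 1].
#' @return The deduplicated \linkS4class{WindowSet}.
#' @export
dedupeSamples <- function(ws, identityThreshold = 1.0) {
  if (identityThreshold <= 0 || identityThreshold > 1)
    stop("identityThreshold must be in (0, 1]")
  n <- nrow(ws@features)
  if (n < 2L) return(ws)
  w <- ws@window
  if (identityThreshold == 1.0) {
    # identity 1 requires all w positions to match, which an 'X' never does
    xfree <- !grepl("X", ws@windowSeq, fixed = TRUE)
    key <- paste(ws@labels, ws@windowSeq)
    keep <- !(xfree & duplicated(key))
    return(ws[which(keep)])
  }
  chars <- matrix(unlist(strsplit(ws@windowSeq, "")), nrow = n, byrow = TRUE)
  keep <- logical(n)
  byLabel <- split(seq_len(n), ws@labels)
  for (idxs in byLabel) {
    retained <- integer()
    for (i in idxs) {
      drop <- FALSE
      for (r in retained) {
        ident <- sum(chars[i, ] == chars[r, ] & chars[i, ] != "X") / w
        if (ident >= identityThreshold) { drop <- TRUE; break }
      }
      if (!drop) retained <- c(retained, i)
    }
    keep[retained] <- TRUE
  }
  ws[which(keep)]
}

#' Write window samples to TSV
#'
#' One row per sample: \code{protein_id}, \code{center}, \code{window_seq},
#' \code{label}, then the named feature columns.
#'
#' @param ws a \linkS4class{WindowSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSamples <- function(ws, path) {
  tab <- data.frame(protein_id = ws@proteinId, center = ws@center,
                    window_seq = ws@windowSeq,
                    label = as.character(ws@labels),
                    check.names = FALSE)
  tab <- cbind(tab, as.data.frame(ws@features, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read window samples from TSV
#'
#' Inverse of \code{\link{writeSamples}}.
#'
#' @param path TSV file.
#' @return A \linkS4class{WindowSet}.
#' @export
readSamples <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta <- c("protein_id", "center", "window_seq", "label")
  if (!all(meta %in% names(tab)))
    stop("sample table must have columns ", paste(meta, collapse = ", "))
  featCols <- setdiff(names(tab), meta)
  nfeat <- length(featCols)
  if (nfeat %% N_BLOCK_CHANNELS != 0L)
    stop("feature column count is not a multiple of 31")
  w <- nfeat %/% N_BLOCK_CHANNELS
  feats <- as.matrix(tab[, featCols, drop = FALSE])
  WindowSet(feats, tab$label, tab$protein_id, tab$center, w,
            tab$window_seq)
}
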