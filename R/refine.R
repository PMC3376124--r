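# Run-length scanning refinement of per-residue code tracks. A track is
# a string over {'1','2'}: '1' marks a predicted domain residue, '2' a
# non-domain residue. The scan removes sporadic calls embedded in long
# runs of the opposite code, then maximal '1' runs become domain regions.

#' Code track from per-residue predictions
#'
#' Positive calls become \code{'1'} (domain), negative \code{'2'}.
#'
#' @param predictions vector of \code{"positive"}/\code{"negative"} calls.
#' @return Single character string over \code{1}/\code{2}.
#' @export
codesFromPredictions <- function(predictions) {
  p <- as.character(predictions)
  bad <- setdiff(unique(p), c("positive", "negative"))
  if (length(bad)) stop("unknown prediction value(s): ",
                        paste(bad, collapse = ", "))
  paste(ifelse(p == "positive", "1", "2"), collapse = "")
}

checkTrack <- function(track) {
  if (length(track) != 1L || !is.character(track))
    stop("a code track is a single character string")
  codes <- strsplit(track, "")[[1L]]
  bad <- setdiff(unique(codes), c("1", "2"))
  if (length(bad)) stop("track alphabet must be {'1','2'}, found: ",
                        paste(bad, collapse = ", "))
  codes
}

#' Scanning refinement of a code track
#'
#' One left-to-right pass over the track applying two rules at each
#' position p, measured on the working (already-modified) track:
#' \itemize{
#'   \item a \code{'2'} preceded by a run of at least five continuous
#'     \code{'1'} codes and followed (from p+1) by at most three
#'     continuous \code{'2'} codes becomes \code{'1'};
#'   \item a \code{'1'} preceded by a run of at least five continuous
#'     \code{'2'} codes and followed by at most two continuous \code{'1'}
#'     codes becomes \code{'2'}.
#' }
#' The examined position is not counted in its own following run. Because
#' the preceding run is measured on the working track, earlier flips can
#' extend it (the scan cascades); there is no fixpoint iteration.
#'
#' @param track code string over \code{1}/\code{2}.
#' @return The refined track, same length.
#' @examples
#' refineTrack("1111121111")  # the lone '2' is flipped
#' @export
refineTrack <- function(track) {
  codes <- checkTrack(track)
  n <- length(codes)
  if (n == 0L) return(track)
  ## following-run lengths on the original suffix are recomputed lazily:
  ## positions after p are never modified before p is examined, so the
  ## working track and the original agree from p+1 onward.
  runAfter <- function(p, code) {
    q <- p + 1L
    while (q <= n && codes[q] == code) q <- q + 1L
    q - p - 1L
  }
  precRun <- 0L   # length of the run of codes[p-1] ending at p-1
  for (p in seq_len(n)) {
    cur <- codes[p]
    if (p > 1L) {
      prev <- codes[p - 1L]
      if (cur == "2" && prev == "1" && precRun >= 5L &&
          runAfter(p, "2") <= 3L) {
        codes[p] <- "1"
      } else if (cur == "1" && prev == "2" && precRun >= 5L &&
                 runAfter(p, "1") <= 2L) {
        codes[p] <- "2"
      }
    }
    precRun <- if (p > 1L && codes[p] == codes[p - 1L]) precRun + 1L else 1L
  }
  paste(codes, collapse = "")
}

#' Domain regions from a code track
#'
#' Maximal runs of \code{'1'} as 1-based inclusive intervals.
#'
#' @param track code string over \code{1}/\code{2}.
#' @return \code{IRanges} of the domain regions (possibly empty).
#' @export
extractRegions <- function(track) {
  codes <- checkTrack(track)
  r <- rle(codes)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == "1"
  IRanges(start = starts[keep], end = ends[keep])
}

#' Per-residue confusion counts of a track against truth labels
#'
#' @param track predicted code string over \code{1}/\code{2}.
#' @param truth per-residue truth, either another code track string or a
#'   vector of \code{"positive"}/\code{"negative"} labels.
#' @return Named integer vector \code{c(TP, TN, FP, FN)}.
#' @export
evaluateTrack <- function(track, truth) {
  codes <- checkTrack(track)
  if (is.character(truth) && length(truth) == 1L &&
      nchar(truth) == length(codes) && grepl("^[12]+$", truth)) {
    truthLab <- ifelse(strsplit(truth, "")[[1L]] == "1",
                       "positive", "negative")
  } else {
    truthLab <- as.character(truth)
  }
  if (length(truthLab) != length(codes))
    stop("track and truth lengths differ")
  predLab <- ifelse(codes == "1", "positive", "negative")
  confusionCounts(predLab, truthLab)
}

#' Read/write code tracks as TSV
#'
#' Tracks are stored as a two-column table (\code{protein_id},
#' \code{codes}).
#'
#' @param tracks named character vector (or list) of code strings.
#' @param path file path.
#' @return For the writer, \code{path} invisibly; for the reader, a named
#'   character vector of tracks.
#' @export
writeTracks <- function(tracks, path) {
  tracks <- unlist(tracks)
  tab <- data.frame(protein_id = names(tracks), codes = unname(tracks))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeTracks
#' @export
readTracks <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("protein_id", "codes") %in% names(tab)))
    stop("track file must have columns protein_id, codes")
  stats::setNames(tab$codes, tab$protein_id)
}
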