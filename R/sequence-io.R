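# Readers and writers for the external formats the pipeline touches:
# FASTA, domain-interval TSVs, PSI-BLAST ASCII PSSMs and per-residue
# feature tables (disorder / secondary structure / solvent accessibility).
# Coordinates are 1-based inclusive everywhere on disk.

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased; characters outside the 20-letter amino-acid
#' alphabet (plus \code{X}) are replaced by \code{X} with a warning, the
#' same nominal residue used for window padding.
#'
#' @param path FASTA file.
#' @return A \linkS4class{ProteinSet} with empty domain annotations. Ids
#'   are the first whitespace-delimited token of each header.
#' @export
readFastaProteins <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  names(seqs) <- ids
  ProteinSet(seqs)
}

#' Write a ProteinSet's sequences to FASTA
#'
#' @param proteins a \linkS4class{ProteinSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFastaProteins <- function(proteins, path) {
  Biostrings::writeXStringSet(sequences(proteins), path)
  invisible(path)
}

#' Read domain annotations and attach them to proteins
#'
#' Reads a tab-separated table with header columns \code{protein_id},
#' \code{start}, \code{end} (1-based inclusive residue coordinates) and
#' returns the proteins with their domain intervals filled in.
#' Overlapping or adjacent intervals of the same protein are merged.
#'
#' @param path TSV file.
#' @param proteins a \linkS4class{ProteinSet}; every row must reference one
#'   of its ids.
#' @return A \linkS4class{ProteinSet} with domains replaced by the file's
#'   (merged, sorted) intervals.
#' @export
readDomainAnnotations <- function(path, proteins) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "start", "end")
  if (!all(need %in% names(tab)))
    stop("annotation file must have columns ", paste(need, collapse = ", "))
  ids <- proteinIds(proteins)
  unknown <- setdiff(unique(tab$protein_id), ids)
  if (length(unknown))
    stop("annotation rows reference unknown protein id(s): ",
         paste(unknown, collapse = ", "))
  lens <- stats::setNames(Biostrings::width(sequences(proteins)), ids)
  for (r in seq_len(nrow(tab))) {
    s <- tab$start[r]; e <- tab$end[r]; id <- tab$protein_id[r]
    if (is.na(s) || is.na(e) || s < 1L || s > e)
      stop(sprintf("row %d (%s): invalid interval [%s, %s]", r, id, s, e))
    if (e > lens[[id]])
      stop(sprintf("row %d (%s): end %d exceeds sequence length %d",
                   r, id, e, lens[[id]]))
  }
  dom <- split(IRanges(start = as.integer(tab$start),
                       end = as.integer(tab$end)),
               factor(tab$protein_id, levels = ids))
  dom <- IRangesList(lapply(dom, IRanges::reduce))
  names(dom) <- ids
  new("ProteinSet", sequences = sequences(proteins), domains = dom)
}

#' Write domain regions to TSV
#'
#' Emits a tab-separated table (\code{protein_id}, \code{start},
#' \code{end}; 1-based inclusive) that round-trips through
#' \code{\link{readDomainAnnotations}}.
#'
#' @param regions named list of \code{IRanges} (or two-column
#'   start/end matrices), or a data.frame with columns \code{protein_id},
#'   \code{start}, \code{end}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRegions <- function(regions, path) {
  if (is.data.frame(regions)) {
    tab <- regions[, c("protein_id", "start", "end")]
  } else {
    rows <- lapply(names(regions), function(id) {
      r <- regions[[id]]
      if (is(r, "IRanges")) {
        data.frame(protein_id = rep(id, length(r)),
                   start = IRanges::start(r), end = IRanges::end(r))
      } else {
        r <- as.data.frame(r)
        if (NROW(r) == 0L) return(NULL)
        data.frame(protein_id = rep(id, nrow(r)),
                   start = as.integer(r[[1L]]), end = as.integer(r[[2L]]))
      }
    })
    tab <- do.call(rbind, c(rows, list(
      data.frame(protein_id = character(), start = integer(),
                 end = integer()))))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the ASCII matrix that PSI-BLAST writes (header lines, one row per
#' residue with position, residue letter and 20 log-odds columns,
#' optionally followed by 20 weighted-percentage columns and a trailing
#' statistics block, which is ignored). Columns are remapped from the
#' file's own amino-acid header to the canonical PSI-BLAST order
#' (\code{A R N D C Q E G H I L K M F P S T W Y V}), so \code{pssm_13} is
#' always the methionine column whatever the file's layout.
#'
#' Rows are returned in file order; the parser never reorders them.
#'
#' @param path PSSM file.
#' @param sequence optional amino-acid string; if given, the row count must
#'   equal its length.
#' @param scores which score block feeds the features: the log-odds columns
#'   (default) or the weighted percentages (requires a 40-column file).
#' @return Numeric matrix L x 20, columns named by the canonical order,
#'   rows named by the file's residue letters.
#' @export
readPssmAscii <- function(path, sequence = NULL,
                          scores = c("logodds", "percent")) {
  scores <- match.arg(scores)
  lines <- readLines(path, warn = FALSE)
  tok <- lapply(lines, function(x) strsplit(trimws(x), "[ \t]+")[[1L]])
  isHeader <- vapply(tok, function(tk)
    length(tk) %in% c(20L, 40L) && all(tk %in% AA_ALPHABET), NA)
  hi <- which(isHeader)
  if (length(hi) == 0L) stop("no amino-acid column header found in ", path)
  hi <- hi[1L]
  header <- tok[[hi]]
  ncols <- length(header)
  if (scores == "percent" && ncols != 40L)
    stop("percent scores requested but ", path, " has no percentage block")
  rowRe <- "^[0-9]+$"
  mat <- NULL; resid <- character()
  for (k in seq(hi + 1L, length.out = max(0L, length(lines) - hi))) {
    tk <- tok[[k]]
    if (length(tk) == 0L) break
    if (!grepl(rowRe, tk[1L]) || !(tk[2L] %in% AA_ALPHABET_X)) break
    vals <- suppressWarnings(as.numeric(tk[-(1:2)]))
    if (length(vals) < ncols || anyNA(vals[seq_len(ncols)]))
      stop("truncated or malformed PSSM row at line ", k, " of ", path)
    use <- if (scores == "logodds") seq_len(20L) else 21:40
    mat <- rbind(mat, vals[use])
    resid <- c(resid, tk[2L])
  }
  if (is.null(mat)) stop("no PSSM data rows found in ", path)
  hdr <- header[seq_len(20L)]
  if (anyDuplicated(hdr)) stop("duplicate amino-acid columns in ", path)
  colnames(mat) <- hdr
  mat <- mat[, PSSM_AA_ORDER, drop = FALSE]
  rownames(mat) <- resid
  if (!is.null(sequence) && nrow(mat) != nchar(sequence))
    stop(sprintf("PSSM has %d rows but sequence has %d residues",
                 nrow(mat), nchar(sequence)))
  mat
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Companion writer used by the synthetic generator; output parses back
#' with \code{\link{readPssmAscii}}.
#'
#' @param pssm L x 20 matrix, columns in canonical PSI-BLAST order.
#' @param sequence the residue string (length L) for the row labels.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePssmAscii <- function(pssm, sequence, path) {
  stopifnot(ncol(pssm) == 20L, nrow(pssm) == nchar(sequence))
  res <- strsplit(sequence, "")[[1L]]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed"), con)
  writeLines(paste0("            ",
                    paste(sprintf("%3s", PSSM_AA_ORDER), collapse = " ")),
             con)
  for (i in seq_len(nrow(pssm)))
    writeLines(paste0(sprintf("%5d %s  ", i, res[i]),
                      paste(sprintf("%3d", round(pssm[i, ])),
                            collapse = " ")), con)
  writeLines(c("", "                      K         Lambda",
               "Standard Ungapped    0.1337     0.3176"), con)
  invisible(path)
}

#' Read a per-residue feature table
#'
#' Reads a tab-separated table with header \code{protein_id},
#' \code{position}, \code{value} holding one of the per-residue feature
#' tracks: intrinsic disorder scores in [0, 1], 3-state secondary
#' structure calls (\code{H} helix, \code{E} strand, \code{O} other) or
#' 2-state solvent accessibility (\code{B} buried, \code{E} exposed).
#' Every residue of every referenced protein must be present exactly once.
#'
#' @param path TSV file.
#' @param kind \code{"disorder"}, \code{"ss"} or \code{"sa"}.
#' @param proteins a \linkS4class{ProteinSet} giving ids and lengths.
#' @return Named list, one entry per protein: a numeric vector for
#'   disorder, a character vector of state symbols for ss/sa.
#' @export
readResidueTable <- function(path, kind = c("disorder", "ss", "sa"),
                             proteins) {
  kind <- match.arg(kind)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "integer",
                                          "character"))
  need <- c("protein_id", "position", "value")
  if (!all(need %in% names(tab)))
    stop("residue table must have columns ", paste(need, collapse = ", "))
  ids <- proteinIds(proteins)
  unknown <- setdiff(unique(tab$protein_id), ids)
  if (length(unknown))
    stop("residue table references unknown protein id(s): ",
         paste(unknown, collapse = ", "))
  lens <- stats::setNames(Biostrings::width(sequences(proteins)), ids)
  out <- vector("list", length(ids)); names(out) <- ids
  for (id in intersect(ids, unique(tab$protein_id))) {
    sub <- tab[tab$protein_id == id, ]
    L <- lens[[id]]
    if (any(sub$position < 1L | sub$position > L))
      stop("position out of range for ", id)
    if (anyDuplicated(sub$position))
      stop("duplicate positions for ", id)
    if (nrow(sub) != L)
      stop(sprintf("%s: %d of %d residue positions present", id,
                   nrow(sub), L))
    v <- sub$value[order(sub$position)]
    if (kind == "disorder") {
      v <- as.numeric(v)
      if (anyNA(v) || any(v < 0 | v > 1))
        stop("disorder scores must be numbers in [0, 1] (", id, ")")
    } else {
      states <- if (kind == "ss") SS_STATES else SA_STATES
      bad <- setdiff(unique(v), states)
      if (length(bad))
        stop("unknown ", kind, " state symbol(s): ",
             paste(bad, collapse = ", "))
    }
    out[[id]] <- v
  }
  missing <- ids[vapply(out, is.null, NA)]
  if (length(missing))
    stop("no ", kind, " values for protein(s): ",
         paste(missing, collapse = ", "))
  out
}

#' Write a per-residue feature table
#'
#' @param values named list (one entry per protein) of per-residue values,
#'   as returned by \code{\link{readResidueTable}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeResidueTable <- function(values, path) {
  tab <- do.call(rbind, lapply(names(values), function(id)
    data.frame(protein_id = rep(id, length(values[[id]])),
               position = seq_along(values[[id]]),
               value = values[[id]])))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
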