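# End-to-end orchestration: encode -> rank -> IFS -> winnow -> train ->
# predict -> refine -> evaluate, as one function over in-memory objects,
# with optional writing of every stage artifact plus the resolved
# configuration for provenance.

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the whole pipeline with their
#' reference defaults: window size 13 (403 features), mRMR discretization
#' at mean +/- 1 sd, IFS step 5, a 10-tree forest with
#' \code{floor(log2(M)) + 1} features per node, and the scanning
#' refinement enabled.
#'
#' @param window odd sliding-window size (13, 15 or 17).
#' @param kSigma mRMR discretization width.
#' @param step IFS step (features added per subset; also the winnowing
#'   gap).
#' @param nTrees trees per forest.
#' @param m features per node (NULL = \code{floor(log2(M)) + 1}).
#' @param seed master seed (feature selection CV, final CV, forests).
#' @param identityThreshold window dedup threshold in (0, 1]; 1 removes
#'   exact duplicates only.
#' @param refine apply the scanning refinement to the predicted tracks.
#' @param criterion tree split criterion.
#' @return A config list (class \code{"PipelineConfig"}).
#' @export
pipelineConfig <- function(window = 13L, kSigma = 1, step = 5L,
                           nTrees = 10L, m = NULL, seed = 1L,
                           identityThreshold = 1.0, refine = TRUE,
                           criterion = c("entropy", "gini")) {
  criterion <- match.arg(criterion)
  window <- checkWindowSize(window)
  if (step < 1L) stop("step must be >= 1")
  if (nTrees < 1L) stop("nTrees must be >= 1")
  structure(list(window = window, kSigma = kSigma,
                 step = as.integer(step), nTrees = as.integer(nTrees),
                 m = m, seed = as.integer(seed),
                 identityThreshold = identityThreshold,
                 refine = isTRUE(refine), criterion = criterion),
            class = "PipelineConfig")
}

#' Encode proteins from the pipeline's input files
#'
#' Reads FASTA sequences, domain annotations, per-protein PSSM files and
#' the disorder/ss/sa residue tables, and assembles the per-residue
#' feature blocks.
#'
#' @param fasta FASTA path.
#' @param domains domain-annotation TSV path (NULL for none).
#' @param pssmDir directory of \code{<id>.pssm} PSI-BLAST ASCII files.
#' @param disorder,ss,sa residue-table TSV paths.
#' @return List with \code{proteins} and \code{blocks}, ready for
#'   \code{\link{makeWindows}}.
#' @export
encodeFromFiles <- function(fasta, domains = NULL, pssmDir, disorder,
                            ss, sa) {
  proteins <- readFastaProteins(fasta)
  if (!is.null(domains))
    proteins <- readDomainAnnotations(domains, proteins)
  seqs <- as.character(sequences(proteins))
  pssm <- lapply(stats::setNames(nm = proteinIds(proteins)), function(id) {
    path <- file.path(pssmDir, paste0(id, ".pssm"))
    if (!file.exists(path)) stop("no PSSM file for ", id, ": ", path)
    readPssmAscii(path, sequence = seqs[[id]])
  })
  disorderT <- readResidueTable(disorder, "disorder", proteins)
  ssT <- readResidueTable(ss, "ss", proteins)
  saT <- readResidueTable(sa, "sa", proteins)
  blocks <- buildFeatureBlocks(proteins, pssm, disorderT, ssT, saT)
  list(proteins = proteins, blocks = blocks)
}

#' Run the whole prediction pipeline
#'
#' Encodes windows, ranks features by mRMR, scans the IFS curve with
#' cross-validated forests, picks the optimal subset and the winnowed
#' final set, derives per-protein code tracks from the out-of-fold
#' predictions on the final set, applies the scanning refinement, and
#' reports pre/post-refinement metrics.
#'
#' @param proteins a \linkS4class{ProteinSet} with domain annotations.
#' @param blocks per-residue feature blocks
#'   (\code{\link{buildFeatureBlocks}}).
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional directory; when given, every stage artifact is
#'   written there (samples, rankings, IFS curve, model JSON, tracks,
#'   regions, the metrics report and the resolved config).
#' @return List with the stage outputs: \code{samples}, \code{ranked},
#'   \code{curve}, \code{optimalFeatures}, \code{finalFeatures},
#'   \code{cv}, \code{forest}, \code{tracks} (raw),
#'   \code{tracksRefined}, \code{regions}, and \code{report} (one metrics
#'   row per refinement state).
#' @export
runPipeline <- function(proteins, blocks, config = pipelineConfig(seed = 1L),
                        outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  samples <- makeWindows(proteins, blocks, config$window)
  samples <- dedupeSamples(samples, config$identityThreshold)
  ranked <- mrmrRank(samples, kSigma = config$kSigma)
  curve <- ifsCurve(samples, ranked, step = config$step,
                    seed = config$seed, nTrees = config$nTrees,
                    m = config$m, criterion = config$criterion)
  optimal <- optimalSet(curve, ranked)
  final <- winnowFinal(curve, ranked, gap = config$step)
  cv <- fiveFoldCV(samples, final, seed = config$seed,
                   nTrees = config$nTrees, m = config$m,
                   criterion = config$criterion)
  forest <- fitForest(featureMatrix(samples)[, final, drop = FALSE],
                      sampleLabels(samples), nTrees = config$nTrees,
                      m = config$m, seed = config$seed,
                      criterion = config$criterion)
  ## per-residue predictions: out-of-fold where a sample was retained,
  ## full-data forest for residues dropped by the dedup
  labs <- labelResidues(proteins)
  predAll <- lapply(stats::setNames(nm = proteinIds(proteins)),
                    function(id) rep(NA_character_, length(labs[[id]])))
  keyRetained <- paste(samples@proteinId, samples@center)
  for (s in seq_along(keyRetained))
    predAll[[samples@proteinId[s]]][samples@center[s]] <-
      as.character(cv$predictions[s])
  needFill <- vapply(predAll, anyNA, NA)
  if (any(needFill)) {
    full <- makeWindows(proteins[which(needFill)],
                        blocks[needFill], config$window)
    fullKey <- paste(full@proteinId, full@center)
    gap <- !(fullKey %in% keyRetained)
    if (any(gap)) {
      gapPred <- predict(forest,
                         featureMatrix(full)[gap, final, drop = FALSE])
      gp <- full@proteinId[gap]; gc <- full@center[gap]
      for (s in seq_along(gp))
        predAll[[gp[s]]][gc[s]] <- as.character(gapPred[s])
    }
  }
  tracks <- vapply(predAll, codesFromPredictions, character(1L))
  tracksRefined <- if (config$refine) vapply(tracks, refineTrack,
                                             character(1L)) else tracks
  regions <- lapply(tracksRefined, extractRegions)
  truth <- unlist(labs, use.names = FALSE)
  rawCounts <- confusionCounts(
    ifelse(strsplit(paste(tracks, collapse = ""), "")[[1L]] == "1",
           "positive", "negative"), truth)
  refCounts <- confusionCounts(
    ifelse(strsplit(paste(tracksRefined, collapse = ""), "")[[1L]] == "1",
           "positive", "negative"), truth)
  report <- rbind(
    data.frame(refinement = "no", t(metrics(rawCounts))),
    if (config$refine) data.frame(refinement = "yes",
                                  t(metrics(refCounts))))
  names(report) <- c("refinement", "Sn", "Sp", "Ac", "MCC")
  out <- list(samples = samples, ranked = ranked, curve = curve,
              optimalFeatures = optimal, finalFeatures = final, cv = cv,
              forest = forest, tracks = tracks,
              tracksRefined = tracksRefined, regions = regions,
              report = report, config = config)
  if (!is.null(outDir)) writePipelineOutputs(out, outDir)
  out
}

writePipelineOutputs <- function(out, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeSamples(out$samples, file.path(outDir, "samples.tsv"))
  writeRankedFeatures(out$ranked, file.path(outDir, "maxrel.tsv"),
                      file.path(outDir, "mrmr.tsv"))
  utils::write.table(out$curve, file.path(outDir, "ifs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  writeForestJSON(out$forest, file.path(outDir, "model.json"))
  writeTracks(out$tracks, file.path(outDir, "tracks.tsv"))
  writeTracks(out$tracksRefined, file.path(outDir, "refined.tsv"))
  writeRegions(out$regions, file.path(outDir, "regions.tsv"))
  utils::write.table(out$report, file.path(outDir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  cfg <- out$config
  attr(cfg, "class") <- NULL
  cfg$finalFeatures <- out$finalFeatures
  jsonlite::write_json(cfg, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outDir)
}
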