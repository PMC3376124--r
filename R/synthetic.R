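# Synthetic proteins, domain architectures and per-residue feature
# tracks with controllable class-conditional signal. The generator
# emulates what the external predictors would supply (PSSM conservation
# scores, disorder scores, secondary structure, solvent accessibility)
# so the whole pipeline can be exercised and validated offline: PSSM-like
# channels are integer-rounded Gaussians, not real alignment profiles.

#' Configuration for the synthetic generator
#'
#' Effect sizes are expressed as the domain-minus-linker mean shift in
#' within-class standard deviation units. Directions of the defaults
#' follow what is seen in real data: domain residues are less disordered,
#' more often buried, and more often in regular secondary structure than
#' linker residues. Segment lengths are geometric, emulating the
#' run-length structure of real domain architectures.
#'
#' @param nProteins number of proteins.
#' @param lengthRange integer c(min, max) protein length (uniform).
#' @param domainMeanLen,linkerMeanLen mean segment lengths (geometric,
#'   minimum 1); proteins alternate linker/domain starting with a linker.
#' @param pssmEffect length-20 vector of per-channel mean shifts (sigma
#'   units) for domain residues.
#' @param aafEffect length-5 vector tilting the domain residue
#'   composition along the Atchley factors: domain residues are sampled
#'   with weights proportional to \code{exp(sum(aafEffect * factors))},
#'   which shifts the factor-channel means.
#' @param disorderBase,disorderSd,disorderEffect linker disorder is
#'   N(disorderBase, disorderSd) clamped to [0, 1]; domain disorder is
#'   shifted by \code{disorderEffect} sigma units (negative = more
#'   ordered).
#' @param ssProbs 2 x 3 matrix of H/E/O state probabilities, rows
#'   \code{domain}, \code{linker}.
#' @param saProbs 2 x 2 matrix of B/E state probabilities, rows
#'   \code{domain}, \code{linker}.
#' @param labelNoise per-residue probability that the features are drawn
#'   from the opposite class (annotation stays truthful).
#' @param plantChannels PSSM channel indices (1..20) given an additional
#'   planted shift of \code{plantEffect} sigma units - the designated
#'   informative features for recovery checks.
#' @param plantEffect sigma shift of the planted channels.
#' @param pssmSd within-class standard deviation of the PSSM channels
#'   before integer rounding.
#' @param null if TRUE, zero every class-conditional difference (features
#'   become independent of the labels).
#' @param seed mandatory integer seed.
#' @return A config list (class \code{"SimConfig"}).
#' @export
simConfig <- function(nProteins = 20L, lengthRange = c(80L, 200L),
                      domainMeanLen = 60, linkerMeanLen = 15,
                      pssmEffect = c(rep(0.5, 4), rep(0, 16)),
                      aafEffect = c(0, 0, 0, 0.4, 0.4),
                      disorderBase = 0.55, disorderSd = 0.15,
                      disorderEffect = -1.0,
                      ssProbs = rbind(domain = c(H = 0.38, E = 0.28, O = 0.34),
                                      linker = c(H = 0.22, E = 0.18, O = 0.60)),
                      saProbs = rbind(domain = c(B = 0.55, E = 0.45),
                                      linker = c(B = 0.35, E = 0.65)),
                      labelNoise = 0, plantChannels = integer(0),
                      plantEffect = 3, pssmSd = 2, null = FALSE,
                      seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (null) {
    pssmEffect <- rep(0, 20)
    aafEffect <- rep(0, 5)
    disorderEffect <- 0
    ssProbs[] <- rep(colMeans(ssProbs), each = 2)
    saProbs[] <- rep(colMeans(saProbs), each = 2)
    plantChannels <- integer(0)
  }
  stopifnot(length(pssmEffect) == 20L, length(aafEffect) == 5L,
            nrow(ssProbs) == 2L, ncol(ssProbs) == 3L,
            nrow(saProbs) == 2L, ncol(saProbs) == 2L,
            all(abs(rowSums(ssProbs) - 1) < 1e-8),
            all(abs(rowSums(saProbs) - 1) < 1e-8),
            labelNoise >= 0, labelNoise <= 1,
            all(plantChannels %in% 1:20),
            lengthRange[1L] >= 1L, lengthRange[2L] >= lengthRange[1L])
  structure(list(nProteins = as.integer(nProteins),
                 lengthRange = as.integer(lengthRange),
                 domainMeanLen = domainMeanLen,
                 linkerMeanLen = linkerMeanLen,
                 pssmEffect = pssmEffect, aafEffect = aafEffect,
                 disorderBase = disorderBase, disorderSd = disorderSd,
                 disorderEffect = disorderEffect,
                 ssProbs = ssProbs, saProbs = saProbs,
                 labelNoise = labelNoise,
                 plantChannels = as.integer(plantChannels),
                 plantEffect = plantEffect, pssmSd = pssmSd,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

geomSegment <- function(n, meanLen)
  1L + stats::rgeom(n, prob = 1 / max(meanLen, 1))

#' Generate synthetic proteins with class-conditional feature tracks
#'
#' Builds alternating linker/domain architectures, samples residue
#' identities (with the configured composition tilt for domain residues)
#' and the four external feature tracks conditional on each residue's
#' class, then assembles the canonical 31-channel feature blocks. Fully
#' deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{simConfig}}.
#' @return List with \code{proteins} (\linkS4class{ProteinSet} carrying
#'   the true domain annotations), \code{blocks} (per-protein L x 31
#'   matrices), \code{labels} (per-protein truth labels) and
#'   \code{tracks} (the raw pssm/disorder/ss/sa tracks, writable with the
#'   package's writers).
#' @export
generateProteins <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  localSeed(config$seed, {
    ids <- sprintf("SYN%04d", seq_len(config$nProteins))
    totalShift <- config$pssmEffect
    totalShift[config$plantChannels] <-
      totalShift[config$plantChannels] + config$plantEffect
    domWeights <- exp(as.vector(ATCHLEY_TABLE %*% config$aafEffect))
    domWeights <- domWeights / sum(domWeights)
    aaNames <- rownames(ATCHLEY_TABLE)
    seqs <- character(config$nProteins)
    domList <- vector("list", config$nProteins)
    tracks <- list(pssm = list(), disorder = list(), ss = list(),
                   sa = list())
    labels <- vector("list", config$nProteins)
    for (i in seq_along(ids)) {
      L <- sample(config$lengthRange[1L]:config$lengthRange[2L], 1L)
      isDom <- logical(0)
      ## geometric segments + a stationary initial state make the label
      ## process stationary in position, so terminus proximity (visible
      ## through window padding) carries no label information
      pDom <- config$domainMeanLen /
        (config$domainMeanLen + config$linkerMeanLen)
      state <- stats::runif(1L) < pDom
      while (length(isDom) < L) {
        len <- geomSegment(1L, if (state) config$domainMeanLen
                               else config$linkerMeanLen)
        isDom <- c(isDom, rep(state, len))
        state <- !state
      }
      isDom <- isDom[seq_len(L)]
      labels[[i]] <- ifelse(isDom, "positive", "negative")
      ## feature class: truth, except for label-noise residues
      featDom <- isDom
      if (config$labelNoise > 0) {
        flip <- stats::runif(L) < config$labelNoise
        featDom[flip] <- !featDom[flip]
      }
      res <- character(L)
      nd <- sum(featDom)
      res[featDom] <- sample(aaNames, nd, replace = TRUE,
                             prob = domWeights)
      res[!featDom] <- sample(aaNames, L - nd, replace = TRUE)
      seqs[i] <- paste(res, collapse = "")
      shift <- outer(as.numeric(featDom), totalShift * config$pssmSd)
      pssm <- matrix(stats::rnorm(L * 20L, sd = config$pssmSd), L, 20L)
      pssm <- round(pssm + shift)
      colnames(pssm) <- PSSM_AA_ORDER
      dis <- stats::rnorm(L, mean = config$disorderBase +
                            featDom * config$disorderEffect *
                            config$disorderSd,
                          sd = config$disorderSd)
      dis <- pmin(1, pmax(0, dis))
      ssRow <- config$ssProbs[ifelse(featDom, 1L, 2L), , drop = FALSE]
      u <- stats::runif(L)
      ssIdx <- 1L + (u > ssRow[, 1L]) + (u > ssRow[, 1L] + ssRow[, 2L])
      saRow <- config$saProbs[ifelse(featDom, 1L, 2L), , drop = FALSE]
      saIdx <- 1L + (stats::runif(L) > saRow[, 1L])
      ## domain segments are the truth annotation
      r <- rle(isDom)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      domList[[i]] <- cbind(start = starts[r$values],
                            end = ends[r$values])
      tracks$pssm[[ids[i]]] <- pssm
      tracks$disorder[[ids[i]]] <- dis
      tracks$ss[[ids[i]]] <- SS_STATES[ssIdx]
      tracks$sa[[ids[i]]] <- SA_STATES[saIdx]
    }
    names(seqs) <- ids
    names(domList) <- ids
    names(labels) <- ids
    proteins <- ProteinSet(seqs, domList)
    blocks <- buildFeatureBlocks(proteins, tracks$pssm, tracks$disorder,
                                 tracks$ss, tracks$sa)
    list(proteins = proteins, blocks = blocks, labels = labels,
         tracks = tracks, config = config)
  })
}

#' Write a generated dataset to disk in the pipeline's input formats
#'
#' Emits \code{proteins.fasta}, \code{domains.tsv}, one
#' \code{<id>.pssm} per protein under \code{pssm/}, and
#' \code{disorder.tsv} / \code{ss.tsv} / \code{sa.tsv}; everything reads
#' back with the package's readers.
#'
#' @param sim output of \code{\link{generateProteins}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulatedData <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pssm"), showWarnings = FALSE)
  writeFastaProteins(sim$proteins, file.path(dir, "proteins.fasta"))
  doms <- domains(sim$proteins)
  regs <- lapply(stats::setNames(nm = proteinIds(sim$proteins)),
                 function(id) doms[[id]])
  writeRegions(regs, file.path(dir, "domains.tsv"))
  seqs <- as.character(sequences(sim$proteins))
  for (id in proteinIds(sim$proteins))
    writePssmAscii(sim$tracks$pssm[[id]], seqs[[id]],
                   file.path(dir, "pssm", paste0(id, ".pssm")))
  writeResidueTable(sim$tracks$disorder, file.path(dir, "disorder.tsv"))
  writeResidueTable(sim$tracks$ss, file.path(dir, "ss.tsv"))
  writeResidueTable(sim$tracks$sa, file.path(dir, "sa.tsv"))
  invisible(dir)
}

#' Names of the planted (designated informative) window features
#'
#' The generator plants its signal on per-residue PSSM channels; the
#' direct window-level readout of channel c is the center-subsite feature
#' \code{AA<(w+1)/2>_pssm_<c>}, so those are the designated features a
#' ranking should recover.
#'
#' @param config a \code{\link{simConfig}} with non-empty
#'   \code{plantChannels}.
#' @param w window size.
#' @return Character vector of feature names.
#' @export
plantedFeatures <- function(config, w = 13L) {
  w <- checkWindowSize(w)
  paste0("AA", (w + 1L) %/% 2L, "_pssm_", config$plantChannels)
}

#' Recovery of planted features by a ranking
#'
#' The fraction of the designated planted features found among the top-k
#' of the mRMR ordering.
#'
#' @param config the \code{\link{simConfig}} used to generate the data.
#' @param ranked a \linkS4class{RankedFeatures} (or a character vector of
#'   mRMR-ordered names).
#' @param k how many top features to look at.
#' @return Recall in [0, 1].
#' @export
plantCheck <- function(config, ranked, k) {
  if (is(ranked, "RankedFeatures")) ranked <- mrmrOrder(ranked)
  if (length(config$plantChannels) == 0L)
    stop("config has no planted channels")
  subsites <- parseFeatureNames(ranked)$subsite
  w <- max(subsites)
  planted <- plantedFeatures(config, w)
  mean(planted %in% utils::head(ranked, k))
}
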