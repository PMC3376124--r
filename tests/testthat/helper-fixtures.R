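# Small in-code fixtures shared across test files.

## single-tree prediction, bypassing the forest vote
.predictTreeForTest <- function(tree, x)
  domainsweep:::.cppPredictTree(tree, as.matrix(x))

tinyFasta <- function(entries, dir = withr::local_tempdir(.local_envir =
                                                            parent.frame())) {
  path <- file.path(dir, "tiny.fasta")
  writeLines(unlist(lapply(names(entries), function(id)
    c(paste0(">", id), entries[[id]]))), path)
  path
}

tinyTsv <- function(df, name = "tiny.tsv",
                    dir = withr::local_tempdir(.local_envir =
                                                 parent.frame())) {
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## a hand-built PSI-BLAST-style ASCII PSSM with header noise and a
## trailing statistics block; values = position * 100 + column (before
## remapping), so provenance of every cell is checkable
tinyPssmFile <- function(sequence = "ACDE",
                         order = c("A", "R", "N", "D", "C", "Q", "E", "G",
                                   "H", "I", "L", "K", "M", "F", "P", "S",
                                   "T", "W", "Y", "V"),
                         dir = withr::local_tempdir(.local_envir =
                                                      parent.frame())) {
  path <- file.path(dir, "tiny.pssm")
  res <- strsplit(sequence, "")[[1]]
  lines <- c("", "Last position-specific scoring matrix computed",
             paste0("      ", paste(order, collapse = "  ")))
  for (i in seq_along(res))
    lines <- c(lines, paste(i, res[i],
                            paste(i * 100 + seq_along(order),
                                  collapse = " ")))
  lines <- c(lines, "", "                 K         Lambda",
             "Standard Ungapped 0.13 0.31")
  writeLines(lines, path)
  path
}

## deterministic small feature blocks: value = position + channel / 100
tinyBlocks <- function(proteins) {
  labs <- labelResidues(proteins)
  out <- lapply(labs, function(l) {
    L <- length(l)
    B <- matrix(rep(seq_len(L), 31) + rep(seq_len(31) / 100, each = L),
                nrow = L, ncol = 31,
                dimnames = list(NULL, blockChannels()))
    B
  })
  out
}

## a small planted-signal dataset reused by several suites
plantedSim <- function(seed = 42L, nProteins = 6L,
                       lengthRange = c(60L, 100L),
                       plantChannels = 1:10, plantEffect = 3) {
  cfg <- simConfig(nProteins = nProteins, lengthRange = lengthRange,
                   plantChannels = plantChannels,
                   plantEffect = plantEffect, seed = seed)
  sim <- generateProteins(cfg)
  sim$windows <- makeWindows(sim$proteins, sim$blocks, 13L)
  sim
}
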