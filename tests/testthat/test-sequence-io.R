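# Readers/writers: FASTA, domain annotations, PSSM ASCII, residue tables.

test_that("FASTA reading uppercases, validates ids and substitutes X", {
  p <- tinyFasta(list(p1 = "ACDE"))
  ps <- readFastaProteins(p)
  expect_s4_class(ps, "ProteinSet")
  expect_identical(proteinIds(ps), "p1")
  expect_identical(as.character(sequences(ps)), c(p1 = "ACDE"))

  p2 <- tinyFasta(list(p1 = "acde", p2 = "KKK"))
  ps2 <- readFastaProteins(p2)
  expect_identical(unname(as.character(sequences(ps2))), c("ACDE", "KKK"))

  p3 <- tinyFasta(list(p1 = "AC?E"))
  expect_warning(ps3 <- readFastaProteins(p3), "replaced by 'X'")
  expect_identical(unname(as.character(sequences(ps3))), "ACXE")

  dup <- tinyFasta(list(a = "AC"))
  writeLines(c(">a", "AC", ">a", "DE"), dup)
  expect_error(readFastaProteins(dup), "duplicate")

  empty <- tempfile(fileext = ".fasta"); file.create(empty)
  expect_error(readFastaProteins(empty))
})

test_that("domain annotations are merged, sorted and bounds-checked", {
  ps <- ProteinSet(c(p1 = "ACDE", p2 = "KKKKKK"))
  path <- tinyTsv(data.frame(protein_id = "p1", start = 2, end = 3))
  out <- readDomainAnnotations(path, ps)
  expect_equal(as.data.frame(domains(out)$p1)[, c("start", "end")],
               data.frame(start = 2L, end = 3L))
  expect_equal(length(domains(out)$p2), 0L)

  merged <- tinyTsv(data.frame(protein_id = c("p1", "p1"),
                               start = c(1, 2), end = c(2, 4)))
  out2 <- readDomainAnnotations(merged, ps)
  expect_equal(as.data.frame(domains(out2)$p1)[, c("start", "end")],
               data.frame(start = 1L, end = 4L))

  oob <- tinyTsv(data.frame(protein_id = "p1", start = 5, end = 9))
  expect_error(readDomainAnnotations(oob, ps), "row 1")
  rev <- tinyTsv(data.frame(protein_id = "p1", start = 3, end = 2))
  expect_error(readDomainAnnotations(rev, ps), "row 1")
  unk <- tinyTsv(data.frame(protein_id = "zz", start = 1, end = 2))
  expect_error(readDomainAnnotations(unk, ps), "unknown")
})

test_that("annotation/region writers round-trip through the reader", {
  ps <- ProteinSet(c(p1 = "ACDEFGHIK", p2 = "KKKKKK"))
  regions <- list(p1 = IRanges::IRanges(start = c(2, 7), end = c(5, 9)),
                  p2 = IRanges::IRanges())
  path <- tempfile(fileext = ".tsv")
  writeRegions(regions, path)
  back <- readDomainAnnotations(path, ps)
  expect_equal(as.data.frame(domains(back)$p1)[, c("start", "end")],
               data.frame(start = c(2L, 7L), end = c(5L, 9L)))
  expect_equal(length(domains(back)$p2), 0L)

  ## header-only file for no regions at all
  writeRegions(list(p1 = IRanges::IRanges()), path)
  expect_equal(length(readLines(path)), 1L)
})

test_that("PSSM parser reads rows in order, remaps columns, skips stats", {
  path <- tinyPssmFile("ACDE")
  m <- readPssmAscii(path)
  expect_equal(dim(m), c(4L, 20L))
  expect_identical(colnames(m),
                   c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                     "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"))
  ## cell value encodes (position, original column); file was written in
  ## canonical order so cell (i, j) = i * 100 + j
  expect_equal(m[3, "N"], 303)
  expect_equal(m[1, "V"], 120)

  ## an alphabetically ordered file must land on the same canonical matrix
  alpha <- sort(colnames(m))
  path2 <- tinyPssmFile("ACDE", order = alpha)
  m2 <- readPssmAscii(path2)
  ## column "A" was column 1 in both files; column "C" was col 5 vs col 2
  expect_equal(m2[2, "C"], 202)
  expect_equal(m[2, "C"], 205)
  expect_identical(colnames(m2), colnames(m))

  expect_error(readPssmAscii(path, sequence = "ACDEF"), "4 rows")
  expect_silent(readPssmAscii(path, sequence = "ACDE"))
})

test_that("PSSM parser preserves input row order and rejects bad rows", {
  dir <- withr::local_tempdir()
  path <- tinyPssmFile("ACDE", dir = dir)
  lines <- readLines(path)
  ## swap the two middle data rows; output rows must swap identically
  rows <- grep("^[0-9]+ ", lines)
  swapped <- lines
  swapped[rows[2:3]] <- lines[rows[3:2]]
  path2 <- file.path(dir, "swapped.pssm")
  writeLines(swapped, path2)
  m <- readPssmAscii(path)
  m2 <- readPssmAscii(path2)
  expect_equal(unname(m2), unname(m[c(1, 3, 2, 4), ]))

  truncated <- lines
  truncated[rows[2]] <- "2 C 1 2 3"
  path3 <- file.path(dir, "trunc.pssm")
  writeLines(truncated, path3)
  expect_error(readPssmAscii(path3), "truncated")
})

test_that("residue tables validate ranges, symbols and completeness", {
  ps <- ProteinSet(c(p1 = "A"))
  d <- tinyTsv(data.frame(protein_id = "p1", position = 1, value = "0.9"))
  expect_equal(readResidueTable(d, "disorder", ps), list(p1 = 0.9))

  bad <- tinyTsv(data.frame(protein_id = "p1", position = 1,
                            value = "1.7"))
  expect_error(readResidueTable(bad, "disorder", ps), "\\[0, 1\\]")

  s <- tinyTsv(data.frame(protein_id = "p1", position = 1, value = "Q"))
  expect_error(readResidueTable(s, "ss", ps), "unknown ss")

  ps3 <- ProteinSet(c(p1 = "ACD"))
  partial <- tinyTsv(data.frame(protein_id = "p1", position = c(1, 3),
                                value = c("H", "E")))
  expect_error(readResidueTable(partial, "ss", ps3), "2 of 3")
})

test_that("ss and sa symbols one-hot code as 100/010/001 and 10/01", {
  ps <- ProteinSet(c(p1 = "ACD"))
  psiOrder <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  blocks <- buildFeatureBlocks(
    ps,
    pssm = list(p1 = matrix(0, 3, 20, dimnames = list(NULL, psiOrder))),
    disorder = list(p1 = c(0.1, 0.5, 0.9)),
    ss = list(p1 = c("H", "E", "O")),
    sa = list(p1 = c("B", "E", "B")))
  B <- blocks$p1
  expect_equal(unname(B[1, c("ss_1", "ss_2", "ss_3")]), c(1, 0, 0))
  expect_equal(unname(B[2, c("ss_1", "ss_2", "ss_3")]), c(0, 1, 0))
  expect_equal(unname(B[3, c("ss_1", "ss_2", "ss_3")]), c(0, 0, 1))
  expect_equal(unname(B[1, c("sa_1", "sa_2")]), c(1, 0))
  expect_equal(unname(B[2, c("sa_1", "sa_2")]), c(0, 1))
})

test_that("residue-table writer round-trips through the reader", {
  ps <- ProteinSet(c(p1 = "ACD", p2 = "KK"))
  vals <- list(p1 = c(0.25, 0.5, 0.75), p2 = c(0, 1))
  path <- tempfile(fileext = ".tsv")
  writeResidueTable(vals, path)
  expect_equal(readResidueTable(path, "disorder", ps), vals)
})
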