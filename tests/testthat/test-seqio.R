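test_that("FASTA reading folds case, preserves order and validates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">t1", "acgT"), f)
  ts <- readTranscripts(f)
  expect_equal(names(ts), "t1")
  expect_equal(as.character(ts[[1]]), "ACGT")

  writeLines(c(">t1", "ACG", ">t2", "TTT"), f)
  ts <- readTranscripts(f)
  expect_equal(names(ts), c("t1", "t2"))
  expect_equal(unname(as.character(ts)), c("ACG", "TTT"))

  writeLines(c(">t1", "ACXG"), f)
  expect_error(readTranscripts(f), "t1")

  writeLines(c("ACGT", ">t1", "ACGT"), f)
  expect_error(readTranscripts(f), "line 1")

  writeLines(c(">t1", "ACG", ">t1", "TTT"), f)
  expect_error(readTranscripts(f), "duplicate")
})

test_that("reverse complement is the Watson-Crick involution", {
  expect_equal(revComp("ATGC"), "GCAT")
  expect_equal(revComp("AAANN"), "NNTTT")
  expect_error(revComp("ATXG"), "invalid")
  set.seed(5)
  for (i in 1:20) {
    s <- randomSeq(sample(1:50, 1))
    expect_equal(revComp(revComp(s)), s)
  }
})

makeCalls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

test_that("output writer converts coordinates and splits regions", {
  # CDS spanning internal offsets [3, 9) of a 12 nt plus-strand transcript
  ts <- transcriptSet(c(t1 = "AAAATGTTGTAG", t2 = "ACGTACGTACGT"))
  calls <- S4Vectors::DataFrame(
    transcriptId = c("t1", "t2"),
    start = c(3L, NA), end = c(9L, NA),
    strand = c("+", NA), frame = c(0L, NA),
    hasStart = c(TRUE, NA), hasStop = c(FALSE, NA),
    logScore = c(-12.3456, NA), modelTag = c("full", NA))
  out <- withr::local_tempdir()
  writePredictions(ts, calls, out)
  gtf <- readLines(file.path(out, "predictions.gtf"))
  expect_length(gtf, 1L)                       # uncalled t2 absent
  f <- strsplit(gtf, "\t", fixed = TRUE)[[1]]
  expect_length(f, 9L)
  expect_equal(f[1], "t1")
  expect_equal(f[3], "CDS")
  expect_equal(as.integer(f[4:5]), c(4L, 9L))  # 1-based inclusive
  expect_equal(f[6], "-12.346")
  expect_equal(f[7], "+")
  expect_equal(f[8], "0")
  cds <- readTranscripts(file.path(out, "CDS.fasta"))
  u5 <- readTranscripts(file.path(out, "UTR5.fasta"))
  u3 <- readTranscripts(file.path(out, "UTR3.fasta"))
  expect_equal(names(cds), "t1")
  expect_equal(nchar(as.character(u5[["t1"]])), 3L)
  expect_equal(nchar(as.character(u3[["t1"]])), 3L)
  # concatenation property for the plus-strand call
  expect_equal(paste0(as.character(u5[[1]]), as.character(cds[[1]]),
                      as.character(u3[[1]])),
               as.character(ts[["t1"]]))
})

test_that("minus-strand calls are reverse-complemented onto the coding strand", {
  plusSeq <- paste0("CCCCC", "ATG", "GGGTTT", "TAA", "AAAA")  # 21 nt
  inputSeq <- revComp(plusSeq)
  ts <- transcriptSet(c(m1 = inputSeq))
  L <- nchar(inputSeq)
  # CDS on plus layout at [5, 17); in input orientation [L-17, L-5)
  calls <- S4Vectors::DataFrame(
    transcriptId = "m1", start = L - 17L, end = L - 5L, strand = "-",
    frame = 0L, hasStart = TRUE, hasStop = TRUE, logScore = 1.5,
    modelTag = "full")
  out <- withr::local_tempdir()
  writePredictions(ts, calls, out)
  cds <- as.character(readTranscripts(file.path(out, "CDS.fasta"))[[1]])
  expect_equal(substr(cds, 1, 3), "ATG")
  expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                c("TAA", "TAG", "TGA"))
  expect_equal(cds, "ATGGGGTTTTAA")
  gtf <- strsplit(readLines(file.path(out, "predictions.gtf")), "\t")[[1]]
  expect_equal(gtf[7], "-")
  u5 <- as.character(readTranscripts(file.path(out, "UTR5.fasta"))[[1]])
  expect_equal(u5, "CCCCC")
})

test_that("FASTA writing round-trips and duplicate ids are rejected", {
  ts <- transcriptSet(c(a = "ACGTN", b = "TTTT"))
  out <- withr::local_tempdir()
  calls <- S4Vectors::DataFrame(
    transcriptId = c("a", "b"), start = c(0L, NA), end = c(4L, NA),
    strand = c("+", NA), frame = c(0L, NA), hasStart = c(FALSE, NA),
    hasStop = c(FALSE, NA), logScore = c(0, NA), modelTag = c("full", NA))
  writePredictions(ts, calls, out)
  back <- readTranscripts(file.path(out, "CDS.fasta"))
  expect_equal(as.character(back[["a"]]), "ACGT")
  expect_error(transcriptSet(c("ACG", "TTT"), ids = c("x", "x")),
               "duplicate")
})

test_that("GTF annotations round-trip through write and read", {
  corp <- sharedTestCorpus()[1:6]
  mc <- S4Vectors::mcols(corp)
  calls <- S4Vectors::DataFrame(
    transcriptId = names(corp), start = mc$cdsStart, end = mc$cdsEnd,
    strand = "+", frame = 0L, hasStart = TRUE, hasStop = TRUE,
    logScore = 0, modelTag = "full")
  out <- withr::local_tempdir()
  writePredictions(corp, calls, out)
  bare <- transcriptSet(as.character(corp), names(corp))
  back <- readCdsAnnotations(file.path(out, "predictions.gtf"), bare)
  mcb <- S4Vectors::mcols(back)
  expect_equal(mcb$cdsStart, mc$cdsStart)
  expect_equal(mcb$cdsEnd, mc$cdsEnd)
  expect_true(all(mcb$hasStart & mcb$hasStop))
  expect_error(readCdsAnnotations(file.path(out, "predictions.gtf"),
                                  bare[1:2]), "unknown transcript")
})

test_that("GTF lines satisfy the 9-column and coordinate invariants", {
  bundle <- sharedBundle()
  test <- sharedTestCorpus()[1:8]
  calls <- predictTranscripts(bundle, test)
  out <- withr::local_tempdir()
  writePredictions(test, calls, out)
  gtf <- readLines(file.path(out, "predictions.gtf"))
  expect_gt(length(gtf), 0L)
  for (ln in gtf) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    expect_length(f, 9L)
    w <- Biostrings::width(test)[match(f[1], names(test))]
    expect_true(1L <= as.integer(f[4]))
    expect_true(as.integer(f[4]) <= as.integer(f[5]))
    expect_true(as.integer(f[5]) <= w)
  }
})
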