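test_that("GC fraction excludes N and handles edge compositions", {
  expect_equal(gcFraction("ATGC"), 0.5)
  expect_equal(gcFraction("GGCC"), 1.0)
  expect_equal(gcFraction("ANGC"), 2 / 3)
  expect_equal(gcFraction("NNN"), 0.5)
  expect_error(gcFraction(""), "empty")
})

test_that("GC bin assignment uses half-open intervals with a closed top", {
  breaks <- c(0, 0.45, 0.55, 1)
  expect_equal(assignBin(breaks, 0.5), 2L)
  expect_equal(assignBin(breaks, 0.45), 2L)
  expect_equal(assignBin(breaks, 1.0), 3L)
  expect_equal(assignBin(breaks, 0), 1L)
  bundle <- sharedBundle()
  expect_equal(assignBin(bundle, 0.4), 1L)
})

test_that("Laplace smoothing gives the textbook estimate on all-A data", {
  n <- 17L
  codes <- transcds:::encodeSeq(strrep("A", n))
  m <- transcds:::fitMarkovChain(list(codes), list(seq_len(n)), 0L,
                                 pseudocount = 1, minContextObs = 0L)
  expect_equal(exp(m@logProb[1, 1]), (n + 1) / (n + 4), tolerance = 1e-12)
})

test_that("sparse contexts back off to lower-order conditionals", {
  # order-2 fit on data with only ~A contexts: unseen contexts inherit the
  # order-0/1 estimate instead of the flat Laplace prior
  set.seed(2)
  s <- paste(sample(c("A", "C"), 500, TRUE, prob = c(0.8, 0.2)),
             collapse = "")
  codes <- transcds:::encodeSeq(s)
  m <- transcds:::fitMarkovChain(list(codes), list(3:500), 2L,
                                 pseudocount = 1, minContextObs = 10L)
  # context "TT" never occurs; its conditional should still lean A-ward
  ttRow <- which(rownames(m@logProb) == "TT")
  expect_gt(exp(m@logProb[ttRow, 1]), 0.5)
})

test_that("training estimates structure frequencies and validates input", {
  corp <- sharedTrainingCorpus()
  bundle <- sharedBundle()
  arch <- bundle@bins[[2]]$full
  expect_equal(arch@transLog["UTR5", "Start"], 0)   # only exit, frequency 1
  # every generated transcript has a non-empty 5'UTR: initial ~ {UTR5: 1}
  expect_gt(exp(arch@initLog[["UTR5"]]), 0.98)
  expect_true(validObject(bundle))
  expect_error(trainBundle(corp[1:10]), "at least 50")
  # transcripts violating the reference invariants are skipped with a warning
  broken <- corp[1:60]
  mc <- S4Vectors::mcols(broken)
  mc$cdsStart[1] <- mc$cdsStart[1] + 1L   # breaks the ATG anchor
  S4Vectors::mcols(broken) <- mc
  expect_warning(trainBundle(broken, trainingConfig(minOverall = 50L)),
                 "skipped")
})

test_that("trained parameters beat uniform parameters on training data", {
  bundle <- sharedBundle()
  corp <- sharedTrainingCorpus()
  unifBundle <- bundle
  for (b in seq_along(unifBundle@bins)) {
    for (mode in c("full", "partial")) {
      arch <- unifBundle@bins[[b]][[mode]]
      for (s in names(arch@states)) {
        st <- arch@states[[s]]
        st@emission <- if (is(st@emission, "PeriodicMarkovModel"))
          uniformPeriodic()
        else if (is(st@emission, "PositionalModel"))
          positionalModel(st@emission@windowStart,
                          matrix(0.25, nrow(st@emission@logProbs), 4))
        else uniformChain()
        arch@states[[s]] <- st
      }
      unifBundle@bins[[b]][[mode]] <- arch
    }
  }
  seqs <- as.character(corp[1:15])
  llTrained <- llUniform <- 0
  for (s in seqs) {
    b <- assignBin(bundle, gcFraction(s))
    llTrained <- llTrained + viterbiDecode(bundle@bins[[b]]$full, s)@logScore
    llUniform <- llUniform +
      viterbiDecode(unifBundle@bins[[b]]$full, s)@logScore
  }
  expect_gt(llTrained, llUniform)
})

test_that("bundles round-trip losslessly through the text format", {
  bundle <- sharedBundle()
  f <- withr::local_tempfile(fileext = ".bundle")
  saveBundle(bundle, f)
  back <- loadBundle(f)
  expect_equal(back@gcBreaks, bundle@gcBreaks)
  expect_equal(back@metadata$binCounts, bundle@metadata$binCounts)
  # decoding a fixed sequence before save and after load is bit-identical
  seq <- as.character(sharedTestCorpus()[[3]])
  b <- assignBin(bundle, gcFraction(seq))
  expect_identical(viterbiDecode(bundle@bins[[b]]$full, seq)@logScore,
                   viterbiDecode(back@bins[[b]]$full, seq)@logScore)
  expect_identical(viterbiDecode(bundle@bins[[b]]$partial, seq)@logScore,
                   viterbiDecode(back@bins[[b]]$partial, seq)@logScore)
})

test_that("corrupted or mismatched bundle files are rejected", {
  bundle <- sharedBundle()
  f <- withr::local_tempfile(fileext = ".bundle")
  saveBundle(bundle, f)
  lines <- readLines(f)
  # tamper with a payload number
  tampered <- sub("\"nTraining\": 200", "\"nTraining\": -200", lines)
  expect_false(identical(tampered, lines))
  writeLines(tampered, f)
  expect_error(loadBundle(f), "checksum")
  # truncated file
  writeLines(lines[1:(length(lines) %/% 2)], f)
  expect_error(loadBundle(f), "checksum|truncated")
  # version mismatch
  hdr <- jsonlite::fromJSON(lines[1])
  lines[1] <- sprintf('{"format": "%s", "version": 99, "md5": "%s"}',
                      hdr$format, hdr$md5)
  writeLines(lines, f)
  expect_error(loadBundle(f), "version")
})
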