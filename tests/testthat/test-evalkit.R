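refRow <- function(id = "t", cs = 10L, ce = 43L, strand = "+",
                   hasStop = TRUE, coding = TRUE)
  list(id = id, cdsStart = cs, cdsEnd = ce, strand = strand,
       hasStop = hasStop, coding = coding)

callRow <- function(id = "t", s = 10L, e = 43L, strand = "+",
                    hasStop = TRUE)
  list(transcriptId = id, start = s, end = e, strand = strand,
       hasStop = hasStop)

test_that("match criteria distinguish stop-codon from whole-CDS agreement", {
  expect_equal(matchCall(refRow(), callRow(), "stop_match"), "TP")
  expect_equal(matchCall(refRow(), callRow(), "full_cds_match"), "TP")
  # correct stop but start 3 nt downstream
  shifted <- callRow(s = 13L)
  expect_equal(matchCall(refRow(), shifted, "stop_match"), "TP")
  expect_equal(matchCall(refRow(), shifted, "full_cds_match"), "FP")
  expect_equal(matchCall(refRow(), NULL, "stop_match"), "FN")
  expect_equal(matchCall(refRow(), NULL, "full_cds_match"), "FN")
  # wrong strand is never a match
  expect_equal(matchCall(refRow(), callRow(strand = "-"), "stop_match"),
               "FP")
  expect_error(matchCall(refRow(id = "a"), callRow(id = "b")), "mismatch")
  # negative-set convention
  expect_equal(matchCall(refRow(), callRow(), "any_call"), "FP")
  expect_equal(matchCall(refRow(), NULL, "any_call"), "TN")
})

test_that("metric formulas match hand arithmetic including degenerate cases", {
  m <- precisionRecallF1(evalOutcome(tp = 8, fp = 2, fn = 0))
  expect_equal(unname(m), c(0.8, 1.0, 2 * 0.8 / 1.8))
  expect_equal(unname(precisionRecallF1(evalOutcome(fn = 5))), c(0, 0, 0))
  # precision == recall implies f1 == precision
  set.seed(8)
  for (i in 1:10) {
    tp <- sample(0:20, 1); k <- sample(0:10, 1)
    m <- precisionRecallF1(evalOutcome(tp = tp, fp = k, fn = k))
    expect_equal(m[["f1"]], m[["precision"]])
  }
})

test_that("both specificity conventions are reported and complementary", {
  s <- specificityAsPrinted(evalOutcome(fp = 5, tn = 95,
                                        criterion = "any_call"))
  expect_equal(unname(s), c(0.05, 0.95))
  s0 <- specificityAsPrinted(evalOutcome(fp = 0, tn = 10,
                                         criterion = "any_call"))
  expect_equal(unname(s0), c(0, 1))
  set.seed(9)
  for (i in 1:10) {
    s <- specificityAsPrinted(evalOutcome(fp = sample(0:50, 1),
                                          tn = sample(1:50, 1),
                                          criterion = "any_call"))
    expect_equal(sum(s), 1)
  }
  expect_error(specificityAsPrinted(evalOutcome()), "empty negative")
})

test_that("confusion tallies agree with per-sequence recounting", {
  bundle <- sharedBundle()
  test <- sharedTestCorpus()[1:20]
  tt <- as.data.frame(truthTable(test))
  calls <- predictTranscripts(bundle, test)
  out <- evaluatePredictions(tt, calls, "stop_match")
  # independent recount straight from the definitions
  dfc <- as.data.frame(calls)
  labs <- vapply(seq_len(nrow(tt)), function(i) {
    cl <- dfc[dfc$transcriptId == tt$id[i], ]
    if (is.na(cl$start)) return("FN")
    if (cl$hasStop && cl$strand == tt$strand[i] &&
        cl$end == tt$cdsEnd[i]) "TP" else "FP"
  }, character(1))
  expect_equal(out@tp, sum(labs == "TP"))
  expect_equal(out@fp, sum(labs == "FP"))
  expect_equal(out@fn, sum(labs == "FN"))
  expect_equal(out@tp + out@fp + out@fn + out@tn, nrow(tt))
})

test_that("test-set constructions honor size floors and provenance", {
  corp <- sharedTestCorpus()
  sets <- buildTestSets(corp, seed = 21L)
  sets2 <- buildTestSets(corp, seed = 21L)
  for (nm in names(sets))
    expect_identical(as.character(sets[[nm]]), as.character(sets2[[nm]]))

  src <- as.character(corp)
  tt <- truthTable(corp)
  for (nm in c("NoStart", "NoStop", "NoStartNoStop")) {
    ds <- sets[[nm]]
    mc <- as.data.frame(truthTable(ds))
    for (i in seq_along(ds)) {
      s <- as.character(ds[[i]])
      orig <- src[[mc$id[i]]]
      # derived sequence is a contiguous substring of its source
      expect_true(grepl(s, orig, fixed = TRUE))
      # minimum resulting size unless the fallback applied
      j <- match(mc$id[i], tt$id)
      full <- nchar(orig)
      if (full >= 170) expect_gte(nchar(s), 150)
    }
    expect_true(all(mc$cdsEnd <= mc$width))
  }

  ns <- sets$NoStart
  mc <- as.data.frame(truthTable(ns))
  for (i in 1:10) {
    # coordinate bookkeeping: the fragment is the CDS suffix; re-derive the
    # truncation offset and check the frame annotation
    j <- match(mc$id[i], tt$id)
    orig <- src[[mc$id[i]]]
    t1 <- (tt$cdsEnd[j] - tt$cdsStart[j]) - (mc$cdsEnd[i] - mc$cdsStart[i])
    expect_gte(t1, 3L)
    expect_equal(mc$frame[i], (3L - (t1 %% 3L)) %% 3L)
    expect_false(mc$hasStart[i])
    expect_true(mc$hasStop[i])
    # fragment still ends with the original stop codon
    expect_equal(substr(as.character(ns[[i]]), mc$cdsEnd[i] - 2L,
                        mc$cdsEnd[i]),
                 substr(orig, tt$cdsEnd[j] - 2L, tt$cdsEnd[j]))
  }

  # strand-blind: flipped records are exact reverse complements
  sb <- sets$FullStrandBlind
  mcsb <- as.data.frame(truthTable(sb))
  flipped <- which(mcsb$strand == "-")
  expect_equal(length(flipped), length(corp) %/% 2L)
  for (i in head(flipped, 5))
    expect_equal(as.character(sb[[i]]), revComp(src[[mcsb$id[i]]]))

  # UTR3 negatives are the complete 3'UTRs, labeled non-coding
  u3 <- sets$UTR3Negatives
  expect_true(all(!S4Vectors::mcols(u3)$coding))
})

test_that("mixed runs filter short negatives and shuffle deterministically", {
  corp <- sharedTestCorpus()
  sets <- buildTestSets(corp, seed = 3L)
  negs <- transcriptSet(
    c(n1 = strrep("ACGT", 60), n2 = strrep("AC", 50), n3 = strrep("GT", 120)),
    coding = FALSE)
  expect_warning(
    mixed <- buildMixedNegativeSet(sets$FullStrandSpecific, sets$NoStart,
                                   negs, seed = 4L, nFull = 30L,
                                   nPartial = 30L),
    NA)
  # n2 (100 nt) dropped by the >= 200 nt rule
  expect_equal(sum(grepl("^negative:", names(mixed))), 2L)
  expect_equal(length(mixed), 62L)
  tt <- truthTable(mixed)
  expect_equal(sum(transcds:::isTRUE2(tt$coding)), 60L)
  mixed2 <- buildMixedNegativeSet(sets$FullStrandSpecific, sets$NoStart,
                                  negs, seed = 4L, nFull = 30L,
                                  nPartial = 30L)
  expect_identical(names(mixed), names(mixed2))
})
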