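singleGeomArch <- function(q = log(0.8)) {
  st <- ghmmState("UTR", uniformChain(), "geometric", selfLoopLogP = q)
  ghmmArchitecture(list(st), matrix(-Inf, 1, 1), 0, 0)
}

test_that("a single geometric state covers any sequence in one segment", {
  arch <- singleGeomArch()
  for (s in c("A", "ACGT", randomSeq(37))) {
    p <- viterbiDecode(arch, s)
    expect_equal(nrow(p@segments), 1L)
    expect_equal(p@segments$from, 0L)
    expect_equal(p@segments$to, nchar(s))
    expect_equal(p@logScore,
                 nchar(s) * log(0.25) + (nchar(s) - 1) * log(0.8))
  }
})

test_that("impossible segmentations yield no path, not an exception", {
  # only a fixed length-3 state, but a 4 nt sequence
  st <- ghmmState("Start", forcingPositional(0, c("A", "T", "G")), "fixed",
                  fixedLen = 3L, requiredCodons = "ATG")
  arch <- ghmmArchitecture(list(st), matrix(-Inf, 1, 1), 0, 0)
  expect_null(viterbiDecode(arch, "ATGC"))
  expect_s4_class(viterbiDecode(arch, "ATG"), "StatePath")
  expect_null(viterbiDecode(arch, "CTG"))   # hard codon constraint
})

test_that("decoder agrees with exhaustive enumeration on toy architectures", {
  set.seed(41)
  nOK <- 0L
  for (rep in 1:30) {
    arch <- randomToyArchitecture()
    s <- randomSeq(sample(4:10, 1))
    ora <- oracleBestPath(arch, s)
    dec <- viterbiDecode(arch, s)
    if (is.null(ora)) {
      expect_null(dec)
    } else {
      expect_false(is.null(dec))
      expect_equal(dec@logScore, ora$logScore, tolerance = 1e-9)
      # the decoder's path must itself be admissible at the optimal score
      rescored <- oracleScorePath(arch, s, dec@segments)
      expect_equal(rescored, ora$logScore, tolerance = 1e-9)
      nOK <- nOK + 1L
    }
  }
  expect_gt(nOK, 5L)   # enough non-degenerate cases exercised
})

test_that("decoded score dominates random admissible paths", {
  set.seed(17)
  bundle <- sharedBundle()
  arch <- bundle@bins[[2]]$full
  seq <- as.character(sharedTestCorpus()[[1]])
  dec <- viterbiDecode(arch, seq)
  L <- nchar(seq)
  tt <- truthTable(sharedTestCorpus())
  a <- tt$cdsStart[1]; b <- tt$cdsEnd[1]
  # hand-constructed admissible paths: the truth path and jittered variants
  mkPath <- function(s, e) data.frame(
    state = c("UTR5", "Start", "fullCDS", "Stop", "UTR3"),
    from = c(0L, s, s + 3L, e - 3L, e),
    to = c(s, s + 3L, e - 3L, e, L))
  cand <- list(mkPath(a, b))
  for (sh in c(-9L, -3L, 3L, 9L))
    if (a + sh > 0) cand <- c(cand, list(mkPath(a + sh, b)))
  for (p in cand)
    expect_gte(dec@logScore + 1e-9, oracleScorePath(arch, seq, p))
  expect_equal(dec@logScore, oracleScorePath(arch, seq, mkPath(a, b)),
               tolerance = 1e-9)   # truth path is optimal at high signal
})

test_that("CDS calls are extracted with correct flags and frames", {
  mk <- function(states, bounds) {
    new("StatePath",
        segments = data.frame(state = states,
                              from = head(bounds, -1), to = bounds[-1]),
        logScore = -1)
  }
  p1 <- mk(c("UTR5", "Start", "fullCDS", "Stop", "UTR3"),
           c(0L, 10L, 13L, 40L, 43L, 60L))
  c1 <- extractCdsCall(p1, 60L)
  expect_equal(c1[c("start", "end", "hasStart", "hasStop", "frame")],
               list(start = 10L, end = 43L, hasStart = TRUE,
                    hasStop = TRUE, frame = 0L))
  p2 <- mk(c("pCDS2", "Stop", "UTR3"), c(0L, 20L, 23L, 50L))
  c2 <- extractCdsCall(p2, 50L)
  expect_equal(c2[c("start", "end", "hasStart", "hasStop", "frame")],
               list(start = 0L, end = 23L, hasStart = FALSE,
                    hasStop = TRUE, frame = 2L))
  p3 <- mk("UTR", c(0L, 200L))
  expect_null(extractCdsCall(p3, 200L))
})

test_that("high-signal decoding recovers generator ground truth", {
  bundle <- sharedBundle()
  test <- sharedTestCorpus()[1:15]
  tt <- truthTable(test)
  for (i in seq_along(test)) {
    seq <- as.character(test[[i]])
    arch <- bundle@bins[[assignBin(bundle, gcFraction(seq))]]$full
    p <- viterbiDecode(arch, seq)
    call <- extractCdsCall(p, nchar(seq))
    expect_equal(call$start, tt$cdsStart[i])
    expect_equal(call$end, tt$cdsEnd[i])
  }
})

test_that("paths never contain two disjoint coding segments", {
  bundle <- sharedBundle()
  coding <- c("Start", "fullCDS", "pCDS0", "pCDS1", "pCDS2", "Stop")
  for (i in 1:10) {
    seq <- as.character(sharedTestCorpus()[[i]])
    for (mode in c("full", "partial")) {
      arch <- bundle@bins[[assignBin(bundle, gcFraction(seq))]][[mode]]
      p <- viterbiDecode(arch, seq)
      idx <- which(p@segments$state %in% coding)
      if (length(idx) > 1) expect_true(all(diff(idx) == 1L))
    }
  }
})
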