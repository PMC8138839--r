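test_that("chain scoring matches hand-computed conditionals", {
  u <- uniformChain()
  expect_equal(scoreChain(u, "ACGT", 0, 4), 4 * log(0.25))
  expect_equal(scoreChain(u, "ACGT", 2, 2), 0)   # empty product
  expect_error(scoreChain(u, "ACGT", 0, 5), "out of range")

  # order-1 chain trained on an all-A corpus: P(A | A) ~ 1 without smoothing
  codes <- transcds:::encodeSeq("AAAAAAAAAA")
  m <- transcds:::fitMarkovChain(list(codes), list(2:10), order = 1L,
                                 pseudocount = 1e-12, minContextObs = 0L)
  expect_equal(scoreChain(m, "AAAA", 1, 4), 0, tolerance = 1e-9)
})

test_that("chain scores are additive over interval splits", {
  set.seed(7)
  for (i in 1:10) {
    m <- randomChain(sample(0:2, 1))
    s <- randomSeq(30)
    a <- sample(0:10, 1); b <- a + sample(0:10, 1); c <- b + sample(0:9, 1)
    expect_equal(scoreChain(m, s, a, c),
                 scoreChain(m, s, a, b) + scoreChain(m, s, b, c),
                 tolerance = 1e-12)
  }
})

test_that("N bases and missing contexts marginalize instead of failing", {
  m <- randomChain(2L)
  expect_equal(scoreChain(m, "NNNN", 0, 4), 0)
  s <- "ACGNTA"
  expect_true(is.finite(scoreChain(m, s, 0, 6)))
  # first bases (no full context) use the uniform-context marginal
  expect_equal(scoreChain(m, "AC", 0, 1), m@logMarg0[[1]])
})

test_that("periodic scoring threads phases and degenerates to a chain", {
  ch <- randomChain(0L)
  per <- periodicMarkovModel(ch, ch, ch)
  s <- randomSeq(20)
  expect_equal(scorePeriodic(per, s, 2, 17, 1), scoreChain(ch, s, 2, 17))

  p0 <- compChain(c(0.7, 0.1, 0.1, 0.1))
  p1 <- compChain(c(0.1, 0.7, 0.1, 0.1))
  p2 <- compChain(c(0.1, 0.1, 0.7, 0.1))
  per <- periodicMarkovModel(p0, p1, p2)
  s <- "ACGACG"
  # phase 0 at position 0: A|p0, C|p1, G|p2 ... all consensus
  expect_equal(scorePeriodic(per, s, 0, 6, 0), 6 * log(0.7))
  # phase_at_from = 1 shifts every position's model by one
  expect_equal(scorePeriodic(per, s, 0, 6, 1), 6 * log(0.1))
})

test_that("codon-biased periodic model prefers in-frame over shifted reading", {
  usage <- codonUsageTable("strong")
  # order-0 phase compositions implied by the usage table
  phaseComp <- function(pos) {
    p <- numeric(4); names(p) <- c("A", "C", "G", "T")
    for (cod in names(usage)) {
      b <- substr(cod, pos, pos)
      p[b] <- p[b] + usage[[cod]]
    }
    compChain(p)
  }
  per <- periodicMarkovModel(phaseComp(1), phaseComp(2), phaseComp(3))
  run <- withSeed2(991L, paste(
    sample(names(usage), 1000, replace = TRUE, prob = usage),
    collapse = ""))
  inframe <- scorePeriodic(per, run, 0, 3000, 0)
  shifted <- scorePeriodic(per, run, 0, 3000, 1)
  expect_gt(inframe, shifted)
})

test_that("positional windows honor hard constraints and sequence edges", {
  atg <- forcingPositional(0L, c("A", "T", "G"))
  expect_equal(scorePositional(atg, "CCATGCC", 2), 0)
  expect_equal(scorePositional(atg, "CCATCCC", 2), -Inf)
  # anchor at offset 0 with upstream columns skips the absent columns
  up <- forcingPositional(-6L, c("G", "G", "G", "G", "G", "G"))
  expect_equal(scorePositional(up, "ATGAAA", 0), 0)
  unif <- positionalModel(0L, matrix(0.25, nrow = 5, ncol = 4))
  expect_equal(scorePositional(unif, "ACGTACGT", 1), 5 * log(0.25))
})

test_that("duration models score, normalize and extrapolate correctly", {
  pm <- pointDuration(300L)
  expect_equal(durationLogP(pm, 300L), 0)
  expect_equal(durationLogP(pm, 299L), -Inf)
  expect_equal(durationLogP(pm, 301L), -Inf)

  d <- durationModel(2L, 4L, log(c(0.3, 0.3, 0.2)),
                     tailLogMass = log(0.2), tailLogP = log(0.5))
  # total mass: body + geometric tail sums to 1
  tot <- sum(exp(durationLogP(d, 1:200)))
  expect_equal(tot, 1, tolerance = 1e-9)
  # survival at minLen is 1 and decreases
  expect_equal(durationLogSurvival(d, 1L), 0)
  sv <- durationLogSurvival(d, 1:50)
  expect_true(all(diff(sv) <= 1e-12))
  expect_equal(durationMean(d),
               sum((1:500) * exp(durationLogP(d, 1:500))),
               tolerance = 1e-6)
})

test_that("duration fitting recovers location and degenerates to point mass", {
  f <- fitDuration(c(300, 300, 600), bandwidth = 20)
  expect_gt(durationLogP(f, 300L), durationLogP(f, 600L))
  expect_true(validObject(f))

  nearPoint <- fitDuration(rep(120L, 50), bandwidth = 1e-6)
  expect_gt(exp(durationLogP(nearPoint, 120L)), 0.9)

  set.seed(12)
  x <- round(stats::rlnorm(1000, log(400), 0.4))
  fx <- fitDuration(x)
  expect_lt(abs(durationMean(fx) - mean(x)) / mean(x), 0.1)
  expect_error(fitDuration(300L), "at least 2")
})

test_that("maximum-likelihood chain maximizes its own training likelihood", {
  # toy corpus; compare the fitted order-1 chain against perturbed tables
  set.seed(3)
  s <- randomSeq(400, probs = c(0.4, 0.3, 0.2, 0.1))
  codes <- transcds:::encodeSeq(s)
  fit <- transcds:::fitMarkovChain(list(codes), list(2:400), 1L,
                                   pseudocount = 1e-9, minContextObs = 0L)
  ll <- scoreChain(fit, s, 1, 400)
  for (i in 1:10) {
    p <- exp(fit@logProb) + matrix(stats::runif(16, 0, 0.2), 4)
    p <- p / rowSums(p)
    other <- markovChainModel(1L, log(p))
    expect_gte(ll, scoreChain(other, s, 1, 400))
  }
})
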