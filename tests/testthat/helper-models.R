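# Shared toy models and memoized expensive fixtures.  Everything is built
# in code; nothing is read from disk.

uniformChain <- function(order = 0L) {
  markovChainModel(order, matrix(log(0.25), nrow = 4L^order, ncol = 4L))
}

# order-0 chain with the given base probabilities (A,C,G,T)
compChain <- function(p) {
  markovChainModel(0L, matrix(log(p / sum(p)), nrow = 1L))
}

uniformPeriodic <- function(order = 0L) {
  periodicMarkovModel(uniformChain(order), uniformChain(order),
                      uniformChain(order))
}

# point-mass duration at len
pointDuration <- function(len, step = 1L) {
  durationModel(len, len, 0, tailLogMass = -Inf, tailLogP = -Inf,
                step = step)
}

# uniform duration over lens (a contiguous lattice)
uniformDuration <- function(minLen, maxLen, step = 1L) {
  nb <- (maxLen - minLen) %/% step + 1L
  durationModel(minLen, maxLen, rep(log(1 / nb), nb), step = step)
}

# positional model forcing the given bases with probability 1
forcingPositional <- function(windowStart, bases) {
  probs <- matrix(0, nrow = length(bases), ncol = 4)
  probs[cbind(seq_along(bases), match(bases, c("A", "C", "G", "T")))] <- 1
  positionalModel(windowStart, probs)
}

withSeed2 <- function(seed, expr) transcds:::withSeed(seed, expr)

# memoized strong-signal corpus + bundle shared by the heavier tests
.fixtures <- new.env(parent = emptyenv())

sharedTrainingCorpus <- function() {
  if (is.null(.fixtures$corpus))
    .fixtures$corpus <- generateCorpus(generatorConfig(seed = 301L, n = 200L))
  .fixtures$corpus
}

sharedBundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- trainBundle(sharedTrainingCorpus())
  .fixtures$bundle
}

sharedTestCorpus <- function() {
  if (is.null(.fixtures$test))
    .fixtures$test <- generateCorpus(generatorConfig(seed = 302L, n = 60L))
  .fixtures$test
}
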