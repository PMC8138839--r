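# Independent decoding oracle: exhaustive enumeration over every admissible
# labeled segmentation of a sequence, scored directly from the model
# definitions (per-position emission sums, duration pmf/survival, transition
# and initial/final terms).  Shares no code with the dynamic-programming
# decoder beyond the emission/duration primitives it checks against.

# per-state emission scorer over a segment [from, to), 0-based half-open
oracleSegmentScorers <- function(arch, seq) {
  codes <- transcds:::encodeSeq(seq)
  L <- length(codes)
  stops0 <- transcds:::stopCodonStarts(seq)
  lapply(arch@states, function(st) {
    em <- st@emission
    if (is(em, "PositionalModel") || st@durationKind == "fixed") {
      force(st)
      return(function(from, to) {
        if (to - from != st@fixedLen) return(-Inf)
        if (length(st@requiredCodons) > 0L) {
          cod <- substr(seq, from + 1L, from + 3L)
          if (!cod %in% st@requiredCodons) return(-Inf)
        }
        base <- if (is(em, "PositionalModel"))
          transcds:::positionalLogProb(em, codes, from)
        else sum(transcds:::emissionLogProb(em, codes)[(from + 1L):to])
        # out-of-segment window columns replace the flanking content models
        if (is(em, "PositionalModel") &&
            (!is.null(st@flankUp) || !is.null(st@flankDown))) {
          offs <- em@windowStart + seq_len(nrow(em@logProbs)) - 1L
          for (cc in offs) {
            pos <- from + cc
            if (pos < 0L || pos >= L) next
            fl <- if (cc < 0L) st@flankUp
                  else if (cc >= st@fixedLen) st@flankDown
                  else NULL
            if (is.null(fl)) next
            v <- if (is(fl, "PeriodicMarkovModel")) {
              ph <- (cc - st@fixedLen) %% 3L
              transcds:::emissionLogProb(fl@phases[[ph + 1L]],
                                         codes)[pos + 1L]
            } else transcds:::emissionLogProb(fl, codes)[pos + 1L]
            if (is.finite(v)) base <- base - v
          }
        }
        base
      })
    }
    if (is(em, "PeriodicMarkovModel")) {
      M <- vapply(em@phases, transcds:::emissionLogProb,
                  numeric(L), codes = codes)
      if (is.null(dim(M))) M <- matrix(M, nrow = 1L)
      function(from, to) {
        tot <- 0
        for (j in from:(to - 1L)) {
          ph <- (st@inPhase + j - from) %% 3L
          if (st@noInternalStops && ph == 0L && (j %in% stops0))
            return(-Inf)
          tot <- tot + M[j + 1L, ph + 1L]
        }
        tot
      }
    } else {
      v <- transcds:::emissionLogProb(em, codes)
      function(from, to) {
        if (st@noInternalStops) {
          for (j in from:(to - 1L)) {
            ph <- (st@inPhase + j - from) %% 3L
            if (ph == 0L && (j %in% stops0)) return(-Inf)
          }
        }
        sum(v[(from + 1L):to])
      }
    }
  })
}

oracleDurationScore <- function(st, d, isFinal) {
  switch(st@durationKind,
    geometric = (d - 1) * st@selfLoopLogP,
    fixed = if (d == st@fixedLen) 0 else -Inf,
    explicit = {
      if (isFinal) durationLogSurvival(st@duration, d)
      else if (!is.na(st@congruence) && d %% 3L != st@congruence) -Inf
      else durationLogP(st@duration, d)
    })
}

oracleExitTerm <- function(st) {
  if (st@durationKind == "geometric")
    transcds:::log1mexp(st@selfLoopLogP)
  else 0
}

# score one complete labeled segmentation; segs = data.frame(state, from, to)
oracleScorePath <- function(arch, seq, segs, scorers = NULL) {
  if (is.null(scorers)) scorers <- oracleSegmentScorers(arch, seq)
  nms <- names(arch@states)
  m <- nrow(segs)
  s1 <- segs$state[1]
  tot <- arch@initLog[[s1]]
  for (i in seq_len(m)) {
    st <- arch@states[[segs$state[i]]]
    tot <- tot + scorers[[segs$state[i]]](segs$from[i], segs$to[i]) +
      oracleDurationScore(st, segs$to[i] - segs$from[i], i == m)
    if (i < m)
      tot <- tot + oracleExitTerm(st) +
        arch@transLog[segs$state[i], segs$state[i + 1L]]
    if (!is.finite(tot)) return(-Inf)
  }
  tot + arch@finalLog[[segs$state[m]]]
}

# exhaustive enumeration of the best path; returns NULL when no admissible
# path exists, else list(segments, logScore, nPaths).  Branches are pruned
# only when they become impossible (-Inf), never by score comparison, so
# every admissible segmentation is visited.
oracleBestPath <- function(arch, seq) {
  L <- nchar(seq)
  nms <- names(arch@states)
  scorers <- oracleSegmentScorers(arch, seq)
  best <- list(score = -Inf, segs = NULL)
  npaths <- 0L
  recurse <- function(segs, t, last, acc) {
    for (s2 in nms) {
      entry <- acc + (if (is.null(last)) arch@initLog[[s2]]
                      else arch@transLog[last, s2])
      if (!is.finite(entry)) next
      st <- arch@states[[s2]]
      for (d in seq_len(L - t)) {
        emis <- scorers[[s2]](t, t + d)
        if (!is.finite(emis)) next
        newSegs <- c(segs, list(list(state = s2, from = t, to = t + d)))
        if (t + d == L) {
          tot <- entry + emis + oracleDurationScore(st, d, TRUE) +
            arch@finalLog[[s2]]
          if (is.finite(tot)) {
            npaths <<- npaths + 1L
            if (tot > best$score) best <<- list(score = tot, segs = newSegs)
          }
        } else {
          mid <- entry + emis + oracleDurationScore(st, d, FALSE) +
            oracleExitTerm(st)
          if (is.finite(mid)) recurse(newSegs, t + d, s2, mid)
        }
      }
    }
  }
  recurse(list(), 0L, NULL, 0)
  if (!is.finite(best$score)) return(NULL)
  segs <- do.call(rbind, lapply(best$segs, function(x)
    data.frame(state = x$state, from = x$from, to = x$to,
               stringsAsFactors = FALSE)))
  list(segments = segs, logScore = best$score, nPaths = npaths)
}

# random nucleotide string
randomSeq <- function(L, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = probs),
        collapse = "")
}

randomChain <- function(order = 0L) {
  k <- 4L^order
  p <- matrix(stats::rgamma(k * 4, 1) + 0.05, nrow = k)
  p <- p / rowSums(p)
  markovChainModel(order, log(p))
}

randomDuration <- function() {
  minLen <- sample(1:3, 1)
  maxLen <- minLen + sample(0:3, 1)
  nb <- maxLen - minLen + 1L
  w <- stats::rgamma(nb, 1) + 0.05
  if (stats::runif(1) < 0.5) {
    durationModel(minLen, maxLen, log(w / sum(w)))
  } else {
    tailMass <- stats::runif(1, 0.05, 0.3)
    durationModel(minLen, maxLen, log(w / sum(w) * (1 - tailMass)),
                  tailLogMass = log(tailMass),
                  tailLogP = log(stats::runif(1, 0.1, 0.5)))
  }
}

# random toy architecture with <= 3 states and bounded branching, so that
# exhaustive enumeration stays tractable
randomToyArchitecture <- function(maxStates = 3L) {
  S <- sample(seq_len(maxStates), 1)
  states <- vector("list", S)
  for (i in seq_len(S)) {
    kind <- sample(c("geometric", "explicit", "fixed"), 1,
                   prob = c(0.4, 0.4, 0.2))
    nm <- paste0("S", i)
    emission <- if (stats::runif(1) < 0.3)
      periodicMarkovModel(randomChain(0L), randomChain(0L), randomChain(0L))
    else randomChain(sample(0:1, 1))
    inPhase <- sample(0:2, 1)
    states[[i]] <- switch(kind,
      geometric = ghmmState(nm, if (is(emission, "PeriodicMarkovModel"))
                              randomChain(0L) else emission,
                            "geometric",
                            selfLoopLogP = log(stats::runif(1, 0.2, 0.9))),
      explicit = ghmmState(nm, emission, "explicit",
                           duration = randomDuration(), inPhase = inPhase,
                           congruence = if (stats::runif(1) < 0.25)
                             sample(0:2, 1) else NA_integer_,
                           noInternalStops = stats::runif(1) < 0.3),
      fixed = ghmmState(nm, if (is(emission, "PeriodicMarkovModel"))
                              randomChain(0L) else emission,
                        "fixed",
                        fixedLen = sample(2:3, 1), inPhase = inPhase,
                        requiredCodons = character()))
  }
  tr <- matrix(-Inf, S, S)
  for (i in seq_len(S)) {
    targets <- sample(seq_len(S), sample(0:min(2, S), 1))
    if (length(targets) > 0) {
      w <- stats::runif(length(targets), 0.1, 1)
      tr[i, targets] <- log(w / sum(w) * stats::runif(1, 0.5, 1))
    }
  }
  nInit <- sample(seq_len(S), 1)
  ini <- rep(-Inf, S)
  w <- stats::runif(nInit, 0.1, 1)
  ini[sample(seq_len(S), nInit)] <- log(w / sum(w))
  fin <- ifelse(stats::runif(S) < 0.7, 0, -Inf)
  if (all(!is.finite(fin))) fin[sample(seq_len(S), 1)] <- 0
  ghmmArchitecture(states, tr, ini, fin)
}
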