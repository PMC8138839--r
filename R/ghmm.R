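# GHMM architectures over transcripts and the explicit-duration Viterbi
# decoder.  The decoder itself is a generic semi-Markov DP (src/viterbi.cpp);
# this file prepares per-sequence emission/duration tables and builds the
# two transcript architectures (full, partial).

BIG_NEG <- -1e30
NEG_TH <- -1e25
CODING_STATES <- c("Start", "fullCDS", "pCDS0", "pCDS1", "pCDS2", "Stop")

#' Construct a GHMM state
#'
#' @param name state name.
#' @param emission emission model (MarkovChainModel, PeriodicMarkovModel or
#'   PositionalModel for fixed states).
#' @param durationKind "geometric", "explicit" or "fixed".
#' @param fixedLen segment length for fixed states.
#' @param duration [DurationModel-class] for explicit states.
#' @param selfLoopLogP log self-transition probability (geometric states).
#' @param inPhase codon phase of a segment's first base (periodic scoring).
#' @param congruence internal-segment length constraint `len %% 3` (NA: none).
#' @param requiredCodons hard constraint on the first codon of fixed states.
#' @param noInternalStops forbid in-frame stop codons inside segments.
#' @param flankUp,flankDown flanking content models replaced by
#'   out-of-segment window columns of fixed signal states (see
#'   [GhmmState-class]).
#' @return a [GhmmState-class].
#' @export
ghmmState <- function(name, emission, durationKind,
                      fixedLen = NA_integer_, duration = NULL,
                      selfLoopLogP = NA_real_, inPhase = 0L,
                      congruence = NA_integer_, requiredCodons = character(),
                      noInternalStops = FALSE, flankUp = NULL,
                      flankDown = NULL) {
  new("GhmmState", name = name, emission = emission,
      durationKind = durationKind, fixedLen = as.integer(fixedLen),
      duration = duration, selfLoopLogP = as.numeric(selfLoopLogP),
      inPhase = as.integer(inPhase), congruence = as.integer(congruence),
      requiredCodons = requiredCodons,
      noInternalStops = isTRUE(noInternalStops),
      flankUp = flankUp, flankDown = flankDown)
}

#' Construct a GHMM architecture
#'
#' @param states list of [GhmmState-class] objects.
#' @param transLog S x S log transition matrix (rows = from state); default
#'   all `-Inf`.
#' @param initLog,finalLog per-state initial log probabilities (must sum to
#'   one) and final log weights (`-Inf` = not final).
#' @return a [GhmmArchitecture-class].
#' @export
ghmmArchitecture <- function(states, transLog, initLog, finalLog) {
  nms <- vapply(states, function(s) s@name, character(1))
  names(states) <- nms
  dimnames(transLog) <- list(nms, nms)
  names(initLog) <- nms
  names(finalLog) <- nms
  new("GhmmArchitecture", states = states, transLog = transLog,
      initLog = initLog, finalLog = finalLog)
}

stateNames <- function(arch) names(arch@states)

# ---- per-sequence decoding tables ------------------------------------------

# 3 x L matrix of per-position emission log-probs by codon phase.  Positions
# with -Inf emission are reported separately (mask matrix) so cumulative
# sums stay finite and exact: a segment containing a masked position is
# inadmissible, all other segment scores are plain finite differences.
phaseEmissionMatrix <- function(emission, codes) {
  L <- length(codes)
  if (is(emission, "PeriodicMarkovModel")) {
    M <- t(vapply(emission@phases, emissionLogProb, numeric(L), codes = codes))
  } else {
    v <- emissionLogProb(emission, codes)
    M <- rbind(v, v, v)
  }
  if (L == 1L) M <- matrix(M, nrow = 3L)
  M
}

# positions (0-based) of stop codons fully inside the sequence
stopCodonStarts <- function(seq) {
  L <- nchar(seq)
  if (L < 3L) return(integer(0))
  cod <- substring(seq, seq_len(L - 2L), 3:L)
  which(cod %in% STOP_CODONS) - 1L
}

decodePrep <- function(arch, seq) {
  codes <- encodeSeq(seq)
  L <- length(codes)
  S <- length(arch@states)
  stops0 <- stopCodonStarts(seq)
  cumL <- vector("list", S)
  maskL <- vector("list", S)
  anchorL <- vector("list", S)
  dlogL <- vector("list", S)
  survL <- vector("list", S)
  kind <- integer(S); fixedLen <- integer(S)
  selfQ <- numeric(S); exitQ <- numeric(S)
  congR <- integer(S); inPh <- integer(S)
  emisCache <- list()
  for (si in seq_len(S)) {
    st <- arch@states[[si]]
    key <- paste0(class(st@emission), "@",
                  format(data_address(st@emission)))
    M <- emisCache[[key]]
    if (is.null(M) && !is(st@emission, "PositionalModel")) {
      M <- phaseEmissionMatrix(st@emission, codes)
      emisCache[[key]] <- M
    }
    if (isTRUE(st@noInternalStops) && length(stops0) > 0L)
      M[1L, stops0 + 1L] <- -Inf   # phase-0 base opening a stop codon
    kind[si] <- switch(st@durationKind, geometric = 0L, explicit = 1L,
                       fixed = 2L)
    inPh[si] <- st@inPhase
    congR[si] <- if (is.na(st@congruence)) -1L else st@congruence
    fixedLen[si] <- if (is.na(st@fixedLen)) 0L else st@fixedLen
    selfQ[si] <- if (kind[si] == 0L) st@selfLoopLogP else 0
    exitQ[si] <- if (kind[si] == 0L) log1mexp(st@selfLoopLogP) else 0
    if (kind[si] == 2L) {
      cumL[[si]] <- matrix(0, nrow = L + 1L, ncol = 3L)
      maskL[[si]] <- matrix(0, nrow = L + 1L, ncol = 3L)
      anchorL[[si]] <- fixedAnchorScores(st, seq, codes)
    } else {
      # -Inf emissions (impossible positions) go into a separate cumulative
      # mask count so finite segment scores stay exact
      bad <- !is.finite(M)
      Mf <- M
      Mf[bad] <- 0
      storage.mode(bad) <- "double"
      cumL[[si]] <- phaseCumsum(Mf, L)
      maskL[[si]] <- phaseCumsum(bad, L)
      anchorL[[si]] <- numeric(0)
    }
    if (kind[si] == 1L) {
      dm <- st@duration
      horizon <- dm@maxLen
      if (is.finite(dm@tailLogMass))
        horizon <- horizon +
          as.integer(ceiling(10 * dm@step / (1 - exp(dm@tailLogP))))
      horizon <- min(horizon, L)
      dlogL[[si]] <- if (horizon >= 1L) durationLogP(dm, seq_len(horizon))
                     else numeric(0)
      survL[[si]] <- durationLogSurvival(dm, seq_len(L))
    } else {
      dlogL[[si]] <- numeric(0)
      survL[[si]] <- numeric(0)
    }
  }
  list(L = L, kind = kind, cum = cumL, mask = maskL, anchor = anchorL,
       fixedLen = fixedLen, selfQ = selfQ, exitQ = exitQ, dlog = dlogL,
       surv = survL, congR = congR, inPhase = inPh)
}

# identity key helper (environment-free): serialize-free address surrogate
data_address <- function(x) {
  # model objects are immutable within a decode call; a content hash over
  # the few numeric slots is cheap and collision-safe enough here
  if (is(x, "PeriodicMarkovModel"))
    return(sum(vapply(x@phases, function(p) sum(p@logProb), numeric(1))))
  if (is(x, "MarkovChainModel")) return(sum(x@logProb) + x@order)
  if (is(x, "PositionalModel")) return(sum(pmax(x@logProbs, -1e6)))
  0
}

phaseCumsum <- function(M, L) {
  C <- matrix(0, nrow = L + 1L, ncol = 3L)
  if (L == 0L) return(C)
  for (r in 0:2) {
    rows <- ((r + 0:(L - 1L)) %% 3L) + 1L
    C[, r + 1L] <- c(0, cumsum(M[cbind(rows, seq_len(L))]))
  }
  C
}

fixedAnchorScores <- function(st, seq, codes) {
  L <- length(codes)
  d <- st@fixedLen
  if (L < d) return(numeric(0))
  nA <- L - d + 1L
  A <- numeric(nA)
  if (is(st@emission, "PositionalModel")) {
    for (u in seq_len(nA))
      A[u] <- positionalLogProb(st@emission, codes, u - 1L)
  } else {
    v <- emissionLogProb(st@emission, codes)
    bad <- !is.finite(v)
    vf <- v
    vf[bad] <- 0
    cs <- c(0, cumsum(vf))
    cnt <- c(0, cumsum(bad))
    A <- cs[(d + 1L):(L + 1L)] - cs[seq_len(nA)]
    A[cnt[(d + 1L):(L + 1L)] - cnt[seq_len(nA)] > 0] <- -Inf
  }
  if (length(st@requiredCodons) > 0L) {
    cod <- substring(seq, seq_len(nA), seq_len(nA) + d - 1L)
    A[!cod %in% st@requiredCodons] <- -Inf
  }
  A - flankCorrection(st, codes, nA)
}

# total flank-model log-probability under the out-of-segment columns of a
# fixed state's positional window, per anchor position (0-based anchor
# u = array index - 1).  Subtracting it makes the window a replacement for
# the flanking content models rather than a second emission of those bases.
flankCorrection <- function(st, codes, nA) {
  corr <- numeric(nA)
  if (!is(st@emission, "PositionalModel")) return(corr)
  if (is.null(st@flankUp) && is.null(st@flankDown)) return(corr)
  L <- length(codes)
  d <- st@fixedLen
  offs <- st@emission@windowStart +
    seq_len(nrow(st@emission@logProbs)) - 1L
  addCols <- function(model, cols) {
    if (length(cols) == 0L || is.null(model)) return()
    if (is(model, "PeriodicMarkovModel")) {
      M <- phaseEmissionMatrix(model, codes)
      for (cc in cols) {
        pos <- seq_len(nA) - 1L + cc
        ok <- pos >= 0L & pos < L
        ph <- (cc - d) %% 3L
        v <- M[ph + 1L, pos[ok] + 1L]
        v[!is.finite(v)] <- 0
        corr[ok] <<- corr[ok] + v
      }
    } else {
      vv <- emissionLogProb(model, codes)
      for (cc in cols) {
        pos <- seq_len(nA) - 1L + cc
        ok <- pos >= 0L & pos < L
        v <- vv[pos[ok] + 1L]
        v[!is.finite(v)] <- 0
        corr[ok] <<- corr[ok] + v
      }
    }
  }
  addCols(st@flankUp, offs[offs < 0L])
  addCols(st@flankDown, offs[offs >= d])
  corr
}

# ---- decoding ---------------------------------------------------------------

#' Decode a sequence with an explicit-duration Viterbi algorithm
#'
#' Computes the maximum-probability state path under the architecture: joint
#' log score = initial + segment emissions (with codon phases threaded
#' through coding segments) + explicit/fixed/geometric duration terms +
#' transitions + final-state weight.  Final segments of explicit-duration
#' states are scored with the duration survival function (right-censored).
#'
#' @param arch a [GhmmArchitecture-class].
#' @param seq nucleotide string (length >= 1).
#' @return a [StatePath-class], or `NULL` when no admissible path exists.
#' @export
viterbiDecode <- function(arch, seq) {
  if (nchar(seq) < 1L) stop("sequence must be non-empty")
  prep <- decodePrep(arch, seq)
  res <- viterbi_ghmm_cpp(prep$L, prep$kind, prep$cum, prep$mask,
                          prep$anchor, prep$fixedLen, prep$selfQ,
                          prep$exitQ, prep$dlog, prep$surv, prep$congR,
                          prep$inPhase, arch@transLog,
                          unname(arch@initLog), unname(arch@finalLog))
  if (!is.finite(res$score) || res$score < NEG_TH) return(NULL)
  nms <- stateNames(arch)
  segs <- data.frame(state = nms[res$state + 1L], from = res$from,
                     to = res$to, stringsAsFactors = FALSE)
  new("StatePath", segments = segs, logScore = res$score)
}

#' Best non-coding path score
#'
#' Log score of the best admissible path that visits no coding state.  In
#' both transcript architectures the only such paths are single UTR-state
#' segments spanning the whole sequence, so the score has a closed form.
#'
#' @param arch a [GhmmArchitecture-class].
#' @param seq nucleotide string.
#' @return log score (`-Inf` when the architecture admits no such path).
#' @export
noncodingScore <- function(arch, seq) {
  codes <- encodeSeq(seq)
  L <- length(codes)
  best <- -Inf
  for (st in arch@states) {
    if (st@name %in% CODING_STATES) next
    if (st@durationKind != "geometric") next
    nm <- st@name
    if (!is.finite(arch@initLog[nm]) || !is.finite(arch@finalLog[nm])) next
    e <- sum(emissionLogProb(st@emission, codes))
    sc <- arch@initLog[[nm]] + e + (L - 1) * st@selfLoopLogP +
      arch@finalLog[[nm]]
    if (sc > best) best <- sc
  }
  if (best < NEG_TH) best <- -Inf
  best
}

#' Extract the CDS call from a decoded path
#'
#' @param path a [StatePath-class].
#' @param seqLength length of the decoded sequence.
#' @return `NULL` when the path has no coding segment; otherwise a list with
#'   `start`, `end` (0-based half-open, spanning Start..Stop inclusive of
#'   both codons when present), `hasStart`, `hasStop`, `frame` (offset of
#'   the first complete codon within the interval).
#' @export
extractCdsCall <- function(path, seqLength) {
  sg <- path@segments
  cod <- sg$state %in% CODING_STATES
  if (!any(cod)) return(NULL)
  idx <- which(cod)
  if (any(diff(idx) != 1L))
    stop("internal error: non-contiguous coding states in path")
  first <- sg$state[idx[1]]
  frame <- switch(first, Start = 0L, fullCDS = 0L, pCDS0 = 0L, pCDS1 = 1L,
                  pCDS2 = 2L, Stop = 0L)
  list(start = sg$from[idx[1]], end = sg$to[idx[length(idx)]],
       hasStart = "Start" %in% sg$state[idx],
       hasStop = "Stop" %in% sg$state[idx],
       frame = frame, logScore = path@logScore)
}

# ---- the two transcript architectures --------------------------------------

#' Build the full-transcript architecture
#'
#' Linear skeleton UTR5 - Start - fullCDS - Stop - UTR3 with a no-CDS escape
#' path (a path ending in UTR5), fixed-length ATG-anchored Start and
#' stop-codon-anchored Stop states, an explicit codon-quantized fullCDS
#' duration and geometric UTRs.
#'
#' @param utr5Chain,utr3Chain [MarkovChainModel-class] UTR emissions.
#' @param cdsPeriodic [PeriodicMarkovModel-class] coding emission.
#' @param startModel,stopModel [PositionalModel-class] codon-context models.
#' @param cdsDuration [DurationModel-class] (step 3) for fullCDS lengths
#'   (start/stop codons excluded).
#' @param q5,q3 log self-loop probabilities of the UTR states.
#' @param pUtr5 probability that a transcript begins with a non-empty 5'UTR
#'   (the remainder enters at Start).
#' @return a [GhmmArchitecture-class].
#' @export
fullArchitecture <- function(utr5Chain, cdsPeriodic, startModel, stopModel,
                             utr3Chain, cdsDuration, q5, q3, pUtr5 = 1) {
  states <- list(
    ghmmState("UTR5", utr5Chain, "geometric", selfLoopLogP = q5),
    ghmmState("Start", startModel, "fixed", fixedLen = 3L,
              requiredCodons = "ATG", flankUp = utr5Chain,
              flankDown = cdsPeriodic),
    ghmmState("fullCDS", cdsPeriodic, "explicit", duration = cdsDuration,
              inPhase = 0L, noInternalStops = TRUE),
    ghmmState("Stop", stopModel, "fixed", fixedLen = 3L,
              requiredCodons = STOP_CODONS, flankDown = utr3Chain),
    ghmmState("UTR3", utr3Chain, "geometric", selfLoopLogP = q3))
  S <- 5L
  tr <- matrix(-Inf, S, S)
  tr[1, 2] <- 0; tr[2, 3] <- 0; tr[3, 4] <- 0; tr[4, 5] <- 0
  init <- c(log(pUtr5), log1p(-pUtr5), -Inf, -Inf, -Inf)
  if (pUtr5 >= 1) init <- c(0, -Inf, -Inf, -Inf, -Inf)
  final <- c(0, -Inf, -Inf, -Inf, 0)
  ghmmArchitecture(states, tr, init, final)
}

#' Build the partial-transcript architecture
#'
#' Adds the frame-offset partial coding states pCDS0/pCDS1/pCDS2 (entry
#' states for fragments missing the start codon) and allows ending inside
#' the coding region (missing stop).  State pCDSf emits fragments whose
#' first complete codon begins at offset f; internal pCDSf segments must
#' satisfy `len %% 3 == f` so that the following Stop codon is in frame.
#'
#' @inheritParams fullArchitecture
#' @param utrChain emission for the generic UTR entry state (by default the
#'   same model as the 5'UTR).
#' @param pcdsDuration [DurationModel-class] (step 1) for partial coding
#'   fragments.
#' @param qU log self-loop probability of the generic UTR state.
#' @return a [GhmmArchitecture-class].
#' @export
partialArchitecture <- function(utrChain, cdsPeriodic, startModel, stopModel,
                                utr3Chain, cdsDuration, pcdsDuration,
                                qU, q3) {
  states <- list(
    ghmmState("UTR", utrChain, "geometric", selfLoopLogP = qU),
    ghmmState("Start", startModel, "fixed", fixedLen = 3L,
              requiredCodons = "ATG", flankUp = utrChain,
              flankDown = cdsPeriodic),
    ghmmState("fullCDS", cdsPeriodic, "explicit", duration = cdsDuration,
              inPhase = 0L, noInternalStops = TRUE),
    ghmmState("pCDS0", cdsPeriodic, "explicit", duration = pcdsDuration,
              inPhase = 0L, congruence = 0L, noInternalStops = TRUE),
    ghmmState("pCDS1", cdsPeriodic, "explicit", duration = pcdsDuration,
              inPhase = 2L, congruence = 1L, noInternalStops = TRUE),
    ghmmState("pCDS2", cdsPeriodic, "explicit", duration = pcdsDuration,
              inPhase = 1L, congruence = 2L, noInternalStops = TRUE),
    ghmmState("Stop", stopModel, "fixed", fixedLen = 3L,
              requiredCodons = STOP_CODONS, flankDown = utr3Chain),
    ghmmState("UTR3", utr3Chain, "geometric", selfLoopLogP = q3))
  nms <- vapply(states, function(s) s@name, character(1))
  S <- length(states)
  tr <- matrix(-Inf, S, S, dimnames = list(nms, nms))
  tr["UTR", "Start"] <- 0
  tr["Start", "fullCDS"] <- 0
  tr["fullCDS", "Stop"] <- 0
  tr["pCDS0", "Stop"] <- 0
  tr["pCDS1", "Stop"] <- 0
  tr["pCDS2", "Stop"] <- 0
  tr["Stop", "UTR3"] <- 0
  entry <- c("UTR", "Start", "pCDS0", "pCDS1", "pCDS2")
  init <- setNames(rep(-Inf, S), nms)
  init[entry] <- log(1 / length(entry))
  final <- setNames(rep(0, S), nms)
  final["Start"] <- -Inf
  ghmmArchitecture(states, tr, init, unname(final))
}
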