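#' @import methods
#' @importFrom stats dnorm quantile runif setNames
#' @importFrom utils head tail
NULL

DNA_BASES4 <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Markov chain emission model
#'
#' A homogeneous order-\eqn{k} Markov chain over \{A,C,G,T\} with a totally
#' populated conditional table (Laplace pseudocounts guarantee every context
#' has an entry).  Contexts are the \eqn{k} bases preceding a position;
#' conditional distributions are stored in log space.
#'
#' @slot order non-negative integer, the chain order \eqn{k}.
#' @slot logProb numeric matrix, \eqn{4^k \times 4}; row = context (encoded
#'   index, see `contextIndex()`), column = emitted base A,C,G,T.
#' @slot logMarg0 numeric length-4 log marginal over bases obtained by
#'   averaging the conditional table over contexts with uniform weight; used
#'   for positions whose context is unavailable or contains N.
#' @slot pseudocount positive real used during estimation.
#' @export
setClass("MarkovChainModel",
  representation(order = "integer", logProb = "matrix",
                 logMarg0 = "numeric", pseudocount = "numeric"))

setValidity("MarkovChainModel", function(object) {
  k <- object@order
  if (length(k) != 1L || is.na(k) || k < 0L)
    return("order must be a single non-negative integer")
  if (nrow(object@logProb) != 4L^k || ncol(object@logProb) != 4L)
    return(sprintf("logProb must be a %d x 4 matrix for order %d", 4L^k, k))
  rs <- rowSums(exp(object@logProb))
  if (any(abs(rs - 1) > 1e-9))
    return("conditional distributions must each sum to 1 (tol 1e-9)")
  if (abs(sum(exp(object@logMarg0)) - 1) > 1e-9)
    return("logMarg0 must normalize")
  if (object@pseudocount <= 0) return("pseudocount must be positive")
  TRUE
})

#' Three-periodic Markov chain model
#'
#' Codon-position-cycling emission model for coding regions: one
#' [MarkovChainModel-class] per codon position 0, 1, 2, all of the same order.
#'
#' @slot phases list of exactly 3 MarkovChainModel objects, indexed by codon
#'   position (phase) 0..2.
#' @export
setClass("PeriodicMarkovModel", representation(phases = "list"))

setValidity("PeriodicMarkovModel", function(object) {
  if (length(object@phases) != 3L)
    return("exactly 3 phase models are required")
  if (!all(vapply(object@phases, is, logical(1), "MarkovChainModel")))
    return("phases must all be MarkovChainModel objects")
  ords <- vapply(object@phases, function(m) m@order, integer(1))
  if (length(unique(ords)) != 1L)
    return("phase models must share one order")
  TRUE
})

#' Positional weight model
#'
#' Per-column base distributions over a fixed window anchored at a codon's
#' first base; used for start- and stop-codon context scoring.  Columns
#' falling outside the sequence are skipped at scoring time (score 0), which
#' is required for CDS at sequence edges.
#'
#' @slot windowStart integer offset of the first column relative to the
#'   anchored codon's first base (may be negative).
#' @slot logProbs numeric matrix, window length x 4 (A,C,G,T), log
#'   probabilities; each column distribution sums to 1.
#' @export
setClass("PositionalModel",
  representation(windowStart = "integer", logProbs = "matrix"))

setValidity("PositionalModel", function(object) {
  if (ncol(object@logProbs) != 4L) return("logProbs needs 4 columns (ACGT)")
  if (nrow(object@logProbs) < 1L) return("window length must be positive")
  rs <- rowSums(exp(object@logProbs))
  if (any(abs(rs - 1) > 1e-9))
    return("each window column must sum to 1 (tol 1e-9)")
  TRUE
})

#' Explicit state-duration distribution
#'
#' Probability mass over segment lengths for explicit-duration GHMM states:
#' a smoothed empirical pmf on `[minLen, maxLen]` (optionally on a lattice of
#' `step` = 3 for frame-locked complete CDS segments) plus a geometric tail
#' for lengths beyond `maxLen`.  Body and tail masses sum to 1.
#'
#' @slot minLen,maxLen positive integers bounding the pmf body.
#' @slot step lattice step of the body support (1, or 3 for codon-quantized).
#' @slot logPmf numeric log masses at `seq(minLen, maxLen, by = step)`.
#' @slot tailLogP log of the per-step geometric continuation ratio of the
#'   tail (lengths `maxLen + step*j`).
#' @slot tailLogMass log of the total mass beyond `maxLen` (`-Inf` for none).
#' @export
setClass("DurationModel",
  representation(minLen = "integer", maxLen = "integer", step = "integer",
                 logPmf = "numeric", tailLogP = "numeric",
                 tailLogMass = "numeric"))

setValidity("DurationModel", function(object) {
  if (object@minLen < 1L) return("minLen must be >= 1")
  if (object@minLen > object@maxLen) return("minLen must be <= maxLen")
  if (!object@step %in% c(1L, 3L)) return("step must be 1 or 3")
  if ((object@maxLen - object@minLen) %% object@step != 0L)
    return("maxLen - minLen must be a multiple of step")
  nb <- (object@maxLen - object@minLen) %/% object@step + 1L
  if (length(object@logPmf) != nb)
    return("logPmf length does not match the [minLen, maxLen] lattice")
  tot <- sum(exp(object@logPmf)) + exp(object@tailLogMass)
  if (abs(tot - 1) > 1e-9)
    return("body plus tail mass must sum to 1 (tol 1e-9)")
  if (is.finite(object@tailLogMass) && object@tailLogP >= 0)
    return("tail continuation ratio must be < 1")
  TRUE
})

setClassUnion("DurationModelOrNULL", c("DurationModel", "NULL"))

#' GHMM state
#'
#' One state of a transcript architecture.  `durationKind` selects how
#' segment lengths are scored: `"geometric"` (self-loop), `"explicit"`
#' (a [DurationModel-class]) or `"fixed"` (exactly `fixedLen` bases; used by
#' the Start and Stop states, which additionally carry a hard codon
#' constraint).  `inPhase` is the codon position of the first emitted base
#' for periodic emissions; `congruence` (if not `NA`) requires internal
#' (non-final) segment lengths to satisfy `len %% 3 == congruence`.
#'
#' @slot name state name (UTR5, Start, fullCDS, Stop, UTR3, UTR, pCDS0,
#'   pCDS1, pCDS2, or arbitrary for toy architectures).
#' @slot emission a MarkovChainModel, PeriodicMarkovModel or PositionalModel.
#' @slot durationKind one of "geometric", "explicit", "fixed".
#' @slot fixedLen segment length for fixed states (3 for Start/Stop).
#' @slot duration DurationModel for explicit states, else NULL.
#' @slot selfLoopLogP log self-transition probability for geometric states.
#' @slot inPhase integer 0..2, codon phase of the first base of a segment.
#' @slot congruence integer 0..2 or NA; internal-length mod-3 constraint.
#' @slot requiredCodons character vector of codons that the first 3 emitted
#'   bases of a fixed state must match (empty = unconstrained).
#' @slot noInternalStops logical; when TRUE, in-frame stop codons inside the
#'   state's segments are forbidden (score `-Inf`), guaranteeing
#'   translatable coding calls.
#' @slot flankUp,flankDown optional content models of the states flanking a
#'   fixed signal state.  Positional window columns that fall outside the
#'   emitted segment overlap the flanking states' segments; their window
#'   score replaces (rather than adds to) the flanking chain's score, which
#'   is achieved by subtracting the flank model's per-position
#'   log-probability over the overlapping columns (log-odds signal scoring).
#' @export
setClass("GhmmState",
  representation(name = "character", emission = "ANY",
                 durationKind = "character", fixedLen = "integer",
                 duration = "DurationModelOrNULL", selfLoopLogP = "numeric",
                 inPhase = "integer", congruence = "integer",
                 requiredCodons = "character", noInternalStops = "logical",
                 flankUp = "ANY", flankDown = "ANY"))

setValidity("GhmmState", function(object) {
  if (!object@durationKind %in% c("geometric", "explicit", "fixed"))
    return("durationKind must be geometric, explicit or fixed")
  if (object@durationKind == "explicit" && is.null(object@duration))
    return("explicit states need a DurationModel")
  if (object@durationKind == "fixed") {
    if (is.na(object@fixedLen) || object@fixedLen < 1L)
      return("fixed states need a positive fixedLen")
    if (object@name %in% c("Start", "Stop") && object@fixedLen != 3L)
      return("Start and Stop states have fixed length 3")
  }
  if (object@durationKind == "explicit" &&
      !object@name %in% c("fullCDS", "pCDS0", "pCDS1", "pCDS2") &&
      object@name %in% c("UTR5", "Start", "Stop", "UTR3", "UTR"))
    return("only the coding states may be explicit-duration")
  if (object@durationKind == "geometric" &&
      (!is.finite(object@selfLoopLogP) || object@selfLoopLogP >= 0))
    return("geometric states need selfLoopLogP in (-Inf, 0)")
  if (!object@inPhase %in% 0:2) return("inPhase must be 0, 1 or 2")
  if (!is.na(object@congruence) && !object@congruence %in% 0:2)
    return("congruence must be NA or 0..2")
  TRUE
})

#' GHMM architecture
#'
#' A set of [GhmmState-class] objects with log transition matrix, initial
#' log distribution and final-state log weights.  Two instances matter in
#' practice: the full-transcript architecture
#' (UTR5 - Start - fullCDS - Stop - UTR3) and the partial-transcript
#' architecture, which adds the frame-offset partial coding states
#' pCDS0/pCDS1/pCDS2 and a generic UTR entry state.
#'
#' @slot states list of GhmmState, named by state name.
#' @slot transLog S x S log transition matrix (rows = from).
#' @slot initLog length-S initial log distribution (sums to 1).
#' @slot finalLog length-S log weights; `-Inf` marks states that may not end
#'   a sequence.
#' @export
setClass("GhmmArchitecture",
  representation(states = "list", transLog = "matrix", initLog = "numeric",
                 finalLog = "numeric"))

setValidity("GhmmArchitecture", function(object) {
  S <- length(object@states)
  if (S < 1L) return("at least one state required")
  if (!all(vapply(object@states, is, logical(1), "GhmmState")))
    return("states must be GhmmState objects")
  nms <- unname(vapply(object@states, function(s) s@name, character(1)))
  if (anyDuplicated(nms)) return("state names must be unique")
  if (!identical(names(object@states), nms))
    return("states list must be named by state name")
  if (!all(dim(object@transLog) == c(S, S)))
    return("transLog must be S x S")
  if (length(object@initLog) != S || length(object@finalLog) != S)
    return("initLog and finalLog must have one entry per state")
  if (abs(sum(exp(object@initLog)) - 1) > 1e-9)
    return("initial distribution must sum to 1")
  outs <- rowSums(exp(object@transLog))
  if (any(outs > 1 + 1e-9))
    return("outgoing transition probabilities must sum to <= 1")
  if (all(!is.finite(object@finalLog)))
    return("at least one final state required")
  TRUE
})

#' Decoded state path
#'
#' Result of explicit-duration Viterbi decoding: an ordered tiling of
#' `[0, L)` by labeled segments, plus the joint log score.
#'
#' @slot segments data.frame with columns `state`, `from`, `to`
#'   (0-based half-open offsets).
#' @slot logScore joint log probability of the path.
#' @export
setClass("StatePath",
  representation(segments = "data.frame", logScore = "numeric"))

setValidity("StatePath", function(object) {
  sg <- object@segments
  if (!all(c("state", "from", "to") %in% names(sg)))
    return("segments needs columns state, from, to")
  if (nrow(sg) > 0) {
    if (sg$from[1] != 0L) return("path must start at offset 0")
    if (any(sg$to <= sg$from)) return("segments must be non-empty")
    if (nrow(sg) > 1 && any(sg$from[-1] != sg$to[-nrow(sg)]))
      return("segments must tile without gaps or overlaps")
  }
  TRUE
})

#' Trained model bundle
#'
#' All parameters needed for prediction: GC-content bins over `[0, 1]`, one
#' pair of architectures (full, partial) per bin, and training metadata.
#' Bins too sparse to train borrow the nearest populated bin's parameters
#' (recorded in `metadata$borrowed`).
#'
#' @slot gcBreaks numeric break points (first 0, last 1); bin i is
#'   `[gcBreaks[i], gcBreaks[i+1])`, with 1.0 assigned to the last bin.
#' @slot bins list, one element per bin: `list(full = , partial = )`
#'   GhmmArchitecture pair.
#' @slot metadata list: per-bin training counts, model orders, pseudocount,
#'   borrowing map, format version.
#' @export
setClass("TrainedBundle",
  representation(gcBreaks = "numeric", bins = "list", metadata = "list"))

setValidity("TrainedBundle", function(object) {
  b <- object@gcBreaks
  if (length(b) < 2L || b[1] != 0 || b[length(b)] != 1 || any(diff(b) <= 0))
    return("gcBreaks must increase from 0 to 1")
  if (length(object@bins) != length(b) - 1L)
    return("one parameter set per bin is required")
  ok <- vapply(object@bins, function(x)
    is(x$full, "GhmmArchitecture") && is(x$partial, "GhmmArchitecture"),
    logical(1))
  if (!all(ok)) return("every bin needs full and partial architectures")
  TRUE
})

#' Evaluation confusion counts
#'
#' Confusion counts for one evaluated dataset under one matching criterion:
#' `stop_match` (predicted stop codon coincides with the reference),
#' `full_cds_match` (start, end and strand all coincide) or `any_call`
#' (any prediction counts as positive; used on negative sets).
#'
#' @slot tp,fp,fn,tn non-negative integer counts.
#' @slot criterion character, the matching criterion used.
#' @export
setClass("EvalOutcome",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 tn = "integer", criterion = "character"))

setValidity("EvalOutcome", function(object) {
  cnt <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(is.na(cnt)) || any(cnt < 0L)) return("counts must be >= 0")
  if (!object@criterion %in% c("stop_match", "full_cds_match", "any_call"))
    return("unknown criterion")
  TRUE
})
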