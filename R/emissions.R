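# Emission models: homogeneous Markov chains, three-periodic chains and
# anchored positional weight models.  All scores are natural-log
# probabilities; offsets are 0-based half-open.

#' Construct a Markov chain emission model
#'
#' @param order chain order k (non-negative integer).
#' @param logProb 4^k x 4 matrix of log conditional probabilities (rows =
#'   contexts in `contextIndex()` order, columns = A,C,G,T).
#' @param pseudocount positive real recorded with the model.
#' @return a [MarkovChainModel-class].
#' @export
markovChainModel <- function(order, logProb, pseudocount = 1) {
  logProb <- as.matrix(logProb)
  rownames(logProb) <- contextStrings(order)
  colnames(logProb) <- DNA_BASES4
  marg <- log(colMeans(exp(logProb)))
  new("MarkovChainModel", order = as.integer(order), logProb = logProb,
      logMarg0 = marg, pseudocount = as.numeric(pseudocount))
}

#' Construct a three-periodic Markov chain model
#'
#' @param phase0,phase1,phase2 [MarkovChainModel-class] objects of one order,
#'   indexed by codon position.
#' @return a [PeriodicMarkovModel-class].
#' @export
periodicMarkovModel <- function(phase0, phase1, phase2) {
  new("PeriodicMarkovModel", phases = list(phase0, phase1, phase2))
}

#' Construct a positional weight model
#'
#' @param windowStart offset of the first column relative to the anchored
#'   codon's first base (negative = upstream).
#' @param probs window-length x 4 matrix of per-column base probabilities
#'   (columns A,C,G,T); zeros are allowed and score `-Inf`.
#' @return a [PositionalModel-class].
#' @export
positionalModel <- function(windowStart, probs) {
  probs <- as.matrix(probs)
  colnames(probs) <- DNA_BASES4
  new("PositionalModel", windowStart = as.integer(windowStart),
      logProbs = log(probs))
}

# Fit an order-k chain from counted transitions with Laplace smoothing and
# automatic back-off: any context observed fewer than minContextObs times
# inherits the conditional of its (k-1)-suffix (recursively down to order 0).
fitMarkovChain <- function(codesList, positionsList, order,
                           pseudocount = 1, minContextObs = 10L) {
  k <- as.integer(order)
  counts <- matrix(0, nrow = 4L^k, ncol = 4L)
  for (s in seq_along(codesList)) {
    codes <- codesList[[s]]
    pos <- positionsList[[s]]            # 1-based positions to count
    if (length(pos) == 0L) next
    idx <- contextIndex(codes, k)[pos]
    sym <- codes[pos]
    ok <- !is.na(idx) & !is.na(sym)
    if (!any(ok)) next
    tab <- tabulate(idx[ok] + 4L^k * (sym[ok] - 1L), nbins = 4L^k * 4L)
    counts <- counts + matrix(tab, nrow = 4L^k)
  }
  prob <- chainProbFromCounts(counts, k, pseudocount, minContextObs)
  markovChainModel(k, log(prob), pseudocount)
}

chainProbFromCounts <- function(counts, k, pseudocount, minContextObs) {
  # aggregate full-order counts down to each lower order, then fill sparse
  # contexts from the next-lower-order conditional
  countsByOrder <- vector("list", k + 1L)
  countsByOrder[[k + 1L]] <- counts
  if (k > 0L) for (m in (k - 1L):0L) {
    hi <- countsByOrder[[m + 2L]]
    nhi <- nrow(hi)
    suff <- ((seq_len(nhi) - 1L) %% 4L^m) + 1L
    lo <- matrix(0, nrow = 4L^m, ncol = 4L)
    for (col in 1:4) lo[, col] <- as.vector(rowsum(hi[, col], suff))
    countsByOrder[[m + 1L]] <- lo
  }
  prob <- NULL
  for (m in 0:k) {
    cm <- countsByOrder[[m + 1L]]
    pm <- (cm + pseudocount) / (rowSums(cm) + 4 * pseudocount)
    if (m > 0L) {
      sparse <- rowSums(cm) < minContextObs
      if (any(sparse)) {
        suff <- ((which(sparse) - 1L) %% 4L^(m - 1L)) + 1L
        pm[sparse, ] <- prob[suff, , drop = FALSE]
      }
    }
    prob <- pm
  }
  prob
}

# Per-position emission log-probabilities over a whole encoded sequence.
# Position i uses the k preceding bases as context; positions with no full
# in-sequence context, or whose context contains N, fall back to the
# uniform-context marginal; N symbols contribute 0 (marginalized out).
emissionLogProb <- function(model, codes) {
  L <- length(codes)
  out <- numeric(L)
  if (L == 0L) return(out)
  idx <- contextIndex(codes, model@order)
  symOk <- !is.na(codes)
  ctxOk <- !is.na(idx)
  both <- symOk & ctxOk
  out[both] <- model@logProb[cbind(idx[both], codes[both])]
  onlySym <- symOk & !ctxOk
  out[onlySym] <- model@logMarg0[codes[onlySym]]
  out  # N positions stay 0
}

#' Score an interval under a Markov chain model
#'
#' Sum of conditional log-probabilities of the symbols in `[from, to)`
#' (0-based half-open).  Contexts reaching left of `from` use the preceding
#' bases of `seq` when available, otherwise the uniform-context marginal;
#' N symbols contribute 0 after marginalization.
#'
#' @param model a [MarkovChainModel-class].
#' @param seq nucleotide string.
#' @param from,to 0-based half-open interval bounds.
#' @return log-probability (0 for an empty interval).
#' @export
scoreChain <- function(model, seq, from, to) {
  codes <- encodeSeq(seq)
  checkInterval(from, to, length(codes))
  if (from == to) return(0)
  sum(emissionLogProb(model, codes)[(from + 1L):to])
}

#' Score an interval under a three-periodic chain
#'
#' Position `i` in `[from, to)` is scored by the phase model with index
#' `(phaseAtFrom + i - from) %% 3`.
#'
#' @param model a [PeriodicMarkovModel-class].
#' @param seq nucleotide string.
#' @param from,to 0-based half-open interval bounds.
#' @param phaseAtFrom codon position (0..2) of the base at `from`.
#' @return log-probability.
#' @export
scorePeriodic <- function(model, seq, from, to, phaseAtFrom = 0L) {
  codes <- encodeSeq(seq)
  checkInterval(from, to, length(codes))
  stopifnot(phaseAtFrom %in% 0:2)
  if (from == to) return(0)
  M <- vapply(model@phases, emissionLogProb, numeric(length(codes)),
              codes = codes)
  if (is.null(dim(M))) M <- matrix(M, nrow = 1L)   # length-1 sequence
  i <- (from + 1L):to
  ph <- (phaseAtFrom + (i - 1L) - from) %% 3L
  sum(M[cbind(i, ph + 1L)])
}

#' Score an anchored positional window
#'
#' The window spans `[anchor + windowStart, anchor + windowStart + length)`;
#' columns outside the sequence are skipped (score 0), as needed for CDS at
#' sequence edges.  N symbols contribute 0.
#'
#' @param model a [PositionalModel-class].
#' @param seq nucleotide string.
#' @param anchor 0-based offset of the anchored codon's first base.
#' @return log-probability.
#' @export
scorePositional <- function(model, seq, anchor) {
  codes <- encodeSeq(seq)
  positionalLogProb(model, codes, anchor)
}

positionalLogProb <- function(model, codes, anchor) {
  L <- length(codes)
  len <- nrow(model@logProbs)
  pos <- anchor + model@windowStart + seq_len(len) - 1L   # 0-based
  keep <- pos >= 0L & pos < L
  if (!any(keep)) return(0)
  sym <- codes[pos[keep] + 1L]
  cols <- which(keep)
  ok <- !is.na(sym)
  sum(model@logProbs[cbind(cols[ok], sym[ok])])
}

checkInterval <- function(from, to, L) {
  if (from < 0L || to < from || to > L)
    stop(sprintf("interval [%d,%d) out of range for length %d", from, to, L))
}
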