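# Supervised parameter estimation from annotated transcripts, partitioned
# into GC-content sub-models.  No expectation-maximization: models are
# trained once from curated annotations.

#' GC fraction of a sequence
#'
#' `(G + C) / (A + C + G + T)`; N bases are excluded from both numerator
#' and denominator; an all-N sequence scores 0.5.
#'
#' @param seq nucleotide string (non-empty).
#' @return real in `[0, 1]`.
#' @export
gcFraction <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  f <- Biostrings::letterFrequency(Biostrings::DNAString(seq),
                                   c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0) return(0.5)
  unname((f[["C"]] + f[["G"]]) / tot)
}

#' Assign a GC fraction to a bin
#'
#' Bins are half-open `[b_i, b_{i+1})`; a GC of exactly 1.0 maps to the
#' last bin.
#'
#' @param bins a [TrainedBundle-class] or a numeric break vector
#'   (0 ... 1).
#' @param gc GC fraction in `[0, 1]`.
#' @return 1-based bin index.
#' @export
assignBin <- function(bins, gc) {
  breaks <- if (is(bins, "TrainedBundle")) bins@gcBreaks else bins
  stopifnot(gc >= 0, gc <= 1)
  findInterval(gc, breaks, rightmost.closed = TRUE)
}

#' Training configuration
#'
#' @param cdsOrder order of the three-periodic coding chains.
#' @param utrOrder order of the UTR chains.
#' @param pseudocount Laplace pseudocount per (context, symbol) cell.
#' @param minContextObs contexts observed fewer times back off to the
#'   next-lower order.
#' @param gcBreaks GC bin edges (first 0, last 1).
#' @param minTrainSequences bins with fewer transcripts borrow the nearest
#'   populated bin's parameters.
#' @param minOverall minimum total usable training transcripts.
#' @param durationBandwidth kernel bandwidth for duration fitting
#'   (NULL = data-driven).
#' @param truncationSeed seed of the simulated truncations that train the
#'   partial-CDS duration model.
#' @return a list of class `trainingConfig`.
#' @export
trainingConfig <- function(cdsOrder = 4L, utrOrder = 3L, pseudocount = 1,
                           minContextObs = 10L,
                           gcBreaks = c(0, 0.45, 0.55, 1),
                           minTrainSequences = 30L, minOverall = 50L,
                           durationBandwidth = NULL,
                           truncationSeed = 7L) {
  structure(list(cdsOrder = as.integer(cdsOrder),
                 utrOrder = as.integer(utrOrder),
                 pseudocount = pseudocount,
                 minContextObs = as.integer(minContextObs),
                 gcBreaks = gcBreaks,
                 minTrainSequences = as.integer(minTrainSequences),
                 minOverall = as.integer(minOverall),
                 durationBandwidth = durationBandwidth,
                 truncationSeed = as.integer(truncationSeed)),
            class = "trainingConfig")
}

#' Train a model bundle from annotated transcripts
#'
#' Per GC bin: the three-periodic CDS chains are estimated from in-frame
#' codon positions (start and stop codons excluded), UTR chains from their
#' regions, start/stop positional models from aligned windows, the fullCDS
#' duration from CDS lengths minus the six codon-anchor bases (mod-3
#' lattice), the partial-CDS duration from simulated uniform truncations of
#' the training CDSs (150 nt retained when possible), and initial/self-loop
#' probabilities from region presence frequencies and lengths.  All counts
#' are Laplace-smoothed.  Transcripts violating the reference invariants
#' are skipped with a warning count.
#'
#' @param transcripts annotated DNAStringSet ([transcriptSet()]); every
#'   record must have `hasStart` and `hasStop` TRUE.
#' @param config a [trainingConfig()].
#' @return a [TrainedBundle-class].
#' @export
trainBundle <- function(transcripts, config = trainingConfig()) {
  mc <- S4Vectors::mcols(transcripts)
  seqs <- as.character(transcripts)
  # orient everything onto the coding strand
  minus <- !is.na(mc$strand) & mc$strand == "-"
  if (any(minus)) {
    for (i in which(minus)) {
      L <- nchar(seqs[i])
      seqs[i] <- revComp(seqs[i])
      a <- mc$cdsStart[i]; b <- mc$cdsEnd[i]
      mc$cdsStart[i] <- L - b; mc$cdsEnd[i] <- L - a
    }
  }
  ok <- !is.na(mc$cdsStart) & !is.na(mc$cdsEnd) &
    isTRUE2(mc$hasStart) & isTRUE2(mc$hasStop) &
    mc$cdsStart >= 0L & mc$cdsEnd <= nchar(seqs) &
    (mc$cdsEnd - mc$cdsStart) %% 3L == 0L &
    (mc$cdsEnd - mc$cdsStart) >= 9L &
    substr(seqs, mc$cdsStart + 1L, mc$cdsStart + 3L) == "ATG" &
    substr(seqs, mc$cdsEnd - 2L, mc$cdsEnd) %in% STOP_CODONS
  if (any(!ok))
    warning(sum(!ok), " transcript(s) skipped: reference CDS invariants ",
            "violated")
  if (!any(ok)) stop("no usable training transcripts")
  seqs <- seqs[ok]
  cs <- mc$cdsStart[ok]; ce <- mc$cdsEnd[ok]
  if (length(seqs) < config$minOverall)
    stop("training requires at least ", config$minOverall,
         " transcripts (got ", length(seqs), ")")
  gc <- vapply(seqs, gcFraction, numeric(1), USE.NAMES = FALSE)
  breaks <- config$gcBreaks
  nb <- length(breaks) - 1L
  binIdx <- findInterval(gc, breaks, rightmost.closed = TRUE)
  counts <- tabulate(binIdx, nbins = nb)
  populated <- which(counts >= config$minTrainSequences)
  if (length(populated) == 0L) {
    # train a single global parameter set shared by all bins
    populated <- which.max(counts)
    binIdx[] <- populated
    counts <- tabulate(binIdx, nbins = nb)
  }
  params <- vector("list", nb)
  for (b in populated)
    params[[b]] <- trainBinParams(seqs[binIdx == b], cs[binIdx == b],
                                  ce[binIdx == b], config)
  borrowed <- setNames(rep(NA_integer_, nb), paste0("bin", seq_len(nb)))
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  for (b in setdiff(seq_len(nb), populated)) {
    src <- populated[which.min(abs(centers[populated] - centers[b]))]
    params[[b]] <- params[[src]]
    borrowed[b] <- src
  }
  new("TrainedBundle", gcBreaks = breaks, bins = params,
      metadata = list(version = "transcds-bundle-1",
                      nTraining = length(seqs),
                      binCounts = as.integer(counts),
                      borrowed = as.list(borrowed),
                      cdsOrder = config$cdsOrder,
                      utrOrder = config$utrOrder,
                      pseudocount = config$pseudocount))
}

trainBinParams <- function(seqs, cs, ce, config) {
  n <- length(seqs)
  codesList <- lapply(seqs, encodeSeq)
  lens <- nchar(seqs)
  # periodic CDS chains from interior codon positions
  phasePos <- lapply(0:2, function(p) vector("list", n))
  utr5Pos <- vector("list", n); utr3Pos <- vector("list", n)
  for (i in seq_len(n)) {
    a <- cs[i]; b <- ce[i]
    interior <- if (b - 3L > a + 3L) (a + 4L):(b - 3L) else integer(0)
    ph <- (interior - 1L - (a + 3L)) %% 3L
    for (p in 0:2) phasePos[[p + 1L]][[i]] <- interior[ph == p]
    utr5Pos[[i]] <- if (a > 0L) seq_len(a) else integer(0)
    utr3Pos[[i]] <- if (b < lens[i]) (b + 1L):lens[i] else integer(0)
  }
  chains <- lapply(1:3, function(p)
    fitMarkovChain(codesList, phasePos[[p]], config$cdsOrder,
                   config$pseudocount, config$minContextObs))
  cdsPeriodic <- periodicMarkovModel(chains[[1]], chains[[2]], chains[[3]])
  utr5Chain <- fitMarkovChain(codesList, utr5Pos, config$utrOrder,
                              config$pseudocount, config$minContextObs)
  utr3Chain <- fitMarkovChain(codesList, utr3Pos, config$utrOrder,
                              config$pseudocount, config$minContextObs)
  startModel <- fitPositional(codesList, cs, windowStart = -6L, len = 12L,
                              pseudocount = config$pseudocount)
  stopModel <- fitPositional(codesList, ce - 3L, windowStart = 0L, len = 6L,
                             pseudocount = config$pseudocount)
  cdsDur <- fitDuration(ce - cs - 6L, config$durationBandwidth, step = 3L)
  u5len <- cs
  u3len <- lens - ce
  pcdsDur <- fitDuration(simulateTruncatedLengths(ce - cs, u3len,
                                                  config$truncationSeed),
                         config$durationBandwidth, step = 1L)
  q5 <- log(geomSelfLoop(u5len[u5len > 0L]))
  q3 <- log(geomSelfLoop(u3len[u3len > 0L]))
  pUtr5 <- (sum(u5len > 0L) + 1) / (n + 2)
  full <- fullArchitecture(utr5Chain, cdsPeriodic, startModel, stopModel,
                           utr3Chain, cdsDur, q5, q3, pUtr5 = pUtr5)
  partial <- partialArchitecture(utr5Chain, cdsPeriodic, startModel,
                                 stopModel, utr3Chain, cdsDur, pcdsDur,
                                 qU = q5, q3 = q3)
  list(full = full, partial = partial)
}

# smoothed ML estimate of a geometric self-loop from run lengths
geomSelfLoop <- function(runs) {
  if (length(runs) == 0L) return(0.5)
  tot <- sum(runs)
  q <- (tot - length(runs) + 1) / (tot + 2)
  min(max(q, 1e-6), 1 - 1e-6)
}

fitPositional <- function(codesList, anchors, windowStart, len,
                          pseudocount = 1) {
  counts <- matrix(0, nrow = len, ncol = 4L)
  for (i in seq_along(codesList)) {
    codes <- codesList[[i]]
    pos <- anchors[i] + windowStart + seq_len(len) - 1L   # 0-based
    keep <- pos >= 0L & pos < length(codes)
    sym <- codes[pos[keep] + 1L]
    col <- which(keep)[!is.na(sym)]
    sym <- sym[!is.na(sym)]
    if (length(sym))
      counts[cbind(col, sym)] <- counts[cbind(col, sym)] + 1L
  }
  probs <- (counts + pseudocount) / (rowSums(counts) + 4 * pseudocount)
  positionalModel(windowStart, probs)
}

# fragment lengths of simulated uniform CDS truncations (the partial-state
# duration training data; no natural partial training data exist).  The
# 150 nt floor applies to the resulting sequence, i.e. fragment + 3'UTR for
# start-pruned transcripts, mirroring the standard test-set construction.
simulateTruncatedLengths <- function(cdsLens, utr3Lens, seed,
                                     minRetained = 150L) {
  withSeed(seed, {
    out <- integer(0)
    for (i in seq_along(cdsLens)) {
      len <- cdsLens[i]
      if (len < 12L) next
      # NoStart-style: fragment between truncation point and stop codon
      hi <- min(len - 6L, len + utr3Lens[i] - minRetained)
      t1 <- if (hi >= 3L) unifInt(3L, hi) else 3L
      out <- c(out, len - 3L - t1)
      # interior-only fragment (both codons pruned; no UTRs remain)
      if (len - 6L >= minRetained + 6L) {
        a <- unifInt(3L, len - 3L - minRetained)
        b <- unifInt(a + minRetained, len - 3L)
        out <- c(out, b - a)
      } else out <- c(out, len - 6L)
    }
    out[out >= 1L]
  })
}
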