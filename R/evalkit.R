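# Evaluation protocol: stop-codon-match / whole-CDS-match confusion counts,
# the metric formulas (precision, recall, F1, and specificity in both its
# printed and standard forms), and the standard test-set constructions
# (strand-blind flip, NoStart / NoStop / NoStart&NoStop truncations, 3'UTR
# negatives, mixed positive/negative runs).

#' Construct evaluation confusion counts
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @param criterion "stop_match", "full_cds_match" or "any_call".
#' @return an [EvalOutcome-class].
#' @export
evalOutcome <- function(tp = 0L, fp = 0L, fn = 0L, tn = 0L,
                        criterion = "stop_match") {
  new("EvalOutcome", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn), criterion = criterion)
}

#' Match one prediction against its reference
#'
#' A missing prediction is a false negative.  Under `stop_match` a
#' prediction is a true positive iff its stop codon coincides with the
#' reference stop codon on the same strand; under `full_cds_match` iff
#' start, end and strand all coincide; any other prediction is a false
#' positive.  Under `any_call` (negative sets) any prediction is "FP" and
#' none is "TN".
#'
#' @param ref one-row reference (list/DataFrame row with `id`, `cdsStart`,
#'   `cdsEnd`, `strand`, `hasStop`).
#' @param call one-row prediction (with `transcriptId`, `start`, `end`,
#'   `strand`, `hasStop`) or `NULL` / NA-start row for no prediction.
#' @param criterion matching criterion.
#' @return one of "TP", "FP", "FN" ("FP"/"TN" under `any_call`).
#' @export
matchCall <- function(ref, call,
                      criterion = c("stop_match", "full_cds_match",
                                    "any_call")) {
  criterion <- match.arg(criterion)
  none <- is.null(call) || is.na(call$start)
  if (!none && !is.null(call$transcriptId) && !is.null(ref$id) &&
      call$transcriptId != ref$id)
    stop("transcript id mismatch: ", ref$id, " vs ", call$transcriptId)
  if (criterion == "any_call") return(if (none) "TN" else "FP")
  if (none) return("FN")
  if (criterion == "stop_match") {
    ok <- isTRUE2(ref$hasStop) && isTRUE2(call$hasStop) &&
      call$strand == ref$strand &&
      (if (ref$strand == "+") call$end == ref$cdsEnd
       else call$start == ref$cdsStart)
    return(if (ok) "TP" else "FP")
  }
  ok <- call$start == ref$cdsStart && call$end == ref$cdsEnd &&
    call$strand == ref$strand
  if (ok) "TP" else "FP"
}

#' Tally predictions against a truth table
#'
#' @param truth truth table (see [truthTable()]); rows with `coding` FALSE
#'   are counted under the `any_call` convention (prediction = FP, none =
#'   TN), coding rows under `criterion`.
#' @param calls prediction table from [predictTranscripts()].
#' @param criterion criterion for the coding rows.
#' @return an [EvalOutcome-class]; tp+fp+fn+tn equals the number of rows.
#' @export
evaluatePredictions <- function(truth, calls,
                                criterion = c("stop_match",
                                              "full_cds_match")) {
  criterion <- match.arg(criterion)
  truth <- as.data.frame(truth)
  calls <- as.data.frame(calls)
  idx <- match(truth$id, calls$transcriptId)
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(truth))) {
    ref <- truth[i, ]
    call <- if (is.na(idx[i])) NULL else calls[idx[i], ]
    crit <- if (isTRUE2(ref$coding)) criterion else "any_call"
    lab <- matchCall(ref, call, crit)
    if (lab == "TP") tp <- tp + 1L
    else if (lab == "FP") fp <- fp + 1L
    else if (lab == "FN") fn <- fn + 1L
    else tn <- tn + 1L
  }
  evalOutcome(tp, fp, fn, tn, criterion)
}

#' Precision, recall and F1
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `f1 = 2*precision*recall/(precision+recall)`; each defined as 0 when its
#' denominator is 0.
#'
#' @param out an [EvalOutcome-class].
#' @return named numeric `c(precision, recall, f1)`.
#' @export
precisionRecallF1 <- function(out) {
  tp <- out@tp; fp <- out@fp; fn <- out@fn
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Specificity, in printed and standard forms
#'
#' On a negative set where any prediction counts as a false positive, the
#' quantity `FP/(FP+TN)` is reported together with its complement
#' `TN/(TN+FP)` (the conventional specificity); the two always sum to 1.
#' Both are returned, clearly labeled, and neither is silently corrected
#' into the other.
#'
#' @param out an [EvalOutcome-class] from a negative set.
#' @return named numeric `c(printed_specificity, standard_specificity)`.
#' @export
specificityAsPrinted <- function(out) {
  fp <- out@fp; tn <- out@tn
  if (fp + tn == 0L) stop("empty negative set: fp + tn == 0")
  c(printed_specificity = fp / (fp + tn),
    standard_specificity = tn / (tn + fp))
}

# ---- dataset constructions --------------------------------------------------

# uniform integer draw in [lo, hi]
unifInt <- function(lo, hi) {
  if (hi <= lo) return(lo)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

truncateCorpus <- function(corpus, seed, dropStart, dropStop,
                           minSize = 150L) {
  mc <- S4Vectors::mcols(corpus)
  if (!all(isTRUE2(mc$hasStart) & isTRUE2(mc$hasStop)))
    stop("truncation requires complete annotations")
  withSeed(seed, {
    seqs <- as.character(corpus)
    n <- length(seqs)
    outSeq <- character(n); cs <- integer(n); ce <- integer(n)
    hs <- logical(n); hp <- logical(n); fr <- integer(n)
    keep <- rep(TRUE, n)
    for (i in seq_len(n)) {
      L <- nchar(seqs[i])
      a <- mc$cdsStart[i]; b <- mc$cdsEnd[i]
      cdsLen <- b - a
      if (cdsLen < 9L) { keep[i] <- FALSE; next }
      t1 <- 0L
      t2 <- cdsLen
      if (dropStart && dropStop) {
        # retain only CDS interior; both codons pruned
        if (cdsLen - 6L >= minSize + 6L) {
          t1 <- unifInt(3L, cdsLen - 3L - minSize)
          t2 <- unifInt(t1 + minSize, cdsLen - 3L)
        } else {                      # fallback: prune exactly both codons
          t1 <- 3L; t2 <- cdsLen - 3L
        }
        frag <- substr(seqs[i], a + t1 + 1L, a + t2)
        outSeq[i] <- frag
        cs[i] <- 0L; ce[i] <- nchar(frag)
        hs[i] <- FALSE; hp[i] <- FALSE
        fr[i] <- (3L - (t1 %% 3L)) %% 3L
      } else if (dropStart) {
        lo <- 3L; hi <- cdsLen - 6L
        hiFloor <- L - a - minSize    # need L - (a + t) >= minSize
        hi2 <- min(hi, hiFloor)
        t1 <- if (hi2 >= lo) unifInt(lo, hi2) else 3L
        outSeq[i] <- substr(seqs[i], a + t1 + 1L, L)
        cs[i] <- 0L; ce[i] <- cdsLen - t1
        hs[i] <- FALSE; hp[i] <- TRUE
        fr[i] <- (3L - (t1 %% 3L)) %% 3L
      } else {
        lo <- 6L; hi <- cdsLen - 3L
        loFloor <- minSize - a        # need a + t2 >= minSize
        lo2 <- max(lo, loFloor)
        t2 <- if (lo2 <= hi) unifInt(lo2, hi) else cdsLen - 3L
        outSeq[i] <- substr(seqs[i], 1L, a + t2)
        cs[i] <- a; ce[i] <- a + t2
        hs[i] <- TRUE; hp[i] <- FALSE
        fr[i] <- 0L
      }
    }
    if (any(!keep))
      message(sum(!keep), " transcript(s) excluded (CDS interior too short)")
    transcriptSet(outSeq[keep], names(corpus)[keep],
                  cdsStart = cs[keep], cdsEnd = ce[keep], strand = "+",
                  hasStart = hs[keep], hasStop = hp[keep],
                  frame = fr[keep], coding = TRUE)
  })
}

flipHalf <- function(corpus, seed) {
  withSeed(seed, {
    n <- length(corpus)
    flip <- sort(sample.int(n, n %/% 2L))
    seqs <- as.character(corpus)
    mc <- S4Vectors::mcols(corpus)
    cs <- mc$cdsStart; ce <- mc$cdsEnd
    strand <- rep_len(as.character(mc$strand), n)
    for (i in flip) {
      L <- nchar(seqs[i])
      seqs[i] <- revComp(seqs[i])
      if (!is.na(cs[i])) {
        newCs <- L - ce[i]; newCe <- L - cs[i]
        cs[i] <- newCs; ce[i] <- newCe
      }
      strand[i] <- if (strand[i] == "+") "-" else "+"
    }
    transcriptSet(seqs, names(corpus), cdsStart = cs, cdsEnd = ce,
                  strand = strand, hasStart = mc$hasStart,
                  hasStop = mc$hasStop, frame = mc$frame,
                  coding = mc$coding)
  })
}

#' Build the standard validation sets from a full-length corpus
#'
#' Given full-length transcripts with both codons annotated, returns the
#' named list of derived datasets: the corpus as-is (`FullStrandSpecific`),
#' a copy with a random half replaced by its reverse complement
#' (`FullStrandBlind`), the three truncation sets (`NoStart`, `NoStop`,
#' `NoStartNoStop`; truncation points uniform over admissible CDS offsets
#' subject to a 150 nt minimum resulting size, falling back to pruning
#' exactly at the codon(s) when the transcript is too short), and the
#' complete 3'UTR of each transcript as a negative set (`UTR3Negatives`).
#' Every derived sequence carries updated coordinates, frame and
#' completeness flags.
#'
#' @param corpus annotated DNAStringSet, all records complete.
#' @param seed seed for the truncation and flip draws.
#' @return named list of annotated DNAStringSet objects.
#' @export
buildTestSets <- function(corpus, seed = 1L) {
  mc <- S4Vectors::mcols(corpus)
  if (!all(isTRUE2(mc$hasStart) & isTRUE2(mc$hasStop)))
    stop("buildTestSets requires full-length annotated transcripts")
  u3 <- as.character(Biostrings::subseq(
    corpus, start = mc$cdsEnd + 1L, end = Biostrings::width(corpus)))
  nonempty <- nchar(u3) > 0L
  if (any(!nonempty))
    message(sum(!nonempty), " transcript(s) without 3'UTR excluded from ",
            "UTR3Negatives")
  list(
    FullStrandSpecific = corpus,
    FullStrandBlind = flipHalf(corpus, seed + 1L),
    NoStart = truncateCorpus(corpus, seed + 2L, TRUE, FALSE),
    NoStop = truncateCorpus(corpus, seed + 3L, FALSE, TRUE),
    NoStartNoStop = truncateCorpus(corpus, seed + 4L, TRUE, TRUE),
    UTR3Negatives = transcriptSet(u3[nonempty],
                                  paste0(names(corpus)[nonempty], "_utr3"),
                                  coding = FALSE))
}

#' Assemble a mixed positive/negative evaluation run
#'
#' Concatenates full-length transcripts, partial transcripts and non-coding
#' negatives (each negative must be at least 200 nt; shorter ones are
#' dropped) into one seeded-shuffled dataset with a coding truth table.
#' When fewer sequences than requested are available the counts scale down
#' with a warning.
#'
#' @param full,partial annotated coding corpora.
#' @param negatives non-coding corpus (e.g. `UTR3Negatives` or generated
#'   ncRNA stand-ins).
#' @param seed shuffle seed.
#' @param nFull,nPartial requested counts from each positive set.
#' @return annotated DNAStringSet with an `origin` column in `mcols()`.
#' @export
buildMixedNegativeSet <- function(full, partial, negatives, seed = 1L,
                                  nFull = 500L, nPartial = 500L) {
  if (length(negatives) == 0L) stop("negatives must be non-empty")
  keep <- Biostrings::width(negatives) >= 200L
  negatives <- negatives[keep]
  if (length(negatives) == 0L)
    stop("no negatives of length >= 200 nt")
  if (length(full) < nFull || length(partial) < nPartial)
    warning("fewer positives than requested; scaling counts down")
  nFull <- min(nFull, length(full))
  nPartial <- min(nPartial, length(partial))
  pick <- function(x, n, tag) {
    x <- x[seq_len(n)]
    mc <- S4Vectors::mcols(x)
    names(x) <- paste0(tag, ":", names(x))
    S4Vectors::mcols(x) <- cbind(mc, S4Vectors::DataFrame(
      origin = rep(tag, length(x))))
    x
  }
  parts <- list(pick(full, nFull, "full"),
                pick(partial, nPartial, "partial"),
                pick(negatives, length(negatives), "negative"))
  all <- do.call(c, parts)
  withSeed(seed, all[sample.int(length(all))])
}
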