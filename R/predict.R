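# Prediction orchestration: GC-bin selection, full vs partial architecture,
# strand-specific vs strand-blind decoding, the coding/non-coding gate and
# batch prediction.

emptyCall <- function(id, gc = NA_real_, bin = NA_integer_,
                      outcome = "no_call") {
  list(transcriptId = id, start = NA_integer_, end = NA_integer_,
       strand = NA_character_, frame = NA_integer_, hasStart = NA,
       hasStop = NA, logScore = NA_real_, noncodingScore = NA_real_,
       modelTag = NA_character_, gcBin = bin, gc = gc, outcome = outcome)
}

decodeOneStrand <- function(arch, seq) {
  path <- viterbiDecode(arch, seq)
  if (is.null(path)) return(NULL)
  extractCdsCall(path, nchar(seq))
}

#' Predict the CDS of one transcript
#'
#' Selects the GC sub-model from the whole transcript's GC fraction,
#' decodes with the requested architecture and, in strand-blind mode
#' (`strand = "both"`), also decodes the reverse complement with the same
#' strand-specific model, keeping the higher-scoring call mapped back to
#' input coordinates (plus strand wins exact ties).  A call is emitted only
#' when the best coding path outscores the best non-coding path by at
#' least `margin`.
#'
#' @param bundle a [TrainedBundle-class].
#' @param seq nucleotide string (or DNAString).
#' @param id transcript identifier carried into the call.
#' @param mode "full" (complete transcripts) or "partial".
#' @param strand "plus" (strand-specific) or "both" (strand-blind).
#' @param margin required log-score margin of the best coding path over
#'   the best non-coding path (>= 0).
#' @param minLen sequences shorter than this yield no call.
#' @return a one-row call list (see [predictTranscripts()] for the
#'   columns); `outcome` is "called", "no_call" or "too_short".
#' @export
predictCds <- function(bundle, seq, id = "seq1",
                       mode = c("full", "partial"),
                       strand = c("plus", "both"), margin = 0,
                       minLen = 60L) {
  mode <- match.arg(mode)
  strand <- match.arg(strand)
  stopifnot(margin >= 0)
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  if (L < minLen) return(emptyCall(id, outcome = "too_short"))
  gc <- gcFraction(seq)
  bin <- assignBin(bundle, gc)
  arch <- bundle@bins[[bin]][[mode]]
  plusCall <- decodeOneStrand(arch, seq)
  call <- plusCall
  callStrand <- "+"
  if (strand == "both") {
    rcCall <- decodeOneStrand(arch, revComp(seq))
    if (!is.null(rcCall) &&
        (is.null(plusCall) || rcCall$logScore > plusCall$logScore)) {
      # map back to input coordinates
      rcCall[c("start", "end")] <- list(L - rcCall$end, L - rcCall$start)
      call <- rcCall
      callStrand <- "-"
    }
  }
  if (is.null(call)) return(emptyCall(id, gc, bin))
  ncs <- noncodingScore(arch, if (callStrand == "+") seq else revComp(seq))
  if (is.finite(ncs) && call$logScore < ncs + margin)
    return(emptyCall(id, gc, bin))
  list(transcriptId = id, start = call$start, end = call$end,
       strand = callStrand, frame = call$frame, hasStart = call$hasStart,
       hasStop = call$hasStop, logScore = call$logScore,
       noncodingScore = ncs, modelTag = mode, gcBin = bin, gc = gc,
       outcome = "called")
}

#' Predict CDSs for a set of transcripts
#'
#' Pure per-sequence computation: results are in input order and identical
#' for any number of workers.  Per-sequence errors are isolated (outcome
#' "error") and the batch continues.
#'
#' @param bundle a [TrainedBundle-class].
#' @param transcripts DNAStringSet (or named character vector).
#' @param mode,strand,margin,minLen see [predictCds()].
#' @param workers number of worker processes ([parallel::mclapply]).
#' @return a [S4Vectors::DataFrame] with one row per transcript:
#'   `transcriptId`, `start`, `end` (0-based half-open, input
#'   orientation), `strand`, `frame`, `hasStart`, `hasStop`, `logScore`,
#'   `noncodingScore`, `modelTag`, `gcBin`, `gc`, `outcome`.
#' @export
predictTranscripts <- function(bundle, transcripts,
                               mode = c("full", "partial"),
                               strand = c("plus", "both"), margin = 0,
                               minLen = 60L, workers = 1L) {
  mode <- match.arg(mode)
  strand <- match.arg(strand)
  seqs <- as.character(transcripts)
  ids <- names(transcripts)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  worker <- function(i) {
    tryCatch(predictCds(bundle, seqs[i], ids[i], mode, strand, margin,
                        minLen),
             error = function(e) {
               out <- emptyCall(ids[i], outcome = "error")
               out$reason <- conditionMessage(e)
               out
             })
  }
  res <- if (workers > 1L)
    parallel::mclapply(seq_along(seqs), worker, mc.cores = workers,
                       mc.preschedule = TRUE)
  else lapply(seq_along(seqs), worker)
  callsToDataFrame(res)
}

callsToDataFrame <- function(res) {
  S4Vectors::DataFrame(
    transcriptId = vapply(res, `[[`, character(1), "transcriptId"),
    start = vapply(res, function(x) as.integer(x$start), integer(1)),
    end = vapply(res, function(x) as.integer(x$end), integer(1)),
    strand = vapply(res, function(x) as.character(x$strand), character(1)),
    frame = vapply(res, function(x) as.integer(x$frame), integer(1)),
    hasStart = vapply(res, function(x) as.logical(x$hasStart), logical(1)),
    hasStop = vapply(res, function(x) as.logical(x$hasStop), logical(1)),
    logScore = vapply(res, function(x) as.numeric(x$logScore), numeric(1)),
    noncodingScore = vapply(res, function(x)
      as.numeric(x$noncodingScore), numeric(1)),
    modelTag = vapply(res, function(x) as.character(x$modelTag),
                      character(1)),
    gcBin = vapply(res, function(x) as.integer(x$gcBin), integer(1)),
    gc = vapply(res, function(x) as.numeric(x$gc), numeric(1)),
    outcome = vapply(res, `[[`, character(1), "outcome"))
}

#' Classify a sequence as coding or non-coding
#'
#' A sequence is called coding iff strand-blind prediction yields a call
#' whose log score exceeds the best non-coding path's log score by at
#' least `margin`.
#'
#' @param bundle a [TrainedBundle-class].
#' @param seq nucleotide string.
#' @param margin classification margin (`Inf` forces "noncoding").
#' @param mode architecture used for the decision.
#' @param strand decoding mode (default strand-blind).
#' @return `"coding"` or `"noncoding"`.
#' @export
classifyCoding <- function(bundle, seq, margin = 0,
                           mode = c("full", "partial"),
                           strand = c("both", "plus")) {
  mode <- match.arg(mode)
  strand <- match.arg(strand)
  if (is.infinite(margin) && margin > 0) return("noncoding")
  call <- predictCds(bundle, seq, mode = mode, strand = strand,
                     margin = margin)
  if (call$outcome == "called") "coding" else "noncoding"
}
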