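# Synthetic transcript generator: ground-truth corpora with the statistical
# structure the GHMM assumes (5'UTR + ATG + in-frame sense-codon run + stop
# codon + 3'UTR), plus compositional non-coding negatives standing in for
# ncRNA.  Everything is deterministic under the config seed.

ALL_CODONS <- as.vector(outer(outer(DNA_BASES4, DNA_BASES4, paste0),
                              DNA_BASES4, paste0))
SENSE_CODONS <- setdiff(sort(ALL_CODONS), STOP_CODONS)

#' Synthetic corpus generator configuration
#'
#' @slot seed RNG seed.
#' @slot n number of records to generate.
#' @slot codonUsage named probability vector over the 61 sense codons.
#' @slot stopUsage named probability vector over TAA, TAG, TGA.
#' @slot utr5Comp,utr3Comp,ncComp base compositions (A,C,G,T) of the 5'UTR,
#'   3'UTR and non-coding sequences.
#' @slot startContext 6 x 4 matrix of per-column base probabilities for the
#'   six bases immediately upstream of the start codon (Kozak-like context).
#' @slot lenCds,lenUtr5,lenUtr3,lenNoncoding length distributions as
#'   `c(meanlog, sdlog, min, max)` of a rounded, clamped log-normal;
#'   `lenCds` counts sense codons between the start and stop codons, the
#'   others count bases.
#' @slot gcTarget numeric(0), or `c(mean, tol)` for per-sequence GC
#'   rejection sampling.
#' @slot fracNoncoding fraction of generated records that are non-coding.
#' @export
setClass("GeneratorConfig",
  representation(seed = "integer", n = "integer", codonUsage = "numeric",
                 stopUsage = "numeric", utr5Comp = "numeric",
                 utr3Comp = "numeric", ncComp = "numeric",
                 startContext = "matrix", lenCds = "numeric",
                 lenUtr5 = "numeric", lenUtr3 = "numeric",
                 lenNoncoding = "numeric", gcTarget = "numeric",
                 fracNoncoding = "numeric"))

setValidity("GeneratorConfig", function(object) {
  if (length(object@codonUsage) != 61 ||
      abs(sum(object@codonUsage) - 1) > 1e-9)
    return("codonUsage must be a normalized vector over 61 sense codons")
  if (!identical(names(object@codonUsage), SENSE_CODONS))
    return("codonUsage must be named by the sorted sense codons")
  if (abs(sum(object@stopUsage) - 1) > 1e-9 ||
      !identical(names(object@stopUsage), STOP_CODONS))
    return("stopUsage must be normalized over TAA, TAG, TGA")
  for (nm in c("utr5Comp", "utr3Comp", "ncComp")) {
    v <- slot(object, nm)
    if (length(v) != 4 || abs(sum(v) - 1) > 1e-9)
      return(paste(nm, "must be a normalized length-4 composition"))
  }
  if (!all(dim(object@startContext) == c(6, 4)) ||
      any(abs(rowSums(object@startContext) - 1) > 1e-9))
    return("startContext must be a 6 x 4 matrix with normalized rows")
  for (nm in c("lenCds", "lenUtr5", "lenUtr3", "lenNoncoding")) {
    v <- slot(object, nm)
    if (length(v) != 4 || v[3] > v[4] || v[3] < 0)
      return(paste(nm, "must be c(meanlog, sdlog, min, max)"))
  }
  if (object@lenCds[3] < 2)
    return("lenCds support must be at least 2 codons")
  if (!length(object@gcTarget) %in% c(0L, 2L))
    return("gcTarget must be numeric(0) or c(mean, tol)")
  if (object@fracNoncoding < 0 || object@fracNoncoding > 1)
    return("fracNoncoding must be in [0, 1]")
  TRUE
})

# run expr under a private RNG stream, restoring global RNG state afterwards
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Codon usage tables of controllable signal strength
#'
#' `"strong"` draws i.i.d. exponential weights (markedly non-uniform usage,
#' the default study condition); `"weak"` is near-uniform, for hard-case
#' testing.  The table is deterministic for a given preset and seed.
#'
#' @param preset "strong" or "weak".
#' @param seed seed of the table's private RNG stream.
#' @return named probability vector over the 61 sense codons.
#' @export
codonUsageTable <- function(preset = c("strong", "weak"), seed = 101L) {
  preset <- match.arg(preset)
  w <- withSeed(seed, stats::rexp(61))
  if (preset == "weak") w <- 1 + 0.1 * w
  setNames(w / sum(w), SENSE_CODONS)
}

#' Build a generator configuration
#'
#' Defaults describe a realistic strong-signal eukaryotic mRNA corpus:
#' median CDS of ~150 sense codons, median 5'UTR of 80 nt and 3'UTR of
#' 150 nt (rounded clamped log-normals), AT-leaning UTR compositions, a
#' Kozak-like start context and exponential-weight codon usage.
#'
#' @param seed,n RNG seed and corpus size.
#' @param codonUsage,stopUsage,utr5Comp,utr3Comp,ncComp,startContext,
#'   lenCds,lenUtr5,lenUtr3,lenNoncoding,gcTarget,fracNoncoding see
#'   [GeneratorConfig-class].
#' @return a validated [GeneratorConfig-class].
#' @export
generatorConfig <- function(seed = 1L, n = 100L,
                            codonUsage = codonUsageTable("strong"),
                            stopUsage = c(TAA = 0.45, TAG = 0.2, TGA = 0.35),
                            utr5Comp = c(A = 0.30, C = 0.22, G = 0.18, T = 0.30),
                            utr3Comp = c(A = 0.32, C = 0.18, G = 0.17, T = 0.33),
                            ncComp = c(A = 0.31, C = 0.20, G = 0.18, T = 0.31),
                            startContext = kozakContext(),
                            lenCds = c(log(150), 0.35, 50, 600),
                            lenUtr5 = c(log(80), 0.6, 10, 400),
                            lenUtr3 = c(log(150), 0.6, 10, 800),
                            lenNoncoding = c(log(400), 0.5, 200, 2000),
                            gcTarget = numeric(0),
                            fracNoncoding = 0) {
  new("GeneratorConfig", seed = as.integer(seed), n = as.integer(n),
      codonUsage = codonUsage, stopUsage = stopUsage,
      utr5Comp = utr5Comp, utr3Comp = utr3Comp, ncComp = ncComp,
      startContext = startContext, lenCds = as.numeric(lenCds),
      lenUtr5 = as.numeric(lenUtr5), lenUtr3 = as.numeric(lenUtr3),
      lenNoncoding = as.numeric(lenNoncoding),
      gcTarget = as.numeric(gcTarget),
      fracNoncoding = as.numeric(fracNoncoding))
}

#' Kozak-like start-codon context matrix
#'
#' Six upstream columns with a gccacc-style consensus at 70% per column.
#'
#' @param strength consensus base probability per column.
#' @return 6 x 4 matrix (columns A,C,G,T).
#' @export
kozakContext <- function(strength = 0.7) {
  cons <- c("G", "C", "C", "A", "C", "C")
  m <- matrix((1 - strength) / 3, nrow = 6, ncol = 4,
              dimnames = list(NULL, DNA_BASES4))
  m[cbind(1:6, match(cons, DNA_BASES4))] <- strength
  m
}

sampleLen <- function(spec, n) {
  v <- round(stats::rlnorm(n, spec[1], spec[2]))
  pmin(pmax(v, spec[3]), spec[4])
}

#' Exact pmf of a generator length distribution
#'
#' The rounded, clamped log-normal used by the generator, as an exact pmf
#' over `min..max` (boundary mass lumped at the clamps).
#'
#' @param spec `c(meanlog, sdlog, min, max)`.
#' @return named numeric pmf.
#' @export
lengthDistPmf <- function(spec) {
  k <- spec[3]:spec[4]
  p <- stats::plnorm(k + 0.5, spec[1], spec[2]) -
    stats::plnorm(k - 0.5, spec[1], spec[2])
  p[1] <- stats::plnorm(spec[3] + 0.5, spec[1], spec[2])
  p[length(p)] <- 1 - stats::plnorm(spec[4] - 0.5, spec[1], spec[2])
  setNames(p, k)
}

sampleComp <- function(comp, n) {
  if (n == 0L) return("")
  paste(sample(DNA_BASES4, n, replace = TRUE, prob = comp), collapse = "")
}

generateOnePositive <- function(cfg) {
  u5len <- sampleLen(cfg@lenUtr5, 1L)
  u3len <- sampleLen(cfg@lenUtr3, 1L)
  ncod <- sampleLen(cfg@lenCds, 1L)
  u5 <- sampleComp(cfg@utr5Comp, u5len)
  nctx <- min(6L, u5len)
  if (nctx > 0L) {
    ctxCols <- (6L - nctx + 1L):6L
    ctx <- vapply(ctxCols, function(j)
      sample(DNA_BASES4, 1L, prob = cfg@startContext[j, ]), character(1))
    substr(u5, u5len - nctx + 1L, u5len) <- paste(ctx, collapse = "")
  }
  body <- paste(sample(SENSE_CODONS, ncod, replace = TRUE,
                       prob = cfg@codonUsage), collapse = "")
  stopc <- sample(STOP_CODONS, 1L, prob = cfg@stopUsage)
  u3 <- sampleComp(cfg@utr3Comp, u3len)
  seq <- paste0(u5, "ATG", body, stopc, u3)
  list(seq = seq, cdsStart = u5len, cdsEnd = u5len + 6L + 3L * ncod)
}

#' Generate a synthetic transcript corpus
#'
#' Positives are 5'UTR + ATG + sense-codon run (no in-frame stop by
#' construction) + stop codon + 3'UTR with exact reference annotations;
#' negatives are drawn from the non-coding composition with no constraint
#' against chance ORFs.  Fully deterministic under `cfg@seed`.
#'
#' @param cfg a [GeneratorConfig-class].
#' @return annotated DNAStringSet (see [transcriptSet()]); `mcols()$coding`
#'   is the truth label.
#' @export
generateCorpus <- function(cfg) {
  validObject(cfg)
  withSeed(cfg@seed, {
    nPos <- cfg@n - as.integer(round(cfg@n * cfg@fracNoncoding))
    nNeg <- cfg@n - nPos
    seqs <- character(cfg@n)
    cs <- rep(NA_integer_, cfg@n); ce <- rep(NA_integer_, cfg@n)
    coding <- c(rep(TRUE, nPos), rep(FALSE, nNeg))
    for (i in seq_len(nPos)) {
      attempts <- 0L
      repeat {
        rec <- generateOnePositive(cfg)
        if (length(cfg@gcTarget) == 0L) break
        gc <- gcFraction(rec$seq)
        if (abs(gc - cfg@gcTarget[1]) <= cfg@gcTarget[2]) break
        attempts <- attempts + 1L
        if (attempts >= 200L)
          stop("gcTarget infeasible after 200 rejection attempts")
      }
      seqs[i] <- rec$seq
      cs[i] <- rec$cdsStart; ce[i] <- rec$cdsEnd
    }
    for (i in seq_len(nNeg)) {
      len <- sampleLen(cfg@lenNoncoding, 1L)
      seqs[nPos + i] <- sampleComp(cfg@ncComp, len)
    }
    ids <- c(sprintf("tx%05d", seq_len(nPos)),
             if (nNeg > 0L) sprintf("nc%05d", seq_len(nNeg)))
    transcriptSet(seqs, ids, cdsStart = cs, cdsEnd = ce, strand = "+",
                  hasStart = coding, hasStop = coding,
                  frame = ifelse(coding, 0L, NA_integer_), coding = coding)
  })
}

#' Truth table of an annotated corpus
#'
#' @param corpus annotated DNAStringSet.
#' @return DataFrame with id, coding status and, when coding, exact
#'   reference coordinates, strand, completeness flags and frame.
#' @export
truthTable <- function(corpus) {
  mc <- S4Vectors::mcols(corpus)
  S4Vectors::DataFrame(id = names(corpus), width = Biostrings::width(corpus),
                       mc)
}

#' Degrade a corpus into a partial / strand-scrambled variant
#'
#' Applies one of the standard test-set constructions to the coding records
#' of a complete corpus (see [buildTestSets()] for the semantics):
#' truncations removing the start codon, the stop codon or both (150 nt
#' minimum retained, with the prune-at-codon fallback), or reverse
#' complementing of a random half.
#'
#' @param corpus annotated DNAStringSet with complete annotations.
#' @param kind one of "no_start", "no_stop", "no_start_no_stop",
#'   "strand_blind".
#' @param seed RNG seed for the truncation / flip draws.
#' @return annotated DNAStringSet with updated coordinates and flags.
#' @export
degradeCorpus <- function(corpus,
                          kind = c("no_start", "no_stop",
                                   "no_start_no_stop", "strand_blind"),
                          seed = 1L) {
  kind <- match.arg(kind)
  coding <- isTRUE2(S4Vectors::mcols(corpus)$coding)
  sub <- corpus[coding]
  switch(kind,
         no_start = truncateCorpus(sub, seed, dropStart = TRUE,
                                   dropStop = FALSE),
         no_stop = truncateCorpus(sub, seed, dropStart = FALSE,
                                  dropStop = TRUE),
         no_start_no_stop = truncateCorpus(sub, seed, dropStart = TRUE,
                                           dropStop = TRUE),
         strand_blind = flipHalf(sub, seed))
}
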