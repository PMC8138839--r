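# Transcript input/output: FASTA reading with strict alphabet validation,
# annotated transcript containers (DNAStringSet + mcols), and the four-file
# output contract (CDS / 5'UTR / 3'UTR FASTA plus a 9-column GTF).

#' Assemble an annotated transcript set
#'
#' Transcripts are held as a [Biostrings::DNAStringSet] whose `mcols()`
#' carry the optional reference CDS annotation in internal coordinates
#' (0-based half-open, input orientation).
#'
#' @param seqs character vector of sequences over \{A,C,G,T,N\} or a
#'   DNAStringSet.
#' @param ids unique whitespace-free identifiers.
#' @param cdsStart,cdsEnd 0-based half-open CDS bounds (NA when unannotated).
#' @param strand "+" or "-" (input orientation of the coding strand).
#' @param hasStart,hasStop completeness flags.
#' @param frame offset (0..2) of the first complete codon within the CDS
#'   interval.
#' @param coding logical truth label (for generated / evaluation corpora).
#' @return a DNAStringSet with annotation columns in `mcols()`.
#' @export
transcriptSet <- function(seqs, ids = names(seqs), cdsStart = NA_integer_,
                          cdsEnd = NA_integer_, strand = "+",
                          hasStart = NA, hasStop = NA, frame = NA_integer_,
                          coding = NA) {
  if (is.character(seqs)) {
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad))
      stop("invalid nucleotide characters in record(s): ",
           paste(head(ids[bad], 5), collapse = ", "))
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  n <- length(seqs)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  if (anyDuplicated(ids)) stop("duplicate transcript ids")
  if (any(grepl("\\s", ids))) stop("transcript ids must not contain whitespace")
  names(seqs) <- ids
  S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
    cdsStart = as.integer(rep_len(cdsStart, n)),
    cdsEnd = as.integer(rep_len(cdsEnd, n)),
    strand = rep_len(strand, n),
    hasStart = rep_len(hasStart, n),
    hasStop = rep_len(hasStop, n),
    frame = as.integer(rep_len(frame, n)),
    coding = rep_len(coding, n))
  validateAnnotations(seqs)
  seqs
}

validateAnnotations <- function(ts) {
  mc <- S4Vectors::mcols(ts)
  ann <- !is.na(mc$cdsStart)
  if (!any(ann)) return(invisible(ts))
  w <- Biostrings::width(ts)[ann]
  s <- mc$cdsStart[ann]; e <- mc$cdsEnd[ann]
  if (any(s < 0L | s >= e | e > w))
    stop("reference CDS coordinates out of range")
  both <- ann & isTRUE2(mc$hasStart) & isTRUE2(mc$hasStop)
  if (any(both)) {
    len <- mc$cdsEnd[both] - mc$cdsStart[both]
    if (any(len %% 3L != 0L) || any(mc$frame[both] != 0L))
      stop("complete CDS annotations must have length %% 3 == 0 and frame 0")
  }
  if (any(ann & isTRUE2(mc$hasStart) & mc$frame != 0L))
    stop("annotations with a start codon must have frame 0")
  invisible(ts)
}

isTRUE2 <- function(x) !is.na(x) & x

#' Read transcripts from a FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet()] with the package's alphabet
#' contract: sequences are uppercased, must be non-empty and may contain
#' only A, C, G, T or N; the first record must start with a header line.
#'
#' @param path FASTA file (wrapped or single-line; lowercase permitted).
#' @return a DNAStringSet with empty annotation columns (see
#'   [transcriptSet()]).
#' @export
readTranscripts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- which(nzchar(trimws(first)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(first[nonblank[1]]), ">"))
    stop(sprintf("malformed FASTA: sequence before header at line %d of %s",
                 nonblank[1], path))
  x <- Biostrings::readBStringSet(path)   # strict: keep bytes for validation
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) stop("duplicate transcript ids in ", path)
  sq <- toupper(as.character(x))
  if (any(Biostrings::width(x) == 0L))
    stop("empty sequence for record ",
         ids[which(Biostrings::width(x) == 0L)[1]])
  bad <- grepl("[^ACGTN]", sq)
  if (any(bad)) {
    ch <- gsub("[ACGTN]", "", sq[bad][1])
    stop(sprintf("disallowed character(s) '%s' in record %s",
                 substr(ch, 1, 5), ids[bad][1]))
  }
  transcriptSet(sq, ids)
}

# region of `seq` on the coding strand: for minus calls the extracted
# subsequence is reverse-complemented
orientedRegion <- function(seq, from, to, strand) {
  if (to <= from) return("")
  sub <- substr(seq, from + 1L, to)
  if (strand == "-") revComp(sub) else sub
}

#' Read CDS annotations from a GTF file onto a transcript set
#'
#' Reads 9-column GTF `CDS` feature lines (the dialect written by
#' [writePredictions()]: seqname = transcript id, 1-based inclusive
#' coordinates in input orientation) and attaches them as reference CDS
#' annotations to `transcripts`.  Completeness flags are taken from
#' `has_start` / `has_stop` attributes when present, else assumed TRUE.
#'
#' @param path GTF file.
#' @param transcripts DNAStringSet to annotate.
#' @return `transcripts` with filled annotation columns.
#' @export
readCdsAnnotations <- function(path, transcripts) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  mc <- S4Vectors::mcols(transcripts)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop("malformed GTF line (", length(f), " fields): ", substr(ln, 1, 60))
    if (f[3] != "CDS") next
    id <- f[1]
    i <- match(id, names(transcripts))
    if (is.na(i)) stop("GTF annotation for unknown transcript: ", id)
    attr1 <- function(key, default) {
      m <- regmatches(f[9], regexec(paste0(key, ' "([^"]*)"'), f[9]))[[1]]
      if (length(m) < 2) default else m[2]
    }
    mc$cdsStart[i] <- as.integer(f[4]) - 1L
    mc$cdsEnd[i] <- as.integer(f[5])
    mc$strand[i] <- f[7]
    mc$frame[i] <- suppressWarnings(as.integer(f[8]))
    mc$hasStart[i] <- !identical(attr1("has_start", "true"), "false")
    mc$hasStop[i] <- !identical(attr1("has_stop", "true"), "false")
    mc$coding[i] <- TRUE
  }
  S4Vectors::mcols(transcripts) <- mc
  validateAnnotations(transcripts)
  transcripts
}

#' Write prediction outputs
#'
#' Writes the tool's four-file contract into `outdir`: `CDS.fasta`,
#' `UTR5.fasta`, `UTR3.fasta` (a record appears only when the region is
#' non-empty; minus-strand regions are reverse-complemented onto the coding
#' strand) and `predictions.gtf` with one 9-column CDS feature line per
#' called transcript.  GTF coordinates are 1-based inclusive on the input
#' transcript in input orientation; attributes carry the completeness flags.
#'
#' @param transcripts DNAStringSet of the input transcripts.
#' @param calls prediction table as returned by [predictTranscripts()]
#'   (rows with NA `start` are uncalled and are omitted everywhere).
#' @param outdir output directory (created if needed).
#' @param source GTF source column value.
#' @return invisibly, the four file paths.
#' @export
writePredictions <- function(transcripts, calls, outdir,
                             source = "transcds") {
  ids <- names(transcripts)
  if (anyDuplicated(ids)) stop("duplicate transcript ids")
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", outdir)
  }
  calls <- as.data.frame(calls)
  called <- calls[!is.na(calls$start), , drop = FALSE]
  validateCalls(called, transcripts)
  paths <- file.path(outdir, c("CDS.fasta", "UTR5.fasta", "UTR3.fasta",
                               "predictions.gtf"))
  cdsRec <- character(0); u5Rec <- character(0); u3Rec <- character(0)
  gtf <- character(0)
  for (i in seq_len(nrow(called))) {
    cl <- called[i, ]
    id <- cl$transcriptId
    seq <- as.character(transcripts[[id]])
    L <- nchar(seq)
    if (cl$strand == "+") {
      cds <- orientedRegion(seq, cl$start, cl$end, "+")
      u5 <- orientedRegion(seq, 0L, cl$start, "+")
      u3 <- orientedRegion(seq, cl$end, L, "+")
    } else {
      cds <- orientedRegion(seq, cl$start, cl$end, "-")
      u5 <- orientedRegion(seq, cl$end, L, "-")
      u3 <- orientedRegion(seq, 0L, cl$start, "-")
    }
    cdsRec[id] <- cds
    if (nzchar(u5)) u5Rec[id] <- u5
    if (nzchar(u3)) u3Rec[id] <- u3
    attrs <- sprintf(
      'transcript_id "%s"; has_start "%s"; has_stop "%s"; model "%s";',
      id, tolower(cl$hasStart), tolower(cl$hasStop),
      if (is.null(cl$modelTag) || is.na(cl$modelTag)) "full" else cl$modelTag)
    gtf <- c(gtf, paste(id, source, "CDS", cl$start + 1L, cl$end,
                        sprintf("%.3f", cl$logScore), cl$strand, cl$frame,
                        attrs, sep = "\t"))
  }
  writeFasta(cdsRec, paths[1])
  writeFasta(u5Rec, paths[2])
  writeFasta(u3Rec, paths[3])
  writeLines(gtf, paths[4])
  invisible(paths)
}

writeFasta <- function(named, path) {
  if (length(named) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(named)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

# boundary assertions on emitted calls (CdsCall invariants)
validateCalls <- function(called, transcripts) {
  if (nrow(called) == 0L) return(invisible(TRUE))
  if (!all(called$transcriptId %in% names(transcripts)))
    stop("call for unknown transcript id")
  w <- Biostrings::width(transcripts)[match(called$transcriptId,
                                            names(transcripts))]
  if (any(called$start < 0L | called$start >= called$end | called$end > w))
    stop("call coordinates out of range")
  both <- isTRUE2(called$hasStart) & isTRUE2(called$hasStop)
  for (i in which(both)) {
    cl <- called[i, ]
    if ((cl$end - cl$start) %% 3L != 0L)
      stop("complete call with length not a multiple of 3: ",
           cl$transcriptId)
    seq <- as.character(transcripts[[cl$transcriptId]])
    cds <- orientedRegion(seq, cl$start, cl$end, cl$strand)
    if (substr(cds, 1, 3) != "ATG" ||
        !substr(cds, nchar(cds) - 2, nchar(cds)) %in% STOP_CODONS)
      stop("complete call does not begin ATG / end in a stop codon: ",
           cl$transcriptId)
  }
  invisible(TRUE)
}
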