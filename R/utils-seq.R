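# Low-level sequence primitives shared across modules.  Internal coordinates
# are 0-based half-open throughout; serialization converts to 1-based
# inclusive (GTF convention).

#' Encode a nucleotide string as integer codes
#'
#' A,C,G,T map to 1..4; N maps to NA (the marginalization symbol).  Any
#' other character is an error.
#'
#' @param seq character scalar over \{A,C,G,T,N\} (uppercase).
#' @return integer vector of length `nchar(seq)`.
#' @keywords internal
encodeSeq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(v, c("A", "C", "G", "T"))
  bad <- is.na(code) & v != "N"
  if (any(bad))
    stop("invalid nucleotide character(s): ",
         paste(unique(v[bad]), collapse = ", "))
  code
}

#' Reverse complement of a nucleotide string
#'
#' Standard Watson-Crick complement, reversed; N maps to N.  Thin wrapper
#' around [Biostrings::reverseComplement()].
#'
#' @param seq character scalar over \{A,C,G,T,N\}.
#' @return character scalar.
#' @examples
#' revComp("ATGC")   # "GCAT"
#' revComp("AAANN")  # "NNTTT"
#' @export
revComp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl("[^ACGTN]", seq))
    stop("invalid nucleotide character in sequence")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Codon at 0-based offset `at` of `seq` (character scalar), or NA if truncated.
codonAt <- function(seq, at) {
  if (at + 3L > nchar(seq)) return(NA_character_)
  substr(seq, at + 1L, at + 3L)
}

# 0-based context index per position: index over the k preceding bases,
# weight 4^(j-1) for the base j steps back.  NA where the context window
# leaves the sequence or contains N.
contextIndex <- function(codes, k) {
  L <- length(codes)
  if (k == 0L) return(rep(1L, L))
  idx <- rep(1, L)
  for (j in seq_len(k)) {
    prev <- c(rep(NA_integer_, j), codes[seq_len(L - j)])
    idx <- idx + (prev - 1) * 4^(j - 1)
  }
  as.integer(idx)
}

# Context strings (oldest base first) in index order, for readable tables.
contextStrings <- function(k) {
  if (k == 0L) return("")
  g <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                   stringsAsFactors = FALSE)
  # column j of g is the base j steps back; string shows oldest..newest
  apply(g[, rev(seq_len(k)), drop = FALSE], 1L, paste, collapse = "")
}
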