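`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random DNA sequence
#'
#' @param n Length in bp.
#' @param gc Target GC fraction (base composition, not a hard constraint).
#' @return A character scalar over A/C/G/T.
#' @export
random_dna <- function(n, gc = 0.44) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of a character DNA sequence
#' @param seq Character scalar or vector over A/C/G/T/N.
#' @return Reverse-complemented sequence(s).
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# substring of a chromosome held as a plain character string (1-based closed)
subseq_chr <- function(seq, start, end) {
  substr(seq, max(1L, start), min(nchar(seq), end))
}

# cached nucleotide substitution matrix: explicit matrices avoid
# pairwiseAlignment's per-call construction of quality-based ones
.align_cache <- new.env(parent = emptyenv())
dna_submat <- function() {
  if (is.null(.align_cache$mat)) {
    .align_cache$mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE)
  }
  .align_cache$mat
}

# merged (union) length of a set of integer intervals clipped to [lo, hi]
interval_union_length <- function(starts, ends, lo = -Inf, hi = Inf) {
  if (length(starts) == 0L) return(0L)
  s <- pmax(starts, lo); e <- pmin(ends, hi)
  keep <- s <= e
  if (!any(keep)) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = s[keep], end = e[keep]))
  sum(IRanges::width(ir))
}
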