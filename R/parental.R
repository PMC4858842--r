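#' Mask intervals of a sequence with N
#'
#' @param seq Character sequence.
#' @param hits data.frame with `start, end` in query coordinates (1-based
#'   closed), e.g. non-MULE repeat hits on a gene sequence.
#' @return The masked sequence; length preserved.
#' @export
mask_non_mule <- function(seq, hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(seq)
  n <- nchar(seq)
  if (any(hits$start < 1L | hits$end > n | hits$start > hits$end)) {
    stop("mask interval outside sequence bounds")
  }
  for (i in seq_len(nrow(hits))) {
    substr(seq, hits$start[i], hits$end[i]) <-
      strrep("N", hits$end[i] - hits$start[i] + 1L)
  }
  seq
}

#' GC content of a DNA sequence
#'
#' (#G + #C) / (#A + #C + #G + #T); N and other ambiguity codes are
#' excluded from the denominator.
#'
#' @param seq Character sequence.
#' @return Fraction in `[0, 1]`, or `NA` for a sequence with no
#'   unambiguous base.
#' @export
gc_content <- function(seq) {
  b <- strsplit(toupper(seq), "")[[1L]]
  acgt <- sum(b %in% c("A", "C", "G", "T"))
  if (acgt == 0L) return(NA_real_)
  sum(b %in% c("G", "C")) / acgt
}

#' Identify candidate parental sequences of a MULE-derived gene
#'
#' From the hits of the (repeat-masked) gene sequence against its own
#' genome, discards hits overlapping annotated TE intervals, hits with a
#' MULE TIR within `tir_flank` bp on either side, hits failing the
#' E-value cut (when E-values are absent, an identity/coverage proxy is
#' applied instead), and the gene's own locus (>= 50% reciprocal
#' overlap); among the survivors the highest-identity hit(s) are returned
#' as parental intervals.
#'
#' @param hits Hit table (see [read_hit_table()]) of the masked gene vs
#'   the genome.
#' @param tir_coords data.frame/GRanges-like with `chrom, start, end` of
#'   MULE TIR copies.
#' @param te_coords Same, for non-MULE TEs.
#' @param self_locus One-row data.frame `chrom, start, end` of the gene's
#'   own locus.
#' @param tir_flank Flanking window for the "not flanked by a TIR" rule
#'   (bp).
#' @param evalue_max E-value threshold (exclusive).
#' @param proxy_identity,proxy_coverage Fallback thresholds when hits
#'   carry no E-value.
#' @return data.frame of parental hit intervals (possibly 0 rows).
#' @export
find_parental_sequences <- function(hits, tir_coords = NULL,
                                    te_coords = NULL, self_locus = NULL,
                                    tir_flank = 500L,
                                    evalue_max = 1e-10,
                                    proxy_identity = 90,
                                    proxy_coverage = 0.5) {
  if (is.null(hits) || nrow(hits) == 0L) return(hits)
  keep <- rep(TRUE, nrow(hits))
  hgr <- GenomicRanges::GRanges(hits$chrom,
                                IRanges::IRanges(hits$start, hits$end))
  if (!is.null(te_coords) && NROW(te_coords) > 0L) {
    tgr <- GenomicRanges::GRanges(te_coords$chrom,
                                  IRanges::IRanges(te_coords$start,
                                                   te_coords$end))
    keep[unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(hgr, tgr)))] <- FALSE
  }
  if (!is.null(tir_coords) && NROW(tir_coords) > 0L) {
    flank <- GenomicRanges::GRanges(
      hits$chrom,
      IRanges::IRanges(pmax(1L, hits$start - tir_flank),
                       hits$end + tir_flank))
    rgr <- GenomicRanges::GRanges(tir_coords$chrom,
                                  IRanges::IRanges(tir_coords$start,
                                                   tir_coords$end))
    keep[unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(flank, rgr)))] <- FALSE
  }
  has_e <- !is.na(hits$evalue)
  proxy_ok <- hits$identity >= proxy_identity &
    !is.na(hits$coverage) & hits$coverage >= proxy_coverage
  keep <- keep & ifelse(has_e, hits$evalue < evalue_max, proxy_ok)
  if (!is.null(self_locus)) {
    ov <- pmax(0L, pmin(hits$end, self_locus$end) -
                 pmax(hits$start, self_locus$start) + 1L)
    hl <- hits$end - hits$start + 1L
    sl <- self_locus$end - self_locus$start + 1L
    recip <- hits$chrom == self_locus$chrom & ov / hl >= 0.5 &
      ov / sl >= 0.5
    keep <- keep & !recip
  }
  surv <- hits[keep, , drop = FALSE]
  if (nrow(surv) == 0L) return(surv)
  surv[surv$identity == max(surv$identity), , drop = FALSE]
}

#' Assign parental genes to parental intervals
#'
#' Parental genes are the annotated genes overlapping any parental
#' interval; the gene is chimeric when at least two distinct parental
#' genes contribute.
#'
#' @param parental_intervals data.frame with `chrom, start, end`.
#' @param annotation Gene annotation data.frame (`gene_id, chrom, start,
#'   end`).
#' @param gene_id Id of the derived gene (carried through).
#' @return list `gene_id, parental_intervals, parental_genes, chimera`.
#' @export
assign_parental_genes <- function(parental_intervals, annotation,
                                  gene_id = NA_character_) {
  genes <- character(0)
  if (!is.null(parental_intervals) && nrow(parental_intervals) > 0L &&
      !is.null(annotation) && nrow(annotation) > 0L) {
    pgr <- GenomicRanges::GRanges(
      parental_intervals$chrom,
      IRanges::IRanges(parental_intervals$start, parental_intervals$end))
    agr <- GenomicRanges::GRanges(annotation$chrom,
                                  IRanges::IRanges(annotation$start,
                                                   annotation$end))
    ov <- GenomicRanges::findOverlaps(pgr, agr)
    genes <- unique(annotation$gene_id[S4Vectors::subjectHits(ov)])
  }
  list(gene_id = gene_id, parental_intervals = parental_intervals,
       parental_genes = genes, chimera = length(genes) >= 2L)
}

#' Select non-TE control genes
#'
#' Genes that neither overlap nor lie within `flank` bp of any TE or MULE
#' TIR interval; the standard background set for methylation,
#' recombination and GC comparisons.
#'
#' @param annotation Gene annotation data.frame (`gene_id, chrom, start,
#'   end`).
#' @param te_coords data.frame `chrom, start, end` of TE and TIR copies.
#' @param flank Flanking window, 500 or 1000 bp.
#' @return Subset of `annotation`.
#' @export
select_non_te_genes <- function(annotation, te_coords,
                                flank = c(500L, 1000L)) {
  flank <- as.integer(flank[1L])
  stopifnot(flank %in% c(500L, 1000L))
  if (is.null(te_coords) || nrow(te_coords) == 0L) return(annotation)
  agr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(pmax(1L, annotation$start - flank),
                     annotation$end + flank))
  tgr <- GenomicRanges::GRanges(te_coords$chrom,
                                IRanges::IRanges(te_coords$start,
                                                 te_coords$end))
  bad <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(agr, tgr)))
  if (length(bad)) annotation[-bad, , drop = FALSE] else annotation
}
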