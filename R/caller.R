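#' Mismatch/indel allowance for a candidate TSD length
#'
#' 7-bp target-site duplications must match perfectly; 8-bp TSDs may carry
#' one mismatch or indel; 9-11-bp TSDs up to two.
#'
#' @param len TSD length (7-11).
#' @return Integer allowance.
#' @export
tsd_allowance <- function(len) {
  stopifnot(all(len >= 7L), all(len <= 11L))
  ifelse(len == 7L, 0L, ifelse(len == 8L, 1L, 2L))
}

#' Find the best target-site duplication flanking a putative element
#'
#' Searches all TSD lengths 7-11 bp and all placements within `swing` bp
#' of the putative TIR ends: the left copy ends at `tir_start - 1 + dl`,
#' the right copy starts at `tir_end + 1 + dr` for offsets `dl`, `dr` in
#' `-swing..swing`.  A candidate is valid when the Levenshtein distance
#' between the two copies is within [tsd_allowance()] for its length.
#' Among valid candidates the winner has the fewest mismatches, then the
#' greatest length, then the smallest total offset `|dl| + |dr|` (residual
#' ties go to the smaller `dl`, then `dr`, making the search
#' deterministic).
#'
#' @param chrom_seq Chromosome sequence (character scalar).
#' @param tir_start,tir_end 1-based first base of the left TIR and last
#'   base of the right TIR.
#' @param swing Maximum offset from the putative TIR ends (bp).
#' @param lengths Candidate TSD lengths.
#' @return A one-row data.frame `tsd_len, left_seq, right_seq, mismatches,
#'   left_offset, right_offset`, or `NULL` when no candidate is valid.
#' @export
find_tsd <- function(chrom_seq, tir_start, tir_end, swing = 10L,
                     lengths = 7:11) {
  n <- nchar(chrom_seq)
  offs <- seq.int(-swing, swing)
  # a full search needs max(lengths) + swing bases on either side
  need <- max(lengths) + swing
  if (tir_start - 1L < need || n - tir_end < need) {
    warning("insufficient flank to evaluate all TSD candidates")
  }
  best <- NULL
  any_candidate <- FALSE
  for (len in sort(lengths, decreasing = TRUE)) {
    # admissible offsets given the available flank
    dl <- offs[tir_start + offs - len >= 1L & tir_start + offs - 1L <= n]
    dr <- offs[tir_end + offs + len <= n & tir_end + offs + 1L >= 1L]
    if (!length(dl) || !length(dr)) next
    any_candidate <- TRUE
    left <- vapply(dl, function(d)
      substr(chrom_seq, tir_start + d - len, tir_start + d - 1L),
      character(1L))
    right <- vapply(dr, function(d)
      substr(chrom_seq, tir_end + d + 1L, tir_end + d + len),
      character(1L))
    dist <- utils::adist(left, right)
    allow <- tsd_allowance(len)
    ok <- which(dist <= allow, arr.ind = TRUE)
    if (nrow(ok) == 0L) next
    cand <- data.frame(
      tsd_len = len,
      left_seq = left[ok[, 1L]], right_seq = right[ok[, 2L]],
      mismatches = dist[ok],
      left_offset = dl[ok[, 1L]], right_offset = dr[ok[, 2L]],
      stringsAsFactors = FALSE)
    ord <- order(cand$mismatches,
                 abs(cand$left_offset) + abs(cand$right_offset),
                 cand$left_offset, cand$right_offset)
    top <- cand[ord[1L], ]
    if (is.null(best) ||
        top$mismatches < best$mismatches ||
        (top$mismatches == best$mismatches &&
         top$tsd_len > best$tsd_len)) {
      best <- top
    }
  }
  if (!any_candidate || is.null(best)) return(NULL)
  rownames(best) <- NULL
  best
}

#' Scan a genome for TIR-family hits
#'
#' Two-tier scan: exact full-length matches of each consensus (both
#' orientations) are found directly; diverged copies are recovered by
#' exact k-mer seeding followed by verification with a global-local
#' alignment, accepted at `min_identity` over at least `min_cov` of the
#' consensus length.  Intended for synthetic genomes; real-data runs
#' import RepeatMasker/BLAST tables via [read_hit_table()] or
#' [read_intervals()] instead.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param consensi Named character vector of TIR family consensi.
#' @param min_identity Minimum alignment identity (fraction).
#' @param min_cov Minimum consensus coverage (fraction).
#' @param kmer Seed length.
#' @param fuzzy Run the seeded tier (set `FALSE` for mutation-free data).
#' @return data.frame `chrom, start, end, strand, family, identity`
#'   sorted by position.
#' @export
scan_tir_hits <- function(genome, consensi, min_identity = 0.8,
                          min_cov = 0.8, kmer = 16L, fuzzy = TRUE) {
  rows <- list()
  for (chrom in names(genome)) {
    subject <- Biostrings::DNAString(genome[[chrom]])
    for (fam in names(consensi)) {
      cons <- consensi[[fam]]
      for (ori in c("+", "-")) {
        pat <- if (ori == "+") cons else revcomp(cons)
        m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject)
        if (length(m)) {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, start = Biostrings::start(m),
            end = Biostrings::end(m), strand = ori, family = fam,
            identity = 100, stringsAsFactors = FALSE)
        }
        if (fuzzy) {
          rows[[length(rows) + 1L]] <- seeded_scan(
            genome[[chrom]], subject, pat, chrom, fam, ori,
            min_identity, min_cov, kmer)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      family = character(), identity = numeric()))
  }
  # collapse duplicate calls of the same copy, preferring higher identity
  out <- out[order(out$chrom, out$family, out$strand, -out$identity), ]
  keep <- rep(TRUE, nrow(out))
  gr <- GenomicRanges::GRanges(
    paste(out$chrom, out$family, out$strand),
    IRanges::IRanges(out$start, out$end))
  hitsel <- GenomicRanges::findOverlaps(gr, gr)
  q <- S4Vectors::queryHits(hitsel); s <- S4Vectors::subjectHits(hitsel)
  keep[s[s > q]] <- FALSE
  out <- out[keep, ]
  out[order(out$chrom, out$start), , drop = FALSE]
}

# k-mer seeded candidate discovery + alignment verification (one strand)
seeded_scan <- function(chrom_seq, subject, pattern, chrom, fam, ori,
                        min_identity, min_cov, kmer) {
  plen <- nchar(pattern)
  if (plen < kmer) return(NULL)
  starts <- unique(c(seq(1L, plen - kmer + 1L, by = max(1L, kmer %/% 2L)),
                     plen - kmer + 1L))
  seeds <- vapply(starts, function(s) substr(pattern, s, s + kmer - 1L),
                  character(1L))
  ok <- !duplicated(seeds)
  seeds <- seeds[ok]; starts <- starts[ok]
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
  mi <- Biostrings::matchPDict(pd, subject)
  diag <- integer(0)
  for (i in seq_along(mi)) {
    st <- Biostrings::start(mi[[i]])
    if (length(st)) diag <- c(diag, st - starts[i] + 1L)
  }
  if (!length(diag)) return(NULL)
  diag <- sort(diag)
  # cluster implied copy starts within 30 bp
  grp <- cumsum(c(1L, diff(diag) > 30L))
  anchors <- vapply(split(diag, grp), function(x)
    as.integer(round(stats::median(x))), integer(1L))
  rows <- list()
  for (a in anchors) {
    ws <- max(1L, a - 30L)
    we <- min(nchar(chrom_seq), a + plen + 29L)
    window <- Biostrings::DNAString(substr(chrom_seq, ws, we))
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(pattern), window, type = "global-local",
      substitutionMatrix = dna_submat(), gapOpening = 4,
      gapExtension = 1)
    matched <- Biostrings::nmatch(al)
    span <- Biostrings::nchar(al)
    if (span < min_cov * plen) next
    if (matched / span < min_identity) next
    sr <- al@subject@range
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start = ws + Biostrings::start(sr) - 1L,
      end = ws + Biostrings::end(sr) - 1L, strand = ori, family = fam,
      identity = 100 * matched / span, stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Pair TIR hits into candidate MULE elements
#'
#' Greedy deterministic left-to-right sweep over position-sorted hits:
#' each unpaired hit seeks its nearest following unpaired partner of the
#' same family in the opposite orientation, with inner-edge distance below
#' `max_gap`, and accepts the first such partner for which [find_tsd()]
#' returns a valid target-site duplication for the implied element span.
#' A hit joins at most one element.
#'
#' @param hits data.frame from [scan_tir_hits()] (or an imported table
#'   with the same columns).
#' @param genome Named character vector of chromosome sequences.
#' @param max_gap Maximum inner-edge distance between the paired TIRs (bp,
#'   exclusive bound).
#' @param swing TSD swing passed to [find_tsd()].
#' @return data.frame of elements: `element_id, chrom, family, start, end,
#'   ltir_start, ltir_end, internal_start, internal_end, rtir_start,
#'   rtir_end, tsd_len, tsd_left, tsd_right, tsd_mismatches`.
#' @export
pair_tirs <- function(hits, genome, max_gap = 20000L, swing = 10L) {
  empty <- data.frame(
    element_id = character(), chrom = character(), family = character(),
    start = integer(), end = integer(), ltir_start = integer(),
    ltir_end = integer(), internal_start = integer(),
    internal_end = integer(), rtir_start = integer(),
    rtir_end = integer(), tsd_len = integer(), tsd_left = character(),
    tsd_right = character(), tsd_mismatches = integer(),
    stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  hits <- hits[order(hits$chrom, hits$start, hits$end), ]
  used <- rep(FALSE, nrow(hits))
  rows <- list()
  n <- nrow(hits)
  for (i in seq_len(n)) {
    if (used[i]) next
    cand <- which(!used & seq_len(n) > i &
                    hits$chrom == hits$chrom[i] &
                    hits$family == hits$family[i] &
                    hits$strand != hits$strand[i] &
                    hits$start > hits$end[i] &
                    (hits$start - hits$end[i] - 1L) < max_gap)
    if (!length(cand)) next
    cand <- cand[order(hits$start[cand])]
    for (j in cand) {
      tsd <- suppressWarnings(find_tsd(
        genome[[hits$chrom[i]]], hits$start[i], hits$end[j],
        swing = swing))
      if (is.null(tsd)) next
      used[i] <- TRUE; used[j] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        element_id = NA_character_, chrom = hits$chrom[i],
        family = hits$family[i],
        start = hits$start[i], end = hits$end[j],
        ltir_start = hits$start[i], ltir_end = hits$end[i],
        internal_start = hits$end[i] + 1L,
        internal_end = hits$start[j] - 1L,
        rtir_start = hits$start[j], rtir_end = hits$end[j],
        tsd_len = tsd$tsd_len, tsd_left = tsd$left_seq,
        tsd_right = tsd$right_seq, tsd_mismatches = tsd$mismatches,
        stringsAsFactors = FALSE)
      break
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), ]
  out$element_id <- sprintf("MULE_%s_%04d", out$chrom,
                            seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Label elements autonomous/non-autonomous from transposase evidence
#'
#' An element whose span overlaps a transposase protein hit with E-value
#' below `evalue_max` carries its own transposase and is flagged
#' autonomous; the remainder constitute the non-autonomous set analysed
#' downstream.
#'
#' @param elements data.frame from [pair_tirs()].
#' @param transposase_hits data.frame with `chrom, start, end, evalue`.
#' @param evalue_max E-value threshold (exclusive).
#' @return `elements` with an `element_class` column.
#' @export
screen_transposase <- function(elements, transposase_hits,
                               evalue_max = 1e-9) {
  elements$element_class <- "non-autonomous"
  if (is.null(transposase_hits) || nrow(transposase_hits) == 0L ||
      nrow(elements) == 0L) {
    return(elements)
  }
  th <- transposase_hits[!is.na(transposase_hits$evalue) &
                           transposase_hits$evalue < evalue_max, ]
  if (nrow(th) == 0L) return(elements)
  egr <- GenomicRanges::GRanges(elements$chrom,
                                IRanges::IRanges(elements$start,
                                                 elements$end))
  tgr <- GenomicRanges::GRanges(th$chrom,
                                IRanges::IRanges(th$start, th$end))
  hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(egr, tgr)))
  elements$element_class[hit] <- "autonomous"
  elements
}

# extract a CDS and check the intact-ORF rules
check_orf <- function(genome, chrom, cds_start, cds_end, strand,
                      min_cds = 150L) {
  cds <- subseq_chr(genome[[chrom]], cds_start, cds_end)
  if (strand == "-") cds <- revcomp(cds)
  len <- nchar(cds)
  if (len < min_cds || len %% 3L != 0L) return(FALSE)
  if (substr(cds, 1L, 3L) != "ATG") return(FALSE)
  stops <- c("TAA", "TAG", "TGA")
  if (!substr(cds, len - 2L, len) %in% stops) return(FALSE)
  codons <- substring(cds, seq(1L, len - 2L, by = 3L),
                      seq(3L, len, by = 3L))
  internal <- codons[seq(2L, length(codons) - 1L)]
  !any(internal %in% stops)
}

#' Classify elements as genic or nongenic
#'
#' An element is genic when it overlaps at least `min_overlap` of the
#' length of an annotated transcript whose CDS is at least `min_cds` bp
#' with an intact ATG start, a stop codon, and no internal stop, and which
#' itself carries no transposase hit.  Autonomous elements are left
#' `unclassified` (only non-autonomous elements can be genic).
#'
#' @param elements data.frame with `element_class` (see
#'   [screen_transposase()]).
#' @param transcripts data.frame `gene_id, chrom, start, end, strand,
#'   cds_start, cds_end`.
#' @param genome Named character vector of chromosomes (for ORF checks).
#' @param min_cds Minimum CDS length (bp).
#' @param min_overlap Minimum overlapped fraction of the transcript
#'   length.
#' @param transposase_hits Optional hit table to disqualify
#'   transposase-bearing transcripts.
#' @return `elements` with a `gene_class` column.
#' @export
classify_genic <- function(elements, transcripts, genome,
                           min_cds = 150L, min_overlap = 0.3,
                           transposase_hits = NULL) {
  elements$gene_class <- ifelse(elements$element_class == "autonomous",
                                "unclassified", "nongenic")
  if (nrow(elements) == 0L || is.null(transcripts) ||
      nrow(transcripts) == 0L) {
    return(elements)
  }
  tx <- qualifying_transcripts(transcripts, genome, min_cds,
                               transposase_hits)
  if (nrow(tx) == 0L) return(elements)
  for (i in seq_len(nrow(elements))) {
    if (elements$element_class[i] == "autonomous") next
    sel <- tx$chrom == elements$chrom[i]
    if (!any(sel)) next
    ol <- pmax(0L, pmin(elements$end[i], tx$end[sel]) -
                 pmax(elements$start[i], tx$start[sel]) + 1L)
    frac <- ol / (tx$end[sel] - tx$start[sel] + 1L)
    if (any(frac >= min_overlap)) elements$gene_class[i] <- "genic"
  }
  elements
}

qualifying_transcripts <- function(transcripts, genome, min_cds = 150L,
                                   transposase_hits = NULL) {
  ok <- vapply(seq_len(nrow(transcripts)), function(i)
    check_orf(genome, transcripts$chrom[i], transcripts$cds_start[i],
              transcripts$cds_end[i], transcripts$strand[i], min_cds),
    logical(1L))
  tx <- transcripts[ok, , drop = FALSE]
  if (!is.null(transposase_hits) && nrow(transposase_hits) &&
      nrow(tx)) {
    tgr <- GenomicRanges::GRanges(
      transposase_hits$chrom,
      IRanges::IRanges(transposase_hits$start, transposase_hits$end))
    xgr <- GenomicRanges::GRanges(tx$chrom,
                                  IRanges::IRanges(tx$start, tx$end))
    bad <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(xgr, tgr)))
    if (length(bad)) tx <- tx[-bad, , drop = FALSE]
  }
  tx
}

#' Identify MULE-derived putative genes
#'
#' Returns the annotated transcripts with an intact CDS (>= `min_cds` bp,
#' ATG start, clean stop, no internal stop) of which at least
#' `min_overlap` of the transcript length is covered by non-autonomous
#' element spans; each gene is linked to the element(s) overlapping it.
#'
#' @inheritParams classify_genic
#' @return data.frame `gene_id, chrom, start, end, strand, cds_len,
#'   overlap_fraction, element_ids`.
#' @export
call_mule_derived_genes <- function(elements, transcripts, genome,
                                    min_cds = 150L, min_overlap = 0.3,
                                    transposase_hits = NULL) {
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), cds_len = integer(),
                      overlap_fraction = numeric(),
                      element_ids = character(), stringsAsFactors = FALSE)
  na_el <- elements[elements$element_class == "non-autonomous", ,
                    drop = FALSE]
  if (nrow(na_el) == 0L || is.null(transcripts) ||
      nrow(transcripts) == 0L) {
    return(empty)
  }
  tx <- qualifying_transcripts(transcripts, genome, min_cds,
                               transposase_hits)
  if (nrow(tx) == 0L) return(empty)
  egr <- GenomicRanges::GRanges(na_el$chrom,
                                IRanges::IRanges(na_el$start, na_el$end))
  rows <- list()
  for (i in seq_len(nrow(tx))) {
    txlen <- tx$end[i] - tx$start[i] + 1L
    xgr <- GenomicRanges::GRanges(tx$chrom[i],
                                  IRanges::IRanges(tx$start[i], tx$end[i]))
    ov <- GenomicRanges::findOverlaps(xgr, egr)
    js <- S4Vectors::subjectHits(ov)
    if (!length(js)) next
    covered <- sum(IRanges::width(IRanges::reduce(IRanges::restrict(
      IRanges::IRanges(na_el$start[js], na_el$end[js]),
      start = tx$start[i], end = tx$end[i]))))
    frac <- covered / txlen
    if (frac >= min_overlap) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = tx$gene_id[i], chrom = tx$chrom[i],
        start = tx$start[i], end = tx$end[i], strand = tx$strand[i],
        cds_len = tx$cds_end[i] - tx$cds_start[i] + 1L,
        overlap_fraction = frac,
        element_ids = paste(na_el$element_id[js], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty
}

#' Accept or reject a candidate TIR family
#'
#' A consensus is accepted as a MULE TIR family only if it has at least
#' `min_copies` genome-wide copies, less than `max_masked_fraction` of its
#' length covered by known non-MULE repeats, and at least `min_elements`
#' TSD-validated paired elements.
#'
#' @param consensus Consensus sequence (character).
#' @param hits data.frame of genome-wide hits of this family (one row per
#'   copy).
#' @param nonmule_mask Optional data.frame/IRanges-like with `start, end`
#'   giving non-MULE repeat intervals on the consensus.
#' @param n_validated Number of TSD-validated elements found for this
#'   family (e.g. rows of [pair_tirs()] output).
#' @param min_copies,max_masked_fraction,min_elements Thresholds.
#' @return list `accepted` (logical), `reason` (character).
#' @export
validate_tir_family <- function(consensus, hits, nonmule_mask = NULL,
                                n_validated = 0L, min_copies = 20L,
                                max_masked_fraction = 0.3,
                                min_elements = 5L) {
  n_copies <- if (is.null(hits)) 0L else nrow(hits)
  if (n_copies == 0L) {
    return(list(accepted = FALSE, reason = "no copies"))
  }
  if (n_copies < min_copies) {
    return(list(accepted = FALSE,
                reason = sprintf("copy number %d < %d", n_copies,
                                 min_copies)))
  }
  if (!is.null(nonmule_mask) && NROW(nonmule_mask) > 0L) {
    masked <- interval_union_length(nonmule_mask$start, nonmule_mask$end,
                                    lo = 1L, hi = nchar(consensus))
    frac <- masked / nchar(consensus)
    if (frac >= max_masked_fraction) {
      return(list(accepted = FALSE,
                  reason = sprintf("%.0f%% masked by non-MULE repeats",
                                   100 * frac)))
    }
  }
  if (n_validated < min_elements) {
    return(list(accepted = FALSE,
                reason = sprintf("only %d TSD-validated elements (< %d)",
                                 n_validated, min_elements)))
  }
  list(accepted = TRUE, reason = "ok")
}

#' Call MULEs in one genome end to end
#'
#' Convenience pipeline: scan (or accept) TIR hits, pair them with TSD
#' validation, screen for transposases and classify genic/nongenic.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param consensi Named character vector of TIR consensi (ignored when
#'   `tir_hits` is supplied).
#' @param tir_hits Optional pre-computed hit table (e.g. imported
#'   RepeatMasker/BLAST evidence).
#' @param transposase_hits Optional transposase hit table.
#' @param transcripts Optional transcript annotation.
#' @param ... Passed to [scan_tir_hits()] and [pair_tirs()].
#' @return Elements data.frame with `element_class` and (when transcripts
#'   are given) `gene_class` columns.
#' @export
call_mules <- function(genome, consensi = NULL, tir_hits = NULL,
                       transposase_hits = NULL, transcripts = NULL,
                       ...) {
  dots <- list(...)
  if (is.null(tir_hits)) {
    scan_args <- dots[names(dots) %in%
                        c("min_identity", "min_cov", "kmer", "fuzzy")]
    tir_hits <- do.call(scan_tir_hits,
                        c(list(genome, consensi), scan_args))
  }
  pair_args <- dots[names(dots) %in% c("max_gap", "swing")]
  elements <- do.call(pair_tirs, c(list(tir_hits, genome), pair_args))
  elements <- screen_transposase(elements, transposase_hits)
  if (!is.null(transcripts)) {
    elements <- classify_genic(elements, transcripts, genome,
                               transposase_hits = transposase_hits)
  }
  elements
}
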