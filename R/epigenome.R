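#' Methylation level of a region in one cytosine context
#'
#' Sites covered by fewer than `min_coverage` reads are excluded; if
#' fewer than `min_mapped_frac` of the region's cytosines (of the
#' requested context) survive, the level is undefined.  The default
#' (read-weighted) estimate pools counts: sum of methylated reads over
#' sum of total reads across mapped sites; `mode = "site"` instead scores
#' each mapped site as methylated if it has at least one methylated read
#' and averages the binary calls.
#'
#' @param calls Cytosine-report data.frame ([read_cytosine_report()]).
#' @param chrom,start,end Region (1-based closed).
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param min_coverage Minimum reads for a site to count as mapped.
#' @param min_mapped_frac Minimum mapped fraction of the region's sites.
#' @param mode `"weighted"` (default) or `"site"`.
#' @return list `level` (`NA` when undefined), `n_sites`, `n_mapped`,
#'   `mapped_frac`, `status` (`"ok"`, `"no_sites"`, `"low_coverage"`).
#' @export
methylation_level <- function(calls, chrom, start, end, context,
                              min_coverage = 3L, min_mapped_frac = 0.5,
                              mode = c("weighted", "site")) {
  mode <- match.arg(mode)
  stopifnot(context %in% c("CG", "CHG", "CHH"))
  sel <- calls$chrom == chrom & calls$pos >= start & calls$pos <= end &
    calls$context == context
  n_sites <- sum(sel)
  if (n_sites == 0L) {
    return(list(level = NA_real_, n_sites = 0L, n_mapped = 0L,
                mapped_frac = NA_real_, status = "no_sites"))
  }
  meth <- calls$meth[sel]; total <- calls$total[sel]
  mapped <- total >= min_coverage
  n_mapped <- sum(mapped)
  frac <- n_mapped / n_sites
  if (frac < min_mapped_frac) {
    return(list(level = NA_real_, n_sites = n_sites, n_mapped = n_mapped,
                mapped_frac = frac, status = "low_coverage"))
  }
  level <- if (mode == "weighted") {
    sum(meth[mapped]) / sum(total[mapped])
  } else {
    mean(meth[mapped] > 0L)
  }
  list(level = level, n_sites = n_sites, n_mapped = n_mapped,
       mapped_frac = frac, status = "ok")
}

#' Partition an element into flank/TIR/internal regions
#'
#' @param element One row of a [pair_tirs()] element table (or the truth
#'   table), needing `chrom, ltir_start, ltir_end, internal_start,
#'   internal_end, rtir_start, rtir_end`.
#' @param flank Flank width (bp).
#' @return data.frame `part, chrom, start, end` with parts
#'   `upstream, ltir, internal, rtir, downstream`.
#' @export
region_partition <- function(element, flank = 500L) {
  data.frame(
    part = c("upstream", "ltir", "internal", "rtir", "downstream"),
    chrom = element$chrom,
    start = c(max(1L, element$ltir_start - flank), element$ltir_start,
              element$internal_start, element$rtir_start,
              element$rtir_end + 1L),
    end = c(element$ltir_start - 1L, element$ltir_end,
            element$internal_end, element$rtir_end,
            element$rtir_end + flank),
    stringsAsFactors = FALSE)
}

#' Methylation meta-profile over MULE anatomy
#'
#' Bins each element into 500-bp flanks (fixed 50-bp windows), TIRs
#' (10 proportional bins each) and the internal region (20 proportional
#' bins), computes per-element, per-bin levels with [methylation_level()]
#' and averages defined levels within each group.
#'
#' @param elements Element data.frame (coordinates as in
#'   [region_partition()]) with an optional `group` column.
#' @param calls Cytosine report.
#' @param context Cytosine context.
#' @param flank,flank_bin Flank width and flank bin width (bp).
#' @param tir_bins,internal_bins Proportional bin counts.
#' @param min_elements Bins with fewer contributing elements are flagged.
#' @param ... Passed to [methylation_level()].
#' @return data.frame `group, bin, part, mean_level, n_elements, flagged`
#'   with bins ordered upstream, left TIR, internal, right TIR,
#'   downstream.
#' @export
meta_profile <- function(elements, calls, context, flank = 500L,
                         flank_bin = 50L, tir_bins = 10L,
                         internal_bins = 20L, min_elements = 10L, ...) {
  if (!"group" %in% names(elements)) elements$group <- "all"
  nf <- flank %/% flank_bin
  parts <- c(rep("upstream", nf), rep("ltir", tir_bins),
             rep("internal", internal_bins), rep("rtir", tir_bins),
             rep("downstream", nf))
  nbins <- length(parts)
  prop_bins <- function(a, b, k) {
    edges <- round(seq(a - 1L, b, length.out = k + 1L))
    cbind(start = edges[-(k + 1L)] + 1L, end = edges[-1L])
  }
  out <- list()
  for (grp in unique(elements$group)) {
    es <- elements[elements$group == grp, , drop = FALSE]
    acc <- matrix(NA_real_, nrow = nrow(es), ncol = nbins)
    for (i in seq_len(nrow(es))) {
      e <- es[i, ]
      up <- cbind(start = seq(e$ltir_start - flank, by = flank_bin,
                              length.out = nf),
                  end = seq(e$ltir_start - flank + flank_bin - 1L,
                            by = flank_bin, length.out = nf))
      down <- cbind(start = seq(e$rtir_end + 1L, by = flank_bin,
                                length.out = nf),
                    end = seq(e$rtir_end + flank_bin, by = flank_bin,
                              length.out = nf))
      bins <- rbind(up,
                    prop_bins(e$ltir_start, e$ltir_end, tir_bins),
                    prop_bins(e$internal_start, e$internal_end,
                              internal_bins),
                    prop_bins(e$rtir_start, e$rtir_end, tir_bins),
                    down)
      for (j in seq_len(nbins)) {
        if (bins[j, "start"] < 1L || bins[j, "start"] > bins[j, "end"])
          next
        ml <- methylation_level(calls, e$chrom, bins[j, "start"],
                                bins[j, "end"], context, ...)
        acc[i, j] <- ml$level
      }
    }
    n_el <- colSums(!is.na(acc))
    out[[grp]] <- data.frame(
      group = grp, bin = seq_len(nbins), part = parts,
      mean_level = ifelse(n_el > 0L, colMeans(acc, na.rm = TRUE),
                          NA_real_),
      n_elements = n_el, flagged = n_el < min_elements,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' TE content of an element's internal region
#'
#' Union length of non-MULE repeat hits overlapping the internal
#' interval, divided by the internal length (overlapping hits merged
#' before summing).
#'
#' @param internal_start,internal_end Internal interval (1-based closed).
#' @param hits data.frame with `start, end` of repeat hits (same
#'   chromosome).
#' @return Fraction in `[0, 1]`; `NA` for a zero-length interval.
#' @export
te_content <- function(internal_start, internal_end, hits) {
  len <- internal_end - internal_start + 1L
  if (len <= 0L) return(NA_real_)
  if (is.null(hits) || nrow(hits) == 0L) return(0)
  interval_union_length(hits$start, hits$end, lo = internal_start,
                        hi = internal_end) / len
}

#' Similarity of a paired-TIR couple
#'
#' Globally aligns the two TIR copies (match +1, mismatch -1, gap open
#' -2, gap extend -0.5) and reports identical aligned bases divided by
#' the left TIR length.  With `orientation = "genomic"` (the default) the
#' right TIR is reverse-complemented into the left orientation first;
#' use `"aligned"` when both inputs are already co-oriented.
#'
#' @param left,right TIR sequences (character).
#' @param orientation `"genomic"` or `"aligned"`.
#' @return Similarity fraction (identical bases / left TIR length).
#' @export
tir_similarity <- function(left, right,
                           orientation = c("genomic", "aligned")) {
  orientation <- match.arg(orientation)
  stopifnot(nchar(left) > 0L, nchar(right) > 0L)
  if (orientation == "genomic") right <- revcomp(right)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                  mismatch = -1)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(left), Biostrings::DNAString(right),
    type = "global", substitutionMatrix = mat,
    gapOpening = 2, gapExtension = 0.5)
  Biostrings::nmatch(al) / nchar(left)
}

#' 24-nt small-RNA occupancy of regions, by group
#'
#' Filters the sRNA table to the requested read length and (optionally)
#' to species mapping to a single genomic location, assigns records to
#' regions by overlap, and summarizes per region and per group/tissue.
#' Both summed read abundance and the count of distinct species are
#' reported.
#'
#' @param regions data.frame `region_id, chrom, start, end` plus optional
#'   `group`.
#' @param srna data.frame `chrom, start, end, length, count, n_loci`
#'   plus optional `tissue`.
#' @param len Read length to keep (nt).
#' @param unique_only Keep only species with `n_loci == 1`.
#' @return list `per_region` (region x tissue rows with `reads` and
#'   `species`), `summary` (group x tissue means).
#' @export
srna_occupancy <- function(regions, srna, len = 24L, unique_only = TRUE) {
  if (!"group" %in% names(regions)) regions$group <- "all"
  if (is.null(srna) || nrow(srna) == 0L) {
    srna <- data.frame(chrom = character(), start = integer(),
                       end = integer(), length = integer(),
                       count = integer(), n_loci = integer(),
                       tissue = character())
  }
  if (!"tissue" %in% names(srna)) srna$tissue <- "pooled"
  keep <- srna$length == len
  if (unique_only) keep <- keep & srna$n_loci == 1L
  srna <- srna[keep, , drop = FALSE]
  tissues <- unique(srna$tissue)
  if (length(tissues) == 0L) tissues <- "pooled"
  rgr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start,
                                                 regions$end))
  rows <- list()
  for (tis in tissues) {
    st <- srna[srna$tissue == tis, , drop = FALSE]
    reads <- numeric(nrow(regions)); species <- integer(nrow(regions))
    if (nrow(st)) {
      sgr <- GenomicRanges::GRanges(st$chrom,
                                    IRanges::IRanges(st$start, st$end))
      ov <- GenomicRanges::findOverlaps(rgr, sgr)
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      for (i in unique(qh)) {
        js <- sh[qh == i]
        reads[i] <- sum(st$count[js])
        species[i] <- length(js)
      }
    }
    rows[[tis]] <- data.frame(
      region_id = regions$region_id, group = regions$group,
      tissue = tis, reads = reads, species = species,
      stringsAsFactors = FALSE)
  }
  per_region <- do.call(rbind, rows)
  rownames(per_region) <- NULL
  summary <- stats::aggregate(
    cbind(reads, species) ~ group + tissue, data = per_region, FUN = mean)
  list(per_region = per_region, summary = summary)
}

#' Two-group comparison (Wilcoxon rank-sum or Welch t)
#'
#' Rank-sum uses the normal approximation with continuity correction
#' (ties handled by midranks); a fully degenerate comparison (all pooled
#' values identical) returns p = 1 with a flag.
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @param test `"ranksum"` or `"t"`.
#' @return list `statistic, p, method, flagged`.
#' @export
group_compare <- function(a, b, test = c("ranksum", "t")) {
  test <- match.arg(test)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 values")
  if (length(unique(c(a, b))) == 1L) {
    return(list(statistic = NA_real_, p = 1, method = test,
                flagged = TRUE))
  }
  if (test == "ranksum") {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
  } else {
    ht <- stats::t.test(a, b)
  }
  list(statistic = unname(ht$statistic), p = ht$p.value, method = test,
       flagged = FALSE)
}
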