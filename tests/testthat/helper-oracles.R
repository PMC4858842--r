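# Independent oracles and shared fixtures for the test suite.
# Oracles re-derive expected values by exhaustive enumeration or direct
# per-site recomputation; they never call the code paths they check.

.fixture_cache <- new.env(parent = emptyenv())

# small 3-taxon bundle used by several unit tests (built once per run)
small_bundle <- function() {
  if (is.null(.fixture_cache$small)) {
    tr <- ape::read.tree(text = "((A:1,B:1)AB:1,C:2)R;")
    cfg <- plant_config(seed = 42, tree = tr, chrom_length = 3e5,
                        insertions_per_branch = c(A = 5, B = 5, C = 5,
                                                  AB = 3, R = 2),
                        n_genes = 10)
    .fixture_cache$small <- simulate_genomes(cfg)
  }
  .fixture_cache$small
}

# exhaustive TSD scorer: flat enumeration of every length x offset pair,
# ordered by the documented tie-break; selection logic independent of
# find_tsd's pruned per-length search
oracle_tsd <- function(chrom_seq, tir_start, tir_end, swing = 10L,
                       lengths = 7:11) {
  n <- nchar(chrom_seq)
  offs <- seq.int(-swing, swing)
  cands <- list()
  for (len in lengths) {
    dl <- offs[tir_start + offs - len >= 1L]
    dr <- offs[tir_end + offs + len <= n]
    if (!length(dl) || !length(dr)) next
    left <- vapply(dl, function(d)
      substr(chrom_seq, tir_start + d - len, tir_start + d - 1L),
      character(1L))
    right <- vapply(dr, function(d)
      substr(chrom_seq, tir_end + d + 1L, tir_end + d + len),
      character(1L))
    dm <- utils::adist(left, right)
    grid <- expand.grid(il = seq_along(dl), ir = seq_along(dr))
    cands[[length(cands) + 1L]] <- data.frame(
      tsd_len = len, left_seq = left[grid$il], right_seq = right[grid$ir],
      mismatches = dm[cbind(grid$il, grid$ir)],
      left_offset = dl[grid$il], right_offset = dr[grid$ir])
  }
  if (!length(cands)) return(NULL)
  all <- do.call(rbind, cands)
  allow <- ifelse(all$tsd_len == 7L, 0L, ifelse(all$tsd_len == 8L, 1L, 2L))
  all <- all[all$mismatches <= allow, , drop = FALSE]
  if (nrow(all) == 0L) return(NULL)
  ord <- order(all$mismatches, -all$tsd_len,
               abs(all$left_offset) + abs(all$right_offset),
               all$left_offset, all$right_offset)
  out <- all[ord[1L], ]
  rownames(out) <- NULL
  out
}

# brute-force region methylation: direct per-site filtering and pooling
oracle_meth_level <- function(calls, chrom, start, end, context,
                              min_coverage = 3L, min_mapped_frac = 0.5) {
  rows <- calls[calls$chrom == chrom & calls$pos >= start &
                  calls$pos <= end & calls$context == context, ]
  if (nrow(rows) == 0L) return(NA_real_)
  mapped <- rows[rows$total >= min_coverage, ]
  if (nrow(mapped) / nrow(rows) < min_mapped_frac) return(NA_real_)
  sum(mapped$meth) / sum(mapped$total)
}

# interval-union oracle: per-base occupancy vector
oracle_union_fraction <- function(starts, ends, lo, hi) {
  covered <- rep(FALSE, hi - lo + 1L)
  for (i in seq_along(starts)) {
    a <- max(starts[i], lo); b <- min(ends[i], hi)
    if (a <= b) covered[(a - lo + 1L):(b - lo + 1L)] <- TRUE
  }
  mean(covered)
}

# random in-frame CDS of n codons (ATG ... stop, no internal stop)
random_cds <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}
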