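#' Transition/transversion fractions of an aligned sequence pair
#'
#' Compares two equal-length aligned sequences column by column, skipping
#' columns with gaps or ambiguity codes, and returns the proportions of
#' transition (P) and transversion (Q) differences among compared sites.
#'
#' @param seq1,seq2 Aligned sequences (equal nchar; `-` for gaps).
#' @return list `P, Q, sites` (gap-excluded site count).
#' @export
aligned_pair_stats <- function(seq1, seq2) {
  a <- strsplit(toupper(seq1), "")[[1L]]
  b <- strsplit(toupper(seq2), "")[[1L]]
  stopifnot(length(a) == length(b))
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  if (length(a) == 0L) stop("no comparable sites")
  diff <- a != b
  purine <- c("A", "G")
  ti <- diff & ((a %in% purine) == (b %in% purine))
  list(P = sum(ti) / length(a), Q = sum(diff & !ti) / length(a),
       sites = length(a))
}

#' Kimura two-parameter distance
#'
#' k = 1/2 ln(1 / (1 - 2P - Q)) + 1/4 ln(1 / (1 - 2Q)) for transition
#' fraction P and transversion fraction Q.  Saturated pairs (either log
#' argument non-positive) yield `NA`.
#'
#' @param P Transition difference fraction, or a list from
#'   [aligned_pair_stats()].
#' @param Q Transversion difference fraction.
#' @return Distance in substitutions/site, or `NA` on saturation.
#' @export
k2p_distance <- function(P, Q = NULL) {
  if (is.list(P)) { Q <- P$Q; P <- P$P }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  0.5 * log(1 / w1) + 0.25 * log(1 / w2)
}

#' Amplification time from divergence, T = k / (2 r)
#'
#' Divergence between an element and its closest paralog accumulates
#' along both lineages since the duplication, hence the factor 2; the
#' default rate is the rice-calibrated neutral rate 1.3e-8
#' substitutions/site/year.
#'
#' @param k Divergence (substitutions/site); `NA` propagates.
#' @param r Substitution rate per site per year.
#' @return list `years, my` (million years).
#' @export
amplification_time <- function(k, r = 1.3e-8) {
  stopifnot(r > 0)
  if (is.na(k)) return(list(years = NA_real_, my = NA_real_))
  stopifnot(k >= 0)
  years <- k / (2 * r)
  list(years = years, my = years / 1e6)
}

#' Closest paralogous partner of an element
#'
#' From an all-by-all hit table, returns the best-scoring non-self hit
#' whose subject belongs to the same TIR family (the "second best hit",
#' the best being the self-hit).  Equal-scoring partners are broken
#' lexicographically by id.
#'
#' @param id Query element id.
#' @param hits data.frame `query, subject, score` (optionally
#'   `identity`).
#' @param families Named character vector mapping element id to TIR
#'   family.
#' @return Partner element id, or `NA` for a singleton family.
#' @export
nearest_paralog <- function(id, hits, families) {
  h <- hits[hits$query == id & hits$subject != id, , drop = FALSE]
  if (nrow(h) == 0L) return(NA_character_)
  h <- h[families[h$subject] == families[id], , drop = FALSE]
  h <- h[!is.na(h$subject), , drop = FALSE]
  if (nrow(h) == 0L) return(NA_character_)
  h <- h[order(-h$score, h$subject), , drop = FALSE]
  h$subject[1L]
}

#' Codon-aware alignment trimming
#'
#' Globally aligns a CDS against a partner sequence, drops partner
#' insertions, removes codon columns containing gaps in either sequence
#' (restoring frame across short indels) and removes codon pairs in which
#' either codon is a stop.  The output is a stop-free in-frame pair of
#' equal length, a multiple of 3.
#'
#' @param cds In-frame coding sequence (length a multiple of 3).
#' @param partner Partner sequence (a paralogous CDS or an unannotated
#'   genomic slice).
#' @param min_codons Minimum surviving codons; below this the pair is
#'   flagged untestable.
#' @return list `cds, partner` (trimmed, equal length), `n_codons`,
#'   `untestable`.
#' @export
codon_align_trim <- function(cds, partner, min_codons = 30L) {
  stopifnot(nchar(cds) %% 3L == 0L)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(cds), Biostrings::DNAString(partner),
    type = "global-local", substitutionMatrix = dna_submat(),
    gapOpening = 8, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  # drop partner-insertion columns (gap in the CDS)
  keep <- p != "-"
  p <- p[keep]; s <- s[keep]
  stopifnot(length(p) %% 3L == 0L)
  n_cod <- length(p) / 3L
  idx <- matrix(seq_along(p), nrow = 3L)
  stops <- c("TAA", "TAG", "TGA")
  out_c <- character(0); out_p <- character(0)
  for (j in seq_len(n_cod)) {
    cc <- p[idx[, j]]; pc <- s[idx[, j]]
    if (any(pc == "-")) next
    c1 <- paste(cc, collapse = ""); c2 <- paste(pc, collapse = "")
    if (c1 %in% stops || c2 %in% stops) next
    out_c <- c(out_c, c1); out_p <- c(out_p, c2)
  }
  list(cds = paste(out_c, collapse = ""),
       partner = paste(out_p, collapse = ""),
       n_codons = length(out_c),
       untestable = length(out_c) < min_codons)
}

# --- NG86 codon tables, built once per session ---------------------------

.ng86_cache <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(.ng86_cache$tab)) return(.ng86_cache$tab)
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  code <- Biostrings::GENETIC_CODE[codons]
  stops <- codons[code == "*"]
  sense <- setdiff(codons, stops)
  # per-codon synonymous/nonsynonymous site counts; changes producing a
  # stop are excluded and each position contributes one full site split
  # by the synonymous fraction among viable changes
  S <- stats::setNames(numeric(length(sense)), sense)
  N <- S
  for (cd in sense) {
    for (i in 1:3) {
      alts <- vapply(setdiff(bases, substr(cd, i, i)), function(b) {
        x <- cd; substr(x, i, i) <- b; x
      }, character(1L))
      alts <- alts[!alts %in% stops]
      if (length(alts) == 0L) next
      syn <- mean(code[alts] == code[cd])
      S[cd] <- S[cd] + syn
      N[cd] <- N[cd] + (1 - syn)
    }
  }
  # per-pair synonymous/nonsynonymous difference counts, averaging over
  # substitution pathways that avoid stop-codon intermediates
  pair_diffs <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
    nd <- length(pos)
    if (nd == 0L) return(c(0, 0))
    paths <- if (nd == 1L) list(pos) else
      lapply(split_permutations(pos), identity)
    acc <- c(0, 0); nval <- 0L
    for (ord in paths) {
      cur <- c1; sd <- 0; ndn <- 0; okpath <- TRUE
      for (i in ord) {
        nxt <- cur
        substr(nxt, i, i) <- substr(c2, i, i)
        if (nxt %in% stops) { okpath <- FALSE; break }
        if (code[cur] == code[nxt]) sd <- sd + 1 else ndn <- ndn + 1
        cur <- nxt
      }
      if (okpath) { acc <- acc + c(sd, ndn); nval <- nval + 1L }
    }
    if (nval == 0L) return(c(NA_real_, NA_real_))
    acc / nval
  }
  Sd <- matrix(NA_real_, length(sense), length(sense),
               dimnames = list(sense, sense))
  Nd <- Sd
  for (a in sense) for (b in sense) {
    d <- pair_diffs(a, b)
    Sd[a, b] <- d[1L]; Nd[a, b] <- d[2L]
  }
  .ng86_cache$tab <- list(sense = sense, stops = stops, S = S, N = N,
                          Sd = Sd, Nd = Nd)
  .ng86_cache$tab
}

split_permutations <- function(pos) {
  if (length(pos) == 2L) {
    list(pos, rev(pos))
  } else {
    out <- list()
    for (i in seq_along(pos)) {
      rest <- pos[-i]
      for (r in split_permutations(rest)) {
        out[[length(out) + 1L]] <- c(pos[i], r)
      }
    }
    out
  }
}

#' Nei-Gojobori (1986) Ka/Ks with a normal-approximation test
#'
#' Counts synonymous and nonsynonymous sites (averaged over the pair,
#' substitution pathways averaged for multi-difference codons, stop-codon
#' pathways excluded), applies the Jukes-Cantor correction to the raw
#' proportions, and tests Ka - Ks = 0 with a two-sided normal
#' approximation using binomial variances.  The selection call is
#' finalised against an FDR-adjusted q-value by [selection_call()].
#'
#' @param seq1,seq2 Stop-free, in-frame codon-aligned sequences of equal
#'   length (see [codon_align_trim()]).
#' @return list `ka, ks, ratio, p, n_sites_syn, n_sites_nonsyn,
#'   nd_syn, nd_nonsyn` (`ratio` is `NA` when Ks is 0 or undefined).
#' @export
ng86_kaks <- function(seq1, seq2) {
  stopifnot(nchar(seq1) == nchar(seq2), nchar(seq1) %% 3L == 0L)
  tab <- ng86_tables()
  n <- nchar(seq1) / 3L
  c1 <- substring(toupper(seq1), 3L * seq_len(n) - 2L, 3L * seq_len(n))
  c2 <- substring(toupper(seq2), 3L * seq_len(n) - 2L, 3L * seq_len(n))
  ok <- c1 %in% tab$sense & c2 %in% tab$sense
  c1 <- c1[ok]; c2 <- c2[ok]
  if (length(c1) == 0L) stop("no comparable codons")
  S <- (sum(tab$S[c1]) + sum(tab$S[c2])) / 2
  N <- (sum(tab$N[c1]) + sum(tab$N[c2])) / 2
  dmat <- cbind(tab$Sd[cbind(c1, c2)], tab$Nd[cbind(c1, c2)])
  dmat <- dmat[stats::complete.cases(dmat), , drop = FALSE]
  Sdiff <- sum(dmat[, 1L]); Ndiff <- sum(dmat[, 2L])
  ps <- Sdiff / S; pn <- Ndiff / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ks <- jc(ps); ka <- jc(pn)
  # delta-method variances of the JC-corrected distances
  vd <- function(p, nsites) {
    if (is.na(jc(p))) return(NA_real_)
    (p * (1 - p) / nsites) / (1 - 4 * p / 3)^2
  }
  vka <- vd(pn, N); vks <- vd(ps, S)
  p <- if (is.na(ka) || is.na(ks) || (vka + vks) == 0) NA_real_ else
    2 * stats::pnorm(-abs((ka - ks) / sqrt(vka + vks)))
  ratio <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  list(ka = ka, ks = ks, ratio = ratio, p = p, ps = ps, pn = pn,
       n_sites_syn = S, n_sites_nonsyn = N,
       nd_syn = Sdiff, nd_nonsyn = Ndiff)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p Vector of p-values in `[0, 1]` (`NA` allowed and propagated).
#' @return Vector of q-values.
#' @export
adjust_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Selection call from Ka, Ks and q-value
#'
#' `purifying` (Ka/Ks < 1) or `positive` (Ka/Ks > 1) only at q <= `alpha`;
#' `untestable` when Ks is zero/undefined; otherwise `neutral`.
#'
#' @param ka,ks Corrected rates.
#' @param q FDR-adjusted p-value.
#' @param alpha Significance cutoff.
#' @return One of `"purifying", "neutral", "positive", "untestable"`.
#' @export
selection_call <- function(ka, ks, q, alpha = 0.05) {
  if (is.na(ka) || is.na(ks) || ks == 0) return("untestable")
  if (!is.na(q) && q <= alpha) {
    if (ka < ks) return("purifying")
    if (ka > ks) return("positive")
  }
  "neutral"
}
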