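#' Best local hit of a query sequence in a genome
#'
#' Exact k-mer seeding (both orientations) followed by a local alignment
#' of the query against the densest seed cluster.  A lightweight stand-in
#' for an external aligner on synthetic genomes; real-data runs import
#' BLAT/BLAST tables instead.
#'
#' @param query Query sequence (character).
#' @param genome Named character vector of chromosome sequences.
#' @param kmer Seed length.
#' @param min_seeds Minimum seeds supporting the winning cluster.
#' @return One-row data.frame `chrom, start, end, strand, identity,
#'   length, coverage` or `NULL` when nothing is found.  `coverage` is the
#'   aligned fraction of the query.
#' @export
best_hit_search <- function(query, genome, kmer = 16L, min_seeds = 1L) {
  qlen <- nchar(query)
  if (qlen < kmer) return(NULL)
  starts <- unique(c(seq(1L, qlen - kmer + 1L, by = max(1L, kmer %/% 2L)),
                     qlen - kmer + 1L))
  best <- NULL
  for (chrom in names(genome)) {
    subject <- Biostrings::DNAString(genome[[chrom]])
    for (ori in c("+", "-")) {
      pat <- if (ori == "+") query else revcomp(query)
      seeds <- vapply(starts, function(s) substr(pat, s, s + kmer - 1L),
                      character(1L))
      ok <- !duplicated(seeds)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds[ok]))
      mi <- Biostrings::matchPDict(pd, subject)
      diag <- integer(0)
      st_ok <- starts[ok]
      for (i in seq_along(mi)) {
        st <- Biostrings::start(mi[[i]])
        if (length(st)) diag <- c(diag, st - st_ok[i] + 1L)
      }
      if (length(diag) < min_seeds) next
      diag <- sort(diag)
      grp <- cumsum(c(1L, diff(diag) > 50L))
      sizes <- table(grp)
      top <- names(sizes)[which.max(sizes)]
      a <- as.integer(round(stats::median(diag[grp == as.integer(top)])))
      ws <- max(1L, a - 50L)
      we <- min(nchar(genome[[chrom]]), a + qlen + 49L)
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(pat),
        Biostrings::DNAString(substr(genome[[chrom]], ws, we)),
        type = "local", substitutionMatrix = dna_submat(),
        gapOpening = 4, gapExtension = 1)
      span <- Biostrings::nchar(al)
      if (span == 0L) next
      idy <- 100 * Biostrings::nmatch(al) / span
      sr <- al@subject@range
      pr <- al@pattern@range
      cand <- data.frame(
        chrom = chrom, start = ws + Biostrings::start(sr) - 1L,
        end = ws + Biostrings::end(sr) - 1L, strand = ori,
        identity = idy, length = span,
        coverage = IRanges::width(pr) / qlen,
        score = Biostrings::score(al), stringsAsFactors = FALSE)
      if (is.null(best) || cand$score > best$score) best <- cand
    }
  }
  best
}

#' Decide presence of an element in another genome
#'
#' Identity criterion: the element's best hit must cover at least
#' `min_coverage` of the element length.  Synteny criterion: either (a)
#' the element's best hit lies on the element's home chromosome (shared
#' chromosome naming) and at least one flank probe's best hit falls
#' within `window` bp of it, or (b) at least two flank best hits fall
#' within `window` bp of it.  Both criteria must pass.
#'
#' @param element_hit Best-hit record of the element sequence (one-row
#'   data.frame from [best_hit_search()] / [read_hit_table()]) or `NULL`.
#' @param flank_hits List of best-hit records for the four flank probes
#'   (1 bp-1 kb and 1-2 kb, up- and downstream); entries may be `NULL`.
#' @param home_chrom Chromosome of the element in its own genome.
#' @param min_coverage Identity-criterion coverage threshold.
#' @param window Synteny distance (bp, closest edges).
#' @return list `present, identity_pass, synteny_pass, n_flanks_close,
#'   flagged` (`flagged` when fewer than 4 flank probes were evaluable).
#' @export
assess_presence <- function(element_hit, flank_hits, home_chrom = NULL,
                            min_coverage = 0.3, window = 4000L) {
  flagged <- length(flank_hits) < 4L
  identity_pass <- !is.null(element_hit) &&
    !is.na(element_hit$coverage) && element_hit$coverage >= min_coverage
  n_close <- 0L
  if (!is.null(element_hit)) {
    for (fh in flank_hits) {
      if (is.null(fh)) next
      if (fh$chrom != element_hit$chrom) next
      gap <- max(0L, max(fh$start, element_hit$start) -
                   min(fh$end, element_hit$end))
      if (gap <= window) n_close <- n_close + 1L
    }
  }
  same_chrom <- !is.null(element_hit) && !is.null(home_chrom) &&
    element_hit$chrom == home_chrom
  synteny_pass <- (n_close >= 2L) || (n_close >= 1L && same_chrom)
  list(present = identity_pass && synteny_pass,
       identity_pass = identity_pass, synteny_pass = synteny_pass,
       n_flanks_close = n_close, flagged = flagged)
}

#' Probe one element against another genome and decide presence
#'
#' Collects the element sequence plus the four flanking probes (1 bp-1 kb
#' and 1-2 kb up- and downstream) from the home genome, finds the best
#' hit of each in the target genome with [best_hit_search()], and applies
#' [assess_presence()].
#'
#' @param home_genome,target_genome Named character chromosome vectors.
#' @param chrom Home chromosome of the element.
#' @param start,end Element span in the home genome (1-based closed).
#' @param ... Passed to [assess_presence()].
#' @return As [assess_presence()].
#' @export
presence_in_genome <- function(home_genome, target_genome, chrom, start,
                               end, ...) {
  seq <- home_genome[[chrom]]
  n <- nchar(seq)
  element <- substr(seq, start, end)
  probes <- list(
    up2 = c(max(1L, start - 2000L), start - 1001L),
    up1 = c(max(1L, start - 1000L), start - 1L),
    down1 = c(end + 1L, min(n, end + 1000L)),
    down2 = c(end + 1001L, min(n, end + 2000L)))
  flank_hits <- list()
  for (nm in names(probes)) {
    p <- probes[[nm]]
    if (p[2L] - p[1L] + 1L < 200L) next  # probe truncated at contig edge
    flank_hits[[nm]] <- best_hit_search(substr(seq, p[1L], p[2L]),
                                        target_genome)
  }
  eh <- best_hit_search(element, target_genome)
  assess_presence(eh, flank_hits, home_chrom = chrom, ...)
}

#' Assign the origin branch of an element by Dollo parsimony
#'
#' Under a single-gain, multi-loss model the element originated on the
#' branch above the most recent common ancestor of all taxa carrying it;
#' absences inside that clade are interpreted as losses and flagged.
#'
#' @param presence Named logical vector over the tree's tip labels.
#' @param tree `phylo` with node labels.
#' @return list `branch` (label), `losses` (tips inside the clade lacking
#'   the element), `clade` (tips below the origin branch).
#' @export
assign_origin_branch <- function(presence, tree) {
  tips <- names(presence)[presence]
  if (length(tips) == 0L) stop("element present in no taxon")
  missing_tips <- setdiff(tips, tree$tip.label)
  if (length(missing_tips)) stop("taxa not in tree: ",
                                 paste(missing_tips, collapse = ", "))
  if (length(tips) == 1L) {
    return(list(branch = tips, losses = character(0), clade = tips))
  }
  node <- ape::getMRCA(tree, tips)
  label <- branch_label(tree, node)
  clade <- branch_clade(tree, label)
  list(branch = label, losses = setdiff(clade, tips), clade = clade)
}

#' Map an origin branch to an evolutionary age group
#'
#' Terminal branches are species-specific; branches whose clade lies
#' within the Asian clade are `Asian` (< ~0.8 MY); within the AA-genome
#' clade, `AA` (~0.8-6.8 MY); within AA+BB, `AB` (~6.8-26 MY); anything
#' older is `other`.
#'
#' @param branch Branch label.
#' @param tree `phylo` with node labels (default [oryza_tree()]).
#' @param clades Named list as from [oryza_age_clades()].
#' @return One of `"species-specific", "Asian", "AA", "AB", "other"`.
#' @export
classify_age_group <- function(branch, tree = oryza_tree(),
                               clades = oryza_age_clades()) {
  clade <- branch_clade(tree, branch)
  if (length(clade) == 1L) return("species-specific")
  if (all(clade %in% clades$asian)) return("Asian")
  if (all(clade %in% clades$aa)) return("AA")
  if (all(clade %in% clades$ab)) return("AB")
  "other"
}

#' Six-frame open reading frame scan
#'
#' Finds ATG-to-stop ORFs of at least `min_len` bp (stop included) on both
#' strands of a sequence.
#'
#' @param seq Character DNA sequence.
#' @param min_len Minimum ORF length in bp.
#' @return data.frame `start, end, strand, length, peptide` (coordinates
#'   on the input sequence, 1-based closed; peptide excludes the stop).
#' @export
find_orfs <- function(seq, min_len = 150L) {
  rows <- list()
  n <- nchar(seq)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") toupper(seq) else revcomp(toupper(seq))
    for (frame in 0:2) {
      starts <- seq(1L + frame, nchar(s) - 2L, by = 3L)
      codons <- substring(s, starts, starts + 2L)
      is_start <- codons == "ATG"
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      open <- NA_integer_
      for (i in seq_along(codons)) {
        if (is.na(open) && is_start[i]) open <- i
        if (!is.na(open) && is_stop[i]) {
          len <- (i - open + 1L) * 3L
          if (len >= min_len) {
            a <- starts[open]; b <- starts[i] + 2L
            if (strand == "-") {
              tmp <- a; a <- n - b + 1L; b <- n - tmp + 1L
            }
            cds <- substring(s, starts[open], starts[i] - 1L)
            pep <- as.character(Biostrings::translate(
              Biostrings::DNAString(cds)))
            rows[[length(rows) + 1L]] <- data.frame(
              start = a, end = b, strand = strand, length = len,
              peptide = pep, stringsAsFactors = FALSE)
          }
          open <- NA_integer_
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), strand = character(),
               length = integer(), peptide = character(),
               stringsAsFactors = FALSE)
}

#' Decide presence of a MULE-derived gene in another taxon
#'
#' Present when the protein best hit (E < `evalue_max`) overlaps the
#' genomic best hit; otherwise the genomic best-hit region is re-annotated
#' with [find_orfs()] and the gene peptide is compared against each ORF
#' peptide (>= `min_identity` identity over >= `min_len_frac` of the gene
#' peptide when no E-value is available).  A gene with no genomic hit
#' anywhere is absent.
#'
#' @param genomic_hit,protein_hit One-row best-hit records or `NULL`.
#' @param region_seq Sequence of the genomic best-hit region (for the ORF
#'   fallback), or `NULL`.
#' @param gene_peptide Peptide of the query gene.
#' @param evalue_max BLASTP-style E-value threshold.
#' @param min_identity,min_len_frac Fallback identity proxy.
#' @return logical: present in the other taxon?
#' @export
gene_present_in_taxon <- function(genomic_hit, protein_hit = NULL,
                                  region_seq = NULL, gene_peptide = NULL,
                                  evalue_max = 1e-10,
                                  min_identity = 0.4,
                                  min_len_frac = 0.5) {
  if (is.null(genomic_hit)) return(FALSE)
  if (!is.null(protein_hit) &&
      (is.na(protein_hit$evalue) || protein_hit$evalue < evalue_max)) {
    ov <- protein_hit$chrom == genomic_hit$chrom &&
      protein_hit$start <= genomic_hit$end &&
      protein_hit$end >= genomic_hit$start
    if (ov) return(TRUE)
  }
  if (is.null(region_seq) || is.null(gene_peptide)) return(FALSE)
  orfs <- find_orfs(region_seq)
  if (nrow(orfs) == 0L) return(FALSE)
  glen <- nchar(gene_peptide)
  for (pep in orfs$peptide) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(gene_peptide), Biostrings::AAString(pep),
      type = "local", substitutionMatrix = "BLOSUM62")
    alen <- IRanges::width(al@pattern@range)
    if (alen >= min_len_frac * glen &&
        Biostrings::nmatch(al) / Biostrings::nchar(al) >= min_identity) {
      return(TRUE)
    }
  }
  FALSE
}

#' Species specificity from per-taxon presence calls
#'
#' @param present_in_others Named logical vector of presence in each
#'   other taxon (e.g. from [gene_present_in_taxon()]).
#' @return TRUE when the gene is absent from every other taxon.
#' @export
species_specific_gene <- function(present_in_others) {
  length(present_in_others) == 0L || !any(present_in_others)
}

#' Origination rate of species-specific genes
#'
#' @param n_genes Count of species-specific genes.
#' @param divergence_my Divergence time of the species (million years).
#' @return Genes per million years.
#' @export
origination_rate <- function(n_genes, divergence_my) {
  if (divergence_my <= 0) stop("divergence time must be positive")
  n_genes / divergence_my
}

#' Presence/absence matrix of planted elements from a truth table
#'
#' @param bundle A `genome_bundle`.
#' @return Logical matrix, elements x taxa.
#' @export
truth_presence_matrix <- function(bundle) {
  taxa <- bundle$config$tree$tip.label
  ids <- bundle$elements$element_id
  m <- matrix(FALSE, nrow = length(ids), ncol = length(taxa),
              dimnames = list(ids, taxa))
  m[cbind(bundle$truth$element_id, bundle$truth$taxon)] <- TRUE
  m
}
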