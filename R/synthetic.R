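#' Configuration for the synthetic MULE genome generator
#'
#' Bundles every knob of the generator: the species tree (branch lengths in
#' million years), chromosome size, TIR family consensus sequences, how
#' many elements to plant on each branch, the neutral substitution rate and
#' the capture/autonomous/nested-TE mix.  Defaults emulate a desk-scale
#' *Oryza*-like study: 2 Mb per taxon on the 11-taxon tree of
#' [oryza_tree()], 50 non-autonomous elements per terminal taxon with clean
#' (unmutated) TSDs, ~40% of elements carrying a captured slice of a
#' GC-rich donor gene, and r = 1.3e-8 substitutions/site/year when branch
#' mutation is switched on.
#'
#' @param seed Integer random seed (mandatory; the whole bundle is a pure
#'   function of the config).
#' @param tree `phylo` species tree with node labels and branch lengths in
#'   MY.
#' @param chrom_length Chromosome length per taxon (bp).
#' @param tir_families Named character vector of TIR consensus sequences
#'   (100-500 bp).  Default: three random consensi of 150/200/250 bp.
#' @param insertions_per_branch Named integer vector over branch labels
#'   (see [tree_branch_labels()]); branches absent from the vector get 0.
#'   Default: 50 on every terminal branch.
#' @param tsd_range Allowed TSD lengths (drawn uniformly per insertion).
#' @param internal_range Internal-region length range (bp).
#' @param capture_fraction Fraction of elements whose internal region
#'   carries a full captured donor ORF (making them genic).
#' @param autonomous_fraction Fraction of elements flagged as carrying a
#'   transposase (reported in the emitted transposase hit table).
#' @param nested_te_fraction Fraction of elements receiving a planted
#'   non-MULE TE fragment inside the internal region.
#' @param n_genes Number of donor genes per genome.
#' @param donor_pool Optional integer indices of the genes eligible as
#'   capture donors (default: all genes).  Lets a study design plant
#'   parental loci in chosen genomic regions.
#' @param gc_background,gc_genes GC content of intergenic sequence and of
#'   donor genes.
#' @param r Neutral substitution rate (substitutions/site/year).
#' @param ti_tv Transition:transversion event ratio for [evolve_sequence()].
#' @param mutate `"none"` for clean genomes (default) or `"age"` to mutate
#'   each planted element for the midpoint age of its origin branch.
#' @return A `plant_config` list.
#' @export
plant_config <- function(seed,
                         tree = oryza_tree(),
                         chrom_length = 2e6,
                         tir_families = NULL,
                         insertions_per_branch = NULL,
                         tsd_range = 7:11,
                         internal_range = c(800L, 2500L),
                         capture_fraction = 0.4,
                         autonomous_fraction = 0.1,
                         nested_te_fraction = 0.1,
                         n_genes = 40L,
                         donor_pool = NULL,
                         gc_background = 0.43,
                         gc_genes = 0.58,
                         r = 1.3e-8,
                         ti_tv = 2,
                         mutate = c("none", "age")) {
  if (missing(seed)) stop("plant_config() requires an explicit seed")
  mutate <- match.arg(mutate)
  stopifnot(all(tsd_range >= 7L), all(tsd_range <= 11L), r > 0,
            chrom_length > 1e4)
  if (is.null(tir_families)) {
    set.seed(seed + 1L)
    tir_families <- vapply(c(150L, 200L, 250L), random_dna, character(1L))
    names(tir_families) <- paste0("TIRfam", seq_along(tir_families))
  }
  tl <- nchar(tir_families)
  stopifnot(all(tl >= 100L), all(tl <= 500L))
  if (is.null(insertions_per_branch)) {
    insertions_per_branch <- stats::setNames(
      rep(50L, length(tree$tip.label)), tree$tip.label)
  }
  unknown <- setdiff(names(insertions_per_branch), tree_branch_labels(tree))
  if (length(unknown)) stop("insertions_per_branch names not in tree: ",
                            paste(unknown, collapse = ", "))
  if (!is.null(donor_pool)) {
    stopifnot(all(donor_pool >= 1L), all(donor_pool <= n_genes))
  }
  structure(list(
    seed = seed, tree = tree, chrom_length = as.integer(chrom_length),
    tir_families = tir_families,
    insertions_per_branch = insertions_per_branch,
    tsd_range = tsd_range, internal_range = as.integer(internal_range),
    capture_fraction = capture_fraction,
    autonomous_fraction = autonomous_fraction,
    nested_te_fraction = nested_te_fraction,
    n_genes = as.integer(n_genes),
    donor_pool = if (is.null(donor_pool)) NULL else as.integer(donor_pool),
    gc_background = gc_background, gc_genes = gc_genes,
    r = r, ti_tv = ti_tv, mutate = mutate
  ), class = "plant_config")
}

# one random gene: ATG + non-stop codons + stop, GC steered by codon draw
make_gene_seq <- function(n_codons, gc) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste,
                  collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  gcw <- vapply(strsplit(codons, ""), function(x)
    sum(x %in% c("G", "C")), numeric(1L))
  w <- gc^gcw * (1 - gc)^(3 - gcw)
  body <- sample(codons, n_codons, replace = TRUE, prob = w)
  paste0("ATG", paste(body, collapse = ""), sample(c("TAA", "TAG", "TGA"), 1L))
}

#' Simulate genomes with planted, ground-truthed MULEs on a species tree
#'
#' Builds an ancestral chromosome carrying donor genes, assigns each
#' planted element to a tree branch, and emits one genome per taxon in
#' which every element is present at its orthologous site in exactly the
#' taxa descending from its origin branch (insertion shifts downstream
#' coordinates; the 7-11 bp target site is duplicated verbatim on both
#' sides of the element at insertion time).  Everything is reproducible
#' from the config seed.
#'
#' @param config A [plant_config()].
#' @return A `genome_bundle` list with components:
#'   \describe{
#'     \item{genomes}{named list (taxon) of named character vectors
#'       (chromosome sequences).}
#'     \item{genes}{named list of per-taxon gene annotations (data.frame:
#'       `gene_id, chrom, start, end, strand, cds_start, cds_end, origin`
#'       where origin is `"host"` or `"captured"`).}
#'     \item{truth}{data.frame, one row per (element, carrying taxon) with
#'       TIR/internal/TSD coordinates and sequences.}
#'     \item{elements}{per-element metadata: family, origin branch, donor
#'       gene, autonomous flag, nested-TE flag.}
#'     \item{transposase_hits}{simulated TBLASTN hit table covering the
#'       autonomous elements (per taxon).}
#'     \item{te_library}{named character vector of non-MULE TE sequences
#'       used for nested insertions.}
#'     \item{config}{the input config.}
#'   }
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "plant_config"))
  set.seed(config$seed)
  tree <- config$tree
  taxa <- tree$tip.label
  L <- config$chrom_length

  ancestral <- random_dna(L, config$gc_background)

  # donor genes, evenly spaced with jitter, strictly non-overlapping
  ng <- config$n_genes
  slots <- round(seq(0.03, 0.97, length.out = ng) * L)
  genes <- vector("list", ng)
  anc <- ancestral
  for (i in seq_len(ng)) {
    n_codons <- sample(100:300, 1L)
    gseq <- make_gene_seq(n_codons, config$gc_genes)
    glen <- nchar(gseq)
    gstart <- slots[i]
    substr(anc, gstart, gstart + glen - 1L) <- gseq
    genes[[i]] <- data.frame(
      gene_id = sprintf("gene%03d", i), chrom = "chr1",
      start = gstart, end = gstart + glen - 1L, strand = "+",
      cds_start = gstart, cds_end = gstart + glen - 1L,
      origin = "host", stringsAsFactors = FALSE)
  }
  ancestral <- anc
  gene_tab <- do.call(rbind, genes)

  te_library <- c(nonMuleTE1 = random_dna(600, 0.40),
                  nonMuleTE2 = random_dna(400, 0.40))

  # element definitions, one per planted insertion.  Sites carried by the
  # same taxon are kept >= ~5 kb apart (clean flank probes and pairing);
  # sites never co-occurring may sit closer, but all sites are distinct by
  # a 200-bp guard so TSD/coordinate bookkeeping never collides.
  counts <- config$insertions_per_branch
  counts <- counts[counts > 0L]
  defs <- list()
  gene_iv <- IRanges::IRanges(gene_tab$start - 200L, gene_tab$end + 200L)
  # branches co-occur when one is ancestral to the other
  brs <- names(counts)
  clades <- lapply(brs, branch_clade, tree = tree)
  names(clades) <- brs
  co_occur <- outer(brs, brs, Vectorize(function(x, y)
    length(intersect(clades[[x]], clades[[y]])) > 0L))
  dimnames(co_occur) <- list(brs, brs)
  def_pos <- integer(0); def_branch <- character(0)
  eid <- 0L
  for (br in names(counts)) {
    for (k in seq_len(counts[[br]])) {
      eid <- eid + 1L
      fam <- sample(names(config$tir_families), 1L)
      tir <- config$tir_families[[fam]]
      tsd_len <- sample(config$tsd_range, 1L)
      int_len <- sample(seq(config$internal_range[1L],
                            config$internal_range[2L]), 1L)
      captured <- stats::runif(1) < config$capture_fraction
      donor <- NA_character_; cap_seq <- NULL; cap_off <- NA_integer_
      if (captured) {
        pool <- config$donor_pool %||% seq_len(nrow(gene_tab))
        di <- pool[sample(length(pool), 1L)]
        donor <- gene_tab$gene_id[di]
        cap_seq <- subseq_chr(ancestral, gene_tab$start[di],
                              gene_tab$end[di])
        pad <- max(int_len - nchar(cap_seq), 200L)
        pad1 <- sample(100:(pad - 100L), 1L)
        internal <- paste0(random_dna(pad1, config$gc_background), cap_seq,
                           random_dna(pad - pad1, config$gc_background))
        cap_off <- pad1  # captured ORF starts at internal offset pad1 + 1
      } else {
        internal <- random_dna(int_len, config$gc_background)
      }
      nested <- stats::runif(1) < config$nested_te_fraction
      nest_rel <- NULL
      if (nested) {
        te <- sample(names(te_library), 1L)
        teseq <- te_library[[te]]
        # append the TE fragment at the far end of the internal region so
        # it never disrupts a captured ORF
        nest_rel <- c(nchar(internal) + 1L,
                      nchar(internal) + nchar(teseq))
        internal <- paste0(internal, teseq)
      }
      autonomous <- stats::runif(1) < config$autonomous_fraction
      # draw an insertion site away from genes, away from every other
      # site by a small guard, and away from co-occurring sites widely
      pos <- NA_integer_
      clean_element <- paste0(tir, internal, revcomp(tir))
      for (try in 1:200) {
        p <- sample(seq(3000L, L - 3000L), 1L)
        if (length(IRanges::findOverlaps(
          IRanges::IRanges(p - 2500L, p + 2500L), gene_iv)) > 0L) next
        near <- which(abs(def_pos - p) <= 5000L)
        if (any(abs(def_pos - p) <= 200L)) next
        if (length(near) &&
            any(co_occur[br, def_branch[near]])) next
        # the planted TSD must be the unambiguous best candidate at this
        # site: chance coincidences between flank and TIR-edge bases can
        # otherwise make a longer perfect duplication outscore the truth
        local <- paste0(subseq_chr(ancestral, p - 40L, p + tsd_len),
                        clean_element,
                        subseq_chr(ancestral, p + 1L, p + tsd_len + 40L))
        ts <- tsd_len + 42L
        te <- tsd_len + 41L + nchar(clean_element)
        got <- suppressWarnings(find_tsd(local, ts, te))
        if (is.null(got) || got$tsd_len != tsd_len ||
            got$left_offset != 0L || got$right_offset != 0L ||
            got$mismatches != 0L) next
        pos <- p
        def_pos <- c(def_pos, p); def_branch <- c(def_branch, br)
        break
      }
      if (is.na(pos)) stop("could not place insertion after 200 retries; ",
                           "reduce insertion count or enlarge chromosome")
      defs[[eid]] <- list(
        element_id = sprintf("MULE%04d", eid), branch = br, family = fam,
        tir = tir, internal = internal, tsd_len = tsd_len,
        pos = pos, donor = donor, captured = captured,
        cap_seq = cap_seq, cap_off = cap_off,
        nested = nested, nest_rel = nest_rel, autonomous = autonomous)
    }
  }

  # carriers: taxa descending from each element's origin branch
  carriers <- lapply(defs, function(d) branch_clade(tree, d$branch))
  ages <- node_ages(tree)  # MY
  parent_of <- function(node) {
    e <- tree$edge[tree$edge[, 2L] == node, 1L]
    if (length(e)) e else NA_integer_
  }

  genomes <- list(); taxa_genes <- list(); truth_rows <- list()
  tn_rows <- list()
  for (tx in taxa) {
    mine <- which(vapply(carriers, function(cc) tx %in% cc, logical(1L)))
    mine <- mine[order(vapply(defs[mine], `[[`, numeric(1L), "pos"))]
    parts <- character(0)
    cursor <- 1L
    shift <- 0L
    gene_rows <- gene_tab
    ins_pos <- integer(0); ins_len_all <- integer(0)
    for (i in mine) {
      d <- defs[[i]]
      tirseq <- d$tir
      internal <- d$internal
      # optional per-element mutation for the element's age
      if (config$mutate == "age") {
        node <- branch_node(tree, d$branch)
        par <- parent_of(node)
        mid_my <- if (is.na(par)) ages[node] else
          (ages[node] + ages[par]) / 2
        t_years <- mid_my * 1e6
        tirL <- evolve_sequence(tirseq, config$r, t_years, config$ti_tv)
        tirR <- evolve_sequence(tirseq, config$r, t_years, config$ti_tv)
        internal <- evolve_sequence(internal, config$r, t_years,
                                    config$ti_tv)
      } else {
        tirL <- tirseq; tirR <- tirseq
      }
      k <- d$tsd_len
      tsd <- subseq_chr(ancestral, d$pos + 1L, d$pos + k)
      element <- paste0(tirL, internal, revcomp(tirR))
      elen <- nchar(element)
      # splice: ...[..pos+k] ELEMENT [pos+1..]... (duplicates the TSD)
      parts <- c(parts, subseq_chr(ancestral, cursor, d$pos + k), element)
      cursor <- d$pos + 1L
      p1 <- d$pos + shift           # last base before left TSD copy
      lt_start <- p1 + k + 1L
      tirlen <- nchar(tirL)
      row <- data.frame(
        element_id = d$element_id, taxon = tx, chrom = "chr1",
        family = d$family, origin_branch = d$branch,
        tsd = tsd, tsd_len = k,
        ltsd_start = p1 + 1L, ltsd_end = p1 + k,
        ltir_start = lt_start, ltir_end = lt_start + tirlen - 1L,
        internal_start = lt_start + tirlen,
        internal_end = lt_start + tirlen + nchar(internal) - 1L,
        rtir_start = lt_start + tirlen + nchar(internal),
        rtir_end = lt_start + elen - 1L,
        rtsd_start = p1 + k + elen + 1L, rtsd_end = p1 + k + elen + k,
        donor_gene = d$donor, captured = d$captured,
        autonomous = d$autonomous, nested = d$nested,
        stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- row
      # captured ORF becomes an annotated transcript inside the element
      if (d$captured) {
        cstart <- row$internal_start + d$cap_off
        cend <- cstart + nchar(d$cap_seq) - 1L
        gene_rows <- rbind(gene_rows, data.frame(
          gene_id = paste0(d$element_id, ".cap"), chrom = "chr1",
          start = cstart, end = cend, strand = "+",
          cds_start = cstart, cds_end = cend,
          origin = "captured", stringsAsFactors = FALSE))
      }
      if (d$autonomous) {
        tn_rows[[length(tn_rows) + 1L]] <- data.frame(
          taxon = tx, chrom = "chr1",
          start = row$internal_start + 10L,
          end = min(row$internal_end, row$internal_start + 500L),
          evalue = 1e-20, stringsAsFactors = FALSE)
      }
      ins_len <- elen + k
      ins_pos <- c(ins_pos, d$pos); ins_len_all <- c(ins_len_all, ins_len)
      shift <- shift + ins_len
    }
    # shift host-gene coordinates past all insertions (ancestral -> taxon)
    host <- gene_rows$origin == "host"
    if (length(ins_pos) && any(host)) {
      shift_of <- function(x) vapply(
        x, function(p) sum(ins_len_all[ins_pos < p]), numeric(1L))
      dd <- shift_of(gene_rows$start[host])
      gene_rows$start[host] <- gene_rows$start[host] + dd
      gene_rows$end[host] <- gene_rows$end[host] + dd
      gene_rows$cds_start[host] <- gene_rows$cds_start[host] + dd
      gene_rows$cds_end[host] <- gene_rows$cds_end[host] + dd
    }
    parts <- c(parts, subseq_chr(ancestral, cursor, L))
    genomes[[tx]] <- c(chr1 = paste(parts, collapse = ""))
    taxa_genes[[tx]] <- gene_rows[order(gene_rows$start), ]
  }

  elements <- do.call(rbind, lapply(defs, function(d) data.frame(
    element_id = d$element_id, family = d$family, origin_branch = d$branch,
    tir_length = nchar(d$tir), tsd_len = d$tsd_len,
    donor_gene = d$donor, captured = d$captured,
    autonomous = d$autonomous, nested = d$nested,
    stringsAsFactors = FALSE)))

  structure(list(
    genomes = genomes, genes = taxa_genes,
    truth = do.call(rbind, truth_rows), elements = elements,
    transposase_hits = if (length(tn_rows)) do.call(rbind, tn_rows) else
      data.frame(taxon = character(), chrom = character(),
                 start = integer(), end = integer(), evalue = numeric()),
    te_library = te_library, config = config
  ), class = "genome_bundle")
}

#' Evolve a sequence under the Kimura two-parameter model
#'
#' Applies a Poisson number of substitution events (expectation
#' `length * r * t_years`) at uniform positions; each event is a
#' transition with probability `ti_tv / (ti_tv + 2)` and otherwise one of
#' the two transversions.  Multiple hits at a site are allowed, so the
#' K2P-corrected distance to the ancestor is an unbiased estimate of
#' `r * t_years`.
#'
#' @param seq Character DNA sequence.
#' @param r Substitution rate per site per year.
#' @param t_years Elapsed time in years.
#' @param ti_tv Transition:transversion event ratio (default 2).
#' @param seed Optional seed for a self-contained draw.
#' @return The mutated sequence (same length).
#' @export
evolve_sequence <- function(seq, r, t_years, ti_tv = 2, seed = NULL) {
  stopifnot(t_years >= 0, r > 0, ti_tv > 0)
  if (!is.null(seed)) set.seed(seed)
  if (t_years == 0) return(seq)
  bases <- strsplit(seq, "")[[1L]]
  L <- length(bases)
  n_events <- stats::rpois(1L, L * r * t_years)
  if (n_events == 0L) return(seq)
  pos <- sample.int(L, n_events, replace = TRUE)
  p_ti <- ti_tv / (ti_tv + 2)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversion <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))
  is_ti <- stats::runif(n_events) < p_ti
  for (i in seq_len(n_events)) {
    b <- bases[pos[i]]
    if (!b %in% c("A", "C", "G", "T")) next
    bases[pos[i]] <- if (is_ti[i]) transition[[b]] else
      sample(transversion[[b]], 1L)
  }
  paste(bases, collapse = "")
}

#' Locate cytosines and their methylation contexts in a sequence
#'
#' Both strands are scanned: a plus-strand cytosine's context is read from
#' the two following bases (CG if the next base is G, CHG if the base after
#' next is G, else CHH); minus-strand contexts mirror this on the
#' complement.
#'
#' @param seq Character chromosome sequence.
#' @param chrom Chromosome name for the output.
#' @return data.frame `chrom, pos, strand, context`.
#' @export
cytosine_contexts <- function(seq, chrom = "chr1") {
  b <- strsplit(toupper(seq), "")[[1L]]
  L <- length(b)
  out <- list()
  ip <- which(b == "C")
  if (length(ip)) {
    nxt1 <- ifelse(ip + 1L <= L, b[pmin(ip + 1L, L)], "N")
    nxt2 <- ifelse(ip + 2L <= L, b[pmin(ip + 2L, L)], "N")
    ctx <- ifelse(nxt1 == "G", "CG", ifelse(nxt2 == "G", "CHG", "CHH"))
    out$plus <- data.frame(chrom = chrom, pos = ip, strand = "+",
                           context = ctx, stringsAsFactors = FALSE)
  }
  im <- which(b == "G")
  if (length(im)) {
    prv1 <- ifelse(im - 1L >= 1L, b[pmax(im - 1L, 1L)], "N")
    prv2 <- ifelse(im - 2L >= 1L, b[pmax(im - 2L, 1L)], "N")
    ctx <- ifelse(prv1 == "C", "CG", ifelse(prv2 == "C", "CHG", "CHH"))
    out$minus <- data.frame(chrom = chrom, pos = im, strand = "-",
                            context = ctx, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$pos), , drop = FALSE]
}

#' Simulate a per-cytosine bisulfite report with region-specific levels
#'
#' Per cytosine, read depth is Poisson and the methylated count binomial
#' at the target level of the first region covering the site (or the
#' background level).  Target levels may differ by context via columns
#' `level_CG, level_CHG, level_CHH` in `regions`, or be shared via a
#' single `level` column.
#'
#' @param seq Chromosome sequence (character) used to place cytosines.
#' @param regions data.frame with `start, end` and level column(s);
#'   optional `chrom` (default all on `chrom`).
#' @param mean_depth Mean Poisson read depth per site.
#' @param background Background methylation level outside regions.
#' @param chrom Chromosome name.
#' @param seed Optional seed.
#' @return Cytosine-report data.frame (see [read_cytosine_report()]).
#' @export
simulate_methylome <- function(seq, regions, mean_depth = 10,
                               background = 0.05, chrom = "chr1",
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sites <- cytosine_contexts(seq, chrom)
  lev <- rep(background, nrow(sites))
  if (!is.null(regions) && nrow(regions)) {
    for (ctx in c("CG", "CHG", "CHH")) {
      colnm <- if (paste0("level_", ctx) %in% names(regions))
        paste0("level_", ctx) else "level"
      if (!colnm %in% names(regions)) stop("regions needs a 'level' or ",
                                           "'level_<context>' column")
      if (any(regions[[colnm]] < 0 | regions[[colnm]] > 1))
        stop("target methylation levels must lie in [0, 1]")
      sel <- sites$context == ctx
      hit <- findInterval(sites$pos[sel], regions$start)
      ok <- hit >= 1L & sites$pos[sel] <= regions$end[pmax(hit, 1L)]
      lev[sel][ok] <- regions[[colnm]][hit[ok]]
    }
  }
  depth <- stats::rpois(nrow(sites), mean_depth)
  meth <- stats::rbinom(nrow(sites), depth, lev)
  data.frame(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
             context = sites$context, meth = meth, total = depth,
             stringsAsFactors = FALSE)
}

#' Simulate 24-nt small-RNA mapping records and per-gene expression counts
#'
#' Small RNAs: each region spawns `Poisson(abundance)` distinct sRNA
#' species per tissue, uniformly placed, of length 24 (a small fraction of
#' 21/22-nt species is mixed in as negatives for the length filter); each
#' species is multi-mapping with probability `multi_frac`, and carries a
#' read count.  Expression: per-gene, per-tissue fragment counts are
#' Poisson at the profile mean.
#'
#' @param srna_regions data.frame `chrom, start, end, abundance` (expected
#'   species per region), optionally per-`tissue` rows.
#' @param expr_profiles data.frame `gene_id, tissue, mean_count`.
#' @param multi_frac Probability that an sRNA species is multi-mapping.
#' @param other_len_frac Fraction of non-24-nt species.
#' @param seed Optional seed.
#' @return list(srna = data.frame `chrom, start, end, length, count,
#'   n_loci, tissue`, expression = data.frame `gene_id, tissue, count`).
#' @export
simulate_srna_and_expression <- function(srna_regions = NULL,
                                         expr_profiles = NULL,
                                         multi_frac = 0.2,
                                         other_len_frac = 0.1,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  srna <- NULL
  if (!is.null(srna_regions) && nrow(srna_regions)) {
    if (!"tissue" %in% names(srna_regions)) srna_regions$tissue <- "pooled"
    rows <- list()
    for (i in seq_len(nrow(srna_regions))) {
      rg <- srna_regions[i, ]
      n <- stats::rpois(1L, rg$abundance)
      if (n == 0L) next
      len <- ifelse(stats::runif(n) < other_len_frac,
                    sample(c(21L, 22L), n, replace = TRUE), 24L)
      start <- sample(seq(rg$start, max(rg$start, rg$end - 23L)), n,
                      replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = rg$chrom, start = start, end = start + len - 1L,
        length = len,
        count = 1L + stats::rpois(n, 2),
        n_loci = ifelse(stats::runif(n) < multi_frac,
                        sample(2:5, n, replace = TRUE), 1L),
        tissue = rg$tissue, stringsAsFactors = FALSE)
    }
    srna <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 length = integer(), count = integer(),
                 n_loci = integer(), tissue = character())
  }
  expr <- NULL
  if (!is.null(expr_profiles) && nrow(expr_profiles)) {
    expr <- expr_profiles
    expr$count <- stats::rpois(nrow(expr), expr$mean_count)
    expr$mean_count <- NULL
  }
  list(srna = srna, expression = expr)
}

#' Write a genome bundle to disk as plain-text files
#'
#' FASTA per taxon, gene annotation GFF3 per taxon, the truth table as
#' TSV and the species tree as Newick.
#'
#' @param bundle A `genome_bundle` from [simulate_genomes()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tx in names(bundle$genomes)) {
    dna <- Biostrings::DNAStringSet(bundle$genomes[[tx]])
    Biostrings::writeXStringSet(dna, file.path(dir, paste0(tx, ".fa")))
    g <- bundle$genes[[tx]]
    gr <- GenomicRanges::GRanges(
      g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      source = "mulescout", type = "gene", score = ".", phase = ".",
      attributes = paste0("ID=", g$gene_id, ";origin=", g$origin))
    write_intervals(gr, file.path(dir, paste0(tx, ".genes.gff3")), "gff3")
  }
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(bundle$config$tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}
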