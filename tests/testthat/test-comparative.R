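test_that("presence needs both identity coverage and synteny evidence", {
  eh <- data.frame(chrom = "chr2", start = 10000L, end = 12000L,
                   strand = "+", identity = 95, length = 2000L,
                   coverage = 0.5)
  near <- data.frame(chrom = "chr2", start = 13000L, end = 13900L,
                     strand = "+", identity = 95, length = 900L,
                     coverage = 0.9)
  far <- data.frame(chrom = "chr2", start = 40000L, end = 40900L,
                    strand = "+", identity = 95, length = 900L,
                    coverage = 0.9)
  other_chrom <- transform(near, chrom = "chr3")
  # rule (a): coverage 50%, one flank 1 kb away, same (home) chromosome
  r <- assess_presence(eh, list(near), home_chrom = "chr2")
  expect_true(r$present)
  # identity failure: coverage 20%
  eh_low <- transform(eh, coverage = 0.2)
  expect_false(assess_presence(eh_low, list(near, near),
                               home_chrom = "chr2")$present)
  # synteny failure: flanks 28 kb away / other chromosome
  expect_false(assess_presence(eh, list(far, other_chrom),
                               home_chrom = "chr9")$present)
  # rule (b): two close flanks rescue a translocated home chromosome
  expect_true(assess_presence(eh, list(near, near),
                              home_chrom = "chr9")$present)
  # edge elements with missing probes are flagged
  expect_true(assess_presence(eh, list(near), home_chrom = "chr2")$flagged)
})

test_that("presence probing is symmetric for clean orthologous insertions", {
  b <- small_bundle()
  shared <- b$truth[b$truth$origin_branch == "R", ]
  el <- shared[shared$taxon == "A", ][1, ]
  el_b <- shared[shared$taxon == "B" &
                   shared$element_id == el$element_id, ]
  ab <- presence_in_genome(b$genomes[["A"]], b$genomes[["B"]],
                           el$chrom, el$ltsd_start, el$rtsd_end)
  ba <- presence_in_genome(b$genomes[["B"]], b$genomes[["A"]],
                           el_b$chrom, el_b$ltsd_start, el_b$rtsd_end)
  expect_true(ab$present)
  expect_true(ba$present)
  # an element on A's terminal branch is not found in C
  priv <- b$truth[b$truth$origin_branch == "A", ][1, ]
  ac <- presence_in_genome(b$genomes[["A"]], b$genomes[["C"]],
                           priv$chrom, priv$ltsd_start, priv$rtsd_end)
  expect_false(ac$present)
})

test_that("Dollo origin assignment returns the MRCA branch", {
  tree <- oryza_tree()
  taxa <- tree$tip.label
  p1 <- stats::setNames(taxa == "japonica", taxa)
  expect_equal(assign_origin_branch(p1, tree)$branch, "japonica")
  expect_equal(classify_age_group("japonica", tree), "species-specific")
  p2 <- stats::setNames(taxa %in% c("japonica", "rufipogon"), taxa)
  r2 <- assign_origin_branch(p2, tree)
  expect_equal(r2$branch, "Asian")
  expect_setequal(r2$losses, c("nivara", "indica"))
  p_all <- stats::setNames(rep(TRUE, length(taxa)), taxa)
  expect_equal(assign_origin_branch(p_all, tree)$branch, "Root")
  expect_error(assign_origin_branch(stats::setNames(
    rep(FALSE, length(taxa)), taxa), tree), "no taxon")
})

test_that("age groups map clades to Asian/AA/AB windows", {
  tree <- oryza_tree()
  expect_equal(classify_age_group("Asian", tree), "Asian")
  expect_equal(classify_age_group("JapNiv", tree), "Asian")
  expect_equal(classify_age_group("AA", tree), "AA")
  expect_equal(classify_age_group("AmAA", tree), "AA")
  expect_equal(classify_age_group("AB", tree), "AB")
  expect_equal(classify_age_group("Oryza", tree), "other")
  expect_equal(classify_age_group("Root", tree), "other")
  expect_error(classify_age_group("nosuch", tree), "unknown")
})

test_that("simulated losses can only make the inferred origin younger, never older", {
  tree <- oryza_tree()
  taxa <- tree$tip.label
  ages <- stats::setNames(
    mulescout:::node_ages(tree)[vapply(tree_branch_labels(tree),
                                       mulescout:::branch_node,
                                       integer(1), tree = tree)],
    tree_branch_labels(tree))
  set.seed(31)
  for (i in 1:100) {
    br <- sample(tree_branch_labels(tree), 1)
    clade <- branch_clade(tree, br)
    presence <- stats::setNames(taxa %in% clade, taxa)
    # no losses: exact recovery
    expect_equal(assign_origin_branch(presence, tree)$branch, br)
    # random losses keeping at least one carrier
    pres <- presence
    carriers <- which(pres)
    if (length(carriers) > 1) {
      drop <- sample(carriers, sample(length(carriers) - 1, 1))
      pres[drop] <- FALSE
    }
    inferred <- assign_origin_branch(pres, tree)$branch
    expect_lte(ages[[inferred]], ages[[br]])
  }
})

test_that("six-frame ORF scan finds planted ORFs on both strands", {
  set.seed(32)
  orf <- random_cds(60)  # 180 bp
  # C-homopolymer padding cannot harbour upstream in-frame ATGs
  fwd <- paste0(strrep("C", 97), orf, strrep("C", 100))
  found <- find_orfs(fwd, min_len = 150L)
  expect_true(any(found$start == 98L & found$end == 97L + nchar(orf) &
                    found$strand == "+"))
  rev <- paste0(strrep("C", 50), revcomp(orf), strrep("C", 61))
  found_rev <- find_orfs(rev, min_len = 150L)
  expect_true(any(found_rev$strand == "-" & found_rev$start == 51L))
  # no ORF below the length floor
  short <- find_orfs(paste0(strrep("C", 10), random_cds(20),
                            strrep("C", 10)), min_len = 150L)
  expect_true(all(short$length >= 150L))
})

test_that("cross-taxon gene presence follows the protein/ORF decision rule", {
  gh <- data.frame(chrom = "chr1", start = 1000L, end = 2000L,
                   strand = "+", identity = 98, length = 1000L,
                   coverage = 0.9)
  ph_overlap <- data.frame(chrom = "chr1", start = 1500L, end = 1900L,
                           evalue = 1e-20)
  ph_far <- data.frame(chrom = "chr1", start = 99000L, end = 99400L,
                       evalue = 1e-20)
  expect_true(gene_present_in_taxon(gh, ph_overlap))
  expect_false(gene_present_in_taxon(NULL, ph_overlap))
  # no protein hit: ORF fallback on the extracted region
  set.seed(33)
  cds <- random_cds(80)
  pep <- as.character(Biostrings::translate(Biostrings::DNAString(
    substr(cds, 1, nchar(cds) - 3))))
  region <- paste0(random_dna(60), cds, random_dna(60))
  expect_true(gene_present_in_taxon(gh, ph_far, region_seq = region,
                                    gene_peptide = pep))
  expect_false(gene_present_in_taxon(gh, ph_far,
                                     region_seq = random_dna(400),
                                     gene_peptide = pep))
  expect_true(species_specific_gene(c(B = FALSE, C = FALSE)))
  expect_false(species_specific_gene(c(B = TRUE, C = FALSE)))
})

test_that("origination rate is a simple quotient with guarded input", {
  expect_equal(origination_rate(20, 0.5), 40)
  expect_equal(origination_rate(0, 1), 0)
  expect_equal(origination_rate(49, 0.25), 196)
  expect_error(origination_rate(5, 0), "positive")
})

test_that("truth presence matrix matches the planted carrier sets", {
  b <- small_bundle()
  m <- truth_presence_matrix(b)
  tree <- b$config$tree
  for (i in seq_len(nrow(b$elements))) {
    el <- b$elements[i, ]
    expect_setequal(colnames(m)[m[el$element_id, ]],
                    branch_clade(tree, el$origin_branch))
  }
})
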