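test_that("tsd allowances follow the 7/8/9-11 bp rules", {
  expect_equal(tsd_allowance(7L), 0L)
  expect_equal(tsd_allowance(8L), 1L)
  expect_equal(tsd_allowance(9:11), c(2L, 2L, 2L))
  expect_error(tsd_allowance(6L))
})

test_that("find_tsd recovers a perfect 9-mer duplication at offset zero", {
  tsd <- "GATTACAAG"
  # dinucleotide-repeat flanks and a repeat-free element guarantee no
  # longer zero-mismatch candidate can outrank the planted 9-mer
  element <- "GTCAGGCTAAGCTTACGGATCCTGAACGTT"
  chrom <- paste0(strrep("AC", 20), tsd, element, tsd,
                  strrep("AG", 20))
  tir_start <- 50L  # first base of "element"
  tir_end <- 79L
  got <- find_tsd(chrom, tir_start, tir_end)
  expect_equal(got$tsd_len, 9L)
  expect_equal(got$mismatches, 0L)
  expect_equal(got$left_offset, 0L)
  expect_equal(got$right_offset, 0L)
  expect_equal(got$left_seq, tsd)
})

test_that("an 8-bp candidate with two differences is rejected", {
  # flanks built from a fixed alphabet pattern so no other candidate can
  # validate: left AAAAAAAA-like vs right with two substitutions
  chrom <- paste0(strrep("AC", 20), "AAAAAAAA", strrep("G", 30),
                  "AATTAAGA", strrep("CA", 20))
  # verify against the exhaustive oracle rather than asserting blindly
  got <- find_tsd(chrom, 49L, 78L)
  exp <- oracle_tsd(chrom, 49L, 78L)
  if (is.null(exp)) expect_null(got) else
    expect_equal(got$mismatches, exp$mismatches)
  # direct check: the 8-bp pair at offset 0 differs at 2 positions
  expect_gt(utils::adist("AAAAAAAA", "AATTAAGA")[1, 1], 1)
})

test_that("find_tsd equals the exhaustive oracle on random constructions", {
  set.seed(22)
  for (i in 1:200) {
    len <- sample(7:11, 1)
    n_mm <- sample(0:3, 1)
    tsd_l <- random_dna(len)
    tsd_r <- tsd_l
    if (n_mm > 0) {
      pos <- sample(len, min(n_mm, len))
      for (p in pos) {
        substr(tsd_r, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                              substr(tsd_r, p, p)), 1)
      }
    }
    off_l <- sample(-10:10, 1); off_r <- sample(-10:10, 1)
    left_flank <- random_dna(40)
    right_flank <- random_dna(40)
    substr(left_flank, 41 + off_l - len, 40 + off_l) <- tsd_l
    substr(right_flank, 1 + off_r, off_r + len) <- tsd_r
    chrom <- paste0(left_flank, strrep("T", 25), right_flank)
    got <- find_tsd(chrom, 41L, 65L)
    exp <- oracle_tsd(chrom, 41L, 65L)
    if (is.null(exp)) {
      expect_null(got)
    } else {
      expect_equal(got, exp, info = paste("case", i))
    }
  }
})

test_that("a truncated flank triggers a warning", {
  # fewer than 21 bp on the left: the search space is incomplete
  chrom <- paste0(strrep("AC", 5), "GATTACAAG", strrep("GT", 15),
                  "GATTACAAG", strrep("AG", 20))
  expect_warning(res <- find_tsd(chrom, 20L, 49L), "flank")
  expect_true(is.null(res) || res$mismatches <= 2L)
})

test_that("pairing enforces orientation, family and distance rules", {
  set.seed(23)
  genome <- c(chr1 = random_dna(60000))
  # same-orientation pair: no element
  h_same <- data.frame(chrom = "chr1", start = c(1000L, 3000L),
                       end = c(1150L, 3150L), strand = c("+", "+"),
                       family = "f1", identity = 100)
  expect_equal(nrow(pair_tirs(h_same, genome)), 0L)
  # opposite orientations but 25 kb apart: no element
  h_far <- data.frame(chrom = "chr1", start = c(1000L, 26500L),
                      end = c(1150L, 26650L), strand = c("+", "-"),
                      family = "f1", identity = 100)
  expect_equal(nrow(pair_tirs(h_far, genome)), 0L)
  # different families: no element
  h_fam <- data.frame(chrom = "chr1", start = c(1000L, 3000L),
                      end = c(1150L, 3150L), strand = c("+", "-"),
                      family = c("f1", "f2"), identity = 100)
  expect_equal(nrow(pair_tirs(h_fam, genome)), 0L)
})

test_that("clean planted elements are recalled exactly, and each TIR joins one element", {
  b <- small_bundle()
  cfg <- b$config
  for (tx in c("A", "C")) {
    els <- call_mules(b$genomes[[tx]], cfg$tir_families)
    tru <- b$truth[b$truth$taxon == tx, ]
    expect_equal(nrow(els), nrow(tru))
    k1 <- paste(els$ltir_start, els$ltir_end, els$rtir_start,
                els$rtir_end, els$tsd_left)
    k2 <- paste(tru$ltir_start, tru$ltir_end, tru$rtir_start,
                tru$rtir_end, tru$tsd)
    expect_setequal(k1, k2)
    # no TIR interval reused across elements
    ivs <- c(paste(els$ltir_start, els$ltir_end),
             paste(els$rtir_start, els$rtir_end))
    expect_equal(anyDuplicated(ivs), 0L)
  }
})

test_that("TSD mutation load never increases the number of called elements", {
  b <- small_bundle()
  cfg <- b$config
  tx <- "A"
  g <- b$genomes[[tx]]
  tru <- b$truth[b$truth$taxon == tx, ]
  hits <- scan_tir_hits(g, cfg$tir_families, fuzzy = FALSE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n_called <- integer(0)
  for (load in 0:4) {
    # nested corruption: complement the first `load` bases of every left
    # TSD copy, so higher load strictly contains lower load
    seq_mut <- g[["chr1"]]
    for (i in seq_len(nrow(tru))) {
      k <- min(load, tru$tsd_len[i])
      if (k == 0) next
      pos <- tru$ltsd_start[i] + seq_len(k) - 1L
      for (p in pos) {
        substr(seq_mut, p, p) <- comp[[substr(seq_mut, p, p)]]
      }
    }
    els <- pair_tirs(hits, c(chr1 = seq_mut))
    n_called <- c(n_called, nrow(els))
  }
  expect_true(all(diff(n_called) <= 0))
  expect_equal(n_called[1], nrow(tru))
  expect_lt(n_called[5], nrow(tru))
})

test_that("transposase screening applies the E-value threshold strictly", {
  els <- data.frame(element_id = c("m1", "m2", "m3"), chrom = "chr1",
                    start = c(100L, 5000L, 9000L),
                    end = c(2000L, 7000L, 9500L))
  hits <- data.frame(chrom = "chr1", start = c(500L, 5500L),
                     end = c(900L, 5900L), evalue = c(1e-10, 1e-8))
  out <- screen_transposase(els, hits)
  expect_equal(out$element_class,
               c("autonomous", "non-autonomous", "non-autonomous"))
  out0 <- screen_transposase(els, NULL)
  expect_true(all(out0$element_class == "non-autonomous"))
})

test_that("genic classification needs a 150-bp intact CDS and 30% overlap", {
  set.seed(25)
  # element spanning 1001..4000; transcripts with controlled CDS
  genome <- c(chr1 = random_dna(10000))
  g <- genome[["chr1"]]
  put_cds <- function(start, n_codons) {
    cds <- paste0("ATG", strrep("GCT", n_codons - 2L), "TAA")
    substr(g, start, start + nchar(cds) - 1L) <<- cds
    c(start, start + nchar(cds) - 1L)
  }
  c1 <- put_cds(1200L, 100L)   # 300 bp CDS inside the element
  c2 <- put_cds(5000L, 100L)   # fully outside
  c3 <- put_cds(3950L, 50L)    # 150 bp but only 51 bp inside (34%)
  genome <- c(chr1 = g)
  els <- data.frame(element_id = "m1", chrom = "chr1", start = 1001L,
                    end = 4000L, element_class = "non-autonomous")
  tx <- data.frame(
    gene_id = c("t1", "t2", "t3", "t4"), chrom = "chr1",
    start = c(c1[1], c2[1], c3[1], 1300L),
    end = c(c1[2], c2[2], c3[2], 1448L),
    strand = "+",
    cds_start = c(c1[1], c2[1], c3[1], 1300L),
    cds_end = c(c1[2], c2[2], c3[2], 1448L))
  out <- classify_genic(els, tx, genome)
  expect_equal(out$gene_class, "genic")
  # overlap below 30% of transcript length: nongenic
  els2 <- data.frame(element_id = "m1", chrom = "chr1", start = c1[1],
                     end = c1[1] + 80L, element_class = "non-autonomous")
  out2 <- classify_genic(els2, tx[1, ], genome)
  expect_equal(out2$gene_class, "nongenic")
  # 149-bp CDS can never qualify (not a codon multiple; below minimum)
  tx149 <- data.frame(gene_id = "t5", chrom = "chr1", start = 1300L,
                      end = 1448L, strand = "+", cds_start = 1300L,
                      cds_end = 1448L)
  out3 <- classify_genic(els, tx149, genome)
  expect_equal(out3$gene_class, "nongenic")
})

test_that("MULE-derived genes are exactly the planted captures", {
  b <- small_bundle()
  cfg <- b$config
  tx <- "C"
  els <- call_mules(b$genomes[[tx]], cfg$tir_families,
                    transposase_hits = b$transposase_hits[
                      b$transposase_hits$taxon == tx, ])
  genes <- call_mule_derived_genes(els, b$genes[[tx]], b$genomes[[tx]])
  tru <- b$truth[b$truth$taxon == tx, ]
  expected <- paste0(tru$element_id[tru$captured & !tru$autonomous],
                     ".cap")
  expect_setequal(genes$gene_id, expected)
  expect_true(all(genes$overlap_fraction >= 0.3))
  expect_true(all(genes$cds_len >= 150L))
})

test_that("TIR family validation applies copy, mask and element thresholds", {
  cons <- random_dna(200)
  mk_hits <- function(n) data.frame(chrom = rep("chr1", n),
                                    start = seq_len(n) * 1000L,
                                    end = seq_len(n) * 1000L + 199L)
  r1 <- validate_tir_family(cons, mk_hits(19), n_validated = 10)
  expect_false(r1$accepted)
  expect_match(r1$reason, "copy number")
  mask40 <- data.frame(start = 1L, end = 80L)
  r2 <- validate_tir_family(cons, mk_hits(25), nonmule_mask = mask40,
                            n_validated = 10)
  expect_false(r2$accepted)
  expect_match(r2$reason, "masked")
  r3 <- validate_tir_family(cons, mk_hits(25),
                            nonmule_mask = data.frame(start = 1L,
                                                      end = 20L),
                            n_validated = 6)
  expect_true(r3$accepted)
  r4 <- validate_tir_family(cons, mk_hits(25), n_validated = 4)
  expect_false(r4$accepted)
  r5 <- validate_tir_family(cons, mk_hits(0), n_validated = 0)
  expect_match(r5$reason, "no copies")
})
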