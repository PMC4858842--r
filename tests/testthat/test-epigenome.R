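mk_calls <- function(pos, meth, total, context = "CG", chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, strand = "+", context = context,
             meth = meth, total = total, stringsAsFactors = FALSE)
}

test_that("region methylation pools counts over mapped sites", {
  calls <- mk_calls(c(10, 20, 30), meth = c(2, 0, 4), total = c(4, 3, 5))
  r <- methylation_level(calls, "chr1", 1, 100, "CG")
  expect_equal(r$level, 0.5)   # 6 methylated of 12 mapped reads
  expect_equal(r$status, "ok")
  # site-binary mode: 2 of 3 mapped sites carry >= 1 methylated read
  r2 <- methylation_level(calls, "chr1", 1, 100, "CG", mode = "site")
  expect_equal(r2$level, 2 / 3)
})

test_that("coverage and mapped-fraction rules gate the estimate", {
  # 4 of 10 CG sites covered at >= 3 reads: undefined
  calls <- mk_calls(1:10 * 10, meth = rep(1, 10),
                    total = c(rep(5, 4), rep(2, 6)))
  r <- methylation_level(calls, "chr1", 1, 100, "CG")
  expect_true(is.na(r$level))
  expect_equal(r$status, "low_coverage")
  expect_equal(r$mapped_frac, 0.4)
  # a region with no cytosine of the context is flagged distinctly
  r0 <- methylation_level(calls, "chr1", 1, 100, "CHH")
  expect_equal(r0$status, "no_sites")
  # fully methylated covered sites give level 1
  full <- mk_calls(1:5 * 10, meth = rep(4, 5), total = rep(4, 5))
  expect_equal(methylation_level(full, "chr1", 1, 100, "CG")$level, 1)
})

test_that("methylation level equals the brute-force oracle on random fixtures", {
  set.seed(51)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    calls <- mk_calls(sort(sample(1:500, n)),
                      total = stats::rpois(n, 5),
                      meth = 0, context = sample(c("CG", "CHG", "CHH"),
                                                 n, replace = TRUE))
    calls$meth <- vapply(calls$total, function(t)
      if (t == 0) 0L else stats::rbinom(1, t, 0.4), integer(1))
    ctx <- sample(c("CG", "CHG", "CHH"), 1)
    r <- methylation_level(calls, "chr1", 50, 400, ctx)
    expect_equal(r$level, oracle_meth_level(calls, "chr1", 50, 400, ctx))
  }
})

test_that("raising the coverage threshold never increases defined regions", {
  set.seed(52)
  s <- random_dna(50000)
  calls <- simulate_methylome(
    s, data.frame(start = 1, end = 50000, level = 0.3), mean_depth = 4)
  regions <- data.frame(start = seq(1, 45001, by = 5000))
  regions$end <- regions$start + 4999
  n_defined <- vapply(c(3L, 5L, 7L), function(mc) {
    sum(vapply(seq_len(nrow(regions)), function(i)
      !is.na(methylation_level(calls, "chr1", regions$start[i],
                               regions$end[i], "CG",
                               min_coverage = mc)$level), logical(1)))
  }, numeric(1))
  expect_true(all(diff(n_defined) <= 0))
})

test_that("meta-profile recovers planted internal/TIR plateaus", {
  set.seed(53)
  n_el <- 15
  span <- 4000L
  elements <- data.frame(
    element_id = sprintf("m%02d", 1:n_el), chrom = "chr1",
    ltir_start = (0:(n_el - 1)) * span + 1001L)
  elements$ltir_end <- elements$ltir_start + 199L
  elements$internal_start <- elements$ltir_end + 1L
  elements$internal_end <- elements$internal_start + 1499L
  elements$rtir_start <- elements$internal_end + 1L
  elements$rtir_end <- elements$rtir_start + 199L
  s <- random_dna(n_el * span + 2000L)
  regions <- rbind(
    data.frame(start = elements$ltir_start, end = elements$ltir_end,
               level = 0.2),
    data.frame(start = elements$internal_start,
               end = elements$internal_end, level = 0.8),
    data.frame(start = elements$rtir_start, end = elements$rtir_end,
               level = 0.2))
  regions <- regions[order(regions$start), ]
  calls <- simulate_methylome(s, regions, mean_depth = 12,
                              background = 0.05)
  prof <- meta_profile(elements, calls, "CG", min_elements = 10)
  internal <- prof[prof$part == "internal", ]
  tirs <- prof[prof$part %in% c("ltir", "rtir"), ]
  expect_true(all(abs(internal$mean_level - 0.8) < 0.08))
  expect_true(all(abs(tirs$mean_level - 0.2) < 0.08))
  flank <- prof[prof$part %in% c("upstream", "downstream"), ]
  expect_true(all(flank$mean_level < 0.15, na.rm = TRUE))
  expect_false(any(internal$flagged))
})

test_that("TE content is the merged-overlap fraction", {
  expect_equal(te_content(1001L, 2000L, NULL), 0)
  expect_equal(te_content(1001L, 2000L,
                          data.frame(start = 1L, end = 5000L)), 1.0)
  hits <- data.frame(start = c(1101L, 1201L), end = c(1300L, 1400L))
  expect_equal(te_content(1001L, 2000L, hits), 0.3)
  # random cases against the per-base occupancy oracle
  set.seed(54)
  for (i in 1:20) {
    h <- data.frame(start = sample(900:2100, 5))
    h$end <- h$start + sample(0:300, 5)
    expect_equal(te_content(1001L, 2000L, h),
                 oracle_union_fraction(h$start, h$end, 1001L, 2000L))
  }
  expect_true(is.na(te_content(100L, 99L, hits)))
})

test_that("TIR similarity is identical bases over left TIR length", {
  expect_equal(tir_similarity("ACGT", "ACGA", orientation = "aligned"),
               0.75)
  t <- random_dna(120)
  expect_equal(tir_similarity(t, t, orientation = "aligned"), 1.0)
  # genomic orientation: the right TIR arrives reverse-complemented
  expect_equal(tir_similarity(t, revcomp(t)), 1.0)
  # divergence decreases similarity in expectation
  set.seed(55)
  sims <- vapply(c(0, 2e6, 8e6), function(T) {
    mean(vapply(1:10, function(i) {
      tir_similarity(t, evolve_sequence(t, 1.3e-8, T),
                     orientation = "aligned")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sims) < 0))
})

test_that("sRNA occupancy filters by length and mapping uniqueness", {
  regions <- data.frame(region_id = c("r1", "r2"), chrom = "chr1",
                        start = c(1000L, 5000L), end = c(1999L, 5999L),
                        group = c("young", "old"))
  srna <- data.frame(
    chrom = "chr1",
    start = c(1100L, 1200L, 1300L, 5100L),
    end = c(1123L, 1223L, 1320L, 5123L),
    length = c(24L, 24L, 21L, 24L),
    count = c(5L, 3L, 7L, 2L),
    n_loci = c(1L, 3L, 1L, 1L))
  occ <- srna_occupancy(regions, srna)
  pr <- occ$per_region
  expect_equal(pr$reads[pr$region_id == "r1"], 5)   # 21-nt and multi dropped
  expect_equal(pr$species[pr$region_id == "r1"], 1L)
  occ_all <- srna_occupancy(regions, srna, unique_only = FALSE)
  expect_equal(occ_all$per_region$reads[1], 8)
  expect_equal(occ$summary$reads[occ$summary$group == "old"], 2)
})

test_that("group comparison handles degeneracy, extremes and shifts", {
  d <- group_compare(rep(1, 5), rep(1, 5))
  expect_equal(d$p, 1)
  expect_true(d$flagged)
  r <- group_compare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(r$statistic), 0)
  expect_lt(r$p, 0.1)
  set.seed(56)
  a <- stats::rnorm(100); b <- stats::rnorm(100, 2)
  expect_lt(group_compare(a, b)$p, 1e-3)
  expect_lt(group_compare(a, b, test = "t")$p, 1e-3)
  expect_error(group_compare(1, c(1, 2)), ">= 2")
})
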