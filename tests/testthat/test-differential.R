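mk_tiles <- function(values, n_sites = NULL, chrom = "chr1") {
  n <- length(values)
  df <- data.frame(chrom = chrom, start = (seq_len(n) - 1L) * 400L + 1L,
                   end = seq_len(n) * 400L, value = values)
  if (!is.null(n_sites)) df$n_sites <- n_sites
  df
}

test_that("DHR calling requires both the 1.41 difference and the t-test", {
  # three tiles: clear difference, sub-threshold difference, high p
  a <- lapply(c(0.50, 0.52, 0.48), function(eps)
    mk_tiles(c(eps, 0.5, 1.0)))
  b <- list(mk_tiles(c(2.2, 1.48, 3.1)), mk_tiles(c(2.21, 1.52, 1.1)),
            mk_tiles(c(2.19, 1.50, 3.4)))
  res <- call_dhrs(a, b)
  expect_equal(res$called, c(TRUE, FALSE, FALSE))
  expect_equal(res$label, c("DHR", "", ""))
  expect_gt(abs(res$diff[1]), 1.41)
  expect_lt(res$p_value[1], 0.05)
  expect_lt(abs(res$diff[2]), 1.41 + 1e-9)   # significant but small
  expect_lt(res$p_value[2], 0.05)
  expect_gt(res$p_value[3], 0.05)            # large but noisy
  expect_gt(abs(res$diff[3]), 1.41)
})

test_that("a difference of exactly the threshold is not a DHR", {
  a <- list(mk_tiles(0.5), mk_tiles(0.5))
  b <- list(mk_tiles(1.91), mk_tiles(1.91))
  res <- call_dhrs(a, b)   # diff = 1.41 exactly: 'greater than' fails
  expect_false(res$called)
})

test_that("DMR calling enforces the 15% difference and 5-cytosine floor", {
  a <- lapply(1:3, function(i) mk_tiles(c(0.10, 0.10, 0.30) + i / 500,
                                        n_sites = c(6L, 4L, 7L)))
  b <- lapply(1:3, function(i) mk_tiles(c(0.40, 0.40, 0.38) + i / 500,
                                        n_sites = c(6L, 4L, 7L)))
  res <- call_dmrs(a, b)
  expect_equal(res$called, c(TRUE, FALSE, FALSE))
  expect_equal(res$label[1], "DMR")
  expect_equal(res$n_sites, c(6L, 4L, 7L))
})

test_that("replicate tile grids must match", {
  a <- list(mk_tiles(c(1, 2)), mk_tiles(c(1, 2))[1, ])
  b <- list(mk_tiles(c(3, 4)), mk_tiles(c(3, 4)))
  expect_error(call_dhrs(a, b), "chr1:401")
  expect_error(call_dhrs(list(mk_tiles(1)), b), "2 replicates")
})

test_that("swapping group labels negates differences and keeps p-values", {
  set.seed(81)
  a <- lapply(1:3, function(i) mk_tiles(runif(10)))
  b <- lapply(1:3, function(i) mk_tiles(runif(10, 1, 3)))
  r1 <- call_dhrs(a, b)
  r2 <- call_dhrs(b, a)
  expect_equal(r2$diff, -r1$diff, tolerance = 1e-12)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-12)
  expect_equal(r2$called, r1$called)
})

test_that("zero-variance tiles get the degenerate t-test limit", {
  a <- lapply(1:3, function(i) mk_tiles(c(0, 0)))
  b <- lapply(1:3, function(i) mk_tiles(c(2, 0)))
  res <- call_dhrs(a, b)
  expect_equal(res$p_value, c(0, 1))
  expect_equal(res$called, c(TRUE, FALSE))
})

test_that("regions map onto gene bodies by genomic overlap", {
  regions <- data.frame(chrom = "chr1",
                        start = c(401L, 2001L, 3601L),
                        end = c(800L, 2400L, 4000L),
                        called = c(TRUE, TRUE, FALSE),
                        label = c("DHR", "DHR", ""))
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(300, 500, 5000), c(900, 2500, 6000)),
    gene_id = c("geneA", "geneB", "geneC"))
  gc <- annotate_regions(regions, genes)
  # geneA overlaps region 1; geneB overlaps regions 1 and 2; geneC none;
  # the uncalled region is never mapped
  expect_setequal(gc$gene_id, c("geneA", "geneB"))
  expect_equal(gc$n_regions[gc$gene_id == "geneB"], 2L)
  expect_equal(unique(gc$label), "DHRG")
})

test_that("gene annotation is read from GFF3", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t300\t900\t.\t+\t.\tID=geneA",
               "chr1\tsrc\texon\t320\t380\t.\t+\t.\tParent=geneA",
               "chr1\tsrc\tgene\t5000\t6000\t.\t-\t.\tID=geneC"), gff)
  regions <- data.frame(chrom = "chr1", start = 401L, end = 800L,
                        called = TRUE, label = "DHR")
  gc <- annotate_regions(regions, gff)
  expect_equal(gc$gene_id, "geneA")   # exon row ignored, geneC no overlap
  expect_error(annotate_regions(regions, tempfile()), "malformed|cannot")
})

test_that("the overlap test matches the hypergeometric tail", {
  expect_equal(overlap_test(1, 1, 0, 1000), 1, tolerance = 1e-12)
  expect_equal(overlap_test(10, 10, 10, 20),
               1 / choose(20, 10), tolerance = 1e-12)
  # enumeration oracle at small scale: P(overlap >= k) by summing the pmf
  pmf_tail <- function(nA, nB, k, N)
    sum(vapply(k:min(nA, nB), function(x)
      choose(nA, x) * choose(N - nA, nB - x) / choose(N, nB), numeric(1)))
  for (case in list(c(5, 7, 3, 20), c(10, 10, 5, 30), c(4, 9, 2, 15))) {
    expect_equal(overlap_test(case[1], case[2], case[3], case[4]),
                 pmf_tail(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-9)
  }
  expect_error(overlap_test(3, 4, 5, 100), "exceed")
})

test_that("pattern composition tabulates per-sample abundances over the alphabet", {
  s1 <- pattern_counts("0000", 4)
  s2 <- pattern_counts(c("0000", "1111"), c(7, 3))
  comp <- pattern_composition(list(early = s1, late = s2))
  expect_equal(dim(comp), c(2L, 16L))
  expect_equal(unname(rowSums(comp)), c(1, 1), tolerance = 1e-12)
  expect_equal(comp["early", "0000"], 1)
  expect_equal(comp["late", "1111"], 0.3)
  expect_equal(comp["early", "1111"], 0)
  expect_error(pattern_composition(list(s1, pattern_counts("00", 2))),
               "same window width")
})
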