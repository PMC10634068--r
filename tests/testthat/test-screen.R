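# Genome screening over synthetic BAMs generated at test time.

make_sim_bam <- function(spec, prefix = tempfile("sim"), ...) {
  sim <- make_toy_alignment(spec, ...)
  paths <- sim_to_bam(sim, prefix)
  list(sim = sim, bam = paths[["bam"]], fasta = paths[["fasta"]])
}

test_that("screening recovers the specified pattern counts and score values", {
  x <- make_sim_bam(list(
    list(patterns = "0000", counts = 4L),                 # homogeneous
    list(patterns = c("0000", "1111"), counts = c(2L, 2L)),
    list(patterns = "1010", counts = 3L)))                # below depth
  win <- screen_genome(x$bam, x$fasta, scores = c("AB", "PWS", "PHY"))
  expect_equal(nrow(win), 2)   # third locus skipped, not zero-filled
  expect_equal(win$depth, c(4L, 4L))
  expect_equal(win$AB, c(1, 2), tolerance = 1e-12)
  expect_equal(win$PWS, c(0, sqrt(2)), tolerance = 1e-12)
  expect_equal(win$PHY, c(0, 1), tolerance = 1e-12)
  expect_true(all(win$strand == "+"))
  # window coordinates are the first/last cytosine of the window
  ls <- x$sim$locus_set
  expect_equal(win$start, vapply(ls$loci[1:2], `[`, integer(1), 1))
})

test_that("sequence-based calling agrees with the XM tag path", {
  x <- make_sim_bam(list(
    list(patterns = c("0110", "1001", "0000"), counts = c(3L, 2L, 4L))))
  w_tag <- screen_genome(x$bam, x$fasta, scores = c("AB", "PWS"),
                         call_source = "tag")
  w_seq <- screen_genome(x$bam, x$fasta, scores = c("AB", "PWS"),
                         call_source = "sequence")
  expect_equal(w_tag, w_seq, tolerance = 1e-12)
})

test_that("non-CG contexts and minus-strand sites are screened", {
  ls <- synth_locus_set(1, context = "CHH")
  x <- make_sim_bam(list(list(patterns = c("0011", "1100"),
                              counts = c(2L, 2L))), locus_set = ls)
  win <- screen_genome(x$bam, x$fasta, context = "CHH", scores = "PWS")
  expect_equal(nrow(win), 1)
  expect_equal(win$context, "CHH")
  expect_equal(win$PWS, sqrt(2), tolerance = 1e-12)
  # no CG windows exist on this reference
  expect_equal(nrow(screen_genome(x$bam, x$fasta, context = "CG")), 0)

  # a hand-built minus-strand alignment: CG sites at the G positions
  ref <- Biostrings::DNAStringSet("TTACGTTTACGTTTACGTTTACGTTT")
  names(ref) <- "chrM"
  sites_minus <- enumerate_context_sites(ref[[1]], "CG", "-")
  expect_equal(sites_minus, c(5L, 11L, 17L, 23L))
  dirp <- tempfile("minus"); dir.create(dirp)
  fa <- file.path(dirp, "ref.fa")
  Biostrings::writeXStringSet(ref, fa)
  xm <- paste(ifelse(seq_len(26) %in% sites_minus, "Z", "."), collapse = "")
  xm_u <- chartr("Z", "z", xm)
  reads <- vapply(1:4, function(i) {
    tag <- if (i <= 2) xm else xm_u
    paste(sprintf("r%d", i), 16L, "chrM", 1L, 60L, "26M", "*", 0L, 0L,
          gsub("C", "T", as.character(ref[[1]])),
          paste(rep("I", 26), collapse = ""),
          paste0("XM:Z:", tag), sep = "\t")
  }, character(1))
  sam <- file.path(dirp, "m.sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chrM\tLN:26",
               reads), sam)
  bam <- Rsamtools::asBam(sam, file.path(dirp, "m"), overwrite = TRUE,
                          indexDestination = TRUE)
  win <- screen_genome(bam, fa, scores = "AB")
  expect_equal(nrow(win), 1)
  expect_equal(win$strand, "-")
  expect_equal(win$AB, 2, tolerance = 1e-12)
})

test_that("screening rejects contigs missing from the reference", {
  x <- make_sim_bam(list(list(patterns = "0000", counts = 4L)))
  other <- Biostrings::DNAStringSet("ACGTACGT")
  names(other) <- "chrOther"
  expect_error(screen_genome(x$bam, other, scores = "AB"), "chrS")
})

test_that("site methylation levels follow #C/(#C+#T) with the coverage floor", {
  x <- make_sim_bam(list(
    list(patterns = c("1111", "0000"), counts = c(2L, 2L)),
    list(patterns = "1111", counts = 3L)))     # coverage 3: not reported
  lv <- methylation_level(x$bam, x$fasta)
  ls <- x$sim$locus_set
  expect_setequal(lv$pos, ls$loci[[1]])
  expect_equal(lv$level, rep(0.5, 4))
  expect_equal(lv$n_meth + lv$n_unmeth, rep(4L, 4))
  lv2 <- methylation_level(x$bam, x$fasta, min_cov = 3)
  expect_setequal(lv2$pos, c(ls$loci[[1]], ls$loci[[2]]))
})

test_that("tiling averages member windows by start position", {
  win <- data.frame(chrom = "chr1", start = c(100L, 300L, 420L),
                    end = c(130L, 330L, 450L), strand = "+",
                    context = "CG", depth = 4L, PWS = c(1, 2, 5))
  tl <- tile_scores(win, "PWS", tile = 400L)
  expect_equal(nrow(tl), 2)
  expect_equal(tl$value, c(1.5, 5))       # mean of first two, then third
  expect_equal(tl$start, c(1L, 401L))
  expect_equal(tl$end, c(400L, 800L))
  expect_equal(tl$n_windows, c(2L, 1L))
  # a window straddling the boundary is assigned by its start
  win2 <- rbind(win, data.frame(chrom = "chr1", start = 399L, end = 430L,
                                strand = "+", context = "CG", depth = 4L,
                                PWS = 10))
  tl2 <- tile_scores(win2, "PWS", tile = 400L)
  expect_equal(tl2$n_windows, c(3L, 1L))
  expect_error(tile_scores(win, "AB"), "no score column")
})

test_that("tracks round-trip through bedGraph and CSV", {
  tl <- data.frame(chrom = "chr1", start = 1L, end = 400L,
                   context = "CG", score = "PWS",
                   value = 1.4142135624, n_windows = 3L)
  prefix <- tempfile("trk")
  paths <- write_tracks(tl, prefix, params = list(w = 4, depth = 4))
  bg <- readLines(paths[["bedGraph"]])
  expect_equal(bg, "chr1\t0\t400\t1.414214")   # 0-based half-open
  back <- read_tracks(paths[["csv"]])
  expect_equal(back$value, tl$value, tolerance = 1e-9)
  expect_equal(back$start, tl$start)
  hdr <- readLines(paths[["csv"]], n = 4)
  expect_true(any(grepl("^# methylhet", hdr)))
  expect_true(any(grepl("^# w: 4", hdr)))
})

test_that("genome summary reports the mean over scored windows", {
  win <- data.frame(chrom = c("c1", "c1", "c2"), start = c(1L, 2L, 3L),
                    PWS = c(1, 2, 6))
  s <- summarize_genome(win, "PWS", by_chrom = TRUE)
  expect_equal(s$genome_mean, 3)
  expect_equal(s$n_windows, 3)
  expect_equal(unname(s$by_chrom["c2"]), 6)
})
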