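#' Differential heterogeneity and methylation calling
#'
#' Compares tile-level heterogeneity (DHR) or methylation level (DMR)
#' between two groups of replicates with a two-sample Student's t-test,
#' maps qualifying regions onto gene bodies (DHG/DMG), and tests gene-set
#' overlaps.
#'
#' @name differential
#' @keywords internal
NULL

# two-sample pooled-variance t-test p-value; degenerate (zero pooled
# variance) data gets the continuity limit: p = 1 if means are equal,
# p = 0 otherwise
.t_pvalue <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  stats::t.test(a, b, var.equal = TRUE)$p.value
}

# align replicate tile tracks on their shared (chrom, start) grid;
# tiles must be present in every replicate of both groups, otherwise the
# grids are rejected naming the first mismatching coordinate
.match_tiles <- function(tracks_a, tracks_b) {
  keyify <- function(tr) paste(tr$chrom, tr$start, sep = "|")
  all_tracks <- c(tracks_a, tracks_b)
  keys <- lapply(all_tracks, keyify)
  common <- Reduce(intersect, keys)
  universe <- Reduce(union, keys)
  mismatch <- setdiff(universe, common)
  if (length(mismatch))
    stop("tile grids do not match across replicates; first mismatch at ",
         sub("\\|", ":", sort(mismatch)[1]))
  if (length(common) == 0L) return(NULL)
  grid <- do.call(rbind, strsplit(common, "|", fixed = TRUE))
  ord <- order(grid[, 1], as.integer(grid[, 2]))
  common <- common[ord]
  list(keys = common,
       values = lapply(all_tracks, function(tr) {
         tr$value[match(common, keyify(tr))]
       }),
       extra = lapply(all_tracks, function(tr) {
         tr[match(common, keyify(tr)), , drop = FALSE]
       }),
       n_a = length(tracks_a))
}

.call_differential <- function(tracks_a, tracks_b, min_diff, alpha,
                               label, fdr = FALSE, min_sites = NULL) {
  if (length(tracks_a) < 2L || length(tracks_b) < 2L)
    stop("at least 2 replicates per group are required")
  m <- .match_tiles(tracks_a, tracks_b)
  if (is.null(m))
    stop("no tiles shared by all replicates",
         if (length(tracks_a[[1]]$chrom))
           paste0(" (first mismatch near ", tracks_a[[1]]$chrom[1], ":",
                  tracks_a[[1]]$start[1], ")") else "")
  va <- do.call(cbind, m$values[seq_len(m$n_a)])
  vb <- do.call(cbind, m$values[-seq_len(m$n_a)])
  ref <- m$extra[[1]]
  n <- length(m$keys)
  mean_a <- rowMeans(va)
  mean_b <- rowMeans(vb)
  p <- vapply(seq_len(n), function(i) .t_pvalue(va[i, ], vb[i, ]),
              numeric(1))
  out <- data.frame(chrom = ref$chrom, start = ref$start, end = ref$end,
                    mean_a = mean_a, mean_b = mean_b,
                    diff = mean_b - mean_a, p_value = p)
  if (!is.null(min_sites)) {
    ns <- do.call(cbind, lapply(m$extra, function(tr) tr$n_sites))
    out$n_sites <- apply(ns, 1, min)   # every replicate must have >= min_sites
  }
  padj <- if (fdr) stats::p.adjust(out$p_value, "BH") else out$p_value
  out$called <- abs(out$diff) > min_diff & padj < alpha
  if (!is.null(min_sites)) out$called <- out$called & out$n_sites >= min_sites
  out$label <- ifelse(out$called, label, "")
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Call differentially heterogeneous regions (DHRs)
#'
#' A 400-bp tile is a DHR when the absolute difference of the group mean
#' heterogeneity exceeds `min_diff` (default 1.41, the expected score
#' increase when one new maximally distant pattern appears) and the
#' two-sample Student's t-test p-value is below `alpha`.
#'
#' @param tracks_a,tracks_b lists of per-replicate tile data frames
#'   (from [tile_scores]), at least 2 per group; tiles must be present
#'   in every replicate.
#' @param min_diff minimum absolute group-mean difference (default 1.41).
#' @param alpha p-value threshold (default 0.05).
#' @param fdr apply Benjamini-Hochberg adjustment before thresholding
#'   (off by default, matching the raw-p rule).
#' @return Data frame of all shared tiles with `mean_a`, `mean_b`,
#'   `diff`, `p_value`, `called`, `label` ("DHR" where called).
#' @export
call_dhrs <- function(tracks_a, tracks_b, min_diff = 1.41, alpha = 0.05,
                      fdr = FALSE) {
  .call_differential(tracks_a, tracks_b, min_diff, alpha, "DHR", fdr)
}

#' Call differentially methylated regions (DMRs)
#'
#' A tile is a DMR when it contains at least `min_sites` covered
#' cytosines (in every replicate), the absolute difference of group mean
#' methylation level exceeds `min_diff` (default 0.15, i.e. 15%), and
#' the Student's t-test p-value is below `alpha`.
#'
#' @param tracks_a,tracks_b lists of per-replicate tile-level data
#'   frames (from [tile_levels]), at least 2 per group.
#' @param min_diff minimum absolute level difference (default 0.15).
#' @param alpha p-value threshold (default 0.05).
#' @param min_sites minimum covered cytosines per tile (default 5).
#' @param fdr apply BH adjustment (off by default).
#' @return Data frame as for [call_dhrs], plus `n_sites`, with label
#'   "DMR" where called.
#' @export
call_dmrs <- function(tracks_a, tracks_b, min_diff = 0.15, alpha = 0.05,
                      min_sites = 5L, fdr = FALSE) {
  .call_differential(tracks_a, tracks_b, min_diff, alpha, "DMR", fdr,
                     min_sites = min_sites)
}

#' Map differential regions onto gene bodies
#'
#' A gene is called (DHG for DHR input, DMG for DMR input) when at least
#' one qualifying region overlaps its annotated gene body (start..end,
#' introns and UTRs included; promoters are not extended).
#'
#' @param regions data frame from [call_dhrs]/[call_dmrs]; only rows
#'   with `called == TRUE` are mapped.
#' @param genes a [GenomicRanges::GRanges] with a `gene_id` (or `ID`/
#'   `Name`) metadata column, or a GFF3/BED path read with
#'   [rtracklayer::import] (GFF3 rows of type "gene" are used).
#' @return Data frame: `gene_id`, `chrom`, `start`, `end`, `n_regions`,
#'   `label`, and a list-column `regions` of the overlapping region
#'   coordinates.
#' @export
annotate_regions <- function(regions, genes) {
  genes <- .load_genes(genes)
  hits <- regions[regions$called, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_regions = integer(), label = character()))
  gr <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$start, hits$end))
  ov <- GenomicRanges::findOverlaps(gr, genes, ignore.strand = TRUE)
  if (length(ov) == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_regions = integer(), label = character()))
  by_gene <- split(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
  out <- do.call(rbind, lapply(names(by_gene), function(gi) {
    g <- genes[as.integer(gi)]
    ridx <- by_gene[[gi]]
    data.frame(gene_id = g$gene_id,
               chrom = as.character(GenomeInfoDb::seqnames(g)),
               start = BiocGenerics::start(g), end = BiocGenerics::end(g),
               n_regions = length(ridx),
               label = paste0(unique(hits$label[ridx]), "G"))
  }))
  out$regions <- I(lapply(names(by_gene), function(gi) {
    hits[by_gene[[gi]], c("chrom", "start", "end"), drop = FALSE]
  }))
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

.load_genes <- function(genes) {
  if (is.character(genes)) {
    gr <- tryCatch(rtracklayer::import(genes),
                   error = function(e) stop("malformed annotation '",
                                            genes, "': ",
                                            conditionMessage(e)))
    if (!is.null(gr$type) && any(gr$type == "gene"))
      gr <- gr[gr$type == "gene"]
    genes <- gr
  }
  if (!methods::is(genes, "GRanges"))
    stop("'genes' must be a GRanges or an annotation file path")
  id <- genes$gene_id
  if (is.null(id)) id <- genes$ID
  if (is.null(id)) id <- genes$Name
  if (is.null(id)) id <- genes$name
  if (is.null(id)) id <- paste0("gene", seq_along(genes))
  genes$gene_id <- id
  genes
}

#' Hypergeometric test for gene-set overlap
#'
#' Upper-tail probability of observing at least the given overlap
#' between two gene sets drawn from a common universe (one-sided
#' Fisher/hypergeometric test).
#'
#' @param n_a,n_b sizes of the two sets.
#' @param overlap observed overlap.
#' @param universe universe size.
#' @return p-value.
#' @export
overlap_test <- function(n_a, n_b, overlap, universe) {
  if (overlap > min(n_a, n_b))
    stop("overlap cannot exceed the smaller set")
  if (n_a > universe || n_b > universe)
    stop("set sizes cannot exceed the universe")
  stats::phyper(overlap - 1, n_a, universe - n_a, n_b,
                lower.tail = FALSE)
}

#' Pattern composition of one window across samples
#'
#' Relative abundance of every possible pattern of the window's width in
#' each sample; patterns absent from a sample get 0 and each row sums
#' to 1.
#'
#' @param samples named list of [pattern_counts] for the same window.
#' @return Numeric matrix, samples x `2^w` patterns.
#' @export
pattern_composition <- function(samples) {
  stopifnot(length(samples) >= 1L)
  ws <- vapply(samples, function(s) s$w, integer(1))
  if (length(unique(ws)) != 1L)
    stop("all samples must describe the same window width")
  w <- ws[1]
  alphabet <- apply(expand.grid(rep(list(c("0", "1")), w))[, w:1,
                                                           drop = FALSE],
                    1, paste, collapse = "")
  alphabet <- sort(alphabet)
  m <- t(vapply(samples, function(s) {
    v <- stats::setNames(numeric(length(alphabet)), alphabet)
    v[s$patterns] <- s$p
    v
  }, numeric(length(alphabet))))
  if (is.null(rownames(m)))
    rownames(m) <- paste0("sample", seq_along(samples))
  m
}
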