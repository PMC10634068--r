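#' Synthetic methylome generation
#'
#' Generators for every input class the pipeline consumes, built without
#' any external data: toy alignments realizing an exact multiset of
#' read-level patterns per locus, pooled multi-cell-type methylomes,
#' nested single-cell merging series, and error-injected reads. All
#' generators are seed-deterministic and leave the global RNG state
#' untouched.
#'
#' The mini-reference places each locus in its own tile: `w` context
#' cytosines spaced `spacing` bp apart on an A-only backbone, so no
#' accidental context sites arise, and each read covers exactly one
#' locus. Reads are emitted on the plus strand with Bismark-style XM
#' call tags and bisulfite-converted sequence, so both call-extraction
#' paths (tag and sequence) see the same patterns.
#'
#' @name synthetic
#' @keywords internal
NULL

.CONTEXT_MOTIF <- c(CG = "CG", CHG = "CAG", CHH = "CAA")
.CONTEXT_XM <- c(CG = "Z", CHG = "X", CHH = "H")

# run code under a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Lay out a mini-reference of isolated context loci
#'
#' @param n_loci number of loci.
#' @param w context cytosines per locus (default 4).
#' @param spacing bp between consecutive cytosines of a locus (default 10).
#' @param tile bp reserved per locus, so locus i sits alone in tile i
#'   (default 400).
#' @param context cytosine context of the loci.
#' @param chrom name of the synthetic chromosome.
#' @return A `locus_set`: list with `reference` (DNAStringSet), `loci`
#'   (list of site-position vectors), `context`, `w`, `chrom`.
#' @export
synth_locus_set <- function(n_loci, w = 4L, spacing = 10L, tile = 400L,
                            context = "CG", chrom = "chrS") {
  stopifnot(n_loci >= 1L, w >= 2L, spacing >= 4L)
  context <- match.arg(context, .CONTEXTS)
  motif <- .CONTEXT_MOTIF[[context]]
  total <- n_loci * tile + tile
  seqv <- rep("A", total)
  loci <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    first <- (i - 1L) * tile + 100L
    sites <- first + (seq_len(w) - 1L) * spacing
    for (s in sites) {
      seqv[s:(s + nchar(motif) - 1L)] <- strsplit(motif, "")[[1]]
    }
    loci[[i]] <- sites
  }
  ref <- Biostrings::DNAStringSet(paste(seqv, collapse = ""))
  names(ref) <- chrom
  structure(list(reference = ref, loci = loci, context = context,
                 w = as.integer(w), chrom = chrom, tile = as.integer(tile)),
            class = "locus_set")
}

.new_sim <- function(reads, locus_set) {
  structure(list(reads = reads, locus_set = locus_set),
            class = "methylome_sim")
}

#' @export
print.methylome_sim <- function(x, ...) {
  cat(sprintf("methylome_sim: %d reads over %d locus/loci (%s, w = %d)\n",
              nrow(x$reads), length(x$locus_set$loci),
              x$locus_set$context, x$locus_set$w))
  invisible(x)
}

#' Build a toy alignment realizing exact pattern multisets
#'
#' Each locus receives exactly the specified multiset of complete
#' read-level patterns, mirroring hand-drawn toy alignments used to
#' probe score behaviour.
#'
#' @param spec list with one element per locus, each a list (or data
#'   frame) with `patterns` and `counts`.
#' @param locus_set optional [synth_locus_set]; built to fit `spec` when
#'   omitted.
#' @return A `methylome_sim`: reads data frame (`qname`, `chrom`,
#'   `strand`, `locus`, `cell`, `pattern`) plus the locus set.
#' @examples
#' sim <- make_toy_alignment(list(list(patterns = c("0000", "1111"),
#'                                     counts = c(2, 2))))
#' nrow(sim$reads)
#' @export
make_toy_alignment <- function(spec, locus_set = NULL) {
  if (is.null(locus_set)) locus_set <- synth_locus_set(length(spec))
  if (length(spec) > length(locus_set$loci))
    stop("spec has more loci than the locus set")
  reads <- list()
  for (i in seq_along(spec)) {
    pats <- rep(spec[[i]]$patterns, spec[[i]]$counts)
    if (any(nchar(pats) != locus_set$w))
      stop("pattern width does not match locus w at locus ", i)
    if (length(pats) == 0L) next
    reads[[i]] <- data.frame(
      qname = sprintf("L%d_r%03d", i, seq_along(pats)),
      chrom = locus_set$chrom, strand = "+",
      locus = i, cell = "toy", pattern = pats)
  }
  .new_sim(do.call(rbind, reads), locus_set)
}

#' Simulate a pooled multi-cell-type methylome
#'
#' Draws reads per cell from its cell type's per-locus pattern
#' distribution, emulating the pooling of single-cell methylomes from
#' one or several cell types into a bulk sample.
#'
#' @param profiles named list of cell-type profiles; each profile is a
#'   list with one element per locus, a named numeric vector of pattern
#'   probabilities summing to 1.
#' @param n_cells integer vector (recycled over `profiles`): cells per
#'   type.
#' @param coverage reads per cell per locus (default 2).
#' @param seed mandatory RNG seed.
#' @param locus_set optional [synth_locus_set].
#' @return A `methylome_sim`; `reads$cell` identifies the originating
#'   cell (`<type>_c<k>`).
#' @export
simulate_pooled_methylome <- function(profiles, n_cells, coverage = 2L,
                                      seed, locus_set = NULL) {
  if (length(profiles) == 0L) stop("'profiles' must not be empty")
  stopifnot(coverage >= 1L)
  n_loci <- length(profiles[[1]])
  if (is.null(locus_set)) locus_set <- synth_locus_set(n_loci)
  n_cells <- rep_len(as.integer(n_cells), length(profiles))
  reads <- .with_seed(seed, {
    out <- list()
    for (t in seq_along(profiles)) {
      type <- names(profiles)[t]
      if (is.null(type)) type <- paste0("type", t)
      prof <- profiles[[t]]
      for (cell in seq_len(n_cells[t])) {
        cell_id <- sprintf("%s_c%02d", type, cell)
        for (l in seq_len(n_loci)) {
          probs <- prof[[l]]
          pats <- sample(names(probs), coverage, replace = TRUE,
                         prob = probs)
          out[[length(out) + 1L]] <- data.frame(
            qname = sprintf("%s_L%d_r%03d", cell_id, l,
                            seq_len(coverage)),
            chrom = locus_set$chrom, strand = "+", locus = l,
            cell = cell_id, pattern = pats)
        }
      }
    }
    do.call(rbind, out)
  })
  .new_sim(reads, locus_set)
}

#' Pool the first k cells of a simulated methylome
#'
#' Produces nested pools for merging experiments: the pool at `k` is a
#' subset of the pool at any larger `k`.
#'
#' @param sim a `methylome_sim` with per-cell reads.
#' @param k number of cells to keep, in the order cells first appear.
#' @return A `methylome_sim` restricted to the first `k` cells.
#' @export
merge_methylomes <- function(sim, k) {
  stopifnot(inherits(sim, "methylome_sim"))
  cells <- unique(sim$reads$cell)
  if (k > length(cells))
    stop("k = ", k, " exceeds the ", length(cells), " available cells")
  keep <- cells[seq_len(k)]
  .new_sim(sim$reads[sim$reads$cell %in% keep, , drop = FALSE],
           sim$locus_set)
}

#' Inject independent methylation-call errors
#'
#' Flips every methylation call independently with probability `e`,
#' the minimal error model for probing score robustness to sequencing
#' error.
#'
#' @param sim a `methylome_sim`.
#' @param e per-call flip probability in `[0, 1]`.
#' @param seed mandatory RNG seed.
#' @return The `methylome_sim` with perturbed patterns.
#' @export
inject_call_errors <- function(sim, e, seed) {
  stopifnot(inherits(sim, "methylome_sim"), e >= 0, e <= 1)
  pats <- sim$reads$pattern
  sim$reads$pattern <- .with_seed(seed, {
    vapply(pats, function(p) {
      x <- strsplit(p, "")[[1]]
      flip <- stats::runif(length(x)) < e
      x[flip] <- ifelse(x[flip] == "1", "0", "1")
      paste(x, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  sim
}

#' Expected pattern counts of a simulated methylome
#'
#' The lossless-fixture contract: tabulates the simulated reads per
#' locus exactly as the genome screen should recover them.
#'
#' @param sim a `methylome_sim`.
#' @param min_depth loci below this depth are dropped (default 1;
#'   use 4 to mirror the screen's default).
#' @return Named list of [pattern_counts], one per covered locus.
#' @export
expected_pattern_counts <- function(sim, min_depth = 1L) {
  ls <- sim$locus_set
  out <- lapply(split(sim$reads$pattern, sim$reads$locus), function(p) {
    if (length(p) < min_depth) return(NULL)
    tab <- table(p)
    pattern_counts(names(tab), as.integer(tab))
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Write a simulated methylome as FASTA + indexed BAM
#'
#' Renders each read's bisulfite-converted sequence and XM call string
#' against the mini-reference, writes a coordinate-sorted SAM, converts
#' it to an indexed BAM, and writes the reference FASTA.
#'
#' @param sim a `methylome_sim`.
#' @param prefix output prefix; creates `<prefix>.fa`, `<prefix>.bam`,
#'   `<prefix>.bam.bai` (the intermediate `.sam` is removed).
#' @return Invisibly, a named vector with the `fasta` and `bam` paths.
#' @export
sim_to_bam <- function(sim, prefix) {
  ls <- sim$locus_set
  fa <- paste0(prefix, ".fa")
  Biostrings::writeXStringSet(ls$reference, fa)
  refseq <- strsplit(as.character(ls$reference[[1]]), "")[[1]]
  xm_code <- .CONTEXT_XM[[ls$context]]
  reads <- sim$reads
  rows <- character(nrow(reads))
  starts <- integer(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    sites <- ls$loci[[reads$locus[i]]]
    start <- sites[1] - 2L
    end <- sites[length(sites)] + 2L
    seqc <- refseq[start:end]
    xm <- rep(".", length(seqc))
    calls <- strsplit(reads$pattern[i], "")[[1]]
    off <- sites - start + 1L
    seqc[off] <- ifelse(calls == "1", "C", "T")
    xm[off] <- ifelse(calls == "1", xm_code, tolower(xm_code))
    flag <- if (reads$strand[i] == "+") 0L else 16L
    starts[i] <- start
    rows[i] <- paste(reads$qname[i], flag, reads$chrom[i], start, 60L,
                     paste0(length(seqc), "M"), "*", 0L, 0L,
                     paste(seqc, collapse = ""),
                     paste(rep("I", length(seqc)), collapse = ""),
                     paste0("XM:Z:", paste(xm, collapse = "")),
                     sep = "\t")
  }
  rows <- rows[order(reads$chrom, starts)]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ls$reference),
                      Biostrings::width(ls$reference)))
  sam <- paste0(prefix, ".sam")
  writeLines(c(header, rows), sam)
  bam <- Rsamtools::asBam(sam, prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  invisible(c(fasta = fa, bam = bam))
}
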