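#' Genome-wide window screening
#'
#' Streams an alignment file across the genome, scores every window of w
#' context cytosines with enough complete reads, merges window scores
#' into fixed-size tiles, and writes bedGraph/CSV tracks. Also computes
#' per-site methylation levels (#C / (#C + #T)).
#'
#' @name genome_screen
#' @keywords internal
NULL

#' Score all qualifying windows of a methylome
#'
#' For each reference sequence and strand, context cytosines are located
#' on the reference, windows of `w` consecutive sites slide one cytosine
#' at a time, and every window covered by at least `min_depth` complete
#' read patterns receives one value per requested score. Windows below
#' the depth cutoff are skipped, not zero-filled.
#'
#' @param bam path to a coordinate-sorted, indexed BAM.
#' @param reference FASTA path or [Biostrings::DNAStringSet].
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param scores score names (see [score_window]); default `"PWS"`.
#' @param w window size in cytosines (default 4).
#' @param min_depth minimum complete reads per window (default 4).
#' @param metric distance metric for PWS/PHY.
#' @param call_source how methylation calls are obtained, see
#'   [read_bam_calls].
#' @return Data frame with one row per scored window: `chrom`, `start`,
#'   `end` (first/last window cytosine, 1-based), `strand`, `context`,
#'   `depth`, and one column per score.
#' @export
screen_genome <- function(bam, reference, context = "CG", scores = "PWS",
                          w = 4L, min_depth = 4L,
                          metric = c("hamming", "wdk"),
                          call_source = "auto") {
  metric <- match.arg(metric)
  ref <- load_reference(reference)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  chroms <- intersect(names(hdr), names(ref))
  missing_ctg <- setdiff(names(hdr), names(ref))
  if (length(missing_ctg))
    stop("contig(s) absent from reference: ",
         paste(missing_ctg, collapse = ", "))
  rows <- list()
  for (chrom in chroms) {
    for (strand in c("+", "-")) {
      sites <- enumerate_context_sites(ref[[chrom]], context, strand)
      if (length(sites) < w) next
      calls <- read_bam_calls(bam, chrom, strand, sites,
                              call_source = call_source)
      if (nrow(calls) == 0L) next
      rows[[length(rows) + 1L]] <-
        .screen_strand(calls, sites, chrom, strand, context,
                       scores, w, min_depth, metric)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(.empty_window_frame(scores, context))
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

.empty_window_frame <- function(scores, context) {
  base <- data.frame(chrom = character(), start = integer(),
                     end = integer(), strand = character(),
                     context = character(), depth = integer())
  for (s in scores) base[[s]] <- numeric()
  base
}

# score every qualifying window on one chrom/strand from a call table
.screen_strand <- function(calls, sites, chrom, strand, context,
                           scores, w, min_depth, metric) {
  si <- match(calls$pos, sites)
  calls$si <- si
  # per-read contiguous complete coverage; accumulate patterns per window
  acc <- new.env(parent = emptyenv())
  for (d in split(calls, calls$read)) {
    d <- d[order(d$si), , drop = FALSE]
    ok <- !is.na(d$methylated)
    # maximal runs of consecutive site indices with unambiguous calls
    runs <- .complete_runs(d$si[ok])
    states <- d$methylated[ok]
    names(states) <- as.character(d$si[ok])
    for (r in runs) {
      if (length(r) < w) next
      for (i in seq_len(length(r) - w + 1L)) {
        idx <- r[i:(i + w - 1L)]
        pat <- paste(as.integer(states[as.character(idx)]), collapse = "")
        key <- as.character(idx[1])
        cur <- if (exists(key, acc)) get(key, acc) else character()
        assign(key, c(cur, pat), acc)
      }
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0L) return(NULL)
  rows <- lapply(keys, function(key) {
    pats <- get(key, acc)
    if (length(pats) < min_depth) return(NULL)
    i0 <- as.integer(key)
    win_sites <- sites[i0:(i0 + w - 1L)]
    tab <- table(pats)
    pc <- pattern_counts(names(tab), as.integer(tab),
                         window = meth_window(chrom, win_sites,
                                              context, strand))
    vals <- score_window(pc, scores, metric)
    cbind(data.frame(chrom = chrom, start = win_sites[1],
                     end = win_sites[w], strand = strand,
                     context = context, depth = pc$depth),
          as.data.frame(as.list(vals)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

# split sorted site indices into maximal consecutive runs
.complete_runs <- function(si) {
  if (length(si) == 0L) return(list())
  brk <- cumsum(c(0L, diff(si) != 1L))
  unname(split(si, brk))
}

#' Per-site methylation levels
#'
#' Counts methylated (#C) and unmethylated (#T) calls per context
#' cytosine and reports the level `#C / (#C + #T)` at sites covered by at
#' least `min_cov` calls.
#'
#' @param bam indexed BAM path.
#' @param reference FASTA path or DNAStringSet.
#' @param context cytosine context.
#' @param min_cov minimum coverage to report a site (default 4).
#' @param call_source see [read_bam_calls].
#' @return Data frame: `chrom`, `pos`, `strand`, `context`, `n_meth`,
#'   `n_unmeth`, `level`.
#' @export
methylation_level <- function(bam, reference, context = "CG",
                              min_cov = 4L, call_source = "auto") {
  ref <- load_reference(reference)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  chroms <- intersect(names(hdr), names(ref))
  rows <- list()
  for (chrom in chroms) {
    for (strand in c("+", "-")) {
      sites <- enumerate_context_sites(ref[[chrom]], context, strand)
      if (length(sites) == 0L) next
      calls <- read_bam_calls(bam, chrom, strand, sites,
                              call_source = call_source)
      calls <- calls[!is.na(calls$methylated), , drop = FALSE]
      if (nrow(calls) == 0L) next
      nm <- tapply(calls$methylated, calls$pos, sum)
      nt <- tapply(!calls$methylated, calls$pos, sum)
      cov <- nm + nt
      keep <- cov >= min_cov
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, pos = as.integer(names(nm))[keep],
        strand = strand, context = context,
        n_meth = as.integer(nm)[keep], n_unmeth = as.integer(nt)[keep],
        level = (nm / cov)[keep])
    }
  }
  if (length(rows) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      n_meth = integer(), n_unmeth = integer(),
                      level = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}

#' Merge window scores into fixed-size tiles
#'
#' Each window is assigned to the tile containing its start cytosine;
#' the tile value is the arithmetic mean of its member windows. Tiles
#' with no windows are absent from the output. Tile coordinates are
#' 1-based inclusive and aligned to multiples of `tile` (tile k spans
#' `[k*tile + 1, (k+1)*tile]`).
#'
#' @param windows a window-score data frame from [screen_genome].
#' @param score name of the score column to aggregate.
#' @param tile tile width in bp (default 400).
#' @return Data frame: `chrom`, `start`, `end`, `context`, `score`,
#'   `value`, `n_windows`.
#' @export
tile_scores <- function(windows, score = "PWS", tile = 400L) {
  stopifnot(tile > 0)
  if (!score %in% names(windows)) stop("no score column '", score, "'")
  if (nrow(windows) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      score = character(), value = numeric(),
                      n_windows = integer()))
  bin <- (windows$start - 1L) %/% tile
  key <- paste(windows$chrom, bin, sep = "|")
  agg <- lapply(split(seq_len(nrow(windows)), key), function(idx) {
    data.frame(chrom = windows$chrom[idx[1]],
               start = bin[idx[1]] * tile + 1L,
               end = (bin[idx[1]] + 1L) * tile,
               context = windows$context[idx[1]],
               score = score,
               value = mean(windows[[score]][idx]),
               n_windows = length(idx))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Aggregate site levels into tiles
#'
#' Mean methylation level and covered-site count per fixed-size tile,
#' used by the DMR caller.
#'
#' @param levels data frame from [methylation_level].
#' @param tile tile width in bp.
#' @return Data frame: `chrom`, `start`, `end`, `value` (mean level),
#'   `n_sites`.
#' @export
tile_levels <- function(levels, tile = 400L) {
  stopifnot(tile > 0)
  if (nrow(levels) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric(),
                      n_sites = integer()))
  bin <- (levels$pos - 1L) %/% tile
  key <- paste(levels$chrom, bin, sep = "|")
  agg <- lapply(split(seq_len(nrow(levels)), key), function(idx) {
    data.frame(chrom = levels$chrom[idx[1]],
               start = bin[idx[1]] * tile + 1L,
               end = (bin[idx[1]] + 1L) * tile,
               value = mean(levels$level[idx]),
               n_sites = length(idx))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write bedGraph and CSV tracks
#'
#' bedGraph is 0-based half-open with values rounded to 6 decimals; the
#' CSV keeps full precision and 1-based inclusive coordinates, with `#`
#' header lines recording the tool version and parameters for
#' provenance.
#'
#' @param track a tile or window data frame with `chrom`, `start`, `end`
#'   and a value column.
#' @param prefix output path prefix; writes `<prefix>.bedGraph` and
#'   `<prefix>.csv`.
#' @param value_col name of the value column (default `"value"`).
#' @param params named list echoed into the CSV header.
#' @return Invisibly, the two file paths.
#' @export
write_tracks <- function(track, prefix, value_col = "value",
                         params = list()) {
  bg <- paste0(prefix, ".bedGraph")
  csv <- paste0(prefix, ".csv")
  dir <- dirname(bg)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  bed <- data.frame(chrom = track$chrom,
                    start = track$start - 1L,   # 0-based half-open
                    end = track$end,
                    value = round(track[[value_col]], 6))
  utils::write.table(bed, bg, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  hdr <- c(sprintf("# methylhet %s",
                   as.character(utils::packageVersion("methylhet"))),
           "# coordinates: 1-based inclusive",
           vapply(names(params), function(k) {
             sprintf("# %s: %s", k, paste(params[[k]], collapse = ","))
           }, character(1)))
  con <- file(csv, "w")
  writeLines(hdr, con)
  utils::write.csv(track, con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(c(bedGraph = bg, csv = csv))
}

#' Read a CSV track written by [write_tracks]
#'
#' @param path CSV path.
#' @return The track data frame (header comment lines skipped).
#' @export
read_tracks <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Genome-mean score summary
#'
#' Mean of a score over all scored windows, optionally per chromosome —
#' a plain genome-wide summary of a sample's heterogeneity.
#'
#' @param windows window-score data frame from [screen_genome].
#' @param score score column name.
#' @param by_chrom also return per-chromosome means.
#' @return Named list with `genome_mean`, `n_windows` and optionally
#'   `by_chrom`.
#' @export
summarize_genome <- function(windows, score = "PWS", by_chrom = FALSE) {
  if (!score %in% names(windows)) stop("no score column '", score, "'")
  out <- list(genome_mean = mean(windows[[score]]),
              n_windows = nrow(windows))
  if (by_chrom)
    out$by_chrom <- tapply(windows[[score]], windows$chrom, mean)
  out
}
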