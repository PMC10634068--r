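#' Read-level methylation pattern extraction
#'
#' Functions for locating cytosines of a given sequence context on a
#' reference, sliding windows of `w` context cytosines along them, and
#' tabulating the complete read-level methylation patterns (epialleles)
#' observed at each window.
#'
#' @name patterns
#' @keywords internal
NULL

.CONTEXTS <- c("CG", "CHG", "CHH")

#' Construct a pattern-count table for one window
#'
#' A `pattern_counts` object holds the distinct read-level methylation
#' patterns observed at a window of `w` cytosines together with their
#' absolute abundances. Patterns are strings over `{'0','1'}` ('1' =
#' methylated), one character per window cytosine in genomic order.
#'
#' @param patterns character vector of distinct patterns, all of equal width.
#' @param counts positive integer vector, one count per pattern.
#' @param window optional `meth_window` describing the genomic window.
#' @return An object of class `pattern_counts` with elements `patterns`,
#'   `counts`, `p` (relative abundances), `depth`, `w` and `window`.
#' @examples
#' pc <- pattern_counts(c("0000", "1111"), c(2, 2))
#' pc$depth
#' @export
pattern_counts <- function(patterns, counts, window = NULL) {
  patterns <- as.character(patterns)
  counts <- as.integer(counts)
  if (length(patterns) == 0L) stop("at least one pattern is required")
  if (length(patterns) != length(counts))
    stop("'patterns' and 'counts' must have equal length")
  if (anyDuplicated(patterns)) stop("patterns must be distinct")
  if (any(counts < 1L)) stop("counts must be positive integers")
  w <- unique(nchar(patterns))
  if (length(w) != 1L) stop("all patterns must have equal width")
  if (!all(grepl("^[01]+$", patterns)))
    stop("patterns must be strings over {'0','1'}")
  if (!is.null(window) && window$w != w)
    stop("pattern width does not match window w")
  o <- order(patterns)
  patterns <- patterns[o]
  counts <- counts[o]
  depth <- sum(counts)
  structure(
    list(patterns = patterns, counts = counts, p = counts / depth,
         depth = depth, w = w, window = window),
    class = "pattern_counts"
  )
}

#' @export
print.pattern_counts <- function(x, ...) {
  cat(sprintf("pattern_counts: %d distinct pattern(s), depth %d, w = %d\n",
              length(x$patterns), x$depth, x$w))
  print(stats::setNames(x$counts, x$patterns))
  invisible(x)
}

#' Describe a genomic window of context cytosines
#'
#' @param chrom sequence name.
#' @param sites strictly increasing 1-based positions of the `w` cytosines.
#' @param context one of `"CG"`, `"CHG"`, `"CHH"`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `meth_window`.
#' @export
meth_window <- function(chrom, sites, context = "CG", strand = "+") {
  sites <- as.integer(sites)
  if (length(sites) < 2L) stop("a window needs at least 2 sites")
  if (is.unsorted(sites, strictly = TRUE)) stop("sites must be strictly increasing")
  context <- match.arg(context, .CONTEXTS)
  strand <- match.arg(strand, c("+", "-"))
  structure(
    list(chrom = as.character(chrom), sites = sites, context = context,
         strand = strand, w = length(sites)),
    class = "meth_window"
  )
}

#' Locate context cytosines on a reference sequence
#'
#' Scans one reference sequence for cytosines in a given context
#' (CG, CHG or CHH; H = A, C or T) on one strand. Minus-strand sites are
#' reported at the plus-strand coordinate of the cytosine's complement
#' (i.e. the G of a plus-strand CG for a minus-strand CG site).
#'
#' @param seq a [Biostrings::DNAString], or a single character string.
#' @param context one of `"CG"`, `"CHG"`, `"CHH"`.
#' @param strand `"+"` or `"-"`.
#' @return Sorted integer vector of 1-based site positions.
#' @examples
#' enumerate_context_sites("ACGT", "CG")      # 2
#' enumerate_context_sites("ACAGT", "CHG")    # 2
#' @export
enumerate_context_sites <- function(seq, context = "CG", strand = "+") {
  context <- match.arg(context, .CONTEXTS)
  strand <- match.arg(strand, c("+", "-"))
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  if (strand == "+") {
    pat <- context
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), seq, fixed = FALSE)
    sites <- BiocGenerics::start(m)
  } else {
    # reverse complement of the context motif, matched on the plus strand;
    # the minus-strand C sits at the match end (CG->CG, CHG->CDG, CHH->DDG)
    pat <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(context)))
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), seq, fixed = FALSE)
    sites <- BiocGenerics::end(m)
  }
  sort(as.integer(sites))
}

#' Slide windows of w consecutive context sites
#'
#' Windows advance one cytosine at a time, giving `max(0, n - w + 1)`
#' windows over `n` sites.
#'
#' @param sites sorted integer site positions.
#' @param w window size in cytosines (default 4).
#' @return A list of integer vectors, each the `w` site positions of one window.
#' @export
enumerate_windows <- function(sites, w = 4L) {
  w <- as.integer(w)
  if (w < 2L) stop("w must be >= 2")
  sites <- as.integer(sites)
  n <- length(sites)
  if (n < w) return(list())
  lapply(seq_len(n - w + 1L), function(i) sites[i:(i + w - 1L)])
}

#' Extract one read's complete pattern at a window
#'
#' A read contributes a pattern only if it carries an unambiguous
#' methylation call at every one of the window's `w` sites; otherwise the
#' read is excluded from this window (only complete patterns are scored).
#'
#' @param calls named logical vector: names are site positions (as
#'   characters), values `TRUE` for methylated, `FALSE` for unmethylated,
#'   `NA` for ambiguous.
#' @param sites the window's site positions.
#' @return Pattern string, or `NA_character_` if the read is incomplete.
#' @export
extract_read_pattern <- function(calls, sites) {
  v <- calls[as.character(sites)]
  if (length(v) != length(sites) || anyNA(v)) return(NA_character_)
  paste(as.integer(v), collapse = "")
}

#' Tabulate complete read patterns at a window
#'
#' @param read_calls data frame with columns `read`, `pos`, `methylated`
#'   (logical; `NA` = ambiguous call), one row per call.
#' @param sites the window's site positions.
#' @param min_depth minimum number of complete reads required (default 4).
#' @param window optional `meth_window` attached to the result.
#' @return A `pattern_counts`, or `NULL` when fewer than `min_depth`
#'   complete reads cover the window.
#' @export
collect_window_patterns <- function(read_calls, sites, min_depth = 4L,
                                    window = NULL) {
  stopifnot(min_depth >= 1L)
  sub <- read_calls[read_calls$pos %in% sites, , drop = FALSE]
  if (nrow(sub) == 0L) return(NULL)
  pats <- vapply(split(sub, sub$read), function(d) {
    extract_read_pattern(
      stats::setNames(d$methylated, as.character(d$pos)), sites)
  }, character(1))
  pats <- pats[!is.na(pats)]
  if (length(pats) < min_depth) return(NULL)
  tab <- table(pats)
  pattern_counts(names(tab), as.integer(tab), window = window)
}

#' Read a plain-text pattern table
#'
#' Accepts the tab-separated fixture format used throughout the test
#' suite in place of a BAM: columns `chrom`, `strand`, `sites`
#' (comma-separated 1-based positions), `pattern`, `count`. Lines starting
#' with `#` are ignored.
#'
#' @param path path to the TSV file.
#' @param context context recorded on the resulting windows.
#' @return A list of `pattern_counts`, one per distinct (chrom, strand,
#'   sites) window.
#' @export
read_pattern_table <- function(path, context = "CG") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#",
                          colClasses = c("character", "character",
                                         "character", "character", "integer"))
  names(df) <- c("chrom", "strand", "sites", "pattern", "count")
  key <- paste(df$chrom, df$strand, df$sites, sep = "|")
  lapply(split(df, key), function(d) {
    sites <- as.integer(strsplit(d$sites[1], ",")[[1]])
    win <- meth_window(d$chrom[1], sites, context = context,
                       strand = d$strand[1])
    pattern_counts(d$pattern, d$count, window = win)
  })
}
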