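#' Distances between methylation patterns
#'
#' Pairwise distances between equal-width methylation patterns. Two
#' metrics are provided, both on `[0, 1]`: the normalized Hamming
#' distance (default) and a weighted degree kernel (WDK) distance that
#' additionally rewards shared contiguous runs of calls.
#'
#' @name distances
#' @keywords internal
NULL

.check_pair <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("patterns must have equal length")
}

#' Normalized Hamming distance between two patterns
#'
#' @param a,b pattern strings of equal width.
#' @return Fraction of positions at which the patterns differ, in `[0, 1]`.
#' @examples
#' hamming_distance("0000", "0001")  # 0.25
#' @export
hamming_distance <- function(a, b) {
  .check_pair(a, b)
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  sum(x != y) / length(x)
}

#' Weighted-degree-kernel distance between two patterns
#'
#' Computes `1 - sum_k beta_k * s_k`, where `s_k` is the fraction of
#' matching contiguous k-mers at aligned offsets and
#' `beta_k = 2 (w - k + 1) / (w (w + 1))`. The weights sum to 1, so the
#' distance shares the `[0, 1]` range of the Hamming metric; for `w = 1`
#' the two coincide.
#'
#' @param a,b pattern strings of equal width.
#' @return WDK distance in `[0, 1]`; 0 iff the patterns are identical.
#' @examples
#' wdk_distance("0000", "0001")  # 0.4
#' @export
wdk_distance <- function(a, b) {
  .check_pair(a, b)
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  w <- length(x)
  sim <- 0
  for (k in seq_len(w)) {
    n_kmer <- w - k + 1L
    beta <- 2 * n_kmer / (w * (w + 1))
    match_k <- vapply(seq_len(n_kmer), function(i) {
      all(x[i:(i + k - 1L)] == y[i:(i + k - 1L)])
    }, logical(1))
    sim <- sim + beta * sum(match_k) / n_kmer
  }
  1 - sim
}

#' Pairwise distance matrix over distinct patterns
#'
#' @param patterns character vector of distinct, equal-width patterns.
#' @param metric `"hamming"` (default) or `"wdk"`.
#' @return Symmetric numeric matrix with zero diagonal and the patterns
#'   as dimnames, entries in `[0, 1]`.
#' @export
distance_matrix <- function(patterns, metric = c("hamming", "wdk")) {
  metric <- match.arg(metric)
  if (anyDuplicated(patterns)) stop("patterns must be distinct")
  if (length(unique(nchar(patterns))) != 1L)
    stop("patterns must have equal length")
  f <- if (metric == "hamming") hamming_distance else wdk_distance
  n <- length(patterns)
  d <- matrix(0, n, n, dimnames = list(patterns, patterns))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- f(patterns[i], patterns[j])
      }
    }
  }
  d
}
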