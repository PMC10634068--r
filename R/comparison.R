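#' Comparison heterogeneity scores
#'
#' Seven previously published read-level heterogeneity statistics,
#' implemented over the same complete-pattern windows as the model-based
#' scores so that all ten can be benchmarked on identical input. All
#' reads in a window carry complete w-site patterns, so the shared-site
#' set of any read pair is all w sites.
#'
#' @name comparison_scores
#' @keywords internal
NULL

#' Methylation entropy (ME)
#'
#' Per-site Shannon entropy of the pattern distribution:
#' `(1/w) * sum_k -a_k log2 a_k`. 0 for a single pattern, 1 at the
#' uniform distribution over all `2^w` patterns.
#'
#' @param counts a [pattern_counts].
#' @return Value in `[0, 1]`.
#' @export
me_score <- function(counts) {
  stopifnot(inherits(counts, "pattern_counts"))
  p <- counts$p
  -sum(p * log2(p)) / counts$w
}

#' Epipolymorphism (EP)
#'
#' Probability that two reads drawn at random (with replacement) carry
#' different patterns: `1 - sum_k a_k^2`.
#'
#' @param counts a [pattern_counts].
#' @return Value in `[0, 1)`.
#' @export
ep_score <- function(counts) {
  stopifnot(inherits(counts, "pattern_counts"))
  1 - sum(counts$p^2)
}

#' Proportion of discordant reads (PDR)
#'
#' Fraction of reads that are internally discordant, i.e. carry both a
#' methylated and an unmethylated call within the window.
#'
#' @param counts a [pattern_counts].
#' @return Value in `[0, 1]`.
#' @export
pdr_score <- function(counts) {
  stopifnot(inherits(counts, "pattern_counts"))
  discordant <- grepl("0", counts$patterns) & grepl("1", counts$patterns)
  sum(counts$counts[discordant]) / counts$depth
}

#' Fraction of discordant read pairs (FDRP)
#'
#' Fraction of unordered read pairs that disagree at one or more shared
#' sites; on complete-pattern windows this is the fraction of pairs with
#' different patterns.
#'
#' @param counts a [pattern_counts] with depth >= 2.
#' @return Value in `[0, 1]`, or `NA` when depth < 2.
#' @export
fdrp_score <- function(counts) {
  stopifnot(inherits(counts, "pattern_counts"))
  n <- counts$depth
  if (n < 2L) return(NA_real_)
  concordant <- sum(choose(counts$counts, 2))
  (choose(n, 2) - concordant) / choose(n, 2)
}

#' Quantitative FDRP (qFDRP)
#'
#' Mean over unordered read pairs of the normalized Hamming mismatch
#' fraction across shared sites.
#'
#' @param counts a [pattern_counts] with depth >= 2.
#' @return Value in `[0, 1]`, or `NA` when depth < 2.
#' @export
qfdrp_score <- function(counts) {
  stopifnot(inherits(counts, "pattern_counts"))
  n <- counts$depth
  if (n < 2L) return(NA_real_)
  d <- distance_matrix(counts$patterns, "hamming")
  cc <- outer(counts$counts, counts$counts)
  sum(d * cc) / 2 / choose(n, 2)
}

#' Methylation haplotype load (MHL)
#'
#' Length-weighted fraction of fully methylated contiguous substrings,
#' over all substring lengths 1..w:
#' `sum_l l * f_l / sum_l l`, where `f_l` is the fraction of length-l
#' substrings (over all reads and offsets) that are all-methylated.
#'
#' @param counts a [pattern_counts].
#' @return Value in `[0, 1]`.
#' @export
mhl_score <- function(counts) {
  stopifnot(inherits(counts, "pattern_counts"))
  w <- counts$w
  mat <- do.call(rbind, lapply(strsplit(counts$patterns, ""),
                               function(x) x == "1"))
  num <- 0; den <- 0
  for (l in seq_len(w)) {
    n_sub <- w - l + 1L
    full <- 0L
    for (i in seq_len(n_sub)) {
      allm <- rowSums(mat[, i:(i + l - 1L), drop = FALSE]) == l
      full <- full + sum(counts$counts[allm])
    }
    frac <- full / (counts$depth * n_sub)
    num <- num + l * frac
    den <- den + l
  }
  num / den
}

#' Methylation concurrence (MC)
#'
#' Reads are trichotomized as fully methylated, fully unmethylated or
#' mixed; each read is weighted by the number of window sites it covers
#' (w for complete patterns) and the score is the weighted fraction of
#' mixed reads.
#'
#' @param counts a [pattern_counts].
#' @return Value in `[0, 1]`.
#' @export
mc_score <- function(counts) {
  stopifnot(inherits(counts, "pattern_counts"))
  mixed <- grepl("0", counts$patterns) & grepl("1", counts$patterns)
  omega <- counts$w * counts$counts   # per-read coverage, summed per pattern
  sum(omega[mixed]) / sum(omega)
}
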