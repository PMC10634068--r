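#' Hill-number (attribute-diversity) heterogeneity scores
#'
#' The three model-based heterogeneity estimators — abundance-based (AB),
#' pairwise-similarity-based (PWS) and phylogenetic-tree-based (PHY) — are
#' specializations of a single attribute-diversity framework of order q,
#' evaluated at q = 2 (the reciprocal Simpson form). Entities carry an
#' attribute value v_u and an abundance a_u; with V = sum(v_u a_u) the
#' diversity is `[sum_u v_u (a_u / V)^q]^(1 / (1 - q))`.
#'
#' AB takes the distinct patterns as entities with v_u = 1, giving the
#' effective number of patterns. PWS takes pattern pairs as entities with
#' the pairwise distance d_ij as attribute and takes a square root so the
#' score doubles (rather than quadruples) when two equally diverse,
#' maximally separated groups are pooled. PHY takes the branches of a
#' rooted tree over the patterns as entities, with branch length as
#' attribute and descendant-leaf abundance as abundance.
#'
#' @name hill_scores
#' @keywords internal
NULL

#' Attribute diversity of order q
#'
#' General Hill-number form over a set of entities with attribute values
#' `v` and abundances `a`: with `V = sum(v * a)` and relative abundances
#' `a / V`, returns `[sum(v * (a / V)^q)]^(1 / (1 - q))`; the `q = 1` case
#' is the Shannon limit `exp(-sum(v * (a/V) * log(a/V)))`.
#'
#' @param a non-negative abundances, at least one positive.
#' @param v non-negative attribute values (default 1 for every entity).
#' @param q diversity order, `q >= 0` (default 2).
#' @return Positive diversity value.
#' @examples
#' attribute_diversity(c(0.5, 0.5))            # 2
#' attribute_diversity(rep(0.25, 4), q = 1)    # 4
#' @export
attribute_diversity <- function(a, v = rep(1, length(a)), q = 2) {
  if (length(a) == 0L || all(a == 0)) stop("abundances must not be all zero")
  if (any(a < 0) || any(v < 0)) stop("abundances and attributes must be >= 0")
  if (q < 0) stop("q must be >= 0")
  keep <- a > 0
  a <- a[keep]; v <- v[keep]
  V <- sum(v * a)
  rel <- a / V
  if (abs(q - 1) < 1e-9) {
    exp(-sum(v * rel * log(rel)))
  } else {
    sum(v * rel^q)^(1 / (1 - q))
  }
}

#' Abundance-based heterogeneity (AB)
#'
#' The effective number of methylation patterns in a window:
#' `AB = 1 / sum(p_i^2)` over the relative pattern abundances. Ranges
#' from 1 (homogeneous window) to `2^w` (uniform over all patterns).
#'
#' @param counts a [pattern_counts].
#' @return AB score in `[1, 2^w]`.
#' @examples
#' ab_score(pattern_counts(c("0000", "1111"), c(3, 1)))  # 1.6
#' @export
ab_score <- function(counts) {
  stopifnot(inherits(counts, "pattern_counts"))
  1 / sum(counts$p^2)
}

#' Pairwise-similarity-based heterogeneity (PWS)
#'
#' Treats ordered pattern pairs as entities with the pairwise distance
#' `d_ij` as attribute. With `Q = sum_ij d_ij p_i p_j` and pair
#' abundances `p_ij = p_i p_j / Q`, the score is
#' `PWS = (sum_ij d_ij p_ij^2)^(-1/2)` — the square root keeps the
#' pooling behaviour additive (doubling rather than quadrupling).
#' A homogeneous window has no pattern pair and scores 0, the continuity
#' limit.
#'
#' @param counts a [pattern_counts].
#' @param dist optional precomputed [distance_matrix] covering the
#'   window's patterns; built with `metric` when omitted.
#' @param metric distance metric used when `dist` is missing.
#' @return PWS score, `>= 0`.
#' @examples
#' pws_score(pattern_counts(c("0000", "1111"), c(2, 2)))  # sqrt(2)
#' @export
pws_score <- function(counts, dist = NULL,
                      metric = c("hamming", "wdk")) {
  stopifnot(inherits(counts, "pattern_counts"))
  if (length(counts$patterns) == 1L) return(0)
  d <- .resolve_dist(counts, dist, match.arg(metric))
  p <- counts$p
  pp <- outer(p, p)
  Q <- sum(d * pp)
  if (Q == 0) return(0)
  pij <- pp / Q
  sum(d * pij^2)^(-0.5)
}

.resolve_dist <- function(counts, dist, metric) {
  if (is.null(dist)) return(distance_matrix(counts$patterns, metric))
  if (is.null(dimnames(dist)) ||
      !all(counts$patterns %in% rownames(dist)))
    stop("distance matrix must cover all patterns in 'counts'")
  dist[counts$patterns, counts$patterns, drop = FALSE]
}

#' Build the rooted pattern tree used by PHY
#'
#' Average-linkage (UPGMA) agglomerative clustering of the pairwise
#' pattern distances yields a rooted, ultrametric binary tree with the
#' distinct patterns as leaves. Each of its `B = 2R - 2` branches carries
#' a length `L_i` (difference of node heights; leaf height 0, internal
#' node height = merge height / 2) and an abundance `p_i`, the sum of the
#' relative abundances of the leaves below it. Patterns are ordered
#' lexicographically before clustering so ties break deterministically.
#'
#' @param dist a [distance_matrix] over at least two distinct patterns.
#' @param counts a [pattern_counts] whose patterns match `dist`.
#' @return An object of class `pattern_tree`: list with `branches`
#'   (data frame of `length` and `abundance`, one row per branch),
#'   `n_branches`, `hclust` (the underlying clustering) and `leaves`.
#' @examples
#' pc <- pattern_counts(c("0000", "1111"), c(2, 2))
#' build_pattern_tree(distance_matrix(pc$patterns), pc)$n_branches  # 2
#' @export
build_pattern_tree <- function(dist, counts) {
  stopifnot(inherits(counts, "pattern_counts"))
  pats <- sort(counts$patterns)
  if (length(pats) < 2L)
    stop("a pattern tree requires at least 2 distinct patterns")
  d <- dist[pats, pats, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  p_leaf <- counts$p[match(pats, counts$patterns)]
  R <- length(pats)
  n_merge <- R - 1L
  node_height <- hc$height / 2           # ultrametric node heights
  node_abund <- numeric(n_merge)
  # branch bookkeeping: children of each merge contribute one branch each,
  # except the final merge's two children which attach to the root
  lengths <- numeric(0)
  abunds <- numeric(0)
  child_height <- function(idx) if (idx < 0) 0 else node_height[idx]
  child_abund <- function(idx) if (idx < 0) p_leaf[-idx] else node_abund[idx]
  for (k in seq_len(n_merge)) {
    for (child in hc$merge[k, ]) {
      lengths <- c(lengths, node_height[k] - child_height(child))
      abunds <- c(abunds, child_abund(child))
    }
    node_abund[k] <- sum(vapply(hc$merge[k, ], child_abund, numeric(1)))
  }
  structure(
    list(branches = data.frame(length = lengths, abundance = abunds),
         n_branches = length(lengths),
         hclust = hc, leaves = pats,
         leaf_abundance = stats::setNames(p_leaf, pats)),
    class = "pattern_tree"
  )
}

#' @export
print.pattern_tree <- function(x, ...) {
  cat(sprintf("pattern_tree: %d leaves, %d branches\n",
              length(x$leaves), x$n_branches))
  invisible(x)
}

#' Phylogenetic-tree-based heterogeneity (PHY)
#'
#' Treats the branches of the pattern tree as entities with branch length
#' `L_i` as attribute and branch abundance `p_i` as abundance: with
#' `a_i = p_i / sum(L_j p_j)`, `PHY = (sum_i L_i a_i^2)^(-1)`. A
#' homogeneous window has no tree and scores 0 by convention.
#'
#' @param counts a [pattern_counts].
#' @param tree optional precomputed [build_pattern_tree] result; built
#'   from `metric` distances when omitted.
#' @param metric distance metric used when `tree` is missing.
#' @return PHY score, `>= 0`.
#' @examples
#' phy_score(pattern_counts(c("0000", "1111"), c(2, 2)))  # 1
#' @export
phy_score <- function(counts, tree = NULL,
                      metric = c("hamming", "wdk")) {
  stopifnot(inherits(counts, "pattern_counts"))
  if (length(counts$patterns) == 1L) return(0)
  if (is.null(tree)) {
    d <- distance_matrix(counts$patterns, match.arg(metric))
    tree <- build_pattern_tree(d, counts)
  }
  if (!setequal(tree$leaves, counts$patterns))
    stop("tree leaves must match the window's distinct patterns")
  L <- tree$branches$length
  p <- tree$branches$abundance
  if (all(L == 0)) stop("all branch lengths are zero")
  Tbar <- sum(L * p)
  a <- p / Tbar
  1 / sum(L * a^2)
}

#' Score one window with any combination of heterogeneity scores
#'
#' Convenience dispatcher used by the genome screen: computes the
#' requested model-based (`AB`, `PWS`, `PHY`) and comparison (`ME`, `EP`,
#' `PDR`, `FDRP`, `qFDRP`, `MHL`, `MC`) scores from one pattern-count
#' table.
#'
#' @param counts a [pattern_counts].
#' @param scores character vector of score names.
#' @param metric distance metric for PWS/PHY.
#' @return Named numeric vector, one element per requested score.
#' @export
score_window <- function(counts, scores = "PWS",
                         metric = c("hamming", "wdk")) {
  metric <- match.arg(metric)
  known <- c("AB", "PWS", "PHY", "ME", "EP", "PDR", "FDRP", "qFDRP",
             "MHL", "MC")
  bad <- setdiff(scores, known)
  if (length(bad))
    stop("unknown score(s): ", paste(bad, collapse = ", "))
  vapply(scores, function(s) {
    switch(s,
      AB    = ab_score(counts),
      PWS   = pws_score(counts, metric = metric),
      PHY   = phy_score(counts, metric = metric),
      ME    = me_score(counts),
      EP    = ep_score(counts),
      PDR   = pdr_score(counts),
      FDRP  = fdrp_score(counts),
      qFDRP = qfdrp_score(counts),
      MHL   = mhl_score(counts),
      MC    = mc_score(counts))
  }, numeric(1))
}
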