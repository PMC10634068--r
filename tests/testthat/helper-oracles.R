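# Shared fixtures and independent brute-force oracles.
# The oracles deliberately use naive loops (and, for the tree score, an
# independent route through ape) so they never share code with the
# implementations they check.

all_patterns <- function(w) {
  sort(apply(expand.grid(rep(list(c("0", "1")), w)), 1,
             paste, collapse = ""))
}

random_pc <- function(w = 4, max_depth = 50) {
  alpha <- all_patterns(w)
  R <- sample.int(min(length(alpha), 6), 1)
  pats <- sample(alpha, R)
  depth <- sample(seq(max(R, 2), max_depth), 1)
  cnt <- as.integer(tabulate(sample.int(R, depth - R, replace = TRUE),
                             nbins = R)) + 1L
  pattern_counts(pats, cnt)
}

expand_reads <- function(pc) rep(pc$patterns, pc$counts)

pat_chars <- function(p) strsplit(p, "")[[1]]

# --- naive scan for context sites -------------------------------------
oracle_context_sites <- function(seq, context, strand = "+") {
  x <- strsplit(seq, "")[[1]]
  H <- c("A", "C", "T")
  n <- length(x)
  hits <- integer(0)
  if (strand == "+") {
    for (i in seq_len(n)) {
      ok <- switch(context,
        CG  = i + 1 <= n && x[i] == "C" && x[i + 1] == "G",
        CHG = i + 2 <= n && x[i] == "C" && x[i + 1] %in% H && x[i + 2] == "G",
        CHH = i + 2 <= n && x[i] == "C" && x[i + 1] %in% H && x[i + 2] %in% H)
      if (isTRUE(ok)) hits <- c(hits, i)
    }
  } else {
    # minus-strand context read 3'->5' on the plus strand: complement
    Hc <- c("T", "G", "A")   # complements of H
    for (i in seq_len(n)) {
      ok <- switch(context,
        CG  = i - 1 >= 1 && x[i] == "G" && x[i - 1] == "C",
        CHG = i - 2 >= 1 && x[i] == "G" && x[i - 1] %in% Hc && x[i - 2] == "C",
        CHH = i - 2 >= 1 && x[i] == "G" && x[i - 1] %in% Hc && x[i - 2] %in% Hc)
      if (isTRUE(ok)) hits <- c(hits, i)
    }
  }
  hits
}

# --- model-score oracles ----------------------------------------------
oracle_ab <- function(pc) {
  reads <- expand_reads(pc)
  p <- as.numeric(table(reads)) / length(reads)
  1 / sum(p * p)
}

oracle_pws <- function(pc, metric = "hamming") {
  pats <- pc$patterns
  p <- pc$p
  R <- length(pats)
  if (R == 1) return(0)
  dfun <- if (metric == "hamming") hamming_distance else wdk_distance
  Q <- 0
  for (i in seq_len(R)) for (j in seq_len(R))
    Q <- Q + dfun(pats[i], pats[j]) * p[i] * p[j]
  s <- 0
  for (i in seq_len(R)) for (j in seq_len(R))
    s <- s + dfun(pats[i], pats[j]) * (p[i] * p[j] / Q)^2
  s^(-0.5)
}

# tree route through ape: UPGMA tree as a phylo object, branch lengths
# from the phylo edge table, branch abundances by recursive descent
oracle_phy <- function(pc, metric = "hamming") {
  if (length(pc$patterns) == 1) return(0)
  pats <- sort(pc$patterns)
  d <- distance_matrix(pats, metric)
  ph <- ape::as.phylo(stats::hclust(stats::as.dist(d), "average"))
  p_tip <- pc$p[match(ph$tip.label, pc$patterns)]
  n_tip <- length(ph$tip.label)
  desc_ab <- function(node) {
    if (node <= n_tip) return(p_tip[node])
    sum(vapply(ph$edge[ph$edge[, 1] == node, 2], desc_ab, numeric(1)))
  }
  ab <- vapply(ph$edge[, 2], desc_ab, numeric(1))
  L <- ph$edge.length
  Tbar <- sum(L * ab)
  1 / sum(L * (ab / Tbar)^2)
}

# --- comparison-score oracles (explicit loops over reads) -------------
oracle_me <- function(pc) {
  reads <- expand_reads(pc)
  a <- as.numeric(table(reads)) / length(reads)
  -sum(a * log2(a)) / nchar(reads[1])
}

oracle_ep <- function(pc) {
  reads <- expand_reads(pc)
  a <- as.numeric(table(reads)) / length(reads)
  1 - sum(a^2)
}

oracle_pdr <- function(pc) {
  reads <- expand_reads(pc)
  disc <- vapply(reads, function(r) {
    x <- pat_chars(r)
    any(x == "1") && any(x == "0")
  }, logical(1))
  mean(disc)
}

oracle_fdrp <- function(pc) {
  reads <- expand_reads(pc)
  n <- length(reads)
  if (n < 2) return(NA_real_)
  num <- 0
  for (s in 1:(n - 1)) for (t in (s + 1):n)
    num <- num + any(pat_chars(reads[s]) != pat_chars(reads[t]))
  num / choose(n, 2)
}

oracle_qfdrp <- function(pc) {
  reads <- expand_reads(pc)
  n <- length(reads)
  if (n < 2) return(NA_real_)
  num <- 0
  for (s in 1:(n - 1)) for (t in (s + 1):n)
    num <- num + mean(pat_chars(reads[s]) != pat_chars(reads[t]))
  num / choose(n, 2)
}

oracle_mhl <- function(pc) {
  reads <- expand_reads(pc)
  w <- nchar(reads[1])
  num <- 0; den <- 0
  for (l in 1:w) {
    full <- 0; tot <- 0
    for (r in reads) {
      x <- pat_chars(r)
      for (i in 1:(w - l + 1)) {
        tot <- tot + 1
        if (all(x[i:(i + l - 1)] == "1")) full <- full + 1
      }
    }
    num <- num + l * (full / tot)
    den <- den + l
  }
  num / den
}

oracle_mc <- function(pc) {
  reads <- expand_reads(pc)
  w_c <- 0; w_m <- 0; w_u <- 0
  for (r in reads) {
    x <- pat_chars(r)
    omega <- length(x)
    if (all(x == "1")) w_m <- w_m + omega
    else if (all(x == "0")) w_u <- w_u + omega
    else w_c <- w_c + omega
  }
  w_c / (w_c + w_m + w_u)
}

comparison_oracles <- list(
  ME = oracle_me, EP = oracle_ep, PDR = oracle_pdr, FDRP = oracle_fdrp,
  qFDRP = oracle_qfdrp, MHL = oracle_mhl, MC = oracle_mc)

comparison_impls <- list(
  ME = me_score, EP = ep_score, PDR = pdr_score, FDRP = fdrp_score,
  qFDRP = qfdrp_score, MHL = mhl_score, MC = mc_score)

# --- small simulated two-group screening experiment -------------------
# Builds BAMs for `n_rep` replicates per group over `n_loci` loci with
# `w_sites` context cytosines each; `spec_fun(group, locus)` returns the
# pattern multiset (list with patterns, counts) for that group/locus.
two_group_bams <- function(spec_fun, n_loci, w_sites = 8, n_rep = 3,
                           dir = tempfile("grp")) {
  dir.create(dir)
  ls <- synth_locus_set(n_loci, w = w_sites)
  out <- list(A = character(), B = character(), locus_set = ls)
  for (g in c("A", "B")) {
    for (r in seq_len(n_rep)) {
      spec <- lapply(seq_len(n_loci), function(l) spec_fun(g, l))
      sim <- make_toy_alignment(spec, ls)
      paths <- sim_to_bam(sim, file.path(dir, sprintf("%s%d", g, r)))
      out[[g]] <- c(out[[g]], paths[["bam"]])
      out$fasta <- paths[["fasta"]]
    }
  }
  out
}
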