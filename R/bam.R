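#' Methylation-call extraction from alignments
#'
#' Reads a coordinate-sorted, indexed BAM of bisulfite/EM-seq alignments
#' and produces per-read methylation calls at a given set of context
#' cytosines. Calls come from a Bismark-style per-base XM tag when
#' present; otherwise they are inferred from the read sequence against
#' the expected bisulfite conversion (C kept = methylated, C read as T =
#' unmethylated on the plus strand; G/A on the minus strand).
#'
#' Reads are assigned to the strand of their alignment (FLAG 0x10), the
#' convention used for directional bisulfite libraries, and contribute
#' calls only at sites on that strand.
#'
#' @name bam_calls
#' @keywords internal
NULL

#' Extract per-read methylation calls at context sites
#'
#' @param bam path to an indexed BAM file.
#' @param chrom reference sequence name.
#' @param strand `"+"` or `"-"`; only alignments on this strand are used.
#' @param sites sorted 1-based positions of the context cytosines.
#' @param call_source `"auto"` (XM tag when present, else sequence),
#'   `"tag"` or `"sequence"`.
#' @return Data frame with columns `read`, `pos`, `methylated` (logical,
#'   `NA` for ambiguous calls), one row per (read, covered site).
#' @export
read_bam_calls <- function(bam, chrom, strand, sites,
                           call_source = c("auto", "tag", "sequence")) {
  call_source <- match.arg(call_source)
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM index (.bai) not found for: ", bam)
  if (length(sites) == 0L)
    return(data.frame(read = character(), pos = integer(),
                      methylated = logical()))
  which <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(min(sites), max(sites)))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "seq"), tag = "XM", which = which,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  gal <- GenomicAlignments::readGAlignments(bam, param = param,
                                            use.names = FALSE)
  if (length(gal) == 0L)
    return(data.frame(read = character(), pos = integer(),
                      methylated = logical()))
  gal <- gal[as.character(BiocGenerics::strand(gal)) == strand]
  if (length(gal) == 0L)
    return(data.frame(read = character(), pos = integer(),
                      methylated = logical()))
  mc <- S4Vectors::mcols(gal)
  xm <- mc$XM
  have_tag <- !is.null(xm) && !all(is.na(xm))
  use_tag <- switch(call_source,
    auto = have_tag,
    tag = { if (!have_tag) stop("no XM tag present in ", bam); TRUE },
    sequence = FALSE)
  raw <- if (use_tag) Biostrings::BStringSet(ifelse(is.na(xm), "", xm))
         else mc$seq
  # project query-space strings to reference space (CIGAR-aware)
  ref_str <- GenomicAlignments::sequenceLayer(
    raw, GenomicAlignments::cigar(gal),
    from = "query", to = "reference")
  starts <- BiocGenerics::start(gal)
  ends <- BiocGenerics::end(gal)
  qn <- S4Vectors::mcols(gal)$qname
  # disambiguate fragments sharing a name (mates): suffix by index
  qn <- paste0(qn, "/", seq_along(qn))
  out <- vector("list", length(gal))
  for (i in seq_along(gal)) {
    s <- sites[sites >= starts[i] & sites <= ends[i]]
    if (length(s) == 0L) next
    chars <- strsplit(as.character(ref_str[[i]]), "")[[1]]
    calls <- chars[s - starts[i] + 1L]
    meth <- if (use_tag) .call_from_xm(calls)
            else .call_from_base(calls, strand)
    out[[i]] <- data.frame(read = qn[i], pos = s, methylated = meth)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(read = character(), pos = integer(),
                      methylated = logical()))
  do.call(rbind, out)
}

# Bismark XM codes: Z/X/H/U methylated CpG/CHG/CHH/unknown-context,
# lowercase unmethylated; '.' = not a cytosine on this read.
.call_from_xm <- function(chars) {
  meth <- rep(NA, length(chars))
  meth[chars %in% c("Z", "X", "H", "U")] <- TRUE
  meth[chars %in% c("z", "x", "h", "u")] <- FALSE
  meth
}

.call_from_base <- function(chars, strand) {
  meth <- rep(NA, length(chars))
  if (strand == "+") {
    meth[chars == "C"] <- TRUE
    meth[chars == "T"] <- FALSE
  } else {
    meth[chars == "G"] <- TRUE
    meth[chars == "A"] <- FALSE
  }
  meth
}

#' Load a reference genome as a DNAStringSet
#'
#' @param reference path to a FASTA file, or a
#'   [Biostrings::DNAStringSet] passed through unchanged.
#' @return A named [Biostrings::DNAStringSet].
#' @export
load_reference <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) return(reference)
  if (!file.exists(reference)) stop("reference not found: ", reference)
  ref <- Biostrings::readDNAStringSet(reference)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}
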