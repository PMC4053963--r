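#' Combine vlincRNA sets into non-overlapping regions
#'
#' Regions from several call sets that share at least one base are collapsed
#' into one (strand-blind by default, since density-called sets carry no
#' strand); touching regions are not collapsed. This is how a combined
#' non-redundant region count across samples is obtained.
#'
#' @param sets a `GRanges` or list of `GRanges`.
#' @param ignore_strand collapse across strands (default TRUE).
#' @return a flattened `GRanges`.
#' @export
combine_vlinc_sets <- function(sets, ignore_strand = TRUE) {
  if (methods::is(sets, "GRanges")) sets <- list(sets)
  all <- do.call(c, lapply(unname(sets), GenomicRanges::granges))
  GenomicRanges::reduce(all, ignore.strand = ignore_strand,
                        min.gapwidth = 1L)
}

#' Summary statistics of a vlincRNA region table
#'
#' The descriptive statistics reported for a region catalogue: number of
#' regions, median and maximum genomic length, and the total number of
#' distinct bases covered.
#'
#' @param vlincs a `GRanges`.
#' @return a list with `n`, `median_length`, `max_length`, `union_bases`.
#' @export
vlinc_table_stats <- function(vlincs) {
  w <- as.numeric(GenomicRanges::width(vlincs))
  list(n = length(vlincs),
       median_length = if (length(w)) stats::median(w) else NA_real_,
       max_length = if (length(w)) max(w) else NA_real_,
       union_bases = union_length(vlincs))
}

#' Count regions of one set overlapping another
#'
#' Cross-set overlap counting (e.g. regions found in cancerous samples that
#' also occur in non-cancerous ones): the number of `query` regions sharing
#' at least one base with `subject`.
#'
#' @param query,subject `GRanges`.
#' @param strand_specific logical.
#' @return an integer count.
#' @export
cross_set_overlap <- function(query, subject, strand_specific = FALSE) {
  overlap_count(query, subject, strand_specific = strand_specific)$count
}
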