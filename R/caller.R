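#' Caller parameters
#'
#' Thresholds of the two region-calling procedures. Defaults follow the
#' published settings: contigs separated by <= 1 kb are merged, merged blocks
#' of at least 50 kb are kept and then joined across gaps of <= 5 kb; the
#' density caller thresholds at the 80th percentile of per-base expression
#' and merges expressed bases across gaps of <= 500 bp ("blood" mode) or
#' 1 kb ("mouse" mode).
#'
#' @param merge_gap_1 bases; first-stage contig merge gap.
#' @param min_length bases; minimum region length retained.
#' @param merge_gap_2 bases; second-stage merge gap between retained regions.
#' @param density_percentile fraction in (0, 1); expression percentile used
#'   as the density threshold.
#' @param density_merge_gap bases; merge gap for the density caller. Defaults
#'   to 500 for `mode = "blood"`, 1000 for `mode = "mouse"`.
#' @param mode convenience switch setting `density_merge_gap`.
#' @return a list of class `caller_params`.
#' @export
caller_params <- function(merge_gap_1 = 1000, min_length = 50000,
                          merge_gap_2 = 5000, density_percentile = 0.80,
                          density_merge_gap = NULL,
                          mode = c("blood", "mouse")) {
  mode <- match.arg(mode)
  if (is.null(density_merge_gap))
    density_merge_gap <- switch(mode, blood = 500, mouse = 1000)
  p <- list(merge_gap_1 = merge_gap_1, min_length = min_length,
            merge_gap_2 = merge_gap_2,
            density_percentile = density_percentile,
            density_merge_gap = density_merge_gap)
  stopifnot(all(vapply(p, function(v) is.numeric(v) && length(v) == 1L &&
                         !is.na(v) && v >= 0, TRUE)),
            p$min_length > 0,
            p$density_percentile > 0, p$density_percentile < 1)
  class(p) <- "caller_params"
  p
}

.as_vlincs <- function(gr, sample, min_length) {
  gr <- sort(gr, ignore.strand = TRUE)
  if (length(gr))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      name = sprintf("%s_vlinc_%d", sample, seq_along(gr)),
      source_sample = sample)
  gr
}

#' Call vlincRNAs from strand-specific coverage contigs
#'
#' The contig procedure: (1) drop any contig sharing a base with a gene body
#' on the same strand (opposite-strand genes are treated as intergenic);
#' (2) merge surviving contigs per strand across gaps of <= `merge_gap_1`;
#' (3) keep merged blocks of at least `min_length` bases; (4) merge the
#' survivors across gaps of <= `merge_gap_2`. Output regions are
#' strand-specific.
#'
#' @param contigs a stranded `GRanges` (e.g. from [read_contigs()]);
#'   unstranded contigs are an error.
#' @param genes a stranded `GRanges` of gene body spans (transcription start
#'   to end).
#' @param params a [caller_params()] list.
#' @param sample sample identifier recorded on the called regions.
#' @return a `GRanges` of called regions with `name` and `source_sample`
#'   metadata columns.
#' @export
call_from_contigs <- function(contigs, genes, params = caller_params(),
                              sample = "sample") {
  stopifnot(inherits(params, "caller_params"))
  if (any(as.character(GenomicRanges::strand(contigs)) == "*"))
    stop("the contig caller is strand-specific: unstranded contigs supplied")
  hit <- GenomicRanges::countOverlaps(contigs, genes,
                                      ignore.strand = FALSE) > 0L
  kept <- contigs[!hit]
  m1 <- merge_within_gap(kept, params$merge_gap_1)
  m1 <- m1[GenomicRanges::width(m1) >= params$min_length]
  out <- merge_within_gap(m1, params$merge_gap_2)
  .as_vlincs(out, sample, params$min_length)
}

#' Density threshold at a percentile of expression
#'
#' Nearest-rank percentile of per-base density taken over positions with
#' non-zero density (the silent majority of the genome is excluded, otherwise
#' any percentile below the expressed fraction would be zero).
#'
#' @param track a `GRanges` density track with a `score` column.
#' @param percentile fraction in (0, 1).
#' @return the density value at the nearest-rank percentile.
#' @export
density_threshold <- function(track, percentile = 0.80) {
  stopifnot(percentile > 0, percentile < 1)
  v <- S4Vectors::mcols(track)$score
  w <- as.numeric(GenomicRanges::width(track))
  pos <- v > 0
  if (!any(pos)) stop("no expressed positions")
  v <- v[pos]; w <- w[pos]
  o <- order(v)
  v <- v[o]; w <- w[o]
  k <- ceiling(percentile * sum(w))
  v[findInterval(k - 1, cumsum(w)) + 1L]
}

#' Call vlincRNAs from a non-strand-specific density track
#'
#' The density procedure: (1) remove positions inside annotated genes on
#' either strand; (2) keep positions whose density reaches the
#' `density_percentile` threshold computed after gene removal; (3) merge
#' kept positions across gaps of <= `density_merge_gap`; (4) keep regions of
#' at least `min_length` bases. Output regions are unstranded.
#'
#' @param track a `GRanges` density track with a `score` column.
#' @param genes a `GRanges` of gene spans (both strands are removed).
#' @param params a [caller_params()] list.
#' @param sample sample identifier recorded on the called regions.
#' @return an unstranded `GRanges` of called regions.
#' @export
call_from_density <- function(track, genes, params = caller_params(),
                              sample = "sample") {
  stopifnot(inherits(params, "caller_params"))
  if (!length(track) || !any(S4Vectors::mcols(track)$score > 0))
    stop("no expressed positions")
  masked <- .track_subtract(track, genes)
  if (!length(masked) || !any(S4Vectors::mcols(masked)$score > 0))
    return(.as_vlincs(GenomicRanges::GRanges(), sample, params$min_length))
  thr <- density_threshold(masked, params$density_percentile)
  kept <- masked[S4Vectors::mcols(masked)$score >= thr]
  GenomicRanges::strand(kept) <- "*"
  merged <- merge_within_gap(kept, params$density_merge_gap)
  out <- merged[GenomicRanges::width(merged) >= params$min_length]
  .as_vlincs(out, sample, params$min_length)
}

# Remove the parts of a scored track covered by `regions`, preserving the
# score of each surviving fragment (a run overlapping a region boundary is
# cut, not dropped).
.track_subtract <- function(track, regions) {
  if (!length(regions) || !length(track)) return(track)
  mask <- .iset_flatten(.gr_to_iset(regions))
  span <- vapply(.gr_to_iset(track), function(m) max(m[, 2L]), 1)
  for (ch in names(mask))
    span[ch] <- max(span[ch], max(mask[[ch]][, 2L]), na.rm = TRUE)
  comp <- lapply(names(span), function(ch) {
    m <- if (!is.null(mask[[ch]])) mask[[ch]] else .iv_empty
    .iv_complement(m, span[[ch]])
  })
  names(comp) <- names(span)
  comp_gr <- .iset_to_gr(comp)
  GenomeInfoDb::seqlevels(comp_gr) <- GenomeInfoDb::seqlevels(track)
  h <- GenomicRanges::findOverlaps(track, comp_gr, ignore.strand = TRUE)
  pieces <- IRanges::pintersect(
    GenomicRanges::granges(track)[S4Vectors::queryHits(h)],
    comp_gr[S4Vectors::subjectHits(h)], ignore.strand = TRUE)
  S4Vectors::mcols(pieces) <- S4Vectors::DataFrame(
    score = S4Vectors::mcols(track)$score[S4Vectors::queryHits(h)])
  GenomicRanges::strand(pieces) <- "*"
  sort(pieces, ignore.strand = TRUE)
}
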