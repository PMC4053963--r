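#' Construct a genomic interval set from BED-style coordinates
#'
#' Convenience constructor taking 0-based half-open (BED convention)
#' coordinates and returning a `GRanges`. All file readers in the package go
#' through this, so browser-style 1-based input can be handled with
#' `zero_based = FALSE`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors; `start` inclusive, `end` exclusive when
#'   `zero_based = TRUE` (the default), else 1-based closed.
#' @param strand strand vector; `"*"` means unstranded and matches both
#'   strands in strand-specific comparisons.
#' @param zero_based logical; are `start`/`end` BED-style 0-based half-open?
#' @param genome optional named vector of chromosome lengths used to set
#'   sequence lengths (and to validate that intervals fit).
#' @param ... further vectors stored as metadata columns.
#' @return a `GRanges`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*",
                              zero_based = TRUE, genome = NULL, ...) {
  if (zero_based) start <- start + 1
  if (any(end < start))
    stop("invalid intervals: end < start")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand, ...)
  if (!is.null(genome)) {
    genome <- as_genome(genome)
    bad <- setdiff(as.character(GenomeInfoDb::seqnames(gr)), names(genome))
    if (length(bad))
      stop("chromosomes absent from genome: ", paste(bad, collapse = ", "))
    if (any(GenomicRanges::end(gr) >
            genome[as.character(GenomeInfoDb::seqnames(gr))]))
      stop("interval extends past declared chromosome length")
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- unname(genome)
  }
  gr
}

#' Coerce to a genome (named vector of chromosome lengths)
#'
#' @param x a named numeric vector, a `Seqinfo`, or a `GRanges` carrying
#'   sequence lengths.
#' @return named numeric vector of positive chromosome lengths.
#' @export
as_genome <- function(x) {
  if (methods::is(x, "Seqinfo")) {
    g <- GenomeInfoDb::seqlengths(x)
  } else if (methods::is(x, "GRanges")) {
    g <- GenomeInfoDb::seqlengths(x)
  } else {
    g <- x
  }
  g <- stats::setNames(as.numeric(g), names(g))
  if (is.null(names(g)) || anyDuplicated(names(g)) || any(is.na(g)) ||
      any(g <= 0))
    stop("a genome must be a uniquely named vector of positive lengths")
  g
}

#' Merge intervals separated by at most a given gap
#'
#' Intervals on the same chromosome and strand whose separation is less than
#' or equal to `max_gap` bases are merged into one. Touching intervals (gap 0)
#' are always merged. The operation is idempotent and order-independent, and
#' the result is flattened (no overlaps remain within a chromosome/strand).
#'
#' @param x a `GRanges`.
#' @param max_gap non-negative number of bases.
#' @return a flattened `GRanges`.
#' @export
merge_within_gap <- function(x, max_gap) {
  if (length(max_gap) != 1L || is.na(max_gap) || max_gap < 0)
    stop("max_gap must be a single non-negative number")
  GenomicRanges::reduce(x, min.gapwidth = max_gap + 1, ignore.strand = FALSE)
}

#' Subtract one interval set from another
#'
#' Returns the bases of `a` not covered by `b`. With
#' `strand_specific = TRUE` only `b` intervals on the same strand (or
#' unstranded) remove coverage; the strand of `a` is preserved either way.
#'
#' @param a,b `GRanges`.
#' @param strand_specific logical.
#' @return a flattened `GRanges`.
#' @export
interval_subtract <- function(a, b, strand_specific = FALSE) {
  strands <- c("+", "-", "*")
  sa <- as.character(GenomicRanges::strand(a))
  pieces <- lapply(strands, function(s) {
    as_ <- a[sa == s]
    if (!length(as_)) return(GenomicRanges::GRanges())
    bs <- if (strand_specific && s != "*") {
      sb <- as.character(GenomicRanges::strand(b))
      b[sb %in% c(s, "*")]
    } else b
    out <- GenomicRanges::setdiff(
      GenomicRanges::reduce(as_, ignore.strand = TRUE),
      GenomicRanges::reduce(bs, ignore.strand = TRUE), ignore.strand = TRUE)
    GenomicRanges::strand(out) <- s
    out
  })
  sort(do.call(c, pieces), ignore.strand = TRUE)
}

#' Total number of distinct bases covered by an interval set
#'
#' The length operator |X| of the space model: overlapping intervals are
#' counted once.
#'
#' @param x a `GRanges`.
#' @param ignore_strand logical; when `TRUE` (default) a base covered on both
#'   strands counts once.
#' @return a number of bases.
#' @export
union_length <- function(x, ignore_strand = TRUE) {
  sum(as.numeric(GenomicRanges::width(
    GenomicRanges::reduce(x, ignore.strand = ignore_strand))))
}

#' Shift interval boundaries outward or inward
#'
#' Each interval `[s, e)` becomes `[s - left_delta, e + right_delta)`,
#' clipped to the chromosome bounds when a genome is supplied. Intervals that
#' collapse (start >= end) are dropped silently; the number dropped is
#' reported via a message when `verbose = TRUE`. No flattening is performed.
#'
#' @param x a `GRanges`.
#' @param left_delta,right_delta signed base counts; positive values extend.
#' @param genome optional genome (see [as_genome()]) for clipping the right
#'   boundary; the left boundary is always clipped at the chromosome origin.
#' @param verbose report the number of collapsed intervals dropped.
#' @return a `GRanges` in the input order (minus dropped intervals).
#' @export
adjust_boundaries <- function(x, left_delta = 0, right_delta = 0,
                              genome = NULL, verbose = FALSE) {
  if (!length(x)) return(x)
  s <- GenomicRanges::start(x) - left_delta
  e <- GenomicRanges::end(x) + right_delta
  s <- pmax(s, 1)
  if (!is.null(genome)) {
    genome <- as_genome(genome)
    e <- pmin(e, genome[as.character(GenomeInfoDb::seqnames(x))])
  }
  keep <- s <= e
  if (verbose && any(!keep))
    message(sum(!keep), " interval(s) collapsed and were dropped")
  out <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(x)[keep],
    ranges = IRanges::IRanges(start = s[keep], end = e[keep]),
    strand = GenomicRanges::strand(x)[keep])
  S4Vectors::mcols(out) <- S4Vectors::mcols(x)[keep, , drop = FALSE]
  GenomeInfoDb::seqinfo(out) <- GenomeInfoDb::seqinfo(x)
  out
}

#' Count queries overlapping a subject set
#'
#' A query overlaps if it shares at least one base with any subject interval;
#' half-open adjacency does not count. With `strand_specific = TRUE` only
#' same-strand subjects count, except that unstranded intervals match both
#' strands.
#'
#' @param query,subject `GRanges`.
#' @param strand_specific logical.
#' @return a list with `count` (number of queries with >= 1 overlap) and
#'   `flags` (logical per query).
#' @export
overlap_count <- function(query, subject, strand_specific = FALSE) {
  flags <- GenomicRanges::countOverlaps(
    query, subject, ignore.strand = !strand_specific) > 0L
  list(count = sum(flags), flags = flags)
}
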