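#' Flag promoters by repeat content
#'
#' Sets, for each promoter, whether it shares at least one base with an LTR
#' repeat, and the repeat class of the overlap with precedence
#' LTR > other retroposon > none. The comparison is strand-blind: chromatin
#' states carry no strand comparable with RepeatMasker strands.
#'
#' @param promoters a `GRanges` of promoters.
#' @param repeats a `GRanges` with a `repeat_class` metadata column
#'   (see [read_repeats()]).
#' @return `promoters` with `ltr_overlap` (logical) and
#'   `repeat_overlap_class` (LTR / non-LTR retroposon / none) columns added.
#' @export
classify_promoter_repeats <- function(promoters, repeats) {
  cls <- S4Vectors::mcols(repeats)$repeat_class
  if (is.null(cls)) {
    if (length(repeats)) stop("repeats lack a repeat_class column")
    cls <- character(0)
  }
  ltr <- GenomicRanges::countOverlaps(
    promoters, repeats[cls == "LTR"], ignore.strand = TRUE) > 0L
  retro <- GenomicRanges::countOverlaps(
    promoters, repeats[cls == "other retroposon"], ignore.strand = TRUE) > 0L
  S4Vectors::mcols(promoters)$ltr_overlap <- ltr
  S4Vectors::mcols(promoters)$repeat_overlap_class <-
    ifelse(ltr, "LTR", ifelse(retro, "non-LTR retroposon", "none"))
  promoters
}

#' Derive cell-line-specific Active promoters
#'
#' Active promoters of the target cell line that share no base with any
#' promoter (Active, Weak or Poised) of any other supplied line.
#'
#' @param promoters_by_line named list of promoter `GRanges`, each with a
#'   `state` metadata column.
#' @param target name of the target cell line (must be in the list).
#' @return the target line's specific Active promoters as a `GRanges`.
#' @export
derive_cellline_specific_promoters <- function(promoters_by_line, target) {
  if (!target %in% names(promoters_by_line))
    stop("target cell line '", target, "' not in promoter list")
  p <- promoters_by_line[[target]]
  active <- p[S4Vectors::mcols(p)$state == "Active"]
  others <- promoters_by_line[setdiff(names(promoters_by_line), target)]
  if (!length(others) || !length(active)) return(active)
  other_all <- suppressWarnings(
    do.call(c, unname(lapply(others, GenomicRanges::granges))))
  # cross-line sets may live on disjoint chromosomes; that is not a problem
  ov <- suppressWarnings(GenomicRanges::countOverlaps(active, other_all,
                                                      ignore.strand = TRUE))
  active[ov == 0L]
}

#' 10 kb windows on vlincRNA boundaries
#'
#' For a stranded region, one window of `2 * halfwidth` centered on its 5'
#' boundary (left border for plus-strand, right border for minus-strand).
#' For an unstranded region, windows on both boundaries.
#'
#' @param vlincs a `GRanges`.
#' @param halfwidth bases on each side of the boundary point (default 5 kb).
#' @param which `"five_prime"` (the default behaviour above) or `"both"`
#'   to force windows on both boundaries regardless of strand.
#' @return a `GRanges` of windows with a `vlinc` metadata column holding the
#'   index of the source region and a `boundary` column (left/right).
#' @export
boundary_windows <- function(vlincs, halfwidth = 5000,
                             which = c("five_prime", "both")) {
  which <- match.arg(which)
  st <- as.character(GenomicRanges::strand(vlincs))
  s <- GenomicRanges::start(vlincs)
  e <- GenomicRanges::end(vlincs)
  ch <- as.character(GenomeInfoDb::seqnames(vlincs))
  idx <- seq_along(vlincs)
  # boundary points in BED coordinates: left = start0, right = end
  left_pt <- s - 1
  right_pt <- e
  use_left <- which == "both" | st %in% c("+", "*")
  use_right <- which == "both" | st %in% c("-", "*")
  pts <- c(left_pt[use_left], right_pt[use_right])
  win <- genomic_intervals(
    chrom = c(ch[use_left], ch[use_right]),
    start = pmax(pts - halfwidth, 0), end = pts + halfwidth,
    vlinc = c(idx[use_left], idx[use_right]),
    boundary = rep(c("left", "right"), c(sum(use_left), sum(use_right))))
  win
}

#' Assign promoters to vlincRNAs via boundary windows
#'
#' A promoter is assigned to a region when it shares at least one base with
#' a 10 kb window on the region's 5' boundary (stranded regions) or on
#' either boundary (unstranded regions). Equivalent to asking whether the
#' boundary point falls inside the promoter set extended by `window_halfwidth`
#' on each side.
#'
#' @param vlincs a `GRanges`.
#' @param promoters a `GRanges` with `state` (and optionally `ltr_overlap`)
#'   metadata columns.
#' @param window_halfwidth bases (default 5 kb, i.e. 10 kb windows).
#' @return a `data.frame` with one row per vlincRNA: `vlinc` (index), `name`
#'   when available, `n_promoters`, `any_promoter`, `active`, `all_states`
#'   (logical: hit by an Active / any-state promoter) and `ltr_driven`
#'   (TRUE when any assigned promoter has `ltr_overlap`); plus an attribute
#'   `"hits"`, a two-column data.frame of (vlinc index, promoter index) pairs.
#' @export
assign_promoters_to_vlincs <- function(vlincs, promoters,
                                       window_halfwidth = 5000) {
  win <- boundary_windows(vlincs, halfwidth = window_halfwidth)
  h <- GenomicRanges::findOverlaps(win, promoters, ignore.strand = TRUE)
  vid <- S4Vectors::mcols(win)$vlinc[S4Vectors::queryHits(h)]
  pid <- S4Vectors::subjectHits(h)
  pairs <- unique(data.frame(vlinc = vid, promoter = pid))
  st <- S4Vectors::mcols(promoters)$state
  ltr <- S4Vectors::mcols(promoters)$ltr_overlap
  n <- length(vlincs)
  tab <- data.frame(
    vlinc = seq_len(n),
    n_promoters = as.integer(tabulate(pairs$vlinc, nbins = n)),
    active = seq_len(n) %in%
      pairs$vlinc[!is.null(st) & st[pairs$promoter] == "Active"],
    stringsAsFactors = FALSE)
  tab$all_states <- tab$n_promoters > 0L
  tab$any_promoter <- tab$all_states
  tab$ltr_driven <- if (is.null(ltr)) rep(NA, n) else
    seq_len(n) %in% pairs$vlinc[ltr[pairs$promoter]]
  nm <- S4Vectors::mcols(vlincs)$name
  if (!is.null(nm)) tab$name <- nm
  attr(tab, "hits") <- pairs
  tab
}

#' Stand-alone classification
#'
#' A region is stand-alone when it overlaps no gene (on either strand) and
#' both its boundaries are more than `min_distance` bases from every gene
#' boundary.
#'
#' @param vlincs,genes `GRanges`.
#' @param min_distance bases (default 50 kb); the comparison is strict
#'   ("more than"), so a gap of exactly `min_distance` fails.
#' @return logical vector per vlincRNA.
#' @export
classify_standalone <- function(vlincs, genes, min_distance = 50000) {
  if (!length(vlincs)) return(logical(0))
  if (!length(genes)) return(rep(TRUE, length(vlincs)))
  ov <- suppressWarnings(
    GenomicRanges::countOverlaps(vlincs, genes, ignore.strand = TRUE)) > 0L
  d <- suppressWarnings(
    GenomicRanges::distanceToNearest(vlincs, genes, ignore.strand = TRUE))
  near <- rep(Inf, length(vlincs))
  near[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  !ov & near > min_distance
}

#' Antisense / bidirectional classification of stranded vlincRNAs
#'
#' `antisense`: the region shares at least one base with a gene on the
#' opposite strand. `bidirectional`: not antisense, and its 5' end lies
#' within `divergent_window` bases of the 5' end of an opposite-strand gene
#' in head-to-head (divergent) orientation. Remaining regions are
#' `standalone-like` when they satisfy [classify_standalone()], else
#' `other`. Precedence: antisense > bidirectional > standalone-like.
#'
#' @param vlincs a stranded `GRanges` (unstranded input is an error).
#' @param genes a stranded `GRanges`.
#' @param divergent_window bases (default 1000).
#' @param standalone_distance passed to [classify_standalone()].
#' @return character vector per vlincRNA.
#' @export
classify_antisense_bidirectional <- function(vlincs, genes,
                                             divergent_window = 1000,
                                             standalone_distance = 50000) {
  st <- as.character(GenomicRanges::strand(vlincs))
  if (any(st == "*"))
    stop("antisense classification requires stranded vlincRNAs")
  gst <- as.character(GenomicRanges::strand(genes))
  opp <- ifelse(st == "+", "-", "+")
  anti <- vapply(seq_along(vlincs), function(i) {
    GenomicRanges::countOverlaps(vlincs[i], genes[gst == opp[i]],
                                 ignore.strand = TRUE) > 0L
  }, TRUE)
  # 5' points (BED coordinate of the boundary)
  v5 <- ifelse(st == "+", GenomicRanges::start(vlincs) - 1,
               GenomicRanges::end(vlincs))
  g5 <- ifelse(gst == "+", GenomicRanges::start(genes) - 1,
               GenomicRanges::end(genes))
  vch <- as.character(GenomeInfoDb::seqnames(vlincs))
  gch <- as.character(GenomeInfoDb::seqnames(genes))
  bidir <- vapply(seq_along(vlincs), function(i) {
    j <- which(gch == vch[i] & gst == opp[i])
    if (!length(j)) return(FALSE)
    # head-to-head: the opposite-strand gene points away from the vlinc
    ok <- if (st[i] == "+") g5[j] <= v5[i] else g5[j] >= v5[i]
    any(ok & abs(g5[j] - v5[i]) <= divergent_window)
  }, TRUE)
  standalone <- classify_standalone(vlincs, genes, standalone_distance)
  out <- rep("other", length(vlincs))
  out[standalone] <- "standalone-like"
  out[!anti & bidir] <- "bidirectional"
  out[anti] <- "antisense"
  out
}

#' Promoter-coverage profile around vlincRNA boundaries
#'
#' Sums promoter-covered bases in fixed-size bins around each region's 5'
#' boundary (both boundaries for unstranded regions). Minus-strand profiles
#' are orientation-flipped so that negative offsets always mean "upstream of
#' the 5' end"; for right (unstranded) boundaries, positive offsets point
#' away from the region.
#'
#' @param vlincs a `GRanges`.
#' @param promoters a `GRanges` (or list of `GRanges`, summed together).
#' @param bin_size bases per bin (must divide `2 * halfwidth`).
#' @param halfwidth bases on each side of the boundary (default 50 kb).
#' @return a `data.frame` with `offset` (bin midpoint relative to the
#'   boundary) and `covered_bases` (summed across regions and promoter sets).
#' @export
boundary_promoter_profile <- function(vlincs, promoters, bin_size = 1000,
                                      halfwidth = 50000) {
  if ((2 * halfwidth) %% bin_size != 0)
    stop("bin_size must divide 2 * halfwidth")
  if (methods::is(promoters, "GRanges")) promoters <- list(promoters)
  nbins <- as.integer(2 * halfwidth / bin_size)
  offsets <- -halfwidth + (seq_len(nbins) - 0.5) * bin_size
  st <- as.character(GenomicRanges::strand(vlincs))
  ch <- as.character(GenomeInfoDb::seqnames(vlincs))
  pt_left <- GenomicRanges::start(vlincs) - 1
  pt_right <- GenomicRanges::end(vlincs)
  # one row per (boundary, flipped?) evaluated
  use_left <- st %in% c("+", "*")
  use_right <- st %in% c("-", "*")
  pts <- c(pt_left[use_left], pt_right[use_right])
  chs <- c(ch[use_left], ch[use_right])
  flip <- c(rep(FALSE, sum(use_left)), rep(TRUE, sum(use_right)))
  total <- numeric(nbins)
  prom_is <- lapply(promoters, function(p) .iset_flatten(.gr_to_iset(p)))
  # per boundary: bin k covers [pt + off_k - bin/2, pt + off_k + bin/2)
  for (b in seq_along(pts)) {
    sgn <- if (flip[b]) -1 else 1
    starts <- pts[b] + sgn * (offsets - bin_size / 2)
    ends <- starts + sgn * bin_size
    bins <- cbind(start = pmin(starts, ends), end = pmax(starts, ends))
    for (p in prom_is) {
      m <- p[[chs[b]]]
      if (is.null(m) || !nrow(m)) next
      ov <- .iv_intersect(bins[order(bins[, 1L]), , drop = FALSE], m)
      if (!nrow(ov)) next
      # map covered pieces back to bins by midpoint
      mid <- (ov[, 1L] + ov[, 2L]) / 2
      k <- floor(sgn * (mid - pts[b]) / bin_size) + halfwidth / bin_size + 1
      w <- ov[, 2L] - ov[, 1L]
      ok <- k >= 1 & k <= nbins
      total <- total + as.numeric(
        tapply(w[ok], factor(k[ok], levels = seq_len(nbins)), sum,
               default = 0))
    }
  }
  data.frame(offset = offsets, covered_bases = total)
}

#' Flag vlincRNAs with reduced upstream alignability
#'
#' TRUE when the mean alignability over the span immediately upstream of the
#' 5' end (either end for unstranded regions; flagged when either qualifies)
#' falls below `threshold`. Windows are clipped at chromosome starts and
#' evaluated over the available span; positions absent from the track count
#' as alignability 0.
#'
#' @param vlincs a `GRanges`.
#' @param alignability a `GRanges` track with `score` in `[0, 1]`.
#' @param upstream_span bases (default 5 kb).
#' @param threshold fraction (default 0.5).
#' @return logical vector per vlincRNA.
#' @export
flag_low_alignability_boundary <- function(vlincs, alignability,
                                           upstream_span = 5000,
                                           threshold = 0.5) {
  alignability <- sort(alignability, ignore.strand = TRUE)
  sc <- S4Vectors::mcols(alignability)$score
  if (any(sc < 0 | sc > 1)) stop("alignability values must lie in [0, 1]")
  al <- .gr_to_iset(alignability)
  al_sc <- split(sc, as.character(GenomeInfoDb::seqnames(alignability)))
  st <- as.character(GenomicRanges::strand(vlincs))
  ch <- as.character(GenomeInfoDb::seqnames(vlincs))
  s0 <- GenomicRanges::start(vlincs) - 1
  e0 <- GenomicRanges::end(vlincs)
  mean_al <- function(chm, lo, hi) {
    lo <- max(lo, 0)
    if (hi <= lo) return(1)
    m <- al[[chm]]
    if (is.null(m)) return(0)
    ov <- .iv_intersect(cbind(start = lo, end = hi), m)
    if (!nrow(ov)) return(0)
    # recover the run score of each piece
    idx <- findInterval(ov[, 1L], m[, 1L])
    sum((ov[, 2L] - ov[, 1L]) * al_sc[[chm]][idx]) / (hi - lo)
  }
  vapply(seq_along(vlincs), function(i) {
    spans <- list()
    if (st[i] %in% c("+", "*"))
      spans <- c(spans, list(c(s0[i] - upstream_span, s0[i])))
    if (st[i] %in% c("-", "*"))
      spans <- c(spans, list(c(e0[i], e0[i] + upstream_span)))
    any(vapply(spans, function(sp)
      mean_al(ch[i], sp[1], sp[2]) < threshold, TRUE))
  }, TRUE)
}
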