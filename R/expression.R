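#' Quantification parameters
#'
#' @param depth_norm_target bases; sequencing-depth normalization target
#'   (default 2e10, i.e. "per 20 gigabases sequenced").
#' @param length_norm_target bases; region-length normalization target
#'   (default 1e6, i.e. "per megabase of region length").
#' @param max_contig_count contigs with a base count above this are dropped
#'   as artifacts (default 1e6).
#' @param total_from `"filtered-contigs"` (default): the per-sample depth
#'   denominator is the sum of its contig base counts after the artifact
#'   filter; `"all-contigs"`: before the filter.
#' @param proportional attribute only the overlapping fraction of a contig's
#'   base count to a region, instead of the full count (default `FALSE`:
#'   contigs sharing >= 1 base contribute wholesale).
#' @return a list of class `quant_params`.
#' @export
quant_params <- function(depth_norm_target = 2e10, length_norm_target = 1e6,
                         max_contig_count = 1e6,
                         total_from = c("filtered-contigs", "all-contigs"),
                         proportional = FALSE) {
  total_from <- match.arg(total_from)
  p <- list(depth_norm_target = depth_norm_target,
            length_norm_target = length_norm_target,
            max_contig_count = max_contig_count,
            total_from = total_from, proportional = proportional)
  stopifnot(p$depth_norm_target > 0, p$length_norm_target > 0,
            p$max_contig_count > 0)
  class(p) <- "quant_params"
  p
}

#' Quantify vlincRNA expression from coverage contigs
#'
#' Per (region, sample): sum the base counts of contigs sharing at least one
#' base with the region (strand-specifically when both carry strand;
#' unstranded entries match both strands), then normalize to the depth and
#' length targets:
#' `value = raw * (depth_norm_target / sample_total) * (length_norm_target / region_length)`.
#' Contigs with base counts above `max_contig_count` are removed first.
#'
#' @param contigs_by_sample named list of contig `GRanges`, each with a
#'   `base_count` metadata column.
#' @param vlincs a `GRanges` of regions.
#' @param params a [quant_params()] list.
#' @param groups optional named character vector (sample -> group label,
#'   e.g. malignant / immortalized / primary / embryonic-stem), stored as
#'   the `"groups"` attribute of the result.
#' @return a numeric matrix (regions x samples) of normalized expression,
#'   with rownames from the regions' `name` column when present.
#' @export
quantify <- function(contigs_by_sample, vlincs, params = quant_params(),
                     groups = NULL) {
  stopifnot(inherits(params, "quant_params"),
            is.list(contigs_by_sample), !is.null(names(contigs_by_sample)))
  n <- length(vlincs)
  vlen <- as.numeric(GenomicRanges::width(vlincs))
  out <- matrix(0, nrow = n, ncol = length(contigs_by_sample),
                dimnames = list(S4Vectors::mcols(vlincs)$name,
                                names(contigs_by_sample)))
  for (s in names(contigs_by_sample)) {
    ctg <- contigs_by_sample[[s]]
    bc <- S4Vectors::mcols(ctg)$base_count
    if (is.null(bc)) stop("contigs for sample '", s, "' lack base_count")
    total_all <- sum(bc)
    keep <- bc <= params$max_contig_count
    ctg <- ctg[keep]; bc <- bc[keep]
    total <- if (params$total_from == "filtered-contigs") sum(bc) else
      total_all
    if (total <= 0) stop("sample '", s, "' has zero total sequenced bases")
    h <- GenomicRanges::findOverlaps(ctg, vlincs, ignore.strand = FALSE)
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    contrib <- bc[qi]
    if (params$proportional) {
      ow <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::granges(ctg)[qi],
        GenomicRanges::granges(vlincs)[si], ignore.strand = TRUE))
      contrib <- contrib * ow / GenomicRanges::width(ctg)[qi]
    }
    raw <- as.numeric(tapply(contrib, factor(si, levels = seq_len(n)), sum,
                             default = 0))
    out[, s] <- raw * (params$depth_norm_target / total) *
      (params$length_norm_target / vlen)
  }
  if (!is.null(groups)) attr(out, "groups") <- groups[colnames(out)]
  out
}

#' Replace zeros by the dataset minimum non-zero value
#'
#' @param mat an expression matrix.
#' @return the matrix with every zero replaced by `min(mat[mat > 0])`.
#' @export
replace_zeros <- function(mat) {
  pos <- mat > 0
  if (!any(pos)) stop("matrix has no non-zero values")
  mat[!pos] <- min(mat[pos])
  mat
}

#' Tissue-specificity index
#'
#' Per region: the ratio of the highest expression across samples to the
#' second highest, after dataset-level zero replacement.
#'
#' @param mat an expression matrix (regions x samples, >= 2 samples).
#' @return numeric vector of indices (one per row).
#' @export
tissue_specificity_index <- function(mat) {
  if (ncol(mat) < 2L) stop("need at least 2 samples")
  mat <- replace_zeros(mat)
  apply(mat, 1L, function(v) {
    v <- sort(v, decreasing = TRUE)
    v[1L] / v[2L]
  })
}

#' Cell-line specificity index
#'
#' Per region: expression in the target sample divided by the maximum over
#' all other samples, after dataset-level zero replacement.
#'
#' @param mat an expression matrix.
#' @param target column name of the target sample.
#' @return numeric vector of indices (one per row).
#' @export
cellline_specificity_index <- function(mat, target) {
  if (!target %in% colnames(mat))
    stop("target sample '", target, "' not in matrix")
  if (ncol(mat) < 2L) stop("need at least one non-target sample")
  mat <- replace_zeros(mat)
  mat[, target] / apply(mat[, setdiff(colnames(mat), target), drop = FALSE],
                        1L, max)
}

#' Stratified expression-ratio summary
#'
#' For each region, computes (after zero replacement) the ratios of the
#' maximal malignant, the immortalized and the embryonic-stem expression to
#' the maximal primary expression, then averages each ratio within the
#' LTR-driven and non-LTR strata.
#'
#' @param mat an expression matrix whose columns carry group labels via
#'   `groups` (or the matrix's `"groups"` attribute): malignant,
#'   immortalized, primary, embryonic-stem (other labels are ignored).
#' @param ltr_driven logical vector per region.
#' @param groups optional named group vector overriding the attribute.
#' @param average `"arithmetic"` (default) or `"geometric"`.
#' @return a data.frame with rows `maxCancer/maxPrimary`,
#'   `immortalized/maxPrimary`, `ESC/maxPrimary` and columns `LTR`,
#'   `nonLTR`; a stratum with no regions is reported as `NA`.
#' @export
group_ratio_summary <- function(mat, ltr_driven, groups = NULL,
                                average = c("arithmetic", "geometric")) {
  average <- match.arg(average)
  if (is.null(groups)) groups <- attr(mat, "groups")
  if (is.null(groups)) stop("no group labels supplied")
  groups <- groups[colnames(mat)]
  stopifnot(length(ltr_driven) == nrow(mat))
  mat <- replace_zeros(mat)
  colmax <- function(g) {
    cols <- which(groups == g)
    if (!length(cols)) return(rep(NA_real_, nrow(mat)))
    apply(mat[, cols, drop = FALSE], 1L, max)
  }
  ratios <- cbind(
    `maxCancer/maxPrimary` = colmax("malignant") / colmax("primary"),
    `immortalized/maxPrimary` = colmax("immortalized") / colmax("primary"),
    `ESC/maxPrimary` = colmax("embryonic-stem") / colmax("primary"))
  avg <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    if (average == "arithmetic") mean(v) else exp(mean(log(v)))
  }
  out <- data.frame(
    LTR = apply(ratios[ltr_driven, , drop = FALSE], 2L, avg),
    nonLTR = apply(ratios[!ltr_driven, , drop = FALSE], 2L, avg))
  rownames(out) <- colnames(ratios)
  out
}

#' Intron/exon density ratio per transcript
#'
#' Per transcript: mean per-base density over introns divided by mean
#' per-base density over exons (positions absent from the track count as
#' zero density). Transcripts with no introns or zero exonic density are
#' excluded from the reported median.
#'
#' @param track a `GRanges` density track with a `score` column.
#' @param transcripts a `GRangesList` of exons per transcript.
#' @return a list with `ratio` (per transcript, `NA` where excluded) and
#'   `median` (over included transcripts).
#' @export
intron_exon_ratio <- function(track, transcripts) {
  if (!length(transcripts)) stop("empty transcript set")
  track <- sort(track, ignore.strand = TRUE)
  tr_is <- .gr_to_iset(track)
  tr_sc <- split(S4Vectors::mcols(track)$score,
                 as.character(GenomeInfoDb::seqnames(track)))
  mean_density <- function(m, ch) {
    # m: interval matrix on one chromosome; returns total signal and bases
    run <- tr_is[[ch]]
    if (is.null(run) || !nrow(m)) return(c(0, .iv_len(m)))
    ov <- .iv_intersect(.iv_flatten(m), run)
    if (!nrow(ov)) return(c(0, .iv_len(m)))
    idx <- findInterval(ov[, 1L], run[, 1L])
    c(sum((ov[, 2L] - ov[, 1L]) * tr_sc[[ch]][idx]), .iv_len(m))
  }
  ratio <- vapply(seq_along(transcripts), function(i) {
    ex <- transcripts[[i]]
    if (!length(ex)) return(NA_real_)
    ch <- as.character(GenomeInfoDb::seqnames(ex))[1L]
    ex_m <- .iv_flatten(.gr_to_iset(ex)[[ch]])
    span <- cbind(start = min(ex_m[, 1L]), end = max(ex_m[, 2L]))
    in_m <- .iv_subtract(span, ex_m)
    if (!nrow(in_m)) return(NA_real_)        # no introns
    exd <- mean_density(ex_m, ch)
    ind <- mean_density(in_m, ch)
    if (exd[1L] <= 0) return(NA_real_)       # zero exonic density
    (ind[1L] / ind[2L]) / (exd[1L] / exd[2L])
  }, 1)
  list(ratio = ratio, median = stats::median(ratio, na.rm = TRUE))
}

#' Read a BED12 file into per-transcript exon structures
#'
#' @param path file path.
#' @param genome optional genome for validation.
#' @return a `GRangesList` of exons, one element per transcript, named by
#'   the BED name column.
#' @export
read_bed12 <- function(path, genome = NULL) {
  d <- .read_tsv(path)
  if (ncol(d) < 12L) stop("BED12 requires 12 columns")
  out <- lapply(seq_len(nrow(d)), function(i) {
    sizes <- as.numeric(strsplit(as.character(d[i, 11L]), ",")[[1L]])
    starts <- as.numeric(strsplit(as.character(d[i, 12L]), ",")[[1L]])
    genomic_intervals(
      chrom = rep(as.character(d[i, 1L]), length(sizes)),
      start = as.numeric(d[i, 2L]) + starts,
      end = as.numeric(d[i, 2L]) + starts + sizes,
      strand = if (d[i, 6L] %in% c("+", "-")) as.character(d[i, 6L]) else "*",
      genome = genome)
  })
  names(out) <- as.character(d[[4L]])
  GenomicRanges::GRangesList(out)
}

#' Cell-line-specific vlincRNAs
#'
#' A region counts as specific to the target sample when it is expressed
#' there and its cell-line specificity index (target over the maximum of
#' all other samples, after zero replacement) reaches `cutoff`.
#'
#' @param mat an expression matrix (regions x samples).
#' @param target column name of the target sample.
#' @param cutoff minimum specificity index (default 5).
#' @return logical vector per region.
#' @export
cellline_specific_vlincs <- function(mat, target, cutoff = 5) {
  idx <- cellline_specificity_index(mat, target)
  unname(mat[, target] > 0 & idx >= cutoff)
}
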