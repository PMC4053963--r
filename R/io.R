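# Readers and writers for the plain-text formats the pipeline consumes.
# All BED-family input is 0-based half-open unless zero_based = FALSE
# (browser-style 1-based closed), and converts to GRanges on ingest.

.read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                    comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Read a chrom.sizes file
#'
#' Two-column TSV: chromosome name, length in bases.
#'
#' @param path file path.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  d <- .read_tsv(path)
  as_genome(stats::setNames(as.numeric(d[[2L]]), d[[1L]]))
}

#' Write a chrom.sizes file
#' @param genome named vector of chromosome lengths.
#' @param path file path.
#' @export
write_chrom_sizes <- function(genome, path) {
  genome <- as_genome(genome)
  utils::write.table(
    data.frame(names(genome), format(genome, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Read a BED3/BED6 file
#'
#' Columns beyond the first six are ignored; the name and score columns are
#' kept as metadata when present.
#'
#' @param path file path.
#' @param zero_based is the input BED-style 0-based half-open?
#' @param genome optional genome for validation.
#' @return a `GRanges` with optional `name`/`score` metadata columns.
#' @export
read_bed <- function(path, zero_based = TRUE, genome = NULL) {
  d <- .read_tsv(path)
  args <- list(chrom = as.character(d[[1L]]), start = as.numeric(d[[2L]]),
               end = as.numeric(d[[3L]]), zero_based = zero_based,
               genome = genome)
  if (ncol(d) >= 4L) args$name <- as.character(d[[4L]])
  if (ncol(d) >= 5L) args$score <- as.numeric(d[[5L]])
  if (ncol(d) >= 6L) args$strand <- ifelse(d[[6L]] %in% c("+", "-"),
                                           as.character(d[[6L]]), "*")
  do.call(genomic_intervals, args)
}

#' Write intervals as BED6 (0-based half-open)
#'
#' Output is bit-stable for a fixed input ordering: coordinates are written
#' as plain integers and no reordering is performed.
#'
#' @param gr a `GRanges`; a `name` metadata column is used when present.
#' @param path file path.
#' @param score optional numeric vector for column 5 (default 0, or the
#'   `score` metadata column when present).
#' @export
write_bed <- function(gr, path, score = NULL) {
  mc <- S4Vectors::mcols(gr)
  name <- if ("name" %in% names(mc)) as.character(mc$name)
          else sprintf("region_%d", seq_along(gr))
  if (is.null(score))
    score <- if ("score" %in% names(mc)) mc$score else rep(0, length(gr))
  d <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = format(GenomicRanges::start(gr) - 1, scientific = FALSE, trim = TRUE),
    end = format(GenomicRanges::end(gr), scientific = FALSE, trim = TRUE),
    name = name,
    score = score,
    strand = as.character(GenomicRanges::strand(gr)))
  d$strand[d$strand == "*"] <- "."
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read an RNA-seq coverage contig BED file
#'
#' ENCODE/CSHL contig dialect: BED with at least 9 columns where column 9
#' holds the total number of bases covered by reads within the contig and
#' column 6 the strand.
#'
#' @inheritParams read_bed
#' @return a `GRanges` with a `base_count` metadata column.
#' @export
read_contigs <- function(path, zero_based = TRUE, genome = NULL) {
  d <- .read_tsv(path)
  if (ncol(d) < 9L)
    stop("contig BED must have >= 9 columns (column 9 = base count)")
  bc <- as.numeric(d[[9L]])
  if (any(is.na(bc)) || any(bc < 0))
    stop("column 9 (base count) must be non-negative numbers")
  genomic_intervals(
    chrom = as.character(d[[1L]]), start = as.numeric(d[[2L]]),
    end = as.numeric(d[[3L]]),
    strand = ifelse(d[[6L]] %in% c("+", "-"), as.character(d[[6L]]), "*"),
    zero_based = zero_based, genome = genome,
    name = as.character(d[[4L]]), base_count = bc)
}

#' Write contigs as BED9 with column 9 = base count
#' @param contigs a `GRanges` with a `base_count` metadata column.
#' @param path file path.
#' @export
write_contigs <- function(contigs, path) {
  bc <- S4Vectors::mcols(contigs)$base_count
  stopifnot(!is.null(bc))
  st <- as.character(GenomicRanges::strand(contigs))
  st[st == "*"] <- "."
  d <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(contigs)),
    start = format(GenomicRanges::start(contigs) - 1, scientific = FALSE,
                   trim = TRUE),
    end = format(GenomicRanges::end(contigs), scientific = FALSE, trim = TRUE),
    name = sprintf("contig_%d", seq_along(contigs)),
    score = 0, strand = st, thickStart = 0, thickEnd = 0,
    base_count = format(bc, scientific = FALSE, trim = TRUE))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a BedGraph density track
#'
#' Four columns: chrom, start (0-based), end, value. Runs must not overlap.
#'
#' @inheritParams read_bed
#' @return a `GRanges` with a `score` metadata column (per-base density).
#' @export
read_bedgraph <- function(path, genome = NULL) {
  d <- .read_tsv(path)
  gr <- genomic_intervals(
    chrom = as.character(d[[1L]]), start = as.numeric(d[[2L]]),
    end = as.numeric(d[[3L]]), genome = genome,
    score = as.numeric(d[[4L]]))
  if (any(S4Vectors::mcols(gr)$score < 0))
    stop("densities must be non-negative")
  gr <- sort(gr, ignore.strand = TRUE)
  if (length(gr) > 1L) {
    same <- as.character(GenomeInfoDb::seqnames(gr))[-1L] ==
      as.character(GenomeInfoDb::seqnames(gr))[-length(gr)]
    if (any(same & GenomicRanges::start(gr)[-1L] <=
            GenomicRanges::end(gr)[-length(gr)]))
      stop("BedGraph runs overlap")
  }
  gr
}

#' Write a density track as BedGraph
#' @param track a `GRanges` with a `score` column.
#' @param path file path.
#' @export
write_bedgraph <- function(track, path) {
  d <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(track)),
    start = format(GenomicRanges::start(track) - 1, scientific = FALSE,
                   trim = TRUE),
    end = format(GenomicRanges::end(track), scientific = FALSE, trim = TRUE),
    value = S4Vectors::mcols(track)$score)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read chromatin-state promoters for one cell line
#'
#' BED whose name column carries the state label (Active, Weak or Poised).
#'
#' @inheritParams read_bed
#' @param cell_line sample identifier attached to every promoter.
#' @return a `GRanges` with `state` and `cell_line` metadata columns.
#' @export
read_promoters <- function(path, cell_line, zero_based = TRUE, genome = NULL) {
  gr <- read_bed(path, zero_based = zero_based, genome = genome)
  state <- S4Vectors::mcols(gr)$name
  if (is.null(state) || !all(state %in% c("Active", "Weak", "Poised")))
    stop("promoter BED name column must be one of Active/Weak/Poised")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(state = state,
                                               cell_line = cell_line)
  GenomicRanges::strand(gr) <- "*"
  gr
}

.repeat_class_from_family <- function(cls) {
  cls <- as.character(cls)
  out <- rep("other", length(cls))
  out[grepl("^LTR|^ERV", cls, ignore.case = TRUE)] <- "LTR"
  out[grepl("^(SINE|LINE|Retroposon|SVA)", cls, ignore.case = TRUE)] <-
    "other retroposon"
  out
}

#' Read repeat annotations (RepeatMasker .out or BED6)
#'
#' For `.out` input the standard RepeatMasker column layout is used (1-based
#' begin/end, strand `C` meaning minus, repeat name and class/family).
#' For BED6 input the name column must be `family|class` or just the family
#' name, in which case the class is inferred from the family prefix.
#'
#' @param path file path.
#' @param format `"auto"`, `"repeatmasker"` or `"bed"`.
#' @param genome optional genome for validation.
#' @return a `GRanges` with `family` and `repeat_class` metadata columns;
#'   `repeat_class` is one of LTR / other retroposon / other.
#' @export
read_repeats <- function(path, format = c("auto", "repeatmasker", "bed"),
                         genome = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("\t", first)) "bed" else "repeatmasker"
  }
  if (format == "repeatmasker") {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*$|^\\s*(SW|score)", lines)]
    f <- strsplit(trimws(lines), "\\s+")
    keep <- lengths(f) >= 11L
    f <- f[keep]
    get <- function(i) vapply(f, `[[`, "", i)
    gr <- genomic_intervals(
      chrom = get(5L), start = as.numeric(get(6L)), end = as.numeric(get(7L)),
      strand = ifelse(get(9L) == "C", "-", "+"),
      zero_based = FALSE, genome = genome,
      family = get(10L),
      repeat_class = .repeat_class_from_family(get(11L)))
    return(gr)
  }
  gr <- read_bed(path, genome = genome)
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) stop("repeat BED requires a name column with the family")
  parts <- strsplit(nm, "|", fixed = TRUE)
  family <- vapply(parts, `[[`, "", 1L)
  cls <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else p[[1L]], "")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    family = family, repeat_class = .repeat_class_from_family(cls))
  gr
}
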