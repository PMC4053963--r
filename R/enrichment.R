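#' Exact binomial upper tail
#'
#' P(X >= n) for X ~ Binomial(N, q), computed through the regularized
#' incomplete beta function in log space, so tails far below 1e-300 remain
#' finite on the log10 scale.
#'
#' @param N number of trials.
#' @param q success probability in `[0, 1]`.
#' @param n threshold (0 <= n <= N).
#' @param log10 return log10 of the tail probability instead.
#' @return the tail probability (or its log10).
#' @export
binomial_upper_tail <- function(N, q, n, log10 = FALSE) {
  if (length(N) != 1L || length(q) != 1L || length(n) != 1L ||
      is.na(N) || is.na(q) || is.na(n) ||
      q < 0 || q > 1 || n < 0 || n > N || N < 0)
    stop("invalid binomial tail arguments: need 0 <= q <= 1, 0 <= n <= N")
  if (n <= 0) return(if (log10) 0 else 1)
  lp <- stats::pbinom(n - 1, size = N, prob = q, lower.tail = FALSE,
                      log.p = TRUE)
  if (log10) lp / log(10) else exp(lp)
}

#' Build the enrichment anti-space
#'
#' The genomic regions excluded from the null: gene bodies plus blacklist
#' (and, in `"with-short-gaps"` mode, inter-gene gaps shorter than
#' `short_gap` bases), minus any bases overlapping the tested regions.
#'
#' @param genes a `GRanges`; in `"stranded-same"` mode only genes on
#'   `strand` (or unstranded genes) are used, otherwise both strands.
#' @param blacklist a `GRanges` (may be empty).
#' @param tested_vlincs a `GRanges`; bases overlapping these are removed.
#' @param mode `"stranded-same"`, `"either-strand"` or `"with-short-gaps"`.
#' @param strand for `"stranded-same"`: the strand of interest.
#' @param short_gap bases; gaps between genes shorter than this are absorbed
#'   in `"with-short-gaps"` mode (default 50 kb).
#' @return a flattened unstranded `GRanges`.
#' @export
build_anti_space <- function(genes, blacklist = GenomicRanges::GRanges(),
                             tested_vlincs = GenomicRanges::GRanges(),
                             mode = c("stranded-same", "either-strand",
                                      "with-short-gaps"),
                             strand = "+", short_gap = 50000) {
  mode <- match.arg(mode)
  gs <- as.character(GenomicRanges::strand(genes))
  g <- if (mode == "stranded-same") genes[gs %in% c(strand, "*")] else genes
  base <- .iset_flatten(.gr_to_iset(g))
  if (mode == "with-short-gaps" && length(g)) {
    base <- .iset_map(base, function(m) {
      if (nrow(m) < 2L) return(m)
      .iv_flatten(m, gap = short_gap - 1, sorted = TRUE)
    })
  }
  if (length(blacklist)) {
    bl <- .gr_to_iset(blacklist)
    base <- .iset_flatten(.iset_binop(base, bl, function(a, b)
      rbind(a, b)))
  }
  if (length(tested_vlincs))
    base <- .iset_subtract(base, .gr_to_iset(tested_vlincs))
  .iset_to_gr(base)
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

.enrichment_result <- function(method, N, n, p_i, m = sum(p_i),
                               extra = list()) {
  q <- if (N > 0) .clamp01(m / N) else 0
  res <- list(
    method = method, N = N, n_observed = n, m_expected = m,
    success_probs = p_i,
    fold = if (m > 0) n / m else if (n > 0) Inf else NA_real_,
    p_value = binomial_upper_tail(N, q, n),
    log10_p = binomial_upper_tail(N, q, n, log10 = TRUE))
  res <- c(res, extra)
  class(res) <- "vlinc_enrichment"
  res
}

#' @export
print.vlinc_enrichment <- function(x, ...) {
  cat("Genomic overlap enrichment (", x$method, ")\n", sep = "")
  cat(sprintf("  trials N = %d, observed n = %g, expected m = %.3f\n",
              x$N, x$n_observed, x$m_expected))
  cat(sprintf("  fold over chance = %.3g\n", x$fold))
  if (x$p_value >= 1e-4)
    cat(sprintf("  P(X >= n) = %.4g\n", x$p_value))
  else
    cat(sprintf("  P(X >= n) = 10^%.2f\n", x$log10_p))
  invisible(x)
}

#' @export
format.vlinc_enrichment <- function(x, ...) {
  sprintf("%s: N=%d n=%g m=%.3f fold=%.3g log10p=%.2f",
          x$method, x$N, x$n_observed, x$m_expected, x$fold, x$log10_p)
}

#' As a one-row data.frame (for result tables)
#' @param x a `vlinc_enrichment` result.
#' @param ... unused.
#' @export
as.data.frame.vlinc_enrichment <- function(x, ...) {
  data.frame(method = x$method, N = x$N, n = x$n_observed,
             m = x$m_expected, fold = x$fold, p_value = x$p_value,
             log10_p = x$log10_p)
}

# Shared machinery: per-element eligible space and promoter-occupied space.
#
# For element i the anti-space intervals are extended (upstream side by
# `left_ext[i]`, downstream by `right_ext[i]`), the eligible space is the
# complement of the extension within the genome, and the occupied space is
# its intersection with the (already extended) subject set.
.space_probs <- function(anti, genome, left_ext, right_ext, subject_ext, V) {
  G <- sum(genome)
  n_el <- length(left_ext)
  p <- numeric(n_el)
  anti <- lapply(anti, .iv_flatten)          # sorted, flattened per chrom
  for (i in seq_len(n_el)) {
    space_len <- G
    occ <- 0
    for (ch in names(genome)) {
      m <- anti[[ch]]
      L <- genome[[ch]]
      if (!is.null(m) && nrow(m)) {
        ext <- .iv_adjust(m, left_ext[i], right_ext[i], L)
        ext <- .iv_flatten(ext, sorted = TRUE)
        ext <- .iv_intersect(ext, cbind(start = 0, end = L))
        space_len <- space_len - .iv_len(ext)
        sp <- .iv_complement(ext, L)
      } else {
        sp <- cbind(start = 0, end = L)
      }
      sub <- subject_ext[[ch]]
      if (!is.null(sub) && nrow(sub))
        occ <- occ + .iv_intersect_len(sp, sub)
    }
    denom <- space_len - V
    if (denom <= 0)
      stop("degenerate space: |Space_i| - V <= 0 for element ", i)
    p[i] <- .clamp01(occ / denom)
  }
  p
}

.check_genome_vlincs <- function(vlincs, genome) {
  genome <- as_genome(genome)
  miss <- setdiff(as.character(GenomeInfoDb::seqnames(vlincs)), names(genome))
  if (length(miss))
    stop("vlincRNAs on chromosomes absent from genome: ",
         paste(miss, collapse = ", "))
  genome
}

#' Promoter overlap enrichment for stranded vlincRNAs (procedure I)
#'
#' Observed n = number of 10 kb 5'-boundary windows overlapping promoters.
#' For each region i, the anti-space (same-strand genes plus blacklist,
#' minus tested regions) has the 5'-side boundary of every interval extended
#' by the region's length L_i; the eligible space is the complement; the
#' per-region success probability is the fraction of that space covered by
#' promoters extended 5 kb per side, with the total tested length V removed
#' from the denominator (an upper-bound correction). The p-value is the
#' binomial tail P(X >= n) with X ~ B(N, m/N), m = sum of the p_i.
#'
#' @param vlincs a stranded `GRanges` (unstranded input is an error).
#' @param promoters a `GRanges`.
#' @param genes,blacklist `GRanges` used to build the anti-space.
#' @param genome named vector of chromosome lengths.
#' @param window_halfwidth bases (default 5 kb): boundary-window halfwidth
#'   and promoter extension.
#' @param v_correction subtract V (total tested length) from the space
#'   denominator; disabling it gives the anti-conservative variant.
#' @return a `vlinc_enrichment` result.
#' @export
test_promoter_overlap_stranded <- function(vlincs, promoters, genes,
                                           blacklist =
                                             GenomicRanges::GRanges(),
                                           genome,
                                           window_halfwidth = 5000,
                                           v_correction = TRUE) {
  st <- as.character(GenomicRanges::strand(vlincs))
  if (any(st == "*")) stop("procedure I requires stranded vlincRNAs")
  genome <- .check_genome_vlincs(vlincs, genome)
  N <- length(vlincs)
  V <- if (v_correction) union_length(vlincs) else 0
  win <- boundary_windows(vlincs, halfwidth = window_halfwidth)
  n <- overlap_count(win, promoters)$count
  prom_ext <- .iset_flatten(.gr_to_iset(
    adjust_boundaries(promoters, window_halfwidth, window_halfwidth,
                      genome = genome)))
  L_i <- as.numeric(GenomicRanges::width(vlincs))
  p_i <- numeric(N)
  for (s in c("+", "-")) {
    idx <- which(st == s)
    if (!length(idx)) next
    anti <- .gr_to_iset(build_anti_space(
      genes, blacklist, vlincs[st == s], mode = "stranded-same", strand = s))
    # top strand: extend the left (upstream) boundary; bottom: the right
    p_i[idx] <- .space_probs(
      anti, genome,
      left_ext = if (s == "+") L_i[idx] else rep(0, length(idx)),
      right_ext = if (s == "-") L_i[idx] else rep(0, length(idx)),
      subject_ext = prom_ext, V = V)
  }
  .enrichment_result("promoter overlap, stranded", N, n, p_i)
}

#' Promoter overlap enrichment for unstranded vlincRNAs (procedure II)
#'
#' As procedure I, but with two 10 kb windows per region (one per boundary);
#' n counts regions with at least one window overlapping a promoter, and the
#' per-region probability combines the two orientations as
#' `p_i = 1 - (1 - p_i+)(1 - p_i-)`, with the anti-space built from genes on
#' either strand.
#'
#' @inheritParams test_promoter_overlap_stranded
#' @return a `vlinc_enrichment` result.
#' @export
test_promoter_overlap_unstranded <- function(vlincs, promoters, genes,
                                             blacklist =
                                               GenomicRanges::GRanges(),
                                             genome,
                                             window_halfwidth = 5000,
                                             v_correction = TRUE) {
  genome <- .check_genome_vlincs(vlincs, genome)
  N <- length(vlincs)
  V <- if (v_correction) union_length(vlincs) else 0
  win <- boundary_windows(vlincs, halfwidth = window_halfwidth,
                          which = "both")
  hit <- overlap_count(win, promoters)$flags
  n <- length(unique(S4Vectors::mcols(win)$vlinc[hit]))
  prom_ext <- .iset_flatten(.gr_to_iset(
    adjust_boundaries(promoters, window_halfwidth, window_halfwidth,
                      genome = genome)))
  anti <- .gr_to_iset(build_anti_space(genes, blacklist, vlincs,
                                       mode = "either-strand"))
  L_i <- as.numeric(GenomicRanges::width(vlincs))
  p_plus <- .space_probs(anti, genome, left_ext = L_i,
                         right_ext = rep(0, N), subject_ext = prom_ext, V = V)
  p_minus <- .space_probs(anti, genome, left_ext = rep(0, N),
                          right_ext = L_i, subject_ext = prom_ext, V = V)
  p_i <- 1 - (1 - p_plus) * (1 - p_minus)
  .enrichment_result("promoter overlap, unstranded", N, n, p_i,
                     extra = list(p_plus = p_plus, p_minus = p_minus))
}

#' Overlap enrichment between two interval sets (procedure III)
#'
#' n = elements of `set1` sharing at least one base with `set2` (strand-
#' blind). For element i of length L_i, anti-space intervals are extended by
#' L_i/2 on both sides; the occupied space is the eligible space covered by
#' `set2` elements extended by L_i/2 on both sides. Applicable to any subject
#' intervals, including single-base SNP positions.
#'
#' @param set1 a `GRanges` (the tested regions; must be non-empty).
#' @param set2 a `GRanges` (regions or SNP positions).
#' @inheritParams test_promoter_overlap_stranded
#' @return a `vlinc_enrichment` result.
#' @export
test_set_overlap <- function(set1, set2, genes,
                             blacklist = GenomicRanges::GRanges(), genome,
                             v_correction = TRUE) {
  if (!length(set1)) stop("set1 must be non-empty")
  genome <- .check_genome_vlincs(set1, genome)
  N <- length(set1)
  V <- if (v_correction) union_length(set1) else 0
  n <- overlap_count(set1, set2)$count
  anti <- .gr_to_iset(build_anti_space(genes, blacklist, set1,
                                       mode = "either-strand"))
  set2_is <- .gr_to_iset(set2)
  L_i <- as.numeric(GenomicRanges::width(set1))
  G <- sum(genome)
  p_i <- numeric(N)
  anti <- lapply(anti, .iv_flatten)
  for (i in seq_len(N)) {
    h <- L_i[i] / 2
    space_len <- G
    occ <- 0
    for (ch in names(genome)) {
      L <- genome[[ch]]
      m <- anti[[ch]]
      if (!is.null(m) && nrow(m)) {
        ext <- .iv_flatten(.iv_adjust(m, h, h, L), sorted = TRUE)
        space_len <- space_len - .iv_len(ext)
        sp <- .iv_complement(ext, L)
      } else {
        sp <- cbind(start = 0, end = L)
      }
      s2 <- set2_is[[ch]]
      if (!is.null(s2) && nrow(s2)) {
        s2e <- .iv_flatten(.iv_adjust(s2, h, h, L))
        occ <- occ + .iv_intersect_len(sp, s2e)
      }
    }
    denom <- space_len - V
    if (denom <= 0)
      stop("degenerate space: |Space_i| - V <= 0 for element ", i)
    p_i[i] <- .clamp01(occ / denom)
  }
  .enrichment_result("set overlap", N, n, p_i)
}

#' Collapse same-family LTR elements into promoter-scoped clusters
#'
#' LTRs of one family are collapsed into a cluster when they lie in the same
#' promoter, or in promoters assigned to the same vlincRNA. An LTR
#' overlapping several promoters is first split into its per-promoter
#' fragments. LTRs outside all promoters form singleton clusters. Different
#' families are never co-clustered (the function takes one family at a
#' time).
#'
#' @param ltrs a `GRanges` of repeats of a single family.
#' @param promoters a `GRanges`.
#' @param promoter_vlinc optional vector (length of `promoters`) giving the
#'   vlincRNA each promoter is assigned to (`NA` = none).
#' @return a `GRanges` of LTR fragments with `cluster` (cluster key) and
#'   `ltr` (source element index) metadata columns.
#' @export
cluster_ltr_elements <- function(ltrs, promoters, promoter_vlinc = NULL) {
  fam <- S4Vectors::mcols(ltrs)$family
  if (!is.null(fam) && length(unique(fam)) > 1L)
    stop("cluster_ltr_elements takes a single repeat family at a time")
  if (is.null(promoter_vlinc))
    promoter_vlinc <- rep(NA_character_, length(promoters))
  promoter_vlinc <- as.character(promoter_vlinc)
  h <- GenomicRanges::findOverlaps(ltrs, promoters, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(h)
  si <- S4Vectors::subjectHits(h)
  frags_in <- if (length(h)) {
    fr <- IRanges::pintersect(GenomicRanges::granges(ltrs)[qi],
                              GenomicRanges::granges(promoters)[si],
                              ignore.strand = TRUE)
    GenomicRanges::strand(fr) <- GenomicRanges::strand(ltrs)[qi]
    key <- ifelse(is.na(promoter_vlinc[si]),
                  paste0("promoter:", si),
                  paste0("vlinc:", promoter_vlinc[si]))
    S4Vectors::mcols(fr) <- S4Vectors::DataFrame(cluster = key, ltr = qi)
    fr
  } else GenomicRanges::GRanges(cluster = character(0), ltr = integer(0))
  out_idx <- setdiff(seq_along(ltrs), unique(qi))
  frags_out <- GenomicRanges::granges(ltrs)[out_idx]
  S4Vectors::mcols(frags_out) <- S4Vectors::DataFrame(
    cluster = sprintf("singleton:%d", out_idx), ltr = out_idx)
  out <- c(frags_in, frags_out)
  S4Vectors::mcols(out)$family <-
    if (is.null(fam)) NA_character_ else fam[S4Vectors::mcols(out)$ltr]
  out
}

# promoters overlapping the 10 kb windows centered on 5' edges of vlincs
.vlinc_promoters <- function(vlincs, promoters, halfwidth = 5000) {
  if (!length(vlincs)) return(promoters[0])
  win <- boundary_windows(vlincs, halfwidth = halfwidth)
  promoters[GenomicRanges::countOverlaps(promoters, win,
                                         ignore.strand = TRUE) > 0L]
}

.ltr_one_side <- function(ltrs, vlincs, promoters, genes, genome,
                          all_vlincs, shrink, halfwidth, gene_strand) {
  gs <- as.character(GenomicRanges::strand(genes))
  g <- if (is.null(gene_strand)) genes else genes[gs %in% c(gene_strand, "*")]
  av <- if (is.null(gene_strand)) all_vlincs else {
    vs <- as.character(GenomicRanges::strand(all_vlincs))
    all_vlincs[vs %in% c(gene_strand, "*")]
  }
  anti <- build_anti_space(g, tested_vlincs = av, mode = "with-short-gaps")
  anti_shrunk <- adjust_boundaries(anti, -shrink, -shrink, genome = genome)
  space <- .iset_to_gr(.iset_complement(.gr_to_iset(anti_shrunk),
                                        as_genome(genome)))
  space_proms <- promoters[GenomicRanges::countOverlaps(
    promoters, space, ignore.strand = TRUE) > 0L]
  vlinc_proms <- .vlinc_promoters(vlincs, promoters, halfwidth)
  clusters <- cluster_ltr_elements(ltrs, promoters)
  ckey <- S4Vectors::mcols(clusters)$cluster
  hit_v <- GenomicRanges::countOverlaps(clusters, vlinc_proms,
                                        ignore.strand = TRUE) > 0L
  hit_s <- GenomicRanges::countOverlaps(clusters, space_proms,
                                        ignore.strand = TRUE) > 0L
  n <- length(unique(ckey[hit_v]))
  N <- length(unique(ckey[hit_s]))
  sp_len <- union_length(space_proms)
  if (sp_len <= 0) stop("degenerate space: |Space_promoters| = 0")
  p <- .clamp01(union_length(vlinc_proms) / sp_len)
  list(n = n, N = N, p = p)
}

#' LTR-family enrichment in vlincRNA promoters (procedures IV and V)
#'
#' vlincRNA promoters are the supplied promoters (join of Active, Weak and
#' Poised) that overlap 10 kb windows centered on 5' edges of the regions.
#' Same-family LTRs are collapsed into promoter-scoped clusters. The success
#' probability is the length ratio of vlincRNA promoters to the promoters
#' overlapping the eligible space (genome minus gene-plus-short-gap
#' anti-space shrunk 5 kb per boundary, the anti-space itself excluding
#' regions from `all_vlincs`). Unstranded: P(X >= n) with X ~ B(N, p).
#' Stranded: n, N and p are computed per strand relative to the vlincRNA
#' strand and the reported tail P(X >= n+ + n-) with
#' X ~ B(N+ + N-, max(p+, p-)) is an explicit upper bound.
#'
#' @param ltrs a `GRanges` of one repeat family.
#' @param vlincs the cell line's vlincRNAs (stranded for `stranded = TRUE`).
#' @param promoters the cell line's promoters (all states).
#' @param genes a `GRanges` of gene spans.
#' @param genome named vector of chromosome lengths.
#' @param all_vlincs regions (across all cell lines) removed from the
#'   anti-space; defaults to `vlincs`.
#' @param stranded use the per-strand upper-bound procedure.
#' @param shrink bases the anti-space boundaries are shrunk by (default 5 kb).
#' @param window_halfwidth bases (default 5 kb) for the 5'-edge windows.
#' @return a `vlinc_enrichment` result; for `stranded = TRUE` the result
#'   carries `per_strand`, a list with the plus/minus components.
#' @export
test_ltr_family_enrichment <- function(ltrs, vlincs, promoters, genes,
                                       genome, all_vlincs = vlincs,
                                       stranded = FALSE, shrink = 5000,
                                       window_halfwidth = 5000) {
  genome <- as_genome(genome)
  if (!stranded) {
    r <- .ltr_one_side(ltrs, vlincs, promoters, genes, genome, all_vlincs,
                       shrink, window_halfwidth, gene_strand = NULL)
    return(.enrichment_result("LTR family, unstranded", r$N, r$n,
                              p_i = rep(r$p, r$N), m = r$N * r$p))
  }
  st_l <- as.character(GenomicRanges::strand(ltrs))
  st_v <- as.character(GenomicRanges::strand(vlincs))
  if (any(st_v == "*"))
    stop("procedure V requires stranded vlincRNAs")
  sides <- lapply(c("+", "-"), function(s)
    .ltr_one_side(ltrs[st_l == s], vlincs[st_v == s], promoters, genes,
                  genome, all_vlincs, shrink, window_halfwidth,
                  gene_strand = s))
  names(sides) <- c("plus", "minus")
  N <- sides$plus$N + sides$minus$N
  n <- sides$plus$n + sides$minus$n
  p <- max(sides$plus$p, sides$minus$p)
  .enrichment_result("LTR family, stranded upper bound", N, n,
                     p_i = rep(p, N), m = N * p,
                     extra = list(per_strand = sides))
}
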