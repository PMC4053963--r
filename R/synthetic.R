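# Synthetic genomes with planted ground truth. Chromosome names use a
# reserved "synthchr" prefix so synthetic annotations cannot be mixed up
# with real data by accident.

.substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  set.seed(as.integer((abs(seed) * 7919 + h) %% (2^31 - 1)))
}

#' Simulation parameters
#'
#' Defaults describe the study conditions the generator emulates: a small
#' multi-chromosome genome carrying genes, six "cell lines" spanning the
#' malignant / immortalized / primary / embryonic-stem spectrum, planted
#' vlincRNAs of 50 kb - 1 Mb whose 5' promoters are preferentially
#' LTR-embedded in the malignant and pluripotent lines (an order of
#' magnitude above the primary lines), decoy promoters and background
#' repeats, a blacklist, and per-sample contig and density tracks.
#'
#' @param seed integer master seed; every layer derives a named substream
#'   from it, so regenerating one layer does not perturb the others.
#' @param n_chroms,chrom_length genome shape (default 2 x 20 Mb).
#' @param n_genes number of gene bodies (default 120), with log-uniform
#'   lengths between `gene_length_range` (default 2-50 kb).
#' @param gene_length_range numeric length-2.
#' @param cell_lines named character vector: line -> group label in
#'   malignant / immortalized / primary / embryonic-stem.
#' @param n_vlincs_per_line planted regions sourced per line (default 5).
#' @param vlinc_length_range log-uniform length range (default 50 kb - 1 Mb).
#' @param ltr_promoter_fraction named numeric per group: probability that a
#'   planted region's promoter embeds an LTR of `planted_ltr_family`
#'   (defaults: malignant 0.30, embryonic-stem 0.30, immortalized 0.10,
#'   primary 0.03).
#' @param planted_ltr_family repeat family embedded in planted promoters.
#' @param promoter_state_probs state distribution of decoy promoters.
#' @param n_decoy_promoters_per_line decoy promoters per line (default 120).
#' @param ltr_decoy_fraction fraction of decoy promoters embedding an LTR of
#'   the planted family (background rate, default 0.02).
#' @param n_background_repeats repeats scattered uniformly (default 200)
#'   over `repeat_families`.
#' @param repeat_families data.frame with columns `family`, `class`.
#' @param blacklist_fraction fraction of the genome blacklisted.
#' @param min_separation bases kept free around every planted feature
#'   (default 6 kb, above the 5 kb second-stage merge gap).
#' @param promoter_halfwidth half-length of planted promoters (default 1 kb).
#' @param contig_length_range,contig_gap_mean contig tiling inside expressed
#'   regions: lengths uniform in the range, gaps geometric with the given
#'   mean, capped below the first-stage merge gap.
#' @param merge_gap_1,merge_gap_2 caller gaps the truth layout respects.
#' @param n_noise_contigs,noise_length_range per-sample background contigs.
#' @param expr_source_meanlog,expr_source_sdlog log-normal expression of a
#'   region in its source line.
#' @param expr_background_meanlog,expr_background_sdlog,expr_background_zero_prob
#'   expression elsewhere (zero with the given probability).
#' @param ltr_skew multiplicative up-regulation of LTR-driven regions in
#'   malignant/embryonic-stem source lines (default 10).
#' @param emit_min_expr minimum expression for a region to leave coverage in
#'   a sample.
#' @param density_percentile percentile the density caller will use; the
#'   density noise level is constructed to sit below it.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(seed = 1,
                       n_chroms = 2, chrom_length = 2e7,
                       n_genes = 120, gene_length_range = c(2e3, 5e4),
                       cell_lines = c(lineA = "malignant",
                                      lineB = "malignant",
                                      lineC = "immortalized",
                                      lineD = "primary",
                                      lineE = "primary",
                                      lineF = "embryonic-stem"),
                       n_vlincs_per_line = 5,
                       vlinc_length_range = c(5e4, 1e6),
                       ltr_promoter_fraction = c(malignant = 0.30,
                                                 immortalized = 0.10,
                                                 primary = 0.03,
                                                 `embryonic-stem` = 0.30),
                       planted_ltr_family = "LTR7",
                       promoter_state_probs = c(Active = 0.6, Weak = 0.25,
                                                Poised = 0.15),
                       n_decoy_promoters_per_line = 120,
                       ltr_decoy_fraction = 0.02,
                       n_background_repeats = 200,
                       repeat_families = data.frame(
                         family = c("LTR12C", "THE1A", "AluY", "L1M", "MER1"),
                         class = c("LTR", "LTR", "other retroposon",
                                   "other retroposon", "other")),
                       blacklist_fraction = 0.005,
                       min_separation = 6000,
                       promoter_halfwidth = 1000,
                       contig_length_range = c(500, 3000),
                       contig_gap_mean = 200,
                       merge_gap_1 = 1000, merge_gap_2 = 5000,
                       n_noise_contigs = 40,
                       noise_length_range = c(200, 2000),
                       expr_source_meanlog = log(5),
                       expr_source_sdlog = 0.5,
                       expr_background_meanlog = log(0.3),
                       expr_background_sdlog = 0.8,
                       expr_background_zero_prob = 0.5,
                       ltr_skew = 10,
                       emit_min_expr = 1,
                       density_percentile = 0.80) {
  p <- as.list(environment())
  stopifnot(p$n_chroms >= 1, p$chrom_length > 0,
            all(unlist(p[c("ltr_promoter_fraction", "ltr_decoy_fraction",
                           "blacklist_fraction",
                           "expr_background_zero_prob")]) >= 0),
            all(unlist(p[c("ltr_promoter_fraction", "ltr_decoy_fraction",
                           "blacklist_fraction",
                           "expr_background_zero_prob")]) <= 1),
            p$vlinc_length_range[1] >= 1, p$gene_length_range[1] >= 1,
            p$density_percentile > 0, p$density_percentile < 1)
  class(p) <- "sim_params"
  p
}

.log_uniform <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

# Place items of given lengths on the genome, mutually separated by at least
# min_sep bases, uniformly at random. Errors when the packing is infeasible.
.place_items <- function(lengths, genome, min_sep) {
  n <- length(lengths)
  if (!n) return(data.frame(chrom = character(0), start = numeric(0),
                            end = numeric(0)))
  ord <- order(lengths, decreasing = TRUE)
  chrom_of <- integer(n)
  used <- stats::setNames(rep(0, length(genome)), names(genome))
  count <- stats::setNames(rep(0L, length(genome)), names(genome))
  for (i in ord) {
    cap <- genome - used - (count + 1) * min_sep - lengths[i]
    ok <- which(cap >= 0)
    if (!length(ok))
      stop("infeasible packing: requested features exceed the genome")
    pick <- if (length(ok) == 1L) ok else
      ok[sample.int(length(ok), 1L, prob = cap[ok] + 1)]
    chrom_of[i] <- pick
    used[pick] <- used[pick] + lengths[i]
    count[pick] <- count[pick] + 1L
  }
  out <- vector("list", length(genome))
  for (c_idx in seq_along(genome)) {
    idx <- which(chrom_of == c_idx)
    if (!length(idx)) next
    idx <- sample(idx)                      # random order along the chrom
    m <- length(idx)
    slack <- genome[c_idx] - sum(lengths[idx]) - (m - 1) * min_sep
    u <- stats::runif(m + 1)
    gaps <- u / sum(u) * slack
    gaps[2:m] <- gaps[2:m] + min_sep        # interior separation
    starts <- cumsum(gaps[seq_len(m)]) +
      cumsum(c(0, lengths[idx][-m]))
    out[[c_idx]] <- data.frame(chrom = names(genome)[c_idx],
                               start = floor(starts),
                               end = floor(starts) + lengths[idx],
                               item = idx)
  }
  d <- do.call(rbind, out)
  d[order(d$item), c("chrom", "start", "end")]
}

# sample n positions uniformly over the bases of an iset (returns data.frame
# chrom/pos in 0-based coordinates)
.sample_positions <- function(space, n) {
  widths <- unlist(lapply(space, function(m) m[, 2L] - m[, 1L]),
                   use.names = FALSE)
  chrom <- rep(names(space), vapply(space, nrow, 1L))
  starts <- unlist(lapply(space, function(m) m[, 1L]), use.names = FALSE)
  pick <- sample.int(length(widths), n, replace = TRUE, prob = widths)
  data.frame(chrom = chrom[pick],
             pos = floor(starts[pick] + stats::runif(n) * widths[pick]))
}

#' Simulate a genome with planted annotations
#'
#' Deterministic given `params$seed`. Genes and planted vlincRNAs are laid
#' out mutually non-overlapping with at least `min_separation` bases between
#' any two features; each planted region receives a promoter spanning its 5'
#' boundary, Active in its source line, and (with the group's
#' `ltr_promoter_fraction`) an LTR of the planted family embedded at the
#' promoter core on the region's strand. Decoy promoters, background
#' repeats and a blacklist are placed uniformly in the remaining space.
#'
#' @param params a [sim_params()] list.
#' @return a list of class `vlinc_simulation` with elements `genome`,
#'   `genes`, `vlincs` (the planted truth as a `GRanges`), `truth` (a
#'   data.frame with source line, LTR status and the true expression
#'   matrix), `promoters_by_line`, `repeats`, `blacklist` and `params`.
#' @export
simulate_annotation <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  genome <- stats::setNames(rep(params$chrom_length, params$n_chroms),
                            sprintf("synthchr%d", seq_len(params$n_chroms)))
  lines <- names(params$cell_lines)
  n_vl <- params$n_vlincs_per_line * length(lines)

  .substream(params$seed, "layout")
  gene_len <- round(.log_uniform(params$n_genes, params$gene_length_range))
  vlinc_len <- round(.log_uniform(n_vl, params$vlinc_length_range))
  placed <- .place_items(c(gene_len, vlinc_len), genome,
                         params$min_separation)
  gpl <- placed[seq_len(params$n_genes), ]
  vpl <- placed[params$n_genes + seq_len(n_vl), ]
  genes <- genomic_intervals(gpl$chrom, gpl$start, gpl$end,
                             strand = sample(c("+", "-"), params$n_genes,
                                             replace = TRUE),
                             genome = genome,
                             name = sprintf("gene_%d", seq_len(params$n_genes)))
  v_strand <- sample(c("+", "-"), n_vl, replace = TRUE)
  source_line <- rep(lines, each = params$n_vlincs_per_line)[sample.int(n_vl)]
  vlincs <- genomic_intervals(vpl$chrom, vpl$start, vpl$end,
                              strand = v_strand, genome = genome,
                              name = sprintf("planted_%d", seq_len(n_vl)),
                              source_sample = source_line)

  .substream(params$seed, "promoters")
  group <- params$cell_lines[source_line]
  ltr_frac <- params$ltr_promoter_fraction[group]
  ltr_driven <- stats::runif(n_vl) < ltr_frac
  tss <- ifelse(v_strand == "+", vpl$start, vpl$end)
  hw <- params$promoter_halfwidth
  planted_prom <- genomic_intervals(
    vpl$chrom, pmax(tss - hw, 0),
    pmin(tss + hw, genome[vpl$chrom]), genome = genome,
    state = "Active", planted_vlinc = seq_len(n_vl))

  # eligible space for decoys / noise: away from planted boundaries
  vl_expand <- adjust_boundaries(vlincs, params$min_separation,
                                 params$min_separation, genome = genome)
  eligible <- .iset_complement(.gr_to_iset(vl_expand), genome)

  promoters_by_line <- list()
  ltr_list <- list()
  for (ln in lines) {
    mine <- which(source_line == ln)
    prom <- planted_prom[mine]
    nd <- params$n_decoy_promoters_per_line
    dpos <- .sample_positions(eligible, nd)
    dlen <- round(stats::runif(nd, 1000, 3000))
    decoys <- genomic_intervals(
      dpos$chrom, pmax(dpos$pos - dlen / 2, 0),
      pmin(dpos$pos + dlen / 2, genome[dpos$chrom]), genome = genome,
      state = sample(names(params$promoter_state_probs), nd, replace = TRUE,
                     prob = params$promoter_state_probs),
      planted_vlinc = NA_integer_)
    all_prom <- c(prom, decoys)
    S4Vectors::mcols(all_prom)$cell_line <- ln
    promoters_by_line[[ln]] <- all_prom
    # LTRs embedded in planted promoters of this line
    emb <- mine[ltr_driven[mine]]
    if (length(emb)) {
      ltr_list[[paste0(ln, "_planted")]] <- genomic_intervals(
        vpl$chrom[emb], pmax(tss[emb] - 300, 0), tss[emb] + 300,
        strand = v_strand[emb], genome = genome,
        family = params$planted_ltr_family, repeat_class = "LTR")
    }
    # background-rate LTRs of the same family in decoy promoters
    demb <- which(stats::runif(nd) < params$ltr_decoy_fraction)
    if (length(demb)) {
      ctr <- (GenomicRanges::start(decoys[demb]) +
                GenomicRanges::end(decoys[demb])) / 2
      ltr_list[[paste0(ln, "_decoy")]] <- genomic_intervals(
        as.character(GenomeInfoDb::seqnames(decoys[demb])),
        pmax(floor(ctr) - 300, 0), floor(ctr) + 300,
        strand = sample(c("+", "-"), length(demb), replace = TRUE),
        genome = genome,
        family = params$planted_ltr_family, repeat_class = "LTR")
    }
  }

  .substream(params$seed, "repeats")
  nb <- params$n_background_repeats
  fam_idx <- sample.int(nrow(params$repeat_families), nb, replace = TRUE)
  rpos <- .sample_positions(
    stats::setNames(lapply(names(genome), function(ch)
      cbind(start = 0, end = genome[[ch]])), names(genome)), nb)
  rlen <- round(stats::runif(nb, 300, 5000))
  background <- genomic_intervals(
    rpos$chrom, pmin(rpos$pos, genome[rpos$chrom] - rlen),
    pmin(rpos$pos, genome[rpos$chrom] - rlen) + rlen,
    strand = sample(c("+", "-"), nb, replace = TRUE), genome = genome,
    family = params$repeat_families$family[fam_idx],
    repeat_class = .repeat_class_from_family(
      params$repeat_families$class[fam_idx]))
  repeats <- c(do.call(c, unname(ltr_list)), background)

  .substream(params$seed, "blacklist")
  n_bl <- 4L
  bl_total <- params$blacklist_fraction * sum(genome)
  bl_len <- rep(bl_total / n_bl, n_bl)
  bpos <- .sample_positions(eligible, n_bl)
  blacklist <- genomic_intervals(
    bpos$chrom, pmin(bpos$pos, genome[bpos$chrom] - bl_len),
    pmin(bpos$pos, genome[bpos$chrom] - bl_len) + round(bl_len),
    genome = genome)

  .substream(params$seed, "expression")
  expr <- matrix(0, nrow = n_vl, ncol = length(lines),
                 dimnames = list(sprintf("planted_%d", seq_len(n_vl)), lines))
  for (j in seq_along(lines)) {
    zero <- stats::runif(n_vl) < params$expr_background_zero_prob
    bg <- stats::rlnorm(n_vl, params$expr_background_meanlog,
                        params$expr_background_sdlog)
    expr[, j] <- ifelse(zero, 0, bg)
  }
  src <- stats::rlnorm(n_vl, params$expr_source_meanlog,
                       params$expr_source_sdlog)
  boost <- ltr_driven & group %in% c("malignant", "embryonic-stem")
  src[boost] <- src[boost] * params$ltr_skew
  expr[cbind(seq_len(n_vl), match(source_line, lines))] <- src

  truth <- data.frame(
    id = sprintf("planted_%d", seq_len(n_vl)),
    chrom = vpl$chrom, start = vpl$start, end = vpl$end,
    strand = v_strand, source_sample = source_line,
    group = unname(group), ltr_driven = ltr_driven,
    stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(expr))

  out <- list(genome = genome, genes = genes, vlincs = vlincs,
              truth = truth, promoters_by_line = promoters_by_line,
              repeats = repeats, blacklist = blacklist, params = params)
  class(out) <- "vlinc_simulation"
  out
}

#' @export
print.vlinc_simulation <- function(x, ...) {
  cat(sprintf(
    "Synthetic genome: %d chromosome(s), %.0f Mb; %d genes, %d planted vlincRNAs, %d cell lines\n",
    length(x$genome), sum(x$genome) / 1e6, length(x$genes),
    length(x$vlincs), length(x$promoters_by_line)))
  invisible(x)
}

.emitted_in <- function(sim, line) {
  which(sim$truth[[line]] >= sim$params$emit_min_expr)
}

#' Emit per-sample coverage contigs from the planted truth
#'
#' Inside every region expressed in a sample (true expression at or above
#' `emit_min_expr`), contigs tile the region from its exact start to its
#' exact end with gaps strictly below the first-stage merge gap, and base
#' counts proportional to true expression times contig length. Background
#' noise contigs are scattered at least `min_separation` bases away from any
#' planted region.
#'
#' @param sim a [simulate_annotation()] result.
#' @param samples cell lines to emit (default all).
#' @param noise number of noise contigs per sample (default
#'   `params$n_noise_contigs`; use 0 for noise-free tracks).
#' @return named list of contig `GRanges` (with `base_count`), one per
#'   sample.
#' @export
emit_contigs <- function(sim, samples = names(sim$promoters_by_line),
                         noise = sim$params$n_noise_contigs) {
  p <- sim$params
  genome <- sim$genome
  vl_expand <- adjust_boundaries(sim$vlincs, p$min_separation,
                                 p$min_separation, genome = genome)
  eligible <- .iset_complement(.gr_to_iset(vl_expand), genome)
  out <- list()
  for (ln in samples) {
    .substream(p$seed, paste0("contigs_", ln))
    rows <- list()
    for (i in .emitted_in(sim, ln)) {
      s0 <- sim$truth$start[i]; e0 <- sim$truth$end[i]
      expr <- sim$truth[[ln]][i]
      pos <- s0
      starts <- ends <- numeric(0)
      while (pos < e0) {
        len <- round(stats::runif(1, p$contig_length_range[1],
                                  p$contig_length_range[2]))
        end_i <- min(pos + len, e0)
        # never leave a trailing fragment shorter than a contig
        if (e0 - end_i < p$contig_length_range[1]) end_i <- e0
        starts <- c(starts, pos); ends <- c(ends, end_i)
        gap <- min(stats::rgeom(1, 1 / (p$contig_gap_mean + 1)),
                   p$merge_gap_1 - 1)
        pos <- end_i + gap
        if (e0 - pos < p$contig_length_range[1] && pos < e0) {
          # close the region exactly at its right boundary
          starts <- c(starts, pos); ends <- c(ends, e0)
          pos <- e0
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = sim$truth$chrom[i], start = starts, end = ends,
        strand = sim$truth$strand[i],
        base_count = pmax(1, round(expr * (ends - starts))))
    }
    if (noise > 0) {
      npos <- .sample_positions(eligible, noise)
      nlen <- round(stats::runif(noise, p$noise_length_range[1],
                                 p$noise_length_range[2]))
      nexpr <- stats::rlnorm(noise, log(0.5), 0.5)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = npos$chrom, start = npos$pos, end = npos$pos + nlen,
        strand = sample(c("+", "-"), noise, replace = TRUE),
        base_count = pmax(1, round(nexpr * nlen)))
    }
    d <- do.call(rbind, rows)
    out[[ln]] <- if (is.null(d)) {
      genomic_intervals(character(0), numeric(0), numeric(0),
                        base_count = numeric(0))
    } else {
      genomic_intervals(d$chrom, d$start, d$end, strand = d$strand,
                        genome = genome, base_count = d$base_count)
    }
  }
  out
}

#' Emit a per-sample non-strand-specific density track
#'
#' Expressed regions contribute a constant per-base density equal to their
#' true expression (strand-collapsed). Uniform low-level noise runs are
#' added outside genes and planted regions, with a value strictly below the
#' weakest expressed region and a total base count constructed so that the
#' caller's expression-percentile threshold falls at the weakest region's
#' density: noise stays below the threshold by construction and every
#' expressed region survives thresholding.
#'
#' @param sim a [simulate_annotation()] result.
#' @param sample cell line name.
#' @param noise logical; emit the noise runs (default TRUE).
#' @return a `GRanges` density track with a `score` column.
#' @export
emit_density <- function(sim, sample, noise = TRUE) {
  p <- sim$params
  genome <- sim$genome
  .substream(p$seed, paste0("density_", sample))
  idx <- .emitted_in(sim, sample)
  sig <- if (length(idx)) {
    genomic_intervals(sim$truth$chrom[idx], sim$truth$start[idx],
                      sim$truth$end[idx], genome = genome,
                      score = sim$truth[[sample]][idx])
  } else genomic_intervals(character(0), numeric(0), numeric(0),
                           score = numeric(0))
  if (!noise) return(sort(sig, ignore.strand = TRUE))
  q <- p$density_percentile
  if (length(idx)) {
    S <- sum(sim$truth$end[idx] - sim$truth$start[idx])
    dmin <- min(sim$truth[[sample]][idx])
    b1 <- sum((sim$truth$end[idx] - sim$truth$start[idx])[
      sim$truth[[sample]][idx] == dmin])
    n_target <- max(0, (q * S - b1 / 2) / (1 - q))
    noise_value <- dmin * 0.1
  } else {
    S <- 0; n_target <- 2e6; noise_value <- 0.01
  }
  avoid <- c(GenomicRanges::granges(sim$vlincs),
             GenomicRanges::granges(sim$genes))
  avoid <- adjust_boundaries(avoid, 500, 500, genome = genome)
  free <- .iset_complement(.gr_to_iset(avoid), genome)
  gaps <- do.call(rbind, lapply(names(free), function(ch)
    data.frame(chrom = ch, start = free[[ch]][, 1L],
               end = free[[ch]][, 2L])))
  capacity <- sum(gaps$end - gaps$start)
  if (n_target > capacity) {
    warning("noise target exceeds free space; density recovery not ",
            "guaranteed at this signal load")
    n_target <- capacity
  }
  runs <- list()
  need <- n_target
  while (need > 0 && nrow(gaps)) {
    w <- gaps$end - gaps$start
    g <- sample.int(nrow(gaps), 1L, prob = w)
    len <- min(need, w[g], round(stats::runif(1, 5000, 30000)))
    off <- floor(stats::runif(1) * (w[g] - len + 1))
    s <- gaps$start[g] + off
    runs[[length(runs) + 1L]] <- data.frame(chrom = gaps$chrom[g],
                                            start = s, end = s + len)
    # carve the used part out of the gap
    before <- gaps[0, ]
    if (s > gaps$start[g])
      before <- data.frame(chrom = gaps$chrom[g], start = gaps$start[g],
                           end = s)
    after <- gaps[0, ]
    if (s + len < gaps$end[g])
      after <- data.frame(chrom = gaps$chrom[g], start = s + len,
                          end = gaps$end[g])
    gaps <- rbind(gaps[-g, ], before, after)
    need <- need - len
  }
  nr <- do.call(rbind, runs)
  track <- sig
  if (!is.null(nr) && nrow(nr)) {
    track <- c(sig, genomic_intervals(nr$chrom, nr$start, nr$end,
                                      genome = genome, score = noise_value))
  }
  sort(track, ignore.strand = TRUE)
}

#' Redraw features uniformly within an eligible space
#'
#' Length-preserving uniform redraw: each feature is placed uniformly over
#' all positions of the eligible space where it fits entirely inside one
#' eligible interval. Overlap between redrawn features is not prevented.
#' Used as the permutation-null generator when calibrating the enrichment
#' procedures.
#'
#' @param features a `GRanges`.
#' @param eligible_space a `GRanges` (flattened internally).
#' @param seed optional integer; when given, the draw is reproducible.
#' @return a `GRanges` of redrawn features (strand and metadata preserved).
#' @export
null_shuffle <- function(features, eligible_space, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed %% (2^31 - 1)))
  es <- .iset_flatten(.gr_to_iset(eligible_space))
  gaps <- do.call(rbind, lapply(names(es), function(ch)
    data.frame(chrom = ch, start = es[[ch]][, 1L], end = es[[ch]][, 2L])))
  w <- gaps$end - gaps$start
  len <- as.numeric(GenomicRanges::width(features))
  new_start <- numeric(length(features))
  new_chrom <- character(length(features))
  for (L in unique(len)) {
    idx <- which(len == L)
    slots <- pmax(0, w - L + 1)
    if (sum(slots) == 0)
      stop("a feature of length ", L, " fits nowhere in the eligible space")
    g <- sample.int(nrow(gaps), length(idx), replace = TRUE, prob = slots)
    new_start[idx] <- gaps$start[g] +
      floor(stats::runif(length(idx)) * slots[g])
    new_chrom[idx] <- gaps$chrom[g]
  }
  out <- genomic_intervals(new_chrom, new_start, new_start + len,
                           strand = as.character(
                             GenomicRanges::strand(features)))
  S4Vectors::mcols(out) <- S4Vectors::mcols(features)
  out
}

#' Simulate an expression matrix with a known LTR-stratum skew
#'
#' A light-weight generator for ratio-recovery checks: regions are
#' log-normally expressed, the malignant / immortalized / embryonic-stem
#' columns are up-regulated relative to primary, and LTR-driven regions
#' receive an extra multiplicative `skew` in those columns.
#'
#' @param n_vlincs number of regions.
#' @param groups named character vector (sample -> group).
#' @param ltr_fraction fraction of regions flagged LTR-driven.
#' @param skew multiplicative LTR up-regulation (the recoverable parameter).
#' @param base_up non-LTR up-regulation of non-primary columns.
#' @param sdlog log-normal noise.
#' @param seed integer.
#' @return list with `mat` (matrix with a `groups` attribute) and
#'   `ltr_driven` (logical).
#' @export
simulate_expression_matrix <- function(n_vlincs = 500,
                                       groups = c(m1 = "malignant",
                                                  m2 = "malignant",
                                                  im = "immortalized",
                                                  p1 = "primary",
                                                  p2 = "primary",
                                                  es = "embryonic-stem"),
                                       ltr_fraction = 0.3, skew = 10,
                                       base_up = 5, sdlog = 0.5, seed = 1) {
  set.seed(as.integer(seed %% (2^31 - 1)))
  ltr <- stats::runif(n_vlincs) < ltr_fraction
  mat <- matrix(0, n_vlincs, length(groups),
                dimnames = list(sprintf("v%d", seq_len(n_vlincs)),
                                names(groups)))
  for (j in seq_along(groups)) {
    mu <- if (groups[j] == "primary") 0 else log(base_up)
    v <- stats::rlnorm(n_vlincs, mu, sdlog)
    if (groups[j] != "primary") v[ltr] <- v[ltr] * skew
    mat[, j] <- v
  }
  attr(mat, "groups") <- groups
  list(mat = mat, ltr_driven = ltr)
}
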