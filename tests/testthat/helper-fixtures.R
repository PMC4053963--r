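# Shared test fixtures and brute-force oracles.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

# 0-based half-open constructor (BED coordinates), matching the on-disk
# convention all contracts are written in.
gr0 <- function(chrom, start, end, strand = "*", ...) {
  genomic_intervals(chrom = chrom, start = start, end = end,
                    strand = strand, zero_based = TRUE, ...)
}

bed_coords <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr) - 1, end = end(gr),
             strand = as.character(strand(gr)),
             stringsAsFactors = FALSE)
}

# per-base boolean coverage over a single toy chromosome of length L
cov_vec <- function(gr, L, chrom = "chr1", strands = c("+", "-", "*")) {
  v <- logical(L)
  gr <- gr[as.character(seqnames(gr)) == chrom &
             as.character(strand(gr)) %in% strands]
  for (i in seq_along(gr)) {
    s <- start(gr)[i]; e <- end(gr)[i]
    v[s:e] <- TRUE           # 1-based closed == covered bases
  }
  v
}

random_intervals <- function(n, L, chrom = "chr1", max_len = NULL,
                             stranded = FALSE) {
  if (is.null(max_len)) max_len <- max(2, L %/% 10)
  s <- floor(runif(n, 0, L - 1))
  len <- pmax(1, floor(runif(n, 1, max_len)))
  e <- pmin(s + len, L)
  st <- if (stranded) sample(c("+", "-"), n, replace = TRUE) else "*"
  gr0(chrom, s, e, strand = st)
}

# reflect all coordinates x -> L - x on one chromosome and swap strands
mirror_gr <- function(gr, L) {
  st <- as.character(strand(gr))
  st <- ifelse(st == "+", "-", ifelse(st == "-", "+", "*"))
  gr0(as.character(seqnames(gr)), L - end(gr), L - (start(gr) - 1),
      strand = st)
}

sorted_bed <- function(gr) {
  d <- bed_coords(gr)
  d[order(d$chrom, d$start, d$end, d$strand), , drop = FALSE]
}

expect_same_regions <- function(a, b) {
  da <- sorted_bed(a); db <- sorted_bed(b)
  rownames(da) <- rownames(db) <- NULL
  expect_equal(da, db)
}

# a small fixed simulation shared by several test files (cheap: ~1 s)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_annotation(sim_params(seed = 42))
    cache
  }
})
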