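# Independent oracle: brute-force binomial tail by direct summation.
tail_by_summation <- function(N, q, n) {
  if (n <= 0) return(1)
  k <- n:N
  sum(exp(lchoose(N, k) + k * log(q) + (N - k) * log1p(-q)))
}

test_that("binomial upper tail matches direct summation exactly", {
  expect_equal(binomial_upper_tail(10, 0.5, 0), 1.0)
  expect_equal(binomial_upper_tail(10, 0.5, 10), 0.0009765625)
  expect_equal(binomial_upper_tail(5, 0.2, 2), 0.26272, tolerance = 1e-12)
  for (N in c(1:10, 20, 30)) {
    for (q in c(0.01, 0.2, 0.5, 0.9)) {
      for (n in unique(c(0, 1, floor(N / 2), N))) {
        expect_equal(binomial_upper_tail(N, q, n),
                     tail_by_summation(N, q, n), tolerance = 1e-12)
      }
    }
  }
  expect_error(binomial_upper_tail(10, 1.5, 2), "invalid")
  expect_error(binomial_upper_tail(10, 0.5, 11), "invalid")
})

test_that("binomial tail is monotone and finite in log space at extreme depths", {
  # decreasing in n, increasing in q
  ps <- vapply(0:20, function(n) binomial_upper_tail(20, 0.3, n), 1)
  expect_true(all(diff(ps) <= 0))
  qs <- vapply(seq(0.05, 0.95, 0.05), function(q)
    binomial_upper_tail(20, q, 10), 1)
  expect_true(all(diff(qs) >= 0))
  # printed-style extreme tails (~1e-150): finite and correctly ordered
  lp <- vapply(c(300, 400, 500), function(n)
    binomial_upper_tail(2147, 0.02, n, log10 = TRUE), 1)
  expect_true(all(is.finite(lp)))
  expect_true(all(diff(lp) < 0))
  expect_lt(lp[3], -150)
})

test_that("anti-space composes genes, blacklist, short gaps and vlinc removal", {
  g <- gr0("chr1", 0, 10000, "+")
  expect_equal(bed_coords(build_anti_space(g))[, c("start", "end")],
               data.frame(start = 0, end = 10000))
  # subtraction of tested regions
  a <- build_anti_space(g, tested_vlincs = gr0("chr1", 5000, 10000))
  expect_equal(bed_coords(a)[, c("start", "end")],
               data.frame(start = 0, end = 5000))
  # blacklist is included regardless of strand mode
  a2 <- build_anti_space(g, blacklist = gr0("chr1", 20000, 21000),
                         mode = "stranded-same", strand = "-")
  expect_equal(bed_coords(a2)[, c("start", "end")],
               data.frame(start = 20000, end = 21000))
  # stranded-same keeps only same-strand (or unstranded) genes
  gs <- gr0("chr1", c(0, 20000), c(10000, 30000), c("+", "-"))
  ap <- build_anti_space(gs, mode = "stranded-same", strand = "+")
  expect_equal(bed_coords(ap)$start, 0)
  # short gaps between genes are absorbed
  g2 <- gr0("chr1", c(0, 40000), c(10000, 50000), c("+", "-"))
  wg <- build_anti_space(g2, mode = "with-short-gaps")
  expect_equal(bed_coords(wg)[, c("start", "end")],
               data.frame(start = 0, end = 50000))
  g3 <- gr0("chr1", c(0, 70000), c(10000, 80000))   # 60 kb gap stays open
  expect_equal(nrow(bed_coords(build_anti_space(g3,
                                                mode = "with-short-gaps"))), 2)
})

# small deterministic scenario used by several blocks
toy_scenario <- function(seed = 1, n_vlincs = 20, genome_mb = 10) {
  set.seed(seed)
  genome <- c(toychr = genome_mb * 1e6)
  starts <- seq(2e5, genome_mb * 1e6 - 4e5, length.out = n_vlincs)
  len <- 1e5
  vl <- gr0("toychr", starts, starts + len,
            strand = rep(c("+", "-"), length.out = n_vlincs))
  tss <- ifelse(as.character(strand(vl)) == "+", starts, starts + len)
  prom <- gr0("toychr", tss - 1000, tss + 1000, state = "Active")
  genes <- gr0("toychr", c(5e4, genome_mb * 1e6 - 1e5),
               c(9e4, genome_mb * 1e6 - 5e4), c("+", "-"))
  list(genome = genome, vlincs = vl, promoters = prom, genes = genes)
}

test_that("procedure I: saturation and emptiness give p-value 1", {
  sc <- toy_scenario()
  sat <- gr0("toychr", 0, 1e7)
  r <- test_promoter_overlap_stranded(sc$vlincs, sat, sc$genes,
                                      genome = sc$genome)
  expect_equal(r$n_observed, r$N)
  expect_equal(unname(r$success_probs), rep(1, r$N))
  expect_equal(r$p_value, 1)
  r0 <- test_promoter_overlap_stranded(sc$vlincs, GRanges(), sc$genes,
                                       genome = sc$genome)
  expect_equal(r0$n_observed, 0)
  expect_equal(r0$m_expected, 0)
  expect_equal(r0$p_value, 1)
  expect_error(test_promoter_overlap_stranded(
    gr0("toychr", 0, 1e5, "*"), sat, sc$genes, genome = sc$genome),
    "stranded")
})

test_that("procedure I: planted promoters at 5' ends are strongly enriched", {
  sc <- toy_scenario()
  set.seed(2)
  decoy_pos <- floor(runif(50, 0, 1e7 - 2000))
  proms <- c(sc$promoters, gr0("toychr", decoy_pos, decoy_pos + 2000,
                               state = "Active"))
  r <- test_promoter_overlap_stranded(sc$vlincs, proms, sc$genes,
                                      genome = sc$genome)
  expect_equal(r$n_observed, 20)
  expect_lt(r$p_value, 1e-6)
  expect_gt(r$fold, 5)
  # order invariance: shuffling the tested regions changes nothing
  set.seed(3)
  r2 <- test_promoter_overlap_stranded(sc$vlincs[sample(20)], proms,
                                       sc$genes, genome = sc$genome)
  expect_equal(r2$m_expected, r$m_expected)
  expect_equal(r2$p_value, r$p_value)
  # the V correction makes the test more conservative
  rn <- test_promoter_overlap_stranded(sc$vlincs, proms, sc$genes,
                                       genome = sc$genome,
                                       v_correction = FALSE)
  expect_gte(r$p_value, rn$p_value)
  expect_true(all(r$success_probs >= rn$success_probs))
})

test_that("per-element space probabilities match a GenomicRanges oracle", {
  sc <- toy_scenario(seed = 4, n_vlincs = 6)
  set.seed(4)
  decoy_pos <- floor(runif(30, 0, 1e7 - 2000))
  proms <- c(sc$promoters, gr0("toychr", decoy_pos, decoy_pos + 2000))
  bl <- gr0("toychr", 4e6, 4.05e6)
  r <- test_promoter_overlap_stranded(sc$vlincs, proms, sc$genes, bl,
                                      genome = sc$genome)
  V <- union_length(sc$vlincs)
  prom_ext <- adjust_boundaries(proms, 5000, 5000,
                                genome = sc$genome)
  st <- as.character(strand(sc$vlincs))
  for (i in seq_along(sc$vlincs)) {
    gsame <- sc$genes[as.character(strand(sc$genes)) %in% c(st[i], "*")]
    anti <- interval_subtract(
      merge_within_gap(c(GenomicRanges::granges(gsame),
                         GenomicRanges::granges(bl)), 0),
      sc$vlincs[st == st[i]])
    L_i <- width(sc$vlincs)[i]
    ext <- if (st[i] == "+") adjust_boundaries(anti, L_i, 0, sc$genome)
           else adjust_boundaries(anti, 0, L_i, sc$genome)
    space_len <- sc$genome[["toychr"]] - union_length(ext)
    space <- interval_subtract(gr0("toychr", 0, 1e7), ext)
    occ <- union_length(GenomicRanges::intersect(
      space, GenomicRanges::reduce(prom_ext, ignore.strand = TRUE),
      ignore.strand = TRUE))
    expect_equal(unname(r$success_probs[i]),
                 min(1, occ / (space_len - V)), tolerance = 1e-12)
  }
})

test_that("degenerate spaces are refused", {
  genome <- c(toychr = 2e5)
  vl <- gr0("toychr", c(0, 1e5), c(1e5, 2e5), c("+", "+"))
  expect_error(test_promoter_overlap_stranded(
    vl, gr0("toychr", 0, 1000), GRanges(), genome = genome),
    "degenerate space")
})

test_that("procedure II combines the two boundary orientations", {
  sc <- toy_scenario()
  vu <- sc$vlincs
  strand(vu) <- "*"
  r0 <- test_promoter_overlap_unstranded(vu, GRanges(), sc$genes,
                                         genome = sc$genome)
  expect_equal(r0$p_value, 1)
  set.seed(6)
  decoy_pos <- floor(runif(50, 0, 1e7 - 2000))
  proms <- c(sc$promoters, gr0("toychr", decoy_pos, decoy_pos + 2000,
                               state = "Active"))
  r <- test_promoter_overlap_unstranded(vu, proms, sc$genes,
                                        genome = sc$genome)
  expect_equal(r$n_observed, 20)
  expect_lt(r$p_value, 1e-6)
  expect_equal(unname(r$success_probs),
               unname(1 - (1 - r$p_plus) * (1 - r$p_minus)),
               tolerance = 1e-12)
  # complement-product arithmetic
  expect_equal(1 - (1 - 0.5) * (1 - 0.5), 0.75)
  # a promoter near the RIGHT boundary is found via the second window
  one <- gr0("toychr", 3e6, 3.1e6, "*")
  pr <- gr0("toychr", 3.102e6, 3.104e6)
  expect_equal(test_promoter_overlap_unstranded(
    one, pr, sc$genes, genome = sc$genome)$n_observed, 1)
})

test_that("procedure III handles saturation, emptiness and self-overlap", {
  sc <- toy_scenario()
  expect_error(test_set_overlap(GRanges(), sc$vlincs, sc$genes,
                                genome = sc$genome), "non-empty")
  rsat <- test_set_overlap(sc$vlincs, gr0("toychr", 0, 1e7), sc$genes,
                           genome = sc$genome)
  expect_equal(rsat$n_observed, rsat$N)
  expect_equal(rsat$p_value, 1)
  r0 <- test_set_overlap(sc$vlincs, GRanges(), sc$genes, genome = sc$genome)
  expect_equal(r0$n_observed, 0)
  expect_equal(r0$p_value, 1)
  rself <- test_set_overlap(sc$vlincs, sc$vlincs, sc$genes,
                            genome = sc$genome)
  expect_equal(rself$n_observed, rself$N)
  expect_lt(rself$p_value, 0.05)
  # single-base SNP subjects are legal
  snps <- gr0("toychr", start(sc$vlincs)[1:5] + 10,
              start(sc$vlincs)[1:5] + 11)
  rsnp <- test_set_overlap(sc$vlincs, snps, sc$genes, genome = sc$genome)
  expect_equal(rsnp$n_observed, 5)
})

test_that("LTR clustering follows the promoter-scoped collapse rules", {
  prom <- gr0("chr1", c(0, 10000, 20000), c(2000, 12000, 22000))
  # two same-family LTRs in one promoter -> one cluster
  l2 <- gr0("chr1", c(100, 1500), c(400, 1900), family = c("LTR7", "LTR7"))
  cl <- cluster_ltr_elements(l2, prom)
  expect_equal(length(unique(S4Vectors::mcols(cl)$cluster)), 1L)
  # one LTR spanning two promoters of different regions -> split into two
  lspan <- gr0("chr1", 1900, 10100, family = "LTR7")
  cl2 <- cluster_ltr_elements(lspan, prom[1:2],
                              promoter_vlinc = c("v1", "v2"))
  expect_equal(length(cl2), 2L)
  expect_equal(length(unique(S4Vectors::mcols(cl2)$cluster)), 2L)
  # ... but promoters of the same region collapse the fragments
  cl3 <- cluster_ltr_elements(lspan, prom[1:2],
                              promoter_vlinc = c("v1", "v1"))
  expect_equal(length(unique(S4Vectors::mcols(cl3)$cluster)), 1L)
  # an LTR outside promoters is a singleton cluster
  cl4 <- cluster_ltr_elements(gr0("chr1", 5e4, 5.1e4, family = "LTR7"), prom)
  expect_equal(S4Vectors::mcols(cl4)$cluster, "singleton:1")
  # mixed families are refused
  expect_error(cluster_ltr_elements(
    gr0("chr1", c(0, 10), c(5, 20), family = c("LTR7", "LTR12C")), prom),
    "single repeat family")
})

ltr_scenario <- function(seed = 8, frac_seeded = 0.3, n_vlincs = 40,
                         n_decoy = 600, decoy_ltr_frac = 0.02) {
  set.seed(seed)
  genome <- c(toychr = 2e7)
  starts <- seq(2e5, 1.94e7, length.out = n_vlincs)
  vl <- gr0("toychr", starts, starts + 1e5,
            strand = rep(c("+", "-"), length.out = n_vlincs))
  tss <- ifelse(as.character(strand(vl)) == "+", starts, starts + 1e5)
  vprom <- gr0("toychr", tss - 1000, tss + 1000, state = "Active")
  decoy_pos <- floor(runif(n_decoy, 0, 2e7 - 2000))
  dprom <- gr0("toychr", decoy_pos, decoy_pos + 2000, state = "Weak")
  proms <- c(vprom, dprom)
  seeded <- which(runif(n_vlincs) < frac_seeded)
  dseed <- which(runif(n_decoy) < decoy_ltr_frac)
  ltrs <- c(
    gr0("toychr", tss[seeded] - 300, tss[seeded] + 300,
        strand = as.character(strand(vl))[seeded], family = "LTR7"),
    gr0("toychr", decoy_pos[dseed] + 500, decoy_pos[dseed] + 1100,
        strand = sample(c("+", "-"), length(dseed), replace = TRUE),
        family = "LTR7"))
  genes <- gr0("toychr", c(5e4, 1e7), c(9e4, 1.005e7), c("+", "-"))
  list(genome = genome, vlincs = vl, promoters = proms, ltrs = ltrs,
       genes = genes, n_seeded = length(seeded))
}

test_that("procedure IV finds family seeding far above background", {
  sc <- ltr_scenario()
  r <- test_ltr_family_enrichment(sc$ltrs, sc$vlincs, sc$promoters,
                                  sc$genes, sc$genome)
  expect_gt(r$fold, 5)
  expect_lt(r$p_value, 1e-4)
  expect_gte(r$n_observed, sc$n_seeded)  # decoys can add chance hits
  # family absent from all promoters: n = 0, p-value 1
  far <- gr0("toychr", 1.0e7 + 2e5, 1.0e7 + 2.06e5, family = "LTR7")
  r0 <- test_ltr_family_enrichment(far, sc$vlincs, sc$promoters, sc$genes,
                                   sc$genome)
  expect_equal(r0$n_observed, 0)
  expect_equal(r0$p_value, 1)
  # saturated: every promoter is a vlinc promoter
  rsat <- test_ltr_family_enrichment(sc$ltrs, sc$vlincs, sc$promoters[1:40],
                                     sc$genes, sc$genome)
  expect_equal(unname(rsat$success_probs[1]), 1)
  expect_equal(rsat$p_value, 1)
})

test_that("procedure V upper-bounds the exact per-strand tail", {
  sc <- ltr_scenario()
  r5 <- test_ltr_family_enrichment(sc$ltrs, sc$vlincs, sc$promoters,
                                   sc$genes, sc$genome, stranded = TRUE)
  expect_lt(r5$p_value, 1e-4)
  ps <- r5$per_strand
  # exact tail of X+ + X- with X+/- ~ B(N+/-, p+/-) by convolution
  conv <- outer(stats::dbinom(0:ps$plus$N, ps$plus$N, ps$plus$p),
                stats::dbinom(0:ps$minus$N, ps$minus$N, ps$minus$p))
  tot <- row(conv) + col(conv) - 2
  exact <- sum(conv[tot >= r5$n_observed])
  expect_gte(r5$p_value + 1e-12, exact)
})
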