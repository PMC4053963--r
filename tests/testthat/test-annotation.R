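test_that("promoter repeat classification uses overlap and precedence", {
  prom <- gr0("chr1", c(0, 0, 10000, 20000),
              c(2000, 2000, 12000, 22000))[c(1, 3, 4)]
  reps <- gr0("chr1", c(1500, 2000, 10500), c(3000, 3000, 11000),
              family = c("LTR7", "LTR7", "AluY"),
              repeat_class = c("LTR", "LTR", "other retroposon"))
  out <- classify_promoter_repeats(prom, reps)
  expect_equal(S4Vectors::mcols(out)$ltr_overlap, c(TRUE, FALSE, FALSE))
  expect_equal(S4Vectors::mcols(out)$repeat_overlap_class,
               c("LTR", "non-LTR retroposon", "none"))
  # half-open adjacency: LTR starting exactly at the promoter end is no hit
  p2 <- gr0("chr1", 0, 2000)
  r2 <- gr0("chr1", 2000, 3000, family = "LTR7", repeat_class = "LTR")
  expect_false(S4Vectors::mcols(classify_promoter_repeats(p2, r2))$ltr_overlap)
  # LTR precedence over a co-occurring retroposon
  r3 <- gr0("chr1", c(100, 200), c(300, 400), family = c("AluY", "LTR7"),
            repeat_class = c("other retroposon", "LTR"))
  expect_equal(
    S4Vectors::mcols(classify_promoter_repeats(p2, r3))$repeat_overlap_class,
    "LTR")
})

test_that("cell-line-specific Active promoters exclude any cross-line overlap", {
  mk <- function(start, end, state) gr0("chr1", start, end, state = state)
  lines <- list(
    K = gr0(c("chr1", "chr1", "chr2"), c(0, 10000, 0),
            c(2000, 12000, 2000), state = c("Active", "Active", "Active")),
    G = gr0("chr1", 11000, 13000, state = "Weak"),
    H = gr0("chr2", 5000, 7000, state = "Active"))
  sp <- derive_cellline_specific_promoters(lines, "K")
  # promoter 2 removed (Weak overlap in line G); 1 and 3 retained
  expect_equal(bed_coords(sp)$start, c(0, 0))
  expect_equal(length(sp), 2L)
  expect_error(derive_cellline_specific_promoters(lines, "X"), "not in")
  # invariant: zero shared bases with every other line
  for (ln in c("G", "H"))
    expect_equal(union_length(GenomicRanges::intersect(
      sp, lines[[ln]], ignore.strand = TRUE)), 0)
})

test_that("promoter assignment uses 5' windows (both ends when unstranded)", {
  v <- gr0("chr1", 100000, 200000, "+")
  expect_true(assign_promoters_to_vlincs(
    v, gr0("chr1", 96000, 98000, state = "Active"))$any_promoter)
  expect_false(assign_promoters_to_vlincs(
    v, gr0("chr1", 89000, 94000, state = "Active"))$any_promoter)
  # minus strand: 5' boundary is the right border
  vm <- gr0("chr1", 100000, 200000, "-")
  expect_true(assign_promoters_to_vlincs(
    vm, gr0("chr1", 203000, 206000, state = "Active"))$any_promoter)
  expect_false(assign_promoters_to_vlincs(
    vm, gr0("chr1", 96000, 98000, state = "Active"))$any_promoter)
  # unstranded: either boundary counts
  vu <- gr0("chr1", 100000, 200000, "*")
  expect_true(assign_promoters_to_vlincs(
    vu, gr0("chr1", 203000, 206000, state = "Active"))$any_promoter)
  # ltr_driven flows from promoter flags
  prom <- gr0("chr1", c(96000, 97000), c(98000, 99000),
              state = c("Active", "Weak"), ltr_overlap = c(FALSE, TRUE))
  a <- assign_promoters_to_vlincs(v, prom)
  expect_true(a$ltr_driven)
  expect_true(a$active)
  expect_equal(a$n_promoters, 2L)
})

test_that("window assignment equals the point-in-extended-promoters oracle", {
  set.seed(77)
  for (rep in 1:30) {
    v <- random_intervals(15, 1e6, max_len = 2e5, stranded = TRUE)
    v <- v[width(v) > 2e4]
    prom <- random_intervals(40, 1e6, max_len = 4000)
    got <- assign_promoters_to_vlincs(v, gr0(
      as.character(seqnames(prom)), start(prom) - 1, end(prom),
      state = "Active"))$any_promoter
    # oracle: does the 5' boundary point fall inside promoters +/- 5 kb?
    ext <- adjust_boundaries(prom, 5000, 5000)
    pt <- ifelse(as.character(strand(v)) == "+", start(v) - 1, end(v))
    oracle <- vapply(seq_along(v), function(i) {
      any(as.character(seqnames(ext)) == as.character(seqnames(v))[i] &
            start(ext) - 1 <= pt[i] & pt[i] < end(ext))
    }, TRUE)
    expect_equal(got, oracle)
  }
})

test_that("stand-alone calls require > 50 kb clearance and no gene overlap", {
  genes <- gr0("chr1", 0, 10000, "+")
  expect_true(classify_standalone(gr0("chr1", 70000, 130000), genes))
  # exactly 50 kb fails the strict comparison
  expect_false(classify_standalone(gr0("chr1", 60000, 130000), genes))
  expect_true(classify_standalone(gr0("chr1", 60001, 130000), genes))
  expect_false(classify_standalone(gr0("chr1", 5000, 130000), genes))
  # genes on another chromosome do not interfere
  expect_true(classify_standalone(gr0("chr2", 0, 60000), genes))
})

test_that("antisense/bidirectional labels are exclusive and follow orientation", {
  genes <- gr0("chr1", c(60000, 29000, 500000),
               c(160000, 49500, 560000), c("-", "-", "+"))
  v <- gr0("chr1", c(50000, 50000, 580000), c(150000, 59000, 680000),
           c("+", "+", "+"))
  lab <- classify_antisense_bidirectional(v, genes)
  expect_equal(lab[1], "antisense")       # overlaps minus-strand gene
  expect_equal(lab[2], "bidirectional")   # gene 5' (49500) within 1 kb of 50000
  expect_equal(lab[3], "other")           # near a same-strand gene: neither
  expect_equal(classify_antisense_bidirectional(
    gr0("chr1", 50000, 150000, "+")[0], genes), character(0))
  expect_error(classify_antisense_bidirectional(
    gr0("chr1", 0, 60000, "*"), genes), "stranded")
  # standalone-like when far from everything
  far <- gr0("chr1", 1000000, 1100000, "+")
  expect_equal(classify_antisense_bidirectional(far, genes),
               "standalone-like")
  # labels partition the input
  set.seed(13)
  vr <- random_intervals(40, 2e6, max_len = 1e5, stranded = TRUE)
  labs <- classify_antisense_bidirectional(vr, genes)
  expect_true(all(labs %in% c("antisense", "bidirectional",
                              "standalone-like", "other")))
})

test_that("boundary promoter profile peaks where promoters are planted", {
  # no promoters: flat zero
  v <- gr0("chr1", 500000, 700000, "+")
  prof0 <- boundary_promoter_profile(v, GRanges(), 1000, 50000)
  expect_equal(nrow(prof0), 100L)
  expect_true(all(prof0$covered_bases == 0))
  # promoters exactly at each 5' boundary -> central bins maximal
  set.seed(9)
  starts <- seq(2e5, 9e6, by = 3e5)
  vs <- gr0("chr1", starts, starts + 1e5, "+")
  prom <- gr0("chr1", starts - 1000, starts + 1000)
  prof <- boundary_promoter_profile(vs, prom, 1000, 50000)
  central <- prof$covered_bases[prof$offset %in% c(-500, 500)]
  expect_equal(central, rep(1000 * length(vs), 2))
  expect_true(all(prof$covered_bases[abs(prof$offset) > 2000] == 0))
  # minus-strand orientation flip: promoter upstream of the 5' (right) end
  vm <- gr0("chr1", 500000, 700000, "-")
  pm <- gr0("chr1", 703000, 705000)   # 3-5 kb upstream of the 5' end
  profm <- boundary_promoter_profile(vm, pm, 1000, 50000)
  expect_equal(profm$covered_bases[profm$offset %in% c(-4500, -3500)],
               c(1000, 1000))
  expect_true(all(profm$covered_bases[profm$offset > 0] == 0))
})

test_that("uniformly placed promoters give a flat profile within noise", {
  set.seed(101)
  starts <- seq(5e5, 1.9e7, by = 6e5)
  vs <- gr0("synth", starts, starts + 2e5, "+")
  prom_pos <- floor(runif(1000, 0, 2e7 - 2000))
  prom <- gr0("synth", prom_pos, prom_pos + 2000)
  prof <- boundary_promoter_profile(vs, prom, 5000, 50000)
  expected <- 1000 * 2000 / 2e7 * 5000 * length(vs)
  expect_true(all(abs(prof$covered_bases - expected) < expected))
})

test_that("low-alignability flags use the upstream mean with clipping", {
  v <- gr0("chr1", c(100000, 300000), c(200000, 400000), "+")
  flat <- gr0("chr1", 0, 1e6, score = 1)
  expect_equal(flag_low_alignability_boundary(v, flat), c(FALSE, FALSE))
  # zero alignability 5 kb upstream of the first region only
  holey <- gr0("chr1", c(0, 95000, 100000), c(95000, 100000, 1e6),
               score = c(1, 0, 1))
  expect_equal(flag_low_alignability_boundary(v, holey), c(TRUE, FALSE))
  # mean over the window decides: half-zero upstream at threshold 0.4
  half <- gr0("chr1", c(0, 97500, 100000), c(97500, 100000, 1e6),
              score = c(1, 0, 1))
  expect_equal(flag_low_alignability_boundary(v, half, threshold = 0.4),
               c(FALSE, FALSE))
  expect_equal(flag_low_alignability_boundary(v, half, threshold = 0.6),
               c(TRUE, FALSE))
  # region at the chromosome start: evaluated over the available span
  v0 <- gr0("chr1", 2000, 60000, "+")
  up0 <- gr0("chr1", c(0, 2000), c(2000, 1e6), score = c(0, 1))
  expect_true(flag_low_alignability_boundary(v0, up0))
  # unstranded: flagged when either end qualifies
  vu <- gr0("chr1", 100000, 200000, "*")
  right0 <- gr0("chr1", c(0, 200000, 205000), c(200000, 205000, 1e6),
                score = c(1, 0, 1))
  expect_true(flag_low_alignability_boundary(vu, right0))
  expect_error(flag_low_alignability_boundary(v, gr0("chr1", 0, 10, score = 2)),
               "\\[0, 1\\]")
})
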