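# Internal flat-interval primitives.
#
# Representation: a numeric 2-column matrix per chromosome, columns (start, end),
# 0-based half-open, start < end. An "iset" is a named list of such matrices
# keyed by chromosome. These back the enrichment space model, where per-element
# eligible-space construction is evaluated thousands of times during Monte-Carlo
# calibration; equivalence with the GenomicRanges route is asserted in tests.

.iv_empty <- matrix(numeric(0), ncol = 2L,
                    dimnames = list(NULL, c("start", "end")))

.iv <- function(start, end) {
  m <- cbind(start = as.numeric(start), end = as.numeric(end))
  m[m[, 1L] < m[, 2L], , drop = FALSE]
}

# Merge intervals separated by <= gap; input need not be sorted unless
# sorted = TRUE (starts non-decreasing), in which case the sort is skipped.
.iv_flatten <- function(m, gap = 0, sorted = FALSE) {
  n <- nrow(m)
  if (n <= 1L) return(m)
  if (!sorted) m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  s <- m[, 1L]
  e <- cummax(m[, 2L])
  new <- c(TRUE, s[-1L] - e[-n] > gap)
  first <- which(new)
  last <- c(first[-1L] - 1L, n)
  cbind(start = s[first], end = e[last])
}

.iv_len <- function(m) if (nrow(m)) sum(m[, 2L] - m[, 1L]) else 0

.iv_union_len <- function(m) .iv_len(.iv_flatten(m))

# Intersection of two flattened, sorted interval matrices.
.iv_intersect <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(.iv_empty)
  # first b with b_end > a_start; last b with b_start < a_end
  lo <- findInterval(a[, 1L], b[, 2L]) + 1L
  hi <- findInterval(a[, 2L], b[, 1L], left.open = TRUE)
  nhit <- pmax(0L, hi - lo + 1L)
  if (all(nhit == 0L)) return(.iv_empty)
  ai <- rep.int(seq_len(nrow(a)), nhit)
  bi <- sequence(nhit, from = pmax(lo, 1L))
  s <- pmax(a[ai, 1L], b[bi, 1L])
  e <- pmin(a[ai, 2L], b[bi, 2L])
  keep <- s < e
  cbind(start = s[keep], end = e[keep])
}

.iv_intersect_len <- function(a, b) .iv_len(.iv_intersect(a, b))

# a minus b (both arbitrary); result flattened.
.iv_subtract <- function(a, b) {
  a <- .iv_flatten(a)
  if (!nrow(a)) return(a)
  b <- .iv_flatten(b)
  if (!nrow(b)) return(a)
  big <- max(a[, 2L], b[, 2L]) + 1
  comp <- cbind(start = c(-1, b[, 2L]), end = c(b[, 1L], big))
  comp <- comp[comp[, 1L] < comp[, 2L], , drop = FALSE]
  .iv_intersect(a, comp)
}

# Complement within [0, L)
.iv_complement <- function(m, L) {
  m <- .iv_flatten(m)
  m <- .iv_intersect(m, cbind(start = 0, end = L))
  if (!nrow(m)) return(cbind(start = 0, end = L))
  s <- c(0, m[, 2L])
  e <- c(m[, 1L], L)
  keep <- s < e
  cbind(start = s[keep], end = e[keep])
}

# Shift boundaries: start - left, end + right, clip to [0, L); drop collapsed.
.iv_adjust <- function(m, left, right, L = Inf) {
  if (!nrow(m)) return(m)
  s <- pmax(0, m[, 1L] - left)
  e <- pmin(L, m[, 2L] + right)
  keep <- s < e
  cbind(start = s[keep], end = e[keep])
}

## iset helpers -------------------------------------------------------------

.iset_map <- function(x, f, ...) {
  out <- lapply(x, f, ...)
  out[vapply(out, nrow, 1L) > 0L]
}

.iset_len <- function(x) if (length(x)) sum(vapply(x, .iv_len, 1)) else 0

.iset_union_len <- function(x) {
  if (!length(x)) return(0)
  sum(vapply(x, .iv_union_len, 1))
}

.iset_binop <- function(a, b, f) {
  chroms <- union(names(a), names(b))
  out <- lapply(chroms, function(ch) {
    ma <- if (!is.null(a[[ch]])) a[[ch]] else .iv_empty
    mb <- if (!is.null(b[[ch]])) b[[ch]] else .iv_empty
    f(ma, mb)
  })
  names(out) <- chroms
  out[vapply(out, nrow, 1L) > 0L]
}

.iset_subtract <- function(a, b) .iset_binop(a, b, .iv_subtract)

.iset_intersect_len <- function(a, b) {
  chroms <- intersect(names(a), names(b))
  if (!length(chroms)) return(0)
  sum(vapply(chroms, function(ch)
    .iv_intersect_len(.iv_flatten(a[[ch]]), .iv_flatten(b[[ch]])), 1))
}

.iset_flatten <- function(x, gap = 0) .iset_map(x, .iv_flatten, gap = gap)

# genome: named numeric vector of chromosome lengths
.iset_complement <- function(x, genome) {
  out <- lapply(names(genome), function(ch) {
    m <- if (!is.null(x[[ch]])) .iv_flatten(x[[ch]]) else .iv_empty
    .iv_complement(m, genome[[ch]])
  })
  names(out) <- names(genome)
  out[vapply(out, nrow, 1L) > 0L]
}

## GRanges <-> iset ----------------------------------------------------------

.gr_to_iset <- function(gr) {
  if (!length(gr)) return(structure(list(), names = character(0)))
  ch <- as.character(GenomeInfoDb::seqnames(gr))
  s <- GenomicRanges::start(gr) - 1
  e <- GenomicRanges::end(gr)
  out <- lapply(split(seq_along(gr), ch), function(i)
    cbind(start = s[i], end = e[i]))
  out
}

.iset_to_gr <- function(x, strand = "*") {
  if (!length(x)) return(GenomicRanges::GRanges())
  n <- vapply(x, nrow, 1L)
  if (sum(n) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = rep(names(x), n),
    ranges = IRanges::IRanges(
      start = unlist(lapply(x, function(m) m[, 1L]), use.names = FALSE) + 1,
      end = unlist(lapply(x, function(m) m[, 2L]), use.names = FALSE)),
    strand = strand)
}
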