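---
title: "Calling vlincRNAs and testing their promoter associations: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling vlincRNAs and testing their promoter associations: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlincscan)
```

# The analysis in one paragraph

Very long intergenic non-coding RNAs (vlincRNAs) are regions of 50 kb and
more of contiguous RNA-seq coverage outside annotated genes. `vlincscan`
calls such regions from coverage, asks whether chromatin-state promoters
(and LTR retroviral repeats inside them) concentrate at the regions' 5'
boundaries far beyond chance, and quantifies how strongly LTR-driven
regions are up-regulated in malignant and pluripotent samples. The null
model for "beyond chance" is the load-bearing piece and is described in
detail below.

# Region calling

## Contig caller (strand-specific)

Input is the coverage-contig dialect: BED with at least nine columns, where
column 9 holds the number of bases covered by reads within the contig.
The caller is four set operations:

1. drop every contig sharing at least one base with a gene body on the
   *same* strand (a gene on the opposite strand is treated as intergenic —
   the data are strand-specific);
2. merge contigs separated by at most `merge_gap_1` (default 1000 bases);
3. keep merged blocks at least `min_length` long (default 50,000 bases —
   the defining length cutoff of the transcript class);
4. merge survivors separated by at most `merge_gap_2` (default 5000
   bases).

"Gene body" means the full transcription-start-to-end span: exons plus
introns together are exactly that span, so no exon structure is needed.

## Density caller (non-strand-specific)

For platforms without strand information the input is a per-base density
track (BedGraph). Gene positions (either strand) are removed *first*, then
a density threshold is computed as the nearest-rank percentile
(`density_percentile`, default 0.80) of per-base density **over positions
with non-zero density**. Including the silent majority of the genome would
drive any percentile below the expressed fraction to zero and make the
threshold vacuous; nearest rank avoids interpolation ambiguity. Both
choices are overridable. Surviving positions are merged across gaps of at
most `density_merge_gap` (500 bases in `"blood"` mode, 1000 in `"mouse"`
mode) and regions of at least `min_length` are reported, unstranded.

## Boundary semantics

All file I/O is BED-convention 0-based half-open; internally intervals
live in `GenomicRanges` (1-based closed) with identical semantics. Two
consequences worth stating: touching intervals do **not** overlap, and a
merge gap of `g` joins intervals whose half-open separation is `<= g`
(touching intervals always merge). Boundary adjustment clips to chromosome
bounds and silently drops intervals that collapse to nothing — planted
edge cases in the tests pin both behaviours.

# The overlap-enrichment null

Each tested region `i` (length `L_i`) contributes one Bernoulli trial:
does its 10 kb boundary window (±5 kb around the 5' end for stranded
regions; either of the two boundary windows for unstranded ones) overlap a
promoter? The success probability under the null places the region's
boundary uniformly over the part of the genome where an intergenic region
of that length could actually sit:

* **Anti-space** — gene bodies plus blacklisted intervals (for the
  LTR-family procedures also inter-gene gaps shorter than 50 kb), *minus*
  any bases overlapping the tested regions themselves (the tested regions
  prove those bases transcribable).
* **Space_i** — the genome minus the anti-space intervals after extending
  each interval's upstream-side boundary by `L_i` (a region of length
  `L_i` whose 5' end fell there would collide with the anti-space). The
  set-vs-set procedure extends both sides by `L_i/2`.
* **Occupied_space_i** — the part of `Space_i` covered by promoters
  extended 5 kb per side. Testing "boundary window overlaps promoter" is
  identical to testing "boundary point falls in the promoter set extended
  by the window half-width"; a property test asserts the equivalence on
  random instances.
* `p_i = |Occupied_space_i| / (|Space_i| − V)` with `V` the total tested
  length. Subtracting `V` acknowledges that `N` regions are tested at
  once and makes the p-value an upper bound; a test asserts that removing
  the correction can only make the p-value smaller.

With `m = Σ p_i`, the p-value is `P(X ≥ n)` for `X ~ B(N, m/N)`, computed
through `stats::pbinom` (regularized incomplete beta) in log space — the
reported `log10_p` stays finite at any realistic depth. The unstranded
variant combines the two boundary orientations per region as
`p_i = 1 − (1 − p_i⁺)(1 − p_i⁻)`.

**LTR-family procedures.** VlincRNA promoters are the promoters (all
states) overlapping 10 kb windows centered on 5' edges. Same-family LTRs
collapse into one cluster when they lie in the same promoter or in
promoters of the same region (an LTR spanning several promoters is split
into its overlap fragments first); LTRs outside promoters are singletons.
The success probability is the length ratio of vlincRNA promoters to the
promoters overlapping the eligible space, `n` and `N` count clusters
hitting each set, and the tail is `P(X ≥ n), X ~ B(N, p)`. The stranded
variant computes everything per strand relative to the region's strand and
reports `P(X ≥ n⁺ + n⁻)` under `B(N⁺ + N⁻, max(p⁺, p⁻))` — an explicit
upper bound on the exact two-binomial convolution, and the property the
test suite asserts. It is *not* ordered in general against the unstranded
p-value: the per-strand vlincRNA-promoter sets are roughly half of the
unstranded ones while the space-promoter sets are not, so with
sense-seeded LTRs the stranded statistic can be the more significant one.

**Numerical guard rails.** `p_i` and `m/N` are clamped to `[0, 1]`: on
desk-scale genomes the boundary extensions and the `−V` correction can
push them out of range. When `|Space_i| − V ≤ 0` the procedure refuses to
produce a number (`degenerate space`) rather than silently report one —
the correction presumes the tested catalogue is small relative to the
genome, which holds at real genome scale but must be respected when
choosing simulation sizes (see below). Element order never matters; a
shuffle test asserts it.

## What the calibration shows — and at what size

The suite's calibration check redraws subject features uniformly in
eligible space 500 times for each of the five procedures and verifies
`P(p < α) ≤ α + 3·SE` at α = 0.05 and 0.01 — conservativeness, not
exactness, which is what an upper-bound construction promises. The
fixture is one 20 Mb chromosome with 24 planted regions of 50–150 kb and
equal-length promoters. Two sizing notes, both the package's own choices:
regions much longer than ~150 kb on a 20 Mb genome push `V` past the
per-element eligible space and trip the degenerate-space guard (at real
genome scale the same catalogue is a negligible fraction of the genome);
and equal promoter lengths make the LTR procedures' length-ratio success
probability exact rather than approximate, isolating what the check is
meant to measure.

# Expression quantification

`value = raw × (2·10¹⁰ / sample_total) × (10⁶ / region_length)`, where
`raw` sums base counts of contigs sharing at least one base with the
region (strand-specifically when both carry strand; a contig straddling a
boundary contributes its full count — a proportional-attribution option
exists but defaults off). Contigs with more than 10⁶ counted bases are
removed first as artifacts (rRNA/snRNA-type pileups); the depth
denominator is the post-filter contig total (the source procedure does not
state the denominator; this is configurable). Zeros are replaced by the
dataset-wide minimum non-zero value before any ratio. Specificity indices:
highest/second-highest expresser (tissue specificity) and
target/max-of-others (cell-line specificity). The stratified summary
reports arithmetic means (geometric optional) of max-cancer /
immortalized / embryonic-stem over max-primary ratios within the
LTR-driven and non-LTR strata.

The intron/exon ratio uses mean per-base densities (not totals), so
transcript length does not confound; single-exon transcripts and
transcripts with zero exonic density are excluded from the reported
median.

# The synthetic-data generator

`sim_params()` defaults define the study conditions: 2 × 20 Mb
chromosomes, 120 genes (2–50 kb, log-uniform), six cell lines (two
malignant, one immortalized, two primary, one embryonic-stem), five
planted regions per line with log-uniform lengths 50 kb–1 Mb, an Active
promoter spanning every planted 5' boundary in the source line, and an
embedded sense-strand LTR of one designated family with per-group
probability 0.30 / 0.10 / 0.03 / 0.30 (malignant / immortalized / primary /
embryonic-stem) against a 2% background rate in decoy promoters — an
order-of-magnitude malignant-over-primary gradient. Expression is
log-normal: high in the source line, low-with-dropout elsewhere, and
LTR-driven regions sourced in malignant or embryonic-stem lines get a
×10 boost (`ltr_skew`), which the stratified ratio summary recovers within
25% at 500 regions in the tests. One master seed drives named substreams
(layout / promoters / repeats / blacklist / expression / per-sample
tracks), so regenerating one layer does not perturb the others, and
chromosome names carry a reserved `synthchr` prefix so synthetic files
cannot be mistaken for real annotation.

Contig tracks tile each expressed region exactly from its start to its
end with gaps strictly below `merge_gap_1`, so the caller's zero-noise
recovery is exact by construction — that is the point of the fixture, and
the planted features are kept `min_separation` (6 kb) apart so no two
regions can merge. Density tracks add uniform noise whose value sits
strictly below the weakest expressed region and whose total base count is
chosen so that the 80th-percentile threshold lands exactly at that
weakest region's density — the stated "noise below the threshold by
construction". With *no* noise and heterogeneous expression, an
80th-percentile-of-signal threshold necessarily truncates the weakest
regions; the noise-free recovery check therefore uses equal planted
expression, which is the honest reading of that boundary condition.

What the generator does **not** emulate: read-level sampling noise and
mappability structure, splicing, overlapping genes and promoters of real
annotation density, chromosome-scale heterogeneity, and any sequence
content. Passing tests demonstrate the pipeline's contracts and the null
model's calibration under these idealized conditions — they do not certify
recovery rates on real libraries, where boundary precision is limited by
coverage depth and alignability (which is why the low-alignability flag
exists).

# Known limitations

* Enrichment p-values are reported raw, per subject set; no
  multiple-testing correction is applied across families or cell lines
  (an optional Bonferroni column exists in the pipeline report only).
* The binomial null treats regions as independent trials; clustered
  catalogues violate this in the direction the `−V` correction is meant
  to absorb, which is why the construction is an upper bound rather than
  exact.
* The "bidirectional" class needs a definition the source material never
  gives: here, a non-antisense region whose 5' end lies within
  `divergent_window` (default 1000 bases) of an opposite-strand gene's 5'
  end in head-to-head orientation. The default is a judgement call and is
  exposed as a parameter.
* Cell-line-specific region sets are defined as "called in the target
  sample with cell-line specificity index above a cutoff (default 5)" —
  also a parameterized reading of an inherited, unstated criterion.
* `Li/2` extensions in the set-vs-set procedure are kept in exact
  (possibly half-integer) arithmetic rather than rounded.
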