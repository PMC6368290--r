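---
title: "Models and methods behind ccrwalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ccrwalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ccrwalk` analyses complex chromosomal rearrangements (CCRs) -
rearrangements involving more than two chromosomes or more than two
breakpoints - from the structural-variant (SV) call sets that
different detection technologies produce.  This vignette explains the
data model, the algorithms, the tunable parameters and their
defaults, the simulator that the test suite is built on, and the
design decisions taken where the problem was genuinely open.

## The data model

The atom of the analysis is the **breakpoint junction**: the novel
adjacency joining two breakends in a derivative chromosome.  A
junction record holds two oriented breakends - chromosome, 1-based
position, and a *retained side* stating which reference direction
(`pter` or `qter`) continues into the derivative at that end -
plus nucleotide-level evidence at the join: a microhomology string, a
non-templated insertion, or neither (blunt).  Microhomology and
insertion are mutually exclusive on one junction.

Coordinates are 1-based inclusive throughout, matching the
coordinate frame in which breakpoint tables are printed; BED input is
converted on read.  Interval sizes use the difference convention
`end - start`, which matches VCF `SVLEN = END - POS` and reproduces
every published Mb-scale deletion size at one-decimal rounding (the
inclusive convention rounds identically at that precision, so the
choice is immaterial for reporting but fixed for internal
consistency).

SV calls are technology-agnostic records (type DEL / DUP / INS / INV
/ BND / UNKNOWN, two breakpoint coordinates, size, quality flag,
supporting read pairs and split reads, source label).
Normalization orders chromosomes by genome order and positions
ascending, and is idempotent.

## Breakpoint clustering

The two sides of one physical breakpoint are reported at slightly
different positions by different junctions, because a few bases are
lost or shared at each join.  The number of distinct breakpoints is
therefore computed by **single-linkage clustering** of all junction
endpoints per chromosome.  The default tolerance is **200 bp**:
in the case studies the paired sides of one breakpoint differ by
1-119 bp, so 200 bp merges them while staying far below the smallest
genuine inter-breakpoint distance (about 2.2 kb).  The count is
invariant under permutation of the junctions and under endpoint
jitter well below the tolerance.

On the most complex case table (26 junctions, 52 endpoints on one
chromosome) this procedure yields 34 breakpoints, one more than the
published count of 33.  The two tallies cannot be reconciled at any
defensible tolerance: 33 is only reachable by merging the two flanks
of a 2 kb deletion, which are unambiguously distinct breakpoints.  We
report the computed value; the tolerance sweep in
`analysis/01_breakpoints.R` documents the discrepancy.

## Junction sequence analysis

Given the two reference flanks (each oriented as traversed in the
derivative) and the sequenced derivative junction,
`detect_microhomology()` computes `p`, the longest common prefix of
the derivative with flank A, and `s`, the longest common suffix with
flank B.  With derivative length `D`, `m = p + s - D` decides the
parse: `m > 0` is microhomology of length `m` (shared verbatim by
both flanks abutting their breakpoints), `m = 0` is blunt, `m < 0` is
a non-templated insertion of length `-m`.  When both a homology and
an insertion parse could explain a join, this rule automatically
prefers the parse with the shorter insertion, ties going to
microhomology - the two are treated as exclusive categories, as
junction tables print them.

The search window is **50 nt**: longer homology means the junction
is likely repeat-mediated and cannot be localized, so it is reported
as unresolvable rather than silently mis-parsed.  The implementation
is checked against an independent exhaustive-split oracle that tries
every microhomology and insertion length; on planted junctions
recovery of the planted signal is exact, by construction of the
parse (the flanks cap `p` and `s`, so chance extension is
impossible).

Repeat context uses a **closed ±100 bp window** around each
breakend ("within 100 bp" without boundary semantics is read
inclusively).  Junctions whose breakpoints are flagged *estimated*
print `N.i.` in the sequence columns - an approximate breakpoint has
no meaningful junction sequence - and are excluded from resolution
statistics but included in detection counts.

## Derivative reconstruction

Reconstruction builds a **breakpoint graph**: every involved
chromosome is cut at each breakpoint cluster, giving segments;
junctions attach pairs of segment ends according to their breakend
orientations; chromosome ends are telomere nodes.  Because the two
sides of a cluster carry their own coordinates, segment boundaries
use the per-side breakend position, so micro-losses (or few-bp
micro-duplications) at junctions fall out of the conservation
accounting naturally; placed fragments overlapping by more than the
clustering tolerance raise an inconsistency error.

`walk_derivatives()` starts at each unconsumed telomere and
alternates segment traversals with junction adjacencies until
another telomere is reached; fragment orientation comes from the
traversal direction.  A segment end claimed by two junctions is an
ambiguity error naming the junctions; a walk that exhausts its edges
without reaching a telomere is an error unless it closes on itself,
in which case it is returned as a **ring** derivative (ring products
are first-class outputs, rendered with a `ring` suffix outside the
printed grammar).  Segments touched by no junction and no telomere
are the deleted fragments; `infer_deleted_intervals()` recovers them
as the complement of all placed fragments, merging adjacent pieces.

Each derivative is canonicalized so that the **longest unbroken
reference run** comes first; both p-ter- and q-ter-anchored
derivatives are legal, as published karyotype strings use both.

## Karyotype notation

`render_karyotype()` emits the `seq[<build>]` notation:
one `g.[...]` block per derivative, segments joined by `::`;
telomere-anchored segments `chrN:pter_cen_<pos>` /
`chrN:qter_cen_<pos>` when they span the centromere, terminal
segments `chrN:<pos>_qter` / `chrN:<pos>_pter`, internal segments
`chrN:<start>_<end>` with an `inv` suffix when inverted.

Two conventions deal with interstitial deletions (a deletion
junction joining two same-chromosome, same-orientation runs): the
flanking runs are collapsed into one directional run, and the skipped
interval is annotated as `<posA>_<posB>del` inside the block that
carries that chromosome's centromere.  This is the only convention
we found that reproduces the published strings of both
interchromosomal cases verbatim - the del annotation is printed in
the centromere-bearing derivative block even when the deleted
material travelled with the other derivative.  Deletions lying
*between* translocation breakends (not spanned by any deletion
junction) are simply absent from the string, again matching the
published usage.  The parser reverses both conventions: del tokens
take their chromosome from the nearest preceding segment, and any
run spanning an annotated deletion is re-split around it, so
parse-render round-trips preserve fragment order and orientation
exactly.

## Call-set concordance

Two calls are **similar** when their interval overlap *exceeds* a
Jaccard index of 0.4 (strict, as worded) *and* both corresponding
breakpoint distances are *less than* 100 kb (strict).  Jaccard uses
the difference size convention and is checked against a base-counting
oracle.  For interchromosomal (BND) pairs an interval Jaccard is
undefined; similarity reduces to chromosome-pair identity plus the
per-end distance rule - the only reading under which one criterion
applies "across all comparisons".

Merging is greedy with a deterministic seed order (sorted by
chromosome, position, source): each call joins the first cluster
whose representative it matches.  The published behaviour of SV
merging tools is unspecified on ties, so determinism and
idempotence were prioritized.  Overlap matrices count, for each row
set, calls similar to at least one call of the column set, with the
row set as denominator - the convention recovered from the printed
percentages (626/883 = 70.9%).

The post-calling filter mirrors a short-read SV pipeline, applied in
order: quality flag `PASS` only; frequency (drop anything found in
the population database); small intergenic events (<10 kb, strict);
minimum support (<8 supporting pairs + split reads dropped, so
exactly 8 is kept).  Ranking sorts by frequency ascending, support
descending, then size descending for intrachromosomal calls with
position as the final tie-break ("size, or chromosomal position" is
read as: size where defined, position otherwise and on ties).

## The simulator and the emulators

`simulate_ccr()` generates rearrangements with known truth on a toy
three-chromosome genome (180/120/90 Mb): chromosomes are cut at
random breakpoints (at least 100 kb from ends, at least 5 kb apart),
interior fragments are deleted with probability `p_delete_fragment`
(default 0.15 - a minority of fragments, matching the observed
pattern), survivors are randomly ordered and oriented
(`p_invert = 0.5`, reflecting random inverted/non-inverted joins),
and one linear derivative is assembled per involved chromosome.
In `chromothripsis_mode` all breakpoints fall on one chromosome -
single catastrophic shattering with random rejoining.  Planted
junction evidence uses microhomology lengths 0-6 nt (mass at 0,
spread over 2-6, the observed range) and occasional short
non-templated insertions (`p_insertion = 0.08`, roughly the observed
1-2 junctions in 35).  Flanks are uniform random DNA rather than
reference sequence: the generator then controls the planted signal
exactly, which is what parameter-recovery tests need.

Conservation holds by construction: placed fragments plus deleted
intervals tile every involved chromosome without overlap, and the
noiseless round-trip (simulate, emulate without error, reconstruct)
recovers fragment order, orientation and deleted intervals exactly.

`emulate_technology()` degrades the truth through a
`technology_profile()`: junctions dropped at `fn_rate` (multiplied
inside repeat elements, capped at 1), Gaussian integer jitter on
surviving breakends, a minimum detectable size, and a type-reporting
map.  Jitter is symmetric Gaussian because the real per-technology
error distributions are not published; the benchmark only needs a
controllable median, and the half-normal median `0.674·sigma` gives
the recovery target.  The four built-in profiles are qualitative
stand-ins chosen once: paired-end and linked reads at base-pair
resolution with split-read support; mate-pair at `sigma = 600 bp`
(pooled median ≈ 400 bp) without split reads; optical maps at
`sigma = 10.7 kb` (median ≈ 7.2 kb), blind below 15 kb (a 12 kb
inversion is invisible to them), reporting duplications as
insertions and short-read technologies with a 5-fold elevated miss
rate inside repeats.  No quantitative per-technology error model is
published; these parameters reproduce the qualitative detection,
resolution and type-bias patterns and are not fitted to anything.

## Benchmarking

A detection table holds, per truth junction and technology, the
reported coordinates or a miss.  Detection and false-negative rates
are plain counts (percentage rounded to integer).  **Resolution** is
the median of the pooled per-end absolute distances over all
detected, non-estimated junctions.  The pooled-per-end reading with
the standard median (mean of the two central values on an even pool)
is the only combination that reproduces both published resolution
values from the published detection table (400 bp mate-pair, 7.2 kb
optical); the lower median gives 7.0 kb for optical maps, so it was
rejected.  Reported values render to the nearest 100 bp below 1 kb
and as kb with one decimal above.

Truth matching for emulated call sets assigns each truth junction
its nearest candidate (summed end distance) with the matching
chromosome pair and both ends within a 100 kb window; a relaxed mode
allows one end up to a configurable slack, since published detection
tables contain such assignments (one optical entry is several Mb off
on one end).  The slack default is deliberately conservative and
exposed as an argument.

## Problem sizes and runtime

The test suite runs the full stack at desk scale: 100 simulation
seeds (up to 50 breakpoints, chromothripsis included) for the
round-trip property, 10,000 random interval pairs against the
Jaccard oracle, 500 planted junctions against the exhaustive-split
oracle, and 500 pooled emulated junctions for parameter recovery.
These sizes make every stochastic check statistically comfortable
(binomial 3-SD bands, median concentration) while the whole suite
completes in a few minutes on one core.

## What the simulations do and do not show

The generator produces uniform random DNA, uniformly placed
breakpoints, and independent per-junction errors.  Real genomes
violate all three: breakpoints cluster in repeats and fragile sites,
flanks contain homology that can make junctions unresolvable, and
caller errors are correlated (systematic biases per region, not
i.i.d. drops).  Passing the round-trip and recovery tests therefore
shows the *machinery* is correct - walks, conservation accounting,
similarity logic, medians - not that any technology's real-world
sensitivity equals the emulated one.  Genome-scale published
comparisons (tens of thousands of calls against population
databases) require the original raw data and are out of scope; the
corresponding procedures are validated here on planted fixtures with
known answers instead.

## Known limitations

- Reconstruction requires breakend orientations; junction tables
  without them (or with shared endpoints between junctions, as the
  most complex case exhibits) cannot be walked and are handled by
  the clustering/summary layers only.
- Ploidy and phasing are outside the model: every junction is
  assumed to belong to the single rearranged haplotype.
- The similarity criterion treats calls pairwise; transitive
  merging can chain dissimilar calls through intermediates, as in
  any greedy single-linkage merge.
- Karyotype strings for ring derivatives use an extension (`ring`
  suffix) outside the published grammar.
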