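---
title: "Comparative plastome analysis with plastocomp: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome analysis with plastocomp: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`plastocomp` implements the standard comparative workflow for circular
quadripartite chloroplast genomes: partitioning a plastome into
LSC/IRb/SSC/IRa and profiling the genes at the four IR/SC junctions;
finding and classifying tandem, dispersed and palindromic repeats;
extracting and aligning homologous coding and noncoding regions across
annotated genomes; computing p-distances, per-region variability and
parsimony-informative-site statistics with a hypervariable-marker screen;
coding exon indels as binary characters; and maximum-parsimony inference
with bootstrap support and majority-rule consensus. A fully seeded
synthetic plastome simulator supplies families with complete ground truth
so that every stage can be validated end to end without any external
data.

This vignette records the models, the parameters that matter, the
numerical conventions, and the design decisions taken where a choice was
genuinely open. Everything quantitative stated here is computed by the
package's test suite or by `scripts/acceptance.R`; no external result is
restated.

# Coordinates and containers

All coordinates are 0-based half-open, converted from GenBank's
1-based-inclusive convention only at the file boundary. On a circular
record an interval whose `end` exceeds the genome length wraps through
the origin; all interval arithmetic (feature extraction, junction
distances, repeat deduplication) is performed modulo the genome length.
Sequences are uppercase over `{A,C,G,T,N}`; ambiguity codes other than
`N` are rejected at parse time because every downstream statistic assumes
four states. Alignments (`msa`) are equal-length gapped rows whose
degapped content is guaranteed to reproduce the extracted source
sequences; this invariant is tested property-style.

# Quadripartite structure

The inverted repeats are detected as the maximal-length pair of disjoint,
*exactly* reverse-complementary segments of at least `min_ir_len` bp
(default 1000 bp — plastome IRs are an order of magnitude longer, while
dispersed inverted repeats are two orders shorter, so the default sits in
a wide safe band). Exact matching reflects how plastome assemblies
represent the IR: the two copies are stored identical, and junction
positions are meaningful at single-base resolution. Near-identity
extension is deliberately out of scope.

Detection seeds exact k-mer matches between the genome and its reverse
complement on the doubled sequence (so IRs spanning the origin are found)
and extends seed runs to maximal exact matches. The longer single-copy
arc becomes the LSC; when both arcs are equal the arc free of rRNA genes
is taken as LSC, with the lower coordinate breaking remaining ties, so
output is deterministic. Junctions are named J_LB (LSC/IRb), J_SB
(IRb/SSC), J_SA (SSC/IRa) and J_LA (IRa/LSC).

Junction profiling reports, per gene of interest, the bases by which it
extends into an IR (for genes such as *rps19* at J_LB and *ycf1* at J_SA,
whose truncated second copies appear as pseudogenes on the opposite
border), or its distance to the nearest IR border when it lies wholly in
a single-copy region (*ndhF*, *trnH*). A profiled gene absent from the
annotation is reported as missing, not an error, because junction tables
are routinely built across heterogeneously annotated records.

# Repeat detection

The three repeat classes share one similarity model: two copies count as
a repeat when their Hamming distance is at most `max_mm` (default 3)
*and* their identity (matches/length) is at least `min_ident` (default
0.90), with no indels inside a copy. Type-specific minima are 15 bp total
span for tandem arrays, 30 bp for dispersed repeats and 20 bp for
palindromic repeats, and palindromic copies may be separated by at most
3 kb. A hit is *maximal*: flush against mismatches (or sequence ends) on
both sides and not contained in a longer valid hit — the automated
equivalent of the manual redundancy filtering that repeat-finder output
normally requires.

Search is seed-and-extend. The seed size is the largest k that cannot
miss a valid window: a window of length L with q mismatches contains an
exact run of at least `ceiling((L - q)/(q + 1))` bases, and the identity
constraint forces `L >= q/(1 - min_ident)` before q mismatches are
admissible at all; minimising over q gives k = 7 for dispersed and k = 6
for palindromic defaults. (The often-quoted `ceiling(min_len/(max_mm+1))`
bound ignores the interaction of the two constraints and can miss
mismatch-saturated windows, so it is not used.) A vectorised triage step
then discards seed matches around which no qualifying fixed-length window
fits, which removes almost all random seed noise before the exact
maximal-window machinery runs; the triage tests are implied by the
validity conditions, so no hit can be lost. On the desk-scale genomes
used throughout the test suite a full scan takes seconds; full-size
(~156 kb) plastomes take a few minutes.

Whole-genome scans run on the doubled sequence and deduplicate modulo the
genome length, so repeats spanning the origin are found and the scan is
rotation-invariant. Both IR copies are scanned; hits that are merely the
IRa/IRb duplication itself (longer than 10 kb, or mapping onto themselves
under the IR mirror when a partition is supplied) are excluded from
repeat statistics. Overlapping hits of one type merge into a single
motif, and a region claimed by several types is emitted once under the
precedence tandem > dispersed > palindromic; only the tandem-over-
dispersed rule is biologically motivated (a tandem array always also
matches the dispersed definition), the rest of the order simply makes the
output deterministic. Merging is idempotent. Context annotation calls a
hit `coding(gene)` when the midpoint of its first copy lies inside any
gene feature under half-open containment.

The exhaustive oracle in the test suite re-derives the same definition by
enumerating *every* diagonal window of every length on sequences of a few
hundred bases; the finders must reproduce the oracle's hit set exactly,
including planted repeats at known coordinates.

# Homology extraction and alignment

Homologous regions are anchored on a reference annotation: every gene
shared by all records, every intron of shared multi-exon genes (reading
order is strand-aware, so minus-strand introns are extracted and
orientated correctly), and every intergenic spacer between
reference-consecutive genes, named `geneA-geneB` in reference order.
IR-duplicated genes contribute one copy — the IRb copy whenever a
partition can localise the duplicates, per record, so spacer coordinates
stay consistent across taxa. A spacer longer than five times its
reference length (plus 1 kb) in some taxon is treated as evidence of
non-colinearity and dropped with a warning rather than force-aligned.

Alignment is a built-in progressive aligner rather than an external
program: pairwise and profile-profile steps use global affine-gap dynamic
programming (Gotoh) over 4-letter frequency profiles with sum-of-pairs
column scoring; the guide tree comes from shared k-mer distances (k = 8)
by neighbour joining; a gap once opened is never removed. Scoring
defaults are +1/-1 with gap open -4 and extension -1 (a gap of length l
costs `open + (l-1) * ext`) — a common DNA default, configurable, since
nothing downstream is calibrated to a particular scheme. Ties in the DP
break deterministically (diagonal, then up), so alignments are
reproducible to the byte. Column-level agreement with any particular
external aligner is *not* claimed; all downstream statistics are defined
on whatever alignment is supplied, and the acceptance pipeline uses the
built-in aligner throughout. Whole-genome alignments are produced as
annotation-anchored concatenations of per-region alignments, which keeps
the problem tractable and the partition table exact.

# Divergence statistics and the marker screen

p-distance is the uncorrected mismatch proportion per pair. Complete
deletion (every column containing a gap or `N` anywhere is dropped for
all pairs) is the default everywhere, mirroring the convention of
excluding alignment-introduced gaps from phylogenetic statistics;
pairwise deletion is available. A column is *variable* when at least two
distinct bases occur and *parsimony-informative* when at least two bases
each occur in at least two taxa; percentages are taken over the full
aligned length, so the mutation-event proportion is `(NS/L) * 100` with
NS the variable-site count — the count of substitution events that is
computable from an alignment without ancestral-state inference.

The marker screen restricts to single-copy regions (IR regions
accumulate point mutations more slowly and would dilute the ranking) of
at least 350 bp in the reference, retains regions whose percentage of
variable sites exceeds 5%, and ranks them by decreasing variability with
alphabetical tie-breaking. The companion regression of percent
parsimony-informative sites on percent variable sites is ordinary least
squares with the usual two-sided slope test.

# Indel coding and parsimony

Exon indels are coded by simple indel coding: every distinct maximal gap
run with identical start and end columns is one binary
presence/absence character; nested or overlapping runs with different
coordinates are distinct characters; terminal runs are ignored as
missing data. Simple indel coding was chosen over complex coding because
it is the standard deterministic scheme and requires no arbitration of
overlapping events. "Potentially informative" means
parsimony-informative (at least two taxa in each state), matching the
matrix's use.

Parsimony uses the Fitch two-pass algorithm over unordered states with
bitmask state sets; `?`, `-` and `N` join any state. Tree length is
computed on the tree re-rooted along a terminal edge, where Fitch is
exact, and is invariant to the rooting choice (tested). Exhaustive search
enumerates all `(2n-5)!!` unrooted binary topologies by stepwise edge
insertion and is the authority up to 10 taxa. The heuristic search uses
random stepwise addition followed by hill-climbing branch swapping (NNI
or SPR on the subtree away from a reference tip; because the addition
order and hence the reference tip are randomised per replicate, the
union of neighbourhoods over replicates covers the tree space well, and
exhaustive search bounds the answer wherever it is feasible). All
equally parsimonious trees found are kept, capped at a configurable 1000
distinct topologies with a message when the cap is hit. Site patterns
are compressed and parsimony-uninformative patterns contribute their
fixed minimum steps as a constant, which makes search cost independent
of alignment length.

Bootstrap support resamples columns with replacement; each replicate is
analysed by a compact heuristic search, and a split is credited when it
appears in *all* of the replicate's shortest trees (the conservative,
strict-consensus convention). Majority-rule consensus tallies splits
(keyed canonically by the side not containing the reference taxon) and
keeps those with frequency strictly above the cutoff; retained splits at
>50% are mutually compatible, so the tree is assembled by nesting
clades. CI and RI use the textbook definitions summed over all columns,
uninformative ones included, with per-column minimum `states - 1` and
maximum `non-missing taxa - largest state frequency`; RI is reported as
missing when the matrix carries no informative variation. Zero-length
branches are not collapsed in reported trees; their effective absence is
visible as near-zero bootstrap support instead, which keeps every
reported tree strictly binary and scoreable.

# The synthetic plastome family simulator

The simulator is first-class, tested code, and its defaults define the
conditions under which the package validates itself:

* **Genome**: 20 kb desk-scale quadripartite genome (LSC 12 kb, IRs
  3 kb, SSC 2 kb) — two orders of magnitude faster to analyse than a
  real ~156 kb plastome while preserving every structural element the
  pipeline touches. The layout scales with the configured region
  lengths.
* **Layout**: ~15 unique genes including a *trnH*-like gene 10 bp from
  J_LA, an *rps19*-like gene crossing J_LB with 49 bp inside the IR
  (within the 38–52 bp band typical of asterid plastomes) and a
  truncated pseudo copy at the opposite border, a *ycf1*-like gene
  crossing J_SA with its 3' end in the IR and a pseudo copy at J_SB, an
  *ndhF*-like gene 40 bp from J_SB, rRNA/tRNA genes duplicated in the
  IR, and two spliced genes (one minus-strand) so intron extraction is
  exercised.
* **Planted repeats**: one tandem array (12 bp unit, two copies), one
  40 bp dispersed pair and one 24 bp palindromic pair with a 60 bp gap,
  all in intergenic spacers and all registered in the truth bundle.
* **Evolution**: Jukes–Cantor substitutions as a Poisson event process
  (rate 1 per site per unit branch length, uniform target base — the
  closed-form JC divergence expectation holds exactly and is verified
  distributionally), plus insertions/deletions at `indel_rate` (default
  0.1 relative to substitutions) with geometric lengths (p = 0.35,
  capped at 24 bp). Only LSC+IRb+SSC evolve; IRa is regenerated as the
  exact reverse complement of each descendant's IRb, so IR copies
  co-evolve as they do through biological copy correction. Indels avoid
  planted repeats and the junction-spanning genes (a flagged margin of
  5 bp), so the structural ground truth stays checkable; substitutions
  are unrestricted. One consequence worth noting: the simulator does
  *not* reproduce the empirically slower IR substitution rate — IR
  columns evolve at the genome-wide rate — so passing tests say nothing
  about rate heterogeneity between regions in real data.
* **Truth bundle**: the rooted tree, the true multiple alignment
  threaded through every indel (its degapped rows reproduce the leaf
  genomes exactly — a hard invariant of the implementation), per-leaf
  junction positions, the planted repeat registry and per-branch
  substitution event counts.
* **Determinism**: a seed is mandatory; one seed yields byte-identical
  families, records, alignments and downstream reports.

Branch lengths are in expected substitutions per site. When no tree is
supplied, a random topology is drawn and scaled so the mean root-to-tip
path equals `sub_rate` (default 0.02, giving pairwise distances of a few
percent — the regime of congeneric chloroplast comparisons).

# Pipeline and reproducibility

`run_pipeline()` chains every stage and emits TSV/JSON reports plus a
manifest with every parameter and the seed; two runs with identical
inputs and seed produce identical reports. Partition datasets follow the
classical seven: whole genome, LSC, SSC, IR, protein-coding genes,
intergenic spacers and introns, assembled by concatenating per-region
alignments according to the reference partition. A failed stage is
recorded in the manifest and skipped, not fatal.

Problem sizes used by the shipped validation runs were chosen to keep a
laptop-scale run comfortable: unit tests use 6–20 kb genomes with 4–8
taxa; the acceptance script simulates an eight-taxon family on the 20 kb
default genome with a fixed tree whose depths mirror a typical
two-clade-plus-outgroup plastome study (ingroup pairwise distances
around 0.005–0.011, a distant outgroup near 0.09), runs the full
pipeline at 100 bootstrap replicates, and reports the quantities it
measured. The same code path scales to full plastomes; only wall-clock
time changes.

# Known limitations

* IR detection is exact-match only; a genuinely polymorphic IR pair
  (differing copies) would be reported at the longest exactly identical
  core.
* The Hamming repeat model admits no indels within a repeat copy, and
  tandem arrays longer than the configured maximum unit (500 bp) are
  not sought.
* The progressive aligner is built for the high-identity regime of
  congeneric plastomes; at deep divergence a dedicated aligner will
  produce better columns, and all column-dependent statistics inherit
  alignment quality.
* Parsimony only: no likelihood or Bayesian inference, no model
  selection, no rate-corrected distances.
* The simulator is colinear by construction — no inversions or gene
  order changes — so rearrangement detection is untested and out of
  scope.
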