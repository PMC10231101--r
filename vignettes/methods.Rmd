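---
title: "Methods: gene-order rearrangement inference and control-region profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-order rearrangement inference and control-region profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

This vignette is the package's own account of its methods: the models and
decision rules, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate,
and the numerical choices that make results reproducible.

## Scope and data model

An annotated mitogenome is a circular DNA sequence plus typed, stranded
gene features over a fixed vocabulary: 13 protein-coding genes, 22 tRNAs
(with the two leucine and two serine isoacceptors distinguished as
trnL1/trnL2 and trnS1/trnS2), the two rRNAs (rrnS, rrnL), and
control-region markers (CR, or CR1/CR2 for a split control region).
Coordinates are 0-based half-open internally; a feature that wraps the
sequence origin carries `end > length` and every consumer normalizes
modulo the length. GenBank's 1-based inclusive convention (and its
`join()` wraparound locations) exists only at the file boundary. Strands
are labelled J (majority) and N (minority), with J equal to the GenBank
plus strand.

## Composition statistics

AT-skew is (A − T)/(A + T) and GC-skew is (G − C)/(G + C), computed on
uppercase sequence with N ignored entirely — in numerators, denominators
and percentage bases. A zero denominator yields `NA` plus an explicit
undefined flag rather than a silent 0, because a skew of 0 asserts
symmetry that an AT-free sequence cannot support. Report-precision
values (skews to 3 decimals, percentages to 1) accompany the raw values
so that tabulated output matches the conventional printed style.
Per-class statistics pool features on their *coding* strand (N-strand
features are reverse-complemented first) into J-strand PCGs, N-strand
PCGs, rRNAs, tRNAs and control regions: strand asymmetry is a property
of the coding strand, so pooling genome-strand sequence would cancel the
signal the statistic exists to measure.

## Junctions and codon classification

The junction table reports, for every adjacent feature pair on the
circle, the signed gap `downstream start − upstream end`; negative gaps
are overlaps and carry the overlapping sequence. The signed gaps close
the circle exactly: feature lengths plus gaps sum to the genome length,
an identity the tests assert on every generated genome.

Start codons are read as the first coding triplet and flagged against
the mitochondrial repertoire ATN, GTG, TTG. Stops are a trailing
TAA/TAG when the gene length is a multiple of three; otherwise a
trailing T or TA is accepted as an incomplete stop (completed to TAA by
polyadenylation) only when the next feature begins within 2 bp on the
coding side — an isolated short remainder far from the neighbouring gene
is more likely an annotation problem than a genuine truncated stop, so
it is flagged unresolved instead.

Codon usage counts complete codons over all 13 PCGs on their coding
strands; incomplete terminal codons are excluded, and stop codons are
counted but excluded from amino-acid percentages. RSCU uses the
invertebrate mitochondrial genetic code (table 5), under which ATA
joins ATG in the methionine family, TGA joins TGG in tryptophan, and
AGA/AGG extend serine to an eight-codon family. The family-sum identity
(RSCU summing to family size) is enforced to 1e-9 in the tests.

## Non-coding region homology

`ncr_homology_scan` asks whether an intergenic spacer is a degraded
duplicate of a neighbouring gene — the signature a duplication-loss
event leaves behind. The spacer is aligned locally against each
candidate gene on both strands with fixed scores: match +1, mismatch −1,
gap open 2, gap extend 1. Identity is matches over alignment columns,
and hits are ranked by alignment score (ranking by identity alone would
favour trivially short perfect matches). The identity floor defaults to
55%, below which hits are dropped and an empty result returned — an
empty result is an answer, not an error. Because percent identity of a
local alignment depends on the scoring scheme, identities produced under
other schemes are comparable only approximately; the scheme is fixed
here precisely so the number is reproducible.

## Signed gene orders, breakpoints and translocations

Gene orders are circular signed permutations linearized at trnI, the
conventional origin of the insect arrangement; equality is
rotation-invariant, so the choice of sequence origin never changes any
result. Control-region markers ride along as positional tokens but are
excluded from permutation arithmetic — a duplicated CR would otherwise
break the one-copy-per-gene invariant — while remaining available for
display, which is what lets a split arrangement like
`rrnS CR1 trnI CR2 trnQ` be rendered faithfully.

Breakpoints count signed adjacencies of one order missing from the
other, orientation-aware: (x, y) matches (−y, −x). The count is
symmetric, which the tests check against an independently implemented
adjacency-set oracle on random signed orders.

Translocated genes are the minimal set whose removal makes the remaining
orders identical. The search is exact over candidate subsets up to size
4 (candidates are genes flanking a changed adjacency or adjacent to a
control marker) and greedy beyond, flagged heuristic. The comparison
runs on the marker-inclusive token sequence with all control markers
collapsed to one symbol and adjacent duplicates merged after removal.
That last rule is what detects a gene moved *into* the control region:
in `... rrnS CR1 trnI CR2 trnQ ...` the gene permutation itself is
unchanged relative to `... rrnS CR trnI trnQ ...`, but removing trnI
fuses CR1 and CR2 back into a single CR and restores the ancestral
token sequence — so trnI, and only trnI, is called translocated.

The affected cluster is reported as a named rearrangement hot-spot block
(ARNS1EF for the trnA–trnF tRNA cluster, IQM for the trnI–trnM block
around the control region) when all affected genes fall inside one, and
as the minimal contiguous ancestral span otherwise. The named blocks are
wider than the minimal span on purpose: they are the units in which this
literature discusses rearrangement hot spots, so reports stay in the
field's vocabulary.

## TDRL scenario search

A TDRL event is a window `[i, j)` of the linearized order plus a
retention choice (first or second copy) for every windowed gene:
duplicate the window in tandem, delete the non-retained copies. The
genes kept from the first copy precede those kept from the second, each
group in source order, and no sign can change — which yields the
decision rule's hard barrier: any sign difference between source and
target is immediate infeasibility.

The search exploits a characterization of one-step reachability. Write
q(m) for the position in the source window of the gene at target-window
position m; one TDRL produces the target iff q splits into two
increasing runs. Restricted to the minimal differing span, that split is
unique and the recovered event canonical: the first windowed gene is
retained from the second copy and the last from the first (anything
else would shrink the window). Minimal two-event scenarios enumerate
all distinct one-event successors within the localized span, then apply
the one-step test from each intermediate. Scenario enumeration is
therefore exact, and every step is additionally re-applied through
`apply_tdrl` — the independent application path — before a scenario is
returned.

Three design choices bound the search. First, localization: candidate
windows are confined to the smallest contiguous span containing all
differences, which is what makes exhaustive minimal-scenario enumeration
tractable and is justified because observed insect rearrangements are
cluster-local. Second, deduplication: scenarios are keyed by their
sequence of intermediate orders, each step represented by its canonical
minimal-window event; enumerating every cosmetically enlarged window
would multiply scenarios without adding information. Third, the budget:
`max_events` defaults to 2 (the observed cases need 1) and is capped at
3; windows are linear on the trnI-linearized order, so an event spanning
the linearization origin is not representable — no case in the
motivating literature requires one, but it is a real limitation.

`tdrl_reachable_oracle` is a deliberately naive literal enumeration of
every (window, retention) composition, hard-limited to 7 genes and depth
2. The acceptance suite checks `tdrl_search` against it on *all* 5,040
sign-free permutations of a 7-gene order, and scenario soundness on
1,000 random cases.

## Control-region tandem repeats

Candidate periods come from the distance spectrum of repeated 8-mers: a
distance at which at least three identical 8-mers recur becomes a
candidate period p within the configured unit bounds (8–700 bp by
default, matching the range of repeat units reported in these genomes;
copies bound 2–50 likewise). Each candidate is screened with the
self-match vector m(i) = [s(i) = s(i+p)]. Substitutional divergence
between copies punches short mismatch gaps into m, so segments are
delimited by a sliding-window density threshold (window `max(5, min(p,
20))`, density ≥ 0.55) that bridges those gaps while random flanking
sequence (expected density ~25–32%) stays below it, then trimmed back
to matching endpoints and required to hold ≥ 70% matches overall.
Arrays are refined by consensus: unit-sized frames are stacked, a
column-majority consensus built, and identity computed as the mean
frame-versus-consensus match percentage, with an 80% floor — repeat
units in these control regions are near-identical, consistent with
concerted evolution. Two-copy arrays carry little internal evidence, so
they must additionally reach 95% identity. Copy number is reported both
real (span/unit) and rounded, because the field's "N × L bp" notation
is integral; comparisons use the integer form.

Overlapping candidates are resolved greedily by score (copies ×
identity), ties to the smaller unit and then the leftmost start. Score
resolution automatically prefers the primitive period: an array
explained at both L and 2L scores roughly twice as high at L. Circular
control regions can be scanned on the doubled sequence
(`circular = TRUE`), with arrays reported modulo the original length.

The recovery target the tests enforce — unit within 1 bp and copies
within 1 for planted arrays of unit 20–200 bp at ≤ 5% divergence, in at
least 95% of 200 seeded trials — reflects what the detector is for:
reproducing the published "N × L bp" descriptions, not base-perfect
boundary calls.

## The synthetic-data generator

The generator exists so every pipeline stage can be tested against known
truth without downloads. Its defaults are the study conditions: a
circular genome near 15.5 kb (gene lengths at typical insect values:
tRNAs 65 bp, rRNAs 780/1280 bp, PCGs from 159 bp for ATP8 to 1716 bp
for ND5), A+T content 0.75, whole-genome AT-skew +0.16 and GC-skew
−0.24 — the middle of the ranges reported for AT-rich insect
mitogenomes — with the two hallmark junction overlaps (4 bp ATAA at
ATP8/ATP6, 8 bp AAGCCTTA at trnW/trnC) planted by default, COX1 and
COX2 ending in an incomplete T stop, and a 900 bp control region.

Sequences are i.i.d. draws from the base distribution implied by the
composition targets, with three structural constraints: PCGs get an
enforced start codon (ATN/GTG/TTG repertoire), a stop (TAA, or the
configured incomplete T), and no in-frame internal stops; N-strand
features are drawn from the base-swapped distribution so that their
reverse complement preserves the genome-strand composition; and planted
motifs/arrays/NCRs are written over the affected positions.
Rearrangements are applied to the ancestral order *through the same
`apply_tdrl`/inversion/translocation operations the analysis side
tests*, so a planted event is by construction a reachable one. The
pseudo-random stream is consumed in one documented order — genes in
ancestral order, then control-region segments, then the NCR, then
assembly spacers — so adding configuration options can never silently
shift existing draws, and the same config is byte-reproducible.

What the generator does **not** emulate: codon-position structure beyond
the enforced starts/stops, realistic substitution processes or
among-site rate variation, tRNA secondary structure, indel divergence
between repeat copies, and sequencing artefacts. Passing tests
therefore demonstrate that the analysis operations recover what they
claim from annotation-and-order-driven structure; they do not
demonstrate robustness to annotation error or alignment-scale sequence
evolution, which real data can add.

`perturb_composition` retargets A+T content (±1 percentage point) by
resampling third codon positions (never starts, stops, shared overlap
bases, or codons where the substitution could create a stop) and
non-coding bases, leaving all annotations intact.

## Problem sizes and runtime choices

The test suite and the acceptance script run the oracle sweep over all
5,040 permutations of 7 genes at depth 2, 1,000 scenario-soundness
cases, 200 planted-repeat trials, 200 mechanism round-trip seeds and
1,000 composition-identity sequences; these sizes were chosen as the
smallest that exercise the full combinatorial space (the oracle sweep is
complete, not sampled) while keeping a full run in the low minutes on
one core. The nine-genome cohort in `analysis/` mirrors the size of a
typical comparative study.

## Known limitations

- TDRL windows cannot span the trnI linearization origin.
- Translocation minimality is heuristic beyond 4 moved genes (flagged).
- Mechanism classification returns `unexplained` for mixed patterns
  (inversions in place combined with independent translocations) rather
  than guessing a composite history.
- The repeat detector assumes substitution-only divergence between
  copies; indel-diverged arrays shift the period and will be reported
  with a drifted unit or split arrays.
- Benchmarks against deposited GenBank records require those records on
  disk (`options(mitocomp.deposited_dir = ...)`); they are not
  redistributed with the package.
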