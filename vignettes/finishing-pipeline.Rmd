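---
title: "Reference-guided finishing of fragmented bacterial assemblies"
author: "refscaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided finishing of fragmented bacterial assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refscaf)
```

## The problem

De novo assembly of a bacterial genome from very short reads (~36 bp)
stalls at repeats: insertion sequences (IS, ~1-1.5 kbp in multiple
near-identical copies), rRNA operons, tRNA clusters and prophages all
exceed the read and insert length, so assemblers emit dozens to hundreds
of scaffolds whose ends coincide with repeat copies. When a finished
genome of a closely related strain exists, most of that fragmentation is
resolvable in silico: the scaffolds can be ordered and oriented along
the related genome, and many inter-scaffold gaps can be closed either
because adjacent scaffolds actually overlap or because a read-consensus
over the reference covers the intervening bases confidently.

`refscaf` implements that finishing strategy as four composable stages —

1. **draft**: map the short reads onto the reference and call a
   per-base consensus (the *reference-guided draft*) with a Phred-scale
   confidence and a confident-position mask;
2. **place**: find spaced-seed *anchors* between each de novo scaffold
   and the reference, and order/orient scaffolds by their longest
   anchor;
3. **close**: walk adjacent scaffolds, merging suffix–prefix overlaps,
   splicing fully-confident draft intervals, and emitting sized N-runs
   for what remains (those are the junctions a lab would close by long
   PCR);
4. **validate**: in-silico restriction digestion against a physical
   map, in-silico PCR for structural events such as operon deletions,
   and held-out read remapping.

A seeded synthetic-data generator reproduces the statistical structure
this pipeline is designed for (multi-copy IS elements, an operon-scale
deletion, scattered SNPs/1-bp indels, scaffolds broken at repeats,
36-bp paired-end reads) together with truth tables, so each stage and
the whole pipeline can be tested for exact recovery at desk scale.

## Anchors

An anchor is a maximal well-conserved **ungapped** match between a
scaffold interval and a reference interval. Ungapped is a deliberate
modelling choice: indels split anchors, which keeps anchor coordinates
exact, makes the "longest anchor" placement rule meaningful, and lets a
brute-force maximal-exact-match enumeration serve as an oracle in the
tests.

Anchoring is seed-and-extend. The reference is hashed with a spaced
seed (a mask of required-match and free positions); every seed hit from
either strand of the query starts an extension along its diagonal.
Extension is greedy and alternating: from the exact run containing the
seed, the anchor is extended to the farthest right boundary that keeps
overall identity at or above `minIdentity`, then the farthest left
boundary, repeating until neither side moves. At the fixpoint the
anchor starts and ends on a match and cannot be lengthened on either
side without dropping below the identity floor; with
`minIdentity = 1` this reduces exactly to maximal exact matches.

Defaults: a contiguous weight-16 seed, `minLen = 40`,
`minIdentity = 0.9`. The weight is chosen so that random 16-mer
collisions are negligible at megabase scale (4^-16 per position pair)
while a strain diverging by a fraction of a percent still presents
abundant clean 16-mers; 40 bp and 90% identity keep anchors
well-conserved in the sense that matters for ordering scaffolds, while
tolerating the SNP density of a close strain. `N` bases never
participate in seeds and always count as mismatches.

When a scaffold has several anchors, the representative one is the
longest, with ties broken by smaller reference start and then smaller
query start — a deterministic total order. Scaffolds whose secondary
anchors disagree with the representative (opposite strand, or a
diagonal offset larger than the scaffold length) are flagged as
misassembly candidates but still placed by the longest-anchor rule;
nothing is split automatically.

## The reference-guided draft

`mapReads()` is a deliberately simple substitution-only mapper: each
read (and its reverse complement) is seeded by its first and last
`k = 18` exact bases, every seed hit proposes an ungapped placement,
placements are scored by mismatch count, and the best one is reported.
A read is left unmapped when its best placement exceeds
`floor(0.1 × read length)` mismatches, and flagged multi-mapping
(MAPQ 0) when several placements tie. Any externally produced SAM is
accepted interchangeably by the downstream stages; the built-in mapper
exists so that the whole pipeline runs and is testable without external
tools.

The consensus model is an additive Phred vote. For a pileup column the
called base maximises the summed quality of agreeing observations, and
its quality is

    q = (sum of agreeing Phred) − (sum of disagreeing Phred)

floored at 0 and capped at 93; empty columns and ties yield `N` with
quality 0. Gap observations (read deletions) count against every base;
`N` observations carry no vote. This is not the Bayesian
genotype-likelihood model of mature mappers — it is chosen because it
is monotone (more agreeing evidence never lowers the call quality),
trivially recomputable by hand in tests, and sufficient for the one
decision the pipeline needs: is this position trustworthy enough to
splice into an assembly? A position is *confident* when its quality
reaches the cutoff (default Phred 40, roughly one error per 10^4) and
its depth reaches `minDepth` (default 1).

Multi-mapping reads are excluded from the consensus so that multi-copy
IS elements cannot write one copy's variant bases over another's
locus. Insertions relative to the reference are recorded by the pileup
but never placed: the draft is coordinate-locked to the reference, and
novel insertions are exactly what the de novo scaffolds contribute —
that division of labour is the point of combining the two assemblies.

## Placement and gap closing

Scaffolds at or below 1 kbp (strictly "greater than" is kept) are set
aside before anchoring; they are later screened for containment in the
final sequence instead, since short repeat-bearing scaffolds mostly
re-describe sequence already present. Placed scaffolds are sorted by
the reference start of their representative anchor, ties broken by
scaffold id.

Each junction between adjacent placed scaffolds is tried in a fixed
order:

1. **Overlap merge** — the longest suffix–prefix alignment of at least
   `minOverlap = 30` bases with mismatch rate at most
   `maxMismatchRate = 0.02` merges the two scaffolds. Within the
   overlap an `N` yields to the other sequence's base and remaining
   conflicts resolve to the left scaffold's base. The left-wins rule is
   a documented package choice: the two de novo scaffolds carry no
   per-base qualities to arbitrate with, and a deterministic rule keeps
   the AGP component walk byte-exact (see below).
2. **Draft fill** — the terminal 1 kbp of each scaffold is anchored
   onto the draft; when both ends locate uniquely (all comparable
   anchors on one diagonal, no comparable opposite-strand anchor), in
   order, and *every* intervening draft position is confident, the
   intervening draft subsequence is spliced in. Requiring full
   confidence is conservative on purpose: a single masked position is
   enough to withhold reference sequence from a junction, which is what
   prevents a reference-only region (for example an operon the
   sequenced strain has deleted) from being pasted into the new genome.
3. **Open gap** — the junction is emitted as an N-run whose length is
   the projected reference distance between the flanking scaffolds,
   floored at `minGapN = 100` so that gaps survive round-trips through
   standard formats. Reference distance is the best in-silico estimate
   available (a wet lab would size these by PCR); physical-map
   comparisons show such estimates are good to a few percent except
   where large strain-specific indels intervene.

Junctions whose scaffold ends project out of order on the draft are
left open with a note: that signature is routine where a novel
insertion (an IS copy absent from the reference) sits in the junction,
and is also what a genuine rearrangement would look like.

The `FinalAssembly` records the census (overlap-merged + draft-filled +
open = placed − 1, an invariant asserted across all randomized tests),
per-gap records, and an AGP 2.1 table. Concatenating the AGP components
(with gap rows as N-runs) reproduces the final sequence exactly; the
single caveat is that inside a merged overlap where the left scaffold
carried an `N`, the final sequence contains the right scaffold's base
rather than the `N` the left component names.

Unplaced scaffolds are never forced into the assembly. For each open
gap the package reports *suggestions*: an unplaced scaffold qualifies
for a gap when one of its ends overlap-merges with a gap flank. The
report never mutates the assembly, because end-overlap evidence alone
cannot order multiple candidates within one gap.

## In-silico validation

**Restriction map.** `digestSequence()` matches an IUPAC recognition
motif (SfiI's interrupted palindrome GGCCNNNNNGGCC is built in) on both
strands, cuts at motif starts, and returns fragments in genome order
for linear or circular topology. Cut position within the motif is
irrelevant at the tolerance of genome-scale physical maps, with one
documented consequence: under reverse complement the two end fragments
of a linear digest shift by up to one motif length (internal fragments
and the circular fragment multiset are exact). Comparison against an
experimental map is order-preserving pairwise — both maps are
position-anchored — with fragments matching when their sizes agree
within `relTol = 0.03`, the conventional gel sizing error.

**PCR.** `predictProducts()` reports a product wherever the forward
primer matches the forward strand at `i`, the reverse primer's reverse
complement matches at `j ≥ i + |fwd|`, and `(j + |rev|) − i` does not
exceed `maxProduct`. The 3'-terminal base of each primer must match
exactly regardless of the mismatch allowance (default 0), because
extension cannot start from a mismatched 3' end. Sizes are reported in
bp and rounded to 0.01 kb, the precision at which predicted product
sizes are conventionally quoted. An unknown template base (`N`) never
satisfies a specific motif letter, so primers cannot "bind" into gap
N-runs.

**Read remapping.** `remapValidation()` maps a held-out read set
against the finished sequence and reports the mapped fraction — the
split-half completeness check for an assembly.

## The synthetic generator

`deriveGenome()` applies, in coordinate-stable order, fixed deletions,
IS insertions and 1-bp indels at sampled positions, then SNPs, each
recorded in a truth table whose replay (`applyEdits()`, an independent
descending-coordinate reimplementation) must reproduce the derived
genome byte-exactly. `shredToScaffolds()` breaks the genome optionally
inside every repeat copy — emulating assemblers terminating contigs at
repeats — with configurable true overlaps or true gaps between
consecutive pieces, a reverse-complemented fraction, and shuffled
output order. `simulateReads()` draws
`ceiling(coverage × L / (2 × readLen))` fragments with insert sizes
from a truncated normal (minimum one read length) and applies
independent substitution errors.

The `nattoLikePreset()` bundles the scenario the pipeline is aimed at:
a 200 kbp reference; a derived genome with two IS elements of 1.2 and
1.3 kbp at 5 and 6 copies, one 20 kbp operon-scale deletion, SNP rate
0.002 and 1-bp indel rate 10^-4; scaffolds broken at every repeat copy
with 30% reverse-complemented; and 36 bp paired-end reads with a
163 bp mean insert at 30-fold coverage and 1% substitution error. Read
length and insert mean mirror the sequencing chemistry this class of
data comes from; the insert standard deviation (15 bp) and the indel
rate are package choices in the realistic range for short-insert
libraries and close bacterial strains. Base qualities are a constant
Phred 35 with errors drawn independently of the printed quality — a
simplification that suffices for consensus testing but does not mimic
real instrument quality profiles.

What the generator does *not* emulate — and therefore what passing
recovery tests do not demonstrate about real data: position-dependent
quality decay, GC-coverage bias, chimeric pairs, indel sequencing
errors, diverged-but-homologous regions (the generator's IS sequences
are random, so cross-mapping between IS families cannot occur), and
biological rearrangements. Real genomes also contain low-complexity
and horizontally transferred sequence with intermediate similarity,
which is harder than either the identical or the random case.

## Determinism, degenerate inputs, numerical choices

Every sampling function takes a `seed` and restores the caller's RNG
state, so identical seeds give byte-identical FASTA/FASTQ and layouts;
the pipeline is single-threaded, making results trivially independent
of any thread setting. Consensus ties and empty columns call `N` with
quality 0 rather than guessing. Closing a single-scaffold layout
returns the scaffold unchanged. Breakpoint sets are thinned greedily to
a minimum spacing (default 1.5 kbp) so shreds stay anchorable.
Overlap scanning walks lengths from longest to shortest and accepts
the first admissible overlap, which makes "longest acceptable overlap"
exact rather than heuristic. All internal coordinates are 0-based
half-open; conversion to 1-based happens only in the SAM and AGP
writers.

The test suite exercises round trips at 200 kbp (exact string-identity
reconstruction via overlaps and via draft fills), placement recovery on
~50 shreds of a 1%-SNP derived genome, consensus accuracy at 30-fold /
1% error, and exact agreement with brute-force oracles (maximal exact
matches, all-offsets overlap scan, regex motif scan, double-scan PCR)
on 100 seeded instances each; these problem sizes were chosen so a
desk-scale machine reproduces them in minutes while remaining large
enough for repeat structure to matter.

## Limitations

* Anchoring is ungapped and single-reference; gapped chaining,
  rearrangement detection and multi-replicon references are out of
  scope (plasmids are handled as separate references).
* The built-in mapper is substitution-only; indel-containing reads are
  either placed with elevated mismatch counts or dropped. Use any
  external mapper and feed its SAM in where this matters.
* The draft's confidence model is a vote, not a genotype likelihood;
  it has no concept of ploidy, strand bias or base-quality
  recalibration.
* Open gaps are sized from reference coordinates; where the sequenced
  strain carries a large insertion relative to the reference, the
  emitted N-run underestimates the true gap (and conversely for
  deletions) — exactly the cases the physical-map comparison is there
  to flag.
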