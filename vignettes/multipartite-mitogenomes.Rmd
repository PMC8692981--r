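---
title: "Resolving multipartite mitochondrial genomes from junction evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving multipartite mitochondrial genomes from junction evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Plant mitochondrial genomes rarely live as the single master circle that
GenBank flat files suggest. Within one individual, the genome typically
coexists as several circular (and sometimes linear or branched)
subgenomic molecules, and homologous recombination between long
(>1 kb) two-copy repeats continuously interconverts these arrangements:
recombination across a *direct* repeat fuses two circles into one (or
splits one into two), while recombination across an *inverted* repeat
reversibly flips the segment between the two copies ("flip-flop"
isomerization). An assembly pipeline that stops at contigs therefore
answers the wrong question; the object of interest is the set of
circular molecules and the recombination algebra relating them.

`mitomosaic` implements this resolution step for the common data
situation: a set of assembled organelle scaffolds, long reads (~5-20 kb)
deep enough to span scaffold junctions, and paired short reads at high
coverage. It was designed around the multipartite genome of marama
(*Tylosema esculentum*), whose published tables ship with the package as
plain-text fixtures, but the machinery is generic.

## The procedure

1. **Contig seeding** (`classifyContigs`). Organelle contigs are
   recognized in a mixed assembly by homology to reference
   mitochondrial and plastid gene coding sequences, using the package's
   own seed-and-extend aligner (`localAlign`): exact k-mer seeds
   (default k = 13) on both strands, merging of seeds on one diagonal
   band (+/- 30 bp), and two-sided x-drop extension under unit costs
   (match +1, mismatch -1, gap -2). A contig takes the label of the
   gene set with its best-scoring hit; ties go to the mitochondrial
   label, the pipeline's focus, and are recorded.
2. **Junction graph** (`extractAnchors`, `mapReadsToAnchors`,
   `callSpanning`, `buildJunctionGraph`). A 500 bp terminal anchor is
   taken at both ends of each scaffold. Long reads are aligned to all
   anchors; per read, the ordered chain of anchor hits is scanned, and
   every consecutive, orientation-consistent pair of ends from
   different scaffolds within 500 bp of each other becomes a junction
   observation. Observations aggregate into an undirected graph over
   oriented scaffold ends, weighted by the number of *distinct*
   supporting reads; edges below 2 supporting reads are dropped so one
   chimeric read cannot invent a junction. The orientation convention
   is the standard bidirected assembly-graph one: a traversal entering
   a tail exits the head (forward) and vice versa, which is what makes
   inverted-repeat flip-flop representable.
3. **Copy number** (`depthProfile`, `flagRepeatNodes`). Short reads are
   assigned to scaffold positions by exact 21-mer matching; a k-mer
   matching n positions contributes 1/n to each, so reads from a
   collapsed two-copy repeat split their weight instead of being
   discarded, preserving the doubled-depth signal. Raw window counts
   are calibrated back to read depth (an interior position is covered
   by up to k windows; a read of length r contributes r-k+1 k-mers).
   A scaffold's copy number is its median depth over the single-copy
   baseline, rounded half-up with floor 1; the baseline is the median
   of per-scaffold medians, re-estimated after excluding nodes that
   round to copy >= 2. Two-copy repeats additionally show two distinct
   neighbors per end in the graph, which is recorded as corroborating
   evidence rather than a hard criterion (with exactly two copies
   there are exactly two alternative neighbors, and an edge lost to
   thin coverage should not unflag a clearly doubled scaffold).
4. **Conformation enumeration** (`decomposeCircles`,
   `conformationSpace`, `applyRecombination`). The graph is decomposed
   into circular walks using each single-copy scaffold once and each
   repeat scaffold twice, by exhaustive backtracking with a fixed
   start rule (each walk starts at the smallest remaining scaffold id,
   forward strand) and deduplication by canonical form. Independently,
   the recombination closure of any state can be enumerated: fusion,
   fission and inversion as defined above, breadth-first, again
   deduplicated canonically. Both views meet in the tests: the
   decomposition of a simulated graph must contain the generator's
   states, and every enumerated state must conserve total genome
   length exactly.
5. **Mixture estimation** (`estimateMixture`). Alternative
   conformations share all single junctions around a repeat (both the
   fused and the split arrangement contain the same scaffold-end
   adjacencies), so the states are distinguished only by reads that
   traverse a repeat *completely*, flank to flank. For every repeat
   whose flank pairings differ between candidate states, such
   traversals vote for the state(s) consistent with their pairing;
   a state's frequency at a repeat is its exclusive votes over all
   exclusive votes, and the overall frequency is the mean over
   distinguishing repeats, renormalized. This is a deliberate
   counting estimator, not a latent-variable fit; it matches the
   junction-counting argument used in practice, and when every circle
   is longer than the typical read it is unbiased, because a
   traversal's sampling probability is then proportional to repeat
   copy count over genome length in *every* state.
6. **MTPT detection** (`findMTPT`, `coverageFraction`). Plastid-derived
   fragments are local alignments between mitochondrial molecules and
   a plastid genome at >= 200 bp and >= 70% identity; the floor sits
   below the ~74% identities of the oldest transfers usually reported.
   Coverage fractions are interval unions (overlaps counted once) in
   either coordinate space, as a percentage rounded half-up to one
   decimal.
7. **Reporting** (`baseComposition`, `summaryStats`). Composition to
   two decimals (half-up), GC as C+G; scaffold medians use the
   midpoint convention (mean of the central pair for even counts),
   which is the convention required to reproduce the published
   scaffold median from the published lengths.

## The synthetic-data generator

`buildMasterGenome` emulates the statistical structure the analysis
assumes: single-copy units with lengths drawn from a configurable range
(default 2,351-56,817 bp, the published scaffold extremes), two-copy
repeats placed as recombination substrate (direct repeats shared
between two circles, inverted repeats as opposite-strand copies on one
circle; defaults 5,212 / 2,351 / 3,908 / 4,926 bp, three direct and
one inverted), i.i.d. background sequence at configurable GC (default
44.7%, the published compositional regime), and optional
plastid-derived insertions copied from a donor sequence and mutated by
substitution to a stated divergence, all on one molecule, as observed.
The truth conformation space is the recombination closure of the base
state, and the default read mixture is an equal split between the base
(most-fissioned) state and the most-fused state -- the approximately
1:1 coexistence regime reported for such genomes.

Long reads are log-normal in length (the conventional long-read shape;
the source study does not print its length distribution, so the
dispersion 0.3 and the 50:30:20 substitution:insertion:deletion error
mix at 10% total error are declared defaults, not inferred values).
Reads start uniformly on circular coordinates, sampled on the doubled
sequence so origin wrap needs no special casing, and are truncated to
the circle length when a circle is shorter than the drawn read (with a
warning when that affects the configured mean). Short reads are paired,
fixed-length, substitution-only, with normal insert sizes clamped to at
least twice the read length. Qualities are constant placeholders; the
pipeline never consumes them.

What the generator does *not* emulate -- chimeric and adapter
artifacts, quality-correlated errors, heteroplasmy beyond the
conformation mixture, linear and branched molecule forms, tandem and
short (<100 bp) repeats -- bounds what green tests mean: they show the
method is correct under its stated model, not that real libraries are
free of these complications.

### The validation genome

The structure-recovery tests run on `topologyDemoConfig()`: a
five-circle analogue of the published topology (three direct repeats
each shared between two circles, so that three fusions merge the five
circles into two master rings of a 3-circle and a 2-circle component;
one inverted repeat with both copies on the largest circle), with eight
single-copy units (4 x 4,250 bp and 4 x 8,500 bp) and four 2 kb
repeats, 67 kb in total. Two sizing considerations fix this scale.
First, mixture votes come only from full repeat traversals, so 1,000
reads of 8 kb mean must yield several hundred of them, which caps the
genome at roughly 100 kb. Second, every circle (10.5-25 kb) is kept
comfortably longer than the typical read: when reads can cover a whole
circle, the circular extraction breaks anchor chains at the read
boundary and the smaller (split-state) circles lose votes
preferentially, biasing the counting estimator; with circles longer
than reads the estimator is unbiased by construction. A study-scale
default (~100-400 kb) remains the package default for general
simulation; the compact genome is the validation condition.

## Numerical choices

* **Canonical forms.** A circular molecule is represented by the
  lexicographically smallest token string over all rotations of both
  strand readings; a conformation by its sorted canonical molecule
  strings. This gives deterministic deduplication of circular
  isomorphs, idempotent and invariant under rotation and
  reverse-complement (property-tested).
* **Alignment identity** is matches over all alignment columns
  (including gap columns), reported from the best-scoring cell of the
  x-drop extension, not from the termination point. Extension can
  overshoot a homology boundary by a short run of chance matches
  before the maximum is fixed; tests allow for this at the scale of a
  few dozen bases.
* **Seeding guarantee.** With k = 13, a shared segment of >= 200 bp at
  <= 10% divergence contains an exact 13-mer with near certainty
  (expected ~0.25 seeds per position), which is the basis for the
  default thresholds in contig classification and MTPT detection.
* **Rounding** follows the reporting conventions of the field's
  tables: half-up, two decimals for composition, one decimal for
  genome-fraction percentages.
* **Degenerate inputs** are contracts, not crashes: empty scaffold
  sets, anchors shorter than 50 bp, k-mers longer than the reads,
  missing depth entries (named in the error), repeats longer than the
  rest of their host circle, fragments longer than the donor, and
  mechanism/kind mismatches in recombination events all raise
  immediate, specific errors. A graph node with junction evidence on
  only one end is a structural error; a graph admitting no
  decomposition reports an empty list rather than failing.
* **Reproducibility.** Every stochastic step derives from the
  configured seed (with small fixed offsets per stage), and identical
  configurations produce byte-identical FASTA/FASTQ output. In YAML
  configurations the key `n` is protected against the YAML 1.1
  boolean reading.

## Design decisions on open points

* The published per-junction read counts are shown only graphically in
  the source material, so no numeric targets exist for real-data edge
  weights; the junction weights here are validated against simulator
  truth instead.
* The exact scaffold composition of each published molecule is not
  recoverable from the published tables (the scaffold table lists two
  units under one label, and unit sums do not match molecule sums), so
  `maramaTopology()` reconstructs the topology with one aggregated
  single-copy filler unit per molecule, sized so that all molecule and
  fused-ring lengths match the published values exactly. Tests on the
  real structure are therefore topology-level.
* How the published ~1:1 ratio was counted is not stated; the
  estimator here defines it as the mean over repeat-wise diagnostic
  proportions, and the caveat that such counts rest on a small number
  of informative reads carries over.
* A repeat-identity floor of 98% is used for repeat discovery:
  repeats that actively recombine are expected to be near-identical.
  This is a declared default, not a published value.
* Mixture estimation consumes the raw junction observations retained
  on the graph object (not just aggregated edge weights), because a
  traversal count per read is needed; a read spanning two repeat
  copies legitimately votes twice.

## Problem sizes

The test suite and the acceptance script run the full pipeline on the
67 kb validation genome with 1,000 long reads (8 kb mean, 10% error)
and 50x paired short reads, the oracle comparisons on 100 random
instances each (graphs of <= 8 nodes against exhaustive pairing
enumeration; <= 2 kb sequence pairs against full dynamic programming;
interval unions against per-base marking), and the bookkeeping checks
on the packaged published tables. These sizes were chosen as the
smallest at which every claimed effect (depth doubling, state
enumeration, mixture recovery, component separation) is comfortably
identifiable.

## Known limitations

* Repeat discovery operates on the given (linear) rotation of circular
  molecules; a repeat copy spanning the chosen origin can be reported
  split.
* The decomposition enumerator is exhaustive and intended for graphs
  up to a few dozen scaffolds -- the realistic scale for organelle
  assemblies -- not for general genome graphs.
* Gene annotation, linear/branched molecule forms, and short-repeat
  recombination are out of scope.
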