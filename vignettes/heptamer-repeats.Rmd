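---
title: "Surveying quadruplex-forming heptameric repeats in bacterial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying quadruplex-forming heptameric repeats in bacterial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4repeats)
```

## The biological question

G-quadruplexes (G4) are four-stranded nucleic-acid structures built from
stacked guanine tetrads; an intramolecular G4 needs at least four G-tracts
(runs of ≥3 guanines) separated by short loops. Several bacterial lineages
carry G-rich *heptameric* tandem repeats whose unit supplies one G-tract,
so that an array of four or more units is a candidate G4-forming locus.
Two families are built in here:

* **xan** — arrays of the degenerate unit `GGGANTN` containing at least one
  exact `GGGAATC` seed, at least 2 units and ≥14 bp total, as found in
  *Xanthomonas* chromosomes;
* **ana** — arrays of `GGGGANT` containing at least two exact
  `GGGGATT`/`GGGGACT` seeds, as found in the cyanobacterium *Nostoc*.

The package implements the full survey around these definitions: detection
on both strands, G4-capability calling, genomic-context annotation against
ORF annotations, inverted-pair detection, consensus statistics,
cross-genome conservation classification with control sets and one-sample
t-tests, and classification of repeat positions on assembled transcripts.
Everything is testable offline through seeded synthetic-data generators
that emit full ground truth.

## The repeat scanner

`scan_repeats()` anchors every candidate array at an exact seed occurrence
and extends it in 7-base steps while each adjacent window matches the
degenerate unit; arrays are maximal. Design choices that the repeat
definition leaves open, fixed here:

* **Trailing partial units.** After the last full unit, a terminal G-tract
  (the unit's leading G run, `GGG` for both presets) is recorded as a
  trailing partial. It never counts toward the unit number `n`, keeping the
  unit histogram integral, but it contributes a tract to G4 calling — the
  minimal G4-capable array is `(GGGAATC)3GGG`: three intact units plus the
  trailing tract give four consecutive G-tracts.
* **G4 capability.** A unit's tract is *intact* iff its first
  `tract_prefix_length` (default 3) bases are all G; an array is G4-capable
  iff the longest run of consecutive intact tracts is ≥4. Three stacked
  tetrads suffice for a stable quadruplex, so the prefix length is 3 for
  both presets; the ana unit's fourth G is treated as surplus.
* **Overlap resolution.** Overlapping same-strand candidates (possible when
  seeds occur in different reading frames) are resolved by keeping the one
  with more seed units, then more units, then the smaller start. Opposite
  strands never compete: a locus can legitimately carry a G-rich reading on
  both strands.
* **N handling.** A window containing N never matches; N is never a
  wildcard.
* Because extension strictly requires the degenerate unit, a point mutation
  inside a unit's G-tract splits the array at that unit. Such mutated units
  can still be scored by `call_g4_capability()` when supplied directly.

Coordinates are 0-based half-open on the forward strand everywhere inside
the package; 1-based inclusive coordinates appear only in GFF3/GenBank
input and in the 12-column alignment format. Circular topology is stored
but scanners do not wrap the origin.

## The generic PQS scanner

`scan_pqs()` reproduces a regex-style putative-quadruplex query: a tract is
a maximal run of ≥ `g_min` (default 3) guanines, tracts chain across loops
of `loop_min`–`loop_max` (default 1–5) bases, and a hit is a maximal chain
of ≥4 tracts, reported greedily and non-overlapping per strand — a chain of
five tracts is one five-tract hit. A maximal G-run is never split: with
`g_max` set, an over-long run is simply not a qualifying tract, so chains
break across it. Both loop-bound conventions seen for the ana query (1–5
and 1–7) are reachable through the parameters; neither is privileged.

## Context annotation

`annotate_context()` classifies each repeat against the ORF annotation:

* any base overlap with an ORF makes a repeat intragenic (coding when the
  repeat strand equals the ORF strand); ties among overlapped ORFs go to
  the largest overlap, then the smaller ORF start;
* intergenic repeats are evaluated against **both** flanking ORFs. The
  repeat is *upstream* of an ORF whose start codon lies ahead of it in the
  ORF's own orientation and *downstream* of one whose stop codon precedes
  it. Distance counts the bases strictly between repeat boundary and codon
  boundary, with overlap mapping to 0, and is binned 0–50 / 50–100 /
  >100 bp with inclusive upper edges (50 falls in the first bin);
* the neighbor-orientation class (aligned coding/noncoding, convergent,
  divergent) follows the flanking strands; a missing neighbor at a genome
  end yields `undefined`, which is reported, never dropped.

`detect_inverted_pairs()` matches a plus-strand array with a downstream
minus-strand array (G-rich then C-rich on the forward strand). The
proximity criterion is not fixed by the repeat definition, so the maximum
gap defaults to 100 bp and is exposed; matching is nearest-gap first, ties
to the leftmost partner, each array in at most one pair.

## Consensus statistics

`build_pfm()` counts every full unit of every hit, read on the repeat
strand (both strands' hits contribute their G-rich reading); trailing
partials are excluded. Information content is `2 + Σ f·log2 f` bits per
position against the uniform background, without small-sample correction —
the standard sequence-logo convention. `composition_summary()` reports
fractions over three partitions (strand, location, six orientation
categories) that each sum to 1.

## Conservation classification

Cross-genome conservation consumes a 12-column tabular local-alignment
file; the package never executes an aligner. Per query region (an
intergenic span plus both flanking ORFs):

* **repeat presence** — if no alignment covers ≥50% of the repeat span the
  status is `no_alignment`; otherwise the covered span is mapped through
  the alignment, padded by 100 bp, and rescanned with the original preset
  (`conserved` vs `absent_or_mutated`);
* **region class** — an ORF qualifies when a single alignment covers ≥80%
  of it at ≥80% identity. Neither qualifying is `no_homology`, exactly one
  is `flanking_change`, and with both the change in inter-ORF distance
  decides: ≥300 bp more is `insertion`, ≥300 bp fewer `deletion`, else
  `no_change`. The identity, coverage and indel thresholds are defaults of
  this package (the underlying survey was curated manually and states
  none) and are exposed as arguments. Loci whose ORFs align to different
  subject sequences are coerced to `flanking_change` with a message, and
  gene-level deletions are approximated by the large-negative-distance
  rule rather than by manual inspection.

`build_control_sets()` assembles repeat-free control region sets: plain
random draws, position-matched (greedy nearest-midpoint pairing) and
orientation-matched (largest-remainder rounding of the repeat set's
aligned/convergent/divergent composition). The paper-scale defaults are a
260-region pool and 117-region sets; both scale down for synthetic
genomes, and a pool deficit is a contract error, never silently truncated.

`one_sample_t()` treats the control fractions as the sample and the
repeat-group fraction as the reference: `t = (mean − ref)/(sd/√n)`,
`df = n − 1`, two-sided p from the t distribution. A zero-variance sample
is degenerate unless its mean equals the reference (then t = 0, p = 1).

## Transcript position classification

Repeats in coding regions are excluded; the rest split into `g4`
(G4-capable) and `control` sets. For each repeat the overlapping transcript
with the greatest overlap wins (ties: higher expression, then longer, then
smaller start — the assembly provides no canonical choice). The transcript
5' end inside the repeat span gives `start`; the 3' end inside the span or
at most 30 nt past the repeat's boundary *in the transcript's reading
direction* gives `stop`; otherwise `middle`. Each repeat is counted once
via the selection rule even when transcripts cover both strands;
`strand_content` records whether the transcript carries the G-rich or the
C-rich reading.

## The synthetic-data generators

`simulate_survey()` emulates the surveyed genomes: i.i.d. background at a
chosen GC content, scrubbed so no seed heptamer (or reverse complement)
survives outside planted loci; arrays with a unit-count distribution peaked
at 4 units (default `{2: .2, 3: .15, 4: .4, 5: .15, 6: .06, 7: .04}`,
matching the qualitative shape of the observed histograms), degeneracy at
the unit's N positions, optional G-tract mutations, both strands,
convergent inverted pairs, and ORF cassettes realizing an exact
orientation mix via largest-remainder rounding. Array flanks are
additionally scrubbed so no planted array can be extended or gain an
accidental trailing tract, which makes truth complete: with zero mutation
rates the scanner output equals the planted table field-for-field. G-tract
mutations are planted honestly — the truth records the surviving array
segments around the mutated unit, since that is what the scanner
definition implies.

`simulate_ortholog()` applies at most one edit per region (insertion,
deletion, flanking loss, locus loss), never touching a planted repeat, and
emits exact 100%-identity truth alignments for all unedited blocks.
`simulate_transcripts()` realizes an exact class mix and G-rich/C-rich
split per repeat, with transcripts confined between neighboring planted
repeats so the closed loop is exact.

What the generators do **not** emulate: codon structure, GC skew,
operons, transcription units spanning several genes, alignment noise
(mismatches, gaps, paralogy) and read-level artifacts. Passing closed-loop
tests therefore demonstrates correctness of the classification logic under
the stated rules, not robustness to the messiness of real annotations and
alignments.

## Numerical and testing choices

* Deterministic outputs: interval writers use stable field order and fixed
  float formatting; generators are pure functions of (parameters, seed),
  implemented with an isolated RNG scope.
* Degenerate inputs are contract errors with named messages: empty unit
  lists, negative distances, missing contexts, undersized control pools,
  zero-variance t-tests with a discrepant mean.
* The test suite checks the scanners against independent brute-force
  oracles (regex-based enumeration of every strand/frame/extent
  combination) on motif-enriched random sequences of 1–2.5 kb, 100+
  sequences in the acceptance suite; surveys of 20–60 planted repeats on
  genomes of 60–200 kb exercise the closed loops. These sizes keep the
  default suite fast while covering every rule branch; all scale linearly
  for larger inputs.

## Known limitations

* GenBank parsing is minimal (LOCUS/CDS/ORIGIN; `join()` locations are
  collapsed to their span) — sufficient for bacterial chromosome records,
  not for arbitrary GenBank files.
* Conservation assumes locus-level collinearity through single local
  alignments; rearrangements within a region are classified only through
  the coarse category rules.
* The PQS scanner reports one maximal hit per chain; conventions that
  enumerate overlapping quadruplex arrangements will count more hits on
  the same sequence.
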