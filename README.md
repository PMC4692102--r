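# g4repeats

Genome-wide survey of **quadruplex-forming heptameric G-rich tandem
repeats** in bacterial genomes.

Several bacteria carry short tandem repeats whose 7-mer unit starts with a
G-tract, so that an array of units stacks G-tracts head-to-tail: with four
or more consecutive intact tracts the locus can fold into an
intramolecular G-quadruplex (G4). This package finds such arrays,
characterizes their genomic context, and asks the downstream questions a
survey of these loci raises — are they conserved between related genomes,
and where do they sit on transcripts?

It is aimed at microbial genomicists who have a genome (FASTA/GenBank), an
ORF annotation (GenBank/GFF3), and optionally a tabular local-alignment
file and transcript intervals, and want reproducible repeat tables instead
of manual curation.

## What it computes

* **Repeat scan** (`scan_repeats`): maximal tandem arrays of a degenerate
  7-mer unit (xan preset: `(GGGANTN)_n` with ≥1 exact `GGGAATC` seed,
  ≥2 units, ≥14 bp; ana preset: `(GGGGANT)_n` with ≥2 `GGGGA(C/T)T`
  seeds), on both strands, with trailing partial G-tracts recorded.
  An array is **G4-capable** iff its longest run of consecutive intact
  G-tracts is ≥4 — the minimal capable motif is `(GGGAATC)3GGG`.
* **Generic PQS scan** (`scan_pqs`): maximal chains of ≥4 G-tracts
  (`G≥3`, loops 1–5 by default), per strand.
* **Context** (`annotate_context`, `detect_inverted_pairs`): intragenic vs
  intergenic, coding vs non-coding strand, aligned/convergent/divergent
  neighbor orientation, distances to start/stop codons binned
  0–50/50–100/>100 bp, and convergent plus/minus inverted pairs.
* **Statistics** (`build_pfm`, `unit_histogram`, `composition_summary`):
  position frequency matrix with per-position information content, unit
  histogram, composition fractions.
* **Conservation** (`classify_conservation`, `build_control_sets`,
  `one_sample_t`): per-locus repeat presence and region-change category
  (no change / insertion / deletion / flanking change / no homology) from
  12-column alignment tables, control sets (random, position-matched,
  orientation-matched), and category-wise one-sample t-tests
  `t = (mean(controls) − repeat value)/(sd/√n)`, `df = n − 1`.
* **Transcripts** (`classify_transcripts`, `position_summary`): repeat
  position on the best-overlapping transcript (start / stop — within 30 nt
  after the repeat — / middle / no transcript) and G-rich vs C-rich
  strand content, split into G4-capable vs control sets.
* **Synthetic data** (`simulate_survey`, `simulate_ortholog`,
  `simulate_transcripts`): seeded generators with complete ground truth,
  so every stage is testable without downloads.

All coordinates inside the package are 0-based half-open on the forward
strand.

## Worked example

```r
library(g4repeats)

sim  <- simulate_survey(survey_params(n_repeats = 20, genome_length = 80000,
                                      seed = 42))
hits <- scan_repeats(sim$genome, builtin_presets()$xan)
dplyr::select(hits, start, end, strand, n_units, g4_capable)
#> # A tibble: 20 × 5
#>   start   end strand n_units g4_capable
#> 1  3555  3590 -            5 TRUE
#> 2  7769  7804 -            5 TRUE
#> 3 12006 12048 +            6 TRUE
#> 4 12112 12126 -            2 FALSE
#> ...
```

Each row is one maximal array: the 6-unit plus-strand array at
12006–12048 is G4-capable (six intact G-tracts), the 2-unit array at
12112 is not (two tracts cannot form a quadruplex). Those two arrays form
a convergent inverted pair:

```r
detect_inverted_pairs(hits)
#> # A tibble: 1 × 3
#>   plus_repeat_id                  minus_repeat_id                   gap
#> 1 rep:synth_xan_42:12006-12048(+) rep:synth_xan_42:12112-12126(-)    64
```

Context and consensus:

```r
ctx <- annotate_context(hits, sim$orfs)
composition_summary(hits, ctx)
#> # A tibble: 10 × 4
#>    partition   category                 n fraction
#>  3 location    intergenic              16     0.8
#>  4 location    intragenic               4     0.2
#>  5 orientation aligned_coding           5     0.25
#>  ...

build_pfm(hits)
#> <g4_pfm: 78 units>
#>   p1 p2 p3 p4    p5 p6    p7
#> A  0  0  0  1 0.872  0 0.000
#> C  0  0  0  0 0.038  0 0.923
#> G  1  1  1  0 0.013  0 0.026
#> T  0  0  0  0 0.077  1 0.051
#> info (bits): 2.00 2.00 2.00 2.00 1.28 2.00 1.54
```

Positions 1–4 and 6 of the unit are fully conserved (2 bits); the
degenerate positions 5 and 7 carry the planted 10% mutation rate. The
conservation t-test, on its worked example:

```r
one_sample_t(c(0.1, 0.2, 0.3, 0.4, 0.5), 0)
#> <one-sample t-test>
#>   reference 0 vs 5 controls (mean 0.3)
#>   t = 4.2426, df = 4, p = 0.01324
```

`vignettes/heptamer-repeats.Rmd` documents the model, parameter choices
and limitations. A thin command-line wrapper over the same functions is
installed at `inst/scripts/g4repeats.R` (subcommands `scan-repeats`,
`scan-pqs`, `annotate`, `simulate`, `report`).

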