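---
title: "Methods: event model, region rules and statistics in asannot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event model, region rules and statistics in asannot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asannot)
```

This vignette is the package's own account of what it computes and why the
open design choices were resolved the way they were.

## The event model

An alternative-splicing event is a local difference between two isoform
structures, reduced to a gene, a type code, a chromosome, a strand and an
ordered coordinate tuple. Seven types are supported: skipped exon (SE),
mutually exclusive exons (MXE), retained intron (RI), alternative 5′/3′
splice site (A5SS/A3SS) and alternative first/last exon (AF/AL). All
user-facing coordinates are 1-based and inclusive at both ends, matching
GTF and VCF; BED tracks are converted on import.

### Canonical ID grammar and coordinate arities

The canonical ID `gene|type|chrom|strand|c1:c2:...` is a package-defined
grammar: `|` and `:` are reserved (and rejected inside gene and chromosome
names), coordinates are strictly ascending, and the mapping between valid
events and ID strings is a bijection, verified by round-trip property tests.

The arities were chosen so that every coordinate is derivable from *every*
supported input dialect — the precondition for byte-identical IDs across
converters:

* **SE (4)**: upstream-exon end, skipped-exon start/end, downstream-exon
  start.
* **RI (4)**: upstream exon start/end, downstream exon start/end; the
  retained intron is `[c2+1, c3-1]`.
* **MXE (6)**: upstream-exon end, both alternative exons, downstream-exon
  start.
* **A5SS/A3SS (4)**: the constitutive coordinate adjacent to the
  alternative segment, the segment itself `[c2, c3]`, and the flanking
  junction coordinate. Only junction-derivable coordinates are used,
  because SUPPA's A5/A3 grammar does not carry the flanking exon's far
  boundary that rMATS prints.
* **AF/AL (5)**: the two alternative terminal exons plus the shared inner
  junction coordinate. Five, not six: SUPPA's AF/AL strings supply exactly
  five distinct coordinates, and an ID built on information one dialect
  lacks could never agree across converters. Overlapping alternative
  terminal exons cannot satisfy the ascending-tuple invariant and are
  reported as unclassified rather than forced into the type.

### Region decomposition

`decompose_regions()` splits an event into the *distinct* region(s) (one
for SE/RI/A5SS/A3SS, two side-labeled regions for MXE/AF/AL), *common*
anchors, splice-site *boundary windows* and *flanking introns*. From the
coordinate tuple alone only the junction-adjacent coordinates of the
common exons are known, so common regions are 1-bp anchors except for RI,
whose tuple carries the full flanking exon extents. For AF/AL there is
only one common side, so the "distinct lies strictly between the common
anchors" property holds only for the types with two anchors; this is a
geometric fact about terminal-exon events, not a relaxation.

Boundary windows are `[edge - w, edge + w]` (width `2w + 1`) around each
distinct-region edge. The half-width `w` defaults to 10 bp — wide enough
to cover the core donor/acceptor consensus and branch-point-proximal
positions where splice-disrupting variants concentrate, narrow enough not
to swallow whole short introns — and is exposed everywhere
(`--boundary-width` on the CLI).

## Event classification from transcript pairs

`classify_transcript_pair()` operates on junction sets. Candidate brackets
`(l, r)` pair a shared exon-end coordinate with a downstream shared
exon-start coordinate; the exon content strictly inside the bracket, when
each transcript walks it through consecutive junctions, decides SE (one
exon vs none) or MXE (one disjoint exon on each side). A junction of one
transcript lying inside an exon of the other is an RI. Junction pairs
sharing exactly one coordinate give A5SS/A3SS, with the 5′/3′ label
assigned strand-aware. Terminal exons that are disjoint and share their
inner junction are AF/AL.

Two deliberate tie-breaks:

* **Terminal position wins.** A first-exon difference with a shared
  downstream acceptor is AF when the exons are disjoint; when they
  overlap, the difference is inside a single exon and the
  alternative-splice-site rule applies. This is deterministic and
  documented rather than guessed from any external convention.
* **Nothing is silently dropped.** Exonic differences not explained by an
  emitted event (multi-exon skips, overlapping MXE candidates, bare
  terminal truncations) are returned as `$unclassified` intervals.

For MXE/AF/AL the genomically first alternative region is labeled the
inclusion side, matching the junction-listing order of the upstream tools;
the label is only a naming convention and is carried consistently through
PPI assignment and NMD calls.

## Converters

rMATS junction-count tables, SUPPA `.dpsi`/`.ioe` tables, spliceR-style
isoform pairs and a generic TSV (`gene, type, chrom, strand, c1..c6,
p_value, fdr, dpsi`) all convert to canonical events. Conversion is
accounted row by row: `n_input = n_converted + n_duplicates + n_failed`
always holds, row-level failures carry the offending token, and a missing
required column aborts with a schema error naming it. Statistics that fail
to parse leave the event in place with absent statistics — significance
filtering (`filter_events()`, CLI `--pvalue`/`--dpsi`) is always an
explicit caller choice.

In rMATS tables, the `+1` start-coordinate shift is applied exactly to the
columns marked `_0base`; all other coordinate columns are taken as
written. spliceR-style input goes through the documented two-step
conversion: isoform IDs resolve to exon chains through the annotation,
then the pair classifier emits events carrying the row's statistics, so a
pair spanning two structural differences yields two events with identical
statistics.

## The feature store

`build_db()` assembles the gene model (GTF via rtracklayer) and up to
eleven track-backed feature classes (BED via rtracklayer; VCF site records
via vcfR, genotypes ignored; documented TSV schemas for exon usage,
domains, PTMs, PPIs and localization) into a single in-memory store with a
genomic interval index, persisted to one file with
`save_feature_db()`/`load_feature_db()`. Records are deduplicated and
sorted on their full key, so query answers are independent of track
insertion order and rebuilds are idempotent. Interval overlap is 1-based
inclusive (`max(starts) <= min(ends)`): a single-base touch counts.
Protein-coordinate records whose isoform lacks an annotated CDS are
skipped at build time with a warning count, since they can never be
projected.

`project_protein_to_genome()` walks the CDS in transcription order
(strand-aware) and returns the genomic segments covering a codon range;
segment lengths always sum to `3 × aa_count`, a property tested over
randomized CDS structures.

## Annotation rules and the 23-column table

Each of the twelve feature classes is consumed by exactly one region
selector (`default_region_rules()`); annotation refuses rule tables that
break this completeness invariant. The fixed output schema has 23 columns:
nine event/statistics columns, one column per feature class, and a second
genome-space column each for domains and PTMs (protein-space span plus
projected genomic span). Unpopulated cells are empty strings, so the
schema never varies with content; CSV export uses RFC-4180 quoting.

Specific rule mechanics worth knowing:

* RBP/splicing-factor sites are screened over distinct ∪ flanking introns
  with common-region overlap *subtracted before querying*; a site
  straddling a region edge is truncated and kept iff at least 1 bp of
  overlap remains.
* Domains and PTMs must overlap the distinct region *after* projection to
  genomic coordinates; a domain confined to a common exon never populates
  the column.
* NMD is derived, not track-backed: an isoform side is sensitive iff any
  of its CDS-bearing transcripts places the stop codon more than 50 nt
  upstream of its final exon–exon junction; sides without CDS are
  `unknown`. The 50-nt threshold is the classical junction-rule constant
  and is exposed as an argument. Whether to precompute this per transcript
  or derive it per event was open; deriving it per event keeps the store
  free of annotation-version-dependent caches.
* A PPI partner is inclusion-specific iff it appears on at least one
  inclusion isoform and no exclusion isoform; partners on both sides are
  shared. Edges on non-informative isoforms are ignored.

Annotation is monotone in the database — adding records can only populate
more cells — which is tested directly.

## Enrichment and dependency statistics

The gene-set test is hypergeometric over-representation (ORA) of the DAS
gene list, not a ranked-walk GSEA: the pipeline's natural input is an
unranked gene list surviving a DAS filter, and gmt collections carry no
ranking. `P(X >= k)` is computed as the exact upper tail (`k = 0` gives
exactly 1), set sizes are measured *after* intersection with the universe,
and sets below 20 effective genes are excluded by default — small
knowledge-based sets are too unstable to interpret. Benjamini–Hochberg
adjustment is applied across the tested sets; results order by adjusted p
then name, so ties break deterministically. The universe defaults to the
genes of the feature database's annotation and is overridable.

Feature dependency is a two-sided Fisher exact test on the 2×2
presence/absence table over annotated events; two-sided because no
direction is privileged a priori. The reported odds ratio is the sample
odds ratio `(a·d)/(b·c)` with 0.5 added to every cell iff any cell is
zero, not the conditional-MLE estimate, so the printed number matches the
textbook formula. Tables with an all-zero margin (a class present in all
or no events) are rejected as degenerate.

## The synthetic fixture generator

The generator exists so the entire pipeline is testable with planted,
checkable structure and no downloads. Each simulated gene carries two
transcripts on a short contig (gene blocks of 20 kb, exons 90–180 bp,
introns 400–900 bp) whose exon-chain difference is exactly one event of
the requested type mix; the truth table records the canonical ID and the
inclusion/exclusion isoforms. The same events are rendered in every
dialect with statistics drawn once (default: half the events significant
at p < 0.05 with |dPSI| ≈ 0.3 — a typical knockdown-scale effect —
the rest null), feature tracks are planted inside or outside each event's
rule region per class density (default 0.7) with decoys always planted
outside — including variants exactly on and 1 bp outside boundary-window
edges — and a ledger records which class columns must be populated.
Gene-set fixtures plant one enriched target among uniform decoy sets
(default 20 sets of 25 genes, baseline inclusion rate 0.1, target
log-odds boost 3).

Generators are pure functions of their spec: one integer seed drives
per-generator derived streams, so identical specs give byte-identical
files and adding a generator does not perturb earlier outputs. rMATS files
are written only for the five types rMATS defines; AF/AL events appear in
the SUPPA, generic and spliceR renderings.

What the fixtures deliberately do *not* emulate: nucleotide sequence
(the pipeline is coordinate- and identifier-driven), overlapping genes,
multi-event genes, soft intron-boundary noise, or realistic
exon/intron-length and feature-density distributions. Passing the planted
suites therefore demonstrates correctness of the region logic, the
converters and the statistics — not robustness to annotation noise or
biological realism of any particular density.

## Numerical and scale choices

Problem sizes in the shipped tests were chosen to exercise every branch
while keeping brute-force oracles exact and fast: 1000-event codec
round-trips, 210-gene cross-converter runs, 1000 × 100
interval-query-vs-scan comparisons, 100 hand-derived catalog genes, and
2 × 200 seeded enrichment replicates (power and null calibration; the
null check ranks the target with seeded random tie-breaking, since
hypergeometric p-values tie heavily on small collections). Hypergeometric
p-values agree with an explicit tail-sum oracle to 1e-12 for N ≤ 500;
Fisher p-values agree with full margin-fixed enumeration.

## Known limitations

* Chromosome names are matched as plain strings; no genome-version
  liftover, no multi-assembly support.
* Event discovery is annotation-defined; no BAM/read-level PSI
  computation, and no de novo prediction of motifs, domains or
  conservation — all such content arrives as user tracks.
* Complex local differences (multi-exon skips, overlapping alternative
  exons) are surfaced as unclassified intervals rather than decomposed.
* rMATS files produced by rMATS itself mark only some 0-based columns
  with a `_0base` suffix; inputs whose unmarked start columns are 0-based
  should enter through the generic TSV dialect after normalization.
* The enrichment test is ORA; a ranked GSEA over dPSI-ordered genes is a
  possible extension but outside the current surface.
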