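---
title: "Methods: reference-free organelle assembly and nuclear-insertion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-free organelle assembly and nuclear-insertion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organellr)
```

This vignette is the package's own account of its methods: the model behind
each stage, the tunable parameters and why they hold their defaults, the
numerical and design decisions made where the design was genuinely open, and
what the synthetic-data generators do and do not show about real data.

## The pipeline model

The pipeline assumes a whole-genome PacBio HiFi read set in which organellar
reads are a minority of reads but a large majority *within their class
labels*, because organellar genomes are present at high copy number
(chloroplast tens of copies per nuclear genome equivalent, mitochondrion
somewhat fewer). An external read classifier assigns each read a label
(plastid / mitochondrion / nuclear); classification is imperfect in two
characteristic ways that the pipeline is built to correct:

1. nuclear reads carrying organellar insertions (NUPTs/NUMTs) are labeled
   organellar, and reads from high-copy nuclear repeats are mislabeled at an
   increased rate — both corrected by the k-mer coverage filter;
2. chloroplast reads leak into the mitochondrion label — corrected by
   aligning the mitochondrial pool to the finished chloroplast assembly
   graph and removing near-end-to-end alignments.

Chloroplast-first ordering is structural, not cosmetic: the mitochondrial
coverage statistics are only meaningful after chloroplast reads have been
removed from that pool, so the mitochondrial k-mer table and median are
computed freshly on the refined pool, never reused from the initial pass.

External tools — classifier, assembler, graph aligner — enter only through
adapter functions (`f(reads) -> graph`, `f(reads, graph) -> alignments`).
The test suite and the acceptance script use fixture-backed stubs
exclusively, so the package's own logic is exercised without any external
binary.

## Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `k` | 31 | bases | long enough to be nearly unique in plant genomes, short enough that HiFi's residual error rarely corrupts a window |
| `low_mult` | 0.3 | × *mkc* | counts below ~1/3 of the class median indicate single-copy (nuclear) origin |
| `high_mult` | 5 | × *mkc* | counts above 5× the class median indicate high-copy repeats (rDNA, centromeres) |
| `max_outlier_frac` | 1/5 | fraction | a read is removed only when *more than* a fifth of its windows are outliers; chimeric insertion-bearing reads exceed this, clean organellar reads with a few noisy windows do not |
| `reads_per_round` | 800 | reads | roughly 100× coverage of a typical chloroplast genome; assemblers degrade at excessive coverage |
| `max_rounds` | 10 | rounds | cap on the iterative re-sampling; the graph either converges to a recognizable structure quickly or not at all |
| `max_clip` | 100 | bases | "almost end-to-end": clips up to 100 bp tolerate linearization and junction artifacts |
| `min_identity` | 0.95 | fraction | chloroplast reads align to their own graph near read accuracy; mitochondrial reads sharing only transferred segments do not |
| HSP filters | >80%, >100 bp | percent, bases | entry criteria for candidate nuclear insertions |
| completeness e-value | ≤ 1e-3 | — | inclusive, matching aligner-side `-evalue` semantics |
| `n_samples` | 1000 | permutations | resolves empirical p down to 1/1001 |

Threshold comparisons mirror their definitions exactly: the outlier rule
and both identity rules are strict (`>`), the clip rule is inclusive
(`≤`), and a read with *exactly* one fifth outlier windows is kept. The
median of an even number of values is the mean of the two middle values.

## Numerical and representational choices

**Coordinates.** All intervals inside the package are 1-based inclusive,
the R/Bioconductor convention shared by IRanges and the rest of the
ecosystem this package composes with. BED (0-based half-open) and GAF/PAF
(0-based half-open) are converted at the parser/writer boundary; BLAST-6
subject intervals are normalized so `s_start < s_end` with the strand
recorded separately. Using the host ecosystem's convention internally
removes the largest class of off-by-one errors an R implementation could
introduce; the conversion functions are exercised by round-trip tests.

**Canonical k-mers.** Counting is strand-collapsed (each window represented
by the lexicographic minimum of the word and its reverse complement),
matching the default of the counting tools used on HiFi data; windows
containing any non-ACGT base are skipped rather than mapped. The counter is
implemented in C++ (2-bit packing, rolling update); an independent pure-R
tally (substring windows, Biostrings reverse complement, run-length
counting) serves as its oracle in the tests, on inputs up to a megabase.

**Per-class count tables.** The k-mer table for filtering plastid reads is
built from plastid-labeled reads only, and the mitochondrial table from the
refined mitochondrial pool only. The alternative — one table over all
classified reads — would let the abundant chloroplast k-mers dominate the
mitochondrial read medians and defeat the mitochondrial filter; per-class
tables make each class median mean what it claims to mean.

**Reads with very few windows** (1 ≤ windows < 5) are still assessed; no
minimum window count is imposed beyond the existence of at least one
window. Reads shorter than `k` have nothing to assess and are removed with
reason `too_short`.

## Graph topology

A canonical link set is computed first: every GFA link equals its
orientation-flipped complement, so each is replaced by the lexicographically
smaller form and duplicates collapse. Classification then requires, for the
quadripartite call: exactly 3 segments; exactly 4 canonical links; one
segment (the IR) incident to all four links and the other two to two each;
and an explicit closed walk LSC → IR → SSC → IR′ → LSC in which the two IR
traversals have opposite orientation and all four links are distinct. The
walk found is retained and reused for sequence extraction, so
classification and extraction cannot disagree.

Tie-breaks and degenerate inputs:

- LSC/SSC are assigned by length (longer single-copy region is the LSC),
  ties broken by lexicographic segment id — real chloroplasts never tie,
  but the function must be deterministic on adversarial input.
- Self-links in multi-segment graphs (occasionally emitted by assemblers on
  the IR node) are dropped with a warning before classification; isolated
  segments under 50 bp are pruned as assembler debris (threshold
  configurable).
- A single segment whose only link joins its end to its own start is
  `circular` — the expected shape when the IRs have collapsed. A lone
  segment with a head-to-head self-link is a hairpin, not a circle, and
  falls through to `other`.
- Any uncovered segment end makes the graph `incomplete`; the pipeline
  reports this and retries with a fresh read sample, never silently.

Isomer output starts at the LSC start and is not rotation-normalized:
deterministic output mattered more than canonical rotation, and downstream
comparisons in the package are rotation-aware where they need to be. Link
overlap bases are trimmed once per traversed link (four trims per isomer),
so with overlap *v* the isomer length is
`len(LSC) + len(SSC) + 2·len(IR) − 4v`.

## Refinement semantics

Identity is `matches / blocklen` from the alignment record (no
gap-compressed variant: those columns are universally populated and
consistent across aligners). Clips are measured on the read, not the graph
path. A read is removed when *any* of its alignment records qualifies —
the alternative (best-record-only) would keep a chloroplast read whose best
record happens to be a secondary partial alignment, which is exactly the
failure mode the step exists to remove.

## Completeness

The package consumes a translated-search hit table rather than running the
aligner: the computation this stage owns is the presence/absence rule, not
protein alignment. The 41-gene panel (ATP synthase, cytochrome c maturation
and oxidase, NADH dehydrogenase, matR/mttB, ribosomal proteins, succinate
dehydrogenase) ships as configuration; membership can be replaced, the
count 41 is asserted for the default. Copy number and orientation are
deliberately ignored because assembly graphs collapse long repeats into
single nodes.

## Insertion analysis

- **Embedded-HSP removal** allows shared endpoints but requires a strictly
  longer container; exact-duplicate intervals keep the highest bitscore,
  then input order. Removal never changes the union of covered bases (a
  tested invariant).
- **Merging** is transitive with distance 0, so book-ended intervals merge,
  matching the default of the standard interval toolkit. Merged identity is
  the unweighted mean of member HSP identities; a length-weighted variant is
  exposed (`weight_by_length`) but off by default, since each local
  alignment is one observation of the insertion's age.
- **Substitution calling** walks the `cs` difference string directly:
  single-base substitutions only, positioned on the organellar genome;
  indels and long match blocks advance the cursor but contribute nothing.
  Methylation context is read from the *organellar* sequence — the
  pre-insertion ancestral state — on the strand carrying the cytosine
  (G-reference events are resolved on the reverse complement). Context is
  undefined (NA) within two bases of a sequence end and wherever a
  neighboring base is N.
- **Spectra** collapse the twelve directed substitution types onto six
  strand-symmetric classes. Per-context substitution *rates* divide context
  counts by the number of organellar C/G sites of that context within the
  aligned intervals, so CG enrichment is a rate statement, not a raw-count
  artifact of context abundance.
- **Cross-species correlations** are reported on both raw and log10 scales
  for the cumulative-length pairs, since either scaling is defensible for
  quantities spanning orders of magnitude; identity pairs are raw only. A
  correlation over fewer than three species, or over a degenerate
  (zero-variance) column, is NA.

## The enrichment null and its interval

The null re-places each feature uniformly at random within its own
chromosome, preserving lengths and allowing features to overlap one
another, `n_samples` times. This is a deliberate simplification of
workspace-model samplers: it conditions on the feature length distribution
and chromosome assignment only. The empirical p-value uses the
add-one form `(1 + #{null ≥ observed}) / (1 + n_samples)`, so the smallest
attainable p at 1000 samples is 1/1001.

The 95% interval on the fold is `observed / q97.5(null)` to
`observed / q2.5(null)`. This construction is chosen because it is
*calibrated*: under the null, the interval covers fold = 1 exactly when the
observed overlap falls between the null percentiles, which happens ~95% of
the time — a property the test suite verifies over 200 replicate seeds. An
interval built instead from the spread of `null/null_mean` around its own
mean would cover 1 almost always and carry no inferential content. When the
2.5th null percentile is 0 the upper bound is undefined (NA) rather than
infinite.

Implementation note: per-chromosome cumulative coverage of the merged
annotations makes each overlap evaluation two array lookups, so 1000
permutations of tens of features cost milliseconds.

## Synthetic data: what it emulates, what it does not

The generators produce miniature but structurally faithful inputs:

- `make_quadripartite_genome()` — LSC·IR·SSC·IR′ with truth graph and both
  isomers; defaults 12/3/5 kb (23 kb genome).
- `make_mito_genome()` — a 30 kb circle plus a 5 kb small circle, echoing
  the small circular DNAs of real plant mitochondria, with a recorded
  subset of panel genes (default 38/41).
- `plant_insertions()` — organellar fragments copied into non-overlapping
  nuclear positions and mutated to target identities, with substitution
  classes drawn from a programmable spectrum (default 60% C:G>T:A) and
  cytosine events concentrated at CG/CHG sites (weights 6:3:1); every
  planted substitution is recorded with its context.
- `simulate_reads()` — lognormal lengths, uniform starts with origin wrap
  for circles, uniform substitution errors at 0.001/base; copy-ratio
  defaults chloroplast 50×, mitochondrion 20×, nuclear 1×.
- `stub_classifier()` — labels drawn from a programmable confusion matrix
  (default 5% total confusion per class).
- `make_oracle_assembler()` — emits the truth graph when the read pool is
  ≥90% on-target at sufficient coverage, and a deliberately broken graph
  otherwise, so the iterative retry logic is testable.

Deliberately *not* emulated: homopolymer indel errors (the dominant HiFi
artifact after substitutions), chimeric/heteroduplex reads, base-quality
models, and realistic repeat structure inside the organellar genomes.
Passing tests therefore demonstrate the correctness of the pipeline's
logic — thresholds, bookkeeping, graph walking, spectrum accounting — under
idealized sequence models, not robustness to every artifact of real
instruments. The adapters are the seam where real tools replace the stubs.

Problem sizes in the test and acceptance runs — ~2 Mb of simulated reads,
300 kb nuclear sequences, 40 planted insertions (~2000 substitutions),
1000-permutation tests repeated 200 times — were chosen so the full suite
runs in about a minute on a single CPU while every statistical check still
has the resolution it needs (e.g. ±3 percentage points on a 60% class
fraction at n = 2000 is ~4 binomial standard deviations).

## Known limitations

- Quadripartite recognition targets the canonical 3-segment graph; graphs
  where the IR is shorter than the read length usually collapse to a single
  circle and are classified as whatever structure the graph actually shows.
  Graphs with more than three chloroplast segments are reported `other`,
  not resolved.
- Mitochondrial output remains an assembly graph; no attempt is made to
  linearize or untangle it.
- The refinement step trusts the alignment records it is given; it does not
  re-align.
- The enrichment null randomizes the features, not the annotations, and
  ignores composition or mappability workspaces.
- Substitution calling ignores indels and multi-base events entirely.
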