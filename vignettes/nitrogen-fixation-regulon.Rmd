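---
title: "Inferring a nitrogen-fixation regulon, its promoters, operons and expression island"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a nitrogen-fixation regulon, its promoters, operons and expression island}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nifregulon)
```

## The biological problem

Diazotrophic bacteria fix atmospheric N~2~ with nitrogenase, an
oxygen-sensitive, ATP-hungry enzyme whose genes (*nifHDK* and a large
retinue of maturation, electron-transport and regulatory genes) are
under tight transcriptional control. Fixed nitrogen — ammonium in
particular — shuts *nif* transcription down within minutes. Two signals
therefore define the *nitrogen-fixation-inducible regulon*: a gene is a
member if it is induced under nitrogen-fixation conditions (low
ammonium, microaerobic) **and** repressed shortly (10 min) after an
ammonium shock. In γ-proteobacterial diazotrophs this regulon is driven
by the σ^54^ (RpoN) holoenzyme together with the enhancer-binding
activator NifA: σ^54^ recognises a −24/−12 promoter element, and NifA
binds an upstream activator sequence (UAS), consensus `TGT-N10-ACA`,
characteristically located at least 100 bp upstream of the
transcription start. In *Pseudomonas stutzeri* A1501 the *nif* genes
sit in a contiguous ~49-kb chromosomal region that behaves as a
coordinately induced *expression island*.

This package turns that analysis into a reusable pipeline:
classification → regulon → promoter scan → operons → islands, with a
synthetic-data generator that plants all of the above so each stage can
be validated against known truth.

## The procedure and its assumptions

**Fold-change classification.** Inputs are normalized per-gene
intensity means (one positive number per gene per condition); the
pipeline deliberately starts *after* array normalization and does not
model replicate variance. Ratios are linear throughout (the dialect of
published *nif*-island tables); log~2~ appears only in plots. A gene is
`up` iff fold ≥ `up_cut` (default 2) and `down` iff fold ≤ `down_cut`
(default 0.5). The boundaries are inclusive: published island tables
treat genes at exactly 2.05-fold as induced members, and an exclusive
rule would be hostile to round-number reporting. Statistical
significance is **not** re-derived — the original test behind
"significantly altered" is not specified in this literature — but
`classify_contrast()` accepts an `include_mask` so externally computed
significance calls can veto genes without changing the threshold logic.

**Regulon inference** is a pure condition intersection
(`up_in_nfix & down_after_shock`), so the regulon is contained in the
up-set by construction. Ortholog information enters only as a
presence/absence table (`core_subset()` keeps members present in
*every* required reference genome); ortholog detection itself (BLAST
reciprocal hits etc.) is out of scope because no single criterion is
canonical.

**Promoter scanning.** Patterns are dash-separated IUPAC blocks with
fixed-length `Nk` gap tokens. Gaps match anything and never count as
mismatches; at fixed positions, a subject base outside the IUPAC set —
including an ambiguous `N` in the subject — counts as one mismatch.
This "subject N is never a match" rule is conservative and is the rule
the brute-force oracle in the test suite implements. Defaults:

| parameter            | default            | why                                          |
|----------------------|--------------------|----------------------------------------------|
| UAS pattern          | `TGT-N10-ACA`, 0 mm | the published NifA consensus, searched exactly |
| σ^54^ pattern        | `TGGCAC-N5-TTGC`, ≤1 mm | see below                                |
| UAS strands          | both               | enhancer-like elements act orientation-independently |
| σ^54^ strands        | coding only        | the promoter element is directional          |
| upstream window      | 400 bp             | must exceed spacing rule + motif length; generous enough for bacterial UAS placement |
| minimum UAS distance | 100 bp             | the "at least 100 bp upstream" rule          |

The −24/−12 element is named by its position, not its sequence, in most
of the *nif* literature; we adopt `TGGCAC-N5-TTGC`, the strongly
conserved GG-N~10~-GC core of the σ^54^ consensus with its flanks, and
allow one mismatch because natural −24/−12 promoters are rarely exact.
Both patterns, budgets, window and spacing are configurable
(`scan_config()`), and no claim is made that the defaults reproduce any
particular published scan beyond the packaged worked example, whose
flags are printed data, not recomputed.

Distances are measured from the motif's 3′ edge to the annotated gene
start. Annotated starts are translation starts, used as a proxy because
transcription start sites are generally unavailable; the published
spacing rule refers to the transcription start, so our rule is the
same rule applied to the best available anchor. Upstream windows are
truncated at contig edges (a `circular` flag enables wrap-around;
linear is the default since most assemblies annotate the origin
sensibly), and overlapping neighbour gene bodies are *not* masked out
of the window — the simplest rule, stated here so nobody mistakes it
for TSS-aware extraction.

**Operon prediction.** Every gene flagged Yes for both elements seeds
an operon; extension proceeds in the transcription direction over
consecutive genes while the strand is unchanged and intergenic gaps
stay ≤ 200 bp (a standard bacterial heuristic — the source analyses do
not state their joining rule), stopping at the next Yes/Yes promoter.
Genes with No or blank flags are absorbed as internal members: in
published island tables, blank consensus cells mark operon-internal
genes that were not independently evaluated, which is why the package
keeps blank as a third state distinct from No everywhere.

**Island detection** runs over the gene *order*, not coordinates:
maximal runs of regulon members tolerating up to 4 consecutive interior
non-members, reported when ≥ 5 members long, with boundaries always on
member genes and spans reported in bp (`max(end) − min(start)`). Real
islands carry interior runs of 2–3 non-regulated genes (regulators,
transporters), hence the tolerance; the detector at tolerance 0 is
exactly the maximal-run oracle, a property the tests assert.

## The synthetic generator

`simulation_spec()` defaults encode the study conditions the pipeline
is designed for: 1,000 genes; an island of 58 genes starting at gene
400 spanning exactly 49 kb, containing 52 regulon genes organised into
11 operons (sizes 5, 2, 7, 3, 8, 2, 5, 6, 1, 4, 9) with the 6
non-regulated genes placed at interior operon junctions (≤ 2 per
junction); 114 regulon members scattered outside the island, kept ≥ 6
genes clear of its edges; 20-fold induction under nitrogen fixation;
0.1-fold (10-fold repression) at the 10-minute shock point;
multiplicative log-normal noise with σ = 0.2 on the log scale (a
typical between-condition reproducibility for array summary
intensities); ortholog retention 0.6 per reference genome, independent
across genes and references (the simplest null). Baseline intensities
are log-normal (meanlog = log 500, sdlog = 0.5). Every operon leader
receives a planted UAS ending 100–130 bp upstream and a σ^54^ element
12–25 bp upstream of its start.

Two generator design points deserve emphasis:

* **Planted promoters are the only σ^54^ promoters.** A ≤1-mismatch
  15-bp element occurs by chance about three times per 10^5^ windows,
  i.e. roughly once per hundred 400-bp upstream windows; left in place,
  such chance occurrences would make "number of operons" an ill-defined
  quantity of the simulation rather than of the method. The generator
  therefore rescans every upstream window after planting and breaks
  chance σ^54^ occurrences with single-base edits (never touching a
  planted motif). Chance **UAS** occurrences are deliberately left in:
  they are inert without the promoter element, and their background
  rate (~4^−6^ per window per strand) is itself a property the test
  suite checks against the analytic expectation.
* **Determinism.** All generation is a pure function of the spec; the
  seed enters through R's RNG only, and repeated calls are
  bit-identical. The shock is modelled as a single 10-minute snapshot,
  not a time course, because the downstream analysis uses nothing more.

What the generator does *not* emulate: probe-level array artefacts,
normalization residue, correlated noise between neighbouring genes,
operon-level (rather than gene-level) expression coupling, sequence
composition beyond uniform random bases, and orthology that respects
phylogeny. Passing the planted-truth tests therefore demonstrates that
the *algorithms* recover the structure they are specified to recover
under realistic noise — not that real microarray data meet these
idealisations.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 (1-based
  inclusive) is converted only at the IO boundary, and the conversion
  is round-trip tested.
* Classification at exactly the cut goes to `up`/`down` (inclusive).
* A sequence shorter than a pattern scans to zero hits, not an error;
  an empty expression table flows through to an all-zero report.
* Tied best motif hits are all reported; hits are sorted by position
  with `+` before `−` at the same offset.
* `island_partition()` accepts either a locus-ID range (resolved
  against the annotation's gene order when available, else by
  lexicographic comparison, which is correct for zero-padded locus
  tags) or a bp interval (gene-body overlap).
* Report invariants (`inside + outside = regulon`,
  `regulon ⊆ up-set`) are asserted when the report is assembled, so an
  inconsistent report cannot be written.

## Problem sizes

The test suite exercises the scanner against a brute-force
sliding-window oracle on 1,000 random sequences (40–200 bp, mismatch
budgets 0–2, occasional N bases), the island detector against a
run-length oracle, and the full pipeline on ten 1,000-gene synthetic
genomes; unit tests use 30- and 150-gene versions of the same
architecture. These sizes give the binomial checks (e.g. ortholog
retention) non-trivial power while keeping the default suite
comfortably within a coffee break.

## Known limitations

* Promoter flags depend on annotated starts; genes with long 5′ UTRs
  or misannotated starts can fail the 100-bp spacing rule spuriously.
* The operon rule cannot split a same-strand run whose internal
  promoter is below the detection consensus, and never joins across
  > 200 bp gaps, whatever the transcriptional reality.
* Island detection on gene order is robust to gene-length variation
  but blind to strand structure; an island is a run of co-regulated
  genes, not a transcription unit.
* The regulon is threshold-defined; with noisy data near the two-fold
  boundary, membership is unstable by construction — use the
  significance mask if replicate-level calls exist.
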