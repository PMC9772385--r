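---
title: "Methods: editome construction, recurrent edits, microRNA binding sites and clearance statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: editome construction, recurrent edits, microRNA binding sites and clearance statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, rules and numerical choices behind
`editome`, in the order the pipeline applies them, together with the
reasoning for decisions that were genuinely open.

## The measurement model

An A-to-I edit is observed in RNA-seq as an A-to-G mismatch on the
transcript strand: coverage `AN`, edit-supporting reads `AC`, and editing
level `AF = AC / AN`. `AF` is always recomputed from the counts; an `AF`
field in an input file is ignored, so read counts are the single source
of truth. Every call must satisfy `0 <= AC <= AN`, `AN >= 1`.

Coordinates: user-facing positions are 1-based genomic coordinates, as in
variant tables. Internally, intervals live in `GenomicRanges`/`IRanges`
(1-based, closed), the native R/Bioconductor representation; BED's
0-based half-open convention is converted exactly at the read/write
boundary, so a BED line `chr1 99 100` covers 1-based position 100 and
nothing else. Round trips BED→internal→BED and VCF→internal→VCF are
identities (tested).

## Filtering cascade

1. **Known genomic variants.** Any call whose (chromosome, position)
   appears in a supplied known-variant set is removed. This is the
   genomic-contamination control: on data with paired DNA and RNA from
   the same cell it drives the overlap between accepted RNA edit sites
   and DNA variants to zero, which `dna_rna_concordance()` measures per
   sample.
2. **Per-call thresholds** (`filter_config()`): coverage `AN >= 2`,
   level `AF >= 0.1`, and for non-Alu sites `AC >= 2`. These are the
   low-depth single-cell settings; all are exposed rather than
   hard-coded because deeper cohorts warrant stricter values. Read-level
   criteria (mean base quality ≥ 25, mapping quality ≥ 20, duplicates
   removed) belong to the upstream caller and are recorded in the config
   as metadata only.
3. **Cohort support.** Alu sites are kept when observed in ≥ 1 sample
   anywhere; non-Alu sites need ≥ 2 observing samples within one
   (stage, normal) group or within one (stage, abnormal) group. Normal
   and abnormal observations are never pooled: an edit seen once in a
   normal zygote and once in an AG zygote has no same-class support.
   "Observed" always means "passed the per-call filters in that
   sample", not merely covered.

Strand for substitution-class labels comes from the gene model at the
site; sites outside genes, or covered by genes on both strands, are
strand-unknown and fall into the ambiguous classes (e.g. A-to-G/T-to-C),
which is exactly the population the QC A-to-G proportion must include.

## Region annotation and recoding

Each site receives one class per overlapping transcript (CDS, 5′-UTR,
3′-UTR, non-coding exonic, intronic) and the per-site label is the
highest-priority class over *all* overlapping loci, in the fixed order
CDS > 5′-UTR > 3′-UTR > non-coding exonic > intronic > intergenic.
Per-gene reductions are returned as well, because gene-level analyses
need them; whether multi-gene overlaps should be resolved per gene or
per site is ambiguous, so both outputs exist. UTRs are always derived as
exon-minus-CDS and oriented by strand, so gene models with and without
explicit UTR records behave identically. Recoding effects substitute the
alternative base on the coding strand into the affected codon under the
standard genetic code; stop gains/losses are labelled even though the
analysis does not use them (they are free given the codon table).

## REEs, persistence, and loss scans

An REE of a stage is an edit observed in ≥ `ree_fraction` (default 0.5)
of that stage's *normal* samples. The denominator is all normal samples
of the stage, not coverage-restricted samples: recurrence is a
cohort-level property and a coverage-blind denominator makes absences
meaningful (the known cost is that a poorly covered true edit can read
as absent; the loss scan inherits this caveat). REE-targeted genes use
the per-sample union over the gene's REEs with a stricter default
(`gene_fraction = 0.8`).

Stage flows classify each source-stage REE in the target stage as
`remained_REE`, `detected_not_REE`, or `not_detected`; the counts always
sum to the source set size. The loss scan runs twelve (stage, condition)
groups by default — elder-mother oocytes at GV and MII, AG and PG
embryos at zygote through morula — and reports REEs with zero detections
in the group. A `max_detection_fraction > 0` relaxes complete loss to
near-loss; no default is claimed for "nearly lost" because that notion
is analysis-specific.

The editing-expression correlation is Spearman by default (configurable):
editing levels and FPKM live on very different scales with heavy ties
and outliers, and a rank statistic is the conservative choice when the
functional form is unknown. Samples where an REE is not observed
contribute `AF = 0`, consistent with the detection-based definition of
recurrence.

## MicroRNA binding sites

Site types follow the canonical seed-match taxonomy. With the seed being
mature positions 2–8, the 6mer core is the exact reverse complement of
positions 2–7; a match extended by the complement of position 8 (on the
5′ side of the site) gives 7mer-m8; an adenosine opposite position 1
(3′ side) gives 7mer-A1; both give the 8mer. Only Watson–Crick matches
count — wobble pairs are excluded. One site is reported per core
occurrence, labelled with its longest matching type, so an 8mer is never
double-counted as its contained 7mers. `seed_sites()` is tested against
a brute-force window-enumeration oracle on random sequences.

Two predictors stand behind a common prediction interface: the seed
scanner, and a seed-anchored local aligner of the reverse-complemented
mature sequence (match +5, mismatch −4, gap open 8, extend 2, minimum
score 30 — permissive on purpose, so that the predictor intersection is
governed by the seed logic rather than by alignment-score vagaries).
Alignment-level predictions are collapsed to family level by the
four-property key (family, target UTR, site type, seed-site start/end)
and intersected on that key. The classification cascade operates on any
conforming prediction set; the default route is the seed scanner, and
the intersection route is available where a two-predictor protocol is
wanted.

Per (edit, gene, family), counts are taken per transcript over the sites
whose span contains the edit ("falls into"), comparing prediction keys
before and after replacing the edited adenosine with guanine. Because
sites are exact matches, a site not overlapping the edit cannot change,
so the overlap-restricted diff equals a whole-sequence diff; a
whole-transcript sensitivity mode is unnecessary under exact matching.
The five-way cascade is evaluated in its fixed order (no overlaps → site
unchanged → gain → lost → mixed) and is exhaustive and mutually
exclusive over arbitrary count vectors (property-tested, including
edit/revert mirror symmetry: reverting the edit swaps introduced and
removed, turning gains into losses).

## Clearance statistics

Maternal genes: median FPKM > 2 (strict) over normal samples in at least
one oocyte stage. Clearance targets: min(median GV, median MII) > 2 ×
median 8-cell (strict). Both thresholds are parameters.

The MBS-gain enrichment among REEs is tested per stage on the 2×2 table
of MBS-overlapping edits partitioned into REE vs non-REE (disjoint — a
valid independence test requires disjoint rows, so the descriptive
"REEs vs all edits" contrast is not the default) against gaining vs
non-gaining, using the plain chi-square statistic without continuity
correction; p values are BH-adjusted across stages. The paired
gain-vs-loss comparison is a one-sample signed-rank test on per-(gene,
sample) differences with zeros dropped (the standard behaviour of paired
mode in `wilcox.test`; a genuinely paired rank-sum test does not exist).
The clearance-target comparison is the one-tailed Mann–Whitney test with
Hodges–Lehmann estimate and one-sided lower bound; the per-pair
statistic defaults to the raw count of MBS-gaining edits observed in the
sample on the gene, with no length normalisation claimed (none is
justified a priori; the dense pair universe over maternal genes ×
samples, zeros included, is the default because absence of gains is
information).

## The synthetic cohort generator

The generator emulates what a staged embryonic RNA-seq cohort provides
to this pipeline: single-transcript two-exon genes with planted edit
positions; an Alu mask over half the 3′-UTRs; per-sample variant tables
with negative-binomial coverage (`AN = 2 + NB(mu = 6, size = 2)`) and
per-site beta editing levels (`AF = 0.15 + 0.75·Beta(2, 2)`), mimicking
low-depth single-cell profiles; homozygous-like SNP contaminants;
per-stage detection of recurrent edits (probability 0.9 within a
contiguous stage window, residual 0.2 afterwards); sporadic noise edits
(0.2), a tenth of them non-A-to-G so the A-to-G proportion metric is
exercised below 1; a deaminase-like context (G at −1 with probability
0.05, at +1 with 0.5); MBS-gain slots — seed-site patterns carrying an A
where the site needs a G — planted at Poisson rates of 1.5 per clearance
target versus 0.2 per other gene and verified against the classifier at
generation time; oocyte-to-8-cell expression decay of fold 4 with
log-normal noise (sd 0.25 on the log scale) and a negative
editing-expression coupling (expression scaled by `1 − 0.6·AF`).

Two properties make the manifest an exact answer key rather than a
statistical one:

* detection counts are truncated binomials — at or above the recurrence
  threshold for active recurrent edits, below it for noise and residual
  detections — and every non-dropout recurrent edit is guaranteed at
  least one detection in each abnormal group of its active stages. Plain
  binomial draws would, at these cohort sizes, let a few noise edits
  cross the 50% threshold (P ≈ 0.02 per site-stage at 12 samples) and a
  few recurrent edits vanish from a 4-sample abnormal group, so exact
  recovery would fail for reasons that say nothing about the pipeline.
  The truncation is part of the generator's contract and is documented
  behaviour, not a tuning knob.
* expression group definitions are enforced on the empirical medians by
  deterministic per-stage rescaling after noise and coupling are
  applied, so planted clearance annotations are recovered by
  construction.

What the generator does **not** emulate: alignment artefacts, coverage
that varies along the transcript, hyper-editing clusters, multi-isoform
genes (the multi-transcript cascade is exercised by constructed cases in
the unit tests instead), linked edits, batch effects between datasets,
and any dependence between editing and SNP positions. Passing the
closed-loop tests therefore demonstrates that the pipeline's logic is
correct and self-consistent, not that its thresholds are optimal for any
particular real cohort.

Null calibration of the clearance test uses the generator's count-level
mode (`simulate_pair_counts()`): the rank-sum test consumes only
per-(gene, sample) counts, so its type-I behaviour is a property of the
count distribution, and drawing those counts directly (independent
Poisson thinned by detection) keeps 500-replicate calibration runs cheap
while testing exactly the statistic's input distribution under "no
planted excess". Power replicates, in contrast, run the full
sequence-level closed loop.

## Problem sizes and numerical choices

The shipped test suite uses cohorts of 15–80 genes, 2–7 stages, 4–12
normal samples per stage, 20–300 recurrent and 20–500 noise edits; the
oracle-equivalence suite runs 1,000 random (UTR, family, edit) triples
at UTR length ≤ 200, the cascade fuzz 2,000 count vectors and 500
sequence-derived revert pairs, and the calibration 100 power plus 500
null replicates. These sizes were chosen so the whole suite documents
the method at interactive timescales while keeping every check exact.

Ties and degenerate inputs: exact Wilcoxon p values are used for small
tie-free samples and the tie-corrected normal approximation otherwise;
all-zero difference vectors report p = 1 with an explicit flag; empty QC
inputs report NaN with a warning rather than silently returning 0;
stages with no normal samples, unknown sample ids, and malformed records
are errors that name the offending line or identifier. Sort orders of
all result tables are fixed (with the (chrom, pos, sample) tiebreak) so
outputs are byte-stable across runs.

## Known limitations

* The REE denominator is coverage-blind (see above); an optional
  covered-denominator mode would require per-site coverage for all
  samples, which candidate tables do not carry.
* The aligner stand-in anchors on exact seed complements; a binding site
  supported only by extensive 3′-compensatory pairing (no perfect seed
  core) is invisible to both predictors by design, since wobble-free
  seed matching is the classification's substrate.
* Chromosome names are matched verbatim; mixed "chr1"/"1" cohorts must
  be normalised upstream.
* The statistics treat (gene, sample) pairs as exchangeable; planted or
  real gene-level clustering makes the tests anticonservative in the
  same way the underlying published analyses are.
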