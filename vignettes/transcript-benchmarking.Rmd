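---
title: "Benchmarking long-read transcript detection and quantification with txbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking long-read transcript detection and quantification with txbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txbench)
```

# Scope and model

`txbench` evaluates two things about a long-read RNA-seq pipeline: the
*structures* it reports (transcript models, i.e. ordered exon chains on a
genome) and the *abundances* it assigns to them (TPM). Both evaluations are
reference-based comparisons, so the package is organized around three data
structures:

* a **transcript model** — one transcript with strand and ordered,
  non-overlapping exons. Internally all coordinates are 0-based half-open,
  which keeps interval arithmetic free of off-by-one cases; conversion to
  the 1-based inclusive convention happens only at the GTF boundary.
* a **junction chain** — the ordered intron intervals between consecutive
  exons. The chain is the identity under which structures are compared
  ("unique junction chain", UJC): chromosome, strand and every intron
  coordinate must agree *exactly*. End variability is deliberately not part
  of chain identity; it is handled separately by end windows. Mono-exon
  models have an empty chain and are treated by their own rule throughout.
* a **reference catalog** — the reference models indexed by chain, by
  annotated intron, and by strand-aware donor/acceptor coordinate, plus
  per-transcript 5'/3' ends and gene loci (single-linkage clusters of
  exonic overlap, per strand by default — pooling strands would merge
  antisense genes, which real annotations keep apart).

# Structural classification

A multi-exon query is assigned exactly one category:

1. **FSM** if its chain is in the catalog's chain index. When several
   references share the chain, the match goes to the one minimizing
   |ΔTSS| + |ΔTTS| — a deterministic, end-aware tie-break.
2. **ISM** if its chain is a consecutive, *proper* sub-run of the chain of
   a reference at the same locus. A non-consecutive subset of one
   reference's junctions is not a truncation and falls through to NIC.
   Requiring the host reference to share the locus (rather than matching
   any chain genome-wide) avoids calling a truncation against a paralog on
   the other end of the genome.
3. If the query associates with no same-strand locus (no exonic overlap and
   no shared splice feature), it is **other**: *antisense* when it overlaps
   a reference only on the opposite strand, *intergenic* otherwise. This
   gate runs *before* the novel-site test on purpose: splice-site identity
   is strand-aware, so an antisense query's sites are never annotated on
   its own strand and a blind site test would absorb all antisense models
   into NNC.
4. **other/fusion** if its association spans two or more disjoint
   same-strand loci.
5. **NNC** if any donor or acceptor coordinate is unannotated.
6. **NIC** otherwise, with the reason recorded: *intron retention* when a
   query exon strictly contains an annotated intron of an associated
   reference (both flanking splice sites inside the exon); else *novel
   junction between known sites*; else a *novel combination* of annotated
   junctions. Retention is tested first because a retention event also
   produces a non-consecutive junction subset and would otherwise be
   misread as a combination.

Mono-exon queries never receive FSM: a query matching a mono-exon reference
on the same strand with both ends within the window is `other/mono-exon-match`;
same-strand span overlap gives `other/genic`; opposite-strand-only overlap
`other/antisense`; no overlap `other/intergenic`. The evaluation literature
does not print a rule for unspliced models, so this operationalization is a
design choice of the package; it is the only place where span (rather than
exon) overlap decides a call.

## End and junction support

All windows are inclusive: "within 50 nt" means ≤ 50, and the boundary is
tested explicitly in the suite. `ref_5p`/`ref_3p` compare the query ends to
the nearest TSS/TTS of the *matched gene's* references; `reference_match`
additionally requires category FSM and both ends within the window of the
*single* matched reference. CAGE support accepts a 5' end inside or within
the window of a peak; 3' support accepts a peak hit or a poly(A) hexamer
(`AATAAA`/`ATTAAA`) within the 50 genomic bases upstream of the 3' end read
on the transcript strand (this clause needs a genome; requesting it without
one is a configuration error, while simply not supplying evidence degrades
gracefully — the affected clauses evaluate false and are flagged
unevaluable). SRTM composes the two end conditions for FSM/ISM; SNTM does
the same for NIC/NNC and additionally requires a short-read count ≥ 1 at
*every* novel junction (vacuously true when the novel model has none, as in
a pure junction recombination).

# Detection scoring

Truth-side accounting is chain-based: a truth transcript is TP when some
prediction matches its chain and both ends within the window, PTP when only
chain-matched, FN when never chain-matched. Prediction-side, precision is
the fraction of predictions that chain-and-end-match some truth transcript,
and redundancy is chain-matching predictions per distinct matched truth.
Sensitivity = TP/|truth|, PDR = (TP+PTP)/|truth| ≥ sensitivity,
F1 = 2PR/(P+R) with the 0/0 case defined as 0. Mono-exon truth (the long
unspliced spike-in analog) is matched by same-strand overlap with both ends
within the window, since it has no chain. These operationalizations are
recorded here because the detection metrics are named, not printed, in the
evaluation literature; they are the natural chain/end split used throughout
the package.

# Quantification statistics

With ground truth θ and estimate θ̂ (TPM), the evaluation id set is **all
ground-truth transcripts**; ids the estimate does not report count as 0.
This penalizes non-detection rather than silently restricting to the
intersection. MRD additionally restricts to θᵢ > 0 because the relative
difference divides by θᵢ. NRMSE uses the sample (n−1) standard deviation of
θ and is invariant under joint positive rescaling. SCC is the Spearman
correlation with average ranks on ties (computed via `stats::cor`; the test
suite checks it against an independent transcription of the
rank-covariance formula).

Replicate statistics work on log(θ̂+1); all logarithms in the package are
natural. For each transcript × group cell, `CV_ig = s_ig/u_ig` where `u_ig`
is the replicate mean and `s_ig = sqrt(mean((x − u_ig)²))` — the divisor is
the replicate count R, following the printed definition of the replicate
s.d. for this statistic (for a pair of replicates with log values 1 and 3
this gives CV = 1/2). Cells with `u_ig = 0` (all-zero transcripts) have no
defined CV; they are excluded and their count reported, and IM is the
root-mean-square of the remaining CVs. The CV-versus-abundance curve is
summarized by ACVC using 50 equal-frequency bins of `u_ig` and trapezoidal
integration over bin means — the curve itself is defined by the statistic,
but bin count, bin style and integrator are package choices and are exposed
as arguments.

The consistency curve C(α) is the fraction of (transcript, group,
replicate-pair) events where both log abundances fall on the same side of
the threshold α. C(0) = 1 identically because log(θ̂+1) ≥ 0. The scalar CM
is taken at α = 1 and ACC integrates the curve over α ∈ [0, 10] in steps of
0.1; the α grid and the CM point are conventions of this package (the
statistic's definition fixes neither) and are arguments, not constants.

Resolution entropy bins the estimates into M = 100 equal-width bins of
width max(θ̂)/M, with the top edge inclusive so the maximum always counts.
A constant profile lands in one bin and has RE = 0 exactly — regardless of
the edge convention — and a uniformly occupied binning reaches ln M. An
all-zero profile returns 0 by convention. PET is simply the percentage of a
ground-truth set with estimated TPM above 0.

The K-value of a gene is the condition number σ_max/σ_min of its binary
exon-isoform matrix. Exon identity defaults to the distinct exact
(start, end) exon intervals across the gene's isoforms; an alternative
construction over the disjoint segments induced by all exon boundaries is
available behind `mode = "segments"`, since "the gene's exons" is ambiguous
when isoforms use overlapping but unequal exon intervals. Singular values
come from LAPACK via `svd()`; σ_min < 10⁻¹²·σ_max is reported as K = +∞
(e.g. two isoforms with identical exon content). A single-isoform gene has
one singular value and K = 1.

The cell-mixing design: the expected profile of a sample mixing component A
at proportion w is w·a + (1−w)·b re-normalized to sum 10⁶ (mixing is linear
in molar proportions; renormalization keeps the result in TPM units). The
observed mixed-sample estimate is compared to this expectation with SCC,
MRD and NRMSE, and `estimate_mixing_ratio()` recovers w by grid search on
NRMSE — exact to the grid step on noise-free data.

Feature-stratified reports recompute SCC/MRD/NRMSE inside bins of a
transcript feature (truth TPM, exon count, length, isoform count, K-value)
and add a min–max normalized MRD across the report's bins; a bin where a
metric is undefined is reported missing, never zero.

# The synthetic benchmark

The generator is first-class, tested code; its defaults are the study
conditions used by the acceptance checks: 20 genes with 2–4 isoforms on a
5–9 exon skeleton (exons 100–300 nt, introns 200–500 nt, intergenic gaps
1–3 kb), 500 submitted models drawn 50/20/15/10/5% from
FSM/ISM/NIC/NNC/other, replicate matrices with 2 groups × 3 replicates,
log-normal truth (meanlog 3, sdlog 1.5, normalized to 10⁶ — heavy-tailed,
so a sizable fraction of transcripts sit at low TPM where relative errors
spike), multiplicative log-normal noise of s.d. 0.25 and 5% dropout. These
values are chosen once as a realistic miniature of a multi-isoform
annotation and are not tuned per test.

Category constructions mirror the definitions: FSM copies a reference
(with bounded end jitter that never crosses a junction); ISM takes a
consecutive proper intron run; NIC skips two adjacent internal exons (novel
junction, known sites), skips two non-adjacent internal exons (novel
junction combination) or retains an internal intron — internal, because
retaining a terminal intron leaves a consecutive sub-chain, which is
correctly a truncation (ISM) under the category precedence; NNC shifts one
internal splice site 3–10 nt off every annotated coordinate; "other" places
a mono-exon model in intergenic space. Every construction is verified by
classification at build time and re-drawn on the rare topological
collision. The replicate noise draws the standard-normal variates once and
scales them by `noise_sd`, so noise ladders at a fixed seed share their
randomness and the monotonicity of SCC/MRD/IM along the ladder is a
property of the noise model, not of sampling luck. The toy genome is
alphabet-random with GT-AG motifs stamped at annotated introns
(a configurable fraction CT-AC, drawn per connected component of the
site-sharing graph so introns reusing a donor or acceptor stay consistent);
no sequence-composition realism is claimed.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: read-level errors and coverage biases, alignment
artifacts near splice sites, library-preparation end biases (the jitter is
symmetric Gaussian), inter-gene overlap and nested genes, correlated
replicate noise, and compositional coupling beyond the TPM renormalization.
Results on this benchmark validate the *implementation* of the metrics and
classifier, not the field-performance of any pipeline.

# Numerical choices and degenerate inputs

* Spearman with a constant vector is undefined and reported `NA`; MRD with
  no positive-truth transcript and NRMSE with constant truth are errors.
* Detection with empty truth is an error; empty predictions give an
  all-zero result with undefined redundancy (`NA`).
* Empty submissions produce `NaN` rows in UJC agreement matrices, flagged
  by their size vector.
* The formula-oracle tests compare every statistic to independent
  step-by-step transcriptions at tolerance 10⁻¹⁰ on small instances; the
  K-value oracle comparison conditions on full rank because the finite/∞
  verdict exactly at singularity is a threshold call.
* Duplicate transcript ids in a reference are an error, not an overwrite.
* Problem sizes in the test suite (500-query classification benchmark,
  800-transcript noise ladders, 250-instance randomized bound checks) are
  the package's chosen desk-scale conditions; all suite runs and the
  acceptance script complete in well under a minute each on one CPU.

# Known limitations

* ISM hosts are sought among same-locus references only; a truncation of a
  transcript whose locus the query does not touch is not recognized.
* The mono-exon rule is intentionally conservative (never FSM); pipelines
  that report many unspliced models will see them in `other`.
* Intra-priming and RT-switching artifact detection, coding potential,
  BUSCO completeness and read-alignment-derived quantities are out of
  scope.
* The CM/ACC scalars depend on the chosen α conventions; comparisons across
  studies must hold those conventions fixed.

```{r example}
cfg <- sim_config(seed = 1, n_genes = 5, n_models = 50)
ann <- gen_annotation(cfg)
catalog <- build_catalog(ann$reference)
sub <- gen_submission(ann$reference, cfg)
table(classify_submission(sub$models, catalog)$category)
```
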