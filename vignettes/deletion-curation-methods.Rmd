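---
title: "Curating intermediate-sized deletions: models, parameters and design choices"
author: "delrecover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating intermediate-sized deletions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical and
algorithmic choices behind each stage. It documents what is assumed,
what is tunable and why the defaults are what they are, and which
decisions were genuinely open.

## The problem

Intermediate-sized deletions (~30 bp–10 kb) are called per sample from
soft-clipped short reads. The evidence quality splits calls into three
classes by which read orientations contributed soft clips:
`both` (high confidence), `forward_only` and `reverse_only` (lower
confidence, usually a symptom of locally reduced depth or base quality
rather than of the variant's absence). Treating single-orientation
calls as noise discards real carriers; keeping them all floods the set
with artifacts. The cohort-level resolution implemented here: cluster
calls across samples, then let high-confidence calls in *other* samples
vouch for single-orientation calls at the same locus.

## Coordinates

Interval strings `"chrom:A-B"` are interpreted as 0-based half-open, so
the deletion length is `B - A`. This convention is fixed by the three
printed example deletions the package validates against (43, 52 and
315 bp); it is also the BED convention. Internally every interval is a
`GRanges` (1-based closed, the Bioconductor norm); conversion happens
only at I/O boundaries (TSV call tables and BED are 0-based half-open
on disk; VCF export anchors `POS` at the base before the deleted run as
the VCF standard requires). Deletions are unstranded; strand in any
input is ignored.

## Clustering and joint-call recovery

Two calls are "the same deletion" when they are on one chromosome, both
breakpoint deltas are at most `bpTolerance` and reciprocal overlap
(intersection over the longer length) is at least
`minReciprocalOverlap`. Defaults: **10 bp** and **0.8**. Soft-clip
breakpoints are near-base-exact, so a tight positional tolerance is
appropriate; the overlap guard prevents size-discordant chaining at a
shared breakpoint. Clusters are formed by single linkage after a
canonical (chrom, start, end, sample) sort, so the output is
deterministic and independent of input order.

Consensus breakpoints are the modal (start, end) pair over members.
Ties prefer a pair observed in a both-orientation member, then the
smallest start, then the smallest end. Consensus coordinates are
computed once at clustering and not recomputed after recovery — the
recovery step changes which members are kept, not where the locus is.

Recovery rule: a single-orientation member is retained when **two or
more samples other than its own** carry a both-orientation call in the
same cluster ("two or more" is the rule's constant; the word *other* is
implemented literally, so a sample's own both-orientation call never
vouches for its own single-orientation call). Both-orientation members
are never altered and no locus gains members, so recovery is monotone
relative to the drop-all-singles baseline.

## The filter cascade

Applied in order — size, region annotation, depth, soft-clip quality,
similar-repeat — with per-step (n_in, n_out) accounting. The order
follows the narrative the thresholds come from; the runner accepts a
different order because nothing proves order dependence, and the
counts will chain correctly either way. Thresholds are read strictly
from their textual definitions:

| filter | rule | boundary behavior |
|---|---|---|
| size | keep 30 bp ≤ L ≤ 10,000 bp | 29 dropped, 30 kept |
| region | drop on ≥ 1 bp overlap with telomere/centromere, simple repeat or microsatellite; drop when a 100 bp breakpoint flank overlaps a simple repeat | repeat starting exactly 100 bp past the end is the last flank base (dropped); 101 bp is kept |
| depth | drop when member-mean deletion depth > 150, or exceeds member-mean flank depth | 150 kept, 151 dropped; equal depths kept |
| soft-clip quality | drop when member-mean Phred < 15 | 14.9 dropped, 15.0 kept |
| similar-repeat | drop when the two breakpoints lie in *distinct* repeat elements sharing a name (e.g. two AluY copies) | one shared element does not trigger; different names do not trigger |

Depth and quality decisions use **member means** at the locus level:
the filters operate on the merged candidate list, and per-sample
application is not defined there. Loci where no member carries the
required value are kept and flagged rather than dropped — absence of a
QC field is not evidence of failure. The flank width for the depth
comparison is taken to be the same 100 bp used for the annotation
flanks; the source text does not define it separately. "Same class" in
the similar-repeat rule is implemented as the repeat *name* (AluY ≠
AluSx); a `repeatMatch = "family"` option matches on the family prefix
instead, for users who consider any two Alu elements confusable.

## Genotypes, Hardy–Weinberg and the panel

Genotype codes are 0 (ref/ref), 1 (het), 2 (hom-alt), `NA` (missing).
A sample with no call at a kept locus is coded **0**: for an adequately
covered genome, the caller's silence is evidence of the reference
allele. Samples flagged low-coverage are coded missing instead (the
strict-missing mode), since silence there is uninformative. Which
choice the original workflow used is not documented; ref/ref is the
default because it is what makes cohort-scale carrier frequencies
meaningful.

The HWE filter uses the **exact conditional test**: given the observed
allele counts, all heterozygote counts of matching parity are
enumerated and the p-value sums the probabilities of configurations no
more probable than the observed one. The probabilities follow the
standard distribution of heterozygote counts conditional on allele
counts, computed by the adjacent-count ratio recurrence and normalized;
a relative tolerance of 1e-10 guards the "no more probable" comparison
against floating-point ties between symmetric configurations. The
upstream description labels this filter "Fisher's exact test"; a 2×2
Fisher test on genotype data from a single sample set is ill-defined,
and the exact HWE test is the accepted reading. A literal allele-count
Fisher mode is retained behind `method = "allele_fisher"` for fidelity
comparisons only. Monomorphic sites have a single attainable
configuration and p = 1. Sites pass when p > 1e-4, and (optionally)
when MAF ≥ 0.05, boundary inclusive.

Panel VCF export writes symbolic `<DEL>` records with `END` and
`SVLEN`, not REF-sequence spelling, so no reference FASTA is required;
round-tripping through an independent VCF parser is part of the test
suite.

## Long-read evaluation

Deletions are extracted from CIGAR strings by walking reference
consumption (`M/D/=/X/N`); each `D` run is a candidate, adjacent runs
separated by at most `gapMergeBp = 10` reference bases are merged
(noisy long-read alignments often split one deletion into several `D`
operations; 0 disables merging entirely), and merged runs with at
least **120** deleted bases are kept — below that size long-read error
rates make deletion calls unreliable. Per-read deletions cluster by
single linkage (reciprocal overlap ≥ 0.5, breakpoint deltas ≤ 100 bp —
looser than the short-read tolerances because long-read breakpoints are
imprecise) and an event requires **≥ 2 distinct reads**; the event
interval is the median start/median end over members.

Concordance uses greedy one-to-one matching in descending
reciprocal-overlap order with a deterministic tie-break (smaller query
start first): a query matches when reciprocal overlap ≥ 0.5 and both
breakpoint deltas ≤ 200 bp. Optimal bipartite matching is unnecessary
at these densities; greedy with a fixed order is reproducible. Query
deletions under 120 bp are excluded from the denominator to mirror the
truth set's size floor. All tolerances are arguments. Reported
percentages round half-up to one decimal, matching how consistency
rates are conventionally printed.

## The cis-eQTL scan

For every variant within 1 Mb of a gene's TSS (boundary inclusive at
exactly 1 Mb — the window definition does not exclude its endpoint), an
additive OLS of expression on dosage with intercept is fit; the slope's
two-sided t-test has n − 2 degrees of freedom. Pairs with missing
values are dropped per test; a genotype constant after dropping is
skipped as `monomorphic` rather than reported with an undefined
statistic. No covariates enter the default model (none are defined for
it); a covariate hook would be the first extension for real data, where
expression factors and population structure matter. q-values are
Benjamini–Hochberg **within each gene's cis-window**, significant at
q ≤ 0.01. Genomic inflation λ is the median association χ²₁ (obtained
by inverting p-values) over the null χ²₁ median, 0.4549364.

Fine-mapping is an external step. The provided `flagLeadVariants()`
stand-in flags, per window, the minimum-p variant and anything within
one log10 of it; it ignores LD structure and is **not** equivalent to
credible-set fine-mapping — pipelines with real fine-mapping output
should supply the causal flag as input. Feature enrichment uses the
two-sided Fisher exact test with the sample odds ratio a·d/(b·c);
zero cells yield an infinite or zero odds ratio that is flagged, not
continuity-corrected. Conservation-style scores are averaged per base
over the covered fraction of each deletion, with the coverage fraction
reported so sparse tracks are visible.

## The synthetic cohort

The generator's defaults are the study conditions the pipeline targets:
**174 samples**, ~30× mean depth (SD 5), a bimodal deletion-size
mixture (60% in 30–100 bp, 40% in 300–400 bp — the second mode is what
polymorphic Alu insertions look like against a reference that carries
the insertion), allele frequencies uniform on [0.05, 0.5] (panel-worthy
polymorphic deletions), and a both→single orientation degradation
probability of 0.2 at mean depth, scaled by `meanDepth/sampleDepth` and
capped at 0.9 — lower-depth samples degrade more, which is precisely
the failure mode joint-call recovery repairs. Four violations per
filter rule are planted with engineered QC signatures, labeled in the
truth table, and placed (like all clean loci) by rejection sampling at
≥ 500 bp from every annotation feature so that no clean locus can
trip a filter by accident. Long reads cover each true locus 5× as
`500M <len>D 500M` alignments with Gaussian breakpoint jitter
(default SD 10 bp; tests of exactness use 0). Expression gives a
configurable fraction of genes (default 5%) one causal cis variant
with |β| equal to `effectSize` noise-SDs and a TSS within half the
cis-window of it.

All randomness flows from one master seed through fixed per-component
sub-seeds (tracks, cohort, long reads, expression), so each stage is
independently reproducible and identical seeds give byte-identical
files.

What the generator does **not** emulate: read-level sequences and
base qualities, mapping artifacts, GC-dependent coverage waves,
reference errors, segmental duplications, expression normalization
structure (batch, PEER-style factors) and LD between deletion loci.
Passing the synthetic suite therefore demonstrates the *logic* of
clustering, recovery, filtering, testing and matching — boundary
behavior included — not performance on real cohorts, where tolerance
choices (breakpoint jitter, overlap thresholds) would need tuning
against a long-read truth set.

## Problem sizes and numerical checks

The test and acceptance suites run, as the package's chosen problem
sizes: the full default cohort (174 samples × 300 clean + 20 violation
loci) end to end; 200 random clustering instances of ≤ 20 calls against
a transitive-closure oracle; every orientation assignment of clusters
up to six members against the recovery rule; every genotype triple with
n ≤ 50 against an independent enumeration of the exact HWE
distribution (agreement < 1e-12); 1,000 random CIGARs against an
independent CIGAR engine; 10,000 null eQTL tests for calibration
(KS uniformity, λ within [0.95, 1.05]) and 60 windows for power at
β = 1 SD, n = 82, MAF ≥ 0.2. OLS slopes are checked against `lm()` to
1e-10.

Degenerate inputs are contracts, not accidents: empty call sets cluster
to empty output; empty clusters, all-zero genotype counts, empty query
sets in concordance, zero-coverage score intervals and p-values outside
(0, 1] all raise or return documented sentinels.

## Known limitations

* The similar-repeat filter queries breakpoints as single bases; a
  breakpoint just outside an element (within soft-clip uncertainty)
  does not trigger it.
* Locus-level member-mean filtering can keep a locus whose calls are
  individually marginal but jointly acceptable; per-sample filtering is
  not offered because the candidate list is locus-level.
* The lead-variant causal stand-in is LD-blind (see above).
* Genotypes are caller-supplied; no re-genotyping from reads.
* The panel export is unphased and unindexed (no bgzip/tabix), by
  scope.
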