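---
title: "Methods: CNVR construction, read-depth genotyping, and Vst divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNVR construction, read-depth genotyping, and Vst divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvpop)
```

## Scope and data model

`cnvpop` starts where CNV callers stop. Its inputs are per-sample,
per-caller call sets (interval, DEL/DUP type, optional quality fields),
per-sample windowed depth tracks, a gene annotation, a QTL interval table,
and a sample-to-population map. Caller identities are abstracted to three
roles — `RD` (single-sample read depth), `PAIRED` (discordant/split read
pairs), `POPRD` (population-aware read depth) — because the pipeline never
executes the tools; only the shape of their output matters.

All internal coordinates are 0-based half-open, BED-style. GFF3 (1-based
inclusive) is converted at the I/O boundary and nowhere else; interval
arithmetic therefore needs no ±1 bookkeeping, and abutting intervals share
no base. Chromosome names are matched as exact strings: silent "chr"
prefix normalisation can double-count or zero out overlaps, so any aliasing
must be done explicitly upstream.

## Call filtering

A read-depth CNV call is retained when

* its significance satisfies `pval < 0.001` (strict),
* its fraction of zero-mapping-quality reads satisfies `q0 < 0.5` (strict;
  high q0 marks repeat-confounded calls), and
* it spans strictly more than 1 kb (`end − start > 1000`; a call of exactly
  1000 bp is removed).

A missing quality field passes its condition vacuously — callers that never
report a p-value (e.g. split-read callers) are not penalised, and the same
policy is applied uniformly across callers. Whether population-aware
read-depth output should receive the same thresholds is genuinely open; the
uniform default is the conservative reading, and all three thresholds are
plain policy fields.

## Consensus merging

Per sample, calls form a graph: an edge joins two calls from *different*
callers, on the same chromosome, of the same type (configurable), whose
reciprocal overlap — overlap length divided by each call's own length —
is at least 0.5 for both. Connected components supported by at least two
distinct callers, including the anchor role `POPRD`, emit one consensus
call. The anchor default operationalises a merge that keeps
population-level variation (the population-aware caller is the base set)
while discarding singleton calls private to one caller; both the anchor
and the support threshold are exposed, because a plain ≥ 2-of-3 union is an
equally defensible reading.

Consensus breakpoints are the per-coordinate medians of the member calls,
with even-count medians rounded *down* — a deterministic tie-break that
keeps coordinates integral. Quality fields aggregate conservatively:
minimum p-value, maximum q0, mean copy-number estimate. Filtering happens
before merging because the quality fields are call-level quantities.

The merge is O(n²) per sample in the number of filtered calls, which is
well under a thousand here; a sweep would be needed only for call sets
orders of magnitude larger.

## CNVR construction and the landscape summary

Cohort-wide, consensus calls of any type and sample that transitively
overlap by at least 1 bp are unioned into one CNVR spanning the minimum
start to maximum end — the common CNVR definition; no reciprocal-overlap
requirement is applied at this stage (that stringency already acted within
samples). Each region is classified *gain* (only DUP calls), *loss* (only
DEL), or *both*. Regions longer than their class cap — 50 kb for loss and
mixed regions, 500 kb for gain regions — are discarded rather than
truncated: truncation would invent breakpoints no caller reported.
Identifiers are assigned in genomic order after filtering, and the
construction is invariant to input order.

The landscape summary reports class counts, total and mean length
(the mean floored to integer bp, as such averages are conventionally
printed; the exact ratio is kept alongside), the fraction of the genome
covered, and a histogram over half-open length bins [0, 2 kb), [2, 5 kb),
[5, 10 kb), [10 kb, ∞) — half-open so the bins partition.

## Read-depth genotyping

For a diploid genome, the copy number of a region is estimated as

$$\widehat{CN} = 2 \cdot r / m$$

where `r` is the overlap-weighted mean count of the depth windows
intersecting the region (a window contributes in proportion to the bp it
shares with the region) and `m` is a global per-sample reference depth.

The reference statistic is the **median** window count by default. The
mean over all windows is biased by the very CNV windows it includes —
upward in duplication-heavy samples, downward in deletion-heavy ones, by a
per-sample factor of a few percent at realistic CNV loads — whereas the
median equals the diploid background depth whenever CNVs cover a minority
of windows. The median makes the estimator exact on noiseless tracks and
is the robust normalisation read-depth genotypers conventionally use; the
mean remains available (`stat = "mean"`) for sensitivity checks. The
estimator is scale-invariant in sequencing depth either way.

A CNVR with no window coverage is imputed CN = 2 and flagged in a mask that
travels with the matrix (and survives the TSV round trip); downstream Vst
includes imputed cells at face value but reports how many were used. No GC
correction is applied — the synthetic tracks are GC-free — but the tracks
are ordinary window counts, so a per-window correction can be applied
before genotyping.

## Annotation

Each CNVR receives exactly one genomic context by precedence: *exonic* if
it overlaps any exon, else *intronic* if it overlaps a gene body, else
*upstream* / *downstream* if it lies within 1 kb 5′ / 3′ of a gene
(strand-aware), else *intergenic*. Finer annotation classes (splicing, UTR, ncRNA) are
deliberately collapsed into these five, which is the granularity CNVR
studies report. Independently of the label, every gene
whose span inflated by 1 kb intersects the CNVR is assigned to it,
strand-ignorant — "within 1 kb" is a symmetric notion — giving the gene
sets used for enrichment and for outlier-gene reporting.

QTL colocalization removes QTLs spanning ≥ 5 Mb first (the interval stands
in for the mapping confidence interval; wide QTLs colocalize with
everything and inform nothing), then reports every ≥ 1 bp (CNVR, QTL) pair
with its overlap, plus distinct-CNVR / distinct-QTL / per-trait counts.

Term enrichment is an explicit one-sided hypergeometric test per term with
Benjamini–Hochberg adjustment across tested terms; terms absent from the
query set are skipped. Raw-p thresholds (0.01 for GO-style, 0.05 for
KEGG-style term maps) mirror common practice in web enrichment tools, so
the `significant` flag uses raw p by default — but both p and q are always
reported so an adjusted cutoff can be applied instead. Term maps are taken
as given; no GO-DAG propagation is attempted.

## Vst divergence

For one CNVR and populations of sizes $n_1, n_2$:

$$V_{ST} = \frac{V_T - V_S}{V_T}, \qquad
V_S = \frac{n_1 V_1 + n_2 V_2}{n_1 + n_2}$$

with $V_T$ the copy-number variance over the pooled pair and $V_k$ the
within-population variances. Variances use divisor *n* (population
variance), the classical convention for this statistic; the divisor is a
parameter for sensitivity analysis, and Vst is invariant to relabelling
the pair, shifting all CN values, or scaling them positively.

Numerical conventions: $V_T = 0$ (an invariant locus) defines Vst as 0
rather than NaN — invariant loci are minimally differentiated and the
ranking stays total. Negative Vst (within-population variance exceeding
pooled) is retained in records and means. Outliers are called either as
the top `ceil(0.05 · N)` records (scanning default) or as records strictly
above an interpolated percentile of the Vst distribution (98th by default,
for gene listing); the percentile uses linear interpolation between order
statistics (`stats::quantile` type 7), pinned because percentile
definitions differ across ecosystems and determinism requires one.

## The synthetic cohort

The generator's defaults describe the validation study: three populations
(NY = 7, PN = 10, XN = 10 samples) on a 3 × 10 Mb genome; 60 shared loci
and 12 divergent loci; locus lengths log-uniform in 2–20 kb; carrier
frequency of shared loci uniform in 0.3–0.9 (with at least one carrier
forced); carrier copy numbers 3–6 for duplications (weighted toward 3–4)
and 1 (mostly) or 0 for deletions; boundary jitter SD 50 bp; per-caller
false-negative rate 0.05; decoy false calls at rate 0.02 per locus per
sample/caller; Poisson depth with 30 reads per 1 kb window at CN 2. These
are desk-scale stand-ins chosen to be realistic for resequencing CNV work:
cohort structure mirrors a three-breed design, jitter of tens of bp and
5% miss rates are typical of read-depth callers at ~10× coverage, and
2–20 kb loci populate all reported CNVR size classes.

Divergent loci rotate through the three population pairs: one pair member
is fixed at CN 2, the other fixed at the locus carrier CN (so the expected
Vst for the target pair is exactly 1), and the third population segregates
at frequency 0.5 (yielding intermediate Vst for off-target pairs, so each
pair's outlier ranking is dominated by its own loci). The truth table's
`expected_vst_*` columns are computed from the assigned copy numbers by
the Vst formula itself, never estimated.

Two placement choices matter. Loci sit on the depth-window grid (starts
and lengths are multiples of the window size): windows then nest exactly
inside loci, so noiseless genotyping is exactly calibrated and the
noiseless limit of the whole pipeline is a sharp test (recovery must be
100%, Vst must equal the truth table to floating tolerance). Observed
calls are de-aligned from the grid by jitter, so the noisy regime exercises
partial-window weighting. Second, loci are kept ≥ 10 kb apart, so jittered
calls from neighbouring loci cannot merge into one CNVR and
locus-to-CNVR matching stays unambiguous.

What the generator does *not* emulate: GC and mappability bias, breakpoint
microhomology, caller-specific error profiles (callers differ only by
independent noise draws), linkage between loci, and real genome annotation
density. Passing recovery tests therefore demonstrates the correctness of
the downstream logic under a controlled error model, not caller accuracy
on real data.

## Pipeline mechanics and problem sizes

`run_pipeline()` executes the stages over plain files with a TSV manifest:
each stage records an md5 over its input files and parameters, and is
skipped on rerun when nothing changed, so corrupting an intermediate file
reruns only the stages downstream of it. Every product carries the hash of
the scientific configuration (filesystem paths excluded) in a `#` header
line, and two runs with the same seed are byte-identical.

The shipped validation uses the default-scale cohort (27 samples, 72 loci,
30 Mb genome) for end-to-end recovery, and smaller cohorts (2 × 2 Mb,
18 loci) for pipeline mechanics; oracle cross-checks run on randomized toy
instances (≤ 50 calls on 100 kb chromosomes for per-base region scans,
≤ 20 × 50 matrices for the Vst brute force, N ≤ 30 for exhaustive
hypergeometric enumeration). These sizes were chosen so the whole suite
exercises every code path at comfortably interactive runtimes.

## Known limitations

* Only DEL/DUP are modelled; inversions, translocations and insertions are
  out of scope (a VCF structural-variant adapter would be the natural
  extension of the readers).
* The genotyper estimates a continuous CN; it does not call integer
  genotypes or segment ploidy, and sex chromosomes receive no special
  normalisation.
* Vst significance is rank-based (top fraction / percentile); no
  permutation p-values are computed, though the per-pair records expose
  everything such a test would need.
* Enrichment treats terms independently (no DAG-aware propagation or
  redundancy trimming).
* The consensus stage assumes the anchor caller produces calls for the
  loci of interest; with `anchor_caller = NULL` it degrades gracefully to
  a support-count rule.
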