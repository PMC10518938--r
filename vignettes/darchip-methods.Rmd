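---
title: "Methods: set-theoretic DARs, ChIP-seq overlap enrichment, and triad evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: set-theoretic DARs, ChIP-seq overlap enrichment, and triad evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darchip)
```

## The model

`darchip` links a chemical perturbation to candidate disorders through the
transcription factors whose binding sites are differentially represented in
chromatin that the chemical opens versus closes. The statistical object is,
per ChIP-seq experiment, a 2×2 contingency table over the condition's DARs:

|              | overlaps peaks | does not |
|--------------|---------------|----------|
| opened DARs  | a             | b        |
| closed DARs  | c             | d        |

with margins fixed at the opened/closed DAR counts. The null hypothesis is
that opened and closed DARs overlap the experiment's peaks in equal
proportion; it is tested with the exact two-tailed Fisher test (sum of all
hypergeometric tables at most as probable as the observed one) and
corrected with Benjamini–Hochberg across all experiments of one enrichment
call — the natural family, since one call corresponds to one submission of
one DAR set against one library. The enrichment score is −log₁₀ *Q*.

Two modelling assumptions deserve emphasis. First, **overlap is binary per
region**: a DAR either touches an experiment's peaks (≥ 1 bp, half-open
semantics) or it does not, however many peaks it touches. Counting overlap
*events* instead would break the fixed table margins. Second, **DARs are
set-theoretic**, not quantitative: a region is differential when one
group's common accessible regions have zero base-pair overlap with the
other group's. No read-count modelling is attempted, so subtle quantitative
accessibility shifts below total presence/absence are invisible by design.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `peak_score_threshold` | 100 | int(−10·log₁₀ Q) | admits only peaks with caller Q ≤ 10⁻¹⁰; applied to ATAC replicates and the ChIP-seq library |
| `flank` | 5000 | bp | gene-list mode represents a gene as [TSS − 5 kb, TSS + 5 kb), symmetric regardless of strand (strand only decides which gene end is the TSS) |
| `score_cap` | 500 | −log₁₀ Q | Q underflows to 0 for extreme tables; the cap keeps scores, ranks and "maximum score" summaries finite |
| continuity correction | +0.5 | — | fold enrichment log₂[((a+½)/(a+b+½)) / ((c+½)/(c+d+½))] stays finite when c = 0; p values always use raw counts |

## Numerical choices

* **Two-tailed sum tolerance.** Tables whose point probability ties the
  observed one must be included; the comparison `p_i ≤ p_obs` is done at
  relative tolerance 10⁻⁷ so floating-point noise cannot drop an
  equal-probability table.
* **Tie-breaks.** Collapsing multiple experiments of one antigen keeps the
  highest enrichment score, then the larger |log₂ fold enrichment|, then
  the lexicographically smallest experiment id. Triad cells tied at the
  maximum score record the lexicographically smallest TF symbol. Both rules
  make outputs deterministic.
* **ROC/PR ties.** AUROC is the Mann–Whitney statistic with half credit for
  tied scores; AUPR sweeps thresholds with tied scores processed as one
  block, so neither depends on within-tie ordering. Under constant scores
  AUROC is 0.5 and AUPR equals the positive prevalence.
* **Degenerate inputs.** A 2×2 table with an empty margin carries no
  information and returns p = 1 with a warning; a condition with zero
  opened or zero closed DARs is carried to the enrichment step, which
  refuses it with an explanatory error rather than silently dropping it.
  Conditions whose evaluation labels are single-class are excluded from
  per-condition means (and logged) but their cells remain in the merged
  global vector as negatives.

## Design decisions where the design was open

* **Replicate "common" regions** are the base-pair-level genomic
  intersection across replicates (the output of chained BED intersection),
  not a per-peak voting rule; replicate-count imbalance between groups is
  irrelevant because each group is intersected independently.
* **DARs are whole intervals.** The group non-overlap filter is a per-region
  predicate: a region survives intact or is discarded, never truncated.
* **Chromosome names match as exact strings** ("chr1" ≠ "1"); an optional
  `chr_normalize` flag prefixes bare names. Silent cross-dialect matching
  is a worse failure mode than an explicit empty intersection.
* **Peaks within one set are never merged**: merging would change overlap
  counts relative to the caller's raw output.
* **Missing chemical–disease cells score 0** rather than being dropped, so
  every condition has a complete score vector; the per-condition negative
  set is the matrix's shared disease columns minus the standard's
  positives.
* **Symbol matching is uppercase-exact** between ChIP antigens and the
  TF–disease table; no ortholog mapping is attempted, mirroring how a mouse
  antigen vocabulary meets a human disease-gene table in practice.

## What the simulator emulates — and what it does not

`sim_config()` describes a toy genome (2 chromosomes × 1 Mb) carrying 200
opened-truth and 200 closed-truth loci of 500 bp, placed uniformly with a
clearance (2·jitter + 50 bp) that guarantees replicate jitter can never
create cross-group overlap. Exposed replicates cover the opened loci plus a
shared 200-peak accessible background; control replicates cover the closed
loci plus the same background; each replicate jitters every peak edge by up
to ±25 bp. The ChIP-seq library holds 10 TFs × 2 experiments of 300 bp
peaks: a planted TF (TF01, TF02 by default) covers each opened locus with
probability `p_fg` = 0.9, any other coverage happens at `p_bg` = 0.1, and
100 uniform decoy peaks are added per experiment. Each planted TF is linked
to one dedicated true disease among 20; 30 noise links connect non-planted
TFs to non-true diseases. Noise links deliberately avoid planted TFs: a
random link on a truly activated TF would create a chemical–disease pair
that is arguably real but unlabelled in the standard — label noise rather
than annotation noise — and the generator's job is to plant unambiguous
truth. These sizes are the package's fixed study conditions; they keep a
full pipeline run in the low seconds while leaving planted effects far
above sampling noise.

Every stage draws from its own RNG stream derived from the master seed by a
fixed offset, so changing the library shape does not perturb DAR placement,
and all outputs are byte-reproducible functions of the configuration.

The simulator does **not** emulate read-level data, realistic peak-width or
inter-peak distance distributions, chromosomal clustering of regulatory
elements, correlated TF binding, DNA-methylation levels, or incomplete/
biased disease annotation. Passing the planted-recovery tests therefore
demonstrates that the pipeline's set operations, statistics and joins are
correct and well-calibrated under its own assumptions — not that the
biological signal in real exposure data is as clean as the planted one.

One property of the null simulation is worth knowing when reading its
numbers: negative diseases may be linked to several (non-planted) TFs while
each positive disease links to exactly one, so under `p_fg = p_bg` the
maximum-over-TFs score of a negative cell is stochastically slightly larger
and the null AUROC sits somewhat below 0.5 rather than exactly at it. This
is a property of max-aggregation over unequal link counts, not a bug in the
evaluator — the tie-free evaluator itself is checked against pairwise and
threshold-enumeration oracles.

## Problem sizes used in validation

The test suite checks the Fisher implementation against full enumeration of
all 2×2 tables with both margins ≤ 20, the overlap engine against an
all-pairs scan on 100 instances of 1,000 × 1,000 intervals, BH against the
hand step-up on 1,000 random vectors, AUROC/AUPR against their oracles on
200 vectors including heavy ties, and the end-to-end planted recovery on 20
seeded runs at the default study conditions plus an 8-run null pool and a
500-experiment null library for false-positive control.

## Known limitations

* The set-theoretic DAR definition is sensitive to peak-caller stringency:
  a region marginally called in one control replicate removes an opened
  DAR entirely.
* Fisher's test treats DARs as exchangeable units; genomic autocorrelation
  (neighbouring DARs bound by the same TF) makes the effective sample size
  smaller than the DAR count, so Q values on real data are anti-
  conservative to an unknown degree. Ranking TFs is safer than interpreting
  absolute Q.
* Max-aggregation over TFs (and over experiments per TF) favours
  well-assayed TFs and densely annotated diseases; scores are comparable
  within a run, not across libraries of different depth.
* No disease-ontology traversal or synonym resolution: disease identifiers
  must match between the TF–disease table and the standard.
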