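---
title: "Max-min exon scoring: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Max-min exon scoring: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mmes)
```

## The problem and the model

Alternative splicing changes *which* exons of a gene are expressed, not
necessarily *how much* the gene is expressed overall. On an exon array each
probeset measures one exonic target, so an isoform switch shows up as a
subset of a gene's probesets moving relative to the rest of the gene. Two
classical summaries exist: splicing-index methods compare each probeset to
a gene-level summary between groups, and spread-based methods treat a large
intragenic range of probeset signals as suggestive. The max-min exon score
combines the two ideas: probeset signals are first normalized against a
reference (normal) cohort, then the *range* of exon-level signals within
the gene is the statistic.

Given a log2 intensity matrix $x_{is}$ (probeset $i$, sample $s$) with
tumor/normal labels:

1. $P_{itN} = x_{it} - \overline{x}_{iN}$, where $\overline{x}_{iN}$ is the
   arithmetic mean of probeset $i$ over the normal samples. Zero means
   "indistinguishable from normal" for that probeset.
2. $\mathrm{Exon}_{et} = \mathrm{mean}_{i \in e}\, P_{itN}$, the unweighted
   mean over the exon's probesets.
3. $\mathrm{MMES}_{gt} = \max_{e \in g} \mathrm{Exon}_{et} -
   \min_{e \in g} \mathrm{Exon}_{et}$, one score per gene per tumor, and
   the per-gene mean over all tumors is the ranking statistic.

Two structural properties follow directly and are enforced as tests:

* **Shift invariance.** Adding a constant to every probeset of a tumor
  (a whole-array or whole-gene expression change) leaves every
  $\mathrm{MMES}_{gt}$ of that tumor unchanged — the score cannot be
  inflated by ordinary differential expression.
* **Scale response.** Multiplying a gene's exon deviations by $k \ge 0$
  multiplies its score by $k$; scores are in log2 units.

The model's assumptions are worth stating plainly: it assumes the
annotation's probeset-to-exon assignment is correct, that the normal cohort
is a valid reference for every probeset, and that "an exon subset moving
against the gene" is splicing — copy-number breakpoints inside a gene, 3′
bias, or probeset-specific artifacts produce the same signature and are not
distinguished. That is why the pipeline ends in *screening plots* for human
review, not in a significance call.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_probesets` | 3 | probesets/gene | fewer gives no intragenic contrast; single- and two-probeset genes are uninformative for a range statistic |
| `top_n` (`select_top`) | 900 | genes | the screening depth handed to manual plot review |
| SD threshold (cohort plots) | 1 | normal-cohort SD | flags tumors beyond the normal band per probeset; counts above and below are kept separate |
| `splice_delta` | 1.5 | log2 | simulator effect size: a ~2.8-fold isoform shift, the magnitude validated events show |
| `splice_tumor_fraction` | 0.5 | — | isoform switches are typically present in a subset of tumors |
| `noise_sd` | 0.25 | log2 | realistic post-RMA residual noise for exon-array probeset summaries |

Ranking ties are broken by ascending `gene_id` so rank lists are
byte-reproducible; the mean is taken over *all* tumors with no trimming or
QC subsetting.

## Numerical choices

* **"Normalized to the mean" is subtraction on the log2 scale.** The data
  arrive log2-transformed and every screening plot displays signal relative
  to normal at zero on a log2 axis, so the natural reading is a log
  fold-change. The normal-cohort mean is likewise the arithmetic mean of
  log2 values (not the log of the linear-scale mean), consistent with the
  matrix being an RMA-style summary. The choice is isolated inside
  `normalize_to_normal_mean()`, so the linear-scale alternative is a
  one-line change.
* **Deviation SD and thresholds.** The cohort-plot histogram uses the
  normal cohort's per-probeset sample SD (n−1 denominator) and *strict*
  inequalities at mean ± 1 SD. At least two normal samples are required,
  otherwise the SD is undefined and the plot builder errors. Counting on
  raw signals against a shifted threshold is mathematically identical to
  counting on normalized signals, so only one path exists.
* **Floored baseline.** The flat reference line in cohort plots is
  `floor(grand mean)` of the gene's raw log2 signal over all samples. It is
  cosmetic and never enters scoring.
* **Degenerate inputs.** Missing/non-finite cells are hard errors (exon
  array summaries are complete by construction; imputation would silently
  bias the range statistic). A gene whose exons all drop out of the matrix
  is excluded from the rank list with a logged count rather than scored 0,
  so rank lists are never silently deflated. An all-zero splicing index
  (`short + long = 0`) is undefined and the sample is excluded from the
  Welch comparison with a logged count.
* **Annotation contract.** Coordinates are 0-based half-open (BED
  convention). Each probeset belongs to exactly one exon and each exon to
  exactly one gene; probesets annotated to two genes are rejected at load.
  Probesets that genuinely span annotated exon boundaries are outside the
  data model and must be resolved (or dropped) upstream. Exon order within
  a gene follows transcription: ascending genomic start on `+`, descending
  on `-`.
* **Welch test.** The tumor/normal comparison of splicing indices uses the
  unequal-variance two-sample t test with Welch–Satterthwaite (real-valued)
  degrees of freedom, two-sided. The implementation delegates to
  `stats::t.test`; the test suite checks it against an independently coded
  textbook formula and against a null-calibration simulation.
* **Standard curves.** Ordinary least squares of Ct on log10(copies) via
  `stats::lm`; efficiency is `10^(-1/slope) - 1`; inversion is
  `10^((ct - intercept)/slope)`. A non-negative slope flags the curve
  invalid rather than erroring, so a batch of assays can be triaged.

## What the simulator emulates — and what it does not

`simulate_annotation()` / `simulate_expression()` generate a discovery
cohort in the study's geometry — 44 tumors and 25 normal samples by
default — with per-probeset baselines around 6.0 log2 units (SD 1.0
between probesets), i.i.d. Gaussian measurement noise, whole-gene
differential-expression confounders (`de_delta` added to all probesets in
all tumors) and splice-switch events: a contiguous block of exons at the
5′ or 3′ end of the transcript (mirroring alternative first/last-exon
usage, the pattern the validated genes show) shifted by `splice_delta` in
a per-gene random subset of tumors. Ground truth (which genes, which
exons, which tumors) is recorded exactly. `simulate_qpcr()` emulates the
47-tumor / 19-normal validation cohort: log-normal copy numbers around
group-specific short-isoform proportions (0.8 vs 0.3 by default), a
log-normal 18S reference channel, and a 10-fold dilution standard series
from a configured slope/intercept with Gaussian Ct noise.

One seed drives everything: the annotation stream uses `seed`, the
expression stream `seed + 1`, the qPCR stream `seed + 2`, each isolated
with a save/restore of the caller's RNG state, so stages can be regenerated
independently and full runs are byte-reproducible.

Deliberately *not* simulated: probe-sequence effects, cross-hybridization,
background signal, correlated (batch) noise, partial isoform mixtures, and
events in interior exon blocks. Passing the recovery tests therefore shows
the scoring chain is correct and well-calibrated against its own error
model — it does not show field performance on real arrays, where
annotation error and probe effects dominate.

## Test problem sizes

The suite exercises the arithmetic oracle on 20 random instances of up to
~50 genes × ≤10 tumors against a naive triple-loop reference; exact effect
propagation on noise-free cohorts (where a spiked delta of 2.0 must appear
as a score of exactly 2.0 and DE-only genes as exactly 0); recovery on
five 1000-gene, 44/25 cohorts (recall@100 of spiked genes, and the
DE-confounder enrichment AUC, which is computed against the unspiked
background so that genuinely top-ranked splice genes do not mechanically
depress it); null calibration of the deviation histograms over 20 seeds
(expected fraction beyond ±1 SD ≈ 2Φ(−1) ≈ 0.317, slightly inflated
because mean and SD are estimated from 25 normals); Welch-test uniformity
under the null at 1000 replicates; and byte-identical reruns of the full
simulate → score → plot → validate workflow.

## Known limitations

* The score has no null distribution and no p-value; ranking depth
  (`top_n`) is a screening budget, not an error rate.
* A gene with exactly one exon always scores 0 even if it has ≥3 probesets;
  intra-exon splice variation is invisible to the exon-level mean.
* The normal-cohort mean is unweighted; a contaminated or outlying normal
  sample shifts every tumor's reference.
* Only two isoform channels (short, pooled long) are modeled in the
  validation stage; assays resolving more than two isoform classes need to
  be collapsed before `compare_groups()`.
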