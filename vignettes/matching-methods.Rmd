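---
title: "Matching aCGH features to expression features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching aCGH features to expression features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnmatch)
```

## The problem

Integrative analyses of tumour genomes routinely pair a DNA copy number
platform (aCGH, measured as log2 ratios per genomic probe, then segmented
into piecewise-constant profiles and called as
loss/normal/gain/amplification) with an mRNA or microRNA expression
platform. Before any cis-effect of gene dosage on expression can be
studied, every expression feature must be assigned copy number data — but
the two arrays interrogate different, mostly disjoint genomic intervals.
cnmatch implements six assignment procedures plus summarization
extensions, a downstream cis-correlation stage, and a simulator that
generates paired platforms with known ground truth.

## The data model

Each platform is an annotation table (`feature_id`, `chromosome`,
`start`, `end`) plus data matrices. Coordinates are **1-based inclusive**:
a feature's length is `end - start + 1` and overlap uses the closed-interval
`min(end) - max(start) + 1` formula. Array annotation files are
conventionally 1-based, so this convention is fixed once and BED input
(0-based half-open) is converted at the I/O boundary. Chromosome labels
are compared after stripping an optional `chr` prefix and upper-casing
X/Y/MT, since annotation dialects mix freely in the wild. Midpoints
`(start + end) / 2` are kept as exact half-integers; rounding them can
silently change which of two probes is "nearest".

All matching functions canonicalize their inputs (sort by chromosome,
start, end, ID), so results never depend on input row order.

## The six procedures

Let $g$ be an expression feature and $j$ index copy number features on
the same chromosome, with midpoints $m_g$, $m_j$.

* **label** — both platforms are mapped to a common descriptor set (gene
  symbols, say) and matched on shared descriptors; weights uniform. Works
  without coordinates but inherits all flaws of the maps, and can in
  principle link features on different chromosomes (an optional strict
  flag drops such pairs).
* **distance** — $g$ gets the single feature minimizing $|m_j - m_g|$.
  Always succeeds when the chromosome carries any probe, but the winner
  may be megabases away; matches beyond `warn_distance` (default 1 Mb)
  are flagged in a report.
* **distanceAny** — all features with $|m_j - m_g| < w$ contribute, with
  weights $\propto 1/(|m_j - m_g| + \delta)$, normalized to sum one. The
  offset $\delta$ (default 1 bp) keeps the weight finite when a probe
  midpoint coincides with the gene midpoint.
* **overlap** — $g$ gets the feature maximizing the overlap fraction:
  overlapping bp divided by the **copy number probe length** (not the
  gene length), so a probe inside the gene scores exactly 1. Genes with
  no overlapping probe stay unmatched.
* **overlapAny** — all features with fraction $> t$ contribute, weights
  proportional to their fractions.
* **overlapPlus** — overlap first; an unmatched gene is then assigned the
  nearer of its two flanking features, but only when no sample shows a
  breakpoint (a change in segmented value) between the flanks. Because
  copy number is discrete along the genome, interpolating across a
  breakpoint-free gap is safe; across a breakpoint the gene's true dosage
  is undecidable and it stays unmatched. Note this procedure reads the
  experimental data, so the matching can differ between data sets from
  the same platform.

**Tie-breaks.** Equal distances or equal overlap fractions are resolved
toward the smallest start, then smallest end, then lexicographic feature
ID. Any rule would do statistically; a deterministic one makes runs
reproducible and matches the convention that, among several fully
contained probes, the leftmost is reported. Window and threshold
comparisons are strict (`< w`, `> t`).

**overlapPlus details.** "Closest down-/upstream feature" is measured by
midpoint, for consistency with the distance procedure. A gene with only
one flank (chromosome end) stays unmatched. Flank equality of segmented
rows is tested with absolute tolerance `1e-8`: segmented data are
piecewise constant, so exact equality is expected and the tolerance only
guards against float round-trips through text files.

## Summarization

When several features match one gene their data must be reduced to one
signature per gene:

* **weighted** — per sample, the weight-weighted mean of normalized and
  segmented values. Missing values are dropped with per-sample weight
  renormalization. Calls are categorical and are not averaged: the
  dominant-weight feature's call is used, with weight ties resolved per
  sample toward the call closest to 0 (the least aberrant reading), then
  the smaller start. The original tools do not document their call
  handling, so this choice is documented here as this package's own.
* **maximum** — per sample, the segmented value with the largest absolute
  deviation from zero, carrying along that feature's normalized value and
  call. More variable dosage signatures can help cis-effect discovery but
  raise the false-discovery risk.
* **split at breakpoints** — before averaging, each matched set is cut
  wherever any sample's segmented value changes between consecutive
  features, so no average ever mixes copy number segments. Genes may then
  recur in the matched set (same expression signature, different dosage
  signatures), which enlarges the multiple-testing burden downstream;
  provenance output always records the recurrences so corrections can
  count them.
* **expand to singletons** — every matched feature becomes its own entry
  with weight 1; idempotent.

Weights are normalized to sum one inside matching, so summarization is a
plain weighted mean and every match map is self-describing.

## Cis-effect stage

Per matched entry, the Spearman rank correlation (average ranks for
ties) between expression and the segmented dosage signature is computed
across samples, with a two-sided p-value from the asymptotic rank test
and Benjamini-Hochberg adjustment across entries at level 0.05
(`stats::p.adjust`). Constant vectors yield missing results and are
excluded from the adjustment denominator. Spearman was chosen as the
association measure because it is also the statistic used to compare
procedures: `pairwise_win_counts()` counts, over the genes matched by
every procedure under comparison, how often procedure A's rho strictly
exceeds B's (ties count for neither). More elaborate dose–response
models (e.g. constrained piecewise-linear splines) are deliberately out
of scope; the rank test is assumption-light and sufficient for ranking
procedures.

## The simulator

`simulate_platforms()` generates what the procedures assume:
non-overlapping probes laid out along each chromosome (one probe per
equal-width slot, uniformly placed inside it), piecewise-constant
segmented profiles whose breakpoints sit at randomly drawn segment
borders, normalized = segmented + Gaussian noise, calls by thresholding,
and expression = per-gene baseline + `beta` x segmented dosage at the
gene midpoint for cis genes, plus noise. The returned truth records each
gene's cis flag, its truly overlapping probes, and its true dosage
matrix.

Default conditions: 2 chromosomes of 100 Mb, 2000 oligo-like probes of
~60 bp, 500 genes of ~30 kb, 30 samples, 10 segments per chromosome with
state probabilities (loss, normal, gain, amp) = (0.10, 0.70, 0.15, 0.05)
and log2-ratio levels (-0.7, 0, 0.58, 1.3) — roughly the values expected
for single-copy changes in impure tumour samples (log2(3/2) = 0.58) —
noise sd 0.2, cis fraction 0.3 with slope 0.8 and expression noise sd
0.5, and a single global seed from which all randomness flows. Setting
`cn_probe_length = 150000` emulates a legacy BAC platform: probe
midpoints then usually sit farther than 10 kb from any gene midpoint, so
a 10 kb distanceAny window matches far fewer genes than a 100 kb one —
the qualitative signature of BAC-era data. What the simulator does *not*
emulate: scanner-specific noise, probe-level GC or length biases,
segmentation error (its segmented profiles are exact), and
non-autosomal or non-linear dosage–expression relationships. Passing
tests therefore validate the procedures' logic, not robustness to
preprocessing artefacts in real data.

## Numerical choices and degenerate inputs

* Weight sums are validated to 1 within `1e-9`; breakpoint equality uses
  absolute tolerance `1e-8`.
* A perfect correlation underflows the asymptotic p-value to 0; p-values
  are clamped into `(0, 1]` before adjustment.
* Genes on chromosomes absent from the copy number platform, genes with
  no feature in the window/threshold, and single-flank genes in
  overlapPlus are reported per gene with a reason rather than erroring.
* An empty match map summarizes to an empty (headers-only) bundle with a
  warning, not an error.

## Problem sizes in the test suite

The property suites run at desk scale, chosen as the smallest sizes at
which the checked properties are non-trivial: oracle-equivalence on 200
random instances of up to 200 probes x 50 genes; monotonicity of the
window/threshold parameters on 100 instances; and parameter recovery on
100 simulator replicates at the default study conditions (500 genes, 30
samples, cis fraction 0.3, beta 0.8), requiring the mean |rho| of cis
genes to exceed that of background genes in at least 95 replicates.

## A worked example

```{r example}
ann <- example_annotations()
ann$ge$end - ann$ge$start + 1   # a ~71 kb gene on chromosome 14

match_distance(ann$cn, ann$ge)
as.data.frame(match_overlap_any(ann$cn, ann$ge))
```

The distance procedure picks the single probe nearest the gene midpoint;
overlapAny spreads its weight uniformly over the ten probes inside the
gene — every one is fully contained, so all overlap fractions are 1 and
each weight is 0.1.

## Known limitations

* Strand is ignored throughout, as is conventional for copy number work.
* Only the copy-number-to-expression pairing ships, although the
  principles (distance and overlap weighting) generalize to other
  platform pairs.
* No probe re-annotation or liftover: annotations are taken at face
  value, and matching quality is bounded by annotation quality —
  especially for label matching.
* The cis stage is univariate per gene; no spatial smoothing across
  neighbouring genes and no trans-effect analysis.
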