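---
title: "Classifying stem-cell methylomes with AROW: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying stem-cell methylomes with AROW}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylarow)
```

## The problem

Human induced pluripotent stem cells (iPSC) are epigenetically almost
indistinguishable from embryonic stem cells (ESC): unsupervised clustering
of Illumina methylation-array beta values separates pluripotent from
somatic and embryonal carcinoma (ECC) lines, but not iPSC from ESC, and a
per-CpG differential screen finds essentially no site whose group-mean
methylation differs by 0.3 or more between the two. `methylarow`
implements the supervised alternative: train a linear online classifier to
discriminate the four cell types from the beta profile, then read the
iPSC/ESC distinction out of the model's per-CpG coefficients
("determination weights") rather than out of univariate statistics.

## The model

The learner is AROW — Adaptive Regularization of Weight vectors — in its
diagonal-covariance form. Each binary model keeps a mean weight vector
$\mu \in \mathbb{R}^p$ and a per-feature confidence $\Sigma =
\mathrm{diag}(\sigma)$, initialised at $\mu = 0$, $\sigma = 1$. For an
example $(x, y)$ with $y \in \{+1, -1\}$ and margin $m = y\,\mu^\top x$,
nothing happens when $m \ge 1$; otherwise

$$
\beta = \frac{1}{\sum_j \sigma_j x_j^2 + r}, \qquad
\alpha = (1 - m)\,\beta,
$$
$$
\mu_j \leftarrow \mu_j + \alpha\, y\, \sigma_j x_j, \qquad
\sigma_j \leftarrow \sigma_j - \beta\, (\sigma_j x_j)^2 .
$$

The confidences are positive and non-increasing: a feature that has
participated in many updates moves less and less. The scalar $r > 0$ (the
"regularization weight") damps every update; it is the single
hyperparameter swept by the protocol. The full-covariance variant is
deliberately not implemented — at hundreds of thousands of CpG features a
dense covariance is infeasible, and the diagonal form is the standard
large-scale choice.

Multiclass discrimination is one-vs-others over the fixed class order
(ESC, iPSC, ECC, somatic): four binary models share one feature index;
every training sample updates all four (target $+1$ for its own class,
$-1$ for the rest); a sample is assigned to the class whose linear score
$\sum_j \mu_{c,j} x_j$ is largest. There is no intercept: the score is
purely methylation rate times determination weight, which keeps the
weights directly interpretable per CpG, and ties (measure-zero with real
weights) break by class order for determinism.

One *epoch* presents every training sample exactly once in a freshly
shuffled order. Shuffles are seeded per epoch from a deterministic
derivation of the master seed, so any (fold, regularization) cell of the
protocol is bit-reproducible in isolation. Missing beta values contribute
zero to scores and updates — with diagonal state this is exactly "no
information about that feature from that sample".

## The protocol

Cell lines are split into four groups A–D, stratified by cell type
(`assign_fold_groups()` deals shuffled lines round-robin, so per-class
group sizes differ by at most one). The four series train on BCD/CDA/
DAB/ABC and test on A/B/C/D respectively. The default sweep trains each
of the 4 series at six regularization weights (0.10, 0.25, 0.50, 0.90,
1.00, 1.10) for 300 epochs, checkpointing every 10 — 7,200 epochs and 720
saved models sweep-wide. `select_optimal()` averages the held-out macro
F-score over the four series per (epoch, r) and returns the argmax (ties:
higher training mean, then smaller epoch, then smaller r). Note the
selection uses the test folds — the protocol reproduces that leakage
faithfully rather than fixing it, because the pooled confusion matrix of
the four selected fold models is the quantity of interest downstream.
Pooling ("mixing") concatenates each series' held-out predictions, so
every cohort line contributes exactly once and row sums equal the cohort
class sizes.

Metrics follow the confusion-table conventions exactly: per-class
precision (column fraction) and recall (row fraction); macro averages are
unweighted means over the four classes; the macro F-score is the harmonic
combination $2PR/(P+R)$ of the two *macro* averages — not the mean of
per-class F-scores, a convention worth stating because the two differ.
Undefined per-class values (empty row or column at a degenerate early
checkpoint) enter the macro average as zero with a warning. Displayed
percentages are rounded half-up to two decimals; all internal computation
keeps full precision.

## Input handling

Beta matrices are consumed as already-normalized GenomeStudio-style
exports: tab-separated, `TargetID` first column, values in $[0,1]$, `NA`
for missing. IDAT parsing and normalization are out of scope. Quality
filtering removes a probe when its sequence overlaps a variant with minor
allele frequency $\ge$ 5% *or* its detection p value is $\ge$ 0.05 in at
least one sample. Both boundaries are inclusive; the two criteria are
independent quality failures, hence the union. The per-sample reading of
the detection-p rule is the conservative choice — a probe must be reliable
in every sample — and probes without annotation are kept on the MAF
criterion (absence of evidence) and logged. Filtering never alters a beta
value, only selects rows; after design-intersection
(`intersect_common_probes()`) probes are sorted lexicographically for
determinism, after filtering input order is preserved.

## Weight mining

At the selected sweep cell, the ESC and iPSC weight lists of each fold
model are combined and ranked jointly — a single top-2,000 cut (positive
high-weight sites) and bottom-2,000 cut (negative) across the union of
both classes' entries. The joint reading is what allows per-class counts
inside the cut to differ, which is the observable of interest. Ties at
the cutoff break by class order then probe id. Intersecting each class's
per-sign sets across the four folds gives the common sites, and the two
cross-class intersections define the signature: *iPSC Pos–ESC Neg* (high
positive weight for the iPSC model and high negative weight for the ESC
model in every fold) and its mirror *ESC Pos–iPSC Neg*. Annotation
tallies count a probe once per gene-feature group it carries (Illumina
probes frequently carry several), so gene-feature counts may exceed the
number of sites; proportions normalize by total contributions.

## Variability statistics

A "differentially methylated region" here is a single CpG whose
group-mean beta differs by $\ge 0.3$ (inclusive) between two groups; the
group summary is the arithmetic mean, the convention for beta-difference
screens. Because pools differ in size (27 ESC vs 43 iPSC lines),
between-group counts are compared by resampling: draw 15 lines per pool
without replacement, count, repeat 100 times, report mean ± SEM (SEM =
SD/√reps). Per-probe SD histograms use bins of width 0.05 on $[0, 0.5]$
with an open-ended last bin so counts conserve the probe total, and
"high SD" means SD $\ge$ 0.10; within-one-type variable sites are probes
whose beta range (max − min across the 15 drawn lines) is $\ge 0.3$,
sharing the differential threshold for coherence. The bin edges, both
thresholds, draw size and replicate count are configurable; the defaults
above are the protocol's.

## The synthetic cohort and what it does (not) show

`generate_cohort()` draws a 104-line cohort (27 ESC, 43 iPSC, 9 ECC, 25
somatic; one sample per line) over 20,000 probes by default — genome-wide
scale is unnecessary for structural validation and 20,000 keeps the full
sweep tractable on a desktop; all probe-number-dependent counts are
reported per cohort and never compared with genome-wide values. Beta
noise is Beta-distributed with archetype class means and per-class
concentration, so variance shrinks near 0 and 1 as on arrays. Planted
archetypes:

* **pluripotency_hypo** (2%) — unmethylated in ESC/iPSC/ECC, methylated
  in somatic lines; **somatic_hypo** (2%) the reverse;
  **class_marker_ECC** (1.2%) methylated only in ECC.
* **ipsc_variable** (5%) — the signature source: ESC/ECC/somatic sit near
  0.10 while every iPSC line draws its own level uniformly on
  [0.05, 0.95], emulating stochastic reprogramming-associated aberrant
  hypermethylation with no common hotspot.
* **ipsc_variable_hypo** (0.8%) — the mirrored flavour (others near
  0.90, iPSC line-specific), emulating incomplete erasure; it is why the
  mirror signature set is small but non-empty, matching the strong
  hyper/hypo asymmetry of the real signature.
* **esc_variable** (7.5%) — equal class means (0.30) with ESC
  concentration 10 (SD ≈ 0.13, just above the high-SD cut), carrying the
  higher genome-wide background variability of ESC lines; the global ESC
  concentration (120 vs 150 elsewhere) adds a mild genome-wide excess
  below the high-SD cut.
* The remainder is neutral with a common bimodal-ish mean per probe, plus
  100 probes spiked to fail the MAF filter and 80 to fail the detection-p
  filter (flagged in the truth table).

Variable-in-iPSC probes are annotation-enriched near transcription start
sites and CpG islands so the annotation summaries have signal to find.

What passing on this cohort shows: the learner, protocol, selection,
intersection and resampling machinery recover planted structure of
realistic effect size at realistic dimensionality. What it does not show:
performance on real arrays — no probe-type chemistry, batch, imprinting
or correlation structure is simulated, class differences are cleanly
archetypal, and the planted iPSC-variable effect (mean shift ≈ 0.4)
creates between-class differential sites that the real ESC/iPSC contrast
famously lacks; real-data quantities that depend on the deposited cohort
(the 94.36% best average F-score, the 61/479/93/181 common-site counts,
the 13/117 signature sizes, chromosome enrichments) are therefore not
asserted anywhere.

### A known limitation: per-class high-weight totals

In the published analysis the iPSC model contributes about 2.3 times more
high-weight sites than the ESC model. On the synthetic cohort this
direction holds for positive sites (ratio ≈ 2) and for the within-class
sign pattern (ESC negative-dominant, iPSC positive-dominant), but not for
the pos+neg totals: with one-vs-others training in which *all four*
models update on every sample, every site separating iPSC from ESC
necessarily earns a large iPSC-positive *and* a large ESC-negative
weight, and the ESC model — a class characterised here purely by the
absence of iPSC aberrations — additionally compensates with large weights
on shared pluripotency/somatic markers. Across every generator setting
tried, the ESC total matched or exceeded the iPSC total. A multiclass
update rule that touches only the true class and the top violating class
would concentrate updates on the larger iPSC class and plausibly
reproduce the totals direction, but this package implements the
all-four-updates reading of one-vs-others throughout. The corresponding
acceptance check is left failing rather than redefined.

## Numerical choices

* Checkpoints are versioned serialized containers (weights, confidences,
  r, epoch count, seed, probe list) with bit-exact round trip; truncated
  or foreign files are rejected.
* Beta file round trips write 17 significant digits so
  write-then-read is bitwise identity.
* Seeds: one master seed per run; per (series, r) cell seeds and
  per-stage pipeline seeds derive deterministically from it, all below
  $2^{31}$.
* Zero-denominator metrics, all-missing probes in group means, and
  empty probe intersections all have defined, logged behaviour rather
  than NaN propagation.

## Problem sizes used by the checks

The structural test suite runs on cohorts of 60–400 probes with reduced
class sizes (minimum 5 per class, the floor at which the resampling
operations still run at reduced draw size). The full-scale recovery
checks use the default cohort — 20,000 probes, 104 samples — with a
reduced sweep of two regularization weights (0.50 and 1.00, the
protocol's optimum plus a mid-grid value) over 100 epochs, and the
protocol-bookkeeping check runs the complete 7,200-epoch default sweep on
a 60-probe cohort. These sizes are the package's validation choices:
large enough that every planted effect is at its design strength, small
enough to run on one desktop core in minutes.
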