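---
title: "Deriving and calibrating miRNA sensitivity signatures from qPCR arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and calibrating miRNA sensitivity signatures from qPCR arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsig)
```

## The problem

TaqMan low-density arrays (TLDA cards) measure a few hundred microRNAs per
sample by microfluidic qPCR. A recurring clinical question is whether a small
miRNA expression signature can predict response to a targeted drug — here,
sensitivity of lung and pancreatic cancer cells to the EGFR inhibitor
erlotinib. The statistical workflow is classical and small-sample: a handful
of training cell lines per class, univariate screening, a diagonal linear
discriminant, internal cross-validation, and a random-signature calibration
of the final predictor. mirsig implements that workflow end to end, together
with a simulator of the whole study design so that every stage can be
validated against a known ground truth.

## From raw Ct to the feature space

The raw readout is a cycle-threshold (Ct) per well; lower Ct means more
transcript, and one cycle is a factor of two. Wells that never cross the
fluorescence threshold are reported as `"Undetermined"`; they are imputed at
the maximum cycle of the run (Ct = 40 by default) so the matrix is complete.
Imputed wells keep a provenance flag, and a fold change computed from one
warns, because ceiling imputation truncates the true (unbounded) value and
can inflate ratios.

Normalization subtracts the endogenous-control signal (U6-style wells),
yielding ΔCt. Two conventions are implemented:

* `per_sample` (default): subtract, within each sample, the mean Ct of that
  sample's control wells. This cancels sample-loading differences exactly —
  adding a constant to every well of a sample leaves its ΔCt unchanged —
  and is the standard comparative-Ct convention.
* `global`: subtract one scalar, the grand mean of all control wells. This
  variant is kept because the phrase "average of the endogenous control Ct
  values across all samples" in descriptions of such workflows is genuinely
  ambiguous between the two readings; global subtraction does not correct
  loading, so it is not the default. The mode used is recorded in the output
  so downstream reports are unambiguous.

Single-gene validation uses the comparative Ct method: fold change
\(= 2^{-\Delta\Delta Ct}\), averaging technical replicates on the ΔCt scale
before exponentiation.

## Probe screening

Each assay probe is tested with a two-sample Student's t-test (pooled
variance) between sensitive and resistant training samples. The pooled form
rather than Welch is the named test of the original workflow and is the
default; Welch is a flag. No multiple-testing correction is applied at this
stage — the screen is a candidate filter, and familywise calibration arrives
later through the random-signature null. The screening threshold defaults to
\(\alpha = 0.1\), the value tied to the candidate-set size in the source
workflow, which also quotes \(\alpha = 0.05\) for the same step; the
discrepancy is inherent to the description and the parameter is exposed.
Probes with zero pooled variance (possible when a probe is ceiling-imputed
everywhere) are floored at a pooled SD of 1e-8 cycles and flagged rather
than emitting infinite statistics.

## The DLDA classifier and the identity-line rule

The predictor is diagonal linear discriminant analysis: class means
\(\mu_{kj}\) per probe, one pooled within-class variance \(\sigma_j^2\) per
probe (floored at 1e-8 cycles²), and independence across probes. For an
unknown sample \(x\), each class gets a score

\[ s_k(x) = -\tfrac12 \sum_j \frac{(x_j - \mu_{kj})^2}{\sigma_j^2}, \]

the diagonal-Gaussian log-likelihood up to a constant shared by both classes
(the \(\log\sigma_j^2\) term cancels in the comparison and is omitted, which
keeps the two-score geometry exact). Plotting the sensitive score against
the resistant score, samples above the identity line are called sensitive.
A zero margin is called resistant: for a borderline tumour, predicting
resistance is the conservative clinical error. Equal priors are the default
(training is 4 vs 4); priors are configurable. Tests verify the calls agree
exactly with a brute-force implementation that evaluates the full
log-densities including the cancelled terms.

Internal validation is leave-one-out: refit on n−1 samples, score the
held-out one. Each fold must retain at least two samples per class, so the
full data needs three.

## Signature reduction

The candidate list from the screen (ordered by ascending p) is reduced by
evaluating nested prefixes at every size k, scoring each by LOOCV accuracy;
ties are broken by external-validation accuracy (never used for fitting),
then by smaller k. Exhaustive subset search is not attempted —
\(\binom{38}{13}\approx 10^{10}\) — and a greedy wrapper would be less
reproducible; the nested-prefix rule is deterministic given the screen
order. This is an interpretation of how a 38-probe candidate set becomes a
13-probe signature, not a verified reconstruction of the original authors'
search, and both entry points (a searched signature and the packaged fixed
13-miRNA list, `erlotinib_signature()`) are provided.

A consequence worth knowing: accuracy on eight training samples is a very
coarse score. When the class separation is strong, LOOCV accuracy saturates
at 8/8 from k = 1 and the parsimony tie-break returns very small signatures.
On the default simulation (3-cycle effects, 0.75-cycle noise — a
4-standard-deviation separation per probe) the selected k is typically 1–2,
not 13. Recovering a planted 13-probe set via this selection rule requires a
regime where small prefixes actually fail cross-validation, i.e. weaker
per-probe effects than the default design plants. We kept both the
documented selection rule and the default design as specified rather than
tuning either toward the other; the acceptance suite records the resulting
behaviour honestly.

## The random-signature null

The selected signature's performance is calibrated against chance by drawing
10,000 random signatures of the same size from the assay-probe pool
(controls excluded), fitting DLDA to each on the training data, and scoring
each on the external validation set. The empirical adjusted p-value is the
fraction of random signatures the candidate fails to *strictly* outperform —
ties count against the candidate, with no pseudo-count, so a candidate
beating 9,510 of 10,000 draws reports exactly \(p = 0.049\). The common
\((b+1)/(n+1)\) estimator is available behind a flag. Because DLDA treats
probes independently, each random signature's model is a row-subset of
per-probe statistics computed once; the implementation exploits this (it is
algebraically identical to refitting, and a test asserts so against naive
refits), making 10,000 draws essentially free.

Two properties of this statistic deserve emphasis:

* Under no signal, a random candidate is exchangeable with the draws, so the
  p-value is valid but *conservative* on its discrete grid (ties inflate
  it); the test suite checks super-uniformity rather than exact uniformity.
* The p-value is not monotone in effect strength. Random signatures overlap
  a planted 13-probe set with probability \(1-(1-13/381)^{13}\approx 0.36\),
  and once per-probe effects are strong enough that a single planted probe
  classifies well, overlapping draws tie a saturated candidate more and more
  often. On the default simulation the median empirical p sits near 0.1
  regardless of how decisively the true signature performs — the same order
  as values reported from real data of this design. Decisive p-values
  (≤ 0.01) would require validation cohorts noisy enough that only the full
  signature, not single probes, classifies reliably.

## Clustering and visualization

Signature expression is clustered agglomeratively with Pearson correlation
distance (1 − r) and average linkage — the conventional expression-heatmap
defaults; Euclidean and complete/single linkage are flags. The linkage
heights are checked against a brute-force O(n³) agglomeration oracle. Items
are sorted lexicographically before clustering, making the tree invariant to
input order, with alphabetical tie-breaking of leaf order. Heatmaps map
negated ΔCt to a blue–white–red ramp so that red is high expression, and the
sign convention is printed in the margin; exports include GCT 1.2 and
CDT/GTR/ATR files for GenePattern-style viewers.

## Target filtering

Predicted miRNA→mRNA interactions with mirSVR-style scores are filtered at
score < −1.25, strictly (boundary scores excluded); duplicate miRNA–gene
pairs keep the most negative score, because enrichment tools operate on gene
sets. Pathway enrichment itself is out of scope — published enrichment
p-values of this kind depend on a proprietary knowledge base — so the module
exports plain GMT gene sets any enrichment tool can consume.

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the study design the workflow assumes: 381
assay probes plus 3 control wells (384 wells, a full card), 4 sensitive vs
4 resistant training cell lines, 16 labelled validation samples (8 cell
lines, 4 primary tumours, 4 metastatic tumours generated from the resistant
profile), and a planted 13-probe signature, 11 up- and 2 down-regulated in
sensitive samples. Where the design had to be quantified without a stated
value, we chose once what is realistic for TLDA data: a 3-cycle class
effect (an 8-fold expression difference, typical of a validated miRNA
marker), 0.75-cycle well noise, per-sample loading offsets of 0.5 cycles
(cancelled by per-sample normalization), baselines uniform on 20–32 cycles,
and dropout approaching certainty linearly within 4 cycles of the 40-cycle
ceiling. With these baselines, undetected wells are rare by default —
dropout concentrates where biology puts it, in down-regulated probes pushed
toward the ceiling — and designs with high baselines exercise it heavily.
A `discordant_sample` switch gives one resistant training line the sensitive
expression profile, so the workflow's handling of a single
internal-validation failure is testable.

Not emulated: sequence-level biology, amplification-efficiency curves,
plate spatial effects, multi-plate batches, and tumour-specific biological
heterogeneity beyond the class profiles. Passing tests on this generator
demonstrate the pipeline's statistical machinery, not performance on real
tumours; in real FFPE data, effects are weaker, noise is larger and
non-Gaussian, and validation cohorts are heterogeneous.

## Numerical choices

* Variance floors: 1e-8 cycles (screen SD) and 1e-8 cycles² (DLDA), with
  flags on floored probes.
* Ties: zero DLDA margin → resistant; screen ordering ties → larger |t|,
  then probe id; dendrogram leaves → alphabetical; permutation ties → count
  against the candidate.
* Text formats write doubles with up to 17 significant digits, so every
  round trip (Ct table, GCT, CDT) is bit-exact.
* Seeds: every stochastic entry point takes an explicit seed and restores
  the caller's RNG state.

## Problem sizes used in the test suite

The packaged tests run the full design at 100 simulation seeds for the
screen/LOOCV/permutation/clustering sweeps, 1,000 random instances for the
classifier-against-oracle sweep, 200 replicates for null calibration of the
permutation p, and a 40-probe miniature of the card for property-style
loops. These sizes give stable Monte-Carlo estimates while keeping a full
run in tens of seconds.
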