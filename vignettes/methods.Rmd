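---
title: "Methods: sequence features, network training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence features, network training and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(sgpred)
```

`sgpred` classifies prion-like domains (PrLDs) as recruited or not recruited
into stress granules under heat stress, from three sequence-derived
biophysical features. This vignette is the package's account of the model,
its assumptions, the tunable parameters, the numerical conventions, and what
the synthetic benchmark does and does not demonstrate.

## The model

A PrLD sequence $s$ of length $n$ over the 20 canonical residues is mapped
to a feature vector $(A, q, c)$:

**Aggregation propensity.** Each residue type carries an intrinsic
propensity value a3v (the default scale ships as an editable data file,
`inst/extdata/aggrescan_a3v.tsv`; hydrophobic residues score high, charged
and Q/N residues low). The per-position window average
$\mathrm{a4v}_i = \mathrm{mean}\,\{\mathrm{a3v}_j : |j - i| \le
(w-1)/2\}$ is summarized as

$$\mathrm{Na4vSS} = \frac{100}{n} \sum_{i=1}^{n} \mathrm{a4v}_i ,$$

a length-normalized score spanning positive and negative values. Because
the classifier should see only non-negative aggregation inputs, the raw
score is min–max normalized to $[0,1]$ between the scores of the least and
most aggregation-prone training sequences ($A$); out-of-range values at
prediction time are clamped.

**Net charge per residue.** The Henderson–Hasselbalch fractional charge of
each ionizable group at pH $p$ is $+1/(1+10^{\,p-pK_a})$ for basic and
$-1/(1+10^{\,pK_a-p})$ for acidic groups; summing over the sequence and
dividing by $n$ gives the NCPR $q \in (-1, 1)$. NCPR is a pure composition
statistic — permuting the sequence does not change it.

**Cysteine percentage.** $c = 100 \cdot \#C / n$, a proxy for the
disulfide-bonding and thiol-oxidation potential that heat-associated
oxidative stress can engage.

The binary classifier is a feed-forward network with layer sizes
3–9–6–1 and hyperbolic-tangent units in every layer. Inputs are affinely
scaled per feature to $[-1,1]$ (min–max from the training set, stored in
the model) because the three features live on very different scales
($[0,1]$, roughly $\pm 0.1$, and $[0,100]$) and tanh units need comparable
input magnitudes. Classes are encoded as targets $\pm 1$ and a sequence is
called *positive* (recruited) when the output activation is $\ge 0$, ties
included.

The central assumption is that recruitment is driven by sequence-intrinsic,
largely composition-determined physics — aggregation propensity, net
charge, cysteine content — rather than by positional motifs, cellular
context, or interaction partners. The model also presumes its input is a
pre-delimited PrLD; it makes no attempt to find domain boundaries in
full-length proteins.

## Training

Training minimizes the batch sum of squared errors by backpropagation with
the gdx rule: gradient descent with momentum plus an adaptive learning
rate. Per epoch, with velocity $V$, learning rate $\eta$ and momentum $\mu$:

$$V \leftarrow \mu V - (1-\mu)\,\eta\,\nabla E, \qquad W \leftarrow W + V.$$

After the step, the new error $E_\mathrm{new}$ is compared with the
previous $E_\mathrm{old}$:

* $E_\mathrm{new} > E_\mathrm{old} \cdot \texttt{max\_perf\_inc}$ — the
  step is **rejected**: weights revert, $\eta \leftarrow \eta \cdot
  \texttt{lr\_dec}$, and the velocity is reset to zero (the package's
  choice: a rejected direction should not persist through momentum).
* otherwise the step is accepted, and if $E_\mathrm{new} <
  E_\mathrm{old}$, $\eta \leftarrow \eta \cdot \texttt{lr\_inc}$.

Training stops at the error goal or after the epoch budget. Given the seed
(which fixes the uniform $[-0.5, 0.5]$ weight initialization), the whole
trajectory is deterministic; there is no stochastic shuffling because the
gradient is computed over the full batch.

### Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| window bands | ≤75: 5, ≤175: 7, ≤275: 9, else 11 (residues) | classical length-dependent rule for sliding-window aggregation scoring |
| pH | 7.0 | cytosolic-like conditions |
| terminal charges | excluded | PrLDs are internal domains; free termini would be artifactual |
| pKa set | D 3.65, E 4.25, C 8.3, Y 10.07, H 6.0, K 10.53, R 12.48 | conventional biochemistry values, editable data file |
| epochs / goal | 500 / 0.01 SSE | ample for a 3-9-6-1 net on tens of sequences |
| lr0, lr_inc, lr_dec | 0.01, 1.05, 0.7 | canonical gdx settings |
| max_perf_inc | 1.04 | canonical gdx error-increase tolerance |
| momentum | 0.9 | canonical gdx momentum |
| init range | uniform $[-0.5, 0.5]$ | simple, reproducible, adequate at this scale |
| decision threshold | 0 | midpoint of the $\pm1$ target encoding |

Every default is overridable through `sg_feature_config()` and
`sg_train_config()`; the fitted bundle records all of them, so a serialized
model is self-contained.

## Numerical conventions and degenerate inputs

* **End effects.** Windows shrink one-sided at the sequence ends so every
  residue has an a4v and Na4vSS is defined for short domains; sequences
  shorter than the smallest window (5) are rejected with a clear error.
* **Non-canonical residues** (X, B, Z, U, `*`) are rejected by default —
  the propensity scale, pKa table and cysteine count are undefined on them.
  `skip_invalid = TRUE` (CLI `--skip-invalid`) drops offending records with
  a warning instead.
* **Zero-denominator metrics** are reported as `NA` ("undefined"), never
  silently 0 and never an error: e.g. precision for a predictor that calls
  nothing positive.
* **Constant features.** If a feature has zero range in training, its
  input-scaling gain falls back to 1 and it contributes a constant 0.
* **ROC ties** are handled as a single threshold step, which makes the
  trapezoidal AUC equal the Mann–Whitney identity
  $\mathrm{AUC} = U/(n_1 n_2)$ with ties counted one half; this identity is
  enforced by a brute-force pairwise oracle in the tests.
* **Mann–Whitney p-values** are exact (full enumeration of the
  $\binom{n}{n_1}$ assignments, midrank ties) for combined $n \le 12$, and
  otherwise use the normal approximation with tie and continuity
  correction. The cutoff balances fidelity against cost; the
  approximation path is cross-checked against `stats::wilcox.test`.
* **Stratified splitting** draws per class, rounding half up, and refuses
  classes that cannot populate both halves.
* **Serialization** writes doubles at 17 significant digits, so
  save → load → save is byte-identical and predictions survive a round trip
  bit-exactly.
* **Gradient correctness** is pinned by comparing backpropagation with
  central finite differences (relative error $< 10^{-6}$) on random small
  networks.

## The synthetic generator

Real recruitment datasets are small, expensive microscopy experiments.
`sg_simulate()` provides a fully seeded stand-in: sequences are drawn
residue-by-residue (i.i.d.) from class-specific composition profiles, with
lengths uniform on 60–250 residues, a typical PrLD span. The default
profiles (`sg_default_profiles()`) encode the direction of the real
separation: the positive class is enriched in W/F/I/L/V and H/E/K/R with
cationic mass exceeding anionic (expected NCPR > 0) and ~1.5% cysteine; the
negative class is Q/N/G/S-rich, slightly anionic and nearly cysteine-free.
`sg_profile_expectation()` gives the closed-form feature expectations; the
package tests verify empirical class means match them and that sampled
frequencies converge to the profiles (total-variation distance < 0.02 at
$10^5$ residues).

i.i.d. sampling is a deliberate simplification: every feature the
classifier consumes is composition- or window-average-determined, so
positional structure would add nothing the model can see. Consequently the
synthetic benchmark demonstrates that the pipeline — features, scaling,
training, thresholding, evaluation — recovers a composition-separable
signal; it does **not** demonstrate performance on real PrLDs, whose
classes overlap far more (real recruited and non-recruited domains differ
by shifted means, not disjoint compositions), contain local hydrophobic
hot-spots, and carry evolutionary correlations between positions. Expect
the near-perfect synthetic accuracies reported by the tests to be an upper
bound, not an estimate, of real-data behavior.

## Problem sizes

The tests and the acceptance script mirror a realistic experimental design:
64 labeled PrLDs (32 per class), split 16+16 for training and 16+16 for
held-out evaluation, repeated over five seeds; property checks run on a few
dozen random instances each. At these sizes the entire suite completes in
well under a minute on one core.

## Known limitations

* The propensity scale is an input, not a claim: swapping the data file
  changes the aggregation feature wholesale. The default transcription is
  deliberately kept in one editable place.
* The normalization anchors (min/max Na4vSS) derive from the training set;
  a prediction-time sequence outside that range is clamped, losing
  resolution at the extremes.
* A single fixed topology and a single train/test split: no
  cross-validation, regularization or early stopping. At 32 training
  sequences a more elaborate protocol would mostly fit noise.
* Binary labels only; domains with intermediate recruitment behavior are
  outside the model.
* Feature means, not the full model, decide linearly separable cases; the
  network earns its keep only near the class boundary, and with three
  inputs it remains interpretable but cannot exploit positional motifs.
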