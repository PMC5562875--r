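---
title: "Predicting early-folding residues: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting early-folding residues: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model implemented by `efoldr`, the meaning and
defaults of its parameters, the design of the synthetic data generator used
for testing and demonstration, and the numerical conventions the package
commits to. It is a methods document: code chunks illustrate the API but are
not evaluated when the package is built.

## The problem

During the first milliseconds of protein folding, a subset of residues forms
persistent local structure before the rest of the chain does. Pulsed-labelling
hydrogen/deuterium exchange (HDX) experiments detect these *early-folding
residues*: their backbone amide protons become protected from exchange in the
earliest kinetic phase. Early-folding residues are thought to nucleate foldon
assembly, so predicting them from sequence alone gives a window into folding
pathways where no kinetic experiment exists.

`efoldr` implements a per-residue classifier of early folding from sequence,
together with the evaluation and structure-analysis machinery such a
predictor needs: identity-stratified cross-validation, threshold-free and
thresholded performance metrics, solvent-accessibility and contact-rigidity
calculations, and amino-acid-composition bias correction for downstream
group comparisons.

## The model

### Features

The classifier never sees the raw sequence. It sees five per-residue
*profile channels* — backbone flexibility (`dyna`), side-chain flexibility
(`side`), and helix/strand/coil propensities — each itself predicted from
sequence by a linear regression over a windowed one-hot encoding (11-residue
window by default; `train_profile_predictor()`, `predict_profiles()`). This
two-stage design means the final model can be applied to any sequence with
no external software.

Per protein, the `dyna` channel is min–max shifted onto [0, 1]
(`normalize_profiles()`): backbone-flexibility predictions have
protein-specific offsets, and the shift makes the *relative* rigidity within
a protein the signal. The other four channels are propensity-like and are
left on their native scale by default (`normalize_all = TRUE` shifts them
too).

The feature vector of residue *i* concatenates, channel by channel, the
channel values at positions *i−2 … i+2* (`assemble_features()`). Window
positions past either terminus clamp to the terminal residue's value, so
every residue — including in length-1 sequences — yields exactly
5 × 5 = 25 features.

### Classifier

A support-vector machine with RBF kernel, `C = 100`, `gamma = 0.04`, and
class weights `n / (2 · n_class)` ("balanced") compensating the roughly 1:6
positive:negative imbalance of early-folding data (`efold_train()`). Decision
values are mapped to probabilities by Platt scaling — a sigmoid
`1 / (1 + exp(A·s + B))` fitted by Newton iteration on the regularized
targets `(n1 + 1)/(n1 + 2)` and `1/(n0 + 2)` (`platt_calibrate()`). A residue
is called early folding when its calibrated probability reaches the decision
threshold `tau` (`classify()`, inclusive: `p >= tau`).

### The default threshold: 0.163 versus 0.169

Published operating points for this family of predictors quote two nearby
probability cutoffs, 0.163 (stated as the threshold on estimated
probabilities) and 0.169 (appearing alongside tabulated benchmark metrics).
The two cannot both be the single default. This package adopts **0.163**,
because it is the value tied directly to the probability scale the classifier
outputs; we treat 0.169 as a per-evaluation refit of the same operating
point. Nothing in the package depends on the choice beyond the default value
of `tau`: every thresholded function takes `tau` as an argument, and
`crossvalidate()` refits the threshold per fold by default anyway (see
below), reporting the fitted values.

## Evaluation

### Identity-stratified cross-validation

Residue-level random splits leak: homologous proteins put near-identical
windows on both sides of the split. `crossvalidate()` therefore clusters
proteins by single-linkage over pairwise global alignments (BLOSUM62, gap
open 10, extend 0.5), connecting two proteins when sequence identity exceeds
`si_cutoff = 0.25` over an alignment covering at least `cov_cutoff = 0.90`
of the longer sequence (identity and coverage are computed on the
terminal-gap-trimmed alignment span). Folds are leave-one-cluster-out, so no
held-out protein has a qualifying homolog in training.

Platt calibration and threshold fitting are themselves part of training, so
by default (`calibration = "inner_cv"`) they are fitted on inner
cluster-respecting splits of each fold's training data, never on held-out
data; `calibration = "train"` fits them on the training decision values
directly (cheaper, slightly optimistic). With `threshold = "fit"` (default)
the per-fold threshold maximizes Youden's J on the calibration scores; with
`threshold = "fixed"` the supplied `tau` is used everywhere.

Fold metrics (`metrics_report()`): sensitivity, specificity, accuracy,
balanced accuracy, precision, Matthews correlation, rank-statistic AUC (ties
count 0.5), and precision over the top-scoring 10% and 5% of residues.
`average = "folds"` (default) reports the unweighted mean over folds;
`average = "pooled"` scores the concatenated held-out predictions once.

### Structure metrics

For interpreting predictions against known structures the package provides:
relative solvent accessibility from classic-format DSSP output
(`parse_dssp()`, `rsa()`; maximum-ASA scales: Sander default, Tien
alternative); a contact-based rigidity estimate
`S² = tanh(b·(Σ w·exp(−d_H/r0) + Σ exp(−d_O/r0))) − c` over heavy atoms near
the amide proton and the preceding carbonyl oxygen (`contact_s2()`; amide
protons absent from the input are placed geometrically on the N–H bisector);
per-amino-acid bias correction recentring each residue type's distribution
on the global median (`bias_correct()`); and Wilcoxon rank-sum group
comparisons with Benjamini–Hochberg correction (`compare_groups()`).

## The synthetic data generator

Real pulsed-labelling HDX compilations are small, hand-curated and
license-encumbered; the package instead ships a generator
(`generate_dataset()`, `synthetic_config()`) that reproduces the
*statistical shape* of such a training set so that the full pipeline can be
exercised, demonstrated and property-tested offline.

Design, per protein:

1. **Sequence**: residues drawn independently from Swiss-Prot amino-acid
   frequencies; lengths drawn from a scaled beta distribution on
   [56, 164] with median near 121 (matching the composition of curated
   early-folding training sets: ~30 proteins, ~3,400 residues).
2. **Latent foldability track**: moving-average-smoothed Gaussian noise
   (window 7) plus an equally smoothed hydropathy offset
   (Kyte–Doolittle / 9), because early folding is driven by local segment
   composition, with hydrophobic segments folding earlier.
3. **Labels**: the contiguous runs where the track exceeds a dataset-wide
   cut level, with runs shorter than `min_run = 3` dropped (early-folding
   residues sit in secondary-structure elements, not isolated positions).
   The cut level is chosen on a quantile grid so the *realized*
   post-run-dropping positive fraction matches `early_fraction = 0.142`
   (~482/3,398).
4. **Profile channels**: `0.5 + 0.3·signal·f(track) + N(0, 0.25)` with a
   distinct monotone transform `f` per channel (identity, tanh, logistic,
   `x/(1+|x|)`, asinh), so the channels correlate without being copies, and
   the planted signal disappears entirely at `signal = 0` — the
   leakage-detection configuration.

What the generator deliberately does **not** emulate: real secondary
structure or any structural consistency between sequence and labels;
homology (sequences are independent, so identity clustering on synthetic
data yields singletons unless duplicates are planted); experimental
uncertainty in the HDX labels; position-specific conservation signals; or
the true covariance structure of real flexibility predictors. Conclusions
about absolute real-data performance cannot be read off synthetic runs; the
generator supports *relative* and *structural* claims (signal is recovered,
leakage is absent, interfaces compose).

Companion generators: `generate_structure_fixture()` builds ideal-helix and
extended-zigzag poly-alanine backbones (N, CA, C, O, H) for contact-S²
checks; `generate_labelled_scores()` draws binormal score/label sets whose
population AUC is exactly a requested target; and
`generate_linear_profile_data()` emits windowed-linear profile data with
known, identifiable coefficients for regression-recovery tests.

## Numerical conventions

- **Inclusive threshold**: `classify()` calls `p >= tau` positive, so a
  probability exactly at the threshold is an early-folding call.
- **Terminus handling**: feature windows clamp to the terminal residue
  rather than zero-padding, avoiding artificial feature mass at chain ends.
- **Degenerate min–max shift**: a constant per-protein channel maps to 0.5.
- **Zero-denominator metrics**: sensitivity, specificity, precision and MCC
  return 0 (with one consolidated warning) when undefined, keeping fold
  averages computable.
- **AUC with ties**: tied score pairs count 0.5 (Mann–Whitney convention);
  single-class folds report `NA` and are excluded from fold averages.
- **Youden threshold ties**: among thresholds with equal J, the largest is
  chosen (the most conservative operating point).
- **Top-fraction precision**: the selected count is `ceiling(fraction · n)`
  and scores tied with the boundary are all included.
- **Rank-deficient profile regressions**: the windowed one-hot design is
  structurally collinear (each block sums to the intercept), which is
  expected and silent; the fit uses the SVD pseudoinverse (minimum-norm
  solution) and warns only when the deficit exceeds the structural one.
- **Model persistence**: plain-text key–value format with numbers at 17
  significant digits, so a save/load round trip reproduces predictions
  exactly.
- **SVM reproducibility**: identical inputs give identical fits; row
  permutations can change probabilities by ~1e-4 (iterative SMO solver),
  which is far below any decision-relevant scale but not zero.

## Limitations

- The profile predictor is a linear model over local sequence windows; it
  cannot represent non-local effects, and profiles retrained on different
  data will shift the downstream feature scale.
- `C`, `gamma` and the class-weight rule are fixed defaults, not retuned per
  dataset; on datasets whose feature scale differs substantially from
  [0, 1]-ranged profiles they may be far from optimal.
- Single-linkage identity clustering is conservative: one borderline pair
  can chain large clusters together, shrinking the number of folds.
- The contact-S² model is a geometric proxy fitted elsewhere; its constants
  (`b = 0.8`, `w = 0.8`, `r0 = 1`, `c = 0.1`) are taken as given and the
  first residue of a chain (no preceding carbonyl) is reported as `NA`.
- Exact Wilcoxon p-values are only used for combined sample sizes ≤ 20
  without ties; elsewhere the normal approximation with tie/continuity
  correction applies.
- The synthetic generator's limitations listed above: it validates the
  pipeline, not biological performance.
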