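---
title: "Predicting RTK ligand-receptor pairs from sequence and domain features"
author: "rtkpair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting RTK ligand-receptor pairs from sequence and domain features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Receptor tyrosine kinases (RTKs) are activated by the binding of a
growth-factor ligand to their extracellular domain; knowing which ligand
activates which receptor is central to understanding proliferation and
differentiation signalling and to anticipating how the pathway can be
inhibited. Experimentally mapping these pairs is slow, so rtkpair treats the
question as supervised binary classification: given a (receptor, ligand)
pair of amino-acid sequences, does it interact?

The training signal comes from a curated set of known interacting pairs.
Because only positive interactions are curated, the negative class is
constructed by exhaustive enumeration: every receptor x ligand combination
that is not a known positive is treated as non-interacting. With 34
receptors, 67 ligands and 95 positives this yields 34 x 67 - 95 = 2183
negatives, a roughly 1:23 class imbalance that shapes two design choices
below (class weighting and AUC-centred evaluation).

## Feature recipes

Each protein is encoded independently and the pair vector is the
concatenation of the receptor block followed by the ligand block:

* **k-mer composition** (`kmer1`, `kmer2`): the relative frequency of each
  length-k word over the canonical 20-letter alphabet, in fixed
  lexicographic order; 20 + 20 = 40 dimensions per pair for k = 1 and
  400 + 400 = 800 for k = 2. Frequencies are counts over sliding windows
  divided by the number of valid windows, so every clean sequence sums to
  one per block and sequence length cancels out. Windows containing an
  ambiguity code (X, B, Z, U, O, J) are excluded from both the numerator
  and the denominator: the 20-letter basis cannot represent them and
  pseudo-count conventions would be arbitrary. A sequence with no valid
  window encodes as the zero vector with a warning.
* **domain presence** (`domain`, `superfamily`): binary vectors over the
  conserved-domain (or superfamily) types observed for each role, sorted
  lexicographically so the layout is reproducible. A coordinate is 1 iff
  the protein has at least one retained hit of that type; two domains of
  one superfamily still give a single 1 at superfamily level. Hits are
  retained when their E-value is at or below the cutoff (default 1e-8).
  Receptors and ligands keep separate vocabularies, so an accession
  annotated on both roles occupies one coordinate in each block. Hit
  coordinates are carried through I/O but ignored by the encoding, which
  is presence/absence only.
* **composite**: the 2-mer pair block concatenated with the
  superfamily pair block, letting the classifier see both the sequence
  composition and the domain architecture at once.

Two deliberate non-features: word order and domain order are discarded, and
no positional or structural information enters the encoding.

## Classifier and class imbalance

The classifier is a C-SVM (LIBSVM, via e1071). Misclassification weights
are proportional to the opposite class's size (`w_pos = n_neg / n_pos`,
`w_neg = 1`), which stops the optimizer from trivially predicting the
majority class. The kernel defaults to RBF — the library's default and the
usual choice for dense features in [0, 1] — with a log2-spaced tuning grid
(cost 2^-5..2^15, gamma 2^-15..2^3, step 2^2) searched by inner
cross-validated AUC when tuning is requested; a linear kernel remains a
configuration option. Binary and k-mer features already live in [0, 1], so
no scaling is applied by default (`scaleFeatures` enables per-column
min-max scaling for experimentation). Decision values are oriented so that
positive means "interacting", and labels are cut at 0.

## Combining two models

Two fitted models A and B can be merged at the decision-value level:

    f_comp(x) = (a f_A(x) + b f_B(x)) / (a + b),

with weights `a = AUC_A - 0.5` and `b = AUC_B - 0.5` — each model's
improvement over random guessing. The AUCs entering the weights are
measured by inner cross-validation on the training portion only, never on
the fold being evaluated. Weights are floored at 1e-6 so a chance-level or
worse partner degrades gracefully toward the informative model instead of
producing a negative or undefined weight. Combination can help or hurt;
the protocol makes no monotone-improvement promise.

## Redundancy reduction

Near-duplicate sequences inflate apparent performance, so datasets are
reduced per role before pairing: a greedy representative-based clustering
(longest sequence first, ties by identifier) places each protein into the
first cluster whose representative it matches at >= 80% identity over an
end-to-end global alignment, otherwise it founds a new cluster. The global
(Needleman-Wunsch) alignment with match = 1 / mismatch = 0 / linear gap
cost realizes the "identity over the full-length region" criterion without
a separate coverage test. This is a faithful stand-in for BLASTclust-style
tools, not a bit-exact clone; receptors and ligands are clustered
separately, and only cluster representatives (and pairs among them) are
kept.

## Evaluation protocols

* **Repeated stratified cross-validation** (default 5 folds x 5 repeats):
  per-fold class counts differ from the ideal by at most one. Within each
  fold the domain vocabulary and any hyperparameter tuning are computed
  from the training portion only (`vocabScope = "train"`, the default;
  `"all"` reproduces the simpler whole-dataset convention). Held-out
  decision values are pooled over the five folds into a single confusion
  tetrad, ROC and AUC per repeat; repeats are averaged as reals, so
  averaged counts may be fractional and a metric undefined in any repeat
  stays undefined (reported as an em dash, as happens when a weak recipe
  predicts no positives at all).
* **Independent test**: a stratified holdout of floor(20%) per class
  (19 of 95 positives, 436 of 2183 negatives at the reference shape),
  parameters tuned by 5-fold CV on the training 80% only, one final fit,
  one evaluation on the holdout; repeated three times and averaged.
* **Metrics**: precision TP/(TP+FP), recall TP/(TP+FN), F = 2pr/(p+r),
  and ROC/AUC computed by a descending-score sweep with tied scores
  collapsed into single steps and trapezoidal integration, which equals
  the Mann-Whitney concordance with ties counted one half (the test suite
  checks this equivalence against exhaustive pair counting). Scores
  exactly at the threshold count as negative predictions.

All protocols are deterministic given their seed: fold shuffles restore
the caller's RNG state, repeat i uses `seed + i - 1`, and LIBSVM training
itself is deterministic.

## The synthetic-data generator

Real datasets of this kind are assembled from interaction and annotation
databases; the generator replaces those downloads with a seeded simulation
whose structure matches what the method assumes:

* two disjoint role sets with per-role domain vocabularies and a
  domain-to-superfamily partition (every superfamily nonempty);
* per-protein domain draws without replacement (2-5 domains by default);
* an interaction rule at superfamily level: a pair's true label is 1 iff
  it carries at least one compatible (receptor superfamily, ligand
  superfamily) combination. Placing the signal at superfamily rather than
  domain level mirrors the finding that superfamily features are the most
  informative, and makes the planted signal structurally recoverable by
  the superfamily recipe;
* sequences drawn residue-wise from a mixture of a uniform background and
  per-domain Dirichlet-tilted residue preferences. `compositionBias`
  interpolates between no sequence signal (0) and fully domain-determined
  composition (1), so the k-mer recipes see a continuous-strength,
  tunable echo of the domain truth; 0.5 is the default middle ground;
* optional label noise (default 0) flipping each observed label
  independently;
* ground truth (the noise-free Bayes-optimal label of every pair) shipped
  alongside the data files.

Defaults reproduce the reference dataset shape: 34 x 67 proteins, 80/98
domain types in 26/68 superfamilies, and a positive-rate target of
95/2278. When no compatibility set is supplied, one is calibrated
greedily: combinations are added largest-fitting-gain first while they do
not overshoot the target, an overshooting combination is accepted only if
it lands closer to the target than stopping short, and at least one
combination is always chosen when the target is positive. The achieved
count is reported with a warning when the target cannot be hit exactly.
Sequence lengths default to 200-1200 residues, spanning typical
growth-factor and receptor lengths.

What the generator does **not** emulate: evolutionary relatedness (no
phylogeny, no indels, no sequence redundancy for the clustering step to
remove), realistic domain co-occurrence, motif-level binding sites, or
biased interaction sampling. Passing tests on synthetic data therefore
demonstrate that the pipeline recovers the kind of signal the method
presumes — not that real RTK data carry that signal as cleanly.

## Numerical choices and degenerate inputs

* k-mer normalization uses relative frequency (raw counts would confound
  sequence length with composition in an RBF kernel).
* Tuning ties break toward smaller cost, then smaller gamma — the less
  complex model.
* Domain types seen at prediction time but absent from a training-fold
  vocabulary are dropped with a log message; with fold-restricted
  vocabularies this is routine, not an error.
* The SVM kernel cache is set to hold the full kernel matrix for datasets
  of a few thousand pairs, which roughly halves training time at the
  reference shape.
* Empty feature blocks, all-zero rows and duplicated rows are all legal
  inputs; decision values are always finite.
* Protocol sizes used by the shipped acceptance script: the full
  34 x 67 dataset for the superfamily (5 x 5 CV), 2-mer (one CV repeat)
  and composite (three independent-test repeats) protocols, and a
  17 x 34 dataset for the doubly nested decision-value combination
  protocol, whose inner AUC-weight estimation multiplies the fit count
  by an order of magnitude.

## Known limitations

* The greedy clustering depends on the processing order (length, then
  identifier); it is reproducible but not order-free, and it is not a
  substitute-free reimplementation of any specific published tool's
  output.
* Averaged confusion counts are reals; they are rounded only for display,
  so a table assembled from averaged repeats need not satisfy
  p = TP/(TP+FP) exactly at printed precision.
* With `vocabScope = "train"`, test-fold proteins whose domains were
  never seen in training encode as zero vectors — the honest price of
  leakage-free evaluation.
* The method predicts binding vs non-binding only; affinity is out of
  scope.
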