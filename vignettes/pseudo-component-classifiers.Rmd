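---
title: "Pseudo-component sequence classifiers: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-component sequence classifiers: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psepred)
```

## The problem

Many questions in genome and proteome analysis reduce to binary sequence
classification: does this DNA window position a nucleosome, is this RNA a
microRNA precursor, does this peptide carry a modification site? A
practitioner typically has a benchmark — a positive and a negative set of
sequences — and wants a predictor for new queries without hand-assembling
the feature engineering, parameter tuning, training and validation stages
each time. `psepred` automates that pipeline for DNA, RNA and protein
sequences: encode sequences as pseudo-component vectors, jointly tune the
feature and SVM hyperparameters by cross-validated grid search, refit on the
full benchmark, and apply the model to queries.

## The feature model

Sequences of unequal length are mapped to fixed-dimension vectors that keep
a trace of sequence *order*, not just composition. The vector has two
blocks.

**Composition block.** For a sequence of length $L$ over alphabet $A$, the
$|A|^k$ overlapping $k$-mer frequencies

$$ f_u = \frac{\#\{\text{windows equal to } u\}}{L - k + 1},
   \qquad \sum_u f_u = 1, $$

with $k$-mers ordered lexicographically (A < C < G < T, A < C < G < U,
alphabetical amino acids). This is the classic k-tuple nucleotide
composition for DNA/RNA (PseKNC's first block) and, at $k = 1$, the 20-dim
amino acid composition of PseAAC.

**Pseudo components.** Sequence order enters through physicochemical
correlations. Each *unit* (a dinucleotide for DNA/RNA, a residue for
protein) carries $\Lambda$ standardized property values
$P_\xi(\cdot)$. Properties are standardized over the unit alphabet with the
*population* standard deviation,

$$ P_\xi(s) = \frac{P^0_\xi(s) - \mu_\xi}{\sigma_\xi},
   \qquad \mu_\xi = \tfrac{1}{|U|}\sum_s P^0_\xi(s),\;
   \sigma_\xi^2 = \tfrac{1}{|U|}\sum_s (P^0_\xi(s) - \mu_\xi)^2, $$

so every property has mean 0 and SD 1 over its alphabet and feature vectors
are invariant to the units of the raw scales (a tested invariant). Two
correlation forms are supported:

- *parallel* (type I): one factor per lag $j = 1..\lambda$,
  $$ \theta_j = \frac{1}{N - j}\sum_{i=1}^{N-j}
     \frac{1}{\Lambda}\sum_{\xi=1}^{\Lambda}
     \bigl[P_\xi(u_i) - P_\xi(u_{i+j})\bigr]^2, $$
  where $N$ is the number of units ($L-1$ for dinucleotides, $L$ for
  residues); $\theta_j \ge 0$ and is identically 0 on homopolymers;
- *series* (type II): one factor per (lag, property) pair,
  $$ \tau_{(j-1)\Lambda + \xi} = \frac{1}{N - j}\sum_{i=1}^{N-j}
     P_\xi(u_i)\,P_\xi(u_{i+j}), $$
  which may be negative (amphiphilic-style product correlations).

With $T$ the sum of the factors and weight $w > 0$, the final vector is

$$ x_u = \frac{f_u}{1 + wT} \;\;(u \le |A|^k), \qquad
   x_{|A|^k + j} = \frac{w\,c_j}{1 + wT}, $$

so all components sum to 1. For DNA/RNA the correlation unit is *always*
the dinucleotide, regardless of the composition-block $k$ — $k$ only sizes
the $4^k$ block. Setting $\lambda = 0$ reduces the vector exactly to the
$k$-mer composition.

Admissibility: every tier must average at least one term, so
$\lambda \le L - 2$ (dinucleotide unit) or $\lambda \le L - 1$ (residue
unit); violations are reported per sequence id, and
`extract_features()` lists *all* offending ids. In series mode $T$ can be
negative; if $1 + wT \le 0$ the normalization is degenerate and the vector
is refused with an error rather than silently rescaled.

## Property sets

Built-in defaults (`builtin_properties()`):

- **DNA / RNA** — six dinucleotide helical parameters (Twist, Tilt, Roll,
  Shift, Slide, Rise), the set conventionally used with PseKNC features;
  the RNA table is the A-form ribodinucleotide analogue.
- **Protein** — hydrophobicity, Hopp–Woods hydrophilicity, and side-chain
  mass, the classic PseAAC triple.

All tables pass through `standardize_properties()` before use, so only the
relative pattern of each scale matters. Users can supply any table covering
the full unit alphabet as a TSV (`read_property_table()`); the correctness
tests use randomly generated toy tables, so nothing in the machinery
depends on the shipped constants.

## Classifier and model selection

The classifier is a soft-margin SVM with the RBF kernel
$K(x, y) = \exp(-\gamma \lVert x - y \rVert^2)$, trained by libsvm (via
e1071) on the feature rows as-is — the vectors are already jointly
normalized to sum 1, so no per-column rescaling is applied (a documented
choice; note that because the vectors are small in norm, useful $\gamma$
and $C$ values sit at the upper end of classic libsvm grids). At predict
time the package evaluates the decision function itself from the stored
support vectors, coefficients and bias, with the sign convention that a
positive decision value means class $+1$ and an exact 0 is called $+1$.

The tunables are searched jointly on a Cartesian grid:

| parameter | meaning | default candidates |
|---|---|---|
| $k$ | composition tuple size | DNA/RNA {2, 3}; protein {1} |
| $\lambda$ | correlation tiers (units of lag) | 1..5 |
| $w$ | pseudo-block weight (dimensionless) | 0.1, 0.3, 0.5, 0.7, 0.9 |
| mode | parallel / series | parallel |
| $C$ | SVM cost | $2^{-2}, 2^0, 2^2, 2^4, 2^6$ |
| $\gamma$ | RBF width | $2^{-6}, 2^{-4}, 2^{-2}, 2^0, 2^2$ |

Every candidate is scored by *pooled* cross-validation on **one** fold
assignment computed once from the master seed, so comparisons between
candidates are paired and fold noise does not perturb the ranking.
Candidates inadmissible for the shortest benchmark sequence are skipped
with a logged reason. The selection objective is accuracy by default (AUC
and MCC are selectable); ties go to the lexicographically earlier
candidate in $(k, \lambda, w, \text{mode}, C, \gamma)$ — the simpler model.
After selection the final model is refit on the full benchmark with the
winning parameters, while the reported metrics remain the winning
candidate's CV metrics. Grid evaluation can fork across workers
(`n_workers`); candidates are enumerated and collected in a fixed order, so
the result is identical for any worker count.

## Validation machinery

Folds are stratified per class (round-robin over a seeded permutation), so
per-fold class counts deviate from proportionality by at most one;
`"jackknife"` (= $K = N$) yields leave-one-out folds with no randomness.
Held-out predictions from all folds are pooled and scored once — this keeps
jackknife and K-fold on one code path and keeps MCC well defined with tiny
folds, where per-fold averaging would be degenerate. Metrics are the
standard confusion quantities (Acc, Sn, Sp), MCC with the convention that a
zero denominator factor gives MCC = 0, and AUC computed as the Mann–Whitney
rank statistic with ties counted ½, which equals the trapezoidal area under
the tie-aware ROC curve. Because feature extraction is strictly
per-sequence (no dataset-level statistic is used), features are extracted
once per candidate and reused across folds; the result is identical to
extracting per training split.

## The synthetic benchmark generator

`synth_benchmark()` produces seeded two-class benchmarks with three
regimes: a fixed motif overwritten at a uniform random position in each
positive (with a given insertion probability) over i.i.d. uniform
background; a compositional tilt of the positive class's symbol
frequencies; or a pure null with no signal. Per-sequence randomness is
derived from the master seed by counter-based sub-seeding, so enlarging a
benchmark never changes sequences already generated. The generator emulates
*compositional and motif* signal on a uniform background only — it has no
repeat structure, GC heterogeneity, phylogenetic redundancy or
length variation, so green pipeline tests demonstrate correct mechanics and
recoverable planted signal, not performance on real genomic data.

The standard experiment sizes used throughout the tests and the acceptance
script are 100 sequences per class of length 100 (motif `ACGTACGT`,
insertion probability 1, and a matched null benchmark), searched with a
reduced grid that keeps the full default $C$ and $\gamma$ lists and pins
the feature parameters to their central values ($k \in \{2,3\}$,
$\lambda = 2$, $w = 0.5$; 50 candidates). A single 8-mer planted in a
100-mer uniform background is intentionally a *partial* signal under
$k \le 3$ composition features: it perturbs only ~6 of the 98 overlapping
3-mer windows, so pooled CV accuracy saturates near 0.87–0.89 with AUC near
0.93–0.95, while exact-match detection would be nearly perfect. The null
benchmark calibrates at AUC ≈ 0.5. These are properties of the planted
conditions, reproduced by independent SVM implementations on the same
features, and they are what the acceptance script recomputes.

## Numerical and design choices

- **Determinism.** All randomness (fold shuffles, synthetic generation)
  flows from explicit integer seeds through a scoped RNG helper that never
  disturbs the caller's RNG stream. libsvm's C-SVC solver is deterministic
  at fixed tolerance, and decision values are computed by the package, so
  end-to-end reruns are byte-identical.
- **Persistence.** Model archives are single gzipped text files: a JSON
  metadata document (format version, recipe, property index, CV summary)
  followed by the classifier in the LIBSVM text-model dialect. All numbers
  that feed predictions are written as `%.17g`, which round-trips IEEE
  doubles exactly; reloaded models reproduce decision scores
  bit-identically. Archives with a missing member or an unknown (future)
  format version are refused by name.
- **Strict alphabets.** Ambiguity codes and gaps are rejected rather than
  dropped, because deleting residues silently would shift every correlation
  lag; `skip_invalid` drops whole records with a logged count instead. RNA
  is its own alphabet — no silent U→T mapping.
- **Two-file benchmarks.** The positive/negative convention is two FASTA
  files; duplicated ids across classes are permitted with a warning.
- **Caveat.** The CV metrics reported for the selected candidate are the
  maximum over the searched grid and are therefore optimistically biased as
  generalization estimates; nested CV is out of scope and the bias is
  inherent to reporting the winner's score.

## Problem sizes

The shipped tests run on small fixtures chosen to exercise every code path:
fuzz suites of 500 feature cases per molecule type, 200 oracle comparisons
against naive double-loop reference implementations, grids of 32–50
candidates, and the 100-per-class synthetic benchmarks above. All are
generated in code at run time; nothing depends on external data.
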