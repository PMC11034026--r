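---
title: "Classifying virus fragments by host domain: model and design notes"
author: "viroSGT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying virus fragments by host domain: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Virome sequencing recovers fragments from viruses of both prokaryotic
hosts (phages) and eukaryotic hosts, and separating the two is a routine
first step in downstream ecology and host-association analyses.
Alignment against reference databases fails exactly where the question is
most interesting — novel viruses with little homology to anything known —
so viroSGT classifies fragments purely from sequence composition: the
relative positions of overlapping trinucleotides.

## The sequence graph transform

A DNA sequence is first reduced to its overlapping trinucleotides, each
with its 1-based start offset.  For every ordered pair of trinucleotides
$(u, v)$ the encoder computes

$$\psi_{uv} \;=\; \frac{\sum_{(l,m)\,:\,l<m} e^{-\kappa\,(m-l)}}{|\Lambda_{uv}|},$$

the average over all occurrence pairs ($u$ starting at $l$, $v$ at
$m > l$) of an exponentially decayed distance weight, where
$|\Lambda_{uv}|$ is the number of such pairs.  The 64 × 64 grid of
$\psi_{uv}$ values — the *pattern matrix* — captures both the frequency
and the ordering of trinucleotide pairs and is what the classifier sees.
Entries are bounded by $e^{-\kappa}$ (adjacent tokens are 1 apart), and a
pair that never co-occurs gives exactly 0.

Decisions where the definition left room, and what this package does:

* **Decay rate $\kappa$.**  No canonical value exists; the default is
  $\kappa = 1$ per base.  The value is recorded in every
  `PatternMatrixSet` and in saved classifier weights, and prediction
  refuses matrices encoded at a different $\kappa$, since encodings at
  different decay rates live on different scales.
* **Pair orientation.**  Pairs are directed with strictly increasing
  positions ($l < m$); same-position self-pairs do not exist because
  token positions are distinct.  A directed definition keeps
  $\psi_{uv} \neq \psi_{vu}$ informative.
* **Distance units.**  Distances are differences of start offsets in the
  *original* sequence.  When a window is dropped because it touches a
  degenerate base, the surviving tokens keep their offsets, so genomic
  spacing is preserved across the gap.
* **Degenerate bases.**  Any 3-mer window containing a letter outside
  A/C/G/T (N and the other IUPAC codes, case-insensitive) is skipped
  rather than guessed at.  Letters outside the IUPAC alphabet are an
  error that names the offending position.
* **No normalisation.**  Matrices are fed to the network as-is.  For
  long fragments $|\Lambda_{uv}|$ grows faster than the decayed sum, so
  typical entries shrink with length; the network learns on that scale.
* **Row/column order.**  Lexicographic with A < C < G < T, rows the
  earlier symbol.  This ordering is frozen because trained weights
  depend on it.

The streaming implementation maintains, per symbol, a running
exponentially decayed sum that is decayed by $e^{-\kappa\Delta}$ between
consecutive tokens — numerically safe for arbitrarily long sequences —
plus per-pair counters for $|\Lambda_{uv}|$.  It is verified against a
naive all-pairs enumeration to $10^{-10}$ in the test suite.

## The classifier

The network is the fixed stack

conv(128 filters, 7 × 7, "same", ReLU) → maxpool(2 × 2, stride 2) →
dropout(0.32) → conv(128, 7 × 7, "same", ReLU) → maxpool(2 × 2) →
dropout(0.32) → flatten → dense(64, ReLU) → dense(2) → softmax,

trained with Adam (learning rate 0.0005, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$) on categorical cross-entropy
with batch size 16; the default epoch count is 30.  On 64 × 64 input the
two pooling stages leave a 16 × 16 × 128 tensor, so the model has
2,906,690 trainable parameters — an arithmetic identity the test suite
checks against the built tensors.

The implementation is self-contained compiled code (im2col + BLAS GEMM
with whole mini-batches stacked into single GEMM calls, single-precision
internally, double-precision softmax and losses).  Backpropagation is
verified against central finite differences in the tests.  Further
choices:

* **Dropout semantics.**  The dropout parameter $P = 0.32$ is the *drop*
  probability, as in every mainstream framework, with inverted scaling
  $1/(1-P)$ applied at train time so inference needs no rescaling.
  Dropout sits after each pooling stage.
* **Initialisation.**  Glorot-uniform weights, zero biases, drawn from
  the configuration seed, so two builds with the same configuration are
  identical and a training run is a deterministic function of (data,
  configuration).
* **Class order.**  Index 1 is the prokaryotic virus — the positive
  class everywhere in this package — and index 2 the eukaryotic virus;
  additional classes (e.g. a nonviral class) would follow.
* **Persistence.**  `saveClassifier()` writes a single-file container
  holding a format tag and version, the full configuration (including
  $\kappa$ and the seed), class names, parameters and history;
  `loadClassifier()` validates all of it and reproduces predictions
  bit-for-bit.

## The synthetic virome

Real training corpora for this problem are curated from thousands of
virus genomes; the package instead ships a generator that reproduces the
*experimental design* at desk scale so that every component is testable
end-to-end without downloads.

* **Genome sources.**  Each class is an order-2 Markov chain over
  A/C/G/T.  The two default sources are perturbed copies of one common
  base table (rows Dirichlet(5)): each entry is multiplied by
  $e^{\delta z}$, $z \sim N(0,1)$ drawn independently per class, and
  rows are renormalised.  The divergence $\delta$ defaults to 0.4,
  giving clearly distinct but overlapping trinucleotide usage — the
  compositional signal that separates phage from eukaryotic-virus
  genomes is large (it is the premise of composition-based host
  classifiers), and 0.4 keeps the task non-trivial at short fragment
  lengths.  Genomes are sampled starting from the chain's stationary
  context distribution.
* **Fragmenting.**  Four length groups mirror assembled-contig length
  strata: A 100–400, B 400–800, C 800–1,200, D 1,200–1,800 bp.
  Fragment lengths are uniform (integer-inclusive) within the group and
  start positions uniform over valid offsets — the behaviour of a
  MetaSim-style "exact"/uniform protocol without the unmaintained
  external tool.
* **Sequencing errors.**  Substitutions (to a uniformly chosen different
  base) and indels (insertion or deletion, equiprobable) are independent
  per-base Bernoulli events, separated into two rates as error-robustness
  benchmarks separate them; only total rates, not platform error
  profiles, are modelled.
* **Fold assignment is genome-level.**  Genomes, not fragments, are
  assigned to the k folds before fragmenting, so no genome contributes
  fragments to both sides of any train/test split.  Fragment-level
  splitting lets near-duplicate fragments of one genome leak across the
  boundary and inflates scores; the harness forbids it by construction
  and the `LabeledFragmentSet` validity check enforces it.

What the generator does *not* emulate: real genome length and copy-number
variation, repeats and mosaicism, GC-skew gradients, codon structure, or
homology between training and test beyond shared Markov tables.  Passing
tests demonstrate that the encoder, network, and harness are correct and
that the pipeline separates compositionally distinct sources; they do not
certify accuracy on real viromes, which depends on the breadth of real
training data.

## Inference on assembled contigs

Long records are split into non-overlapping 1,000 bp windows; a final
partial window is kept when it reaches 100 bp, and a record no longer
than one window passes through whole.  Window score vectors are combined
by a weighted average with the window lengths as weights (equal
weighting is available), renormalised to sum exactly 1.  Both window
size and tail threshold sit inside the training length range of groups
A–D and are configuration-exposed.  The forward strand is scored by
default; `rcAverage` averages the forward and reverse-complement scores.
Records without a single usable trinucleotide (e.g. all-N) receive
uniform scores and a `low_information` flag rather than a fabricated
call, and exact score ties resolve to the prokaryotic class with a
`tie` flag.  An optional second-stage filter applies a separately
trained viral-vs-nonviral model of the same architecture and flags (or
drops) records whose viral score falls below a threshold.

## Evaluation

Threshold metrics are the standard confusion-table definitions
(Sn = TP/(TP+FN), Sp = TN/(TN+FP), ACC, Precision, F1), with
zero-denominator cases reported as missing rather than 0.  ROC-AUC is
computed from mid-ranks — exactly the Mann–Whitney pair-counting
probability with half credit for ties, and tested against both an
explicit $O(n^2)$ pair count and an independent library implementation.
Average precision is the step-wise (non-interpolated) sum
$\sum_k (R_k - R_{k-1}) P_k$ with tied scores grouped.  Cross-validation
trains one model per fold on the genome-level folds and reports
per-length-group and pooled metrics per fold with mean ± sd across
folds, plus the per-fragment held-out scores so any reported number can
be recomputed from the prediction table.

## Problem sizes and numerical notes

The shipped experiments are sized for a single CPU: the acceptance
experiment uses 100 genomes per class of 5 kb, 1,000 group-D fragments
per class, an 80/20 genome-level split and 2 training epochs of the
default architecture — enough for the held-out AUC to reach ≈ 0.99 on
the default synthetic task, with the same length and error-rate trends
as at full scale.  Unit tests use far smaller configurations (8–16
filters, tens of fragments).  Network internals run in single precision;
losses, softmax outputs and all reported scores are double precision,
and probability rows sum to 1 to well below $10^{-9}$.  Degenerate
inputs are defined, not special-cased: empty sequences tokenise to empty
tracks, ≤ 1 token yields the all-zero matrix, and the all-zero matrix is
a valid classifier input.

## Known limitations

* Markov sources are a stand-in for real compositional signal; absolute
  accuracies on this synthetic task do not transfer to real viromes.
* Only 3-mers are supported as the token alphabet; the matrix side and
  the trained-weight layout are frozen to 64.
* The classifier trains on a single CPU at single precision; very deep
  training runs (hundreds of epochs) would be slow and are not the
  intended use.
* Strand handling is forward-only by default; reverse-complement
  averaging is approximate strand symmetry, not a strand-aware model.
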