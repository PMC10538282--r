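---
title: "Predicting 5mC sites from k-mer GloVe embeddings: models and methods"
author: "methylGlove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting 5mC sites from k-mer GloVe embeddings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

5-methylcytosine (5mC) is the most intensively studied DNA modification:
methylation of CpG cytosines remodels chromatin accessibility, silences
genes, and is a recurrent biomarker in cancer. The wet-lab gold standards
(whole-genome and reduced-representation bisulfite sequencing) give
single-base resolution but are slow and expensive, which motivates sequence
based predictors: given a short DNA fragment centered on a candidate
cytosine, estimate the probability that the site is methylated.

methylGlove implements such a predictor end to end. Its working unit is the
41-bp fragment

$$E_{-\delta}\,\cdots\,E_{-1}\;C\;E_{+1}\,\cdots\,E_{+\delta},
  \qquad \delta = 20,$$

the candidate cytosine flanked by 20 bases on each side, the fragment
convention bisulfite pipelines report. All coordinates are 0-based
internally, windows include both flank endpoints (length $2\delta+1$), and
processing is single-strand only — no reverse-complement scanning is
performed, so callers who want both strands must extract windows from each
strand themselves.

## From sequence to numbers: k-mer GloVe embeddings

A fragment is tokenized into its $L-k+1$ overlapping k-mers (39 3-mers for
a 41-bp fragment). $k \ge 3$ is required so that every base is observed
jointly with its left and right neighbor in at least one token; $k$ = 3, 5
and 7 are supported, with 3 the default (the larger values grow the
vocabulary as $4^k$ with little benefit at these fragment lengths).

Treating the 3-mers as the words of a small language, a global co-occurrence
matrix $X$ is accumulated over the training corpus: for each ordered pair of
tokens at distance $s \le w$ inside one fragment the directed count is
incremented, and the matrix is symmetrized by mirroring the directed counts
($X_{ij} = X_{ji}$ = count of $i$ before $j$ plus count of $j$ before $i$).
The default window is $w = 1$ (immediate neighbors), matching how often one
3-mer directly follows another; an optional $1/s$ distance weighting is off
by default.

GloVe vectors are then fitted by minimizing the weighted least-squares
energy

$$J = \sum_{i,j:\,X_{ij}>0} f(X_{ij})\,
      \bigl[V_i^\top \tilde V_j + b_i + \tilde b_j - \log X_{ij}\bigr]^2,
\qquad
f(x) = \begin{cases} (x/T_X)^\alpha & x < T_X \\ 1 & \text{otherwise,}
\end{cases}$$

with $\alpha = 0.75$ and $T_X = 100$ (the standard truncation; $f(0)=0$, so
zero-count pairs drop out of the sum and $\log 0$ never arises). The fit
uses per-parameter adaptive (AdaGrad-style) stochastic updates over the
nonzero cells — learning rate 0.05, 50 epochs by default, uniform
$(-0.5/d,\,0.5/d)$ initialization — with the full objective recorded after
every epoch; runs are bit-reproducible for a fixed seed. The analytic
gradient of $J$ is implemented separately and verified against central
finite differences in the test suite.

**Exported vectors and centering.** The embedding exposed for encoding is
the main vector $V_i$ (the context vectors $\tilde V_j$ exist to solve for
$V_i$; a `export = "sum"` switch gives the common $V + \tilde V$ variant).
One postprocessing step is applied by default: the mean token vector is
subtracted. On the small corpora this package targets, the co-occurrence
matrix is close to uniform and its common part is absorbed jointly by the
biases and by a shared direction in the vectors — we measured median
pairwise cosine similarities above 0.9 between fitted token vectors. That
common mode carries no between-token information but dominates the input
scale of the classifier and measurably stalls its optimization. Removing
the mean (standard practice in word-vector postprocessing) leaves the
discriminative geometry untouched; `center = FALSE` restores the raw
vectors.

Each fragment becomes a $(L-k+1) \times d$ matrix by stacking its tokens'
vectors in order — $39 \times 300$ at the defaults ($d = 300$, chosen as
the usual accuracy/cost balance point for this family of models; the
bundled experiments use smaller $d$, see *Problem sizes* below). A one-hot
alternative encodes each token as the unit basis vector of its vocabulary
index ($39 \times 64$ over the full 3-mer vocabulary). One-hot is defined
at the k-mer level rather than the base level so both encodings present the
same sequence length to the classifier and differ only in the feature
dimension; this is a deliberate interpretation choice, recorded here. The
vocabulary is built from the training corpus (positives and negatives
jointly) in deterministic first-occurrence order; tokens unseen at encoding
time raise an error by default, or map to the zero vector with a logged
count under `unknown = "zero"` — silent substitution would quietly corrupt
evaluation.

## The classifier

The network mirrors the architecture the package is named for:

1. **Three parallel dilated 1D convolutions** along the token axis
   (same-length zero padding, kernel 3, dilation rates 1, 2 and 3,
   `convFilters` filters each, ReLU). The three dilation rates read
   adjacent, one-gap and two-gap token contexts, i.e. local structure at
   three scales; their outputs are concatenated to a model width of
   $M = 3 \times$ `convFilters`.
2. **Sinusoidal positional encoding**, added to the concatenated features.
   Token order is biologically meaningful — permuting the 3-mers of a
   fragment describes a different DNA sequence — and self-attention is
   otherwise order-blind.
3. **A Transformer encoder** (1 layer by default): multi-head
   self-attention ($M$ must divide by `nHeads`, 4 by default), Add & Norm,
   a position-wise feed-forward block of width $4M$, Add & Norm.
4. **Mean pooling** over positions (a `flatten` option exists), then a
   dense head of sizes 128, 64, 32 with dropout 0.2 after each layer, and a
   2-unit softmax output trained with categorical cross-entropy. The
   two-class softmax is mathematically equivalent to a single sigmoid
   logit; the softmax form was chosen and the equivalence is noted here
   because descriptions of this architecture family use both
   interchangeably.

Only the dilation rates (1/2/3), the dense sizes (128/64/32), the
$39 \times 300$ input convention and the loss are fixed by the design this
package follows; everything else (filters, kernel, heads, encoder depth,
feed-forward width, dropout, optimizer settings) is an explicit
configuration default chosen by this package and exposed in
`modelConfig()` / `trainModel()`.

Training uses Adam (learning rate $10^{-3}$, $\beta = (0.9, 0.999)$) over
shuffled minibatches of 32, records per-epoch train/validation loss and
accuracy, early-stops on validation loss and restores the best epoch's
weights. By default the model trains on the natural class imbalance;
`classWeighting = "balanced"` reweights inversely to class frequency. Calls
use a 0.5 threshold with a $\ge$ tie-break (a probability exactly at the
threshold is called positive).

The whole network — forward pass, backpropagation through the attention,
layer-norm, convolution and dropout blocks, and the Adam updates — is
implemented in vectorized base R on a `(samples*positions) x channels`
matrix layout, so the heavy lifting is BLAS matrix multiplication. The
backward pass is verified coordinate-by-coordinate against central finite
differences in the test suite, which is the strongest correctness evidence
a hand-written implementation can offer.

## Evaluation

Performance is summarized from the confusion counts as sensitivity
$TP/(TP+FN)$, specificity $TN/(TN+FP)$, accuracy $(TP+TN)/N$ and the
Matthews correlation coefficient

$$\mathrm{Mcc} = \frac{TP \cdot TN - FP \cdot FN}
  {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$

plus the area under the ROC curve computed by trapezoidal integration over
all score thresholds; tied scores receive half credit, so the value equals
the Mann–Whitney pair statistic. Metrics with a zero denominator — easily
reached under strong class imbalance, e.g. when no site is called positive
— are reported as `NA` and flagged, never silently set to 0.

## The synthetic data generator

Real 5mC training sets (hundreds of thousands of genomic fragments with
roughly 12 negatives per positive) are too large, and too externally
sourced, to ship inside a package; `syntheticFragments()` provides a
controllable stand-in that preserves the *structure* of such data: 41-bp
records with the candidate base centered, exact configurable
negative:positive ratios (1:10, 1:12 — the common benchmark ratio — and
1:15 are the presets the experiments use), and a planted positive-class
signal whose difficulty is a knob rather than an unknown.

Background bases are i.i.d. uniform over \{A,C,G,T\} (a composition
argument allows GC skew). Each positive receives an 8-mer motif
(`ACGTACGT` by default) at a uniformly drawn offset with probability
`plantingProb`, optionally corrupted base-by-base at `mutationRate`;
negatives are pure background. Default offsets exclude positions covering
the center base, so restoring the center to `C` never clips the motif. At
`plantingProb = 1` a trivial string-search detector achieves AUC
$\ge 0.99$ — the signal is provably learnable, so an end-to-end learning
test is fair — and at `plantingProb = 0` the classes are exchangeable, so
any classifier's expected AUC is 0.5, giving a null control.

What this generator deliberately does **not** emulate: CpG-island
composition, bisulfite conversion errors, positional dependence between
sites, or the actual (unknown, distributed) sequence determinants of real
methylation. A model that passes the package's tests has demonstrated that
the pipeline can extract a planted, localized, partially corrupted motif
under class imbalance — not that it reaches any particular accuracy on
genomic data.

## Numerical and design choices

* **Co-occurrence symmetrization** mirrors directed counts rather than
  summing windows bidirectionally, matching the adjacency-based counting
  convention described above; the two differ only by a factor shared by
  all entries.
* **Monotonicity of the GloVe fit** is tested "to within stochastic-update
  tolerance": per-cell updates are not guaranteed to decrease the full
  objective every epoch, so small upticks bounded by 5% of the initial
  loss are tolerated while the trajectory must end strictly lower.
* **Exactly-fittable instances** (e.g. a two-token vocabulary) are driven
  below $J < 10^{-4}$ in the tests using learning rate 0.2 for 500 epochs;
  AdaGrad's decaying effective step makes the default rate need ~1000
  epochs for the same fixed point.
* **Permutation symmetry.** With mean pooling and no positional encoding
  the attention/feed-forward stack is permutation equivariant, but the
  convolution front end is not (its kernels read neighboring positions),
  so the often-quoted "no positional encoding ⇒ permutation-invariant
  output" only holds for a position-wise front end. The test suite pins
  the property down exactly where it is true — kernel size 1 — and checks
  that enabling the positional encoding breaks it.
* **Dropped-N policy:** windows containing `N` are discarded at extraction
  with a reported count, because the k-mer vocabulary is defined over
  \{A,C,G,T\} ($4^3 = 64$ tokens).
* **Fragment deduplication** is deliberately not performed: how real
  pipelines deduplicate overlapping genomic candidate sites is
  corpus-specific, and the generator never produces duplicate ids.
* **Ties and degenerate inputs:** ROC ties get half credit; zero-denominator
  metrics are `NA` + flag; empty window scans return empty datasets (not
  errors); empty prediction sets write header-only files.

## Problem sizes used by the bundled experiments

The tests and the acceptance script run the complete pipeline at sizes
chosen to exercise every stage meaningfully on a single CPU: 2,000+2,000
training and 500+500 validation fragments for the balanced planted-motif
run (embedding $d = 50$, 16 filters per branch, 8 epochs), 150 positives
with 1:10/1:12/1:15 negatives for the imbalance sweep (25 epochs, learning
rate $3\times10^{-3}$), and 1,000+1,000/250+250 with `plantingProb = 0.8`
and 10% motif corruption for the encoding ablation. With those sizes the
balanced run reaches validation AUC above 0.99, the imbalance runs all
converge to within a few accuracy points of each other, and GloVe encoding
matches or beats k-mer one-hot on sensitivity and Mcc — the qualitative
pattern expected of this architecture family. Full-scale settings
($d = 300$, 64 filters, hundreds of thousands of fragments) are plain
configuration changes.

## Limitations

* The predictor is sequence-only; no chromatin, conservation or assay
  covariates.
* Single-strand windows; CpG symmetry is not exploited.
* The NN engine is CPU/BLAS-bound; it is intended for desk-scale
  experiments and method studies, not genome-scale training.
* GloVe vectors fitted on small corpora are dominated by a common mode
  (hence the default centering); with very few fragments the embedding
  carries little more than token identity.
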