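# methylGlove

Sequence-based prediction of 5mC DNA methylation sites in R.

Experimental detection of 5-methylcytosine (bisulfite sequencing and its
reduced-representation variants) is accurate but slow and expensive, so a
large part of epigenomics practice rests on sequence-based predictors:
given a 41-bp DNA fragment with a candidate cytosine at its center, estimate
the probability that the site is methylated. methylGlove implements such a
predictor end to end, for methods work and desk-scale experiments:

1. **Fragment handling** — read/write fragments (FASTA or TSV), extract all
   `2δ+1`-bp windows centered on a chosen base from longer sequences
   (`δ = 20` by default, the bisulfite-pipeline convention).
2. **k-mer GloVe embedding** — tokenize each fragment into its 39
   overlapping 3-mers, accumulate a global co-occurrence matrix *X* over
   the corpus, and fit GloVe word vectors by minimizing

   *J* = Σ<sub>X<sub>ij</sub>>0</sub> f(X<sub>ij</sub>) (V<sub>i</sub>ᵀṼ<sub>j</sub> + b<sub>i</sub> + b̃<sub>j</sub> − log X<sub>ij</sub>)²,  f(x) = (x/T<sub>X</sub>)<sup>α</sup> for x < T<sub>X</sub>, else 1

   (α = 0.75, T<sub>X</sub> = 100, AdaGrad-style stochastic updates). Each
   fragment becomes an `(L−k+1) × d` matrix — 39 × 300 at full-scale
   defaults. A k-mer one-hot encoder (39 × 64) is included for ablations.
3. **Classifier** — three parallel dilated 1D convolutions (rates 1/2/3) →
   feature concatenation → sinusoidal positional encoding → Transformer
   encoder (multi-head self-attention, Add & Norm, feed-forward) → mean
   pooling → dense head 128/64/32 with dropout → 2-unit softmax, trained
   with categorical cross-entropy (Adam, early stopping). Forward and
   backward passes are implemented in vectorized base R and verified
   against finite differences in the test suite.
4. **Evaluation** — Sen, Spe, Acc, Mcc from the confusion counts and
   trapezoidal ROC/AUC (ties get Mann–Whitney half credit); undefined
   metrics are flagged `NA`, never silently 0.
5. **Synthetic data** — a planted-motif fragment generator with exact
   configurable class imbalance (1:10 / 1:12 / 1:15 presets), the
   controllable stand-in for real genome-scale methylation sets that lets
   every pipeline stage be tested end to end.

See `vignettes/methylGlove-methods.Rmd` for the full model description,
parameter meanings and design rationale.

## Worked example

Simulate an imbalanced (1:12) planted-motif dataset, fit the embedding,
train the classifier, evaluate on a held-out stratified fold:

```r
library(methylGlove)

ds <- syntheticFragments(nPos = 150, ratio = 12, motif = "ACGTACGT", seed = 101)
sp <- stratifiedSplit(ds, testFraction = 0.2, seed = 1)

vocab <- buildVocab(sp$train, k = 3)
cooc  <- buildCooccurrence(tokenizeFragments(sp$train, vocab), window = 1)
emb   <- fitGlove(cooc, d = 50, epochs = 25, seed = 2)

encTrain <- encodeFragments(sp$train, "glove", embedding = emb)
encTest  <- encodeFragments(sp$test,  "glove", embedding = emb)
cfg   <- modelConfig(inputLen = 39, inputDim = 50, convFilters = 16, seed = 3)
model <- trainModel(buildModel(cfg), encTrain, encTest,
                    maxEpochs = 25, lr = 3e-3, earlyStopPatience = 25, seed = 4)

evaluatePredictions(encodedLabels(encTest), predictProb(model, encTest))
```

Output (abridged; ~3 minutes on one CPU):

```
FragmentDataset: 1950 fragments of 41 bp (delta = 20)
  labels: 150 positive / 1800 negative (0 unlabeled)
CooccurrenceMatrix: 64 x 64, window = 1, 496 nonzero entries
GloveEmbedding: 64 tokens x 50 dims (25 epochs, final J = 5.19)
MetricsReport: TP=29 TN=359 FP=1 FN=1
  Sen=0.9667 Spe=0.9972 Acc=0.9949 Mcc=0.9639 Auc=0.9981
```

Reading: of the 30 held-out positives the model recovers 29 (Sen 0.967)
with a single false alarm among 360 negatives (Spe 0.997); Mcc 0.964 shows
the calls are strongly correlated with the truth despite the 1:12
imbalance, and AUC 0.998 says the ranking is almost perfect. The 64 × 64
co-occurrence matrix has only 496 nonzero cells because consecutive 3-mers
overlap by two bases — each token has at most four possible successors.

The same pipeline is scriptable: `runPipeline(pipelineConfig(...))` chains
simulate → embed → encode → train → evaluate and writes every stage's
artifacts plus a manifest, and `exec/methylglove` exposes the stages as
shell subcommands (`simulate`, `window`, `embed`, `train`, `predict`,
`evaluate`, `run`).

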