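---
title: "Classifying CpG-island methylation inheritance from sequence: models and methods"
author: "cmic package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying CpG-island methylation inheritance from sequence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

During early mammalian development most CpG islands (CGIs) that were
methylated in the oocyte lose that methylation through global epigenetic
reprogramming, but a subset keeps it in the maternal genome of the
blastocyst. `cmic` asks whether the *sequence* of a CGI is enough to
predict which of the two fates it takes: methylation inheritance (M2M)
or methylation loss (M2U). The practical obstacle is data volume — only
a couple of hundred informative CGIs can be labeled from allele-resolved
whole-genome bisulfite sequencing (WGBS) — far too few to train a
recurrent network directly. The package's core idea is a randomized
re-representation of each sequence that acts as data augmentation.

# The pipeline

## Variable-length k-mer sentences

A DNA sequence `s` is split left to right into non-overlapping tokens
whose lengths are drawn i.i.d. from the discrete uniform distribution on
`{kmin, ..., kmax}` (defaults 4 and 12). The split is repeated N times
for `s` and N times for its reverse complement, giving 2N *cognate
sentences* that all carry the label of `s`. Each sentence is an
alternative view of the same sequence: token boundaries differ, so the
set of k-mers differs, while the underlying bases are identical. The
default N is 1000.

Two details the splitting rule must decide:

* **Tail fragments.** When the remaining suffix is shorter than the
  drawn length, the whole suffix is emitted as the final token even if
  it is shorter than `kmin`. Discarding it would make the concatenation
  test fail and would leak sequence length into the token stream; short
  tail tokens are legal vocabulary entries because the embedding step
  counts every token (`min_count = 1`).
* **Ambiguity codes.** Sequences containing `N` are segmented verbatim
  and tokens containing `N` become ordinary vocabulary entries. CGI
  sequences essentially never contain `N`, and silently dropping them
  would be surprising.

Two control tokenizations are provided for comparisons: an overlapping
sliding-window variant (stride one, random lengths — the dna2vec-style
scheme) and a fixed-k/fixed-stride variant.

## splitDNA2vec: k-mer embeddings

All 2N sentences of *all* available sequences (labels unused) form a
text corpus, and a CBOW word2vec model with negative sampling learns a
D-dimensional vector per k-mer (defaults: D = 20, context window 10,
`min_count` 1). This is transductive by design — embedding vectors are
trained on the union of training and test sequences, which is sound
because the step never sees labels; `trainEmbeddings()` can equally be
run on training data only.

Hyper-parameters word2vec needs but the pipeline does not fix are set to
the field's standard values and recorded in the returned table's
metadata: 5 negative samples, 5 epochs, initial learning rate 0.025 with
linear decay. Training is single-threaded and exactly reproducible for a
fixed seed.

**Whitening.** k-mer corpora generated from low-structure backgrounds
produce severely anisotropic word2vec spaces: almost all of the variance
lies on a single "frequency" axis, and cosine similarities between
unrelated frequent tokens approach 1. On the synthetic benchmark below
the leading eigenvalue of the frequency-weighted covariance exceeded the
second by three orders of magnitude. A downstream classifier then has to
extract class signal from a numerically tiny residual. `trainEmbeddings`
therefore applies frequency-weighted PCA whitening to the trained
vectors by default (`whiten = TRUE`), a standard anisotropy correction
for word embeddings. Whitening is skipped when the vocabulary is smaller
than `max(2D, 50)`, where the covariance estimate would be rank
deficient. The shuffled-mapping control (`shuffleEmbedding()`) and the
overlapping-corpus control operate on the same (whitened) footing.

## The BiGRU classifier

Each token of a sentence is mapped to its embedding vector and the
sequence of vectors is processed by a bidirectional gated recurrent
unit. One direction applies, at every step,

* reset gate: `r_t = sigmoid(Wr x_t + Ur h_{t-1} + br)`
* update gate: `z_t = sigmoid(Wz x_t + Uz h_{t-1} + bz)`
* candidate: `hcand_t = tanh(Wh x_t + Uh (r_t * h_{t-1}) + bh)`
* state: `h_t = z_t * h_{t-1} + (1 - z_t) * hcand_t`

with zero initial states. The final hidden states of the forward and
backward passes are concatenated (2H values, H = 256 by default) and a
fully connected layer plus sigmoid yields the probability that the
input is unmethylated (class 1). Dropout (rate 0.5) is applied to the
concatenated vector during training only; the placement follows the
reading that dropout acts on the BiGRU layer's output.

Training minimizes

```
L(w) = E(yhat, y) + alpha * ||w||_2
E = -sum_i [ y_i log yhat_i + (1 - y_i) log(1 - yhat_i) ]
```

with Adam. The decay term uses the *unsquared* L2 norm, exactly as the
loss is written; because that reading is unusual as "weight decay", the
conventional squared form is available via `decayForm = "squared"`.
Biases are excluded from the norm. Probabilities are clipped at 1e-7
before the logarithms. Defaults: 2 epochs, learning rate 1e-4, batch
size 32, weight decay 0.01.

Batches of variable-length sentences are processed by per-sentence
gradient accumulation rather than padding and masking; the two are
mathematically identical, and accumulation avoids wasted computation and
any possibility of padded positions contaminating the final states.

### Initialization

Three initialization choices matter enough to document:

* **Input scaling.** word2vec vectors can have large norms; the
  input-projection matrices are Glorot-initialized and then divided by
  the embedding table's usage-weighted coordinate RMS (stored as
  `params$input_scale`), so gate pre-activations start in the responsive
  region of the sigmoid/tanh rather than saturated.
* **Long-memory start.** Both update-gate biases start at +1, biasing
  `z` toward carrying state across long sentences — the GRU analogue of
  initializing an LSTM forget gate to 1. With `z ~ 0.5` at start, a
  token 20 steps from the sentence end influences the final state by
  less than 1e-6 and the training signal for mid-sentence features
  vanishes.
* **Prior head bias.** `trainCmic()` starts the head bias at the
  training-set class log-odds, so no training budget is spent learning
  the base rate of the (imbalanced) data.

### Per-CGI aggregation

The network scores sentences, but the scientific unit is the CGI. The
2N cognate probabilities are averaged and the CGI is called
unmethylated when the mean is strictly greater than 0.5 (a tie at
exactly 0.5 is called methylated, following the strict inequality in
the decision rule). Per-sentence metrics are reported alongside per-CGI
metrics throughout, since the training instance is the sentence.

At prediction time on new sequences, tokens never seen by the embedding
step receive a zero vector by default (`oov = "zero"`); a strict mode
raises an error instead. Within a transductive evaluation, OOV tokens do
not occur because classifier sentences and embedding corpus coincide:
`crossValidate()` generates the 2N sentences per CGI once and uses them
both as the unsupervised embedding corpus and as classifier instances.

## Labels from WGBS counts

Per-CGI read counts are converted to labels with three thresholds: a
CGI with fewer than `T` covering reads is excluded; otherwise it is M
when its methylation ratio is at least `beta_M` and U when the ratio is
below `beta_U`; intermediate ratios are excluded (the two labeled
regions are all that is defined). Presets: fully grown oocytes
`T = 100, beta_M = 0.8, beta_U = 0.1`; maternal genome of blastocysts
`T = 20, beta_M = 0.4, beta_U = 0.1`. A CGI methylated in the oocyte
that stays M in the blastocyst is M2M (label 0); one that becomes U is
M2U (label 1); everything else is excluded. Sequences longer than 500 bp
(boundary inclusive: 500 bp stays) are routed to a separate long-CGI set
used only for generalization analysis, binned as
`[501, 600], ..., [1001, Inf)`.

Producing count tables from raw reads (alignment, allele splitting) is
upstream of this package; the TSV count-table interface is the boundary.

## Evaluation harness

`stratifiedFolds()` partitions CGIs (never sentences) into K folds
stratified by class; `crossValidate()` trains on K-1 folds' sentences
and evaluates the held-out fold at both levels, reporting balanced
accuracy, F-measure, MCC and rank-statistic AUC as mean ± standard error
over folds (K-1 denominator in the SE). The positive class for
F-measure is "unmethylated" (1), consistent with the head estimating
P(unmethylated). Zero-denominator conventions: precision, recall and
MCC fall back to 0; AUC is reported missing for single-class truth. A
leakage audit inside the harness asserts that no CGI id appears on both
sides of any fold.

`sweepExperiment()` reruns the cross-validation over grids: N (the
augmentation count), (kmin, kmax) pairs with `kmax - kmin >= 1`, and the
eight embedding schemes ({splitDNA2vec, shuffled, dna2vec,
dna2vec-N1000} × {frozen C, trainable V}).

# The synthetic benchmark

Real WGBS accessions are deliberately out of scope; every experiment in
the tests runs on synthetic data with known ground truth.

`generateBackground()` samples a first-order Markov chain whose
stationary base composition matches a target GC content (default 0.65)
while the propensity of G after C is multiplied by `cpgBoost` (default
5) and the remaining transitions are rebalanced by fixed-point
iteration, so the CpG dinucleotide frequency ends up above the
independence expectation without distorting overall composition. The
boost is a conditional propensity, not an exact frequency multiplier —
an exact interpretation is infeasible (5 times the independence
expectation at 65% GC would exceed the maximum possible dinucleotide
frequency).

`generateDataset()` plants `motifCopies` (default 3) non-overlapping
copies of a class-specific 10-mer in each sequence, each on a random
strand, and records every insertion in a manifest. The default motifs
are AT-rich periodic strings (`ATATATATAT` for class 0, `AATTAATTAA`
for class 1) with disjoint substring sets, each closed under reverse
complement. The AT-rich choice is deliberate: a planted motif only
separates the classes if its k-mer substrings are rare in the
background, and in a 65% GC background the substrings of GC-rich motifs
occur in half of all background-only sentences, leaving almost no
token-level signal. Class sizes default to 150/60 and lengths to
200–500 bp, mirroring the size and imbalance regime of the real
labeling pipeline's output.

What the synthetic data does *not* emulate: genuine CGI sequence
structure (real CGIs differ between classes in broad compositional
statistics, not just discrete motifs), sequencing error, and coverage
biases in the count tables. Passing the synthetic recovery experiments
demonstrates that the pipeline's machinery — augmentation, embedding,
recurrence, aggregation, evaluation — is correct and able to extract a
planted signal; it does not certify accuracy on real blastocyst data.

`generateCountTable()` samples read counts inside the constraint region
of each intended class (M2M, M2U, excluded by coverage, excluded by
intermediate ratio), so labeling can be verified exactly.

# Scaled-down experiment configuration

The full-scale defaults (N = 1000, H = 256) are impractical for a test
suite, so the end-to-end experiments run at N = 50, H = 32, D = 20,
2 epochs, on the 150/60 dataset with 3-fold CV and three seeds. One
training knob must change with the scale: at N = 1000 two epochs
provide ~26,000 Adam updates, at N = 50 only ~1,750, and the full-scale
learning rate of 1e-4 cannot leave the initial plateau within that
budget (total parameter displacement is bounded by roughly
lr × steps). The scaled runs therefore use `lr = 2e-3` with a one-cycle
schedule (20% linear warmup, then linear decay to lr/20) — warmup
avoids the early base-rate collapse that a large constant rate causes,
and the decay stabilizes the end of training. Batch size, dropout and
weight decay keep their full-scale defaults.

# Numerical and degenerate-input choices

* Probability clipping at 1e-7 before logarithms.
* Zero-denominator metric conventions as above; empty length bins are
  reported missing rather than dropped.
* Randomness: every operation takes a seed; augmentation derives one
  substream per (sequence, origin, replicate) from the master seed by
  integer mixing, so results are independent of iteration order.
  word2vec and GRU training use a dedicated Mersenne-Twister stream in
  compiled code, single-threaded, fully reproducible.
* A single-class training set triggers a warning and trains anyway (the
  evaluation layer reports the degeneracy); a single-token vocabulary
  can only be "shuffled" to itself; a sequence shorter than any drawn
  k-mer becomes a single token.

# Known limitations

* The decay term `alpha * ||w||_2` (unsquared) interacts oddly with
  Adam for quiescent parameters; the conventional squared form is
  available and the coefficient can be set to zero.
* The transductive embedding protocol means embedding vectors have seen
  test *sequences* (never labels). For strictly inductive use, train
  the table on training folds only and accept OOV zero vectors at test
  time.
* Whitening assumes the embedding covariance is estimated from the same
  corpus the table was trained on; tables loaded from disk without
  count metadata are used as-is.
* The classifier treats each CGI independently and knows nothing about
  genomic context (imprinting control regions, flanking elements,
  histone state), which bounds how far sequence-only prediction can go.
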