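---
title: "Hybrid DDI prediction: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid DDI prediction: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(abte)
```

## The problem

Most knowledge-driven drug–drug interaction (DDI) predictors factorize the
known interaction network: each drug gets a latent vector, and a pair's
interaction probability is read off the latent geometry. That works well for
drugs with many recorded interactions and fails exactly where prediction
matters most — new drugs, whose row of the interaction matrix is almost
empty. This package implements a hybrid predictor that patches the cold-start
hole with a second, content-based signal: fixed per-drug embedding vectors
derived from the biomedical literature, scored by a feed-forward pair
classifier. The two signals are fused by a stacking combiner, and a switching
rule decides, per pair, which output to trust.

Formally, for $n$ drugs $D = d_1,\dots,d_n$ the training release at time $t$
gives a symmetric binary matrix $R$ with $r_{ij} = 1$ for a known
interaction; a later release at $t' > t$ gives $R'$. The task is
retrospective: rank all pairs with $r_{ij} = 0$ by their probability of
appearing in $R'$. Each drug also carries a text embedding
$L_i \in \mathbb{R}^e$ (here $e = 100$, the dimension of the pre-trained
tables the pipeline consumes). An unobserved pair is *implicit feedback*:
usable as a training negative but never a verified non-interaction, which is
why training negatives are re-drawn uniformly from the non-edges at every
epoch rather than fixed once.

## The hybrid model

Let $I_i$ be drug $i$'s interaction count in the training release. With
switching threshold $M$:

$$
\hat r_{ij} =
\begin{cases}
\hat r^{\text{Stacking}}_{ij} & \text{if } I_i \ge M \text{ and } I_j \ge M,\\
\hat r^{\text{Text}}_{ij} & \text{otherwise.}
\end{cases}
$$

The routed output is returned *exactly* as the chosen branch computes it —
the text branch of the hybrid is bitwise-identical to the standalone text
classifier, which the test suite asserts. The threshold follows the
"equal or higher" convention: a drug sitting exactly at $M$ counts as warm.
$M$ is tuned on a validation split by searching 0–10 and keeping the
candidate with the highest validation AUPR, ties resolved toward the
smallest $M$ (favouring the combiner wherever it is not demonstrably worse).

### Bio-text component

The pair classifier is a feed-forward network: feature vector $a^{(0)}$,
hidden layers $a^{(l+1)} = \mathrm{ReLU}(W^{(l)} a^{(l)} + b^{(l)})$, and a
sigmoid output unit, trained with binary cross-entropy and Adam. Four
feature constructions are supported (`build_pair_features()`): plain
concatenation $[L_i, L_j]$; element-wise multiplication $[L_i \odot L_j, 1]$
with an explicit bias component; and two *feature combination* variants that
append $\mathrm{id}_i \odot \mathrm{id}_j$, the product of trainable drug-ID
embedding vectors, to the text features. Text vectors stay frozen throughout
— they are consumed as pre-trained artifacts — while the drug-ID embedding,
where present, trains jointly with the network.

Concatenation is not symmetric in $(i, j)$, and a DDI is undirected. Two
measures make the score well defined: each training batch contains both
orderings of every sampled pair, and prediction averages the scores of the
two orderings. Multiplication-based variants are symmetric by construction.

Dropout (inverted, hidden layers only, inactive at inference) defaults to
0.3. The default is not cosmetic: the input vectors are *constant per drug*,
so a sufficiently expressive network can identify individual training drugs
from their noise signature and memorize their partner lists instead of
learning the neighbourhood structure of embedding space. That failure mode
is visible as a training loss far below the validation loss, and moderate
dropout counters it.

### Factorization component (AMFP)

Adjacency matrix factorization shares one latent vector $U_i \in
\mathbb{R}^k$ per drug between the rows and columns of the symmetric
matrix. The pair score is

$$\hat r_{ij} = \sigma\!\big(w^\top (\tilde U_i \odot \tilde U_j) + b_i + b_j + b_0\big),$$

with learned multiplication weights $w$, per-drug biases $b_i$ and a global
bias $b_0$ — the standard symmetric bias decomposition. $\tilde U$ is the
*propagated* factor matrix:

$$\tilde U_i = (1 - \alpha)\, U_i + \alpha \cdot \mathrm{mean}_{j \in N(i)} U_j,$$

where $N(i)$ are $i$'s training partners and $\alpha \in [0,1]$ is the
propagation factor. Three deliberate choices here:

* **Neighbourhood mean, not sum.** The mean keeps $\tilde U_i$ in the convex
  hull of $\{U_i\} \cup \{U_j : j \in N(i)\}$ (a property the tests check
  coordinate-wise), so propagation is a bounded blend rather than a
  degree-dependent amplification, and $\alpha = 0$ recovers plain AMF
  *exactly* — `train_amf()` and `train_amfp(alpha = 0)` are bitwise
  identical under one seed.
* **One propagation step per forward pass,** inside every gradient step, so
  the propagation's effect on the loss flows back into $U$ (the gradient is
  $P^\top$ applied to the factor gradient, with $P$ the propagation
  operator). Iterating to a fixed point would blur all factors toward the
  component mean.
* **Isolated drugs are fixed points:** with $N(i) = \emptyset$ the vector is
  unchanged at any $\alpha$.

All weights use Glorot-normal initialization; biases start at zero; Adam
uses the conventional $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$.

### Stacking combiner

The two components are trained separately; a small sigmoid-output network
over the two scalar predictions combines them. It is fit on the components'
scores for *held-out validation pairs*, never on training-fit scores —
training-set probabilities are optimistic in a way test-time probabilities
are not, and a combiner calibrated on optimistic inputs would misweight the
components. No auxiliary features enter the stacker.

## Data handling

* Pairs are canonicalized as unordered $(i < j)$; duplicate edge rows in
  either orientation collapse. Self-loops are rejected at parse time.
* The catalog is sorted lexicographically when not supplied, so matrix
  indices are reproducible across runs.
* `validation_split()` removes the held-out positives from the sub-training
  matrix (20% of positives and of non-edges by default, the conventional
  validation fraction for this protocol).
* Negative pools are all training non-edges; newly added test interactions
  are *not* excluded from the pool during training, matching the implicit-
  feedback framing (at realistic sparsity the contamination is negligible).
* Per-epoch negative draws are seeded by an integer mix of `(seed, epoch)`,
  so a run is bit-reproducible end to end given one seed while every epoch
  still sees a fresh negative sample.

## Evaluation

AUROC is computed as the Mann–Whitney statistic (ties count one half). AUPR
uses the step-wise ranked-threshold summation — average precision — rather
than trapezoidal interpolation, which is biased in PR space.
`precision_recall_at_k()` breaks score ties deterministically by original
position. The rare stratum contains pairs whose *smaller* training count is
below the threshold (default 3): one cold endpoint suffices to make the
factorization's view of the pair uninformative. Rare-drug results are
reported both pooled over pairs and per drug (each rare drug's candidate
pairs ranked separately, metrics averaged across drugs), since the two
aggregations answer different questions and neither subsumes the other.

## The synthetic study generator

`simulate_ddi_study()` draws a planted-partition study: drugs fall uniformly
into clusters; within-cluster pairs interact with probability 0.25,
cross-cluster pairs with 0.01; embeddings are the cluster centroid
(orthogonal unit vectors) plus isotropic Gaussian noise (sd 0.3 per
coordinate — chosen so nearest-centroid classification recovers cluster
labels with accuracy above 0.9, i.e. the text channel demonstrably carries
signal); half of the drawn edges move to the future release; 15% of drugs
are forced cold, keeping at most 2 training edges (inside the rare stratum
by construction). Defaults: 300 drugs, 6 clusters, embedding dimension 100.

The generator emulates the features the pipeline depends on — a sparse
symmetric interaction matrix with community structure, embeddings correlated
with that structure, a temporal holdout, designated cold drugs. It does
**not** emulate several properties of real interaction data: degree
distributions are near-Poisson rather than heavy-tailed; the graph carries
*no information beyond cluster membership*, so the network channel can never
know more than the text channel; interaction mechanisms, typed interactions
and literature text itself are out of scope. Passing tests therefore
demonstrate correctness of the machinery and the cold-start ordering of the
components, not real-data effect sizes.

One consequence is worth stating plainly, because the acceptance suite
computes it: at this synthetic scale (~6 training edges per drug) the
factorization component does not overtake the text component even on
well-connected pairs, the stacker consequently learns to lean on the text
score and remains robust on cold pairs, and validation-AUPR tuning selects
$M = 0$. The switching rule earns its keep only in the regime where
factorization dominates warm pairs — which requires a denser, more
structured graph than this generator produces. The routing machinery itself
is exercised and verified exactly, at every $M$.

## Defaults and problem sizes

| Parameter | Default | Notes |
|---|---|---|
| latent factors $k$ | 32 | mid grid; 6 planted clusters need far fewer |
| propagation $\alpha$ | 0.5 | mid range; equal blend of self and neighbourhood |
| learning rate | 0.01 | Adam, both components |
| batch size | 256 | |
| epochs | 30 | loss plateaus well before this on the default study |
| negative ratio | 1 | one negative per positive per epoch |
| hidden widths (text) | 256, 128 | two hidden layers |
| dropout (text) | 0.3 | see memorization note above |
| stacker | one hidden layer of 8, 100 epochs | 2-input function |
| $M$ search | 0–10 | validation AUPR, ties to smallest |
| BCE clipping | $10^{-7}$ | numerical floor for $\log$ |

The test suite and the acceptance script run the full pipeline at the
generator defaults (300 drugs, ~44,000 evaluation pairs) over three seeds,
and the component-level checks on instances of 5–200 drugs; these sizes were
chosen so every stochastic check has enough resolution to fail loudly.

## Known limitations

* The text channel consumes one static vector per drug; contextual or
  subword pooling happens upstream of the input file.
* Unmatched drugs fall back (default) to the mean resolved vector — a
  neutral prior that keeps them scoreable but predicts only base-rate
  behaviour for them.
* Output probabilities are not calibrated; only rankings are evaluated.
* Model checkpointing in the CLI uses R's native serialization rather than
  an interchange format.
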