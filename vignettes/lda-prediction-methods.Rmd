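---
title: "Methods: graph-encoder ensemble prediction of lncRNA-disease associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-encoder ensemble prediction of lncRNA-disease associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldaEnsemble)
```

## The problem

Experimentally validated lncRNA-disease associations (LDAs) are sparse:
curated catalogues record a few hundred to a few thousand pairs over tens
of lncRNAs and hundreds of diseases, while the space of candidate pairs is
orders of magnitude larger. `ldaEnsemble` treats LDA discovery as bipartite
link prediction on the binary matrix $Y \in \{0,1\}^{n \times m}$
(lncRNAs in rows, diseases in columns) and produces a ranked list of
unobserved pairs. A `0` in $Y$ means *unknown*, not negative — this
asymmetry drives several choices below.

## Similarity construction

Both entity types get a fused similarity matrix that serves as the graph
the encoder propagates over.

* **Gaussian interaction-profile kernel.** For profiles $p_i$ (rows of $Y$
  for lncRNAs, columns for diseases),
  $K(i,j) = \exp(-\gamma \lVert p_i - p_j \rVert^2)$ with
  $\gamma = \gamma' / \operatorname{mean}_i \lVert p_i \rVert^2$ and
  $\gamma' = 1$ by default. Normalising by the mean squared profile norm
  makes the bandwidth scale-free in network density, so the same
  $\gamma'$ works for sparse and dense catalogues.
* **Disease semantic similarity.** Over a child-to-parent ontology DAG,
  each disease contributes 1 to itself and $\Delta^{d}$ to an ancestor
  reachable by a best path of $d$ edges ($\Delta = 0.5$ by default, the
  conventional decay in this literature). Two diseases are compared by the
  sum of both contribution vectors over shared ancestors, normalised by
  the sum of all their contributions. The decay is a config knob
  (`decay`); values nearer 1 emphasise deep shared structure.
* **lncRNA functional similarity.** Best-match averaging of the disease
  similarity over the two lncRNAs' associated disease sets. lncRNAs with
  no associations carry no functional signal and fall back to the kernel.
* **Fusion.** Arithmetic mean where both sources are defined, kernel-only
  fallback elsewhere (diseases missing from the ontology,
  association-free lncRNAs). The mean keeps every similarity inside
  $[0,1]$ with a unit diagonal, and the fallback keeps the matrix fully
  defined without imputing semantic values that do not exist.

## The graph encoder

Each similarity graph is encoded by a stacked GCN → GAT → GCN pipeline.
Initial node features are the similarity rows themselves ($H^0 = S$), so
no external feature source is required. The GCN layer is the
symmetric-normalised propagation
$\sigma(A^{-1/2}(I+S)A^{-1/2} H Q)$ with a rectifier; the full weighted
similarity matrix is used as adjacency (no kNN sparsification — the graphs
here have at most a few hundred nodes, and thresholding would discard the
graded similarity values the attention layer feeds on).

The middle layer is multi-head graph attention. For an edge $(i,j)$ the
logit is a LeakyReLU (slope 0.2) of
$a_k^\top [W_k H_i \,\Vert\, W_k H_j \,\Vert\, B_k S_{ij}]$ — the extra
scalar $B_k$ (one trainable weight per head, initialised to 1) injects the
edge's similarity value into the attention score, which is why $a_k$ has
length $2F+1$. Coefficients are softmax-normalised over the neighbourhood
($S_{ij} > 0$ plus self), neighbour features are aggregated, and heads are
combined by averaging rather than concatenation, keeping the feature
dimension fixed at $F$ across layers.

A one-dimensional convolution (two input channels, one output channel,
width 3, same padding, linear) combines the first and third layer outputs
$H^1$ and $H^3$ into the final embeddings; $H^2$ feeds the second GCN but
is not given to the combiner. Training minimises the mean binary
cross-entropy between $\operatorname{sigmoid}(U)$, with preference matrix
$U = X_c^\top X_d$, and $Y$, by Adam (learning rate $10^{-3}$, 200
epochs) over all parameters of both graphs. Gradients are derived
analytically; the test suite checks them against central finite
differences and checks both layer types against literal-loop oracles. $U$
serves only as the training signal — final classification comes from the
ensemble, which consistently outperforms thresholded $U$ on held-out
pairs because it can model interactions between the two embedding halves.

Defaults: $F = 32$, $K = 2$ heads, kernel width 3. All initialisation is
Glorot-uniform under a recorded seed; two runs with the same seed are
bit-identical (no parallelism, no hidden RNG draws).

## The classifier ensemble

A pair $(i,j)$ is represented by the $2F$-vector
$[X_c[,i] \,\Vert\, X_d[,j]]$.

* **Feed-forward network.** Hidden layers (128, 64) with rectifiers and a
  logistic output, trained full-batch with Adam on binary cross-entropy.
* **Boosted trees.** A from-scratch second-order gradient booster:
  logistic loss expanded to second order per round
  ($g_i = p_i - y_i$, $h_i = p_i(1-p_i)$), exact greedy splits maximising
  $\tfrac12[G_L^2/(H_L+\lambda) + G_R^2/(H_R+\lambda) - G^2/(H+\lambda)]$,
  leaf-wise growth to at most 31 leaves, Newton-optimal leaf weights
  $-G/(H+\lambda)$, shrinkage $\nu = 0.1$, $\lambda = 1$, 100 rounds. The
  trainer is deterministic (no sampling, no binning); an established
  boosting library serves as an independent parity reference in one test,
  never as the implementation.
* **Soft voting.** $\text{Score} = 0.4\,C_{\text{DNN}} +
  0.6\,C_{\text{GBM}}$, positive iff strictly greater than 0.5. A tie at
  exactly 0.5 is negative. The weights are fixed constants of the method
  (configurable, but no tuning procedure is provided).

## Evaluation protocols

Negatives are drawn uniformly without replacement from the unknown pairs
at a 1:1 ratio per repeat — the balanced design implied by reporting
accuracy and F1; with heavily imbalanced sampling those threshold metrics
would need re-calibration. Three cross-validation schemes are provided:

* **CV1** holds out 20% of lncRNAs (every pair touching them is test) —
  cold-start prediction for a new lncRNA;
* **CV2** the same over diseases;
* **CV3** holds out 20% of the labelled pairs.

Leakage control: held-out associations are zeroed out of $Y$ before the
kernels are computed and before the encoder is trained, so under CV1/CV2 a
test entity contributes no association signal anywhere upstream; the
ontology-derived semantic similarity is association-free and stays
intact, which is what keeps cold-start prediction meaningful at all.
Metrics are precision, recall, accuracy and F1 at the strict 0.5 cut,
tie-aware rank AUC, and step-interpolated AUPR (no trapezoids);
both rank metrics are checked against brute-force oracles. Repeats
default to 10; each repeat resamples negatives and the split and
aggregates as mean ± sd.

## Synthetic study conditions

The generator plants recoverable structure: non-negative latent factors
($|N(0,1)|$, rank 3) whose outer product is thresholded at the quantile
matching a target density of 0.1 on a 40 × 60 network, followed by
independent label flips. Non-negative factors ensure the planted
similarity is echoed by the interaction-profile kernels — with signed
factors the kernel would fold opposite-sign profiles together and
recovery would not isolate encoder quality. The default conditions (40
lncRNAs, 60 diseases, rank 3, density 0.1, noise 0, with flip rates 0.05
and 0.1 for the robustness sweep) are the fixed study settings used by
the recovery tests and the acceptance script; they were chosen once as a
desk-scale analogue of a curated LDA catalogue and are not adjusted per
run. What passing recovery shows: the pipeline detects planted low-rank
bipartite structure well above a degree baseline. What it does not show:
performance on real catalogues, whose degree distributions are heavily
skewed, whose ontology is deep and uneven, and whose "negatives" include
unverified true associations — none of which the generator attempts to
mimic.

## Numerical choices and degenerate inputs

* BCE probabilities are clamped to $[10^{-12}, 1-10^{-12}]$; attention
  softmax is row-max-stabilised.
* $S' = I + S$ guarantees positive degrees, so the GCN normalisation
  never divides by zero; an isolated node's attention neighbourhood is
  its self-loop (softmax of a singleton is 1).
* Ranking ties are broken lexicographically by lncRNA id; split-gain ties
  keep the first (lowest feature index, lowest threshold) candidate —
  both for determinism.
* A split that would leave a fold without positives is resampled (up to
  100 times, with the retry count reported).
* All-zero profile matrices (kernel bandwidth undefined) and single-class
  label vectors are rejected with errors rather than patched.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the full pipeline on the
40 × 60 study conditions with 5 repeats per setting (3 repeats for the
cold-start and ablation summaries) and the default model sizes above;
layer and metric oracles run on graphs of at most 8 nodes and score
vectors of at most 50 entries, where exhaustive enumeration is exact.

## Known limitations

* The ontology reader accepts any acyclic child-parent table; it does not
  resolve identifier synonyms or cross-ontology mappings.
* No probability calibration: the soft-vote score is a ranking score, and
  the 0.5 cut is a convention, not an estimated operating point.
* No hyperparameter search; every default above is a fixed design choice.
* Full-batch training limits the method to catalogues of (roughly)
  thousands of entities — the intended regime.
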