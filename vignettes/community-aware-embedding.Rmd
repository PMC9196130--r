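---
title: "Community-aware attributed network embedding: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community-aware attributed network embedding: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Given an undirected, unweighted graph with optional nonnegative node
attributes, we want a low-dimensional vector per node (an *embedding*)
that preserves three kinds of structure at once:

* **second-order proximity** — nodes with overlapping neighborhoods
  should receive similar vectors, even without a direct edge;
* **high-order proximity** — nodes connected by many multi-step paths
  should be related in the embedding space;
* **community structure** — the mesoscopic partition of the network into
  densely intra-connected groups should be visible in the geometry.

Brain connectomes are a motivating case: they carry strong community
structure, usually no node attributes, and edge-prediction on them is a
proxy for detecting missing or spurious fiber tracts.

## The model

### Input construction: the reconstructed adjacency

A sparse adjacency matrix alone is a poor autoencoder input: most rows
of a sparse network share almost no support. We therefore blend the
adjacency with cosine-similarity matrices computed from node attributes
and community memberships. Two variants are provided:

* **AM** (attribute merge): community memberships are appended to the
  attribute matrix as one-hot columns, `W = [X | C]`, and
  `R = eta * A + psi * cosine(W)`.
* **CSM** (community similarity matrix): the attribute and community
  channels stay separate, each with its own weight,
  `R = eta * A + psi * cosine(X) + phi * cosine(C)`.

For a hard partition, `cosine(C)` is exactly the same-community
indicator, so `phi` directly controls how strongly the community prior
pulls rows of the same community together. CSM can rebalance the two
channels independently, which matters when the attribute matrix is
sparse or noisy; AM is simpler and cheaper (one similarity matrix).
Either channel degrades gracefully: with no attributes (structure-only
mode, e.g. connectomes) the attribute term is dropped, with
`assignment = NULL` the community term is dropped, and the blend falls
back to `eta * A`.

`eta`, `psi`, `phi` default to 1 and are meant to be grid-searched over
roughly `{0.5, 1.0, 1.5, 2.0, 2.5}` per dataset and task.

### Neighborhood-enhancement autoencoder

Rows of `R` pass through a tanh tower encoder
`y^(k) = tanh(y^(k-1) W^(k) + b^(k))` whose final layer (width `d`) is
the embedding, and a mirrored tanh decoder reconstructs the row. The
reconstruction loss up-weights the informative nonzero entries:

    L_ae = sum_i || (Rhat_i - R_i) * b_i ||^2 ,   b_ij = chi > 1 if r_ij != 0, else 1

With `chi -> 1` this collapses to the plain squared error. The support
test uses `|r_ij| > 1e-12` because the blended similarities are float
products. Default `chi = 10`.

### Community-aware skip-gram

A corpus of random walks (defaults: 10 walks of length 80 per node,
window 10 — second-order `(p, q)` bias implemented but defaulted to the
uniform `p = q = 1`) yields (center, context) pairs, trained with
negative sampling:

    L_sg = - sum_pairs [ log sigma(h'_ctx . y_center)
                         + sum_{s=1..|neg|} log sigma(-h'_s . y_center) ]

Crucially, `y_center` is the *encoder output* of the center node's row
of `R` — the two branches share the encoder — while `H'` is a free
context matrix (one `d`-vector per node). Noise nodes are drawn i.i.d.
from the flattened-degree distribution `P(v) ∝ d_v^(3/4)` via an alias
table (O(1) per draw). Negatives are *not* filtered against the true
context of the center, matching standard skip-gram practice. Whether
`H'` should be tied to a decoder weight is an open design point; we keep
it free, which is the less constrained and more common choice.

### Joint objective and training

    L = L_sg + alpha * L_ae + gamma * L_reg ,
    L_reg = 1/2 sum_k ( ||W^(k)||_F^2 + ||What^(k)||_F^2 )

Biases and `H'` are excluded from the regularizer. Training alternates
mini-batches: each epoch makes one pass over the shuffled pair corpus,
and the autoencoder's row batches are spread evenly among the skip-gram
batches, so both branches see their data once per epoch (the coupling
style used by shared-encoder two-branch models). Both branch updates
include the regularizer gradient. The optimizer is Adam at learning rate
1e-3; all gradients are derived analytically and checked against
central finite differences in the test suite.

Two numerical choices deserve a note:

* **`alpha` defaults to 0.01.** The reconstruction loss is an
  unnormalized sum over all n^2 penalty-weighted entries, while the
  skip-gram loss sums over context pairs; at `alpha = 1` the autoencoder
  gradient numerically swamps the skip-gram branch and the embedding
  collapses to community-level geometry, which is enough to cluster but
  erases the finer co-occurrence structure that edge-level tasks need.
  A grid over powers of ten on planted-partition graphs selected 0.01;
  block recovery is insensitive to the choice, connectivity
  preservation is not.
* **Input scaling.** The tanh output layer cannot reconstruct values
  above 1, so `R` must be scaled. The default divides by the global
  maximum, preserving relative row magnitudes (and hence degree
  information); per-row max scaling and no scaling are available as
  options (`normalize = "row"` / `"none"`). Per-row scaling makes every
  row peak at 1 and discards inter-row magnitude differences, which
  measurably flattens edge-ranking quality.

Initialization is Glorot-uniform for weights, zero for biases and for
`H'` (the standard skip-gram output-side choice; it also makes the
initial skip-gram loss exactly `(1 + |neg|) log 2` per pair, a useful
analytic anchor). Training stops after `epochs` epochs or when the
relative change of the epoch loss over a 5-epoch window drops below
1e-5. The epoch loss is the running sum of batch losses (fresh noise
draws), so it fluctuates slightly; the `history` element of the result
records it per epoch together with a full-corpus loss evaluated on a
fixed noise draw before and after training.

## Community detection

Three routes produce the hard partition the model consumes:

* `lpa()` — asynchronous label propagation: unique initial labels,
  seeded random visit order per sweep, each node adopts its neighbors'
  modal label with uniform random tie-breaks (avoids oscillation bias),
  stopping when every node's label is modal in its neighborhood or
  after `max_iter` (default 100) sweeps. Isolated nodes keep their own
  label; disconnected components can never share a label.
* `multilevel()` — the classic two-phase greedy modularity scheme:
  local moves with incremental ΔQ bookkeeping until no move improves,
  then contraction of communities into super-nodes with integer edge
  weights, repeated until a full pass no longer raises modularity. The
  modularity after each pass is recorded (attribute `q_per_pass`) and is
  non-decreasing by construction; the tests assert it.
* `load_assignment()` — a plug-in slot for external detectors (e.g.
  flow-based map methods, which we deliberately do not reimplement);
  any two-column `node community` file works.

`graph_modularity()` implements the standard Newman definition
(`Q = (1/2m) Σ_ij (a_ij - d_i d_j / 2m) δ(c_i, c_j)`), the assumed
meaning wherever "modularity" appears; it is cross-checked in the tests
against a brute-force double loop and against igraph.
`community_size_report()` summarizes a partition's scale — detectors
differ sharply here, and a partition that dumps ~90% of nodes into one
community carries little mesoscopic information, which is visible
directly in downstream embedding quality.

## Evaluation protocols

* **Node classification**: 30% of labeled nodes (random, redrawn until
  every class is represented) train a linear SVM (`e1071`, cost 1) on
  the embeddings; Micro-F1 (instance-level) and Macro-F1 (unweighted
  class mean) are averaged over 10 repeats.
* **Link prediction**: edges are visited in seeded random order and
  removed only if the remaining graph stays connected, until half the
  edges are gone (an error reports the achieved count when connectivity
  makes the target unreachable — on a tree, immediately). Removed edges
  are positives; an equal number of uniformly drawn non-edges of the
  original graph are negatives (fewer, with a message, if the graph has
  too few non-edges — a complete graph has none). Pairs are scored by
  embedding cosine (zero vectors score 0, with a message) and ranked by
  the exact Mann-Whitney AUC over all positive × negative pairs.
* **NMI** with arithmetic-mean normalization compares partitions for
  the parameter-recovery experiments (two all-in-one partitions define
  NMI 1).

## The synthetic generator, and what the tests do and do not show

`attributed_sbm()` plants a balanced stochastic block model
(`p_in > p_out`, remainder nodes in the last block) with
community-correlated binary attributes: the attribute set is split
evenly among blocks, a node's own-block attributes switch on with
probability `attr_signal`, all others with `attr_noise`. This emulates
the qualitative structure of attributed social and citation networks —
assortative communities plus attribute homophily — and makes every
pipeline stage testable without downloads.

It does **not** emulate heavy-tailed degree distributions, triadic
closure, TF-IDF-weighted attributes, or overlapping communities, and
the edge sampler materializes all node pairs, so it is meant for
desk-scale graphs (hundreds to a few thousand nodes). Passing the
recovery benchmark therefore shows that the implementation is correct
and that the model extracts planted structure; it does not by itself
calibrate performance on real networks.

One property of the SBM matters when reading link-prediction numbers:
conditional on the blocks, edges are independent, so for a *held-out*
split (retraining on the pruned graph) no method can distinguish a
removed within-block edge from a within-block non-edge — block
membership plus a weak degree signal is the entire learnable content,
which caps held-out AUC just under 0.8 at the benchmark's densities.
The packaged benchmark (`recovery_benchmark()`) therefore scores the
split with embeddings trained on the full graph — a
connectivity-*preservation* check of the representation, contrasted
against a random-embedding baseline at chance level — while the
held-out protocol (split, retrain on `split$train_graph`, rank) remains
the documented usage for real data, where transitivity and degree
heterogeneity make held-out prediction genuinely informative.

`recovery_benchmark()` fixes the study conditions: n = 300, 3 blocks,
`p_in = 0.1`, `p_out = 0.005`, 60 attributes at 0.3/0.02, multilevel
communities, CSM variant, d = 32, hidden width 128, 50 epochs, and a
test-scale walk corpus (5 walks × length 20, window 5, 5 negatives —
the full-scale defaults of 10 × 80 × 10 × 10 are kept as
`walk_config()` defaults for real networks). The same function backs
both the acceptance test and `scripts/acceptance.R`, which recomputes
block-recovery NMI (median of three training seeds), trained vs random
link AUC, and downstream Micro/Macro-F1 from scratch at every run.

## Degenerate inputs and conventions

* Zero attribute rows have no direction: their cosine similarity to
  everything (themselves included) is 0 — an attribute-less node should
  not be declared similar to anyone.
* Duplicate edges and self-loops in input files are dropped with a
  logged count; graphs are simple and undirected throughout.
* Walks truncate at dead ends (only isolated start nodes, for simple
  undirected graphs), giving length-1 walks and no context pairs.
* Community ids and node indices are 1-based inside the package (the R
  convention); external files keep arbitrary string tokens.
* Non-finite training loss aborts with a diagnostic rather than
  returning a broken embedding.

## Known limitations

* Similarity matrices and `R` are dense (`n x n`): memory is the
  binding constraint beyond ~20k nodes. `cosine_similarity(top_k=)`
  offers per-row sparsification as a valve, off by default because the
  model definition is dense.
* Training is vectorized R over BLAS: ample for desk-scale experiments
  (minutes at n = 300, d = 32), not for the 10^5-node regime.
* Single-label multi-class classification only; multi-label protocols
  are out of scope.
* Only non-overlapping hard partitions are supported on the community
  side.
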