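---
title: "Edge-shrinkage pooling for molecular graphs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-shrinkage pooling for molecular graphs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mespool)
```

## The problem

Molecular property prediction from structure alone is a workhorse of early
drug discovery. Message-passing networks learn atom and bond embeddings
end-to-end, but a flat message-passing stack struggles to *distinguish*
task-relevant substructures from the rest of the molecule, and it offers
little interpretability. Graph pooling addresses this by coarsening the graph
between convolutions, building a hierarchy of representations. Node-dropping
("sparse") pooling loses atoms entirely; cluster-assignment ("dense") pooling
keeps all information but rebuilds connectivity from scratch, severing the
link to the original molecular topology.

This package implements an *edge-shrinkage* pooling operator: bonds, not
atoms, are the pooling unit. Low-scoring bonds — and the connected
substructures they span — are contracted into supernodes; high-scoring bonds
survive untouched, so the pooled graph inherits the original connectivity and
no atom's information is discarded. Because every pooled node carries the set
of original atoms it represents, the hierarchy reads out directly as a
molecular segmentation (rings, then ring systems, then functional-group
blocks), which is the package's interpretability surface.

## Data model

A molecule is a graph $\mathcal{G} = (\mathcal{V}, \mathcal{E})$ with $n$
heavy atoms and $m$ bonds. Every undirected bond $e(i,j)$ is stored as the two
directed edges $i \to j$ and $j \to i$, each with its own feature row; the
edge update below genuinely breaks the symmetry between the two directions,
so directed storage is the native representation. Node indices are 1-based
and dense per graph (the R convention). Edges are kept sorted
lexicographically and components ordered by smallest member, so identical
inputs produce bitwise-identical outputs.

Initial features follow a fixed table-driven encoding: atom vectors of width
120 (atomic-number one-hot over 1–99 with a 100th "other" slot, aromaticity
flag, bonded-H count 0–3 plus "$\ge 4$", formal charge $-2..{+}2$ clamped,
chirality tag, hybridization tag) and bond vectors of width 13 (bond type,
conjugation flag, ring flag, stereo tag). The widths are fixed by the
encoding; the category lists behind the blocks (which five hybridizations,
which six stereo labels) are conventional choices that match the widths:
hybridization $\{sp, sp^2, sp^3, sp^3d, \text{other}\}$, chirality
$\{\text{unspecified}, \text{CW}, \text{CCW}, \text{other}\}$, bond type
$\{\text{single}, \text{double}, \text{triple}, \text{aromatic},
\text{other}\}$, stereo $\{\text{none}, \text{any}, Z, E, cis, trans\}$.
Out-of-range values map to the block's last slot, so vectors always have
exactly one active position per one-hot block.

### Chemical perception

SMILES parsing, 2D depiction and aromatic-ring detection are delegated to the
OpenBabel backend (ChemmineR/ChemmineOB). The remaining per-atom chemistry is
perceived in-package from the kekulized connection table:

* **Implicit hydrogens** via a standard valence model (C 4, N 3, O 2, …) with
  a formal-charge adjustment ($+1$ on N gives valence 4; charged carbon loses
  a slot). Hydrogens are implicit throughout — the graph holds heavy atoms
  only, with the bonded-H count as an atom feature.
* **Hybridization** heuristically: a triple bond or two doubles gives $sp$;
  aromaticity or one double gives $sp^2$; five connections give $sp^3d$;
  otherwise $sp^3$.
* **Conjugation**: a bond is conjugated if it is aromatic, if it is a single
  bond between two $\pi$-system atoms, or if it is a multiple bond adjacent to
  another $\pi$ atom. Atoms count as $\pi$ when aromatic, multiply bonded, or
  an N/O/S/P lone-pair donor next to a multiple bond (so amide C=O and C–N
  both come out conjugated, while an isolated ethylene double bond does not).
* **Chirality** tags are lexed from the SMILES text itself (`@`/`@@` in
  bracket atoms), relying on OpenBabel's preservation of input atom order;
  if the lexer's atom count disagrees with the connection table the molecule
  falls back to "unspecified" everywhere rather than guessing.
* **Double-bond stereo** is read off the generated 2D depiction (same side =
  *cis*, opposite = *trans*); the $Z$/$E$ CIP labels in the stereo block are
  reserved and currently never emitted. This is a drawing-based heuristic, not
  a CIP implementation.

These rules are deliberately simple and documented here because they are
*part of the featurization contract*: they fix widths and ones-counts, which
the test suite checks molecule-by-molecule, but they are not guaranteed to
reproduce any particular toolkit's perception on exotic chemistry
(organometallics, hypervalent boron, tautomer-dependent aromaticity).

## Convolution: edge-featured isomorphism network

The baseline graph isomorphism update is

$$h_i \leftarrow \mathrm{MLP}\Big((1+\epsilon)\, h_i + \sum_{j \in \mathcal{N}(i)} h_j\Big),$$

with $\epsilon$ learnable (initialized at 0). The edge-featured variant
alternates two steps. First every directed edge absorbs its *starting* node,

$$h_{i \to j} \leftarrow \sigma\big(W\,(h_{i \to j} \,\|\, h_i) + b\big),$$

after which $h_{i \to j}$ is a weighted message from $i$ to $j$ and the two
directions of a bond differ. Then each node concatenates itself with the sum
of its incoming edge messages:

$$h_i \leftarrow \mathrm{MLP}\Big(h_i \,\|\, \sum_{k \in \mathcal{N}(i)} h_{k \to i}\Big).$$

Concatenation (not addition) is used because the central feature and the
aggregated message are different kinds of quantities and may have different
widths. Each MLP is Linear → batch-normalization → ReLU → Linear; the
normalization can be switched off (`use_norm = FALSE`), and during evaluation
it uses running mean/variance buffers so batched and single-molecule forward
passes agree. The $\sigma$ in the edge update defaults to ReLU — the sigmoid
is reserved for edge *scoring*, the one place where a (0,1) squashing is
structurally required.

## Pooling: selection, reduction, connection

**Selection.** Scores must reflect a bond's neighborhood, not just the bond,
so one round of edge message propagation runs first:

$$h^{\mathrm{p}}_{i \to j} = \mathrm{MLP}\Big(h_{i \to j} + \sum_{k \in \mathcal{N}(i)} h_{k \to i}\Big), \qquad h_{e(i,j)} = h^{\mathrm{p}}_{i \to j} + h^{\mathrm{p}}_{j \to i}.$$

The symmetric undirected feature is scored by a learnable vector $s$ through a
sigmoid, $s_{e(i,j)} = \mathrm{sigmoid}(s^\top h_{e(i,j)}) \in (0,1)$, and the
directed features are rescaled by their bond's score,
$h'_{i \to j} = s_{e(i,j)} \cdot h^{\mathrm{p}}_{i \to j}$ — this rescaling is
the gradient path into $s$. The pooled set is chosen by a threshold

$$\mathrm{threshold} = \min(\lambda,\ s_{\mathrm{mean}}),$$

with $\lambda \in (0,1]$ a hyperparameter (default 0.5, per layer) and
$s_{\mathrm{mean}}$ the mean score of the graph's bonds. Edges strictly below
the threshold are pooled; ties survive. Since the maximum score can never be
below the mean, at least one bond always survives — a graph is never
collapsed to a point in one step. On a batch, means and thresholds are
computed per member graph, which is what makes batched and serial processing
equivalent.

**Reduction.** The pooled edges and their endpoints form a subgraph whose
connected components (plain union-find; every pooled edge is present in both
directions, so weak and strong connectivity coincide — the package therefore
uses ordinary connected components) are the units to contract. A *dedicated*
edge-featured convolution pass — its own parameters, distinct from the
block's main convolution — runs on that subgraph, consuming the score-scaled
edge features, and each supernode's feature is the sum of its members'
refined features. With the reduction pass configured to identity, the
supernode feature is the plain member sum and the graph-level summation
readout is exactly conserved by pooling; this conservation is a test target.

**Connection.** Surviving nodes keep their identity; each preserved directed
edge has its endpoints remapped (member → its supernode). Contracting a ring
can produce parallel edges or self-loops: a cycle keeping two adjacent edges
becomes two nodes joined by two parallel edges; a cycle keeping one edge
becomes a single supernode with two directed self-loops (the preserved edge
was stored in both directions). Repeated directed edges with identical
endpoints are then merged by *summing* their feature rows, self-loops
included; self-loops are kept and contribute once to their node's later
aggregations. Merging by sum (rather than mean) follows the additive
message-passing convention used everywhere else in the model.

Degenerate inputs are defined away rather than special-cased downstream: an
edgeless graph, or a selection that comes up empty, returns the input graph
unchanged with an empty selection.

## Architecture, objective, training

The default model is three blocks of (EGIN convolution → pooling → summation
readout); the per-block readouts are concatenated (width = blocks × hidden)
and passed through dropout and one linear head, one output per task.
Classification heads emit raw logits; the sigmoid lives inside the loss and
the metrics. A pooling-free variant (convolution + readout only) is available
as `pooling = FALSE`.

Training is by Adam (default learning rate $10^{-3}$) on a masked objective —
binary cross-entropy on logits or squared error, averaged over labelled
entries only, so multitask tables with missing labels contribute exactly
their observed cells. Early stopping watches the validation metric (AUC-ROC
up / RMSE down) with a default patience of 30 epochs. Everything is
deterministic given the seed: weight draws, split shuffles, batch order and
dropout masks all derive from it.

Because no automatic-differentiation framework is available to R in this
package's dependency set, training runs on a small reverse-mode tape over
dense matrices implemented in `R/tape.R` (`ad_*` functions). It provides
exactly the operations the model needs — matrix product, gather/scatter by
index (the message-passing primitives), concatenation, ReLU/sigmoid,
batch-norm statistics, fused masked losses — and each primitive's gradient is
tested against central finite differences. The non-differentiable structural
decisions (threshold split, component finding, edge merging) sit outside the
tape, as in any straight-through pooling implementation: gradients flow
through feature values, not through the discrete selection.

## Scaffold splitting

Generalization is evaluated across chemotypes: molecules are grouped by
Bemis–Murcko scaffold (iteratively pruning degree-1 atoms leaves the ring
systems and linkers; acyclic molecules share the empty scaffold), groups are
shuffled by seed, and whole groups are assigned greedily — train until ≥ 80%
of molecules, then validation until ≥ 10%, remainder test, with enough groups
held in reserve that validation and test are never empty. A group is never
split across partitions. Scaffold identity uses a canonical graph key (BLISS
canonicalization with atoms colored by element and bond orders encoded as
colored subdivision vertices), so the key is invariant to atom ordering in
the input SMILES. Fewer than three scaffold groups is an error — three
nonempty partitions are impossible. A deterministic group order
(`scaffold_deterministic`) and a plain random split are also available.

## The synthetic task

`make_synthetic_task()` assembles molecules from a small fragment vocabulary
— alkyl chains, branched alkyl, amide, ether/hydroxyl, cyclopentane, benzene,
pyridine, nitro — by string concatenation rules that always yield valid
SMILES, and labels each molecule 1 iff it contains an aromatic ring. The
class is drawn before assembly (alternating), so classes are balanced by
construction. The label is recomputable from the featurized graph (any
aromaticity bit set), which the tests exploit.

One consequence of the design: the label is a deterministic function of the
scaffold, so scaffold-grouped splitting would put whole label classes into
single partitions — the learnability check therefore evaluates under a
*random* split, while scaffold splitting is exercised on its own contract.

What this emulates: a multitask-style CSV of SMILES with a structural
endpoint that a hierarchical model must read out of ring perception —
learnable, but only through the graph structure. What it does **not**
emulate: label noise, activity cliffs, assay artifacts, class imbalance, or
the scale of real benchmark sets. A model passing the learnability test
(validation AUC-ROC ≥ 0.95 within 50 epochs at $n = 300$) is demonstrated to
train end-to-end through pooling; nothing more is claimed about real-data
performance.

Problem sizes used by the test suite and the acceptance script — 300
molecules for learnability, 500 random graphs (≤ 30 nodes) for the invariant
sweep, 1000 instances for the component-finding oracle — were chosen as the
smallest sizes at which the corresponding properties are meaningfully
exercised.

## Interpretability traces

`pooling_trace(model, smiles)` records, per pooling layer, the partition of
original atoms into current nodes, the subsets contracted at that layer (the
reduction stage), and the surviving bonds in original atom coordinates (the
connection stage) — both stages are recorded because a figure drawn from
either is meaningful. Two invariants hold at every depth and are validated on
read: the groups partition the atom set, and each deeper group is a union of
shallower groups. `export_trace()` writes a documented JSON schema
(`inst/schema/pooling_trace.schema.json`); rendering colored depictions from
it is deliberately out of scope — the tested surface is the JSON.

## Design choices made where the design was open

* **$\lambda$ defaults to 0.5** and is exposed per block; it is the natural
  midpoint of the score range and interacts with the mean-score cap.
* **The reduction convolution has its own parameters** rather than sharing
  the block's: it runs on a different graph (the pooled subgraph) over
  score-scaled features, and weight sharing would couple two quite different
  signal distributions.
* **Strict inequality at the threshold**: ties survive. Combined with the
  mean cap this yields the no-total-collapse guarantee, including the
  all-scores-equal case (zero scoring vector ⇒ no pooling at all).
* **Merged repeated edges are summed**, and merged self-loops are kept; a
  self-loop contributes its node to its own neighbor set once per loop.
* **Batch normalization sits inside the MLPs** and can be disabled; the edge
  update is a single affine + nonlinearity with no normalization.
* **Classic modelling surface**: `mespool_fit()` returns an S3
  `mespool_model` with `print`/`summary`/`predict`/`plot`. No `coef` or
  `residuals` methods are provided — a message-passing network has no
  meaningful coefficient vector or residual structure at the object level.
* **1-based node indexing**, matching R; all index arithmetic in the package
  and its JSON exports is 1-based.

## Known limitations

* Chemical perception is heuristic (see above): no CIP stereo, no tautomer
  handling, aromaticity as perceived by the OpenBabel backend plus ring-size
  bounds (rings of ≤ 12 atoms considered; aromatic systems of interest are
  small).
* The training engine is plain R; it is comfortable at the fixture scale
  (hundreds of molecules, hidden widths ≤ 64) and is not a GPU framework.
  Batched message passing keeps it vectorized, but large benchmark datasets
  are outside the intended envelope.
* Pooling decisions are discrete; no gradient flows through *which* edges
  pool, only through the scores' effect on feature magnitudes. This is
  inherent to threshold pooling, not an implementation shortcut.
* `n` below 3 scaffold groups cannot be split; single-class validation tasks
  are skipped in metrics with a warning.
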