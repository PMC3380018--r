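---
title: "Hierarchical taxonomic binning by genomic signature: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical taxonomic binning by genomic signature: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosvm)
```

## The problem

A metagenome sample is sequenced DNA from a mixture of microorganisms.
Before any functional or ecological analysis, each assembled fragment
(contig or scaffold) needs a taxonomic affiliation. Alignment against
reference databases is accurate when close relatives have been sequenced,
but it is slow at the scale of hundreds of megabases and fails outright for
the large uncultured fraction of microbial diversity. Composition-based
binning instead exploits the *genomic signature*: short k-mer frequencies
are characteristic of a genome and more similar between evolutionarily
close organisms than distant ones, so a classifier trained on labelled
genomes can place novel fragments onto a taxonomy from sequence alone.

`phylosvm` implements such a classifier: a hierarchical, structured-output
support vector machine over a reference taxonomy, together with the
training-data machinery, the field's standard evaluation statistics, and a
synthetic community generator that makes the whole pipeline testable
without any external downloads.

## Input space

A fragment is represented by its k-mer composition for k = 4, 5, 6. For
each k, all windows consisting solely of A/C/G/T are counted (windows
covering an ambiguity code are skipped), a k-mer and its reverse complement
are pooled into one canonical feature (metagenome fragments arrive on an
arbitrary strand, and collapsing makes the representation exactly strand
symmetric), and the counts are divided by the number of valid windows.
Normalizing counts to frequencies is what makes fragments of different
lengths comparable; we chose per-k-block L1 normalization — each block is a
probability vector — as the most direct reading of length normalization.
Jointly renormalizing the concatenated blocks instead would only rescale
all features by 1/3 and is therefore equivalent up to the regularization
scale. The canonical dimension is 136 + 512 + 2080 = 2728; a raw
strand-sensitive mode (4⁴ + 4⁵ + 4⁶ = 5376 features) is kept behind
`featurizer_spec(rc_collapse = FALSE)` for comparison experiments.

## Output space and joint feature map

The label set is *every node* of the model taxonomy, a rooted tree
restricted to the seven major ranks (domain, phylum, class, order, family,
genus, species). Internal nodes are legal predictions, which is how
low-confidence fragments end up assigned at a higher level rather than
forced into a leaf.

Each non-root node $v$ owns a weight vector $w_v$ of the feature dimension,
and the score of label $y$ for fragment $x$ is the path sum

$$F(x, y) = \sum_{v \in \mathrm{lineage}(y),\, v \neq \mathrm{root}} w_v^\top x,$$

with the root scoring 0. This is the standard hierarchical construction
for structured SVMs: evidence for a species is automatically evidence for
its genus, family, and so on, because ancestors' weights participate in
every descendant's score. Prediction is the arg-max of $F$ over all nodes,
computed by exhaustive enumeration (taxonomies here have at most a few
thousand nodes, so enumeration is exact and cheap). Ties break toward the
node nearer the root, then toward the smaller identifier — a deterministic
rule that prefers the more conservative (less specific) claim.

## Training

Each member SVM minimizes the 1-slack margin-rescaling objective

$$\min_{w, \xi \ge 0} \tfrac{1}{2}\lVert w \rVert^2 + C\,\xi
\quad \text{s.t.} \quad
\frac{1}{n}\sum_i \left[ \Delta(y_i, \hat y_i) - F(x_i, y_i) + F(x_i, \hat y_i) \right] \le \xi
\;\; \forall (\hat y_1 \dots \hat y_n),$$

where the loss $\Delta$ is the **geodesic distance** on the taxonomy — the
number of edges between the true and predicted nodes. Using the tree
metric as the training loss mirrors the evaluation: predicting a parent of
the truth costs 1 edge, a wrong phylum costs many. Margin rescaling was
chosen over slack rescaling because its separation oracle is an
enumeration of the same arg-max form as prediction.

The cutting-plane algorithm adds, per round, one aggregated constraint
built from the per-example most violated labels, re-solves the dual
quadratic program over the working set, and stops when the newest
constraint is violated by less than `tol` (default 1e-3). The dual QP —
minimize $\tfrac12 \alpha^\top Q \alpha - b^\top \alpha$ over
$\alpha \ge 0$, $\sum \alpha \le C$ — is solved to a fixed tolerance of
1e-8 by a deterministic coordinate-ascent scheme: cyclic single-coordinate
updates plus pairwise exchange moves that move mass between constraints
when the sum constraint is active (single-coordinate moves alone can stall
there because the constraint couples the coordinates). The solver is
warm-started across rounds and constraints whose multiplier stays at zero
for 50 rounds are pruned. Everything is deterministic: training the same
set twice yields bit-identical weights, which the test suite asserts.

**Regularization constant.** `reg_C` defaults to 1000. The scale follows
from the geometry rather than tuning: composition vectors have L2 norms
around 0.05–0.3 (they are L1-normalized probability blocks over thousands
of features), while the margins demanded by the geodesic loss are on the
edge-count scale of 1–10, so the weight norm — bounded through the dual by
$C \cdot \max\lVert g \rVert$ — must be able to reach the hundreds. With
$C = 1$ the optimizer is capped at $\lVert w \rVert \approx 0.1$ and
cannot leave the neighbourhood of the trivial all-root solution. No
hyperparameter cross-validation is performed; all fits use the defaults.

## The length ensemble

Classification accuracy of composition features depends strongly on
fragment length, so the model is an ensemble of six SVMs trained on
fragments of 1, 3, 5, 10, 15 and 50 kb sharing one taxonomy and one
feature space. A query is scored by at most three members: those trained
at the query's length or longer, taking the closest such lengths (a 4 kb
query uses the 5/10/15 kb members). A query longer than every training
length falls back to the single longest member. Member scores are combined
by an unweighted mean — the simplest rule consistent with "at most three
members"; since each member's scores are on the same loss-calibrated
scale, averaging is a reasonable default, and it is documented here as a
design choice rather than an inherited one.

An optional margin threshold `margin = m` moves an assignment from the
arg-max node up to the deepest ancestor whose score lead over the best
node outside that ancestor's subtree is at least `m`. The lead is
non-decreasing toward the root (the outside set shrinks), so the rule is
monotone and always satisfiable at the root. The default is `m = 0`, the
pure arg-max.

At prediction time, scores are computed one sequence at a time rather than
in batched matrix products. This costs a little speed but guarantees that
results do not depend on how a sample was split into batches — the
multiplex-merge identity (combining the halves of a split FASTA reproduces
the unsplit run byte for byte) is part of the I/O contract.

## Training data construction

For a **generic model**, reference genomes are mapped to the lowest
corresponding taxa and a clade is modelled when its subtree holds at least
`min_genomes = 3` distinct genomes — below that, a composition model of
the clade is unlikely to generalize. For a **sample-specific model**, the
user supplies roughly 100 kb of labelled sequence per expected population
(headers carry `label:X` tags); these records are pooled with the generic
references, always modelled regardless of count, and win identifier
conflicts.

Per clade and per training length, about `per_taxon_bp = 100 kb` of
non-overlapping fragments are sampled — equal amounts across clades so no
clade dominates the margin. Fragment positions are a seeded shuffle of a
maximal tiling: reproducible, non-overlapping by construction, and
unbiased along the genome. Clades with insufficient sequence contribute
what they have (with a warning) and drop out of lengths they cannot host a
single fragment for. At least two modelled clades are required to train.

## Evaluation measures

* **Consistency**: a prediction is consistent if it names the correct
  clade or any ancestor of it. Reported weighted by fragments
  (`Const_n_scaff`) and by base pairs (`Const_n_bp`); bp-weighting above
  fragment-weighting means long fragments fare better. Because the root is
  everyone's ancestor, consistency is deliberately coarse — the all-root
  predictor scores exactly 1 — so it is always read together with:
* **Taxonomic distance**: the mean geodesic distance between predicted and
  correct nodes. The all-root predictor pays the full lineage depth here.
  With a `mapped_rank`, both sides are first projected to that rank;
  predictions already above the rank are compared as they stand, and
  truths that skip the rank (some taxa have no defined genus or family)
  are excluded with a warning.
* **Per-rank accuracy**: truth and prediction are mapped to each major
  rank; a fragment is correct where both map and agree. Predictions that
  do not reach a rank count as incorrect there, so a drop toward species
  reflects unassigned rather than misassigned sequence, and accuracy is
  provably non-decreasing from species to domain.
* **Micro vs macro averages** in grouped reports: micro averages over
  fragments, macro unweighted over groups (clades or genome bins).

Denominators cover assigned fragments only; sequences the classifier
declined (below the 100 bp minimum) are excluded from the "assigned"
counts but still appear in abundance summaries under "Other", whose
conservation law (clades + Other = totals, per rank) is asserted in the
tests.

## The synthetic community generator

Real benchmarks for this problem need genome downloads and hours of model
building. The generator instead emulates the single property the
classifier exploits: signature similarity decays with phylogenetic
distance. A toy taxonomy (root → phyla → genus leaves) is built; the root
gets an order-3 Markov chain determined by a base GC content; each edge
perturbs every conditional distribution with Dirichlet noise of
concentration `20 / divergence` times the parent probabilities. Expected
compositional distance between two leaves therefore grows with their
geodesic distance, and `divergence` is a separability dial: accuracy of
the trained ensemble rises monotonically with it, which the tests check at
0.02 / 0.1 / 0.5. Order 3 was chosen so that 4–6-mer features see genuine
higher-order structure, not just GC. The default divergence of 0.1 gives
per-edge conditional-probability perturbations of a few percentage points
— clade separation that is clear but far from trivial at the 1 kb training
scale.

Train/test separation is by genome coordinate: the first 80% of each leaf
genome is available for training fragments, test fragments are drawn only
from the last 20%, so no test base is ever seen in training. All outputs
(tables, genomes, FASTA files) are byte-reproducible from the seed.

What the generator does **not** emulate: sequencing error, read-length
heterogeneity and assembly artefacts, GC- and environment-driven signature
shifts within a clade, horizontal transfer, repeats, and realistic genome
sizes. Passing the recovery tests therefore shows the pipeline is correct
and the model can exploit hierarchical composition signal; it does not
certify accuracy on real metagenomes, where reference coverage of the
sample is the dominant factor.

## Problem sizes used by the tests

The recovery tests train 2-phylum × 2-genus communities with 500 kb
genomes at 1/3/5 kb (100 kb per clade) and score 1000 held-out 5 kb
fragments, for seeds 1–5; the divergence-dial check runs a 200 kb / 200
fragment configuration over three seeds. These sizes keep a full suite run
in a few minutes while leaving the per-clade training amounts at the
documented 100 kb default. The acceptance script
(`scripts/acceptance.R`) re-runs the full-size configuration from scratch
for one seed and writes the measured accuracy, consistency and taxonomic
distance as JSON.

## Known limitations

* Enumeration-based prediction is exact but linear in the number of
  taxonomy nodes; for trees beyond ~10⁴ nodes a dynamic-programming
  arg-max over the tree would be the next step.
* The ensemble combination rule (mean score) and the margin-based
  move-up rule are documented stand-ins; nothing in the training objective
  calibrates scores across members beyond the shared loss scale.
* Genomes are treated as single sequences per record when counting
  "distinct genomes" for the clade-inclusion rule; multi-contig assemblies
  should be concatenated or given one record per genome.
* Training is in-memory; a 100 Mb reference collection at six lengths is
  fine, but whole-RefSeq-scale generic models would need out-of-core
  feature construction.
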