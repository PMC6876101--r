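---
title: "Two-round random walk with restart on a quadruple-layer network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-round random walk with restart on a quadruple-layer network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trwr)
```

## The model

Cancer genes tend to sit close — in a network sense — to other cancer-associated
entities: other cancer genes, cancer-associated microRNAs and lncRNAs, and the
cancers themselves. `trwr` scores candidate genes by running a random walk with
restart (RWR) over a quadruple-layer heterogeneous network whose node layers are
genes, miRNAs, lncRNAs and cancers.

**Layers.** The gene layer is the union of a protein–protein interaction (PPI)
network and a pathway co-membership network (duplicate edges and self-loops
removed). The miRNA and lncRNA layers are k-nearest-neighbour (kNN) functional
similarity networks: two RNAs are similar when the diseases they are associated
with are similar, measured by the symmetric best-match average

$$S(D_1, D_2) = \frac{\sum_{d \in D_1} \max_{d' \in D_2} sim(d,d') +
\sum_{d \in D_2} \max_{d' \in D_1} sim(d,d')}{|D_1| + |D_2|},$$

where $sim$ is a precomputed disease–disease semantic similarity matrix (its
computation from ontologies is outside this package's scope). The cancer layer
is a kNN network over the same disease similarities (k = 3 for cancers, 10 for
each RNA layer, the conventional choices for these data). Six bipartite
association blocks couple the layers; their union with the four intra-layer
adjacencies forms a symmetric block matrix $H$.

**Gene-layer transition.** Rather than row-normalizing the merged gene network
directly, the gene transition averages the two evidence sources and adds a
protein-complex feedback:

$$W_G = \mathrm{rownorm}\!\left(\tfrac{1}{N_i} W_P + \tfrac{1}{N_i} W_{Path} + W_{com}\right),$$

where $W_P$ and $W_{Path}$ are the row-normalized PPI and pathway operators,
$N_i \in \{1,2\}$ counts the evidence networks in which gene $i$ has at least
one edge, and $W_{com}(i,j)$ equals, for every neighbour $j$ of $i$, the largest
fraction of currently-known cancer genes among the protein complexes containing
$i$ (0 for genes in no complex). The feedback boosts transitions out of genes
sitting in cancer-enriched complexes. When a gene belongs to several complexes
the maximum ratio is used; the ratio's denominator is the full complex size
even when some members fall outside the current gene index, because the complex
is a biological unit independent of the walk's node set.

**Global transition.** The walk operator scales each intra-layer block by
$1-\delta$ and splits the jump probability $\delta$ equally over the
*non-empty* inter-layer blocks of each row. A node with no couplings keeps full
mass in its own layer; a node with couplings but no intra-layer edges spreads
mass 1 over its couplings. This per-row reallocation is the standard convention
for heterogeneous-network RWR and is the only reading under which every
non-dangling row sums to exactly one; leaving rows sub-stochastic would leak
probability at every step.

**The walk.** With restart probability $\gamma$ and restart distribution
$P(0)$,

$$P(t+1) = (1-\gamma)\, W^\top P(t) + \gamma P(0),$$

iterated until the Euclidean norm of the difference of successive iterates
falls below `tol` ($10^{-6}$ by default; the contraction factor is $1-\gamma$,
so convergence takes a few dozen iterations). The transpose is deliberate: $W$
is row-stochastic, so probability flows correctly along edges only through
$W^\top$; iterating with $W$ itself would not preserve a distribution.

**Two rounds.** The restart vector spreads per-layer masses
$\eta_1,\dots,\eta_4$ uniformly over each layer's seeds; layers without seeds
have their $\eta$ redistributed proportionally over the seeded layers. The
*first round* seeds every cancer node and every gene, miRNA and lncRNA
associated with *any* cancer — a class-level screen — and retains the
$k = \mathrm{round}(\sigma n)$ top-scoring genes (minimum 1). The network is
then reconstructed with the gene layer restricted to those genes (induced
subgraph; gene rows of the gene–miRNA/lncRNA/cancer blocks restricted) and the
gene transition, including the complex feedback, is recomputed on the restricted
set. The *second round* seeds one specific cancer and its associated entities.
The final score fuses the rounds:

$$Score = \alpha P^1(\infty) + (1-\alpha) P^2(\infty),$$

with $P^2 = 0$ for genes ejected in round one, so all $n$ genes remain
rankable. Scores are reported as rank scores: the fraction of the ranking
population a gene strictly outranks (ties count as losses, making tied genes
indistinguishable and the statistic invariant under monotone transforms of the
score).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `delta` | 0.5 | probability of jumping to another layer per step |
| `eta` | (0.25, 0.25, 0.25, 0.25) | restart-mass share per layer (gene, miRNA, lncRNA, cancer) |
| `gamma` | 0.6 | restart probability |
| `sigma` | 0.6 | fraction of genes retained after round one |
| `alpha` | 0.9 | weight of the first-round score in the fusion |
| `tol` | 1e-6 | Euclidean convergence threshold |

The defaults are the values reported to perform best for this method family:
uniform layer weights with a balanced jump probability, a restart of 0.6, a
screen keeping 60% of genes, and a fusion dominated by the class-level round.
`run_sweep()` reproduces the grid exploration over $\gamma$, $\sigma$ and
$\alpha$ on any fixture.

## What the synthetic generator emulates — and what it does not

Real inputs for this method come from curated databases (HPRD, pathway
collections, HMDD, LncRNADisease, miRTarBase, starBase, NPInter, CORUM, OMIM),
whose acquisition and identifier curation are out of scope. The generator
(`generate_fixture()`) emulates their *statistical shape*: a modular gene
network (Erdős–Rényi background, mean degree 4, with planted 10-gene modules
whose internal edge probability is multiplied by an enrichment factor), one
planted disease per module, gene/miRNA/lncRNA associations to the planted
disease at a signal rate, uniform per-pair association noise, protein complexes
drawn partly from planted modules, and a disease similarity matrix with high
within-group and low between-group values. Defaults are the validation
conditions used throughout: 300 genes, 40 + 40 RNAs, 6 cancers, six 10-gene
modules, signal 0.8, enrichment 5.

The per-pair noise rate defaults to 0.005. Because noise multiplies the full
$n \times c$ pair space while signal multiplies only the planted pairs, a noise
rate must stay well below `signal * module_size / n_genes` for the fixture to
be signal-dominated; at 0.005 spurious associations are roughly 15% of the
gene–cancer table. Each spurious association becomes a cross-validation record
with no recoverable signal, so the attainable pooled AUC is bounded by the
noise fraction regardless of the method — a mixture bound worth keeping in
mind when configuring fixtures.

What passing tests on these fixtures do **not** show: robustness to the heavy
degree tails, identifier noise, ascertainment bias and inter-database
inconsistency of real curated data, nor the method's absolute performance on
any real cancer corpus.

## Evaluation design

`loocv()` holds out each known gene–cancer association in turn, reruns the full
two-round pipeline for that disease, and records the held-out gene's rank score
within {held-out gene} ∪ {genes with no known association to that disease}.
Positives are the held-out rank scores; negatives are the rank scores of genes
never associated with any cancer, pooled across records; `roc_auc()` sweeps a
threshold with ties grouped and integrates by trapezoid. `topk_counts()`
reports how many held-out genes landed in the top k% of their candidate set.
Single-network (`method = "rwr"`) and gene+cancer bilayer (`method = "rwrh"`)
baselines run in the same harness.

**Leakage guard.** While a gene is held out it must not be identifiable as
cancer-associated from the network: the default guard (`guard = "full"`) hides
the gene's entire gene–cancer coupling row and removes it from the class-level
cancer gene set (used by the complex feedback) and from all seed sets. The
weaker `guard = "association"` removes only the held-out pair; genes with
several known cancers then keep an advantage from their remaining couplings,
which inflates measured performance — on a label-shuffled fixture it pushes the
null AUC above the calibration band, so the full guard is the default.

**Calibration caveats discovered during development.** Two properties of this
harness matter when interpreting null experiments. First, candidates associated
with *other* cancers are first-round seeds and occupy the top of every
ranking, so a held-out gene's raw rank score is bounded away from 1; its
distribution under a null is uniform only over the non-seed stratum. The
calibrated null statistic (`holdout_null_ranks()`) therefore measures the
held-out gene's standing among its exchangeable reference population, the
never-associated genes. Second, all records of one fixture share a single
negative panel and network, so their statistics are dependent: a one-sample
uniformity test applied to one fixture's records over-rejects even when the
harness is exactly unbiased. The package's calibration checks pool records over
several independently generated label-shuffled fixtures, which averages the
panel fluctuations out; `exchangeable_null_ranks()` provides matched controls
run through the identical machinery for two-sample comparisons.

## Numerical choices and degenerate inputs

- Zero rows (isolated nodes) are preserved as zero by row normalization;
  dangling rows lose walk mass, which the restart re-injects.
- kNN selection drops zero-similarity candidates (a weight-0 edge is no edge);
  ties at the k-th neighbour break by lexicographic identifier for cross-platform
  determinism; edges are similarity-weighted by default (`weighted = FALSE`
  gives binary edges).
- RNAs with no disease annotations enter their similarity layer as isolated
  nodes; the similarity is undefined (not zero) for empty disease groups, and
  erroring there rather than silently returning 0 is deliberate.
- Genes isolated in both evidence networks get `1/N = 0` rather than a
  division by zero; they can only arise in user-supplied data, not from the
  union construction.
- A gene associated with several cancers seeds the first round once (restart
  mass is spread over distinct nodes, not associations).
- LOOCV records whose disease retains no associated gene, miRNA or lncRNA after
  the removal are skipped with a count: the cancer node itself is always a
  seed, but a walk restarted only there has no disease-specific evidence to
  propagate.
- `k = round(sigma * n)` with a floor of 1; convergence uses the Euclidean
  norm; iteration caps raise an error carrying the residual rather than
  returning silently.

## Problem sizes used in the packaged validation

The shipped tests run entirely on generated fixtures: 300-gene fixtures for the
signal-recovery and null-calibration runs (about 60 planted records and about
285 null records), 10 pooled 300-gene shuffled fixtures (about 900 records) for
the uniformity calibration, and up to 500-node fixtures for the linear-solve
equivalence of the walk. `scripts/acceptance.R` reruns the same computations
from scratch for any seed.

## Known limitations

- The two evidence networks enter the gene transition with equal weight
  (1/N); no learned edge or layer weighting.
- Inter-layer jump mass is split equally among available layers; a per-layer
  pair jump matrix is out of scope.
- The complex feedback uses each gene's best complex regardless of which
  neighbour the step targets — the per-source reading of the feedback term; a
  shared-complex variant would couple source and target.
- Real-data headline numbers from curated corpora are not reproduced here;
  acceptance is property-based on synthetic fixtures.
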