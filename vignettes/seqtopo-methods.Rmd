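---
title: "Graph-theoretic alignment-free sequence descriptors: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretic alignment-free sequence descriptors: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqtopo)
```

## The problem

Pairwise alignment detects homology reliably only above the "twilight
zone": for proteins, below roughly 35% identity inference becomes
unreliable, and below 20% (the "midnight zone") structural homologs are
essentially invisible to alignments; for RNA the analogous boundary sits
near 50–60% identity. Alignment-free (AF) descriptors attack the problem
from a different angle: a sequence is re-expressed as an artificial 2D
graph, and numeric invariants of that graph — topological indices — serve
as features that do not depend on positional alignment at all. seqtopo
implements the main graphical representations used in this line of work
(2D-Cartesian pseudo-folded walks, four-color spiral maps, star graphs),
the descriptor families computed from them (Estrada spectral moments,
Markov-chain stochastic moments and entropies, classical topological
indices, autocorrelation vectors, word/information measures), an
alignment engine for delimiting the twilight zone on real data, and a
seeded generator of synthetic families so that the full pipeline can be
exercised and tested without any external database.

## Graphical representations

**2D-Cartesian pseudo-folding.** A grouping scheme partitions the
alphabet into four classes and assigns each class a unit vector on one
Cartesian semi-axis. The sequence becomes a lattice walk anchored at the
origin (the origin itself is not a residue): residue $i$ sits at
$p_i = p_{i-1} + d(\mathrm{group}(s_i))$. For proteins the default `hp4`
scheme puts nonpolar residues on $+x$, polar on $-x$, basic on $+y$ and
acidic on $-y$; for nucleotides the `nandy_dna`/`nandy_rna` schemes give
each base its own axis. Residues that land on the same lattice point are
merged into one node with a recorded multiplicity, and edges connect the
nodes of consecutive residues (parallel edges collapsed). A sequence that
never revisits a point yields a path; pseudo-folding information is
exactly what shows up as merged nodes and cycles. Keeping the graph
simple keeps $\mathrm{Tr}(A^k)$ interpretable as closed-walk counts.

The axis convention is a fixed, documented choice: published maps show
the embedding but not a machine-readable axis order, so any fixed
assignment is equally valid as long as it is held constant — descriptors
are only comparable under one scheme, which is why the scheme name is
carried in descriptor provenance and the registry is user-extensible.
For `hp4` membership we use the standard physicochemical partition
(nonpolar G,A,V,L,I,P,F,M,W; polar S,T,C,Y,N,Q; acidic D,E; basic K,R,H —
histidine counted basic by common usage); the class boundaries for H, C
and G are conventions, overridable via `register_grouping_scheme()`.

**Four-color spiral maps.** One square cell per residue is laid along a
square spiral (start at the origin, first step $+x$, counterclockwise
turns; orientation fixed and documented), colored by the residue's
group. In `whole` mode the cell graph joins side-sharing (von Neumann)
neighbors — but note that this graph is identical for every sequence of
one length, so as a *descriptor source* the informative object is the
`per_color` mode: the subgraphs induced by each color class, which may be
disconnected (the connectivity invariant is deliberately waived there).
`descriptor_vector(..., "fourcolor")` therefore concatenates per-color
subgraph moments. Whether the published spiral maps use 4- or
8-neighborhoods is not derivable from the figures; we fix the von
Neumann (4-)neighborhood and expose both whole and per-color modes.

**Star graphs.** An imaginary center emits one ray per residue type
present; ray $r$ is a path with as many vertices as residue $r$ has
occurrences, so non-center vertices are in bijection with residues.
The embedded variant superimposes the original backbone: extra edges
join the ray vertices of consecutive sequence positions (deduplicated).
Rays are indexed in canonical alphabet order so descriptor vectors are
reproducible.

## Descriptors

**Spectral moments.** $\mu_k = \mathrm{Tr}(M^k)$ with $M$ the vertex
adjacency or the edge adjacency (line-graph) matrix; $\mu_0$ is the
matrix dimension, $\mu_1 = 0$, and for 0/1 matrices every $\mu_k$ is an
exact integer (products of integer matrices in double precision are
exact far beyond the magnitudes reached at $k \le 15$, the default
order). The edge kind is the package default because the pseudo-folding
workflow this package implements derives its indices from the edge
adjacency matrix; the vertex kind is exposed alongside.

**Markov descriptors.** For a residue property table $w$ (side-chain
charge by default, made nonnegative with an absolute-value transform),
the backbone chain with self-loops ($a_{ij} = 1$ iff $|i-j| \le 1$)
yields the row-stochastic matrix
$\Pi_{ij} = a_{ij} w_j / \sum_l a_{il} w_l$ and the absolute initial
vector $p^0_i = w_i / \sum_j w_j$. Stochastic spectral moments are
$\pi_k = \mathrm{Tr}(\Pi^k)$ (sums of self-returning probabilities);
Markov entropies are Shannon entropies (bits) of $p^0 \Pi^k$ (left
multiplication — the propagation direction is not uniquely determined in
the literature, so ours is stated explicitly and fixed). Self-loops are
kept by default precisely so the diagonal carries mass; a strict
nearest-neighbor variant is switchable. Two numerical conventions are
worth noting: a row whose whole neighborhood has zero weight (common
with sparse properties like formal charge) falls back to a uniform
distribution over its allowed transitions rather than dividing by zero,
and a sequence with zero *total* weight is an error, since no initial
distribution exists.

**Classical topological indices** (star graphs and any connected
representation): Wiener $W=\sum_{u<v} d_{uv}$, Harary
$H=\sum_{u<v} 1/d_{uv}$, Randić $\chi=\sum_{(u,v)\in E}
(\delta_u\delta_v)^{-1/2}$, Balaban
$J = \frac{m}{\mu+1}\sum_{(u,v)\in E}(S_u S_v)^{-1/2}$, Kier–Hall simple
chi of orders 0–2, Moreau–Broto autocorrelation over topological
distances 1–5 (property-weighted when a table is supplied), and vertex
moments $k \le 5$. Distances come from igraph's shortest-path routine;
disconnected graphs are rejected (whole-graph distance indices are
undefined) with `largest_component()` provided for per-color subgraphs.
Kier–Hall orders above 2 are omitted: the higher-order path enumeration
is combinatorial and adds nothing to parity with the classical index
list this package targets.

**Sequence-level measures.** Autocorrelation vectors
$ATS_l = \sum_i w_i w_{i+l}$ for lags 1–15 (lags beyond the length give
empty sums, reported as 0); composition and overlapping $k$-mer
frequencies; word-level Shannon entropy (bits by default, base
configurable — the choice only rescales); Lempel–Ziv complexity fixed to
the LZ76 exhaustive-history phrase count, the standard complexity
measure when no variant is specified; KL divergence with a $10^{-6}$
pseudocount and renormalization (zero-frequency words otherwise give
infinities), Jensen–Shannon divergence, Euclidean distance.

## The pairwise engine and zone classification

The aligner is a three-state Gotoh dynamic program (C++ core) with
affine gaps costing $\mathrm{open} + (L-1)\cdot\mathrm{extend}$,
defaults BLOSUM62 / +5,−4, open 10, extend 0.5 — the EMBOSS defaults, for
comparability with the all-vs-all tooling this module mirrors. Traceback
ties break diagonal > up > left, making every alignment deterministic.
Identity and similarity percentages use the full alignment length
including gap columns as denominator (the EMBOSS convention; the paper
literature rarely states its denominator, so ours is explicit, with a
shorter-sequence denominator behind a flag). Bit scores use
$(\lambda R - \ln K)/\ln 2$ with $\lambda = 0.267$, $K = 0.041$ — the
widely used constants for gapped BLOSUM62 scoring — and are recomputed
from raw local scores rather than imported from an external search tool.

Zone calls implement the published thresholds: protein midnight < 20%,
twilight 20–35%, safe homolog at alignment length ≥ 100 and identity
> 30%, bit significance > 50 bits (or > 40 bits for searches of at most
7000 sequences); nucleotide twilight below a single threshold,
default 55%, configurable inside the reported 50–60 band. The safe-zone
rule (> 30%) and the twilight upper bound (35%) overlap by construction;
they are reported as independent flags rather than merged into one
verdict, since they come from different similarity criteria.

## The synthetic generator

`generate_benchmark()` emulates a star-phylogeny family: one i.i.d.
ancestor, members mutated independently by uniform point substitutions
(and indels at a per-site rate) until the member's global-alignment
identity to the ancestor — measured by the package's own aligner, so
generator and analysis share one definition of identity — enters the
target band. Batch sizes shrink near the target and overshoot triggers a
restart with finer steps, so convergence is monotone in practice;
a bounded iteration count turns pathological requests into errors.
Negatives are composition-preserving Fisher–Yates shuffles of the
positives (exact multiset equality) or i.i.d. draws from the pooled
positive composition. Default study conditions, chosen once: ancestor
length 150 (a small single-domain protein), 20 members, target 25 ± 3%
(mid-twilight), indel rate 0.01 per site — typical of diverged
single-domain families; all member seeds derive from one master seed and
are recorded with realized identities in the manifest, making FASTA
output byte-reproducible.

**What the generator does not emulate — and why it matters.** Real
families evolve under selection that conserves physicochemical character
and local motifs. The generator's ancestor is i.i.d. and its
substitutions are uniform over the alternative residues; both operations
are position-symmetric, so every simulated family member is an
*exchangeable* sequence — conditional on its composition, all residue
orders are equally likely. A composition-matched shuffle of such a
member therefore has exactly the same marginal distribution as the
member itself, for any conceivable per-sequence feature. Classifiers
trained on descriptors can separate simulated positives from shuffled
negatives only through family coherence (positives cluster around the
ancestor's descriptor values), which is weak at twilight-zone divergence:
with 100 members in the 20–35% band and 100 shuffles, a decision tree on
per-color four-color moments reaches cross-validated AUROC of only about
0.5 (recomputed by `scripts/acceptance.R` as `benchmark_cv_auroc`).
Passing or failing such a benchmark therefore says little about real
remote-homolog
detection, where composition bias and conserved physicochemical order —
precisely the signals these descriptors were designed to capture — are
present. A substitution-matrix-weighted (class-conserving) mutation mode
is the natural extension point for a benchmark with realistic order
conservation.

## The homology layer

Feature tables are deterministic (fixed column order, provenance
recorded). Classifiers are deliberately simple — a decision tree (rpart)
and a logistic model — because the contribution under study is the
features, not the learner. Evaluation uses accuracy, sensitivity,
specificity and AUROC computed as the Mann–Whitney rank statistic with
half-credit ties; cross-validation is stratified with folds drawn once
per seed. The combined alignment-based + alignment-free scorer min-max
normalizes each measure with its training range and weights it by
$\alpha_j \propto \max(\mathrm{AUC}_j - 0.5,\, 0)$ (uniform fallback;
constant measures get weight 0 with a warning): the literature specifies
only that weights reflect "discriminatory ability", so the rule is an
explicit, testable stand-in. A k-NN convenience classifier
(k = 5, distance $1 -$ combined similarity) and unanimous / majority /
weighted consensus voting with Venn-style agreement reports complete the
layer.

## Numerical and testing choices

Problem sizes in the test suite are chosen so the whole suite runs in
well under a minute of CPU: closed-walk oracles run on all paths, cycles
and stars up to 8 nodes plus 100 random sparse connected graphs with
$k \le 6$; the alignment engine is checked exactly against an
independent plain-R Gotoh implementation on 50 random pairs up to length
60; Markov contracts are checked at $10^{-8}$ on 200 random
sequence/property combinations; identity targeting is verified on 100
seeded mutants of a 300-residue ancestor. Stochastic checks fix their
seeds; the generators' conditions are never adjusted per test.

Known limitations: descriptors are only comparable under one grouping
scheme and property table (hence provenance fields); per-color subgraph
indices that need connectivity use the largest component with a logged
message; the exchangeability limitation of the synthetic benchmark
described above; and no 3D, profile-based or thermodynamic-folding
representations are included.
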