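---
title: "Sequence-structure alignment of RNA by Lagrangian relaxation"
author: "knotAlign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-structure alignment of RNA by Lagrangian relaxation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knotAlign)
```

## The problem

Non-coding RNAs conserve their secondary structure more strongly than their
primary sequence, so alignments of homologous ncRNAs should reward conserved
base pairing as well as conserved nucleotides. Exact simultaneous folding
and alignment is prohibitively expensive (O(n^6) in the classic
formulation), and the widely used dynamic-programming restrictions cannot
represent *pseudoknots* - base pairs that cross each other in sequence
order, present in an appreciable fraction of known structures.

knotAlign poses one pairwise alignment as an integer linear program over an
*alignment graph* and solves it by Lagrangian relaxation. Because structure
enters only as a weighted set of candidate interactions, crossing pairs are
handled natively, with no nestedness assumption anywhere in the model.

## The model

For sequences of lengths $n_1, n_2$ the graph contains:

* **Lines** $l = (i, j)$, one per position pair, with weight $w_l$ equal to
  the substitution score of the two nucleotides. A line is *active*
  ($x_l = 1$) when $i$ and $j$ are aligned.
* **Interaction edges**: for every pair of interactions
  $(i, i', p_1) \in \mathcal{S}_1$ and $(j, j', p_2) \in \mathcal{S}_2$, two
  directed edges between line $l = (i, j)$ (the left partners) and line
  $m = (i', j')$ (the right partners), each of weight
  $\vec w_{lm} = \vec w_{ml} = (p_1 + p_2)/2$. The crossing combination
  $(i, j')/(i', j)$ is never built.

The objective maximises
$\sum_l w_l x_l + \sum_{(l,m)} \vec w_{lm}\, \vec y_{(l,m)}$ subject to:

1. active lines are mutually conflict-free (non-crossing, node-disjoint);
2. each line touches at most one active interaction edge;
3. an active edge's origin line is active;
4. edges are mutual: $\vec y_{(l,m)} = \vec y_{(m,l)}$.

Note that the structural sum runs over *directed* edges, so a conserved
interaction contributes $\vec w_{lm} + \vec w_{ml} = p_1 + p_2$. All scores
in this package (including the reported `structureScore`) follow that
convention; without it the relaxation bound and the valid score would not be
comparable.

## The solver

Constraint 4 is dualised with one multiplier per directed edge. In the
relaxed problem each line may independently claim its best outgoing edge,
so the profit of line $l$ is
$S(i,j) = w_l + \max(0, \max_m [\vec w_{lm} + \lambda_{(l,m)} -
\lambda_{(m,l)}])$, and the relaxed optimum is found by ordinary global
alignment (Needleman-Wunsch/Gotoh) under the position-specific matrix $S$.
Its score $z_U$ upper-bounds the valid optimum for *any* $\lambda$, because
the dualised terms cancel on every feasible solution. The $\max(0,\cdot)$
reflects that a line may always decline structure; whether the original
method clips here is not documented, but without the clip the relaxation
would not dominate alignments that leave an interaction unused.

A *valid* solution is then extracted from the relaxed one: over the active
lines, every graph edge whose two endpoint lines are both active becomes a
candidate, and a maximum weighted matching selects a conflict-free subset.
Its score $z_L$ (sequence part plus twice the matched undirected weight)
lower-bounds the optimum; the best $z_L$ over all iterations, with its
alignment, is what the solver reports. When $z_U - z_L \le \varepsilon$ the
result is certified (near-)optimal; when the relaxed solution is itself
mutual, it is optimal outright.

Multipliers move by a classic Held-Karp subgradient step
$\lambda \leftarrow \lambda - \gamma_t g$ with
$g_{(l,m)} = y_{(l,m)} - y_{(m,l)} \in \{-1, 0, 1\}$ and
$\gamma_t = \mu\,(z_U^{(t)} - z_L^{best})/\lVert g \rVert^2$. The update
formula is not fixed by the method's published description (which defers to
earlier work), so this standard schedule is adopted: $\mu_0 = 1$, halved
after 50 consecutive iterations without improvement of $z_L$. The iteration
budget (default 500) and $\varepsilon$ (default $10^{-4}$) bound the work
per pair; a pair with no interaction edges at all has no dualised
constraints and is solved by a single DP call.

### Matching

The matching uses the greedy look-ahead heuristic: sort all positive
candidate edges by weight, exhaustively optimise the heaviest $k$ (default
$k = 5$), commit the best compatible subset, discard incident edges,
repeat. With $k \ge$ the edge count, one window is an exhaustive search, so
the exact brute-force matcher (`exactMatching`, guarded to 20 edges) is
both the test oracle and the limiting case. Ties are broken by weight,
then endpoint keys, making results platform-independent. The heuristic can
under-match (it is not exact on dense graphs), which only weakens $z_L$
temporarily - later iterations compensate, and the bound property is
unaffected.

### Determinism

Every tie in the system is broken by a fixed rule: DP traceback prefers
diagonal over vertical over horizontal; the relaxed edge choice prefers the
lowest edge index, forward direction first; matching sorts are total
orders. Consequently `allPairs` is bitwise reproducible for any worker
count - parallelism only schedules independent, deterministic pair states.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| substitution matrix | RIBOSUM85-60 | line weights; `"simple"` (+4/-2) available |
| gap open / extend | -6 / -2 | affine; a run of d gaps costs open + (d-1)*extend |
| `pmin` | 1e-3 | probability cutoff when thresholding a BPPM |
| `k` | 5 | matching look-ahead window |
| `maxIter` / `epsilon` | 500 / 1e-4 | Lagrange loop budget and gap tolerance |
| `mu0` / `stallLimit` | 1 / 50 | subgradient step scale and halving schedule |

Gap penalties and the substitution scheme are not prescribed by the
method's description; the defaults are the field's customary choices
(RIBOSUM log-odds, affine gaps in the same score units) and are exposed for
calibration. `pmin` trades graph size against recall of low-probability
pairs; the published method does not print its cutoff, and `1e-3` keeps
even marginal but plausible pairs. The minimum-hairpin filter (no pair with
fewer than 3 enclosed bases) applies only to dot-bracket input, where the
annotation is nominally sterically valid; probability matrices are trusted
as given.

## The synthetic-data generator

`generateFamily()` emulates a curated family: a template structure
(defaults to an 89-nt three-helix fold), an ancestor drawn to satisfy the
template's complementarity, and independent descendants with

* per-unit mutation by uniform *resampling* (a loop site from the 4 bases,
  a pair - with probability `compensatoryRate`, default 0.9 - jointly from
  the 6 valid pair types), with the per-descendant rate solved numerically
  so that the expected pairwise identity matches `targetIdentity`;
* the number of mutated units fixed at rate x units (stochastic rounding),
  which removes most between-seed variance;
* indels confined to unpaired template sites at rate
  `(1 - targetIdentity)/4` (deletions, plus single-base insertions), so
  every descendant carries the complete planted structure and recovery
  tests are well-posed;
* probability matrices with values near 1 at planted pairs and sparse small
  spurious entries restricted to unpaired positions, keeping every row sum
  at most 1.

What a green test on this generator establishes: the solver recovers
planted, fully supported structure under substitution/indel noise, and the
bound machinery is correct. What it does not establish: behaviour on real
folding ensembles (competing structures, correlated probabilities),
alignment quality against curated databases, or performance at scale -
those require external data and tools that are deliberately out of scope.

## Numerical and design notes

* Coordinates are 0-based internally; every emitted format (T-Coffee
  library, 3-column probability files) is 1-based, as those formats
  require.
* `T` in input FASTA is transliterated to `U` (DNA-style files are
  common); any other unexpected letter is an error rather than silently
  mapped to `N`.
* The T-Coffee library weight is not fixed by the downstream format's
  users; this package scales each line's profit (substitution score plus
  its matched edge weight) by the alignment's maximum profit into
  [1, 100].
* The ViennaRNA dot-plot reader consumes only `ubox` records and squares
  the stored value (dot plots store sqrt(p)); `lbox` (MFE) records are
  ignored.
* Degenerate inputs: empty sequences are rejected; empty interaction sets
  collapse to pure sequence alignment; an all-gap alignment (empty line
  set) is representable and scored as pure gap cost.
* Bounds bookkeeping uses the running minimum of relaxed scores and the
  running maximum of valid scores; per-iteration relaxed scores may
  oscillate, the tracked bounds are monotone by construction.

## Limitations

The duality gap need not close: subgradient iteration carries no
branch-and-bound fallback, so a stubborn pair ends at `maxIter` with an
honest gap (reported per pair). The greedy matching is a heuristic; its
occasional sub-optimality is visible only as a slightly looser lower
bound. Folding is external by design - the package reads probability
matrices or dot-bracket strings but never computes a partition function
itself.
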