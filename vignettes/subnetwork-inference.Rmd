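---
title: "Methods: literature-augmented subnetwork inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: literature-augmented subnetwork inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subnetip)
```

## The inference problem

Genome-scale perturbation experiments produce lists of implicated genes but
not the pathways that organize them. `subnetip` addresses this by selecting,
from a typed background network of known molecular interactions, a
subnetwork of source-to-target paths that explains the experimental lists
under explicit constraints and objectives. Two concrete tasks are modeled:

- **Host–virus**: sources are screen hits, targets are interface genes whose
  products bind a viral component. The inference both organizes the hits
  into paths and nominates *unconfirmed* genes (neither hit nor interface)
  likely to be involved, under a budget.
- **Regulatory**: a single transcription-factor source is connected to the
  genes differentially expressed under its perturbation; every path must end
  in a direct protein–DNA (or text-mined regulatory) interaction.

Two modeling assumptions are worth making explicit. First, explanations are
*path-shaped*: a linear chain of at most `max_edges` interactions (default
3, so at most four nodes). Biology that needs longer or branched routes is
represented only as unions of such chains. Second, the background network is
trusted but incomplete — which is exactly why the package supports
literature-based augmentation of both the source set and the edge set.

## Path semantics

Paths are simple (no repeated node), traverse directed edges only forward,
and may orient an undirected edge either way (fixed per path). A path ends
at the first target it touches; intermediate occurrences of target nodes are
disallowed. This prevents counting a path and its prefix as two
explanations. The choice is genuinely open — one could let paths run through
one interface to another — so `allow_through_targets = TRUE` reverses it.
Nodes that are both source and target (hit ∩ interface overlap is legal and
common) enumerate as sources; zero-edge paths are never emitted, because an
explanation with no interaction explains nothing.

When roles are hidden by the ensemble protocol the reachable path set
changes (a hidden interface is no longer a terminal, and becomes passable);
ensembles therefore re-enumerate paths per run rather than filtering a
master enumeration.

## The integer programs

Relevance indicators σ_p (paths), x_e (edges), y_n (nodes) are linked so
that an edge is relevant iff it lies on a relevant path and a node iff it
touches a relevant edge. The published table-form of these linkage rows
quantifies over all edges ("∀p ∀e: σ_p ≤ x_e"), which would make every
instance infeasible; they are implemented quantified over each path's own
edges E(p) and each edge's own endpoints N(e), the only reading under which
the programs are solvable.

**Host–virus objectives** (in order): maximize Σ_{n∈N_U} score(n)·y_n, then
maximize Σ σ_p. Constraints: Σ_{n∈N_U} y_n ≤ δ; hit and interface coverage
Σ y_n ≥ (1−ε)·|set|; a complex is relevant only if a fraction β of its
subunits is; a reaction only if all its reaction-I/O partners are. The
unconfirmed budget counts gene-kind nodes only — complexes and reactions are
containers, not discoveries. The β formula is typeset ambiguously in the
literature this design follows; it is implemented as
β = 2(|N_H ∪ N_I| + δ)/20000 clamped to (0, 1], the only grouping that
yields a usable fraction at genome scale, and `beta_override` bypasses it
entirely.

δ and ε have no published values. Defaults are ε = 0.1 ("nearly all" hits
and interfaces must be covered, with a 10% miss allowance) and
δ = ⌈0.1·|N_H ∪ N_I|⌉, scaling the budget with the evidence. Both are
routine tuning knobs, not constants.

**Regulatory objectives** (in order): maximize DE genes reached; minimize
intermediates; maximize Σ y_n·r_n over intermediates; maximize included
edges. A DE gene counts as reached only with a supporting path and a
relevant *directed* edge into it, and intermediates may have **no** relevant
incoming directed edge — regulation is only ever inferred *into* the
targets. A consequence verified in the tests: a DE gene whose only route
enters an intermediate through a directed edge is unreachable.

## Solving: sequential objectives, exact search

Objectives are optimized in sequence; after stage i achieves v_i, the
constraint (expression ≥ v_i − slack) is added (≤ for minimization). The
slack is 0 for integral-coefficient objectives (path/edge/target counts) and
`tolerance`·|v_i| (default 1e−6) for fractional score objectives, avoiding
spurious infeasibility from floating-point bounds.

Each stage is solved exactly by depth-first implicit enumeration with
constraint propagation. The formulations have a special structure: once the
σ variables are fixed, the linkage constraints *force* every x and y, so the
search effectively explores path subsets with an optimistic bound
(fixed objective value plus every favorable free coefficient). Branching
prefers path variables ordered by objective weight, trying inclusion first;
ties between optima are therefore resolved deterministically by this fixed
order, and reproducibility does not depend on a solver seed. A `node_limit`
(default 5·10⁵ per stage) turns pathological search into an error that names
the stage rather than an open-ended run. `check_solution()` re-evaluates
every constraint by direct arithmetic, sharing no code with the solver, and
the test suite requires its agreement with an exhaustive-enumeration oracle
on hundreds of randomized instances of both formulations.

This in-package solver replaces the branch-and-cut MILP backends commonly
used for such programs; at the package's target scale (hundreds of binary
variables, path counts in the tens) exact search with propagation solves
instances in milliseconds, and the ensemble protocol — not solver
heuristics — handles optimum multiplicity.

## Scores

*Diffusion scores.* The kernel is K = expm(−bandwidth·L) with L the
symmetric normalized Laplacian of the undirected unit-weight skeleton
(complexes and reactions included — diffusion runs over the whole network).
Each hit contributes its kernel column; score(n) = Σ_h K(n, h). The exact
parameterization behind the published analyses is unstated, so the standard
diffusion kernel with bandwidth 0.5 is the default and both are
configuration. Only relative scores matter to the IP. The kernel is
evaluated by exact eigendecomposition (cubic cost), deliberately favoring
transparency over scalability; the tests pin it against an independent
matrix-exponential route.

*Expression weights.* CPM values are consumed as given (no normalization is
performed here). Genes below `min_cpm` (default 1 CPM) are treated as not
expressed and excluded from candidacy; eligible genes weight objective 3 by
r_n = log2(CPM + 1). Whether the original analyses used raw or transformed
CPM is unstated; the log damping is this package's choice so that a few
very highly expressed genes cannot dominate the objective, and `min_cpm`
plus the transform are both exposed.

## Ensembles, confidence, precision–recall

`subsample_roles()` hides the hit/interface roles of a uniform 25% of the
role-confirmed genes (round(hold_fraction·n), clamped to keep at least one
gene on each side). For the regulatory task the subsampled role is
`de_target` — the analogous "known relevant" set; the original description
does not name the role set it resampled there, so this is the package's
reading. Runs that come back infeasible are excluded from frequency
denominators and logged with their seed.

Hold-aside confidence of a gene is its inclusion frequency over the runs in
which it was hidden. Negatives (never role-labeled genes) carry no such
quantity, so the PR sweep scores them by overall inclusion frequency — the
natural analogue the original evaluation leaves implicit. Precision and
recall are computed at every distinct confidence value; at the lowest
threshold precision equals prevalence by construction. `pr_auc()` is the
step-wise average precision.

Defaults: `n_runs = 100`, `hold_fraction = 0.25`, `freq_threshold = 0.5`
for the consensus. The consensus threshold behind the published consensus
networks is unstated; 0.5 ("majority of the ensemble") is the default here.

## Literature modules

The corpus is an offline abstraction — per-gene and per-query abstract-id
sets — because live literature services are out of scope and the statistic
is what matters: adjusted precision |A_g^q| / (|A_g| + pseudocount) with
pseudocount 10, recall |A_g^q| / |A^q|, ranked by their harmonic mean (F1),
ties broken by support then gene id. Augmentation promotes genes with
support ≥ 2 that are in the network and not already hits or interfaces;
an optional `top_k` cap serves view-style workflows. Text-mined
regulator→target pairs import as directed `literature_regulatory` edges,
deduplicated against existing directed protein–DNA pairs so the two
evidence types behave identically downstream.

*Views.* s(n, N^Q) is the Jaccard overlap between the consensus paths
containing n and those containing any query gene; 0/0 is defined as 0 (a
node with no consensus paths is unrelated to any concept). The top k
(default 10) non-query, non-target nodes become predicted additions — ties
broken by similarity, then path support, then id — and the view keeps
exactly the consensus paths inside query ∪ additions ∪ targets.

## The synthetic benchmark

`make_network()` generates the study conditions for the recovery tests: 40
genes, 6 hits, 5 interfaces, 6 planted unconfirmed genes, planted paths of
2 interactions, decoy edge probability 0.02, a quarter of decoys directed,
plus 2 complexes and 2 reactions (wired into paths when the planted length
is ≥ 3, exercising the complex/reaction constraints). Each hit gets a
planted path through an unconfirmed gene, a direct interface contact, and a
bridge to the next hit; interfaces form a ring. The redundancy is the point:
real interactomes offer multiple routes, and it is what makes a hidden hit
or interface *recoverable* — a path from a remaining source can run through
it. The planted truth is defined as everything enumerable on the decoy-free
network, and decoys that would create additional source–target paths within
the planted depth are pruned post-generation (so planted structure remains
the unique parsimonious explanation; `allow_shortcuts` disables the
pruning).

For hold-aside benchmarks the budget is set to
δ = n_planted + round(hold_fraction · n_confirmed): capacity for every
planted gene plus the hidden ones. This is part of the benchmark protocol,
chosen with the generator design, not a quantity fitted to results.

What the generator does *not* emulate: scale-free degree structure, hub
promiscuity, correlated false negatives in screens, weighted or
context-dependent interactions, and genome-scale size. Passing recovery
tests on this family shows the machinery is correct and well-calibrated at
desk scale; it does not certify accuracy on real interactomes. Matched
corpora (`make_corpus()`: enriched genes co-occur with query abstracts at an
enrichment multiple of a base rate) and log-normal expression tables
(`make_expression()`) make the literature and regulatory modules testable
under the same seeds; all generators are pure functions of (spec, seed).

## Numerical conventions and degenerate inputs

- Constraint feasibility uses an absolute slack of 1e−7 in the solver and
  1e−6 in `check_solution()`; objective comparisons use 1e−9.
- Identifiers are upper-cased and trimmed on entry; undirected edges are
  stored once with endpoints in lexicographic order; duplicate edges
  collapse per (pair, class); self-loops are dropped with a warning (simple
  paths can never use them).
- Empty path sets build empty-but-valid instances; an all-zero assignment is
  feasible for the regulatory program (reaching nothing is always allowed),
  while host-virus coverage can be genuinely infeasible (e.g. a hit with no
  candidate path at ε = 0) — reported as status `infeasible`, not an error.
- Degenerate similarity (both path sets empty) is 0; genes never held aside
  are excluded from PR curves with a warning rather than silently scored.

## Problem sizes used in the checks

The randomized verification suites use networks of ≤ 12 nodes with ≤ 8
candidate paths (where exhaustive enumeration over all 2^|P| path subsets is
the oracle), 200+ instances per formulation; path enumeration is checked
against brute-force scanning on mixed graphs of ≤ 10 nodes; recovery uses
the default 40-gene family with 20-run ensembles over 20 generator seeds.
These sizes are chosen so the oracles are airtight and the full suite runs
in minutes on a laptop; the package code itself has no hard-coded size
assumptions beyond the cubic diffusion kernel and the exponential oracle
used only in tests.

## Known limitations

- The solver is exact but enumerative; genome-scale instances (tens of
  thousands of paths) are outside its envelope and would need a commercial
  MILP backend behind the same `subnetip_ip` interface.
- The diffusion kernel is dense; networks beyond a few thousand nodes need a
  sparse/Krylov evaluation.
- Ensembles re-enumerate and re-solve per run; runtime scales linearly in
  `n_runs`.
- Literature inputs are consumed as precomputed id sets; no text mining, no
  identifier mapping across nomenclatures.
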