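---
title: "Hennigian argumentation on polarity-coded morphological matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hennigian argumentation on polarity-coded morphological matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hennig)
```

## The analytical setting

Classical morphological systematics often works from a small, carefully
argued character matrix rather than from thousands of molecular sites. Each
character is *binary with argued polarity*: the investigator decides, by
outgroup comparison, which state is ancestral (plesiomorphic, coded `0`) and
which derived (apomorphic, coded `1`) before any tree is considered. Taxa
sharing a derived state are candidates for a clade (the derived state is a
putative synapomorphy); characters whose derived sets overlap without
nesting are in conflict, and the conflict is arbitrated by minimizing the
number of characters that must be explained as convergences. This is
Hennigian argumentation, and the cladogram it produces is exactly the tree
a parsimony analysis of the polarity-coded matrix supports.

`hennig` mechanizes the workflow end to end: matrix input with the
uncertainty codes such tables carry, synapomorphy grouping and conflict
arbitration, parsimony reconstruction on the resulting cladogram, an exact
branch-and-bound check of tree length, and a dichotomous-key engine. The
genus-level analysis of the benthic harpacticoid copepod *Laophontodes*
(12 scorable species, 39 characters) ships as a worked fixture; all worked
examples below use it.

## The data model

A `character_matrix` holds taxa, character definitions (the derived
condition plus the bracketed ancestral one), and a grid of six cell codes:

* `0`, `1` — the plain polarity codes;
* `?` — no information (e.g. males of *L. sarsi* are unknown, so its male
  antennule state cannot be scored);
* `1?`, `0?` — the observation argues for 1 (or 0) but the source
  description is contradictory or doubtful;
* `0*` — the species is scored plesiomorphic, but the derived condition
  also occurs *within* the species (intraspecific variability: some female
  *L. whitsoni* lack the seta whose loss defines the derived state).

Cells printed in bold in the source table — derived states the authors
themselves flag as convergent — are carried as annotations, not as a
different state.

```{r}
m <- laophontodes_matrix()
m
```

Downstream analyses work on a `resolved_matrix` over {0, 1, missing}.
`apply_polarity_policy()` offers two reductions. The default, `as-argued`,
follows the argued polarity (`1?` is derived, `0?` and `0*` ancestral):
`0*` in particular is read as a deviation *inside* the species, not as
membership in the derived group, because re-deriving a lost structure is
considered possible but improbable. The `conservative` policy sends all
four non-plain codes to missing and is intended for sensitivity analysis:
if a grouping survives `conservative`, it does not depend on any doubtful
cell.

## Grouping, conflict, and arbitration

`group_by_synapomorphy()` founds one clade hypothesis per distinct derived
taxon set of size ≥ 2. Two rules deserve note:

* **Missing cells.** A character scored `?` for some taxa supports an
  existing hypothesis whose taxon set lies between its observed derived
  set and that set plus the unknowns. This is how the nine-species group
  stands on two characters even though one of them cannot be scored in
  *L. sarsi*. A `strict` mode that demotes such characters to unplaced is
  available via `missing_support`.
* **Level routing.** Characters derived in a single taxon are
  autapomorphies; characters derived in *every* taxon diagnose the whole
  group against its outgroups and are reported at that level rather than
  as an ingroup synapomorphy.

`arbitrate()` then selects a maximum-weight pairwise-compatible subset of
hypotheses, the weight being the number of supporting characters; the
characters of rejected hypotheses become convergences. We solve this
exactly (by search over the connected components of the conflict graph)
rather than greedily: on the packaged matrix the two readings of the
central conflict — nine species sharing the chirocer male antennule versus
nine species sharing two setal losses — tie at twelve supported characters
each, and a greedy accumulation of nesting weights can tip the wrong way.
Ties are broken in favour of the subset containing the lowest character
ids. This encodes, as a deterministic rule, the source argument that the
antennule transformation is the weightier evidence (a program cannot weigh
biological plausibility); users who order their characters differently
should be aware that the tie-break follows the ids.

```{r}
ana <- hennigian_analysis(m)
ana$report
```

`build_cladogram()` turns the accepted clades into the unique minimal
rooted tree displaying them; unplaced taxa attach at the root polytomy.

## Parsimony with a stem edge

Tree length and ancestral reconstruction use an exact two-state dynamic
programme, valid for arbitrary node arity (hard polytomies, i.e. Hartigan
semantics). The root is not itself forced to state 0; instead an implicit
all-plesiomorphic ancestor sits *above* it, joined by a stem edge on which
a single 0→1 change may occur:

$$\mathrm{len}(c) \;=\; \min\bigl(\mathrm{cost}(\rho = 0),\;
\mathrm{cost}(\rho = 1) + 1\bigr)$$

This matters for characters derived in every terminal: they cost one
origin (on the stem) and are reported as the group's own autapomorphy,
instead of one origin per root child as a hard root constraint would
charge. On the packaged matrix this is exactly the reading of character 1
(loss of the antennal exopod), and with it the reference cladogram costs
43 steps: 35 characters with a single origin and 4 (ids 4, 5, 17, 30)
with two.

Missing leaves are unconstrained. Ties among most-parsimonious assignments
are broken by the placement policy: `delay-changes` (default) keeps the
parental state, pushing changes tipward and explaining homoplasy as
independent convergent origins; `accelerate-changes` prefers the earliest
origin and accepts reversals below it. The default matches the source's
stance that secondary re-development of a lost element is improbable.

Because the polytomies of such cladograms are soft (statements of
ignorance, not of simultaneous cladogenesis), hard-polytomy lengths are
conservative: refining a polytomy can only keep or lower the step count,
a property the test suite exercises directly.

## The exact search

`branch_and_bound()` verifies that the argued cladogram actually attains
the minimum length over all rooted binary topologies. Taxa are added in
decreasing order of derived-cell count; the partial-tree length plus the
number of characters whose derived taxa are all still unplaced is the
lower bound; the upper bound is initialized from the argumentation
cladogram. The search is exact whenever it reports `exhausted = TRUE`, and
collects all co-optimal trees up to a cap of 10,000 (beyond which only the
tie count grows). On the packaged 12-taxon matrix it completes in about a
second on one CPU, finding 90 co-optimal binary trees of length 43 — the
strict consensus of which retains, among others, the *L. sarsi* +
*L. scottorum* pair. Unconstrained exact searches are refused above 15
taxa; a backbone constraint tree restricts the space and re-enables them.

The source analysis never claims a total tree length or global optimality
— it is an argumentation, not an optimization. The package therefore
phrases the search result as *consistent with minimum steps* rather than
as a claim of the original study.

Homoplasy is summarised by the consistency index CI = m/s (minimum
conceivable steps over observed steps) and the retention index
RI = (g − s)/(g − m), with g the star-tree step count; both are `NA` with
an `undefined` attribute when their denominator vanishes (e.g. a matrix
with no derived cells).

## The dichotomous key

The key engine stores numbered couplets of two leads, each lead free text
plus a target (couplet or taxon). The packaged key keeps the printed lead
order and wording — including couplet characters that are not in the
character matrix (spinule shapes, body proportions), which is why leads
carry free text rather than matrix predicates; one printed couplet even
overlaps logically with its successor ("chirocer or subchirocer"), and the
transcription deliberately preserves that rather than repairing it.
`validate_key()` checks the structural invariants (two leads, resolvable
targets, reachability, acyclicity, unique entry, one terminal lead per
taxon); for a valid key the couplet count is necessarily one less than the
taxon count. `generate_key()` builds a fresh key from a resolved matrix by
greedy most-even splits (ties to the lowest character id), skipping
characters with missing cells among the remaining taxa; it fails, naming
the pair, if two taxa are indistinguishable.

## The simulator

`simulation_config()` + `simulate_dataset()` generate test data whose
structure mirrors a small morphological matrix. A rooted binary tree is
drawn by sequential uniform leaf addition; each character picks one edge
as the origin of its derived state; with probability `homoplasy_fraction`
a second origin is added on an edge neither ancestral, descendant, nor
sibling to the first, so the two derived patches are disjoint and the
planted convergence is recoverable by reconstruction on the true tree.
Convergence is simulated only as a second origin, never as a reversal,
matching the convergence-only reading of homoplasy in the argumentation
workflow. The stem is excluded from origin draws by default, so all-derived
characters arise only on request (`include_stem`).

Defaults mirror the packaged study's shape: 12 taxa, 39 characters, a
homoplasy fraction of 4/39, and 0.5% missing and uncertain cells each
(the packaged table has 2 missing and 3 uncertain cells of 468). The
`coverage = "clades"` mode plants one clean synapomorphy on every internal
non-root edge first; with no homoplasy and no missing data this guarantees
— and the tests verify — that the argumentation pipeline returns the true
tree exactly, and that the unique most-parsimonious tree is the true one.

What the simulator does *not* emulate: correlated characters, asymmetric
gain/loss rates, reversals, polymorphism (`0*` cells), or the
taxon-specific patterning of missing data in real descriptions (missing
cells cluster in poorly described species, not uniformly). Passing
recovery tests on simulated data therefore show the machinery is correct,
not that real matrices of this size determine their tree.

## Numerical and scale choices

Everything is deterministic: iteration follows the matrix taxon order, all
randomness flows through per-call seeds, and identical configurations give
byte-identical outputs. Test problem sizes were chosen so the whole suite
runs in well under a minute: exhaustive-enumeration oracles use 5–7 taxa
(10,395 rooted binary trees at 7), brute-force assignment enumeration runs
on trees with at most 8 internal nodes, and recovery experiments use 20
replicates of 7–8 taxa. The packaged 12-taxon search itself is exact and
takes about a second.

## Known limitations

* Binary characters only: no multistate, ordered, or continuous
  characters, and no Sankoff cost matrices.
* No model-based inference (Mk likelihood, Bayesian), no resampling
  supports, no implied weighting.
* The arbitration tie-break is lexicographic in character ids; it encodes
  one published analysis's preference and is not a biological argument.
* Exact search is limited to 15 taxa unless a backbone is supplied.
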