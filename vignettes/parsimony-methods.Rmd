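---
title: "Maximum parsimony for morphological matrices: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum parsimony for morphological matrices: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpmorph)
```

## The estimation problem

`mpmorph` implements the classic cladistic workflow for small
morphological matrices: a taxa-by-characters grid of unordered discrete
states is scored on candidate trees by minimum change, the set of
shortest trees is sought over all topologies, and the result is
summarised by a strict consensus, homoplasy indices, and branch-wise
character support. The reference data set is the packaged 20-taxon,
38-character matrix for the tortoise-beetle genus *Stoiba* and its
outgroups, but every step works on any `char_matrix`.

The model is deliberately minimal, matching how such matrices are built
and analysed in practice:

* characters are **unordered** (any state may change to any other in
  one step) and **equally weighted**;
* a **polymorphic** cell contributes its state *set* — the terminal is
  allowed any of its observed states, chosen to minimise changes;
* **missing** (`?`) and **inapplicable** (`N`) cells are wildcards:
  they take whatever state minimises changes, i.e. the character's
  full observed-state set. The two kinds are distinguished in the data
  structure and reports but not in optimization — no inapplicable-aware
  scoring algorithm is attempted, which matches the behaviour of the
  program family these matrices are built for. The cost is well known:
  a wildcard can be assigned a state that is biologically meaningless
  for that taxon (e.g. a wing character in a wingless group).

A character's observed-state set is defined from the matrix cells, not
from the prose state list that may accompany a published table: if a
state is described but never scored, it does not exist for
optimization.

## Scoring

Fully resolved trees are scored with the Fitch state-set recursion
(bitmask sets, one word per character per node, so up to 32 states are
supported although morphological data rarely use more than 3). The pass
is rooted at an arbitrary terminal; a final fold of the root terminal's
own state set against its neighbour accounts for the root edge, and
length is invariant to the choice (a property the test suite checks by
rerooting). Multifurcating trees — consensus trees in particular — are
scored with the equivalent explicit-state dynamic program (unit change
costs), which is exact on any topology; on binary trees the two
programs agree exactly, and both are checked against a brute-force
enumeration of internal labelings on small instances.

Per-character bounds are computed exactly over the observed-state set:
the minimum conceivable steps `m` is one less than the smallest state
subset intersecting every cell (set cover, exhaustive over at most
2^k subsets), and the maximum `g` is the length on the star tree,
where each cell contributes a change exactly when the centre state
lies outside its set. Note that a polymorphic cell can therefore
contribute to `g` — the "assign each ambiguous cell its best covering
state" shortcut is not equivalent and underestimates the star-tree
length whenever the best centre lies outside a polymorphic cell's set;
the star-tree definition is the one the retention index expects, and it
is the one implemented (and tested against the dynamic program on an
actual star topology). A `polymorphism = "fixed"` variant treats a
polymorphic cell as truly carrying all its states (all of them must be
covered for `m`; each uncovered one costs a step in `g`), since the
display convention of legacy programs is not documented; the default is
`"free"`.

## Search

`parsimony_search()` is the fitting function; it returns a classed
object with `print`/`summary`/`plot` methods.

**Exact search.** Branch-and-bound adds taxa in input order, pruning a
partial tree when its length plus a lower bound on the cost of the
remaining taxa exceeds the incumbent. The bound counts, per character,
the states required by not-yet-added taxa (as single-state cells) that
no tip already in the tree could supply — each such state forces at
least one additional change. The incumbent starts at the greedy
stepwise-addition length, and all trees attaining the final incumbent
are returned, so the MPT set is provably complete. The guard refuses
matrices above 14 taxa by default (the enumeration is
super-exponential); the reference matrix at 20 taxa is within reach of
the implementation but takes hours rather than seconds, which is why
the packaged reproduction uses the heuristic (whose result the exact
oracles corroborate on every matrix small enough to check).

**Heuristic search.** Each replicate builds a tree by random-order
stepwise addition (greedy minimal-length insertion, first-found ties in
a deterministic edge order, randomised only by the replicate's taxon
order) and then branch-swaps to a local optimum. The neighbourhoods are
the standard ones — NNI, SPR, TBR (all bisections × all reconnection
pairs) — enumerated in a deterministic order, with an early-exit bound
in the scorer. Equal-best trees are collected and themselves swapped
through ("swap on all"), so the island of optimal topologies is
exhausted up to `max_trees`.

One design choice deserves emphasis, because the usual description of
random-addition searches leaves it open: all replicates share a single
island store. A replicate
that ties the current global best joins the plateau walk (skipping
topologies already seen); a replicate whose local optimum is *worse*
than the global best stops there rather than exhausting its own,
useless plateau. This changes nothing about which trees are reported —
the plateau at the global best level is walked exhaustively either
way — but removes the dominant cost on matrices whose optimum is a
large plateau of zero-length-branch resolutions, which is the normal
situation for simulated morphological data. With the defaults
(100 replicates, TBR, seed 42, `max_trees` 10000) the packaged matrix
completes in a few seconds on one CPU.

**Collapsing and counting.** A reported "number of MPTs" is meaningful
only under a stated collapsing rule. The rule here is *minimum length
zero*: an internal branch is contracted when no character is forced to
change on it in every optimal reconstruction. Forced changes are
detected exactly by an inside-outside dynamic program per character
(tested against brute-force enumeration). Both counts — binary trees
and collapsed/deduplicated topologies — are reported, since the rule's
effect is drastic when taxa have identical rows (three *Elytrogona*
species share one row in the reference matrix). Deduplication and all
topology identity tests use bipartition sets. Collapsing each branch
is licensed by *some* optimal reconstruction, but different branches
may need different reconstructions, so a fully collapsed tree can be
longer than the binary tree it came from; the operation is a support
statement, not a length-preserving transform.

## Consensus, indices, synapomorphies

The strict consensus keeps exactly the bipartitions present in every
input tree (verified against brute-force split intersection and against
an independent implementation). Ensemble CI and RI are computed on one
most-parsimonious tree — all MPTs share the same length — because Fitch
length on a polytomous consensus is a different (and larger) quantity;
both the all-characters and the informative-only display conventions
are always computed and reported side by side, with two-decimal
comparisons done by half-up rounding. Uninformative characters satisfy
s = m = g, so RI is identical under both conventions and only CI moves.

Character changes are mapped on a rooted tree (the reference reports
root on *Spaethiella* sp., the most distant sampled outgroup) by
ACCTRAN and DELTRAN tie-breaking of the exact dynamic program: child
states are chosen preorder from the optimal-completion set, preferring
a change (ACCTRAN) or the parent's state (DELTRAN); both reconstructions
place exactly s changes per character, and a change is *unambiguous*
when both agree on branch and transition. Rooting affects polarity
only; ingroup changes away from the root are rooting-invariant (tested).

## The synthetic-data generator

`simulate_matrix()` emulates the statistical shape of the reference
matrix: 20 taxa, 38 characters, a binary/3-state mixture
(11/38 three-state, the reference proportion), and about one ambiguous
cell in a hundred (4 missing, 4 inapplicable, 1 polymorphic per
760 cells), injected after evolution. The default change model places
an explicit number of state origins per character on distinct branches
of a uniformly sampled topology (probabilities 0.05/0.55/0.25/0.15 for
0-3 origins — mostly clean synapomorphies with occasional homoplasy,
a level chosen once to resemble the reference matrix's CI). Origins
take derived states in round-robin order, so while origins are fewer
than states the realized length on the true tree provably equals the
origin count — the generator's ground truth is exact, which is what the
engine tests need. A per-branch Markov jump model is also provided for
rate-style realism.

What the generator does *not* emulate: correlated characters,
hierarchical character dependencies (the real reason inapplicable cells
exist), rate variation across lineages, and coding practices like
composite characters. Passing recovery tests therefore demonstrate the
correctness of the machinery, not the adequacy of parsimony for any
particular real matrix. At this data scale the distinction bites: with
38 characters over 20 taxa and non-trivial homoplasy, the generating
tree is frequently *not* among the most-parsimonious trees (in our
trials with the default mixture, it was one only about a third of the
time — in the failures the optimum is strictly shorter than the truth).
Homoplasy-free matrices with branch coverage are recovered exactly, and
that is the property the acceptance suite asserts.

## What the reference analysis does and does not reproduce

Running `reproduce_analysis()` on the packaged matrix gives, at every
seed tried: best length **83** steps and ensemble **CI 0.59**
(all-characters convention) — both matching the published values
exactly, which also confirms the transcription. The remaining published
claims do not follow from the printed matrix:

* **RI** computes to 0.7901 → **0.79** (published 0.78). Σm = 49 and
  Σg = 211 are confirmed by two independent routes, RI is insensitive
  to the informative-only convention, and the fixed-polymorphism
  variant moves it up, not down.
* The search finds **2** collapsed MPTs (6 binary), not 4.
* The strict consensus does **not** contain a monophyletic *Stoiba*:
  the globally optimal trees attach the *Spaethiella* +
  *Asteriza*/*Physonota* outgroup trio inside, next to the
  rough-sculptured brachypterous species. The shortest trees with the
  nine *Stoiba* monophyletic are 84 steps — one step worse — and that
  84-step island (8 collapsed MPTs) is where the published consensus
  topology, with its *Stoiba* and brachypterous clades, lives. The
  published tree set is therefore best explained as a search that
  stopped on that island, or as a working matrix that differed slightly
  from the printed table.
* Of the published clade supports, the **brachypterous clade** (five
  species, hind-wing character 29 on its stem) *is* recovered in the
  optimal consensus; the Cuban and Jamaican subclades are not clades
  there.

The package reports all of this as computed — the reproduction report
carries both MPT counts, both index conventions with the matching one
flagged, and a presence/support entry per published clade.

## Numerical and engineering choices

* State sets are 32-bit masks; taxa counts up to 64 are supported by
  the 64-bit bipartition signatures used for topology identity.
* All randomness flows through R's RNG (`set.seed`-driven addition
  orders passed into the C++ engine), so a seed reproduces a search
  byte-for-byte; the RNG state of the caller is restored afterwards.
* Ties everywhere (stepwise insertion, ACCTRAN/DELTRAN state choice,
  consensus construction) are broken by fixed deterministic orders,
  never by additional randomness.
* Degenerate inputs: empty matrices and ragged rows are rejected with
  the offending taxon named; all-wildcard characters score zero
  everywhere; three-taxon matrices are handled by the exact search
  only (there is a single topology).
* Problem sizes in the test suite were chosen to keep the full run at
  desk scale: brute-force oracles at ≤ 7 taxa, exact-vs-heuristic
  comparisons at ≤ 10, reference-matrix searches at 10-100 replicates.

## Limitations

Ordered/additive characters, differential weights, step matrices,
implied weighting, and resampling supports (bootstrap, jackknife,
Bremer) are out of scope, as are likelihood and Bayesian scoring. The
heuristic search has the usual caveat of all branch swappers: it is
exhaustive only over the islands it reaches, which is why every claim
small enough to verify exactly is also checked against the
branch-and-bound engine in the tests.
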