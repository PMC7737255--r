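---
title: "Fire ladder detection: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fire ladder detection: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fireladder)
```

## The problem and the model

Terminologies integrated in a UMLS-style metathesaurus share concepts —
decided by a common concept identifier (CUI) — but disagree on how densely
their IS-A hierarchies populate the space between a parent and a
descendant. `fireladder` mines a three-terminology configuration in which
two *source* terminologies, chained in tandem, bridge a gap in a *target*
terminology: target A and upper source B share concept A1; B refines A1
with a child B2 that A lacks; B2 also lives in lower source C, which
refines it with a child C3; and C3 is exactly A's own child A3 of A1. The
chain A1 → B2 → C3 then overlays A's single edge A1 → A3, and B2 becomes a
candidate for import into A constrained from above (A1) *and* below (A3).
The same configuration suggests a second, weaker candidate: importing C3
into B as a child of B2, constrained from above only.

Two readings of "exists in terminology T" are possible, and they matter
at the margins:

* *presence*: T has at least one retained atom (name row) for the CUI;
* *node membership*: the CUI participates in at least one IS-A edge of T.

The nine defining constraints use **presence** for the three existence
tests and the three non-existence tests, and edges for the three
child-of tests. Under the node-membership reading the existence tests
would be logically implied by the child-of tests (any CUI with a child
edge is a node), collapsing nine constraints to six; the presence reading
keeps the nine independent — which also lets the fixture generator plant
decoys that each violate exactly one constraint, so a failing predicate
is localized by a failing decoy. On a real release the readings coincide
for all practical purposes, because every hierarchy node carries an atom
in its source.

## Input model and edge semantics

Atoms come from MRCONSO, relationships from MRREL, both in the 2018AB
pipe-delimited column layout, addressed positionally (RRF has no
headers). Only `REL = PAR` rows that also carry `RELA = inverse_isa` are
IS-A edges: `PAR` alone mixes in other hierarchical notions
(broader-than, part-of contexts), and the attribute pins the source's own
subsumption. A row `(CUI1, PAR, CUI2)` is read as *CUI2 is a parent of
CUI1*, consistent with the release documentation's convention that REL
describes the second concept's relationship to the first and with
`inverse_isa` read as CUI1 IS-A CUI2.

Suppressed rows (`SUPPRESS` ≠ `"N"`) are dropped by default. The method's
description is silent on suppression; dropping is common release practice
and is exposed as `drop_suppressed` in `source_config()` rather than
hard-coded. Language defaults to `"ENG"`. Edges whose endpoints lack an
atom in their SAB are *kept* (nodes are defined by edge participation)
but counted and reported with a warning: silently deleting them would
hide source inconsistencies, while presence-based constraints already
keep them from fabricating patterns.

## Cycle removal

IS-A cycles and self-loops occur in real releases and would break any
descent-based reasoning. `remove_cycles()` runs a depth-first sweep from
every node in ascending CUI order, following child edges at most
`max_cycle_depth` levels below each root (default 5 — the ladder itself
never descends more than a couple of levels, so deeper sweeps buy nothing
for this purpose). An edge that closes a path back to a node on the
current DFS stack is deleted at the moment of detection and recorded
(`removed_edges.tsv`), with the `self_loop` / `cycle_back_edge` reason.

Numerical/algorithmic choices worth stating:

* **Which edge goes.** The description of the original sweep does not say
  which edge of a detected cycle was removed or in what order nodes were
  visited. Here roots and neighbors iterate in ascending CUI order and
  the *back edge* (the one discovered closing the cycle) is deleted, so
  the removed set is a pure function of the input — required for
  byte-reproducible outputs and for idempotence testing. This is a
  package choice, not a reconstruction.
* **Depth-memoized re-expansion.** A node first reached at depth *d* is
  re-expanded if reached again at a smaller depth; without this, a short
  cycle hiding behind a longer first visit could slip past the depth
  bound.
* **Bound semantics.** Cycles of length ≤ `max_cycle_depth` are
  guaranteed broken after one pass; longer cycles may survive, mirroring
  the bounded sweep's stated limitation. The test suite checks the
  resulting graphs against an independent topological-sort oracle
  (igraph) and checks idempotence (a second sweep removes nothing).

## Detection and its oracle

`detect_fire_ladders()` iterates anchors a1 over the intersection of the
target's and upper source's parent maps, then one child level in B and
one in C — the cheap join order — but the contract is purely
set-defined, and every emitted pattern satisfies all nine constraints.
`brute_force_ladders()` is the independent oracle: it enumerates every
CUI combination over the union of the three terminologies' atoms and
nodes and checks the constraints directly, at cubic cost. The two are
compared on randomized fixtures over 100 seeds in the acceptance suite;
`check_ladder_constraints()` exposes the per-constraint re-check used for
soundness audits.

A pattern set is *ordered-triple scoped*: the same (target, A1, B2, C3)
may appear under several (upper, lower) permutations. Merging is the job
of `build_dataset1()`, whose key (target, A1, B2, C3) pools source
permutations into one candidate — the published example merges two
permutations with the same target into one rhabdomyoma candidate, which
fixes this key.

`build_dataset2()` keeps two modes because the generative rule for the
published pair counts is not stated and cannot be pure projection: the
reported pair count exceeds the pattern count, so sibling C3s must have
been admitted. *Strict* mode is the (B, C, B2, C3) projection of the
patterns; *anchored* mode (default) emits, for every pattern stem
(A1, B2, B, C), **all** children of B2 in C absent from B. Strict output
is provably a subset of anchored output, and the suite tests both the
projection identity and the subset property.

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| `included_sabs` | `source_config` | 10 release SABs | the English IS-A-bearing vocabularies of the reference configuration |
| `excluded_sabs` | `source_config` | `SNOMEDCT_VET`, `UWDA` | subsets of two included vocabularies; importing from a subset is vacuous |
| `language` | `source_config` | `ENG` | cross-source name comparison is out of scope; one language keeps presence well-defined |
| `drop_suppressed` | `source_config` | `TRUE` | suppressed atoms are not part of a source's working content |
| `max_cycle_depth` | `source_config` | 5 levels | ladder legs are single edges; cycles relevant to detection are short |
| `dataset2_mode` | `source_config` | `anchored` | the only rule consistent with pair counts exceeding pattern counts |

## The synthetic world

`generate_fixture(fixture_spec(...))` emits MRCONSO/MRREL files plus
ground truth. It emulates exactly the structural features the method
touches: multiple SABs sharing CUIs (a background CUI is shared into a
second SAB as an atom without edges), PAR/`inverse_isa` rows, a
non-English atom, suppressed atom and relationship rows, planted ladders,
nine kinds of near-miss decoys (decoy *i* violates constraint
((*i*−1) mod 9)+1 and nothing else), and planted 3-cycles confined to one
SAB each. Background hierarchies are random forests whose edges always
point from later to earlier concepts, so they are acyclic by construction
and every cycle in a fixture is a planted one; structure CUIs come from
reserved ranges and are never reused, which (by a short role-forcing
argument: an anchor needs child edges in two terminologies, and only
planted/decoy anchors have them) guarantees the detectable pattern set
equals the planted set.

What the generator does **not** emulate: realistic degree and depth
distributions, polysemy of strings across CUIs, multi-hop density
differences, or release-scale volume. A green property suite therefore
establishes correctness of the predicate logic, the cycle sweep, and the
derivations — not the published release-scale counts (pattern totals,
pattern-bearing triples, pair counts), which require the licensed 2018AB
release and are documented as non-desk benchmarks.

Generation is deterministic per spec (local RNG state, fixed sequencing,
post-sort identifier assignment): identical specs give byte-identical
files, and all pipeline artifacts are byte-stable because every output is
canonically sorted in the C locale and timings are kept out of
`report.json`.

## Agreement statistics

Expert review of candidates is summarized as a 2×2 contingency
(a = both import, b/c = single-rater import, d = both non-import), either
given directly, tabulated from unit-level decisions, or solved uniquely
from marginal counts (`contingency_from_marginals()`). Cohen's
κ = (p₀ − pₑ)/(1 − pₑ) with p₀ = (a+d)/n and
pₑ = ((a+b)(a+c) + (c+d)(b+d))/n². Krippendorff's α uses the two-rater,
binary, complete-data nominal special case: D₀ = (b+c)/n,
Dₑ = 2·n_imp·n_non/(N(N−1)) with N = 2n ratings, α = 1 − D₀/Dₑ — the
closed form equals the general coincidence-matrix computation for this
design, and the test suite verifies that equality against an independent
coincidence-matrix implementation. Printed values are rounded half away
from zero at the reporting precision (three decimals for κ, two for α);
internal computation is full precision. Degenerate inputs (pₑ = 1,
Dₑ = 0) raise explicit undefined-statistic errors rather than returning
NaN.

One derived published rate (42/55 as 76.3%) is a one-decimal *truncation*
of 76.36…%; the acceptance test reproduces it by truncation and asserts
the exact fraction, rather than silently matching a rounded 76.4.

## Known limitations

* Ladder legs are single IS-A edges; multi-hop legs (intermediate
  concepts) and four-terminology chains are out of scope.
* Cycles longer than `max_cycle_depth` survive the sweep.
* "Exists in T" ignores lexical synonymy across CUIs: two CUIs with
  near-identical strings are distinct concepts, which is faithful to the
  identifier model but occasionally proposes near-synonyms for import —
  a decision left to human reviewers.
* Presence is computed from the configured language only; a concept whose
  only atom in T is non-English counts as absent from T.
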