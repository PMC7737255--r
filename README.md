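# fireladder

Cross-terminology IS-A pattern mining for biomedical terminology
enrichment.

Large biomedical terminologies (SNOMED CT, NCIt, MEDCIN, HPO, ...) overlap
heavily in conceptual content but differ in *density*: one vocabulary may
place a concept between a parent and child where another jumps straight
from the parent to the child. `fireladder` detects a three-terminology
topological configuration — the **fire ladder pattern** — that exploits
this: when a target terminology A and an upper source B share a concept A1
(= B1), B's child B2 also lives in a lower source C (= C2), and C's child
C3 is exactly A's child A3 of A1, then B2 is a strong candidate for import
into A as a child of A1 and parent of A3. It is "strong" because it is
constrained from above *and* below by two independent source
terminologies chained in tandem. The audience is terminology curators and
ontology quality-assurance researchers working with UMLS-style releases.

## The pattern

Over an ordered triple (A = target, B = upper source, C = lower source)
of terminologies, a fire ladder is a concept triple (A1, B2, C3) — concept
identity across terminologies decided by shared UMLS CUIs — such that:

1. A1 exists in A, 2. A1 exists in B, 3. A1 exists nowhere in C;
4. B2 is-a-child-of A1 in B, 5. B2 exists nowhere in A, 6. B2 exists in C;
7. C3 is-a-child-of B2 in C, 8. C3 exists nowhere in B,
9. C3 is-a-child-of A1 in A.

IS-A edges are the UMLS `PAR` relationships carrying the `inverse_isa`
attribute. Per-terminology hierarchies are built as DAGs after removing
self-loops and (via a depth-bounded DFS sweep, default five levels)
cycles. With *n* terminologies there are *n*!/(*n*−3)! ordered triples to
scan — 720 for the ten vocabularies of the reference configuration
(`umls_default_config()`).

From detected patterns the package derives:

* **Data Set 1** — import B2 into A; patterns sharing
  (target, A1, B2, C3) across source permutations merge into one
  candidate.
* **Data Set 2** — import C3 into B as a child of B2 (constrained from
  above only); in the default *anchored* mode, all qualifying siblings of
  C3 under an anchored stem are admitted.
* Per-triple pattern counts, and two-rater agreement statistics for
  expert review of the candidates: Cohen's κ = (p₀ − pₑ)/(1 − pₑ) and the
  two-rater nominal Krippendorff's α = 1 − D₀/Dₑ.

## Worked example

The bundled `fig3_fixture()` transcribes the intestinal-atresia example
into RRF form: HPO (target) and NCIt share *Intestinal atresia*, NCIt's
child *Large Intestine Atresia* is SNOMED CT's *Atresia of large
intestine*, and SNOMED CT's child *Congenital atresia of rectum* is HPO's
*Rectal atresia*.

```r
library(fireladder)
fx    <- fig3_fixture()
atoms <- read_mrconso(fx$mrconso, fx$config)
rels  <- read_mrrel(fx$mrrel, fx$config)
dags  <- build_ontdag(atoms, rels, fx$config)
patterns <- annotate_patterns(detect_fire_ladders(dags), atoms)
patterns[, c("target_sab", "upper_sab", "lower_sab",
             "a1_name", "b2_name", "c3_name")]
#>   target_sab upper_sab   lower_sab            a1_name                 b2_name
#> 1        HPO       NCI SNOMEDCT_US Intestinal atresia Large Intestine Atresia
#>                        c3_name
#> 1 Congenital atresia of rectum
```

Exactly one pattern: *Large Intestine Atresia* is proposed for import
into HPO as a child of *Intestinal atresia* and parent of *Rectal
atresia*. HPO's *Colonic atresia* — whose synonym string "Large
intestinal atresia" names a *different* UMLS concept — is present in the
fixture and correctly does not match. `brute_force_ladders(dags)`, the
independent cubic-cost oracle, returns the same set.

Agreement statistics from the published expert review of 55 candidates
(rater import counts 42 and 45, both-import 39):

```r
run_agreement(marginals = c(55, 42, 45, 39))
#> n = 55  (a=39, b=3, c=6, d=7)
#> Cohen's kappa:        0.507  (full precision 0.5074626866)
#> Krippendorff's alpha: 0.51   (full precision 0.5097451274)
```

A full pipeline run (`run_detect(mrconso, mrrel, out_dir, config)`)
writes `patterns.tsv/json`, `dataset1.tsv`, `dataset2.tsv`,
`summary.tsv`, `removed_edges.tsv`, and a `report.json` of counts;
`inst/cli/fireladder.R` exposes the same operations as subcommands
(`detect`, `dataset1`, `dataset2`, `summarize`, `agreement`, `fixture`).
Synthetic fixtures with planted ladders, single-constraint decoys, and
planted cycles come from `generate_fixture(fixture_spec(...))`.

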