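---
title: "Conditional knowledge graphs for precision medicine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional knowledge graphs for precision medicine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condkg)
library(tibble)
```

## The problem

Most pharmacogenomic knowledge is not a plain triple. "Docetaxel treats
breast cancer" is; "docetaxel may be ineffective in breast-cancer patients
carrying the GG genotype at NC_000002.12:g.38071060G>A,C" is not — the
assertion only holds *under a condition*, and the condition attaches to the
treatment relationship itself, not to either endpoint. Conventional
knowledge graphs, restricted to node–node edges, flatten such statements
into "drug–associate–disease" pairs and lose exactly the genetic context
precision medicine needs.

`condkg` represents this knowledge as **hyper-triples**: statements
`(subject, predicate, object)` whose subject or object may itself be another
statement. Formally the graph is `G = <V, E>` with vertices `V` (entities
and gates) and statements `E` partitioned into three edge classes:

* `vv` — vertex to vertex (an ordinary relationship),
* `ev` — vertex to statement, the usual encoding of a *condition*
  (`kg_edge_class()` reports the class of any statement),
* `ee` — statement to statement, the encoding of *causation* between
  events (`leads_to`).

Two further devices complete the model. **Gate nodes** (`kg_make_gate()`)
compose several entities or statements into one addressable concept — an
AND gate is the "all of these together" union used for combination therapy,
an OR gate an alternative set. **Modifiers** express negation and a
three-level qualitative likelihood (`certain`, `probable`, `possible`) on
every relation; likelihood is deliberately not a probability, because the
sources record hedged language, not frequencies.

## Knowledge patterns

Assertions are organised into four declared, machine-checkable patterns
(`builtin_patterns()`), each a template over a small statement cluster:

| pattern | core shape | qualifiers |
|---|---|---|
| `side_effects` | (therapy statement, risk predicate, phenotype) | optional variant/disease condition |
| `drug_sensitivity` | (variant, `affects_response_to`, therapy statement or drug) | aspect + direction required |
| `drug_mechanisms` | (drug, expression/activity predicate, gene) | optional variant condition |
| `drug_indications` | (drug or gate, `treats`, disease) | conditions optional |

A design choice worth spelling out: the therapy context is *reified* as its
own `(drug, treats, disease)` statement, and risk or sensitivity statements
attach to that treatment event rather than to the drug. That is what makes
the knowledge conditional instead of pairwise — "bleeding risk" belongs to
*warfarin-used-for-venous-thromboembolism*, not to warfarin in the
abstract.

`instantiate_pattern()` builds conformant clusters from role bindings;
`validate_cluster()` checks an arbitrary cluster against a template and
reports every violation. The two are deliberately closed: everything the
builder emits validates, and the test suite additionally checks that
flipping any single required element (a category, the predicate, a
qualifier) of a conformant cluster is detected.

The predicate vocabulary is not fixed by the source material, which names
relations only in figures; the default set (`kg_predicates()`) reconstructs
them — `treats`, three risk predicates, `condition_of`, `leads_to`,
`affects_response_to`, `no_effect_on`, and four directional
expression/activity predicates — and is extensible through a plain
`key = value` config file, so users can add relations without code changes.
Pattern templates serialize to the same dialect
(`write_pattern_config()` / `read_pattern_config()`).

## Storage: reification into a property graph

Graph databases store node–node edges, so the hypergraph is reified
(`reify()`): every statement becomes a **relation node** carrying its
predicate and modifiers as properties, with a `from` edge (subject →
relation node) and a `to` edge (relation node → object). A statement about
a statement simply points at the target's relation node. Gates become gate
nodes with ordered `member` edges. Evidence items become **auxiliary
nodes** linked to the relation node, so stores without rich edge properties
can still hold provenance.

The mapping is exactly invertible — `unreify(reify(g))` is structurally
identical to `g` — and obeys simple count laws used as self-checks: the
non-auxiliary nodes number `|entities| + |gates| + |statements|`, and
`from`/`to` edges number `2 × |statements|`. Statement and gate identifiers
are content hashes of `(subject, predicate, object, modifiers, qualifiers)`
— evidence is excluded — so deduplication and evidence-union fall out of
identity, insertion order never matters, and `unreify` can verify stored
ids against recomputed ones.

Two serializations are provided: canonical JSON Lines
(`export_canonical()`; one record per element, keys and records sorted, so
equal graphs give byte-identical files and merges are diffable) and
node/edge CSV tables (`export_bulk_csv()`) in the dialect common
graph-database bulk importers expect.

```{r storage}
g <- worked_examples()
pg <- reify(g)
pg
kg_equal(g, unreify(pg))
```

## Entity disambiguation

Mentions are standardized against per-category controlled vocabularies
(`load_vocabulary()`: id, standard name, pipe-separated synonyms). ID
cross-references are tried first (`map_by_id()`); only names without a
direct ID link go through name mapping. The similarity φ between a query
and a term is 1.0 for a case-insensitive exact match against the standard
name or any synonym, otherwise the Jaccard overlap of their lowercased
alphanumeric token sets, capped at 0.99 so that only true exact matches
reach 1. The mapped term is the argmax over the vocabulary; ties are
**never** auto-resolved — they are flagged `ambiguous` and emitted on a
review queue for manual correction, mirroring how such pipelines handle
genuine homonymy. The default acceptance threshold is 0.80; both the
measure and the threshold were chosen once for determinism and
oracle-checkability (no trained components) and are configurable. The
suite verifies `best_match()` against an exhaustive brute-force scorer over
every (name, term) pair.

## Condition-aware queries

All query verbs are deterministic, return stably ordered tibbles, and never
fabricate statements:

* `drug_centric_view()` — every cluster involving a drug (directly or
  through gate membership), bucketed by pattern.
* `neighborhood_subgraph()` — breadth-first ball around seed nodes.
  Radius is measured in statement traversals: a node is inside radius *r*
  iff its shortest path on the reified property graph is at most `2r` unit
  edges (each statement hop passes through its relation node, hence the
  halving). The result is closed under statement endpoints and gate
  members so it is self-contained.
* `conditions_for()` — the condition entities of a statement, including
  conditions inherited from its therapy sub-statement.
* `personalized_suggestions()` — genotype-filtered therapy advice.
  Condition matching is **conjunctive** (a statement with k variant
  conditions needs all k matched): the worked examples each carry a single
  condition, and conjunction is the conservative reading of a condition
  set. Genotype equality is case-folded and trimmed, with one extension: a
  single-allele condition such as "C" matches any genotype carrying that
  allele ("CC", "AC"), which is required to express allele-level
  assertions against genotype-level queries. Labels (`ineffective`,
  `increased_risk`, `reduced_risk`, `reduced_efficacy`, `no_effect`,
  `unconditional`) are a fixed, documented function of predicate, negation
  and qualifiers.
* `pharmacogenomics_profile()` — a drug's gene-level effects grouped by
  conditioning variant; contradictory effects (e.g. an increased-activity
  statement and a negated one under the same variant) are both reported
  with their evidence, unresolved, since the sources themselves disagree.
* `synergy_report()` — statements about each drug alone, about gates
  covering the query set exactly or partially, and condition-dependent
  divergences in risk.
* `shared_mechanism_candidates()` — repurposing hypotheses: a candidate
  drug B is proposed for a disease when some indicated drug A shares a
  directional gene-level mechanism `(A, p, G)` / `(B, p, G)` and B has no
  existing indication for the disease. The score is the number of distinct
  bridging genes (the sources give single-bridge examples and no scoring
  rule; a count is the least-assumptive ranking), ties broken by name.

```{r queries}
shared_mechanism_candidates(g, "malignant pleural mesothelioma")

personalized_suggestions(
  g, "breast cancer",
  tibble(variant = "NC_000002.12:g.38071060G>A,C", genotype = "CC"))
```

## Grounded text rendering

`render_subgraph()` verbalizes a subgraph deterministically: one sentence
per non-condition statement (sorted by id), negation and likelihood as
explicit wording, conditions folded into a "given …" clause.
`build_prompt()` wraps the fact list in one of four scenario templates
(knowledge unit, multi-evidence, personalized suggestion, synergy — plain
text files under `inst/templates/`, editable without code changes) plus an
explicit instruction to use only the listed facts. The grounding contract
is checkable: `grounding_check()` scans a text for every name in a
universe and verifies all found names belong to the subgraph. Calling a
language model is out of scope by design — `interpret_subgraph()` accepts
any `function(prompt) -> text` callback, so the package never needs
network access. The original prompt wordings were not available; the
templates here are re-specified from the four application scenarios and
keep only the grounding contract.

## Fixtures and the synthetic generator

`worked_examples()` encodes the case-study clusters conservatively — only
assertions literally present in the source figures and text, no inferred
dosages or effect sizes. One known gap: the ivacaftor case names only 3 of
its 11 CFTR variants, so only the 3 named ones are encoded and the count is
not reproducible. Two of those (the "alters CFTR activity" pair) are
stored as variant-level response statements rather than tagged pattern
cores, because their direction is asserted only via the drug's overall
potentiator role.

`generate_synthetic_kg()` produces seeded random graphs whose clusters are
all emitted through `instantiate_pattern()`, hence conformant by
construction. Defaults (10 drugs, 6 diseases, 8 phenotypes, 10 variants, 8
genes; 5 clusters per pattern; condition probability 0.5, gate probability
0.2, negation probability 0.1) give graphs of roughly the size and mix of a
per-drug neighborhood in a real pharmacogenomic resource — big enough to
exercise gates, conditions, and negation together, small enough that
property tests over hundreds of seeds stay fast. Entity names come from
generic pools (`DRUG_0001`, HGVS-shaped or rs-shaped variant names) so no
real pharmacology is implied. What the generator does *not* emulate: the
skewed degree distributions, synonym noise, and cross-source
inconsistencies of real aggregated databases — passing property tests here
demonstrates correctness of the machinery, not robustness to dirty source
data.

Headline corpus sizes of any real aggregated resource depend on the
versions of nine upstream databases and are out of scope; nothing in this
package claims to reproduce them.

## Numerical and degenerate-input choices

* Statement identity uses a 128-bit content hash of the canonical field
  string; hash ties are therefore content equality for practical purposes.
* Tie-breaks everywhere are lexicographic in C-locale (`method = "radix"`),
  which keeps every ordering platform-independent.
* The round-trip property tests run 200 seeds with ~30 statements each and
  the disambiguation oracle runs 50 names × 200 terms × 20 seeds; these
  sizes exercise all code paths while keeping the whole suite in a few
  minutes.
* Empty graphs export to empty files and re-import to empty graphs; empty
  subgraphs render to empty text that is trivially grounded.
* A `condition_of` statement whose subject is a non-variant entity (disease
  or phenotype context, e.g. "in liver-transplant patients") is treated as
  population context: reported with the cluster but not matched against
  genotype assignments.

## Known limitations

* Synonyms containing the `|` character cannot survive the pipe-joined
  property-graph encoding; empty-string property values are read back as
  absent from CSV.
* No ontology reasoning: subsumption and transitive closure over external
  vocabularies are out of scope, as is any probability calculus over the
  qualitative likelihood levels.
* Whether causal (`ee`) statements may themselves carry conditions is left
  open by the sources; the model permits it, but no fixture exercises it.
* Contradictory statements are reported side by side with their evidence;
  the package takes no position on resolution.
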