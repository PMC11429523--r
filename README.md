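# condkg

Condition-based precision-medicine knowledge graphs in R.

Pharmacogenomic knowledge rarely fits a plain triple: a drug's risk,
efficacy, or required dose often holds only for patients with a particular
genotype, and one event (a treatment) can cause another (a side effect).
`condkg` models such knowledge as **hyper-triples** — statements
`(S, R, O)` whose subject or object may itself be another statement — in a
graph `G = <V, E>` whose statements partition into three classes:

* `E_vv`: vertex–vertex (ordinary relationships, e.g. *enzalutamide treats
  prostate cancer*),
* `E_ev`: vertex–statement (*conditions*, e.g. a genotype at
  `NC_000010.11:g.94981296A>C` conditioning a bleeding-risk statement),
* `E_ee`: statement–statement (*causation*, `leads_to`).

AND/OR **gate nodes** compose drugs or statements into single addressable
concepts (combination therapies); every relation carries negation and a
qualitative likelihood. Knowledge is organised into four machine-checkable
patterns — drug side effects, drug sensitivity, drug mechanisms, drug
indications — with validators and a deterministic cluster builder.

For whom: anyone building, storing, or querying conditional biomedical
knowledge — curation pipelines feeding a graph database, methodologists
working on n-ary/reified knowledge representation, and applications that
need genotype-aware drug reasoning.

The package provides:

* a tidyverse-native data model (`kg_new()`, `kg_add_entity()`,
  `kg_add_statement()`, `kg_make_gate()`, `kg_validate()`) with
  content-hashed statement identity and automatic evidence union;
* lossless **reification** into a conventional property graph
  (`reify()` / `unreify()`): relation nodes with `from`/`to` edges,
  ordered gate `member` edges, auxiliary evidence nodes; canonical JSON
  Lines and bulk-import CSV serialization;
* **entity disambiguation** against controlled vocabularies: exact ID
  mapping first, then best-scoring name mapping with ties flagged for
  manual review, plus regex-rule extraction, deduplication, and
  order-insensitive graph merging;
* **condition-aware queries**: drug-centric views, neighborhood subgraphs,
  genotype-filtered personalized suggestions, pharmacogenomics profiles,
  medication-synergy reports, and shared-mechanism repurposing hypotheses;
* **grounded text rendering**: deterministic verbalization of subgraphs and
  prompt construction for four interpretation scenarios, with a token-scan
  grounding check and a pluggable text callback (no hosted model is ever
  called).

## Worked example

The packaged `worked_examples()` graph encodes the canonical case studies
(warfarin/bleeding, metformin, the breast-cancer suggestion case, ivacaftor,
interferon alfa-2b + ribavirin, pemetrexed/methotrexate):

```r
library(condkg)
g <- worked_examples()
glance(g)
#> # A tibble: 1 × 12
#>   n_entities n_drugs n_diseases n_phenotypes n_variants n_genes n_gates
#> 1         58      17          9           14         15       3       1
#> # n_statements 55, n_vv 22, n_ev 32, n_ee 0, valid TRUE
```

Genotype-conditioned drug suggestions for breast cancer at
`NC_000002.12:g.38071060G>A,C` (CC genotype):

```r
personalized_suggestions(
  g, "breast cancer",
  tibble::tibble(variant = "NC_000002.12:g.38071060G>A,C", genotype = "CC"))
#>    drug             label            about
#>  1 cyclophosphamide reduced_risk     peripheral neuropathy
#>  2 cyclophosphamide unconditional    breast cancer
#>  3 doxorubicin      increased_risk   nausea
#>  4 doxorubicin      unconditional    breast cancer
#>  5 epirubicin       reduced_efficacy breast cancer
#>  6 epirubicin       unconditional    breast cancer
#>  7 gemcitabine      no_effect        breast cancer
#>  ...
```

Under CC, doxorubicin carries increased nausea risk, epirubicin reduced
efficacy, cyclophosphamide reduced neuropathy risk, and
gemcitabine/paclitaxel are unaffected; under GG the same call labels
docetaxel `ineffective`. Rows labelled `unconditional` are the plain
indications that hold regardless of genotype.

Shared-mechanism repurposing for malignant pleural mesothelioma — pemetrexed
treats it and lowers KRAS expression; methotrexate shares that mechanism and
has no recorded indication:

```r
shared_mechanism_candidates(g, "malignant pleural mesothelioma")
#>   candidate    candidate_name disease genes     score chain
#> 1 methotrexate methotrexate   mpm     <KRAS>        1 <3 statements>
```

The score counts distinct bridging genes; the `chain` column holds the
supporting statements for re-validation.

Lossless storage round trip and grounded rendering:

```r
pg <- reify(g)           # 163 nodes (58 entity, 1 gate, 55 relation, 49 auxiliary)
kg_equal(g, unreify(pg)) #> TRUE

sub <- neighborhood_subgraph(g, "warfarin", 2)
cat(render_subgraph(sub, "knowledge_unit")$text)
#> The event that warfarin treats venous thromboembolism increases the risk
#> of bleeding, given NC_000010.11:g.94981296A>C.
#> Warfarin treats venous thromboembolism.
```

A thin command-line wrapper over these functions ships in
`inst/cli/condkg.R` (`fixtures`, `validate`, `reify`, `export`, `merge`,
`view`, `suggest`, `repurpose`, `synergy`, `describe`).

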