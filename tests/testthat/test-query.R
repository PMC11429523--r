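test_that("drug-centric views bucket cluster statements by pattern", {
  g <- worked_examples()
  v <- drug_centric_view(g, "warfarin")
  expect_named(v, c("side_effects", "drug_sensitivity", "drug_mechanisms",
                    "drug_indications"))
  se <- v$side_effects
  expect_gt(nrow(se), 0L)
  expect_true("bleeding" %in% se$object)            # the bleeding-risk cluster
  expect_true("v_warf" %in% se$subject)             # with its HGVS condition

  # a drug with no statements yields four empty lists
  g2 <- kg_add_entity(g, "inert", "inertium", "drug")
  v2 <- drug_centric_view(g2, "inertium")
  expect_true(all(vapply(v2, nrow, integer(1)) == 0L))
  expect_error(drug_centric_view(g, "not-a-drug"), "unknown entity")

  # a drug present only inside an AND gate appears in the indications list
  v3 <- drug_centric_view(g, "interferon alfa-2b")
  combo_treats <- v3$drug_indications
  expect_true(any(combo_treats$subject %in% g$gates$gate_id))
})

test_that("neighborhood subgraphs are BFS closures of the reified graph", {
  g <- worked_examples()
  # radius 0: seeds only
  sub0 <- neighborhood_subgraph(g, "metformin", 0)
  expect_equal(nrow(sub0$graph$entities), 1L)
  expect_equal(nrow(sub0$graph$statements), 0L)

  # the metformin radius-2 ball holds the variant responses and side effects
  sub2 <- neighborhood_subgraph(g, "metformin", 2)
  e <- sub2$graph$entities
  expect_true(all(c("rs784888", "rs5219") %in% e$name))
  expect_true(all(c("blurred vision", "urticaria", "pruritus", "skin rash",
                    "tremor", "lethargy", "hypertension", "syncope") %in% e$name))
  # self-contained: the induced graph validates
  expect_equal(nrow(kg_validate(sub2$graph)), 0L)

  expect_error(neighborhood_subgraph(g, "ghost", 1), "unknown entity")
})

test_that("neighborhood membership matches an independent property-graph BFS", {
  skip_if_not_installed("igraph")
  for (seed in c(3, 7)) {
    g <- generate_synthetic_kg(generator_params(seed = seed))
    pg <- reify(g)
    keep_nodes <- pg$nodes$node_id[pg$nodes$kind != "auxiliary"]
    edges <- pg$edges[pg$edges$label != "evidence", ]
    ig <- igraph::graph_from_data_frame(
      edges[, c("source", "target")], directed = FALSE,
      vertices = data.frame(name = keep_nodes))
    seed_id <- g$entities$entity_id[g$entities$category == "drug"][1]
    for (radius in 0:3) {
      d <- igraph::distances(ig, v = seed_id)[1, ]
      reached <- names(d)[d <= 2 * radius]
      # closure: endpoints of reached relation nodes, members of reached gates
      repeat {
        sids <- intersect(reached, g$statements$statement_id)
        gids <- intersect(reached, g$gates$gate_id)
        idx <- match(sids, g$statements$statement_id)
        need <- unique(c(g$statements$subject[idx], g$statements$object[idx],
                         unlist(g$gates$members[match(gids, g$gates$gate_id)])))
        new <- setdiff(need, reached)
        if (!length(new)) break
        reached <- c(reached, new)
      }
      sub <- neighborhood_subgraph(g, seed_id, radius)
      got <- c(sub$graph$entities$entity_id, sub$graph$gates$gate_id,
               sub$graph$statements$statement_id)
      expect_setequal(got, reached)
    }
  }
})

test_that("conditions_for collects direct and inherited conditions", {
  g <- worked_examples()
  # warfarin bleeding-risk statement: exactly the HGVS condition
  core <- g$statements$statement_id[g$statements$pattern %in% "side_effects" &
                                    g$statements$object == "bleeding"]
  conds <- conditions_for(g, core)
  expect_identical(conds$name, "NC_000010.11:g.94981296A>C")

  # an unconditional indication has no conditions
  core2 <- g$statements$statement_id[g$statements$pattern %in% "drug_indications" &
                                     g$statements$subject == "enzalutamide"]
  expect_equal(nrow(conditions_for(g, core2)), 0L)

  # a condition on the therapy sub-statement is inherited by the risk statement
  h <- tiny_graph()
  t1 <- h$statements$statement_id[1]
  s1 <- h$statements$statement_id[2]
  h <- kg_add_entity(h, "v2", "rs000002", "variant", genotype = "GG")
  h <- kg_add_statement(h, "v2", "condition_of", t1)
  conds2 <- conditions_for(h, s1)
  expect_setequal(conds2$entity_id, c("v1", "v2"))
  expect_error(conditions_for(h, "S:missing"), "unresolved")
})

test_that("shared-mechanism inference finds the methotrexate hypothesis", {
  g <- worked_examples()
  h <- shared_mechanism_candidates(g, "malignant pleural mesothelioma")
  expect_equal(nrow(h), 1L)
  expect_identical(h$candidate_name, "methotrexate")
  expect_identical(h$genes[[1]], "KRAS")
  expect_equal(h$score, 1L)
  # the supporting chain re-validates against the graph
  expect_true(all(h$chain[[1]] %in% g$statements$statement_id))

  # no mechanism overlap -> empty result
  h2 <- shared_mechanism_candidates(g, "schizophrenia")
  expect_equal(nrow(h2), 0L)
  expect_error(shared_mechanism_candidates(g, "no such disease"), "unknown")
})

test_that("shared-mechanism inference equals the brute-force join on synthetic graphs", {
  for (seed in 1:6) {
    g <- generate_synthetic_kg(generator_params(seed = seed, p_gate = 0.3))
    for (disease_id in g$entities$entity_id[g$entities$category == "disease"]) {
      got <- shared_mechanism_candidates(g, disease_id)
      want <- oracle_shared_mechanism(g, disease_id)
      expect_identical(got$candidate, want$candidate,
                       info = paste("seed", seed, disease_id))
      expect_identical(as.integer(got$score), want$score)
      # never hypothesize a drug already linked to the disease
      linked <- g$statements$subject[g$statements$predicate == "treats" &
                                     g$statements$object == disease_id]
      expect_false(any(got$candidate %in% linked))
    }
  }
})

test_that("personalized suggestions respect conjunctive genotype conditions", {
  g <- worked_examples()
  gt <- function(geno) tibble::tibble(
    variant = "NC_000002.12:g.38071060G>A,C", genotype = geno)

  gg <- personalized_suggestions(g, "breast cancer", gt("GG"))
  expect_identical(gg$label[gg$drug == "docetaxel"], "ineffective")
  expect_false("increased_risk" %in% gg$label)

  cc <- personalized_suggestions(g, "breast cancer", gt("CC"))
  lab <- function(d) cc$label[cc$drug == d & cc$label != "unconditional"]
  expect_identical(lab("doxorubicin"), "increased_risk")
  expect_identical(lab("epirubicin"), "reduced_efficacy")
  expect_identical(lab("cyclophosphamide"), "reduced_risk")  # C allele in CC
  expect_identical(lab("gemcitabine"), "no_effect")
  expect_identical(lab("paclitaxel"), "no_effect")
  expect_false("docetaxel" %in% cc$drug)                     # GG condition unmet

  # empty genotype list: only unconditional rows
  none <- personalized_suggestions(g, "breast cancer")
  expect_true(all(none$label == "unconditional"))

  # monotonicity: adding assignments never removes an unconditional row
  expect_true(all(none$statement_id %in% cc$statement_id))
  expect_true(all(none$statement_id %in% gg$statement_id))
  expect_error(personalized_suggestions(g, "atlantis fever"), "unknown")
})

test_that("pharmacogenomics profiles group effects by condition variant", {
  g <- worked_examples()
  prof <- pharmacogenomics_profile(g, "ivacaftor")
  expect_equal(nrow(prof), 3L)  # one row per distinct condition variant
  del <- prof$effects[[which(prof$variant == "NC_000007.14:g.117559592_117559594del")]]
  expect_equal(nrow(del), 2L)
  expect_true(any(!del$negated))   # increased transport
  expect_true(any(del$negated))    # thermal stability unaffected

  # drug with no mechanism statements -> empty profile
  expect_equal(nrow(pharmacogenomics_profile(g, "olanzapine")), 0L)

  # row count equals distinct condition variants on a constructed fixture
  h <- kg_new()
  h <- kg_add_entity(h, "d", "drugx", "drug")
  h <- kg_add_entity(h, "gene1", "GENE1", "gene")
  for (i in 1:3)
    h <- kg_add_entity(h, paste0("v", i), paste0("rs", i), "variant",
                       genotype = "AA")
  h <- kg_add_statement(h, "d", "increases_expression_of", "gene1")
  s <- kg_last_ref(h)
  for (i in 1:3) h <- kg_add_statement(h, paste0("v", i), "condition_of", s)
  expect_equal(nrow(pharmacogenomics_profile(h, "drugx")), 3L)
})

test_that("synergy reports compare individual, combination, and divergent knowledge", {
  g <- worked_examples()
  sr <- synergy_report(g, c("interferon alfa-2b", "ribavirin"))

  # anemia risk for each drug alone and for the combination
  ind <- sr$individual
  for (d in c("interferon alfa-2b", "ribavirin"))
    expect_true(any(ind$drug == d & ind$object == "anemia" & !ind$negated))
  com <- sr$combinations
  expect_true(any(com$overlap == "exact" & com$object == "anemia"))

  # ribavirin's reduced anemia severity under the two named variants
  div <- sr$divergences
  rib <- div[div$drug == "ribavirin" & div$phenotype == "anemia", ]
  expect_gt(nrow(rib), 0L)
  expect_true(any(grepl("NC_000020.11:g.3271278A>C", rib$conditions) &
                  grepl("NC_000020.11:g.3213247A>C", rib$conditions)))
  expect_true(all(rib$negated))

  # single drug, no gates: combination section empty
  sr2 <- synergy_report(g, "enzalutamide")
  expect_equal(nrow(sr2$combinations), 0L)

  # a gate holding a superset of the query drugs lands in the partial section
  h <- worked_examples()
  h <- kg_add_entity(h, "boceprevir", "boceprevir", "drug")
  h <- kg_make_gate(h, "AND", c("ifn_a2b", "ribavirin", "boceprevir"))
  h <- kg_add_statement(h, kg_last_ref(h), "treats", "hepatitis_c")
  sr3 <- synergy_report(h, c("interferon alfa-2b", "ribavirin"))
  expect_true("partial" %in% sr3$combinations$overlap)
  expect_true("exact" %in% sr3$combinations$overlap)
})

test_that("query results never fabricate statements and are deterministic", {
  g <- worked_examples()
  v1 <- drug_centric_view(g, "warfarin")
  v2 <- drug_centric_view(g, "warfarin")
  expect_identical(v1, v2)
  all_ids <- g$statements$statement_id
  for (tab in v1) expect_true(all(tab$statement_id %in% all_ids))
  s1 <- personalized_suggestions(g, "breast cancer",
          tibble::tibble(variant = "NC_000002.12:g.38071060G>A,C", genotype = "CC"))
  expect_true(all(s1$statement_id %in% all_ids))
  h <- shared_mechanism_candidates(g, "malignant pleural mesothelioma")
  expect_true(all(unlist(h$chain) %in% all_ids))
})
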