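test_that("entity invariants are enforced at insertion", {
  g <- kg_new()
  g <- kg_add_entity(g, "enz", "enzalutamide", "drug")
  expect_equal(nrow(g$entities), 1L)
  expect_identical(kg_last_ref(g), "enz")

  # idempotent re-add, conflicting re-add rejected
  g2 <- kg_add_entity(g, "enz", "enzalutamide", "drug")
  expect_equal(nrow(g2$entities), 1L)
  expect_error(kg_add_entity(g, "enz", "other name", "drug"), "different content")

  # HGVS-looking variant names must pass the shape check
  g <- kg_add_entity(g, "v1", "NC_000002.12:g.38071060G>A,C", "variant",
                     genotype = "GG")
  expect_equal(sum(g$entities$category == "variant"), 1L)
  expect_error(kg_add_entity(g, "v_bad", "NC_000002:g.oops", "variant"),
               "shape check")
  # non-HGVS-looking names are opaque
  g <- kg_add_entity(g, "v2", "rs784888", "variant", genotype = "G")
  expect_equal(sum(g$entities$category == "variant"), 2L)

  # genotype restricted to variants; category restricted to the enum
  expect_error(kg_add_entity(g, "g1", "CYP2C9", "gene", genotype = "CC"),
               "variant")
  expect_error(kg_add_entity(g, "z", "thing", "protein"), "invalid category")
})

test_that("statement ids are content hashes and evidence merges by union", {
  g <- kg_new()
  g <- kg_add_entity(g, "enz", "enzalutamide", "drug")
  g <- kg_add_entity(g, "pc", "prostate cancer", "disease")
  g <- kg_add_statement(g, "enz", "treats", "pc",
                        evidence = kg_evidence("PharmGKB", "PMID:1"))
  s1 <- kg_last_ref(g)
  expect_identical(kg_edge_class(g, s1), "vv")

  # identical assertion with a different PMID: one statement, two evidence rows
  g <- kg_add_statement(g, "enz", "treats", "pc",
                        evidence = kg_evidence("CTD", "PMID:2"))
  expect_identical(kg_last_ref(g), s1)
  expect_equal(nrow(g$statements), 1L)
  expect_equal(nrow(g$statements$evidence[[1]]), 2L)

  # insertion order of evidence does not change the statement or its id
  h <- kg_new()
  h <- kg_add_entity(h, "enz", "enzalutamide", "drug")
  h <- kg_add_entity(h, "pc", "prostate cancer", "disease")
  h <- kg_add_statement(h, "enz", "treats", "pc",
                        evidence = kg_evidence("CTD", "PMID:2"))
  h <- kg_add_statement(h, "enz", "treats", "pc",
                        evidence = kg_evidence("PharmGKB", "PMID:1"))
  expect_true(kg_equal(g, h))

  # modifiers and qualifiers are part of identity; evidence is not
  id_a <- kg_statement_id("s", "treats", "o")
  expect_identical(id_a, kg_statement_id("s", "treats", "o"))
  expect_false(id_a == kg_statement_id("s", "treats", "o", negated = TRUE))
  expect_false(id_a == kg_statement_id("s", "treats", "o",
                                       aspect = "efficacy", direction = "decreased"))

  # errors: unresolved refs, self-reference, unknown predicate
  expect_error(kg_add_statement(g, "enz", "treats", "nope"), "unresolved")
  expect_error(kg_add_statement(g, "enz", "cures", "pc"), "predicate")
  expect_error(kg_add_statement(g, s1, "leads_to", s1), "identical subject and object")
})

test_that("gates require >= 2 distinct resolvable members and may hold statements", {
  g <- tiny_graph()
  s_ids <- g$statements$statement_id
  expect_error(kg_make_gate(g, "AND", "d1"), "at least 2")
  expect_error(kg_make_gate(g, "AND", c("d1", "d1")), "distinct")
  expect_error(kg_make_gate(g, "AND", c("d1", "ghost")), "unresolved")
  expect_error(kg_make_gate(g, "XOR", c("d1", "x1")), "AND")

  # OR gate over two statements is a legal composite concept
  g <- kg_make_gate(g, "OR", s_ids[1:2])
  expect_equal(nrow(g$gates), 1L)
  expect_equal(nrow(kg_validate(g)), 0L)

  # gates are usable as statement endpoints
  g <- kg_add_entity(g, "d2", "drugtwo", "drug")
  g <- kg_make_gate(g, "AND", c("d1", "d2"))
  combo <- kg_last_ref(g)
  g <- kg_add_statement(g, combo, "treats", "x1")
  expect_identical(kg_edge_class(g, kg_last_ref(g)), "vv")
})

test_that("edge classes partition statements into vv/ev/ee", {
  g <- tiny_graph()
  cls <- kg_edge_class(g, g$statements$statement_id)
  expect_setequal(unique(cls), c("vv", "ev"))

  # a statement over two statements is ee
  t1 <- g$statements$statement_id[1]
  s1 <- g$statements$statement_id[2]
  g <- kg_add_statement(g, s1, "leads_to", t1)
  expect_identical(kg_edge_class(g, kg_last_ref(g)), "ee")

  # partition law across synthetic graphs: every statement in exactly one class
  for (seed in 1:5) {
    sg <- generate_synthetic_kg(generator_params(seed = seed))
    cls <- kg_edge_class(sg, sg$statements$statement_id)
    expect_true(all(cls %in% c("vv", "ev", "ee")))
    expect_equal(length(cls), nrow(sg$statements))
  }
})

test_that("validation reports every violation and passes clean graphs", {
  expect_equal(nrow(kg_validate(tiny_graph())), 0L)
  expect_equal(nrow(kg_validate(worked_examples())), 0L)

  # injected dangling reference
  g <- tiny_graph()
  g$statements$object[2] <- "ghost"
  v <- kg_validate(g)
  expect_true("dangling_reference" %in% v$rule)

  # injected gate cycle: a gate that contains itself
  g <- tiny_graph()
  g <- kg_add_entity(g, "d2", "drugtwo", "drug")
  g <- kg_make_gate(g, "AND", c("d1", "d2"))
  gid <- kg_last_ref(g)
  g$gates$members[[1]] <- c("d1", gid)
  v <- kg_validate(g)
  expect_identical(unique(v$rule), "reference_cycle")

  # injected genotype misplacement and unknown predicate
  g <- tiny_graph()
  g$entities$genotype[g$entities$entity_id == "d1"] <- "CC"
  g$statements$predicate[1] <- "zaps"
  v <- kg_validate(g)
  expect_setequal(unique(v$rule), c("genotype_on_non_variant", "unknown_predicate"))
})

test_that("statement reference graph always admits a topological order", {
  # construction can only reference existing statements, so injected cycles
  # must come from tampering and are always detected
  g <- tiny_graph()
  t1 <- g$statements$statement_id[1]
  s1 <- g$statements$statement_id[2]
  g$statements$object[1] <- s1
  g$statements$subject[2] <- t1
  v <- kg_validate(g)
  expect_true("reference_cycle" %in% v$rule)

  for (seed in 1:5) {
    sg <- generate_synthetic_kg(generator_params(seed = seed))
    expect_equal(nrow(kg_validate(sg)), 0L)
  }
})

test_that("predicate set is configurable through the config dialect", {
  cfg_file <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# extra relations", "predicates = potentiates, inhibits",
               "match_threshold = 0.9"), cfg_file)
  cfg <- read_kg_config(cfg_file)
  preds <- kg_predicates_from_config(cfg)
  expect_true(all(c("potentiates", "inhibits") %in% preds))
  expect_true(all(kg_predicates() %in% preds))
  expect_equal(cfg$match_threshold, 0.9)

  g <- kg_new(predicates = preds)
  g <- kg_add_entity(g, "a", "a", "drug")
  g <- kg_add_entity(g, "b", "b", "gene")
  g <- kg_add_statement(g, "a", "potentiates", "b")
  expect_equal(nrow(kg_validate(g)), 0L)
  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines("oops", bad)
  expect_error(read_kg_config(bad), "malformed")
})
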