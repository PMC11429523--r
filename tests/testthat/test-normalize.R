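toy_vocab_tsv <- function(path) {
  writeLines(c(
    "id\tname\tsynonyms\tcategory",
    "CHEBI:1\twarfarin\tcoumadin|warfarin sodium\tdrug",
    "CHEBI:2\tmetformin\tglucophage\tdrug",
    "CHEBI:3\ttamoxifen\t\tdrug"), path)
  path
}

test_that("vocabularies load with case-folded name and synonym lookup", {
  path <- toy_vocab_tsv(withr::local_tempfile(fileext = ".tsv"))
  v <- load_vocabulary(path)
  expect_equal(nrow(v), 3L)
  expect_identical(vocab_lookup(v, "Coumadin"), "CHEBI:1")
  expect_identical(vocab_lookup(v, "WARFARIN"), "CHEBI:1")

  # duplicate ids are a load-time error
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tname\tsynonyms\tcategory",
               "X:1\ta\t\tdrug", "X:1\tb\t\tdrug"), bad)
  expect_error(load_vocabulary(bad), "duplicate")

  # missing column
  bad2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tname\tcategory", "X:1\ta\tdrug"), bad2)
  expect_error(load_vocabulary(bad2), "missing column")

  # a synonym shared by two terms keeps both retrievable
  v2 <- as_vocabulary(tibble::tibble(
    term_id = c("A", "B"), standard_name = c("alpha", "beta"),
    synonyms = list("shared name", "shared name"), category = "drug"))
  expect_setequal(vocab_lookup(v2, "shared name"), c("A", "B"))
})

test_that("ID mapping is an exact lookup with load-time conflict detection", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source_db\tsource_id\tterm_id",
               "PharmGKB\tPA123\tCHEBI:1",
               "CTD\tC042\tCHEBI:2"), path)
  xref <- load_xref(path)
  expect_identical(map_by_id("PharmGKB", "PA123", xref), "CHEBI:1")
  expect_identical(map_by_id("PharmGKB", "PA999", xref), NA_character_)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source_db\tsource_id\tterm_id",
               "PharmGKB\tPA123\tCHEBI:1",
               "PharmGKB\tPA123\tCHEBI:9"), bad)
  expect_error(load_xref(bad), "conflicting")
})

test_that("best_match scores exact hits 1.0 and flags ties as ambiguous", {
  path <- toy_vocab_tsv(withr::local_tempfile(fileext = ".tsv"))
  v <- load_vocabulary(path)
  m <- best_match("Warfarin", v)
  expect_identical(m$status, "unique")
  expect_equal(m$score, 1.0)
  expect_identical(m$best_ids[[1]], "CHEBI:1")

  # a name equally similar to two terms is ambiguous, never silently chosen
  v2 <- as_vocabulary(tibble::tibble(
    term_id = c("A", "B", "C"),
    standard_name = c("acid alpha", "acid beta", "unrelated"),
    synonyms = list(character(), character(), character()),
    category = "drug"))
  m2 <- best_match("acid", v2, threshold = 0.3)
  expect_identical(m2$status, "ambiguous")
  expect_setequal(m2$best_ids[[1]], c("A", "B"))

  # scores below threshold are unmapped; non-exact scores stay below 1
  m3 <- best_match("completely different", v)
  expect_identical(m3$status, "unmapped")
  expect_lt(best_match("warfarin extra tokens", v)$score, 1.0)
  expect_error(best_match("x", as_vocabulary(tibble::tibble(
    term_id = character(), standard_name = character(),
    synonyms = list(), category = character()))), "empty")
})

test_that("best_match agrees with the exhaustive brute-force argmax", {
  for (seed in 1:4) {
    v <- random_vocab(60, seed)
    names <- random_names(20, seed + 1000)
    for (nm in names) {
      got <- best_match(nm, v)
      want <- oracle_best_match(nm, v)
      expect_equal(got$score, want$score, tolerance = 1e-12)
      expect_identical(got$best_ids[[1]], want$best_ids)
      expect_identical(got$status, want$status)
    }
  }
})

test_that("normalize_entities prefers xrefs, queues ambiguity, drops nothing", {
  v <- as_vocabulary(tibble::tibble(
    term_id = c("CHEBI:1", "CHEBI:2", "CHEBI:8"),
    standard_name = c("warfarin", "metformin", "warfarin lookalike"),
    synonyms = list(character(), character(), "warfarin"),
    category = "drug"))
  g <- kg_new()
  g <- kg_add_entity(g, "PA123", "warfarin", "drug")
  g <- kg_add_entity(g, "m1", "metformin", "drug")
  g <- kg_add_entity(g, "u1", "mystery compound", "drug")
  xref_path <- withr::local_tempfile(fileext = ".tsv")
  # the xref points PA123 somewhere else than its (ambiguous) name match
  writeLines(c("source_db\tsource_id\tterm_id", "PharmGKB\tPA123\tCHEBI:1"),
             xref_path)
  res <- suppressWarnings(
    normalize_entities(g, list(drug = v), xrefs = load_xref(xref_path)))
  e <- res$graph$entities
  expect_identical(e$external_id[e$entity_id == "PA123"], "CHEBI:1") # xref wins
  expect_identical(e$external_id[e$entity_id == "m1"], "CHEBI:2")    # unique name map
  expect_equal(nrow(res$review_queue), 1L)                           # unmapped queued
  expect_identical(res$review_queue$entity_id, "u1")
  expect_equal(nrow(res$graph$entities), nrow(g$entities))           # nothing dropped

  # without the xref, "warfarin" ties two terms and lands on the queue
  res2 <- suppressWarnings(normalize_entities(g, list(drug = v)))
  expect_true("PA123" %in% res2$review_queue$entity_id)
  expect_identical(
    res2$review_queue$status[res2$review_queue$entity_id == "PA123"], "ambiguous")
})

test_that("rule extraction captures fields and reports unmatched lines", {
  rules <- extraction_rules(
    c("^(?<drug>[a-z]+) treats (?<disease>[a-z ]+)$",
      "^(?<drug>[a-z]+) raises the risk of (?<phenotype>[a-z ]+)$"),
    c("drug_indications", "side_effects"))
  out <- extract_with_rules(
    c("enzalutamide treats prostate cancer",
      "olanzapine raises the risk of metabolic syndrome",
      "this line matches nothing"), rules, source_db = "demo")
  expect_equal(nrow(out$records), 2L)
  expect_identical(out$records$drug, c("enzalutamide", "olanzapine"))
  expect_identical(out$records$disease[1], "prostate cancer")
  expect_identical(out$records$pattern_hint, c("drug_indications", "side_effects"))
  expect_equal(out$unmatched$line_no, 3L)

  # overlapping rules emit one record each
  rules2 <- extraction_rules(
    c("(?<drug>warfarin)", "warfarin treats (?<disease>[a-z ]+)"),
    c("drug_indications", "drug_indications"))
  out2 <- extract_with_rules("warfarin treats thrombosis", rules2)
  expect_equal(nrow(out2$records), 2L)

  # invalid patterns fail at rule-load time
  expect_error(extraction_rules("(?<oops", "x"), "invalid rule")
  rule_file <- withr::local_tempfile()
  writeLines(c("# comment", "^(?<drug>[a-z]+) cures .*\tdrug_indications"), rule_file)
  expect_equal(nrow(load_rules(rule_file)), 1L)
})

test_that("deduplicate is idempotent, permutation-invariant, unions evidence", {
  rec <- function(drug, disease, cite) tibble::tibble(
    source_db = "db", drug = drug, disease = disease, phenotype = NA_character_,
    variant = NA_character_, gene = NA_character_, genotype = NA_character_,
    direction = NA_character_, aspect = NA_character_,
    pattern_hint = "drug_indications", citation = cite, text = NA_character_)
  records <- dplyr::bind_rows(
    rec("a", "x", "PMID:1"), rec("a", "x", "PMID:2"),
    rec("a", "x", "PMID:1"), rec("b", "y", "PMID:3"))
  d1 <- deduplicate(records)
  expect_equal(nrow(d1), 2L)
  expect_identical(d1$citation[d1$drug == "a"], "PMID:1|PMID:2")
  expect_identical(deduplicate(d1), d1)
  expect_identical(deduplicate(records[sample.int(4, 4), ]), d1)
  set.seed(99)
  for (i in 1:5)
    expect_identical(deduplicate(records[sample.int(4, 4), ]), d1)
})

test_that("merge_graphs is commutative and associative up to canonical export", {
  g1 <- generate_synthetic_kg(generator_params(seed = 11, statements_per_pattern = 2, prefix = "A"))
  g2 <- generate_synthetic_kg(generator_params(seed = 12, statements_per_pattern = 2, prefix = "B"))
  g3 <- generate_synthetic_kg(generator_params(seed = 13, statements_per_pattern = 2, prefix = "C"))

  expect_true(kg_equal(merge_graphs(list(g1, kg_new())), g1))
  expect_true(kg_equal(merge_graphs(list(g1, g2)), merge_graphs(list(g2, g1))))
  expect_true(kg_equal(
    merge_graphs(list(merge_graphs(list(g1, g2)), g3)),
    merge_graphs(list(g1, merge_graphs(list(g2, g3))))))

  # shared statement with different evidence: union on the merged statement
  a <- tiny_graph()
  b <- tiny_graph()
  sid <- a$statements$statement_id[1]
  a$statements$evidence[[1]] <- kg_evidence("DB1", "PMID:1")
  b$statements$evidence[[1]] <- kg_evidence("DB2", "PMID:2")
  m <- merge_graphs(list(a, b))
  ev <- m$statements$evidence[[match(sid, m$statements$statement_id)]]
  expect_equal(nrow(ev), 2L)
  expect_setequal(ev$source_db, c("DB1", "DB2"))

  # category conflict for the same entity id is an error
  c1 <- kg_new(); c1 <- kg_add_entity(c1, "e1", "thing", "drug")
  c2 <- kg_new(); c2 <- kg_add_entity(c2, "e1", "thing", "gene")
  expect_error(merge_graphs(list(c1, c2)), "conflict")
})
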