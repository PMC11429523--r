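test_that("the four built-in templates encode the pattern shapes", {
  tpl <- builtin_patterns()
  expect_equal(nrow(tpl), 4L)
  expect_setequal(tpl$pattern_id,
                  c("side_effects", "drug_sensitivity", "drug_mechanisms",
                    "drug_indications"))
  # mechanisms target genes; indications accept combination-therapy gates
  expect_identical(tpl$object_spec[tpl$pattern_id == "drug_mechanisms"], "gene")
  expect_identical(tpl$subject_spec[tpl$pattern_id == "drug_indications"],
                   "drug-or-gate")
  # sensitivity requires a directional response aspect
  expect_true(tpl$direction_required[tpl$pattern_id == "drug_sensitivity"])
  expect_setequal(tpl$required_aspects[tpl$pattern_id == "drug_sensitivity"][[1]],
                  c("dose_requirement", "efficacy", "risk"))

  g <- worked_examples()
  combo <- g$gates$gate_id[1]
  g <- kg_add_statement(g, combo, "treats", "prostate_cancer")
  res <- validate_cluster(g, kg_last_ref(g), "drug_indications")
  expect_true(res$conformant)
})

test_that("instantiate_pattern emits clusters that validate conformant", {
  g <- worked_examples()
  # the olanzapine example: therapy vv + risk core + variant condition
  g2 <- instantiate_pattern(g, "side_effects", list(
    drug = "olanzapine", disease = "schizophrenia",
    phenotype = "metabolic_syndrome", variant = "v_olz_C"))
  cluster <- kg_last_ref(g2)
  expect_length(cluster, 3L)
  classes <- kg_edge_class(g2, cluster)
  expect_equal(sort(classes), c("ev", "ev", "vv"))
  expect_true(validate_cluster(g2, cluster, "side_effects")$conformant)

  # minimal indication pattern is a single vv statement
  g3 <- instantiate_pattern(g, "drug_indications",
                            list(drug = "enzalutamide", disease = "prostate_cancer"))
  expect_length(kg_last_ref(g3), 1L)

  # the tacrolimus dose-requirement example validates as sensitivity
  g4 <- instantiate_pattern(g, "drug_sensitivity", list(
    variant = "v_tac_CC", drug = "tacrolimus", disease = "liver_transplantation",
    aspect = "dose_requirement", direction = "decreased"))
  expect_true(validate_cluster(g4, kg_last_ref(g4), "drug_sensitivity")$conformant)

  # missing role and category mismatch are rejected
  expect_error(instantiate_pattern(g, "side_effects", list(drug = "olanzapine")),
               "requires role")
  expect_error(instantiate_pattern(g, "drug_mechanisms",
                                   list(drug = "AKR1C3", gene = "olanzapine")),
               "does not match")
})

test_that("instantiate -> validate closure holds across random bindings", {
  for (seed in 1:8) {
    g <- generate_synthetic_kg(generator_params(seed = seed,
                                                statements_per_pattern = 3))
    cores <- g$statements$statement_id[!is.na(g$statements$pattern)]
    for (core in cores) {
      p <- g$statements$pattern[match(core, g$statements$statement_id)]
      res <- validate_cluster(g, cluster_statements(g, core), p)
      expect_true(res$conformant,
                  info = paste("seed", seed, "pattern", p, "core", core))
    }
  }
})

test_that("every single-field mutation of a conformant cluster is caught", {
  g <- worked_examples()

  mutate_and_check <- function(g, cluster, pattern, mutator) {
    gm <- mutator(g)
    res <- validate_cluster(gm, cluster, pattern)
    expect_false(res$conformant)
    expect_gte(nrow(res$violations), 1L)
  }

  # side-effects cluster (olanzapine): flip each required element
  core <- g$statements$statement_id[g$statements$pattern %in% "side_effects" &
    g$statements$object == "metabolic_syndrome"]
  cluster <- cluster_statements(g, core)
  sidx <- match(core, g$statements$statement_id)
  mutate_and_check(g, cluster, "side_effects", function(g) {
    g$statements$predicate[sidx] <- "leads_to"; g })       # core predicate
  mutate_and_check(g, cluster, "side_effects", function(g) {
    g$statements$object[sidx] <- "AKR1C3"; g })            # object category
  mutate_and_check(g, cluster, "side_effects", function(g) {
    g$statements$subject[sidx] <- "olanzapine"; g })       # subject not a therapy event
  cond <- cluster[g$statements$predicate[match(cluster, g$statements$statement_id)] ==
                    "condition_of"]
  cidx <- match(cond, g$statements$statement_id)
  mutate_and_check(g, cluster, "side_effects", function(g) {
    g$statements$subject[cidx] <- "AKR1C3"; g })           # condition from a gene

  # sensitivity cluster (tacrolimus): qualifiers are load-bearing
  core2 <- g$statements$statement_id[g$statements$pattern %in% "drug_sensitivity" &
    g$statements$subject == "v_tac_CC"]
  cluster2 <- cluster_statements(g, core2)
  sidx2 <- match(core2, g$statements$statement_id)
  mutate_and_check(g, cluster2, "drug_sensitivity", function(g) {
    g$statements$direction[sidx2] <- NA_character_; g })   # missing direction
  mutate_and_check(g, cluster2, "drug_sensitivity", function(g) {
    g$statements$aspect[sidx2] <- NA_character_; g })      # missing aspect
  mutate_and_check(g, cluster2, "drug_sensitivity", function(g) {
    g$statements$subject[sidx2] <- "tacrolimus"; g })      # subject must be variant

  # mechanism cluster validated under the wrong pattern: category mismatch
  core3 <- g$statements$statement_id[g$statements$pattern %in% "drug_indications" &
    g$statements$subject == "enzalutamide"]
  res <- validate_cluster(g, cluster_statements(g, core3), "drug_mechanisms")
  expect_false(res$conformant)
  expect_true("missing_core" %in% res$violations$rule ||
              "core_object_category" %in% res$violations$rule)

  # a conformant sensitivity cluster with the direction removed: exactly one rule fires
  gm <- g
  gm$statements$direction[sidx2] <- NA_character_
  res2 <- validate_cluster(gm, cluster2, "drug_sensitivity")
  expect_equal(nrow(res2$violations), 1L)
  expect_identical(res2$violations$rule, "missing_direction")
})

test_that("pattern templates round-trip through the config dialect", {
  path <- withr::local_tempfile(fileext = ".cfg")
  write_pattern_config(builtin_patterns(), path)
  back <- read_pattern_config(path)
  orig <- builtin_patterns()
  back <- back[match(orig$pattern_id, back$pattern_id), ]
  expect_identical(orig$subject_spec, back$subject_spec)
  expect_identical(orig$object_spec, back$object_spec)
  expect_identical(lapply(orig$core_predicates, sort),
                   lapply(back$core_predicates, sort))
  expect_identical(orig$direction_required, back$direction_required)
})
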