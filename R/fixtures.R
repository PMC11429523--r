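# Packaged worked examples (the case-study clusters the framework was built
# around) and a seeded synthetic knowledge-graph generator, so every module
# is exercisable without downloading any upstream database.

#' Worked-example knowledge graph
#'
#' A small curated graph encoding the canonical example clusters:
#' olanzapine/metabolic syndrome in schizophrenia (side effect under a C
#' allele), tacrolimus dose requirement under the CC genotype in liver
#' transplantation, daunorubicin and AKR1C3 activity under an A allele,
#' enzalutamide for prostate cancer, warfarin/venous thromboembolism/bleeding
#' under NC_000010.11:g.94981296A>C, the metformin neighborhood (rs784888 and
#' rs5219 response effects plus eight listed side effects), the
#' pemetrexed/methotrexate shared KRAS mechanism for malignant pleural
#' mesothelioma, the six-drug breast-cancer suggestion case at
#' NC_000002.12:g.38071060G>A,C, ivacaftor's effects across CFTR variants,
#' and the interferon alfa-2b + ribavirin synergy case for chronic
#' hepatitis C. Only assertions stated in the source material are encoded.
#'
#' @return A validating `cond_kg` in which every cluster conforms to its
#'   knowledge pattern.
#' @export
worked_examples <- function() {
  g <- kg_new()
  ent <- function(g, id, name, category, ...) kg_add_entity(g, id, name, category, ...)
  ev <- function(db, cite) kg_evidence(db, cite)

  # --- entities --------------------------------------------------------------
  drugs <- c(olanzapine = "olanzapine", tacrolimus = "tacrolimus",
             daunorubicin = "daunorubicin", enzalutamide = "enzalutamide",
             warfarin = "warfarin", metformin = "metformin",
             pemetrexed = "pemetrexed", methotrexate = "methotrexate",
             docetaxel = "docetaxel", doxorubicin = "doxorubicin",
             epirubicin = "epirubicin", cyclophosphamide = "cyclophosphamide",
             gemcitabine = "gemcitabine", paclitaxel = "paclitaxel",
             ivacaftor = "ivacaftor", ifn_a2b = "interferon alfa-2b",
             ribavirin = "ribavirin")
  for (i in seq_along(drugs))
    g <- ent(g, names(drugs)[i], unname(drugs[i]), "drug")
  diseases <- c(schizophrenia = "schizophrenia",
                liver_transplantation = "liver transplantation",
                prostate_cancer = "prostate cancer",
                vte = "venous thromboembolism",
                hyperglycemia = "hyperglycemia",
                mpm = "malignant pleural mesothelioma",
                breast_cancer = "breast cancer",
                cystic_fibrosis = "cystic fibrosis",
                hepatitis_c = "chronic hepatitis C")
  for (i in seq_along(diseases))
    g <- ent(g, names(diseases)[i], unname(diseases[i]), "disease")
  phenos <- c(metabolic_syndrome = "metabolic syndrome", bleeding = "bleeding",
              blurred_vision = "blurred vision", urticaria = "urticaria",
              pruritus = "pruritus", skin_rash = "skin rash", tremor = "tremor",
              lethargy = "lethargy", hypertension = "hypertension",
              syncope = "syncope", nausea = "nausea",
              peripheral_neuropathy = "peripheral neuropathy", anemia = "anemia")
  for (i in seq_along(phenos))
    g <- ent(g, names(phenos)[i], unname(phenos[i]), "phenotype")
  # hyperglycemia is also reportable as a phenotype: dual-class entity stored
  # under a second id sharing the external id
  g <- ent(g, "hyperglycemia_ph", "hyperglycemia", "phenotype",
           external_id = "XREF:hyperglycemia")
  g$entities$external_id[g$entities$entity_id == "hyperglycemia"] <- "XREF:hyperglycemia"
  for (gene in c("AKR1C3", "KRAS", "CFTR"))
    g <- ent(g, gene, gene, "gene")

  g <- ent(g, "v_olz_C", "olanzapine metabolic syndrome risk variant", "variant",
           genotype = "C")
  g <- ent(g, "v_tac_CC", "tacrolimus dose requirement variant", "variant",
           genotype = "CC")
  g <- ent(g, "v_dnr_A", "AKR1C3 activity variant", "variant", genotype = "A")
  g <- ent(g, "v_warf", "NC_000010.11:g.94981296A>C", "variant")
  g <- ent(g, "v_rs784888_G", "rs784888", "variant", genotype = "G")
  g <- ent(g, "v_rs5219_T", "rs5219", "variant", genotype = "T")
  g <- ent(g, "v_bc_GG", "NC_000002.12:g.38071060G>A,C", "variant", genotype = "GG")
  g <- ent(g, "v_bc_CC", "NC_000002.12:g.38071060G>A,C", "variant", genotype = "CC")
  g <- ent(g, "v_bc_C", "NC_000002.12:g.38071060G>A,C", "variant", genotype = "C")
  g <- ent(g, "v_bc_any", "NC_000002.12:g.38071060G>A,C", "variant")
  g <- ent(g, "v_cftr_1", "NC_000007.14:g.117603654T>A,C", "variant")
  g <- ent(g, "v_cftr_2", "NC_000007.14:g.117611620A>C", "variant")
  g <- ent(g, "v_cftr_del", "NC_000007.14:g.117559592_117559594del", "variant")
  g <- ent(g, "v_rbv_1", "NC_000020.11:g.3271278A>C", "variant")
  g <- ent(g, "v_rbv_2", "NC_000020.11:g.3213247A>C", "variant")

  # --- olanzapine / metabolic syndrome in schizophrenia ----------------------
  g <- instantiate_pattern(g, "side_effects", list(
    drug = "olanzapine", disease = "schizophrenia",
    phenotype = "metabolic_syndrome", variant = "v_olz_C",
    evidence = ev("PharmGKB", "PMID:R21")))

  # --- tacrolimus dose requirement under the CC genotype ---------------------
  g <- instantiate_pattern(g, "drug_sensitivity", list(
    variant = "v_tac_CC", drug = "tacrolimus", disease = "liver_transplantation",
    aspect = "dose_requirement", direction = "decreased",
    evidence = ev("PharmGKB", "PMID:R24")))

  # --- daunorubicin reduces AKR1C3 activity under the A allele ---------------
  g <- instantiate_pattern(g, "drug_mechanisms", list(
    drug = "daunorubicin", gene = "AKR1C3", predicate = "decreases_activity_of",
    variant = "v_dnr_A", evidence = ev("PharmGKB", "PMID:R27")))

  # --- enzalutamide for prostate cancer --------------------------------------
  g <- instantiate_pattern(g, "drug_indications", list(
    drug = "enzalutamide", disease = "prostate_cancer",
    evidence = ev("PharmacotherapyDB", "PMID:R28")))

  # --- warfarin / venous thromboembolism / bleeding risk ---------------------
  g <- instantiate_pattern(g, "side_effects", list(
    drug = "warfarin", disease = "vte", phenotype = "bleeding",
    variant = "v_warf", evidence = ev("PharmGKB", "PMID:R29")))

  # --- metformin neighborhood ------------------------------------------------
  g <- kg_add_statement(g, "metformin", "treats", "hyperglycemia",
                        pattern = "drug_indications",
                        evidence = ev("CTD", "PMID:R32"))
  t_met <- kg_last_ref(g)
  g <- kg_add_statement(g, "v_rs784888_G", "affects_response_to", t_met,
                        aspect = "efficacy", direction = "increased",
                        pattern = "drug_sensitivity",
                        evidence = ev("PharmGKB", "PMID:R32"))
  g <- kg_add_statement(g, "v_rs5219_T", "affects_response_to", t_met,
                        aspect = "efficacy", direction = "decreased",
                        pattern = "drug_sensitivity",
                        evidence = ev("PharmGKB", "PMID:R33"))
  met_sides <- c("blurred_vision", "urticaria", "pruritus", "skin_rash",
                 "tremor", "lethargy", "hypertension", "syncope")
  for (ph in met_sides)
    g <- kg_add_statement(g, t_met, "associated_with", ph,
                          pattern = "side_effects",
                          evidence = ev("SIDER", "SIDER:metformin"))

  # --- pemetrexed / methotrexate shared KRAS mechanism -----------------------
  g <- instantiate_pattern(g, "drug_indications", list(
    drug = "pemetrexed", disease = "mpm", evidence = ev("CIViC", "PMID:R30")))
  g <- instantiate_pattern(g, "drug_mechanisms", list(
    drug = "pemetrexed", gene = "KRAS", predicate = "decreases_expression_of",
    evidence = ev("CTD", "PMID:R30")))
  g <- instantiate_pattern(g, "drug_mechanisms", list(
    drug = "methotrexate", gene = "KRAS", predicate = "decreases_expression_of",
    evidence = ev("CTD", "PMID:R30")))

  # --- breast-cancer personalized-suggestion case ----------------------------
  g <- kg_add_statement(g, "docetaxel", "treats", "breast_cancer",
                        negated = TRUE, likelihood = "possible",
                        pattern = "drug_indications",
                        evidence = ev("PharmGKB", "PMID:R34"))
  s_doc <- kg_last_ref(g)
  g <- kg_add_statement(g, "v_bc_GG", "condition_of", s_doc)

  g <- kg_add_statement(g, "doxorubicin", "treats", "breast_cancer",
                        evidence = ev("PharmGKB", "PMID:R35"))
  t_dox <- kg_last_ref(g)
  g <- kg_add_statement(g, t_dox, "increases_risk_of", "nausea",
                        pattern = "side_effects",
                        evidence = ev("PharmGKB", "PMID:R35"))
  g <- kg_add_statement(g, "v_bc_CC", "condition_of", kg_last_ref(g))

  g <- kg_add_statement(g, "epirubicin", "treats", "breast_cancer",
                        evidence = ev("PharmGKB", "PMID:R36"))
  t_epi <- kg_last_ref(g)
  g <- kg_add_statement(g, "v_bc_CC", "affects_response_to", t_epi,
                        aspect = "efficacy", direction = "decreased",
                        likelihood = "possible", pattern = "drug_sensitivity",
                        evidence = ev("PharmGKB", "PMID:R36"))

  g <- kg_add_statement(g, "cyclophosphamide", "treats", "breast_cancer",
                        evidence = ev("PharmGKB", "PMID:R38"))
  t_cyc <- kg_last_ref(g)
  g <- kg_add_statement(g, t_cyc, "increases_risk_of", "peripheral_neuropathy",
                        negated = TRUE, likelihood = "possible",
                        pattern = "side_effects",
                        evidence = ev("PharmGKB", "PMID:R38"))
  g <- kg_add_statement(g, "v_bc_C", "condition_of", kg_last_ref(g))

  for (d in c("gemcitabine", "paclitaxel")) {
    g <- kg_add_statement(g, d, "treats", "breast_cancer",
                          evidence = ev("PharmGKB", "PMID:R37"))
    g <- kg_add_statement(g, "v_bc_any", "no_effect_on", kg_last_ref(g),
                          pattern = "drug_sensitivity",
                          evidence = ev("PharmGKB", "PMID:R37"))
  }

  # --- ivacaftor pharmacogenomics case ---------------------------------------
  g <- instantiate_pattern(g, "drug_indications", list(
    drug = "ivacaftor", disease = "cystic_fibrosis",
    evidence = ev("DrugBank", "PMID:R40")))
  for (v in c("v_cftr_1", "v_cftr_2"))
    g <- kg_add_statement(g, v, "affects_response_to", "ivacaftor",
                          aspect = "activity", direction = "increased",
                          evidence = ev("CIViC", "PMID:R39"))
  g <- kg_add_statement(g, "ivacaftor", "increases_activity_of", "CFTR",
                        pattern = "drug_mechanisms",
                        evidence = kg_evidence("CIViC", "PMID:R41",
                          "linked with increased CFTR transport"))
  g <- kg_add_statement(g, "v_cftr_del", "condition_of", kg_last_ref(g))
  g <- kg_add_statement(g, "ivacaftor", "increases_activity_of", "CFTR",
                        negated = TRUE, pattern = "drug_mechanisms",
                        evidence = kg_evidence("CIViC", "PMID:R42",
                          "does not affect the protein's thermal stability"))
  g <- kg_add_statement(g, "v_cftr_del", "condition_of", kg_last_ref(g))

  # --- interferon alfa-2b + ribavirin synergy case ---------------------------
  g <- kg_make_gate(g, "AND", c("ifn_a2b", "ribavirin"))
  combo <- kg_last_ref(g)
  for (d in c("ifn_a2b", "ribavirin", combo)) {
    g <- kg_add_statement(g, d, "treats", "hepatitis_c",
                          pattern = "drug_indications",
                          evidence = ev("DCDB", "PMID:R43"))
    g <- kg_add_statement(g, kg_last_ref(g), "increases_risk_of", "anemia",
                          pattern = "side_effects",
                          evidence = ev("SIDER", "PMID:R43"))
  }
  t_rib <- kg_statement_id("ribavirin", "treats", "hepatitis_c")
  g <- kg_add_statement(g, t_rib, "increases_risk_of", "anemia",
                        negated = TRUE, likelihood = "probable",
                        pattern = "side_effects",
                        evidence = kg_evidence("PharmGKB", c("PMID:R44", "PMID:R45"),
                          "experience less severe anemia after ribavirin treatment"))
  s_div <- kg_last_ref(g)
  g <- kg_add_statement(g, "v_rbv_1", "condition_of", s_div)
  g <- kg_add_statement(g, "v_rbv_2", "condition_of", s_div)
  g
}

# ---- synthetic generator ----------------------------------------------------

#' Parameters for the synthetic knowledge-graph generator
#'
#' @param seed Integer RNG seed.
#' @param n_drugs,n_diseases,n_phenotypes,n_variants,n_genes Entity counts
#'   per category.
#' @param statements_per_pattern Number of clusters generated per knowledge
#'   pattern.
#' @param p_condition Probability a cluster carries a variant condition.
#' @param p_gate Probability the drug role of a cluster is an AND gate of two
#'   drugs (combination therapy).
#' @param p_negation Probability a core statement is negated.
#' @param prefix Prefix for generated entity ids, letting independently
#'   seeded graphs coexist in one merge without id collisions.
#' @return A `kg_generator_params` list.
#' @export
generator_params <- function(seed = 1L, n_drugs = 10L, n_diseases = 6L,
                             n_phenotypes = 8L, n_variants = 10L, n_genes = 8L,
                             statements_per_pattern = 5L,
                             p_condition = 0.5, p_gate = 0.2, p_negation = 0.1,
                             prefix = "") {
  p <- list(seed = as.integer(seed), n_drugs = n_drugs, n_diseases = n_diseases,
            n_phenotypes = n_phenotypes, n_variants = n_variants,
            n_genes = n_genes, statements_per_pattern = statements_per_pattern,
            p_condition = p_condition, p_gate = p_gate, p_negation = p_negation,
            prefix = as.character(prefix))
  probs <- c(p$p_condition, p$p_gate, p$p_negation)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  counts <- unlist(p[c("n_drugs", "n_diseases", "n_phenotypes", "n_variants",
                       "n_genes", "statements_per_pattern")])
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(p, class = "kg_generator_params")
}

#' Generate a seeded synthetic knowledge graph
#'
#' Entity names come from generic pools (`DRUG_0001`, ...; variants alternate
#' between HGVS-style and rs-style names) so no real pharmacology is implied.
#' Every cluster is emitted through [instantiate_pattern()], hence conformant
#' by construction, and the output is fully reproducible: the same parameters
#' always give a byte-identical canonical export.
#'
#' @param params A `kg_generator_params` from [generator_params()].
#' @return A validating `cond_kg` with exactly the requested entity counts
#'   and `statements_per_pattern` clusters per pattern.
#' @export
generate_synthetic_kg <- function(params = generator_params()) {
  stopifnot(inherits(params, "kg_generator_params"))
  if (params$statements_per_pattern > 0 &&
      (params$n_drugs < 1 || params$n_diseases < 1 || params$n_phenotypes < 1 ||
       params$n_variants < 1 || params$n_genes < 1))
    stop("cannot generate pattern clusters without at least one entity per category",
         call. = FALSE)
  set.seed(params$seed)
  g <- kg_new()
  mk <- function(g, n, prefix, category, variant = FALSE) {
    for (i in seq_len(n)) {
      id <- sprintf("%s%s_%04d", params$prefix, prefix, i)
      if (variant) {
        name <- if (i %% 2L == 0L)
          sprintf("NC_%06d.%d:g.%dA>G", i, 10L + i %% 3L, 10000L + 137L * i)
        else sprintf("rs%06d", 100000L + i)
        gt <- sample(c("AA", "AG", "GG", "A", "G", NA_character_), 1L)
        g <- kg_add_entity(g, id, name, category, genotype = gt)
      } else {
        g <- kg_add_entity(g, id, id, category)
      }
    }
    g
  }
  g <- mk(g, params$n_drugs, "DRUG", "drug")
  g <- mk(g, params$n_diseases, "DISEASE", "disease")
  g <- mk(g, params$n_phenotypes, "PHENO", "phenotype")
  g <- mk(g, params$n_variants, "VAR", "variant", variant = TRUE)
  g <- mk(g, params$n_genes, "GENE", "gene")

  pick <- function(pool) pool[sample.int(length(pool), 1L)]
  drug_role <- function(g) {
    if (params$n_drugs >= 2L && stats::runif(1) < params$p_gate) {
      pair <- sort(sample(g$entities$entity_id[g$entities$category == "drug"], 2L))
      g <- kg_make_gate(g, "AND", pair)
    } else {
      g <- `kg_last_ref<-`(g, pick(g$entities$entity_id[g$entities$category == "drug"]))
    }
    g
  }
  pool <- function(g, cat) g$entities$entity_id[g$entities$category == cat]
  evd <- function() kg_evidence("SYNTH", sprintf("PMID:%07d",
                                                 sample.int(9999999L, 1L)))

  for (p in kg_patterns()) {
    emitted <- character()
    tries <- 0L
    while (length(emitted) < params$statements_per_pattern) {
      tries <- tries + 1L
      if (tries > 50L * max(1L, params$statements_per_pattern))
        stop("could not generate ", params$statements_per_pattern,
             " distinct clusters for pattern '", p, "'", call. = FALSE)
      negated <- stats::runif(1) < params$p_negation
      with_cond <- stats::runif(1) < params$p_condition
      g <- drug_role(g)
      drug <- kg_last_ref(g)
      b <- switch(p,
        side_effects = list(drug = drug, disease = pick(pool(g, "disease")),
                            phenotype = pick(pool(g, "phenotype")),
                            predicate = pick(risk_predicates()),
                            variant = if (with_cond) pick(pool(g, "variant")),
                            negated = negated, evidence = evd()),
        drug_sensitivity = list(variant = pick(pool(g, "variant")), drug = drug,
                                disease = if (stats::runif(1) < 0.5)
                                  pick(pool(g, "disease")),
                                aspect = pick(c("dose_requirement", "efficacy", "risk")),
                                direction = pick(c("increased", "decreased")),
                                negated = negated, evidence = evd()),
        drug_mechanisms = list(drug = if (kg_ref_kind(g, drug) == "entity") drug
                                      else pick(pool(g, "drug")),
                               gene = pick(pool(g, "gene")),
                               predicate = pick(mechanism_predicates()),
                               variant = if (with_cond) pick(pool(g, "variant")),
                               negated = negated, evidence = evd()),
        drug_indications = list(drug = drug, disease = pick(pool(g, "disease")),
                                variant = if (with_cond) pick(pool(g, "variant")),
                                negated = negated, evidence = evd()))
      b <- b[!vapply(b, is.null, logical(1))]
      g <- instantiate_pattern(g, p, b)
      core <- kg_last_core(g)
      if (!core %in% emitted) emitted <- c(emitted, core)
    }
  }
  g
}
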