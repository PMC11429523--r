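#' The four built-in knowledge-pattern templates
#'
#' Precision-medicine assertions are organised into four declared patterns,
#' each a machine-checkable template over a statement cluster:
#'
#' * `side_effects` — a phenotype risk attached to a therapy event:
#'   core `(therapy-statement, increases_risk_of/causes/associated_with,
#'   phenotype)`, optionally conditioned on a variant genotype or disease
#'   context.
#' * `drug_sensitivity` — a directional response difference: core
#'   `(variant, affects_response_to, therapy-statement-or-drug)` with a
#'   required aspect (`dose_requirement`, `efficacy`, `risk`) and direction.
#' * `drug_mechanisms` — a gene-level effect: core `(drug,
#'   increases/decreases_expression_of | increases/decreases_activity_of,
#'   gene)`, optionally conditioned on a variant.
#' * `drug_indications` — a treatment recommendation: core `(drug-or-gate,
#'   treats, disease)`; AND gates encode combination therapy.
#'
#' @return A tibble with one row per pattern: `pattern_id`, `subject_spec`,
#'   `core_predicates` (list), `object_spec`, `allowed_conditions` (list),
#'   `conditions_required`, `required_aspects` (list), `direction_required`.
#' @export
builtin_patterns <- function() {
  tibble::tibble(
    pattern_id = kg_patterns(),
    subject_spec = c("therapy-statement", "variant", "drug", "drug-or-gate"),
    core_predicates = list(
      risk_predicates(),
      c("affects_response_to", "no_effect_on"),
      mechanism_predicates(),
      "treats"
    ),
    object_spec = c("phenotype", "therapy-statement-or-drug", "gene", "disease"),
    allowed_conditions = list(
      c("variant", "disease"),
      c("variant", "disease"),
      "variant",
      c("variant", "disease", "phenotype")
    ),
    conditions_required = c(FALSE, FALSE, FALSE, FALSE),
    required_aspects = list(
      character(),
      c("dose_requirement", "efficacy", "risk"),
      character(),
      character()
    ),
    direction_required = c(FALSE, TRUE, FALSE, FALSE)
  )
}

pattern_template <- function(pattern_id, templates = builtin_patterns()) {
  idx <- match(pattern_id, templates$pattern_id)
  if (is.na(idx)) stop("unknown pattern_id '", pattern_id, "'", call. = FALSE)
  templates[idx, ]
}

# ---- role checks ------------------------------------------------------------

ref_matches_spec <- function(graph, ref, spec) {
  kind <- kg_ref_kind(graph, ref)
  if (is.na(kind)) return(FALSE)
  cat <- if (kind == "entity") graph$entities$category[graph$entities$entity_id == ref] else NA
  switch(spec,
    "therapy-statement" = kind == "statement" && is_therapy_statement(graph, ref),
    "therapy-statement-or-drug" =
      (kind == "statement" && is_therapy_statement(graph, ref)) ||
      (kind == "entity" && identical(cat, "drug")) || kind == "gate",
    "drug-or-gate" = (kind == "entity" && identical(cat, "drug")) || kind == "gate",
    # plain entity category
    kind == "entity" && identical(cat, spec)
  )
}

is_therapy_statement <- function(graph, ref) {
  idx <- match(ref, graph$statements$statement_id)
  if (is.na(idx)) return(FALSE)
  s <- graph$statements[idx, ]
  s$predicate == "treats" &&
    ref_matches_spec(graph, s$subject, "drug-or-gate") &&
    ref_matches_spec(graph, s$object, "disease")
}

# ---- instantiation ----------------------------------------------------------

#' Build a conformant pattern cluster from role bindings
#'
#' Emits the core statement of the requested pattern plus, as needed, the
#' reified therapy statement `(drug, treats, disease)` and `condition_of`
#' statements, all deterministically. The resulting cluster always validates
#' as conformant for its pattern ([validate_cluster()]).
#'
#' @param graph A `cond_kg`; all bound entities must already exist.
#' @param pattern_id One of the four pattern ids.
#' @param bindings Named list of role bindings (entity/gate ids):
#'   * `side_effects`: `drug` (or gate), `disease`, `phenotype`; optional
#'     `variant`, `predicate` (default `increases_risk_of`).
#'   * `drug_sensitivity`: `variant`, `drug` (or gate), `aspect`,
#'     `direction`; optional `disease` (reifies a therapy statement),
#'     `predicate` (default `affects_response_to`).
#'   * `drug_mechanisms`: `drug`, `gene`; optional `predicate` (default
#'     `increases_expression_of`), `variant`.
#'   * `drug_indications`: `drug` (or gate), `disease`.
#'   All patterns accept `negated`, `likelihood`, `evidence`.
#' @return The updated graph; [kg_last_ref()] gives the emitted statement ids
#'   in emission order and [kg_last_core()] the pattern-tagged core statement.
#' @export
instantiate_pattern <- function(graph, pattern_id, bindings) {
  stopifnot(inherits(graph, "cond_kg"), is.list(bindings))
  need <- function(role) {
    if (is.null(bindings[[role]]))
      stop("pattern '", pattern_id, "' requires role '", role, "'", call. = FALSE)
    bindings[[role]]
  }
  opt <- function(role, default = NULL) bindings[[role]] %||% default
  check_role <- function(ref, spec, role) {
    if (!ref_matches_spec(graph, ref, spec))
      stop("role '", role, "' binding '", ref, "' does not match category '",
           spec, "'", call. = FALSE)
    ref
  }
  negated <- isTRUE(opt("negated", FALSE))
  likelihood <- opt("likelihood", "certain")
  evidence <- opt("evidence")
  emitted <- character()
  add <- function(g, ...) {
    g <- kg_add_statement(g, ...)
    emitted <<- c(emitted, kg_last_ref(g))
    g
  }

  if (pattern_id == "side_effects") {
    drug <- check_role(need("drug"), "drug-or-gate", "drug")
    disease <- check_role(need("disease"), "disease", "disease")
    phenotype <- check_role(need("phenotype"), "phenotype", "phenotype")
    pred <- opt("predicate", "increases_risk_of")
    graph <- add(graph, drug, "treats", disease, evidence = evidence)
    therapy <- emitted[length(emitted)]
    graph <- add(graph, therapy, pred, phenotype, negated = negated,
                 likelihood = likelihood, pattern = "side_effects",
                 evidence = evidence)
    core <- emitted[length(emitted)]
    if (!is.null(opt("variant"))) {
      variant <- check_role(opt("variant"), "variant", "variant")
      graph <- add(graph, variant, "condition_of", core, evidence = evidence)
    }
  } else if (pattern_id == "drug_sensitivity") {
    variant <- check_role(need("variant"), "variant", "variant")
    drug <- check_role(need("drug"), "drug-or-gate", "drug")
    pred <- opt("predicate", "affects_response_to")
    aspect <- if (identical(pred, "no_effect_on")) opt("aspect") else need("aspect")
    direction <- if (identical(pred, "no_effect_on")) opt("direction") else need("direction")
    target <- drug
    if (!is.null(opt("disease"))) {
      disease <- check_role(opt("disease"), "disease", "disease")
      graph <- add(graph, drug, "treats", disease, evidence = evidence)
      target <- emitted[length(emitted)]
    }
    graph <- add(graph, variant, pred, target, negated = negated,
                 likelihood = likelihood,
                 aspect = aspect %||% NA_character_,
                 direction = direction %||% NA_character_,
                 pattern = "drug_sensitivity", evidence = evidence)
  } else if (pattern_id == "drug_mechanisms") {
    drug <- check_role(need("drug"), "drug", "drug")
    gene <- check_role(need("gene"), "gene", "gene")
    pred <- opt("predicate", "increases_expression_of")
    if (!pred %in% mechanism_predicates())
      stop("mechanism predicate must be one of ",
           paste(mechanism_predicates(), collapse = ", "), call. = FALSE)
    graph <- add(graph, drug, pred, gene, negated = negated,
                 likelihood = likelihood, pattern = "drug_mechanisms",
                 evidence = evidence)
    core <- emitted[length(emitted)]
    if (!is.null(opt("variant"))) {
      variant <- check_role(opt("variant"), "variant", "variant")
      graph <- add(graph, variant, "condition_of", core, evidence = evidence)
    }
  } else if (pattern_id == "drug_indications") {
    drug <- check_role(need("drug"), "drug-or-gate", "drug")
    disease <- check_role(need("disease"), "disease", "disease")
    graph <- add(graph, drug, "treats", disease, negated = negated,
                 likelihood = likelihood, pattern = "drug_indications",
                 evidence = evidence)
    core <- emitted[length(emitted)]
    if (!is.null(opt("variant"))) {
      variant <- check_role(opt("variant"), "variant", "variant")
      graph <- add(graph, variant, "condition_of", core, evidence = evidence)
    }
  } else {
    stop("unknown pattern_id '", pattern_id, "'", call. = FALSE)
  }
  graph <- `kg_last_ref<-`(graph, unique(emitted))
  core <- emitted[graph$statements$pattern[
    match(emitted, graph$statements$statement_id)] %in% pattern_id]
  attr(graph, "last_core") <- core[length(core)]
  graph
}

#' Core statement of the most recently instantiated pattern cluster
#' @param graph A `cond_kg` returned by [instantiate_pattern()].
#' @return A statement id.
#' @export
kg_last_core <- function(graph) attr(graph, "last_core")

# ---- cluster validation -----------------------------------------------------

#' Validate a statement cluster against a knowledge pattern
#'
#' Checks the core-statement shape (subject/object categories, predicate
#' membership), required qualifiers, the reified therapy sub-statement where
#' the pattern calls for one, and that every `condition_of` statement in the
#' cluster has a subject from the pattern's allowed condition categories.
#' Every violation is reported; none stops the check.
#'
#' @param graph A `cond_kg`.
#' @param statement_ids Character vector of statement ids forming the cluster.
#' @param pattern_id One of the four pattern ids.
#' @return A list of class `kg_cluster_validation` with elements `conformant`
#'   (logical) and `violations` (tibble: `ref`, `rule`, `message`).
#' @export
validate_cluster <- function(graph, statement_ids, pattern_id) {
  tpl <- pattern_template(pattern_id)
  idx <- match(statement_ids, graph$statements$statement_id)
  if (anyNA(idx))
    stop("unresolved statement(s): ",
         paste(statement_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  s <- graph$statements[idx, ]
  v <- list(no_violations())

  cores <- s$statement_id[s$predicate %in% tpl$core_predicates[[1]]]
  if (!length(cores)) {
    v[[length(v) + 1L]] <- violation(NA_character_, "missing_core",
      paste0("no statement with a core predicate of pattern '", pattern_id, "'"))
  }
  accounted <- character()
  for (core in cores) {
    row <- s[s$statement_id == core, ]
    accounted <- c(accounted, core)
    if (!ref_matches_spec(graph, row$subject, tpl$subject_spec)) {
      v[[length(v) + 1L]] <- violation(core, "core_subject_category",
        paste0("subject does not match '", tpl$subject_spec, "'"))
    }
    if (!ref_matches_spec(graph, row$object, tpl$object_spec)) {
      v[[length(v) + 1L]] <- violation(core, "core_object_category",
        paste0("object does not match '", tpl$object_spec, "'"))
    }
    aspects <- tpl$required_aspects[[1]]
    if (length(aspects) && row$predicate != "no_effect_on") {
      if (is.na(row$aspect) || !row$aspect %in% aspects)
        v[[length(v) + 1L]] <- violation(core, "missing_aspect",
          paste0("aspect must be one of ", paste(aspects, collapse = ", ")))
      if (tpl$direction_required && is.na(row$direction))
        v[[length(v) + 1L]] <- violation(core, "missing_direction",
          "direction qualifier is required")
    }
    # therapy sub-statements referenced by the core are part of the cluster
    for (ref in c(row$subject, row$object)) {
      if (ref %in% s$statement_id) accounted <- c(accounted, ref)
    }
  }

  conds <- s[s$predicate == "condition_of", ]
  for (i in seq_len(nrow(conds))) {
    accounted <- c(accounted, conds$statement_id[i])
    if (!conds$object[i] %in% c(s$statement_id)) {
      v[[length(v) + 1L]] <- violation(conds$statement_id[i], "condition_target",
        "condition_of does not target a statement in the cluster")
    }
    subj_kind <- kg_ref_kind(graph, conds$subject[i])
    subj_cat <- if (identical(subj_kind, "entity"))
      graph$entities$category[graph$entities$entity_id == conds$subject[i]]
    else NA_character_
    if (is.na(subj_cat) || !subj_cat %in% tpl$allowed_conditions[[1]]) {
      v[[length(v) + 1L]] <- violation(conds$statement_id[i], "condition_subject_category",
        paste0("condition subject must be one of ",
               paste(tpl$allowed_conditions[[1]], collapse = ", ")))
    }
  }

  if (tpl$conditions_required && !nrow(conds)) {
    v[[length(v) + 1L]] <- violation(NA_character_, "missing_condition",
      "pattern requires at least one condition")
  }

  stray <- setdiff(s$statement_id, unique(accounted))
  # treats statements are legitimate cluster members when a core references them
  stray <- stray[!vapply(stray, function(id) {
    r <- s[s$statement_id == id, ]
    r$predicate == "treats" && is_therapy_statement(graph, id)
  }, logical(1))]
  for (id in stray) {
    v[[length(v) + 1L]] <- violation(id, "unrecognized_statement",
      "statement plays no role in this pattern")
  }

  violations <- dplyr::bind_rows(v)
  structure(list(conformant = nrow(violations) == 0L, violations = violations),
            class = "kg_cluster_validation")
}

#' @export
print.kg_cluster_validation <- function(x, ...) {
  cat("<kg_cluster_validation> conformant:", x$conformant, "\n")
  if (nrow(x$violations)) print(x$violations)
  invisible(x)
}

# ---- template serialization -------------------------------------------------

#' Serialize pattern templates to the key=value config dialect
#'
#' @param templates A template tibble as from [builtin_patterns()].
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_pattern_config <- function(templates, path) {
  lines <- character()
  for (i in seq_len(nrow(templates))) {
    p <- templates$pattern_id[i]
    lines <- c(lines,
      paste0("pattern.", p, ".subject = ", templates$subject_spec[i]),
      paste0("pattern.", p, ".predicates = ",
             paste(templates$core_predicates[[i]], collapse = ", ")),
      paste0("pattern.", p, ".object = ", templates$object_spec[i]),
      paste0("pattern.", p, ".conditions = ",
             paste(templates$allowed_conditions[[i]], collapse = ", ")),
      paste0("pattern.", p, ".conditions_required = ",
             tolower(templates$conditions_required[i])),
      paste0("pattern.", p, ".aspects = ",
             paste(templates$required_aspects[[i]], collapse = ", ")),
      paste0("pattern.", p, ".direction_required = ",
             tolower(templates$direction_required[i]))
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read pattern templates from a config file
#'
#' @param path File written by [write_pattern_config()] or hand-edited in the
#'   same dialect.
#' @return A template tibble in the layout of [builtin_patterns()].
#' @export
read_pattern_config <- function(path) {
  cfg <- read_kg_config(path)
  keys <- names(cfg)
  ids <- unique(sub("^pattern\\.([^.]+)\\..*$", "\\1", keys[startsWith(keys, "pattern.")]))
  get <- function(p, field) cfg[[paste0("pattern.", p, ".", field)]]
  tibble::tibble(
    pattern_id = ids,
    subject_spec = unname(vapply(ids, function(p) as.character(get(p, "subject")), "")),
    core_predicates = unname(lapply(ids, function(p) as.character(get(p, "predicates")))),
    object_spec = unname(vapply(ids, function(p) as.character(get(p, "object")), "")),
    allowed_conditions = unname(lapply(ids, function(p) as.character(get(p, "conditions")))),
    conditions_required = unname(vapply(ids, function(p)
      identical(as.character(get(p, "conditions_required")), "true"), logical(1))),
    required_aspects = unname(lapply(ids, function(p) {
      a <- get(p, "aspects")
      if (is.null(a) || identical(a, "")) character() else as.character(a)
    })),
    direction_required = unname(vapply(ids, function(p)
      identical(as.character(get(p, "direction_required")), "true"), logical(1)))
  )
}
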