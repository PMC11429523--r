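#' Create an empty conditional knowledge graph
#'
#' A `cond_kg` holds pharmacogenomic knowledge as *hyper-triples*: statements
#' `(subject, predicate, object)` whose subject or object may be an entity, an
#' AND/OR gate (a composite concept such as a drug combination), or another
#' statement. Vertex-to-statement edges express *conditions* (e.g. "this risk
#' holds for carriers of the CC genotype"); statement-to-statement edges
#' express *causation* (one event leads to another).
#'
#' The container is a list of three tibbles — `entities`, `gates`,
#' `statements` — plus the controlled predicate set, so results of every
#' operation stay pipe-friendly.
#'
#' @param predicates Character vector of allowed predicates. Defaults to
#'   [kg_predicates()].
#' @return A `cond_kg` object.
#' @examples
#' g <- kg_new()
#' g <- kg_add_entity(g, "enzalutamide", "enzalutamide", "drug")
#' @export
kg_new <- function(predicates = kg_predicates()) {
  g <- list(
    entities = tibble::tibble(
      entity_id = character(), name = character(), category = character(),
      external_id = character(), synonyms = list(), genotype = character()
    ),
    gates = tibble::tibble(
      gate_id = character(), gate_type = character(), members = list()
    ),
    statements = tibble::tibble(
      statement_id = character(), subject = character(), predicate = character(),
      object = character(), negated = logical(), likelihood = character(),
      aspect = character(), direction = character(), pattern = character(),
      evidence = list()
    ),
    predicates = sort(unique(predicates))
  )
  structure(g, class = "cond_kg")
}

#' Entity categories recognised by the graph
#' @return Character vector of the five categories.
#' @export
kg_categories <- function() {
  c("drug", "disease", "phenotype", "variant", "gene")
}

kg_likelihoods <- function() c("certain", "probable", "possible")
kg_aspects <- function() c("dose_requirement", "efficacy", "risk", "expression", "activity")
kg_directions <- function() c("increased", "decreased", "none")
kg_patterns <- function() c("side_effects", "drug_sensitivity", "drug_mechanisms", "drug_indications")

#' @export
print.cond_kg <- function(x, ...) {
  cat("<cond_kg>", nrow(x$entities), "entities,", nrow(x$gates), "gates,",
      nrow(x$statements), "statements\n")
  if (nrow(x$entities)) {
    tab <- table(x$entities$category)
    cat("  entities:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  if (nrow(x$statements)) {
    tab <- table(factor(x$statements$pattern, levels = kg_patterns()), useNA = "ifany")
    cat("  pattern-tagged:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

# ---- references -------------------------------------------------------------

#' Resolve the kind of a reference
#'
#' @param graph A `cond_kg`.
#' @param ref Character vector of ids.
#' @return Character vector: `"entity"`, `"gate"`, `"statement"`, or `NA` for
#'   unresolved ids.
#' @export
kg_ref_kind <- function(graph, ref) {
  out <- rep(NA_character_, length(ref))
  out[ref %in% graph$entities$entity_id] <- "entity"
  out[ref %in% graph$gates$gate_id] <- "gate"
  out[ref %in% graph$statements$statement_id] <- "statement"
  out
}

#' Id of the element most recently added to a graph
#'
#' Mutating verbs ([kg_add_entity()], [kg_add_statement()], [kg_make_gate()],
#' [instantiate_pattern()]) return the updated graph; the id(s) of what they
#' created ride along as an attribute readable with this accessor.
#'
#' @param graph A `cond_kg` returned by a mutating verb.
#' @return Character vector of ids (length one for single adds; the whole
#'   emitted cluster for [instantiate_pattern()]).
#' @export
kg_last_ref <- function(graph) attr(graph, "last_ref")

`kg_last_ref<-` <- function(graph, value) {
  attr(graph, "last_ref") <- value
  graph
}

# ---- entities ---------------------------------------------------------------

hgvs_like <- function(name) {
  !is.na(name) & startsWith(name, "NC_") & grepl(":g\\.", name, fixed = FALSE)
}

# Loose syntactic shape check for HGVS genomic descriptions:
# NC_<digits>.<digits>:g.<position[_position]><change>, where change is a
# substitution (ref>alt[,alt]), del/dup/ins/delins, or inversion.
hgvs_shape_ok <- function(name) {
  grepl(
    "^NC_[0-9]+\\.[0-9]+:g\\.[0-9]+(_[0-9]+)?([ACGTN]+>[ACGTN]+(,[ACGTN]+)*|del[ACGTN]*|dup[ACGTN]*|ins[ACGTN]+|delins[ACGTN]+|inv)$",
    name
  )
}

check_entity_fields <- function(entity_id, name, category, genotype) {
  if (!is.character(entity_id) || length(entity_id) != 1L || is.na(entity_id) || !nzchar(entity_id))
    stop("entity_id must be a non-empty string", call. = FALSE)
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    stop("entity name must be a non-empty string", call. = FALSE)
  if (!category %in% kg_categories())
    stop("invalid category '", category, "'; must be one of ",
         paste(kg_categories(), collapse = ", "), call. = FALSE)
  if (!is.na(genotype) && category != "variant")
    stop("genotype is only allowed on variant entities", call. = FALSE)
  if (category == "variant" && hgvs_like(name) && !hgvs_shape_ok(name))
    stop("variant name '", name, "' looks like an HGVS genomic description but ",
         "fails the syntactic shape check", call. = FALSE)
  invisible(TRUE)
}

#' Add an entity to a knowledge graph
#'
#' Entities are the graph vertices: drugs, diseases, phenotypes, variants and
#' genes. Variant entities may carry a `genotype` string (e.g. `"CC"`,
#' `"A"`) that identifies the allele/genotype context a condition refers to;
#' the same genomic variant under two genotypes is two entities sharing a
#' `name`. An entity classifiable as both disease and phenotype is stored
#' twice under two entity ids sharing `external_id`.
#'
#' Re-adding a byte-identical entity is a no-op; re-using an `entity_id` with
#' different content is an error.
#'
#' @param graph A `cond_kg`.
#' @param entity_id Stable identifier, unique within the graph.
#' @param name Display name. Variant names beginning `NC_...:g.` must be
#'   syntactically valid HGVS genomic descriptions.
#' @param category One of `r paste0('"', kg_categories(), '"', collapse = ", ")`.
#' @param external_id Ontology identifier, or `NA` if not yet normalized.
#' @param synonyms Character vector of alternative names.
#' @param genotype Allele/genotype string; variants only.
#' @return The updated graph; [kg_last_ref()] gives the entity id.
#' @export
kg_add_entity <- function(graph, entity_id, name, category,
                          external_id = NA_character_,
                          synonyms = character(),
                          genotype = NA_character_) {
  stopifnot(inherits(graph, "cond_kg"))
  check_entity_fields(entity_id, name, category, genotype)
  row <- tibble::new_tibble(list(
    entity_id = entity_id, name = name, category = category,
    external_id = as.character(external_id),
    synonyms = list(as.character(synonyms)),
    genotype = as.character(genotype)
  ), nrow = 1L)
  hit <- which(graph$entities$entity_id == entity_id)
  if (length(hit)) {
    old <- graph$entities[hit, ]
    if (identical(unclass(old)[names(old)], unclass(row)[names(row)])) {
      return(`kg_last_ref<-`(graph, entity_id))
    }
    stop("entity '", entity_id, "' already exists with different content", call. = FALSE)
  }
  graph$entities <- dplyr::bind_rows(graph$entities, row)
  `kg_last_ref<-`(graph, entity_id)
}

# ---- evidence ---------------------------------------------------------------

#' Construct an evidence table
#'
#' @param source_db Name of the upstream source (non-empty).
#' @param citation PMID or free-form citation.
#' @param sentence Optional verbatim supporting text.
#' @return A tibble with one row per evidence item.
#' @export
kg_evidence <- function(source_db, citation = NA_character_, sentence = NA_character_) {
  if (any(is.na(source_db) | !nzchar(source_db)))
    stop("evidence source_db must be non-empty", call. = FALSE)
  tibble::tibble(
    source_db = as.character(source_db),
    citation = as.character(citation),
    sentence = as.character(sentence)
  )
}

empty_evidence <- function() {
  tibble::tibble(source_db = character(), citation = character(), sentence = character())
}

canonical_evidence <- function(ev) {
  if (is.null(ev) || !nrow(ev)) return(empty_evidence())
  key <- paste(ev$source_db, ev$citation, ev$sentence, sep = "\x1f")
  ev <- ev[!duplicated(key), ]
  ev[order(ev$source_db, ev$citation, ev$sentence, method = "radix", na.last = TRUE), ]
}

# ---- statements -------------------------------------------------------------

#' Content-derived statement identifier
#'
#' Two statements with equal (subject, predicate, object, modifiers,
#' qualifiers) always receive the same id, whatever their evidence or
#' insertion order — deduplication and evidence union fall out of identity.
#'
#' @inheritParams kg_add_statement
#' @return A statement id string.
#' @export
kg_statement_id <- function(subject, predicate, object, negated = FALSE,
                            likelihood = "certain", aspect = NA_character_,
                            direction = NA_character_) {
  key <- paste(subject, predicate, object, as.character(negated), likelihood,
               as.character(aspect), as.character(direction), sep = "\x1f")
  paste0("S:", rlang::hash(key))
}

#' Add a hyper-triple statement
#'
#' The subject and object must already exist in the graph — entities, gates,
#' or previously added statements — which guarantees the statement-reference
#' graph stays acyclic by construction. Adding a statement identical up to
#' evidence merges the evidence lists (set union) instead of duplicating.
#'
#' @param graph A `cond_kg`.
#' @param subject,object Ids of existing entities, gates, or statements.
#' @param predicate A predicate from the graph's configured predicate set.
#' @param negated Logical negation modifier.
#' @param likelihood `"certain"`, `"probable"`, or `"possible"`.
#' @param aspect Optional response aspect
#'   (`r paste0('"', kg_aspects(), '"', collapse = ", ")`).
#' @param direction Optional direction (`"increased"`, `"decreased"`,
#'   `"none"`); only allowed together with `aspect`.
#' @param pattern Optional knowledge-pattern tag marking this as the core
#'   statement of a pattern cluster.
#' @param evidence A tibble from [kg_evidence()].
#' @return The updated graph; [kg_last_ref()] gives the statement id.
#' @export
kg_add_statement <- function(graph, subject, predicate, object,
                             negated = FALSE, likelihood = "certain",
                             aspect = NA_character_, direction = NA_character_,
                             pattern = NA_character_, evidence = NULL) {
  stopifnot(inherits(graph, "cond_kg"))
  if (!predicate %in% graph$predicates)
    stop("predicate '", predicate, "' is not in the configured predicate set", call. = FALSE)
  for (ref in c(subject, object)) {
    if (is.na(kg_ref_kind(graph, ref)))
      stop("unresolved reference '", ref, "'", call. = FALSE)
  }
  if (identical(subject, object))
    stop("a statement may not have identical subject and object", call. = FALSE)
  if (!likelihood %in% kg_likelihoods())
    stop("invalid likelihood '", likelihood, "'", call. = FALSE)
  if (!is.na(aspect) && !aspect %in% kg_aspects())
    stop("invalid aspect '", aspect, "'", call. = FALSE)
  if (!is.na(direction) && !direction %in% kg_directions())
    stop("invalid direction '", direction, "'", call. = FALSE)
  if (!is.na(direction) && is.na(aspect))
    stop("direction requires an aspect", call. = FALSE)
  if (!is.na(pattern) && !pattern %in% kg_patterns())
    stop("invalid pattern tag '", pattern, "'", call. = FALSE)

  sid <- kg_statement_id(subject, predicate, object, negated, likelihood, aspect, direction)
  if (identical(sid, subject) || identical(sid, object))
    stop("a statement may not reference itself", call. = FALSE)
  ev <- canonical_evidence(if (is.null(evidence)) empty_evidence() else evidence)

  hit <- which(graph$statements$statement_id == sid)
  if (length(hit)) {
    merged <- canonical_evidence(dplyr::bind_rows(graph$statements$evidence[[hit]], ev))
    graph$statements$evidence[[hit]] <- merged
    if (!is.na(pattern)) {
      cur <- graph$statements$pattern[hit]
      # keep merges order-insensitive when tags disagree
      graph$statements$pattern[hit] <- if (is.na(cur)) pattern else min(cur, pattern)
    }
    return(`kg_last_ref<-`(graph, sid))
  }
  row <- tibble::new_tibble(list(
    statement_id = sid, subject = subject, predicate = predicate, object = object,
    negated = negated, likelihood = likelihood,
    aspect = as.character(aspect), direction = as.character(direction),
    pattern = as.character(pattern), evidence = list(ev)
  ), nrow = 1L)
  graph$statements <- dplyr::bind_rows(graph$statements, row)
  `kg_last_ref<-`(graph, sid)
}

# ---- gates ------------------------------------------------------------------

#' Compose entities or statements into an AND/OR gate
#'
#' Gate nodes turn a set of members into one addressable concept: an AND gate
#' is the "ALL" union used for combination therapy ("interferon alfa-2b AND
#' ribavirin"); an OR gate is an alternative set. A gate may then serve as
#' subject or object of statements.
#'
#' @param graph A `cond_kg`.
#' @param gate_type `"AND"` or `"OR"`.
#' @param members Character vector (length >= 2, distinct) of ids of existing
#'   entities, gates, or statements. Order is preserved and part of gate
#'   identity.
#' @return The updated graph; [kg_last_ref()] gives the gate id.
#' @export
kg_make_gate <- function(graph, gate_type, members) {
  stopifnot(inherits(graph, "cond_kg"))
  if (!gate_type %in% c("AND", "OR"))
    stop("gate_type must be 'AND' or 'OR'", call. = FALSE)
  if (length(members) < 2L)
    stop("a gate needs at least 2 members", call. = FALSE)
  if (anyDuplicated(members))
    stop("gate members must be distinct", call. = FALSE)
  kinds <- kg_ref_kind(graph, members)
  if (anyNA(kinds))
    stop("unresolved gate member(s): ",
         paste(members[is.na(kinds)], collapse = ", "), call. = FALSE)
  gid <- paste0("G:", rlang::hash(paste(gate_type, paste(members, collapse = "\x1f"), sep = "\x1e")))
  hit <- which(graph$gates$gate_id == gid)
  if (length(hit)) return(`kg_last_ref<-`(graph, gid))
  # members resolve to pre-existing elements, so no membership cycle can arise
  graph$gates <- dplyr::bind_rows(
    graph$gates,
    tibble::new_tibble(list(gate_id = gid, gate_type = gate_type,
                            members = list(members)), nrow = 1L)
  )
  `kg_last_ref<-`(graph, gid)
}

# ---- edge classes -----------------------------------------------------------

#' Classify a statement as vertex-vertex, vertex-edge, or edge-edge
#'
#' Statements partition into three edge classes: `vv` connects two vertices
#' (entities or gates); `ev` connects a vertex with a statement — the usual
#' encoding of a *condition* on a relationship; `ee` connects two statements —
#' the encoding of *causation* between events.
#'
#' @param graph A `cond_kg`.
#' @param statement_id One or more statement ids.
#' @return Character vector of `"vv"`, `"ev"`, `"ee"`.
#' @export
kg_edge_class <- function(graph, statement_id) {
  idx <- match(statement_id, graph$statements$statement_id)
  if (anyNA(idx))
    stop("unresolved statement(s): ",
         paste(statement_id[is.na(idx)], collapse = ", "), call. = FALSE)
  s_subj <- kg_ref_kind(graph, graph$statements$subject[idx]) == "statement"
  s_obj <- kg_ref_kind(graph, graph$statements$object[idx]) == "statement"
  dplyr::case_when(
    s_subj & s_obj ~ "ee",
    s_subj | s_obj ~ "ev",
    TRUE ~ "vv"
  )
}

# ---- validation -------------------------------------------------------------

violation <- function(ref, rule, message) {
  tibble::tibble(ref = ref, rule = rule, message = message)
}

no_violations <- function() violation(character(), character(), character())

# Kahn topological check over the composite reference graph
# (statements -> referenced statements/gates; gates -> member statements/gates).
detect_reference_cycles <- function(graph) {
  nodes <- c(graph$statements$statement_id, graph$gates$gate_id)
  if (!length(nodes)) return(character())
  edges <- list()
  for (i in seq_len(nrow(graph$statements))) {
    for (ref in c(graph$statements$subject[i], graph$statements$object[i])) {
      if (ref %in% nodes) edges[[length(edges) + 1L]] <- c(graph$statements$statement_id[i], ref)
    }
  }
  for (i in seq_len(nrow(graph$gates))) {
    for (ref in graph$gates$members[[i]]) {
      if (ref %in% nodes) edges[[length(edges) + 1L]] <- c(graph$gates$gate_id[i], ref)
    }
  }
  if (!length(edges)) return(character())
  from <- vapply(edges, `[`, "", 1L)
  to <- vapply(edges, `[`, "", 2L)
  adj <- split(to, factor(from, levels = nodes))
  active <- stats::setNames(as.integer(table(factor(to, levels = nodes))), nodes)
  queue <- names(active)[active == 0L]
  seen <- 0L
  while (length(queue)) {
    n <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (m in adj[[n]]) {
      active[m] <- active[m] - 1L
      if (active[m] == 0L) queue <- c(queue, m)
    }
  }
  if (seen == length(nodes)) character() else names(active)[active > 0L]
}

#' Validate structural invariants of a knowledge graph
#'
#' Checks every invariant the data model promises — dangling references,
#' reference cycles through statements or gates, genotype on non-variant
#' entities, malformed HGVS-looking variant names, predicates outside the
#' configured set, degenerate gates, direction without aspect — and reports
#' all violations rather than stopping at the first.
#'
#' @param graph A `cond_kg`.
#' @return A tibble with columns `ref`, `rule`, `message`; zero rows iff the
#'   graph is well-formed.
#' @export
kg_validate <- function(graph) {
  stopifnot(inherits(graph, "cond_kg"))
  v <- list(no_violations())
  e <- graph$entities
  dup <- e$entity_id[duplicated(e$entity_id)]
  if (length(dup))
    v[[length(v) + 1L]] <- violation(unique(dup), "duplicate_entity_id", "entity_id not unique")
  bad_cat <- !e$category %in% kg_categories()
  if (any(bad_cat))
    v[[length(v) + 1L]] <- violation(e$entity_id[bad_cat], "invalid_category",
                                     paste0("unknown category '", e$category[bad_cat], "'"))
  bad_gt <- !is.na(e$genotype) & e$category != "variant"
  if (any(bad_gt))
    v[[length(v) + 1L]] <- violation(e$entity_id[bad_gt], "genotype_on_non_variant",
                                     "genotype present on a non-variant entity")
  bad_hgvs <- e$category == "variant" & hgvs_like(e$name) & !hgvs_shape_ok(e$name)
  if (any(bad_hgvs))
    v[[length(v) + 1L]] <- violation(e$entity_id[bad_hgvs], "malformed_hgvs",
                                     paste0("HGVS-like name fails shape check: ", e$name[bad_hgvs]))

  gts <- graph$gates
  for (i in seq_len(nrow(gts))) {
    m <- gts$members[[i]]
    if (length(m) < 2L)
      v[[length(v) + 1L]] <- violation(gts$gate_id[i], "gate_arity", "gate has fewer than 2 members")
    if (anyDuplicated(m))
      v[[length(v) + 1L]] <- violation(gts$gate_id[i], "gate_duplicate_member", "duplicate gate members")
    unres <- m[is.na(kg_ref_kind(graph, m))]
    if (length(unres))
      v[[length(v) + 1L]] <- violation(gts$gate_id[i], "dangling_reference",
                                       paste0("unresolved member '", unres, "'"))
    if (!gts$gate_type[i] %in% c("AND", "OR"))
      v[[length(v) + 1L]] <- violation(gts$gate_id[i], "invalid_gate_type",
                                       paste0("unknown gate type '", gts$gate_type[i], "'"))
  }

  s <- graph$statements
  for (i in seq_len(nrow(s))) {
    sid <- s$statement_id[i]
    for (ref in c(s$subject[i], s$object[i])) {
      if (is.na(kg_ref_kind(graph, ref)))
        v[[length(v) + 1L]] <- violation(sid, "dangling_reference",
                                         paste0("unresolved reference '", ref, "'"))
    }
    if (!s$predicate[i] %in% graph$predicates)
      v[[length(v) + 1L]] <- violation(sid, "unknown_predicate",
                                       paste0("predicate '", s$predicate[i], "' not configured"))
    if (!is.na(s$direction[i]) && is.na(s$aspect[i]))
      v[[length(v) + 1L]] <- violation(sid, "direction_without_aspect",
                                       "direction qualifier present without aspect")
    if (identical(s$subject[i], sid) || identical(s$object[i], sid))
      v[[length(v) + 1L]] <- violation(sid, "self_reference", "statement references itself")
  }

  cyc <- detect_reference_cycles(graph)
  if (length(cyc))
    v[[length(v) + 1L]] <- violation(cyc, "reference_cycle",
                                     "element participates in a reference cycle")

  dplyr::bind_rows(v)
}

# ---- small accessors --------------------------------------------------------

entity_by_name <- function(graph, name, category = NULL) {
  e <- graph$entities[graph$entities$name == name, ]
  if (!is.null(category)) e <- e[e$category == category, ]
  e
}

statement_row <- function(graph, sid) {
  idx <- match(sid, graph$statements$statement_id)
  if (is.na(idx)) stop("unresolved statement '", sid, "'", call. = FALSE)
  graph$statements[idx, ]
}
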