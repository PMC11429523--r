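# Condition-aware exploration and inference over a conditional knowledge
# graph: drug-centric views, neighborhood subgraphs, genotype-filtered
# personalized suggestions, pharmacogenomics profiles, synergy reports, and
# shared-mechanism repurposing hypotheses. All operations are read-only,
# deterministic, and return stably ordered tibbles.

#' Resolve an entity by id or (unique) name
#'
#' @param graph A `cond_kg`.
#' @param x An entity id or display name.
#' @param category Optional category restriction.
#' @return The entity id.
#' @export
resolve_entity <- function(graph, x, category = NULL) {
  e <- graph$entities
  if (x %in% e$entity_id) {
    if (!is.null(category) && !category %in% e$category[e$entity_id == x])
      stop("entity '", x, "' is not of category '", category, "'", call. = FALSE)
    return(x)
  }
  hit <- e[e$name == x, ]
  if (!is.null(category)) hit <- hit[hit$category == category, ]
  if (nrow(hit) == 1L) return(hit$entity_id)
  if (nrow(hit) > 1L)
    stop("name '", x, "' is ambiguous: ", paste(hit$entity_id, collapse = ", "),
         call. = FALSE)
  stop("unknown entity '", x, "'", call. = FALSE)
}

entity_name <- function(graph, id) {
  idx <- match(id, graph$entities$entity_id)
  graph$entities$name[idx]
}

# leaf drug entity ids reachable from a reference through gates
leaf_drugs <- function(graph, ref) {
  kind <- kg_ref_kind(graph, ref)
  if (identical(kind, "entity")) {
    if (graph$entities$category[graph$entities$entity_id == ref] == "drug") return(ref)
    return(character())
  }
  if (identical(kind, "gate")) {
    members <- graph$gates$members[[match(ref, graph$gates$gate_id)]]
    return(unique(unlist(lapply(members, leaf_drugs, graph = graph))))
  }
  character()
}

# statements attached to a set of statements (referencing any of them as
# subject or object), closed to fixpoint
attached_closure <- function(graph, ids) {
  s <- graph$statements
  repeat {
    more <- s$statement_id[s$subject %in% ids | s$object %in% ids]
    new <- setdiff(more, ids)
    if (!length(new)) break
    ids <- c(ids, new)
  }
  ids
}

# all statement ids referenced (as subject/object) by sid, recursively
sub_statements <- function(graph, sid) {
  out <- character()
  frontier <- sid
  while (length(frontier)) {
    idx <- match(frontier, graph$statements$statement_id)
    refs <- unique(c(graph$statements$subject[idx], graph$statements$object[idx]))
    nxt <- refs[kg_ref_kind(graph, refs) %in% "statement"]
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Statement cluster around a core statement
#'
#' The cluster is the core statement, every statement it references
#' (recursively — e.g. the reified therapy statement), and every
#' `condition_of` statement targeting any cluster member, to fixpoint.
#'
#' @param graph A `cond_kg`.
#' @param core_id A statement id.
#' @return Character vector of statement ids (core first).
#' @export
cluster_statements <- function(graph, core_id) {
  s <- graph$statements
  members <- unique(c(core_id, sub_statements(graph, core_id)))
  repeat {
    conds <- s$statement_id[s$predicate == "condition_of" & s$object %in% members]
    new <- setdiff(conds, members)
    if (!length(new)) break
    members <- c(members, new)
  }
  members
}

# does the cluster around core_id involve this drug (directly or via gates)?
cluster_involves_drug <- function(graph, cluster_ids, drug_id) {
  idx <- match(cluster_ids, graph$statements$statement_id)
  refs <- unique(c(graph$statements$subject[idx], graph$statements$object[idx]))
  refs <- refs[!kg_ref_kind(graph, refs) %in% "statement"]
  drug_id %in% unique(unlist(lapply(refs, leaf_drugs, graph = graph)))
}

statement_tibble <- function(graph, ids) {
  idx <- match(ids, graph$statements$statement_id)
  s <- graph$statements[idx, ]
  tibble::tibble(
    statement_id = s$statement_id,
    subject = s$subject, predicate = s$predicate, object = s$object,
    negated = s$negated, likelihood = s$likelihood,
    aspect = s$aspect, direction = s$direction, pattern = s$pattern,
    edge_class = if (nrow(s)) kg_edge_class(graph, s$statement_id) else character(),
    evidence = s$evidence
  )
}

#' Drug-centric view: all pattern knowledge involving a drug
#'
#' @param graph A `cond_kg`.
#' @param drug Drug entity id or name.
#' @return Named list of four tibbles (one per knowledge pattern), each
#'   containing every statement of every cluster that involves the drug,
#'   directly or through gate membership.
#' @export
drug_centric_view <- function(graph, drug) {
  drug_id <- resolve_entity(graph, drug, "drug")
  s <- graph$statements
  out <- stats::setNames(vector("list", 4L), kg_patterns())
  for (p in kg_patterns()) {
    cores <- s$statement_id[!is.na(s$pattern) & s$pattern == p]
    hit <- character()
    for (core in cores) {
      cl <- cluster_statements(graph, core)
      if (cluster_involves_drug(graph, cl, drug_id)) hit <- c(hit, cl)
    }
    hit <- sort(unique(hit), method = "radix")
    out[[p]] <- statement_tibble(graph, hit)
  }
  out
}

# ---- neighborhood subgraphs -------------------------------------------------

# Undirected adjacency of the reified property graph (non-auxiliary part):
# subject -- relation-node -- object, gate -- member.
pg_adjacency <- function(graph) {
  s <- graph$statements
  g <- graph$gates
  from <- c(s$subject, s$statement_id,
            rep(g$gate_id, lengths(g$members)))
  to <- c(s$statement_id, s$object, unlist(g$members))
  tibble::tibble(a = c(from, to), b = c(to, from))
}

#' Extract a neighborhood subgraph around seed nodes
#'
#' Breadth-first closure over statement endpoints and condition attachments:
#' a node belongs to the subgraph iff its shortest-path distance on the
#' reified property graph (unit edges, undirected) is at most `2 * radius` —
#' each statement traversal passes through its relation node, so
#' property-graph hops are halved. The result is then closed under statement
#' endpoints and gate members so every reference resolves inside it.
#'
#' @param graph A `cond_kg`.
#' @param seeds Entity/gate/statement ids or entity names.
#' @param radius Non-negative integer; `radius = 0` returns the seeds only.
#' @return A `kg_subgraph`: list with `graph` (the induced `cond_kg`),
#'   `roots`, and `provenance` (per-statement evidence-source note).
#' @export
neighborhood_subgraph <- function(graph, seeds, radius = 1L) {
  stopifnot(radius >= 0L)
  seeds <- vapply(seeds, function(x) {
    if (!is.na(kg_ref_kind(graph, x))) x else resolve_entity(graph, x)
  }, "")
  adj <- pg_adjacency(graph)
  dist <- stats::setNames(rep(0L, length(seeds)), seeds)
  frontier <- seeds
  d <- 0L
  max_d <- 2L * as.integer(radius)
  while (length(frontier) && d < max_d) {
    d <- d + 1L
    nxt <- unique(adj$b[adj$a %in% frontier])
    nxt <- setdiff(nxt, names(dist))
    if (length(nxt)) dist[nxt] <- d
    frontier <- nxt
  }
  keep <- names(dist)
  # closure: endpoints of kept statements, members of kept gates
  repeat {
    s_idx <- match(intersect(keep, graph$statements$statement_id),
                   graph$statements$statement_id)
    g_idx <- match(intersect(keep, graph$gates$gate_id), graph$gates$gate_id)
    need <- unique(c(graph$statements$subject[s_idx], graph$statements$object[s_idx],
                     unlist(graph$gates$members[g_idx])))
    new <- setdiff(need, keep)
    if (!length(new)) break
    keep <- c(keep, new)
  }
  sub_kg <- induced_kg(graph, keep)
  prov <- purrr::map2_dfr(sub_kg$statements$statement_id, sub_kg$statements$evidence,
    function(sid, ev) tibble::tibble(
      statement_id = sid,
      note = if (nrow(ev)) paste(unique(ev$source_db), collapse = "; ")
             else "no recorded evidence"))
  structure(list(graph = sub_kg, roots = unname(seeds), provenance = prov),
            class = "kg_subgraph")
}

induced_kg <- function(graph, keep) {
  out <- kg_new(predicates = graph$predicates)
  out$entities <- graph$entities[graph$entities$entity_id %in% keep, ]
  out$gates <- graph$gates[graph$gates$gate_id %in% keep, ]
  out$statements <- graph$statements[graph$statements$statement_id %in% keep, ]
  out
}

#' @export
print.kg_subgraph <- function(x, ...) {
  cat("<kg_subgraph> roots:", paste(x$roots, collapse = ", "), "\n")
  print(x$graph)
  invisible(x)
}

#' Whole graph as a subgraph
#'
#' @param graph A `cond_kg`.
#' @param roots Optional root ids for presentation.
#' @return A `kg_subgraph` containing the whole graph.
#' @export
as_subgraph <- function(graph, roots = character()) {
  prov <- purrr::map2_dfr(graph$statements$statement_id, graph$statements$evidence,
    function(sid, ev) tibble::tibble(
      statement_id = sid,
      note = if (nrow(ev)) paste(unique(ev$source_db), collapse = "; ")
             else "no recorded evidence"))
  structure(list(graph = graph, roots = roots, provenance = prov),
            class = "kg_subgraph")
}

# ---- conditions -------------------------------------------------------------

#' Conditions attached to a statement
#'
#' Collects every `condition_of` statement targeting the statement or —
#' transitively — any statement it references (e.g. the therapy
#' sub-statement), returning the conditioning entities and their genotypes.
#'
#' @param graph A `cond_kg`.
#' @param statement_id A statement id.
#' @return Tibble: `entity_id`, `name`, `category`, `genotype`,
#'   `condition_statement`.
#' @export
conditions_for <- function(graph, statement_id) {
  if (is.na(kg_ref_kind(graph, statement_id)) ||
      !statement_id %in% graph$statements$statement_id)
    stop("unresolved statement '", statement_id, "'", call. = FALSE)
  targets <- unique(c(statement_id, sub_statements(graph, statement_id)))
  s <- graph$statements
  conds <- s[s$predicate == "condition_of" & s$object %in% targets, ]
  conds <- conds[order(conds$statement_id, method = "radix"), ]
  idx <- match(conds$subject, graph$entities$entity_id)
  keep <- !is.na(idx)
  tibble::tibble(
    entity_id = conds$subject[keep],
    name = graph$entities$name[idx[keep]],
    category = graph$entities$category[idx[keep]],
    genotype = graph$entities$genotype[idx[keep]],
    condition_statement = conds$statement_id[keep]
  )
}

# Genotype matching: exact after trim/case-fold; a genotype-free condition
# matches any genotype of that variant; a single-allele condition ("C")
# matches any genotype containing that allele ("CC", "AC").
genotype_matches <- function(cond_genotype, assigned_genotype) {
  if (is.na(cond_genotype)) return(TRUE)
  cg <- toupper(trimws(cond_genotype))
  ag <- toupper(trimws(assigned_genotype))
  if (cg == ag) return(TRUE)
  nchar(cg) == 1L && grepl(cg, ag, fixed = TRUE)
}

variant_condition_matched <- function(graph, cond_row, assignments) {
  for (j in seq_len(nrow(assignments))) {
    a_var <- assignments$variant[j]
    idx <- match(cond_row$entity_id, graph$entities$entity_id)
    same_variant <- a_var == cond_row$entity_id ||
      identical(a_var, graph$entities$name[idx])
    if (same_variant && genotype_matches(cond_row$genotype, assignments$genotype[j]))
      return(TRUE)
  }
  FALSE
}

# ---- personalized suggestions ----------------------------------------------

therapy_disease <- function(graph, core_row) {
  # disease a pattern cluster is about: object of the core treats statement,
  # or of the therapy sub-statement the core references
  if (core_row$predicate == "treats") return(core_row$object)
  for (ref in c(core_row$subject, core_row$object)) {
    if (identical(kg_ref_kind(graph, ref), "statement")) {
      r <- statement_row(graph, ref)
      if (r$predicate == "treats") return(r$object)
    }
  }
  NA_character_
}

therapy_drug_ref <- function(graph, core_row) {
  if (core_row$predicate == "treats") return(core_row$subject)
  for (ref in c(core_row$subject, core_row$object)) {
    kind <- kg_ref_kind(graph, ref)
    if (identical(kind, "statement")) {
      r <- statement_row(graph, ref)
      if (r$predicate == "treats") return(r$subject)
    }
    if (identical(kind, "entity") &&
        graph$entities$category[graph$entities$entity_id == ref] == "drug")
      return(ref)
    if (identical(kind, "gate")) return(ref)
  }
  NA_character_
}

#' Personalized drug suggestions for a disease and genotype profile
#'
#' Scans every pattern cluster about the disease and keeps statements whose
#' variant-condition set is empty or *fully* matched by the supplied genotype
#' assignments (conjunctive matching; a genotype-free condition matches any
#' genotype of that variant, a single-allele condition matches genotypes
#' carrying the allele). Each surviving statement is labelled from its
#' predicate, qualifiers, and negation: `ineffective` (negated indication),
#' `increased_risk` / `reduced_risk`, `reduced_efficacy`, `no_effect`, or
#' `unconditional` (plain indication).
#'
#' @param graph A `cond_kg`.
#' @param disease Disease entity id or name.
#' @param genotypes Tibble with columns `variant` (entity id or HGVS name)
#'   and `genotype`, or `NULL` for none.
#' @return Tibble: `drug`, `label`, `about`, `matched_conditions`,
#'   `statement_id`, `evidence`; ordered by drug then label.
#' @export
personalized_suggestions <- function(graph, disease, genotypes = NULL) {
  disease_id <- resolve_entity(graph, disease, "disease")
  if (is.null(genotypes))
    genotypes <- tibble::tibble(variant = character(), genotype = character())
  genotypes <- tibble::as_tibble(genotypes)
  s <- graph$statements
  cores <- s[!is.na(s$pattern) | s$predicate %in%
               c("treats", "no_effect_on", "affects_response_to", risk_predicates()), ]
  rows <- list()
  for (i in seq_len(nrow(cores))) {
    core <- cores[i, ]
    if (core$predicate == "condition_of") next
    if (!identical(therapy_disease(graph, core), disease_id)) next
    drug_ref <- therapy_drug_ref(graph, core)
    if (is.na(drug_ref)) next
    conds <- conditions_for(graph, core$statement_id)
    # a variant subject (sensitivity-style statements) is itself a condition
    subj_kind <- kg_ref_kind(graph, core$subject)
    if (identical(subj_kind, "entity")) {
      eidx <- match(core$subject, graph$entities$entity_id)
      if (graph$entities$category[eidx] == "variant") {
        conds <- dplyr::bind_rows(conds, tibble::tibble(
          entity_id = core$subject, name = graph$entities$name[eidx],
          category = "variant", genotype = graph$entities$genotype[eidx],
          condition_statement = core$statement_id))
      }
    }
    vconds <- conds[conds$category == "variant", ]
    matched <- vapply(seq_len(nrow(vconds)), function(j)
      variant_condition_matched(graph, vconds[j, ], genotypes), logical(1))
    if (nrow(vconds) && !all(matched)) next
    label <- suggestion_label(core$predicate, core$negated, core$aspect, core$direction)
    if (is.na(label)) next
    if (label == "unconditional" && nrow(vconds)) label <- "conditional_indication"
    drug_names <- sort(entity_name(graph, leaf_drugs(graph, drug_ref)), method = "radix")
    about <- if (core$predicate %in% risk_predicates())
      entity_name(graph, core$object) else entity_name(graph, disease_id)
    ev <- core$evidence[[1]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      drug = paste(drug_names, collapse = " + "),
      label = label,
      about = about %||% NA_character_,
      matched_conditions = paste(
        sprintf("%s=%s", vconds$name,
                ifelse(is.na(vconds$genotype), "any", vconds$genotype)),
        collapse = "; "),
      statement_id = core$statement_id,
      evidence = paste(stats::na.omit(unique(ev$citation)), collapse = "; ")
    )
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(drug = character(), label = character(), about = character(),
                   matched_conditions = character(), statement_id = character(),
                   evidence = character())
  dplyr::arrange(dplyr::distinct(out), .data$drug, .data$label, .data$statement_id)
}

# ---- pharmacogenomics profile ----------------------------------------------

#' Pharmacogenomics profile of a drug
#'
#' Gathers every mechanism statement of the drug (directional gene
#' expression/activity effects, negated or not) and groups them by the
#' conditioning variant: each variant appears once with all its recorded
#' effects.
#'
#' @param graph A `cond_kg`.
#' @param drug Drug entity id or name.
#' @return Tibble with one row per distinct condition variant: `variant`,
#'   `genotype`, and `effects` (list-column of tibbles with `gene`,
#'   `predicate`, `aspect`, `direction`, `negated`, `evidence`).
#' @export
pharmacogenomics_profile <- function(graph, drug) {
  drug_id <- resolve_entity(graph, drug, "drug")
  s <- graph$statements
  mech <- s[s$predicate %in% mechanism_predicates() & s$subject == drug_id, ]
  # variant-subject response statements about this drug's expression/activity
  drug_targets <- c(drug_id, s$statement_id[s$predicate == "treats" &
    vapply(s$subject, function(r) drug_id %in% leaf_drugs(graph, r), logical(1))])
  resp <- s[s$predicate %in% c("affects_response_to", "no_effect_on") &
            s$object %in% drug_targets &
            (!is.na(s$aspect) & s$aspect %in% c("activity", "expression")), ]
  resp <- resp[kg_ref_kind(graph, resp$subject) %in% "entity", ]
  resp <- resp[graph$entities$category[match(resp$subject, graph$entities$entity_id)] ==
                 "variant", ]
  if (!nrow(mech) && !nrow(resp))
    return(tibble::tibble(variant = character(), genotype = character(),
                          effects = list()))
  eff <- list()
  for (i in seq_len(nrow(mech))) {
    conds <- conditions_for(graph, mech$statement_id[i])
    vconds <- conds[conds$category == "variant", ]
    if (!nrow(vconds))
      vconds <- tibble::tibble(entity_id = NA, name = NA_character_,
                               category = "variant", genotype = NA_character_,
                               condition_statement = NA)
    ev <- mech$evidence[[i]]
    for (j in seq_len(nrow(vconds))) {
      eff[[length(eff) + 1L]] <- tibble::tibble(
        variant = vconds$name[j], genotype = vconds$genotype[j],
        gene = entity_name(graph, mech$object[i]),
        predicate = mech$predicate[i], aspect = mech$aspect[i],
        direction = mech$direction[i], negated = mech$negated[i],
        evidence = paste(stats::na.omit(unique(ev$citation)), collapse = "; "))
    }
  }
  for (i in seq_len(nrow(resp))) {
    eidx <- match(resp$subject[i], graph$entities$entity_id)
    ev <- resp$evidence[[i]]
    eff[[length(eff) + 1L]] <- tibble::tibble(
      variant = graph$entities$name[eidx], genotype = graph$entities$genotype[eidx],
      gene = NA_character_,
      predicate = resp$predicate[i], aspect = resp$aspect[i],
      direction = resp$direction[i], negated = resp$negated[i],
      evidence = paste(stats::na.omit(unique(ev$citation)), collapse = "; "))
  }
  flat <- dplyr::bind_rows(eff)
  flat <- dplyr::arrange(flat, .data$variant, .data$gene, .data$predicate,
                         .data$negated)
  flat |>
    dplyr::group_by(.data$variant, .data$genotype) |>
    tidyr::nest(effects = c("gene", "predicate", "aspect", "direction",
                            "negated", "evidence")) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$variant, .data$genotype)
}

# ---- shared-mechanism repurposing hypotheses --------------------------------

#' Shared-mechanism drug-repurposing hypotheses for a disease
#'
#' For each drug A known to treat the disease and each of A's directional
#' gene-level mechanism statements `(A, p, G)`, finds candidate drugs B
#' (B != A, no existing indication for the disease) sharing a mechanism
#' statement with the same predicate direction on the same gene G. Candidates
#' are ranked by the number of distinct bridging genes, ties broken by drug
#' name; the supporting statement chain is returned for re-validation.
#'
#' @param graph A `cond_kg`.
#' @param disease Disease entity id or name.
#' @return Tibble: `candidate`, `candidate_name`, `disease`, `genes`
#'   (list-column of gene ids), `score`, `chain` (list-column of statement
#'   ids).
#' @export
shared_mechanism_candidates <- function(graph, disease) {
  disease_id <- resolve_entity(graph, disease, "disease")
  s <- graph$statements
  treats <- s[s$predicate == "treats" & s$object == disease_id, ]
  treating_drugs <- unique(unlist(lapply(
    treats$subject[!treats$negated], leaf_drugs, graph = graph)))
  all_linked <- unique(unlist(lapply(treats$subject, leaf_drugs, graph = graph)))
  mech <- s[s$predicate %in% mechanism_predicates() & !s$negated, ]
  mech <- mech[kg_ref_kind(graph, mech$subject) %in% "entity", ]
  if (!nrow(mech) || !length(treating_drugs)) {
    return(tibble::tibble(candidate = character(), candidate_name = character(),
                          disease = character(), genes = list(),
                          score = integer(), chain = list()))
  }
  hyp <- list()
  for (a in treating_drugs) {
    a_mech <- mech[mech$subject == a, ]
    a_treats <- treats$statement_id[!treats$negated &
      vapply(treats$subject, function(r) a %in% leaf_drugs(graph, r), logical(1))]
    for (i in seq_len(nrow(a_mech))) {
      gene <- a_mech$object[i]
      pred <- a_mech$predicate[i]
      cands <- mech[mech$object == gene & mech$predicate == pred &
                    mech$subject != a, ]
      cands <- cands[!cands$subject %in% all_linked, ]
      for (j in seq_len(nrow(cands))) {
        hyp[[length(hyp) + 1L]] <- tibble::tibble(
          candidate = cands$subject[j], gene = gene,
          chain = list(c(a_treats, a_mech$statement_id[i], cands$statement_id[j])))
      }
    }
  }
  if (!length(hyp)) {
    return(tibble::tibble(candidate = character(), candidate_name = character(),
                          disease = character(), genes = list(),
                          score = integer(), chain = list()))
  }
  flat <- dplyr::bind_rows(hyp)
  out <- flat |>
    dplyr::group_by(.data$candidate) |>
    dplyr::summarise(
      genes = list(sort(unique(.data$gene), method = "radix")),
      score = length(unique(.data$gene)),
      chain = list(sort(unique(unlist(.data$chain)), method = "radix")),
      .groups = "drop") |>
    dplyr::mutate(candidate_name = entity_name(graph, .data$candidate),
                  disease = disease_id) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$candidate_name)
  out[, c("candidate", "candidate_name", "disease", "genes", "score", "chain")]
}

# ---- medication synergy -----------------------------------------------------

#' Medication synergy report
#'
#' Compares knowledge about a set of drugs used individually and in
#' combination. Three sections: `individual` — statements from clusters
#' involving each drug on its own (not through a gate); `combinations` —
#' statements about AND/OR gates whose drug members exactly equal or partly
#' overlap the query set; `divergences` — risk statements that hold only
#' under specific conditions, i.e. where one member's risk profile diverges
#' from the unconditional picture.
#'
#' @param graph A `cond_kg`.
#' @param drugs Character vector of drug ids or names (length >= 1).
#' @return A `kg_synergy_report`: list of tibbles `individual`,
#'   `combinations`, `divergences`.
#' @export
synergy_report <- function(graph, drugs) {
  stopifnot(length(drugs) >= 1L)
  drug_ids <- vapply(drugs, resolve_entity, "", graph = graph, category = "drug")
  s <- graph$statements

  individual <- list()
  for (d in drug_ids) {
    direct <- s$statement_id[s$subject == d | s$object == d]
    cl <- sort(unique(unlist(lapply(direct, cluster_statements, graph = graph))),
               method = "radix")
    # attached statements (risks on the drug's therapy events)
    attached <- s$statement_id[vapply(seq_len(nrow(s)), function(i) {
      refs <- c(s$subject[i], s$object[i])
      any(refs %in% direct)
    }, logical(1))]
    ids <- sort(unique(c(cl, attached)), method = "radix")
    ids <- ids[vapply(ids, function(sid)
      cluster_involves_drug(graph, cluster_statements(graph, sid), d), logical(1))]
    tab <- statement_tibble(graph, ids)
    if (nrow(tab))
      individual[[length(individual) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(drug = entity_name(graph, d)), tab)
  }
  individual <- if (length(individual)) dplyr::bind_rows(individual) else
    dplyr::bind_cols(tibble::tibble(drug = character()), statement_tibble(graph, character()))

  combos <- list()
  g <- graph$gates
  for (i in seq_len(nrow(g))) {
    members <- leaf_drugs(graph, g$gate_id[i])
    inter <- intersect(members, drug_ids)
    if (!length(inter)) next
    overlap <- if (setequal(members, drug_ids)) "exact" else "partial"
    touching <- s$statement_id[s$subject == g$gate_id[i] | s$object == g$gate_id[i]]
    ids <- attached_closure(graph, touching)
    ids <- sort(unique(unlist(lapply(ids, cluster_statements, graph = graph))),
                method = "radix")
    tab <- statement_tibble(graph, ids)
    combos[[length(combos) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(gate_id = g$gate_id[i], gate_type = g$gate_type[i],
                     members = paste(sort(entity_name(graph, members), method = "radix"),
                                     collapse = " + "),
                     overlap = overlap),
      tab)
  }
  combinations <- if (length(combos)) dplyr::bind_rows(combos) else
    dplyr::bind_cols(tibble::tibble(gate_id = character(), gate_type = character(),
                                    members = character(), overlap = character()),
                     statement_tibble(graph, character()))

  div <- list()
  risk <- s[s$predicate %in% risk_predicates(), ]
  for (i in seq_len(nrow(risk))) {
    sid <- risk$statement_id[i]
    cl <- cluster_statements(graph, sid)
    involved <- drug_ids[vapply(drug_ids, function(d)
      cluster_involves_drug(graph, cl, d), logical(1))]
    if (!length(involved)) next
    conds <- conditions_for(graph, sid)
    vconds <- conds[conds$category == "variant", ]
    if (!nrow(vconds)) next
    counterpart <- risk[risk$object == risk$object[i] &
                        risk$statement_id != sid &
                        risk$negated != risk$negated[i], ]
    div[[length(div) + 1L]] <- tibble::tibble(
      drug = paste(sort(entity_name(graph, involved), method = "radix"),
                   collapse = " + "),
      phenotype = entity_name(graph, risk$object[i]),
      negated = risk$negated[i],
      conditions = paste(sprintf("%s=%s", vconds$name,
                                 ifelse(is.na(vconds$genotype), "any", vconds$genotype)),
                         collapse = "; "),
      differs_from_unconditional = nrow(counterpart) > 0L,
      statement_id = sid)
  }
  divergences <- if (length(div))
    dplyr::arrange(dplyr::bind_rows(div), .data$drug, .data$phenotype, .data$statement_id)
  else tibble::tibble(drug = character(), phenotype = character(), negated = logical(),
                      conditions = character(), differs_from_unconditional = logical(),
                      statement_id = character())

  structure(list(individual = individual, combinations = combinations,
                 divergences = divergences),
            class = "kg_synergy_report")
}

#' @export
print.kg_synergy_report <- function(x, ...) {
  cat("<kg_synergy_report>\n")
  cat("  individual statements:", nrow(x$individual), "\n")
  cat("  combination statements:", nrow(x$combinations), "\n")
  cat("  condition-dependent divergences:", nrow(x$divergences), "\n")
  invisible(x)
}
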