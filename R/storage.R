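# Reification of the hypergraph into a conventional property graph.
#
# Every statement becomes a relation node carrying its predicate and
# modifier/qualifier properties; a "from" edge runs subject-node ->
# relation-node and a "to" edge relation-node -> object-node, so statements
# about statements simply attach to the target statement's relation node.
# Gates become gate nodes with ordered "member" edges; evidence items become
# auxiliary nodes hung off the relation node with "evidence" edges. All node
# and edge ids are deterministic functions of the source ids, making reify a
# pure function.

pg_node_columns <- c(
  "node_id", "kind", "name", "category", "external_id", "synonyms", "genotype",
  "gate_type", "predicate", "negated", "likelihood", "aspect", "direction",
  "pattern", "source_db", "citation", "sentence"
)

empty_pg <- function() {
  nodes <- tibble::as_tibble(stats::setNames(
    rep(list(character()), length(pg_node_columns)), pg_node_columns))
  edges <- tibble::tibble(edge_id = character(), label = character(),
                          source = character(), target = character())
  structure(list(nodes = nodes, edges = edges), class = "cond_pg")
}

#' @export
print.cond_pg <- function(x, ...) {
  cat("<cond_pg>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$nodes)) {
    tab <- table(x$nodes$kind)
    cat("  nodes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Reify a knowledge graph into a property graph
#'
#' Translates the hypergraph into a node/edge form storable in any
#' conventional graph database: entity, gate, relation, and auxiliary
#' (evidence) nodes, with `from`/`to` edges routing each relationship through
#' its relation node, ordered `member` edges for gates, and `evidence` edges
#' to auxiliary nodes. The translation is lossless: [unreify()] inverts it
#' exactly.
#'
#' @param graph A `cond_kg` that passes [kg_validate()] cleanly.
#' @return A `cond_pg`: list of `nodes` and `edges` tibbles (all property
#'   values stored as strings; `NA` = absent).
#' @export
reify <- function(graph) {
  stopifnot(inherits(graph, "cond_kg"))
  viol <- kg_validate(graph)
  if (nrow(viol))
    stop("graph does not validate: ", nrow(viol), " violation(s); see kg_validate()",
         call. = FALSE)
  nodes <- list()
  edges <- list()
  node_row <- function(node_id, kind, ...) {
    props <- c(list(...))
    row <- stats::setNames(rep(NA_character_, length(pg_node_columns)), pg_node_columns)
    row[["node_id"]] <- node_id
    row[["kind"]] <- kind
    for (k in names(props)) row[[k]] <- as.character(props[[k]])
    nodes[[length(nodes) + 1L]] <<- row
  }
  add_edge <- function(label, source, target, ord = NULL) {
    eid <- if (is.null(ord)) paste0("E:", label, ":", source, ":", target)
           else paste0("E:", label, ":", source, ":", sprintf("%04d", ord), ":", target)
    edges[[length(edges) + 1L]] <<- c(eid, label, source, target)
  }

  e <- graph$entities
  for (i in seq_len(nrow(e))) {
    node_row(e$entity_id[i], "entity", name = e$name[i], category = e$category[i],
      external_id = e$external_id[i],
      synonyms = if (length(e$synonyms[[i]])) paste(e$synonyms[[i]], collapse = "|") else NA_character_,
      genotype = e$genotype[i])
  }
  g <- graph$gates
  for (i in seq_len(nrow(g))) {
    node_row(g$gate_id[i], "gate", gate_type = g$gate_type[i])
    for (j in seq_along(g$members[[i]]))
      add_edge("member", g$gate_id[i], g$members[[i]][j], ord = j)
  }
  s <- graph$statements
  for (i in seq_len(nrow(s))) {
    sid <- s$statement_id[i]
    node_row(sid, "relation", predicate = s$predicate[i],
      negated = tolower(s$negated[i]), likelihood = s$likelihood[i],
      aspect = s$aspect[i], direction = s$direction[i], pattern = s$pattern[i])
    add_edge("from", s$subject[i], sid)
    add_edge("to", sid, s$object[i])
    ev <- s$evidence[[i]]
    for (j in seq_len(nrow(ev))) {
      aux_id <- paste0(sid, ":aux:", rlang::hash(paste(
        ev$source_db[j], ev$citation[j], ev$sentence[j], sep = "\x1f")))
      node_row(aux_id, "auxiliary", source_db = ev$source_db[j],
        citation = ev$citation[j], sentence = ev$sentence[j])
      add_edge("evidence", sid, aux_id)
    }
  }
  pg <- empty_pg()
  if (length(nodes)) {
    m <- do.call(rbind, nodes)
    pg$nodes <- tibble::new_tibble(
      stats::setNames(lapply(seq_len(ncol(m)), function(j) unname(m[, j])),
                      pg_node_columns), nrow = nrow(m))
  }
  if (length(edges)) {
    m <- do.call(rbind, edges)
    pg$edges <- tibble::new_tibble(
      list(edge_id = unname(m[, 1]), label = unname(m[, 2]),
           source = unname(m[, 3]), target = unname(m[, 4])), nrow = nrow(m))
  }
  pg
}

#' Validate property-graph invariants
#'
#' @param pg A `cond_pg`.
#' @return A tibble of violations (`ref`, `rule`, `message`); zero rows iff
#'   the property graph is well-formed.
#' @export
pg_validate <- function(pg) {
  v <- list(no_violations())
  known <- c("entity", "relation", "gate", "auxiliary")
  bad <- !pg$nodes$kind %in% known
  if (any(bad))
    v[[length(v) + 1L]] <- violation(pg$nodes$node_id[bad], "unknown_kind",
                                     paste0("unknown node kind '", pg$nodes$kind[bad], "'"))
  dangling <- !(pg$edges$source %in% pg$nodes$node_id & pg$edges$target %in% pg$nodes$node_id)
  if (any(dangling))
    v[[length(v) + 1L]] <- violation(pg$edges$edge_id[dangling], "dangling_edge",
                                     "edge endpoint does not resolve")
  rel <- pg$nodes$node_id[pg$nodes$kind == "relation"]
  n_from <- table(factor(pg$edges$target[pg$edges$label == "from"], levels = rel))
  n_to <- table(factor(pg$edges$source[pg$edges$label == "to"], levels = rel))
  bad_from <- rel[as.integer(n_from) != 1L]
  bad_to <- rel[as.integer(n_to) != 1L]
  if (length(bad_from))
    v[[length(v) + 1L]] <- violation(bad_from, "relation_from_arity",
                                     "relation node must have exactly one 'from' edge")
  if (length(bad_to))
    v[[length(v) + 1L]] <- violation(bad_to, "relation_to_arity",
                                     "relation node must have exactly one 'to' edge")
  dplyr::bind_rows(v)
}

#' Reconstruct a knowledge graph from its reified property graph
#'
#' Inverse of [reify()]: `unreify(reify(g))` is structurally identical to `g`
#' (same entities, gates, statements, modifiers, qualifiers, evidence). The
#' property graph must satisfy [pg_validate()].
#'
#' @param pg A `cond_pg`.
#' @return A `cond_kg`.
#' @export
unreify <- function(pg) {
  viol <- pg_validate(pg)
  if (nrow(viol))
    stop("property graph invalid: ", paste(unique(viol$rule), collapse = ", "),
         call. = FALSE)
  n <- pg$nodes
  graph <- kg_new()

  ent <- n[n$kind == "entity", ]
  for (i in seq_len(nrow(ent))) {
    syn <- ent$synonyms[i]
    syn <- if (is.na(syn) || !nzchar(syn)) character() else strsplit(syn, "|", fixed = TRUE)[[1]]
    graph <- kg_add_entity(graph, ent$node_id[i], ent$name[i], ent$category[i],
                           external_id = ent$external_id[i], synonyms = syn,
                           genotype = ent$genotype[i])
  }

  from_edges <- pg$edges[pg$edges$label == "from", ]
  to_edges <- pg$edges[pg$edges$label == "to", ]
  member_edges <- pg$edges[pg$edges$label == "member", ]
  member_edges <- member_edges[order(member_edges$edge_id, method = "radix"), ]
  ev_edges <- pg$edges[pg$edges$label == "evidence", ]
  aux <- n[n$kind == "auxiliary", ]

  # gates and relation nodes may reference each other; insert in passes
  pending_gates <- n$node_id[n$kind == "gate"]
  pending_rels <- n$node_id[n$kind == "relation"]
  observed_preds <- unique(stats::na.omit(n$predicate))
  graph$predicates <- sort(unique(c(graph$predicates, observed_preds)))
  repeat {
    progress <- FALSE
    for (gid in pending_gates) {
      members <- member_edges$target[member_edges$source == gid]
      if (all(!is.na(kg_ref_kind(graph, members)))) {
        gt <- n$gate_type[n$node_id == gid]
        g2 <- kg_make_gate(graph, gt, members)
        if (!identical(kg_last_ref(g2), gid))
          stop("gate id mismatch on unreify: stored '", gid, "'", call. = FALSE)
        graph <- g2
        pending_gates <- setdiff(pending_gates, gid)
        progress <- TRUE
      }
    }
    for (sid in pending_rels) {
      subj <- from_edges$source[from_edges$target == sid]
      obj <- to_edges$target[to_edges$source == sid]
      if (!is.na(kg_ref_kind(graph, subj)) && !is.na(kg_ref_kind(graph, obj))) {
        row <- n[n$node_id == sid, ]
        aux_ids <- ev_edges$target[ev_edges$source == sid]
        ev <- aux[match(aux_ids, aux$node_id), c("source_db", "citation", "sentence")]
        ev <- if (nrow(ev)) tibble::as_tibble(ev) else empty_evidence()
        g2 <- kg_add_statement(graph, subj, row$predicate, obj,
                               negated = identical(row$negated, "true"),
                               likelihood = row$likelihood,
                               aspect = row$aspect, direction = row$direction,
                               pattern = row$pattern, evidence = ev)
        if (!identical(kg_last_ref(g2), sid))
          stop("statement id mismatch on unreify: stored '", sid, "'", call. = FALSE)
        graph <- g2
        pending_rels <- setdiff(pending_rels, sid)
        progress <- TRUE
      }
    }
    if (!length(pending_gates) && !length(pending_rels)) break
    if (!progress)
      stop("unresolvable references among relation/gate nodes: ",
           paste(c(pending_gates, pending_rels), collapse = ", "), call. = FALSE)
  }
  graph
}

#' Export a property graph as bulk-import CSV tables
#'
#' Writes `nodes.csv` (id, kind, then one column per property) and
#' `edges.csv` (id, label, source, target) in standard RFC-4180 CSV, the
#' dialect expected by common graph-database bulk importers. Absent
#' properties are written as empty fields.
#'
#' @param pg A `cond_pg`.
#' @param dir Destination directory (created if missing).
#' @return Invisibly, the paths of the two files written.
#' @export
export_bulk_csv <- function(pg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nodes_path <- file.path(dir, "nodes.csv")
  edges_path <- file.path(dir, "edges.csv")
  readr::write_csv(pg$nodes, nodes_path, na = "")
  readr::write_csv(pg$edges, edges_path, na = "")
  invisible(c(nodes = nodes_path, edges = edges_path))
}

#' Read a property graph back from bulk CSV tables
#'
#' @param dir Directory containing `nodes.csv` and `edges.csv` as written by
#'   [export_bulk_csv()].
#' @return A `cond_pg`.
#' @export
import_bulk_csv <- function(dir) {
  nodes <- readr::read_csv(file.path(dir, "nodes.csv"), na = "",
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  edges <- readr::read_csv(file.path(dir, "edges.csv"), na = "",
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  pg <- empty_pg()
  if (nrow(nodes)) pg$nodes <- tibble::as_tibble(nodes)[, pg_node_columns]
  if (nrow(edges)) pg$edges <- tibble::as_tibble(edges)
  pg
}
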