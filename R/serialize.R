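# Canonical JSON Lines serialization: one record per entity/gate/statement,
# keys sorted within each record, records sorted by id in C-locale order.
# The export is a pure function of graph content, so export .. import ..
# export is byte-identical — this canonical form also defines structural
# graph equality and makes merges diffable and order-insensitive.

record_json <- function(rec) {
  rec <- rec[order(names(rec), method = "radix")]
  jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null", null = "null", digits = NA)
}

#' Canonical JSON Lines form of a knowledge graph
#'
#' @param graph A `cond_kg`.
#' @return Character vector, one JSON record per element, in canonical order.
#' @export
kg_canonical_lines <- function(graph) {
  stopifnot(inherits(graph, "cond_kg"))
  lines <- character()
  ids <- character()
  e <- graph$entities
  for (i in seq_len(nrow(e))) {
    rec <- list(type = "entity", entity_id = e$entity_id[i], name = e$name[i],
                category = e$category[i], external_id = e$external_id[i],
                synonyms = I(as.character(e$synonyms[[i]])), genotype = e$genotype[i])
    lines <- c(lines, record_json(rec)); ids <- c(ids, e$entity_id[i])
  }
  g <- graph$gates
  for (i in seq_len(nrow(g))) {
    rec <- list(type = "gate", gate_id = g$gate_id[i], gate_type = g$gate_type[i],
                members = I(as.character(g$members[[i]])))
    lines <- c(lines, record_json(rec)); ids <- c(ids, g$gate_id[i])
  }
  s <- graph$statements
  for (i in seq_len(nrow(s))) {
    ev <- canonical_evidence(s$evidence[[i]])
    ev_list <- lapply(seq_len(nrow(ev)), function(j)
      list(citation = ev$citation[j], sentence = ev$sentence[j], source_db = ev$source_db[j]))
    rec <- list(type = "statement", statement_id = s$statement_id[i],
                subject = s$subject[i], predicate = s$predicate[i],
                object = s$object[i], negated = s$negated[i],
                likelihood = s$likelihood[i], aspect = s$aspect[i],
                direction = s$direction[i], pattern = s$pattern[i],
                evidence = ev_list)
    lines <- c(lines, record_json(rec)); ids <- c(ids, s$statement_id[i])
  }
  if (anyDuplicated(ids)) stop("duplicate ids in graph", call. = FALSE)
  as.character(lines[order(ids, method = "radix")])
}

#' Export a knowledge graph to canonical JSON Lines
#'
#' @param graph A `cond_kg` that validates cleanly.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
export_canonical <- function(graph, path) {
  viol <- kg_validate(graph)
  if (nrow(viol))
    stop("graph does not validate: ", nrow(viol), " violation(s)", call. = FALSE)
  writeLines(kg_canonical_lines(graph), path, useBytes = TRUE)
  invisible(path)
}

json_field <- function(rec, key, line_no, required = TRUE) {
  val <- rec[[key]]
  if (is.null(val)) {
    if (required)
      stop("line ", line_no, ": missing field '", key, "'", call. = FALSE)
    return(NA_character_)
  }
  if (length(val) != 1L || is.na(val)) return(NA_character_)
  as.character(val)
}

#' Import a knowledge graph from canonical JSON Lines
#'
#' Records may appear in any order; gates and statements are inserted once
#' their references resolve. Malformed records, unknown record types or
#' categories, and duplicate ids raise errors naming the offending line.
#'
#' @param path A file written by [export_canonical()] (or equivalent).
#' @return A `cond_kg`.
#' @export
import_canonical <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  graph <- kg_new()
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) stop("line ", i, ": malformed JSON record",
                                             call. = FALSE))
    if (is.null(rec$type) || !rec$type %in% c("entity", "gate", "statement"))
      stop("line ", i, ": unknown record type '", rec$type %||% "", "'", call. = FALSE)
    recs[[i]] <- rec
  }
  types <- vapply(recs, function(r) r$type, "")
  seen_ids <- character()

  for (i in which(types == "entity")) {
    rec <- recs[[i]]
    eid <- json_field(rec, "entity_id", i)
    if (eid %in% seen_ids) stop("line ", i, ": duplicate id '", eid, "'", call. = FALSE)
    cat <- json_field(rec, "category", i)
    if (!cat %in% kg_categories())
      stop("line ", i, ": unknown category '", cat, "'", call. = FALSE)
    graph <- kg_add_entity(
      graph, eid, json_field(rec, "name", i), cat,
      external_id = json_field(rec, "external_id", i, required = FALSE),
      synonyms = as.character(rec$synonyms %||% character()),
      genotype = json_field(rec, "genotype", i, required = FALSE))
    seen_ids <- c(seen_ids, eid)
  }

  pending <- which(types != "entity")
  # predicate set: defaults plus anything the file uses
  preds <- unlist(lapply(recs[types == "statement"], function(r) r$predicate))
  graph$predicates <- sort(unique(c(graph$predicates, as.character(preds))))
  repeat {
    progress <- FALSE
    still <- integer()
    for (i in pending) {
      rec <- recs[[i]]
      if (rec$type == "gate") {
        members <- as.character(rec$members %||% character())
        if (any(is.na(kg_ref_kind(graph, members)))) { still <- c(still, i); next }
        gid <- json_field(rec, "gate_id", i)
        if (gid %in% seen_ids) stop("line ", i, ": duplicate id '", gid, "'", call. = FALSE)
        g2 <- kg_make_gate(graph, json_field(rec, "gate_type", i), members)
        if (!identical(kg_last_ref(g2), gid))
          stop("line ", i, ": stored gate id does not match content", call. = FALSE)
        graph <- g2; seen_ids <- c(seen_ids, gid); progress <- TRUE
      } else {
        subj <- json_field(rec, "subject", i)
        obj <- json_field(rec, "object", i)
        if (is.na(kg_ref_kind(graph, subj)) || is.na(kg_ref_kind(graph, obj))) {
          still <- c(still, i); next
        }
        sid <- json_field(rec, "statement_id", i)
        if (sid %in% seen_ids) stop("line ", i, ": duplicate id '", sid, "'", call. = FALSE)
        ev <- rec$evidence
        ev <- if (is.data.frame(ev) && nrow(ev))
          tibble::tibble(source_db = as.character(ev$source_db),
                         citation = as.character(ev$citation),
                         sentence = as.character(ev$sentence))
        else empty_evidence()
        g2 <- kg_add_statement(
          graph, subj, json_field(rec, "predicate", i), obj,
          negated = isTRUE(rec$negated),
          likelihood = json_field(rec, "likelihood", i),
          aspect = json_field(rec, "aspect", i, required = FALSE),
          direction = json_field(rec, "direction", i, required = FALSE),
          pattern = json_field(rec, "pattern", i, required = FALSE),
          evidence = ev)
        if (!identical(kg_last_ref(g2), sid))
          stop("line ", i, ": stored statement id does not match content", call. = FALSE)
        graph <- g2; seen_ids <- c(seen_ids, sid); progress <- TRUE
      }
    }
    pending <- still
    if (!length(pending)) break
    if (!progress)
      stop("line ", pending[1], ": unresolvable reference(s)", call. = FALSE)
  }
  graph
}

#' Structural equality of knowledge graphs
#'
#' Two graphs are equal iff their canonical JSON Lines exports are identical:
#' same entities, gates, statements, modifiers, qualifiers, and evidence,
#' irrespective of insertion order.
#'
#' @param g1,g2 `cond_kg` objects.
#' @return Logical scalar.
#' @export
kg_equal <- function(g1, g2) {
  norm <- function(g) {
    e <- g$entities[order(g$entities$entity_id, method = "radix"), ]
    gt <- g$gates[order(g$gates$gate_id, method = "radix"), ]
    s <- g$statements[order(g$statements$statement_id, method = "radix"), ]
    list(entities = lapply(as.list(e), unname),
         gates = lapply(as.list(gt), unname),
         statements = lapply(as.list(s), unname),
         predicates = g$predicates)
  }
  identical(norm(g1), norm(g2))
}
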