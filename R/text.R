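# Deterministic verbalization of subgraphs and strictly grounded prompt
# construction. Rendering never mentions an entity absent from the input
# subgraph; language-model invocation stays behind a plain callback so the
# package itself never needs network access.

#' The four built-in interpretation scenarios
#'
#' @return Tibble: `scenario_id`, `template` (prompt skeleton with
#'   `{{facts}}` and `{{constraint}}` slots). Templates live in editable
#'   plain-text files under `inst/templates/`.
#' @export
scenarios <- function() {
  ids <- c("knowledge_unit", "multi_evidence", "personalized_suggestion", "synergy")
  tpl <- vapply(ids, function(id) {
    path <- system.file("templates", paste0(id, ".txt"), package = "condkg")
    if (!nzchar(path)) stop("missing template for scenario '", id, "'", call. = FALSE)
    paste(readLines(path, warn = FALSE), collapse = "\n")
  }, "")
  tibble::tibble(scenario_id = ids, template = unname(tpl))
}

grounding_constraint <- function() {
  paste("Use only the facts listed above. Do not introduce any drug, disease,",
        "phenotype, gene, variant, or relationship that is not stated in the",
        "fact list. If the facts are insufficient, say so.")
}

# ---- verbalization ----------------------------------------------------------

predicate_phrase <- function(predicate, negated, likelihood, aspect, direction) {
  adv <- switch(likelihood, probable = "probably ", possible = "possibly ", "")
  base <- switch(predicate,
    treats = if (negated) "does not treat" else "treats",
    increases_risk_of = if (negated) "does not increase the risk of"
                        else "increases the risk of",
    causes = if (negated) "does not cause" else "causes",
    associated_with = if (negated) "is not associated with" else "is associated with",
    condition_of = "is a condition of",
    leads_to = if (negated) "does not lead to" else "leads to",
    no_effect_on = "has no effect on",
    increases_expression_of = if (negated) "does not increase the expression of"
                              else "increases the expression of",
    decreases_expression_of = if (negated) "does not decrease the expression of"
                              else "decreases the expression of",
    increases_activity_of = if (negated) "does not increase the activity of"
                            else "increases the activity of",
    decreases_activity_of = if (negated) "does not decrease the activity of"
                            else "decreases the activity of",
    affects_response_to = {
      a <- if (is.na(aspect)) "response" else gsub("_", " ", aspect)
      if (negated) paste0("does not affect the ", a, " of")
      else if (identical(direction, "decreased")) paste0("decreases the ", a, " of")
      else if (identical(direction, "increased")) paste0("increases the ", a, " of")
      else if (identical(direction, "none")) paste0("does not change the ", a, " of")
      else paste0("affects the ", a, " of")
    },
    if (negated) paste("does not", gsub("_", " ", predicate))
    else gsub("_", " ", predicate)
  )
  paste0(adv, base)
}

ref_phrase <- function(graph, ref) {
  kind <- kg_ref_kind(graph, ref)
  if (identical(kind, "entity")) {
    idx <- match(ref, graph$entities$entity_id)
    nm <- graph$entities$name[idx]
    gt <- graph$entities$genotype[idx]
    if (!is.na(gt)) paste0(nm, " [", gt, "]") else nm
  } else if (identical(kind, "gate")) {
    g <- graph$gates[match(ref, graph$gates$gate_id), ]
    sep <- if (g$gate_type == "AND") " and " else " or "
    paste(vapply(g$members[[1]], ref_phrase, "", graph = graph), collapse = sep)
  } else if (identical(kind, "statement")) {
    paste0("the event that ", statement_clause(graph, ref))
  } else {
    stop("unresolved reference '", ref, "'", call. = FALSE)
  }
}

statement_clause <- function(graph, sid) {
  s <- statement_row(graph, sid)
  paste(ref_phrase(graph, s$subject),
        predicate_phrase(s$predicate, s$negated, s$likelihood, s$aspect, s$direction),
        ref_phrase(graph, s$object))
}

statement_sentence <- function(graph, sid) {
  clause <- statement_clause(graph, sid)
  conds <- graph$statements[graph$statements$predicate == "condition_of" &
                            graph$statements$object == sid, ]
  cond_clause <- ""
  if (nrow(conds)) {
    phrases <- sort(vapply(conds$subject, ref_phrase, "", graph = graph),
                    method = "radix")
    cond_clause <- paste0(", given ", paste(phrases, collapse = " and "))
  }
  paste0(toupper(substr(clause, 1, 1)), substr(clause, 2, nchar(clause)),
         cond_clause, ".")
}

#' Render a subgraph as grounded natural language
#'
#' Emits one deterministic sentence per non-condition statement (sorted by
#' statement id), with negation and likelihood rendered as explicit wording
#' and conditions folded into a "given ..." clause. Identical inputs give
#' byte-identical output.
#'
#' @param subgraph A `kg_subgraph` (or a whole `cond_kg`).
#' @param scenario One of the four scenario ids from [scenarios()].
#' @return A `kg_rendered_text`: list with `text`, `fact_list` (the
#'   statements verbalized), and `grounding_ok`.
#' @export
render_subgraph <- function(subgraph, scenario = "knowledge_unit") {
  if (inherits(subgraph, "cond_kg")) subgraph <- as_subgraph(subgraph)
  stopifnot(inherits(subgraph, "kg_subgraph"))
  if (!scenario %in% scenarios()$scenario_id)
    stop("unknown scenario '", scenario, "'", call. = FALSE)
  g <- subgraph$graph
  ids <- sort(g$statements$statement_id[g$statements$predicate != "condition_of"],
              method = "radix")
  sentences <- vapply(ids, statement_sentence, "", graph = g)
  text <- paste(sentences, collapse = "\n")
  rendered <- structure(
    list(text = text, fact_list = statement_tibble(g, ids), grounding_ok = NA),
    class = "kg_rendered_text")
  rendered$grounding_ok <- grounding_check(text, subgraph)
  rendered
}

#' @export
print.kg_rendered_text <- function(x, ...) {
  cat(x$text, "\n")
  cat("-- facts:", nrow(x$fact_list), "| grounded:", x$grounding_ok, "\n")
  invisible(x)
}

#' Check that a text only names entities present in a subgraph
#'
#' Scans `text` for occurrences of every name in `universe` (fixed-string,
#' case-insensitive) and verifies that each found name belongs to the
#' subgraph. With the default universe (the subgraph's own names) this
#' asserts internal consistency; pass the full graph's names to detect
#' leakage of outside entities.
#'
#' @param text A string (rendered text or prompt).
#' @param subgraph A `kg_subgraph` or `cond_kg`.
#' @param universe Character vector of candidate names to scan for; defaults
#'   to the subgraph's names.
#' @return Logical scalar.
#' @export
grounding_check <- function(text, subgraph, universe = NULL) {
  g <- if (inherits(subgraph, "kg_subgraph")) subgraph$graph else subgraph
  allowed <- tolower(g$entities$name)
  if (is.null(universe)) universe <- g$entities$name
  found <- universe[vapply(tolower(universe), grepl, logical(1),
                           x = tolower(text), fixed = TRUE)]
  all(tolower(found) %in% allowed)
}

#' Build a strictly grounded prompt for a scenario
#'
#' The prompt embeds (i) the scenario instruction, (ii) the verbalized fact
#' list, and (iii) an explicit constraint to use only the listed facts. It
#' contains no entity name absent from the subgraph.
#'
#' @inheritParams render_subgraph
#' @return A single prompt string.
#' @export
build_prompt <- function(subgraph, scenario = "knowledge_unit") {
  sc <- scenarios()
  idx <- match(scenario, sc$scenario_id)
  if (is.na(idx)) stop("unknown scenario '", scenario, "'", call. = FALSE)
  rendered <- render_subgraph(subgraph, scenario)
  facts <- if (nzchar(rendered$text)) {
    lines <- strsplit(rendered$text, "\n", fixed = TRUE)[[1]]
    paste(sprintf("%d. %s", seq_along(lines), lines), collapse = "\n")
  } else "(no facts)"
  tpl <- sc$template[idx]
  out <- gsub("{{facts}}", facts, tpl, fixed = TRUE)
  gsub("{{constraint}}", grounding_constraint(), out, fixed = TRUE)
}

#' Interpret a subgraph through a pluggable text callback
#'
#' Builds the grounded prompt for a scenario and hands it to `llm`, any
#' function mapping a prompt string to a text answer. No hosted model is
#' called by the package itself.
#'
#' @inheritParams render_subgraph
#' @param llm A `function(prompt) -> character`. The default returns the
#'   prompt unchanged, which is useful for inspection and testing.
#' @return The callback's return value.
#' @export
interpret_subgraph <- function(subgraph, scenario = "knowledge_unit",
                               llm = identity) {
  llm(build_prompt(subgraph, scenario))
}
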