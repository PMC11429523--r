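#' Tidy a knowledge graph into one row per statement
#'
#' @param x A `cond_kg`.
#' @param ... Unused.
#' @return A tibble with one row per statement: endpoints (resolved to
#'   display names where possible), predicate, modifiers, qualifiers,
#'   pattern, edge class, and evidence count.
#' @exportS3Method generics::tidy
tidy.cond_kg <- function(x, ...) {
  s <- statement_tibble(x, x$statements$statement_id)
  nm <- function(ref) {
    kind <- kg_ref_kind(x, ref)
    ifelse(kind == "entity", entity_name(x, ref), ref)
  }
  dplyr::mutate(s,
    subject_label = vapply(.data$subject, nm, ""),
    object_label = vapply(.data$object, nm, ""),
    n_evidence = vapply(.data$evidence, nrow, integer(1)),
    .after = "statement_id") |>
    dplyr::select(-"evidence")
}

#' One-row summary of a knowledge graph
#'
#' @param x A `cond_kg`.
#' @param ... Unused.
#' @return A one-row tibble: entity counts per category, gate count,
#'   statement count, edge-class counts, and validation status.
#' @exportS3Method generics::glance
glance.cond_kg <- function(x, ...) {
  classes <- if (nrow(x$statements))
    table(factor(kg_edge_class(x, x$statements$statement_id),
                 levels = c("vv", "ev", "ee")))
  else c(vv = 0L, ev = 0L, ee = 0L)
  cats <- table(factor(x$entities$category, levels = kg_categories()))
  tibble::tibble(
    n_entities = nrow(x$entities),
    n_drugs = as.integer(cats[["drug"]]),
    n_diseases = as.integer(cats[["disease"]]),
    n_phenotypes = as.integer(cats[["phenotype"]]),
    n_variants = as.integer(cats[["variant"]]),
    n_genes = as.integer(cats[["gene"]]),
    n_gates = nrow(x$gates),
    n_statements = nrow(x$statements),
    n_vv = as.integer(classes[["vv"]]),
    n_ev = as.integer(classes[["ev"]]),
    n_ee = as.integer(classes[["ee"]]),
    valid = nrow(kg_validate(x)) == 0L
  )
}

#' @rdname tidy.cond_kg
#' @exportS3Method generics::tidy
tidy.kg_subgraph <- function(x, ...) tidy.cond_kg(x$graph, ...)

#' @rdname glance.cond_kg
#' @exportS3Method generics::glance
glance.kg_subgraph <- function(x, ...) glance.cond_kg(x$graph, ...)
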