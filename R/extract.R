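# Rule-based mining of tabular/free-text source records, deduplication with
# evidence union, and order-insensitive multi-source graph merging.

source_record_fields <- function() {
  c("source_db", "drug", "disease", "phenotype", "variant", "gene", "genotype",
    "direction", "aspect", "pattern_hint", "citation", "text")
}

empty_source_records <- function() {
  tibble::as_tibble(stats::setNames(
    rep(list(character()), length(source_record_fields())), source_record_fields()))
}

#' Build an extraction rule set
#'
#' Each rule is a Perl regular expression with *named capture groups* whose
#' names are source-record fields (`drug`, `disease`, `phenotype`, `variant`,
#' `gene`, `genotype`, `direction`, `aspect`, `citation`), plus the pattern
#' hint to stamp on matching records. Patterns are compiled at load time;
#' invalid syntax errors immediately.
#'
#' @param patterns Character vector of regular expressions.
#' @param pattern_hints Character vector (recycled) of knowledge-pattern
#'   hints.
#' @return A `kg_rules` tibble.
#' @export
extraction_rules <- function(patterns, pattern_hints) {
  for (p in patterns) {
    ok <- tryCatch({ regexpr(p, "", perl = TRUE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("invalid rule pattern: ", p, call. = FALSE)
  }
  structure(tibble::tibble(pattern = patterns,
                           pattern_hint = rep_len(pattern_hints, length(patterns))),
            class = c("kg_rules", class(tibble::tibble())))
}

#' Load extraction rules from a file
#'
#' One rule per line: `regex<TAB>pattern_hint`; `#` lines are comments.
#'
#' @param path Rule file.
#' @return A `kg_rules` tibble.
#' @export
load_rules <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("malformed rule line(s): ", paste(lines[bad], collapse = "; "), call. = FALSE)
  extraction_rules(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
}

match_named_groups <- function(line, pattern) {
  m <- regexpr(pattern, line, perl = TRUE)
  if (m == -1L) return(NULL)
  starts <- attr(m, "capture.start")
  lens <- attr(m, "capture.length")
  nms <- attr(m, "capture.names")
  out <- list()
  for (k in seq_along(nms)) {
    if (nzchar(nms[k]) && starts[k] > 0L)
      out[[nms[k]]] <- substr(line, starts[k], starts[k] + lens[k] - 1L)
  }
  out
}

#' Extract source records from text lines with a rule set
#'
#' Every rule is applied to every line; each match emits one record
#' (overlapping rules emit several — downstream deduplication resolves).
#' Lines matching no rule are reported, never dropped silently.
#'
#' @param text Character vector of input lines.
#' @param rules A `kg_rules` object.
#' @param source_db Source name stamped on every record.
#' @return List with `records` (source-record tibble) and `unmatched`
#'   (tibble: `line_no`, `text`).
#' @export
extract_with_rules <- function(text, rules, source_db = "text") {
  records <- list()
  matched <- logical(length(text))
  for (i in seq_along(text)) {
    for (r in seq_len(nrow(rules))) {
      caps <- match_named_groups(text[i], rules$pattern[r])
      if (is.null(caps)) next
      matched[i] <- TRUE
      rec <- stats::setNames(
        as.list(rep(NA_character_, length(source_record_fields()))),
        source_record_fields())
      rec$source_db <- source_db
      rec$pattern_hint <- rules$pattern_hint[r]
      rec$text <- text[i]
      for (k in intersect(names(caps), source_record_fields()))
        rec[[k]] <- caps[[k]]
      records[[length(records) + 1L]] <- tibble::as_tibble(rec)
    }
  }
  list(
    records = if (length(records)) dplyr::bind_rows(records) else empty_source_records(),
    unmatched = tibble::tibble(line_no = which(!matched), text = text[!matched])
  )
}

#' Deduplicate source records with evidence union
#'
#' The identity key is every field except `citation` and `text`; duplicate
#' records collapse into one whose citations are the sorted union. Output is
#' canonically ordered by key, so the operation is idempotent and invariant
#' under permutation of its input.
#'
#' @param records A source-record tibble.
#' @return The deduplicated tibble with `citation` holding pipe-joined unions.
#' @export
deduplicate <- function(records) {
  if (!nrow(records)) return(records)
  keys <- setdiff(names(records), c("citation", "text"))
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      citation = paste(sort(unique(unlist(strsplit(
        stats::na.omit(.data$citation), "|", fixed = TRUE))), method = "radix"),
        collapse = "|"),
      text = dplyr::first(sort(stats::na.omit(.data$text), method = "radix")),
      .groups = "drop")
  out$citation[!nzchar(out$citation)] <- NA_character_
  out$text[is.na(out$text)] <- NA_character_
  out <- out[do.call(order, c(unname(as.list(out[keys])), list(method = "radix"))), ]
  out[, names(records)]
}

#' Merge knowledge graphs
#'
#' Union keyed by content-derived ids: identical entities/gates/statements
#' coincide, statement collisions union their evidence, predicate sets union.
#' The merge is order-insensitive — any permutation of the inputs yields the
#' same canonical export. A category/content conflict for an existing
#' entity id is an error.
#'
#' @param graphs List of `cond_kg` objects (or several graphs as `...`).
#' @return The merged `cond_kg`.
#' @export
merge_graphs <- function(graphs) {
  if (inherits(graphs, "cond_kg")) graphs <- list(graphs)
  stopifnot(length(graphs) >= 1L, all(vapply(graphs, inherits, TRUE, "cond_kg")))
  out <- kg_new(predicates = sort(unique(unlist(lapply(graphs, `[[`, "predicates")))))
  for (g in graphs) {
    e <- g$entities
    for (i in seq_len(nrow(e))) {
      out <- tryCatch(
        kg_add_entity(out, e$entity_id[i], e$name[i], e$category[i],
                      external_id = e$external_id[i], synonyms = e$synonyms[[i]],
                      genotype = e$genotype[i]),
        error = function(err)
          stop("merge conflict for entity '", e$entity_id[i], "': ",
               conditionMessage(err), call. = FALSE))
    }
  }
  # gates/statements may cross-reference; insert in passes across all graphs
  pend_g <- dplyr::bind_rows(lapply(graphs, `[[`, "gates"))
  pend_s <- dplyr::bind_rows(lapply(graphs, `[[`, "statements"))
  repeat {
    progress <- FALSE
    keep_g <- logical(nrow(pend_g))
    for (i in seq_len(nrow(pend_g))) {
      if (all(!is.na(kg_ref_kind(out, pend_g$members[[i]])))) {
        out <- kg_make_gate(out, pend_g$gate_type[i], pend_g$members[[i]])
        progress <- TRUE
      } else keep_g[i] <- TRUE
    }
    pend_g <- pend_g[keep_g, ]
    keep_s <- logical(nrow(pend_s))
    for (i in seq_len(nrow(pend_s))) {
      s <- pend_s[i, ]
      if (!is.na(kg_ref_kind(out, s$subject)) && !is.na(kg_ref_kind(out, s$object))) {
        out <- kg_add_statement(out, s$subject, s$predicate, s$object,
                                negated = s$negated, likelihood = s$likelihood,
                                aspect = s$aspect, direction = s$direction,
                                pattern = s$pattern, evidence = s$evidence[[1]])
        progress <- TRUE
      } else keep_s[i] <- TRUE
    }
    pend_s <- pend_s[keep_s, ]
    if (!nrow(pend_g) && !nrow(pend_s)) break
    if (!progress)
      stop("merge failed: unresolvable references", call. = FALSE)
  }
  out
}
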