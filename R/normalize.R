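# Entity disambiguation against controlled vocabularies: exact ID mapping
# first, then best-scoring name mapping, with ties flagged for manual review
# rather than silently resolved.

#' Load a controlled vocabulary from TSV
#'
#' Expected columns: `id`, `name`, `synonyms` (pipe-separated, may be empty),
#' `category`.
#'
#' @param path TSV file.
#' @return A `kg_vocabulary`: a tibble (`term_id`, `standard_name`,
#'   `synonyms` list-column, `category`) indexed for case-folded lookup.
#' @export
load_vocabulary <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  need <- c("id", "name", "synonyms", "category")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("vocabulary is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$id))
    stop("duplicate vocabulary id(s): ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "), call. = FALSE)
  if (any(!nzchar(tab$name)))
    stop("vocabulary names must be non-empty", call. = FALSE)
  as_vocabulary(tibble::tibble(
    term_id = tab$id,
    standard_name = tab$name,
    synonyms = lapply(strsplit(tab$synonyms, "|", fixed = TRUE),
                      function(x) x[nzchar(x)]),
    category = tab$category
  ))
}

#' Build a vocabulary from a tibble
#'
#' @param terms Tibble with `term_id`, `standard_name`, `synonyms`
#'   (list-column), `category`.
#' @return A `kg_vocabulary`.
#' @export
as_vocabulary <- function(terms) {
  stopifnot(all(c("term_id", "standard_name", "synonyms", "category") %in% names(terms)))
  v <- tibble::as_tibble(terms)
  # case-folded lookup index: one row per (key, term); a synonym shared by two
  # terms yields two rows and both stay retrievable
  keys <- purrr::map2(v$standard_name, v$synonyms,
                      function(n, s) unique(fold_name(c(n, s))))
  attr(v, "index") <- tibble::tibble(
    key = unlist(keys),
    term_id = rep(v$term_id, lengths(keys))
  )
  class(v) <- c("kg_vocabulary", class(v))
  v
}

fold_name <- function(x) tolower(trimws(x))

#' Look up a name or synonym in a vocabulary
#'
#' @param vocab A `kg_vocabulary`.
#' @param name Name to look up (case-insensitive).
#' @return Character vector of term ids whose standard name or synonyms
#'   include `name` (possibly several, possibly none).
#' @export
vocab_lookup <- function(vocab, name) {
  idx <- attr(vocab, "index")
  unique(idx$term_id[idx$key == fold_name(name)])
}

#' Load an ID cross-reference table from TSV
#'
#' Columns: `source_db`, `source_id`, `term_id`. Conflicting duplicates —
#' the same (source_db, source_id) mapped to two term ids — are a load-time
#' error.
#'
#' @param path TSV file.
#' @return A tibble.
#' @export
load_xref <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("source_db", "source_id", "term_id")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("xref table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  tab <- dplyr::distinct(tibble::as_tibble(tab))
  key <- paste(tab$source_db, tab$source_id, sep = "\x1f")
  if (anyDuplicated(key))
    stop("conflicting xref rows for: ",
         paste(unique(paste(tab$source_db, tab$source_id)[duplicated(key)]),
               collapse = ", "), call. = FALSE)
  tab
}

#' Map a source-database identifier to a vocabulary term id
#'
#' @param source_db,source_id The upstream database and its identifier.
#' @param xref A table from [load_xref()].
#' @return The term id, or `NA` when no mapping exists.
#' @export
map_by_id <- function(source_db, source_id, xref) {
  hit <- xref$term_id[xref$source_db == source_db & xref$source_id == source_id]
  if (length(hit) == 1L) hit else NA_character_
}

# ---- name similarity --------------------------------------------------------

name_tokens <- function(x) {
  toks <- strsplit(tolower(x), "[^a-z0-9]+")[[1]]
  unique(toks[nzchar(toks)])
}

# Name-similarity phi: 1.0 for a case-insensitive exact match, otherwise
# token-set Jaccard capped at 0.99 so non-exact scores stay strictly below 1.
phi_similarity <- function(query, candidate) {
  if (fold_name(query) == fold_name(candidate)) return(1)
  a <- name_tokens(query); b <- name_tokens(candidate)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  min(length(intersect(a, b)) / u, 0.99)
}

phi_term <- function(query, standard_name, synonyms) {
  max(vapply(c(standard_name, synonyms), phi_similarity, numeric(1), query = query))
}

#' Best-scoring vocabulary match for a name
#'
#' Scores every term by the maximum similarity between the query and the
#' term's standard name or any synonym, then takes the argmax term set. A
#' unique maximum at or above `threshold` maps the name; a tie yields status
#' `ambiguous` (queued for manual review, never silently chosen); a maximum
#' below `threshold` yields `unmapped`.
#'
#' @param name Query name (non-empty).
#' @param vocab A `kg_vocabulary` (non-empty).
#' @param threshold Minimum similarity for a mapping (default 0.80).
#' @return One-row tibble: `query_name`, `best_ids` (list), `score`,
#'   `status` (`unique`, `ambiguous`, or `unmapped`).
#' @export
best_match <- function(name, vocab, threshold = 0.80) {
  if (!nrow(vocab)) stop("vocabulary is empty", call. = FALSE)
  if (is.na(name) || !nzchar(trimws(name)))
    stop("query name must be non-empty", call. = FALSE)
  scores <- purrr::map2_dbl(vocab$standard_name, vocab$synonyms,
                            function(n, s) phi_term(name, n, s))
  top <- max(scores)
  best <- sort(vocab$term_id[scores == top], method = "radix")
  status <- if (top < threshold) "unmapped"
            else if (length(best) > 1L) "ambiguous"
            else "unique"
  tibble::tibble(query_name = name, best_ids = list(best), score = top,
                 status = status)
}

#' Normalize graph entities against controlled vocabularies
#'
#' For each entity: an ID cross-reference hit takes precedence and sets
#' `external_id` directly (`id_mapped`); otherwise name mapping via
#' [best_match()] against the vocabulary of the entity's category. Unique
#' matches set `external_id`; ambiguous or unmapped entities keep their local
#' id and are emitted on the review queue together with their match result.
#' No entity is ever discarded. The xref is consulted with the entity's
#' `entity_id` as `source_id`.
#'
#' @param graph A `cond_kg`.
#' @param vocabularies Named list of `kg_vocabulary` objects, one per entity
#'   category (missing categories are skipped with a warning).
#' @param xrefs Optional xref table from [load_xref()].
#' @param threshold Name-mapping similarity threshold.
#' @return List with `graph` (external ids filled in) and `review_queue`
#'   (tibble: `entity_id`, `category`, `query_name`, `best_ids`, `score`,
#'   `status`).
#' @export
normalize_entities <- function(graph, vocabularies, xrefs = NULL, threshold = 0.80) {
  stopifnot(inherits(graph, "cond_kg"))
  queue <- list()
  e <- graph$entities
  missing_cats <- setdiff(unique(e$category), names(vocabularies))
  if (length(missing_cats))
    warning("no vocabulary supplied for categor",
            if (length(missing_cats) > 1) "ies: " else "y: ",
            paste(missing_cats, collapse = ", "), "; skipped", call. = FALSE)
  for (i in seq_len(nrow(e))) {
    cat <- e$category[i]
    if (!is.null(xrefs)) {
      hit <- xrefs$term_id[xrefs$source_id == e$entity_id[i]]
      if (length(hit) == 1L) {
        graph$entities$external_id[i] <- hit
        next
      }
    }
    if (!cat %in% names(vocabularies)) next
    m <- best_match(e$name[i], vocabularies[[cat]], threshold = threshold)
    if (m$status == "unique") {
      graph$entities$external_id[i] <- m$best_ids[[1]]
    } else {
      queue[[length(queue) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(entity_id = e$entity_id[i], category = cat), m)
    }
  }
  review_queue <- if (length(queue)) dplyr::bind_rows(queue) else
    tibble::tibble(entity_id = character(), category = character(),
                   query_name = character(), best_ids = list(),
                   score = numeric(), status = character())
  list(graph = graph, review_queue = review_queue)
}

#' Write a review queue as TSV
#'
#' @param queue The `review_queue` tibble from [normalize_entities()].
#' @param path Destination TSV.
#' @return `path`, invisibly.
#' @export
write_review_queue <- function(queue, path) {
  flat <- dplyr::mutate(queue,
    best_ids = vapply(.data$best_ids, paste, "", collapse = "|"))
  readr::write_tsv(flat, path)
  invisible(path)
}
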