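# Shared builders and independent oracles used across the suite.

# minimal hand-built graph: drug treats disease, risk on the therapy event,
# variant condition on the risk
tiny_graph <- function() {
  g <- kg_new()
  g <- kg_add_entity(g, "d1", "drugone", "drug")
  g <- kg_add_entity(g, "x1", "diseaseone", "disease")
  g <- kg_add_entity(g, "p1", "phenoone", "phenotype")
  g <- kg_add_entity(g, "v1", "rs000001", "variant", genotype = "AA")
  g <- kg_add_statement(g, "d1", "treats", "x1")
  t1 <- kg_last_ref(g)
  g <- kg_add_statement(g, t1, "increases_risk_of", "p1", pattern = "side_effects")
  s1 <- kg_last_ref(g)
  g <- kg_add_statement(g, "v1", "condition_of", s1)
  g
}

# brute-force argmax oracle for name matching, written independently of
# best_match: plain double loop over every (name, term-name) pair
oracle_best_match <- function(name, vocab, threshold = 0.80) {
  sim <- function(a, b) {
    if (tolower(trimws(a)) == tolower(trimws(b))) return(1)
    ta <- unique(strsplit(tolower(a), "[^a-z0-9]+")[[1]])
    tb <- unique(strsplit(tolower(b), "[^a-z0-9]+")[[1]])
    ta <- ta[nzchar(ta)]; tb <- tb[nzchar(tb)]
    u <- length(unique(c(ta, tb)))
    if (u == 0) return(0)
    min(sum(ta %in% tb) / u, 0.99)
  }
  best_score <- -1
  best_ids <- character()
  for (i in seq_len(nrow(vocab))) {
    cand <- c(vocab$standard_name[i], vocab$synonyms[[i]])
    sc <- max(vapply(cand, sim, numeric(1), a = name))
    if (sc > best_score + 1e-12) {
      best_score <- sc; best_ids <- vocab$term_id[i]
    } else if (abs(sc - best_score) <= 1e-12) {
      best_ids <- c(best_ids, vocab$term_id[i])
    }
  }
  list(best_ids = sort(best_ids, method = "radix"), score = best_score,
       status = if (best_score < threshold) "unmapped"
                else if (length(best_ids) > 1) "ambiguous" else "unique")
}

random_vocab <- function(n_terms, seed) {
  set.seed(seed)
  words <- sprintf("w%02d", 1:25)
  tibble::tibble(
    term_id = sprintf("T%04d", seq_len(n_terms)),
    standard_name = vapply(seq_len(n_terms), function(i)
      paste(sample(words, sample(1:3, 1)), collapse = " "), ""),
    synonyms = lapply(seq_len(n_terms), function(i)
      replicate(sample(0:2, 1), paste(sample(words, sample(1:3, 1)), collapse = " "))),
    category = "drug"
  ) |> as_vocabulary()
}

random_names <- function(n, seed) {
  set.seed(seed)
  words <- sprintf("w%02d", 1:25)
  vapply(seq_len(n), function(i)
    paste(sample(words, sample(1:3, 1)), collapse = " "), "")
}

# brute-force nested-loop join oracle for shared-mechanism hypotheses
oracle_shared_mechanism <- function(graph, disease_id) {
  s <- graph$statements
  mech_preds <- c("increases_expression_of", "decreases_expression_of",
                  "increases_activity_of", "decreases_activity_of")
  expand_drugs <- function(ref) {
    kind <- kg_ref_kind(graph, ref)
    if (identical(kind, "gate")) {
      members <- graph$gates$members[[match(ref, graph$gates$gate_id)]]
      unique(unlist(lapply(members, expand_drugs)))
    } else if (identical(kind, "entity") &&
               graph$entities$category[graph$entities$entity_id == ref] == "drug") ref
    else character()
  }
  treats <- s[s$predicate == "treats" & s$object == disease_id, ]
  a_drugs <- unique(unlist(lapply(treats$subject[!treats$negated], expand_drugs)))
  linked <- unique(unlist(lapply(treats$subject, expand_drugs)))
  pred <- s$predicate; subj <- s$subject; obj <- s$object; neg <- s$negated
  kind <- kg_ref_kind(graph, subj)
  pairs <- list()
  for (i in seq_along(pred)) for (j in seq_along(pred)) {
    if (!pred[i] %in% mech_preds || neg[i]) next
    if (!pred[j] %in% mech_preds || neg[j]) next
    if (!subj[i] %in% a_drugs) next
    if (subj[j] %in% linked || subj[j] == subj[i]) next
    if (!identical(kind[j], "entity")) next
    if (obj[i] != obj[j] || pred[i] != pred[j]) next
    pairs[[length(pairs) + 1L]] <- c(subj[j], obj[j])
  }
  if (!length(pairs)) return(tibble::tibble(candidate = character(), score = integer()))
  m <- unique(do.call(rbind, pairs))
  tab <- tapply(m[, 2], m[, 1], function(x) length(unique(x)))
  out <- tibble::tibble(candidate = names(tab), score = as.integer(tab))
  nm <- vapply(out$candidate, function(id)
    graph$entities$name[graph$entities$entity_id == id], "")
  out[order(-out$score, nm, method = "radix"), ]
}
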