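#' The default controlled predicate set
#'
#' Covers every relation used by the four knowledge patterns: indication
#' (`treats`), side-effect risk (`increases_risk_of`, `causes`,
#' `associated_with`), conditioning (`condition_of`), causation between
#' events (`leads_to`), sensitivity (`affects_response_to`, `no_effect_on`),
#' and the four directional mechanism predicates on gene expression/activity.
#' Extensible via a plain-text config file, see [read_kg_config()].
#'
#' @return Character vector of predicates.
#' @export
kg_predicates <- function() {
  c("treats", "increases_risk_of", "causes", "associated_with",
    "condition_of", "leads_to", "affects_response_to",
    "increases_expression_of", "decreases_expression_of",
    "increases_activity_of", "decreases_activity_of", "no_effect_on")
}

mechanism_predicates <- function() {
  c("increases_expression_of", "decreases_expression_of",
    "increases_activity_of", "decreases_activity_of")
}

risk_predicates <- function() c("increases_risk_of", "causes", "associated_with")

#' Read a key=value configuration file
#'
#' The config dialect is one `key = value` pair per line; `#` starts a
#' comment; list values are comma-separated. Recognised keys include
#' `predicates` (extends the default predicate set) and
#' `match_threshold` (name-mapping similarity cutoff).
#'
#' @param path Path to the config file.
#' @return Named list of values (character vectors; numeric where parseable).
#' @export
read_kg_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): '", ln, "'", call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (length(parts) && !anyNA(num)) num else parts
  }
  out
}

#' Build a predicate set from a config
#'
#' @param config A list from [read_kg_config()], or `NULL` for defaults.
#' @return Character vector: the default predicates plus any configured
#'   additions.
#' @export
kg_predicates_from_config <- function(config = NULL) {
  extra <- if (!is.null(config)) as.character(config$predicates) else character()
  sort(unique(c(kg_predicates(), extra)))
}

# Mapping from (predicate, qualifiers, negation) to personalized-suggestion
# labels; fixed here and documented, overridable by advanced callers.
suggestion_label <- function(predicate, negated, aspect, direction) {
  dplyr::case_when(
    predicate == "treats" & negated ~ "ineffective",
    predicate == "no_effect_on" ~ "no_effect",
    predicate %in% risk_predicates() & negated ~ "reduced_risk",
    predicate %in% risk_predicates() ~ "increased_risk",
    predicate == "affects_response_to" & !is.na(aspect) & aspect == "efficacy" &
      !is.na(direction) & direction == "decreased" & !negated ~ "reduced_efficacy",
    predicate == "affects_response_to" & !is.na(aspect) & aspect == "efficacy" &
      (negated | (!is.na(direction) & direction == "none")) ~ "no_effect",
    predicate == "affects_response_to" & !is.na(aspect) & aspect == "risk" &
      !is.na(direction) & direction == "decreased" ~ "reduced_risk",
    predicate == "affects_response_to" & !is.na(aspect) & aspect == "risk" &
      !is.na(direction) & direction == "increased" ~ "increased_risk",
    predicate == "treats" ~ "unconditional",
    TRUE ~ NA_character_
  )
}
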