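#' Construct an information-retrieval screening template
#'
#' The retrieval template holds the required-term categories (an abstract
#' must mention at least one term from every category) and a prohibited-term
#' set (any hit rejects the abstract). Matching is case-insensitive on
#' whole words; synonyms are simply additional terms in a category.
#'
#' @param drugs,enzymes,probes,experiment,experiment_type Character vectors
#'   of required terms, one vector per category. Empty categories are
#'   dropped.
#' @param prohibited Character vector of prohibited terms.
#' @return An object of class `screen_template`.
#' @export
screen_template <- function(drugs, enzymes, probes = character(),
                            experiment = character(),
                            experiment_type = character(),
                            prohibited = character()) {
  required <- list(drugs = drugs, enzymes = enzymes, probes = probes,
                   experiment = experiment, experiment_type = experiment_type)
  required <- required[lengths(required) > 0]
  if (!length(required)) {
    abort("template must have at least one required category",
          class = "cypddi_invalid_argument")
  }
  req_all <- tolower(unlist(required, use.names = FALSE))
  if (length(intersect(req_all, tolower(prohibited)))) {
    abort("required and prohibited term sets must be disjoint",
          class = "cypddi_invalid_argument")
  }
  structure(list(required = lapply(required, tolower),
                 prohibited = tolower(prohibited)),
            class = "screen_template")
}

#' @export
print.screen_template <- function(x, ...) {
  cat("<screen_template>\n")
  for (nm in names(x$required)) {
    cat(sprintf("  %s: %d terms\n", nm, length(x$required[[nm]])))
  }
  cat(sprintf("  prohibited: %d terms\n", length(x$prohibited)))
  invisible(x)
}

#' Default screening template built from a knowledge base
#'
#' Required categories: the knowledge base's drug names, the enzyme
#' dictionary surface forms, the FDA probe names, in vitro experiment
#' system terms, and experiment-type terms. Prohibited terms are
#' oncology-study markers.
#'
#' @param kb A knowledge-base tibble with a `drug` column.
#' @return A `screen_template`.
#' @export
default_screen_template <- function(kb) {
  screen_template(
    drugs = unique(kb$drug),
    enzymes = cyp_enzyme_dictionary()$synonym,
    probes = unique(fda_probes()$probe),
    experiment = c("human liver microsomes", "human hepatocytes",
                   "recombinant"),
    experiment_type = c("incubation", "kinetic", "km", "ic50",
                        "michaelis"),
    prohibited = c("tumor", "tumour", "cancer", "carcinoma",
                   "chemotherapy", "xenograft")
  )
}

.abstract_text <- function(sentences) {
  paste(tolower(unlist(sentences)), collapse = " ")
}

.term_hits <- function(text, terms) {
  terms[map_lgl(terms, function(t) {
    stringr::str_detect(text, stringr::regex(paste0("\\b", stringr::str_replace_all(t, "([\\W])", "\\\\\\1"), "\\b")))
  })]
}

#' Filter abstracts with the retrieval template
#'
#' An abstract is retained iff it contains at least one term from every
#' required category and no prohibited term. Empty abstracts are never
#' retained.
#'
#' @param corpus A corpus tibble with `abstract_id` and a `sentences`
#'   list-column.
#' @param template A [screen_template()].
#' @return The corpus with two added columns: `retained` (logical) and
#'   `matched_terms` (list of per-category hit lists, with a `prohibited`
#'   element).
#' @export
filter_abstracts <- function(corpus, template) {
  stopifnot(inherits(template, "screen_template"),
            all(c("abstract_id", "sentences") %in% names(corpus)))
  reports <- map(corpus$sentences, function(sents) {
    text <- .abstract_text(sents)
    if (!nzchar(trimws(text))) {
      return(list(retained = FALSE,
                  hits = c(lapply(template$required, function(...) character()),
                           list(prohibited = character()))))
    }
    req_hits <- lapply(template$required, function(terms) .term_hits(text, terms))
    pro_hits <- .term_hits(text, template$prohibited)
    list(retained = all(lengths(req_hits) > 0) && length(pro_hits) == 0,
         hits = c(req_hits, list(prohibited = pro_hits)))
  })
  n_empty <- sum(map_lgl(corpus$sentences, function(s) !nzchar(trimws(.abstract_text(s)))))
  if (n_empty > 0) {
    inform(sprintf("%d empty abstract(s) were not retained", n_empty))
  }
  corpus %>%
    mutate(retained = map_lgl(reports, "retained"),
           matched_terms = map(reports, "hits"))
}

#' Full information-retrieval screen: template filter plus pattern scan
#'
#' Step one applies [filter_abstracts()]; step two runs [scan_patterns()]
#' on the retained abstracts. An abstract is `retrieved` when it passes the
#' template and contains at least one DDI-relevant sentence pattern.
#'
#' @param corpus A corpus tibble (`abstract_id`, `sentences`, optionally
#'   annotation columns).
#' @param template A [screen_template()].
#' @param drug_dict,enzyme_dict Scanner dictionaries (see [scan_patterns()]).
#' @param max_gap Token gap limit for the scanner.
#' @return A list with elements `corpus` (input plus `retained`,
#'   `n_matches`, `retrieved` columns) and `matches` (the pattern-match
#'   tibble for retained abstracts).
#' @export
screen_corpus <- function(corpus, template, drug_dict,
                          enzyme_dict = cyp_enzyme_dictionary(),
                          max_gap = 5) {
  filtered <- filter_abstracts(corpus, template)
  kept <- filtered %>% filter(.data$retained)
  matches <- scan_patterns(kept, drug_dict, enzyme_dict, max_gap)
  match_counts <- if (nrow(matches)) {
    matches %>% count(.data$abstract_id, name = "n_matches")
  } else {
    tibble(abstract_id = character(), n_matches = integer())
  }
  out <- filtered %>%
    left_join(match_counts, by = "abstract_id") %>%
    mutate(n_matches = tidyr::replace_na(.data$n_matches, 0L),
           retrieved = .data$retained & .data$n_matches > 0)
  list(corpus = out, matches = matches)
}

#' Estimate the recall of a retrieval run
#'
#' Recall is the fraction of labelled true-positive abstracts that the
#' retrieval selected: `|retrieved intersect positives| / |positives|`.
#'
#' @param retrieval Either a character vector of retrieved abstract ids, or
#'   a function taking the mixed corpus and returning such a vector.
#' @param positives Character vector of true-positive abstract ids.
#' @param mixed_corpus The corpus the retrieval ran over (required when
#'   `retrieval` is a function; also used to check that `positives` are
#'   present).
#' @return Recall in \[0, 1\].
#' @export
#' @examples
#' estimate_recall(c("a", "b"), positives = c("a", "b", "c"))
estimate_recall <- function(retrieval, positives, mixed_corpus = NULL) {
  if (!length(positives)) {
    abort("`positives` must be non-empty", class = "cypddi_invalid_argument")
  }
  if (is.function(retrieval)) {
    if (is.null(mixed_corpus)) {
      abort("`mixed_corpus` is required when `retrieval` is a function",
            class = "cypddi_invalid_argument")
    }
    retrieved <- retrieval(mixed_corpus)
  } else {
    retrieved <- retrieval
  }
  if (!is.null(mixed_corpus)) {
    missing <- setdiff(positives, mixed_corpus$abstract_id)
    if (length(missing)) {
      abort("some positives are absent from the mixed corpus",
            class = "cypddi_invalid_argument")
    }
  }
  length(intersect(retrieved, positives)) / length(positives)
}
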