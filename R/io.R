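# Readers/writers for the external interchange formats:
# knowledge base TSV, corpus JSONL (one abstract per line), EMR CSV trio,
# ground truth YAML.

#' Write / read a knowledge base TSV
#'
#' Columns: `drug`, `enzyme`, `role`, `extent`, `ki_um`.
#'
#' @param kb Knowledge-base tibble.
#' @param path File path.
#' @return `write_knowledge_base()` returns `path` invisibly;
#'   `read_knowledge_base()` returns the tibble.
#' @export
write_knowledge_base <- function(kb, path) {
  readr::write_tsv(as_tibble(kb), path)
  invisible(path)
}

#' @rdname write_knowledge_base
#' @export
read_knowledge_base <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(ki_um = readr::col_double(),
                                          .default = readr::col_character()))
}

#' Write / read an abstract corpus as JSONL
#'
#' One JSON object per line: `{id, sentences: [...], annotations: {...}}`.
#' Annotation fields (`system`, `probe_used`) and any label columns present
#' are carried in `annotations`.
#'
#' @param corpus Corpus tibble (`abstract_id`, `sentences` list-column,
#'   further columns become annotations).
#' @param path File path.
#' @return `write_corpus_jsonl()` returns `path` invisibly;
#'   `read_corpus_jsonl()` returns the corpus tibble.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  ann_cols <- setdiff(names(corpus), c("abstract_id", "sentences"))
  lines <- map_chr(seq_len(nrow(corpus)), function(i) {
    obj <- list(
      id = corpus$abstract_id[i],
      sentences = as.list(corpus$sentences[[i]]),
      annotations = as.list(corpus[i, ann_cols, drop = FALSE])
    )
    jsonlite::toJSON(obj, auto_unbox = TRUE, na = "null", null = "null")
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path)
  rows <- map(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
  ann <- map_dfr(rows, function(r) {
    a <- r$annotations %||% list()
    a <- lapply(a, function(v) if (is.null(v)) NA else v)
    as_tibble(a)
  })
  out <- tibble(
    abstract_id = map_chr(rows, "id"),
    sentences = map(rows, function(r) as.character(unlist(r$sentences)))
  )
  if (nrow(ann)) out <- bind_cols(out, ann)
  out
}

#' Write / read EMR tables as CSV files
#'
#' Three files in `dir`: `person.csv`, `drug_exposure.csv`,
#' `condition_occurrence.csv`, in the minimal OMOP-like dialect
#' (`person_id`, `sex`, `birth_year`; `person_id`, `drug_name`,
#' `start_date`; `person_id`, `concept_name`, `event_date`; dates
#' ISO-8601).
#'
#' @param emr EMR list.
#' @param dir Output directory (created if missing).
#' @return `write_emr()` returns `dir` invisibly; `read_emr()` returns the
#'   EMR list (class `ddi_emr`).
#' @export
write_emr <- function(emr, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(emr$person, file.path(dir, "person.csv"))
  readr::write_csv(emr$drug_exposure, file.path(dir, "drug_exposure.csv"))
  readr::write_csv(emr$condition_occurrence,
                   file.path(dir, "condition_occurrence.csv"))
  invisible(dir)
}

#' @rdname write_emr
#' @export
read_emr <- function(dir) {
  person <- readr::read_csv(file.path(dir, "person.csv"),
                            show_col_types = FALSE)
  dx <- readr::read_csv(file.path(dir, "drug_exposure.csv"),
                        show_col_types = FALSE)
  cond <- readr::read_csv(file.path(dir, "condition_occurrence.csv"),
                          show_col_types = FALSE)
  dx$start_date <- as.Date(dx$start_date)
  cond$event_date <- as.Date(cond$event_date)
  structure(list(person = person, drug_exposure = dx,
                 condition_occurrence = cond),
            class = "ddi_emr")
}

#' Write / read a ground-truth record as YAML
#'
#' @param gt Ground-truth list or tibble (tibbles are stored as row lists).
#' @param path File path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns the parsed list.
#' @export
write_ground_truth <- function(gt, path) {
  serialize_val <- function(x) {
    if (is.data.frame(x))

      return(lapply(seq_len(nrow(x)), function(i) as.list(x[i, , drop = FALSE])))
    if (inherits(x, "Date")) return(format(x))
    if (is.list(x)) return(lapply(x, serialize_val))
    x
  }
  yaml::write_yaml(serialize_val(unclass(gt)), path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  yaml::read_yaml(path)
}
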