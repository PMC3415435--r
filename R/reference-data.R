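#' The CYP enzymes covered by the pipeline
#'
#' The ten major drug-metabolizing cytochrome P450 enzymes screened by the
#' literature-mining stage. CYP3A4 and CYP3A5 are carried as one merged
#' family, `"CYP3A4/5"`, because their probe reagents and clinical DDI
#' interpretation overlap.
#'
#' @return A character vector of canonical enzyme names.
#' @export
#' @examples
#' cyp_enzymes()
cyp_enzymes <- function() {
  c("CYP1A2", "CYP2A6", "CYP2B6", "CYP2C8", "CYP2C9",
    "CYP2C19", "CYP2D6", "CYP2E1", "CYP3A4/5")
}

#' Enzyme dictionary with textual synonyms
#'
#' Maps surface forms found in abstracts (e.g. "cyp3a4", "cyp3a") to the
#' canonical enzyme names of [cyp_enzymes()]. Used by the sentence-pattern
#' scanner and the retrieval template.
#'
#' @return A tibble with columns `name` (canonical) and `synonym`
#'   (lower-case surface form), one row per surface form.
#' @export
cyp_enzyme_dictionary <- function() {
  base <- cyp_enzymes()
  syn <- lapply(base, function(e) {
    if (e == "CYP3A4/5") c("cyp3a4/5", "cyp3a4", "cyp3a5", "cyp3a") else tolower(e)
  })
  tibble(
    name = rep(base, lengths(syn)),
    synonym = unlist(syn)
  )
}

#' FDA-recommended probe substrates and inhibitors per CYP enzyme
#'
#' A compact built-in table of well-established probe reagents used to
#' attribute in vitro metabolism or inhibition to a specific enzyme. An
#' in vitro assertion is only accepted by [extract_invitro()] when the
#' reported probe is listed here for the enzyme in question.
#'
#' @return A tibble with columns `enzyme`, `probe`, `probe_role`
#'   (`"substrate"` or `"inhibitor"`).
#' @export
fda_probes <- function() {
  tribble_rows <- list(
    c("CYP1A2",  "phenacetin",          "substrate"),
    c("CYP1A2",  "caffeine",            "substrate"),
    c("CYP1A2",  "furafylline",         "inhibitor"),
    c("CYP2A6",  "coumarin",            "substrate"),
    c("CYP2A6",  "tranylcypromine",     "inhibitor"),
    c("CYP2B6",  "bupropion",           "substrate"),
    c("CYP2B6",  "ticlopidine",         "inhibitor"),
    c("CYP2C8",  "paclitaxel",          "substrate"),
    c("CYP2C8",  "montelukast",         "inhibitor"),
    c("CYP2C9",  "tolbutamide",         "substrate"),
    c("CYP2C9",  "diclofenac",          "substrate"),
    c("CYP2C9",  "sulfaphenazole",      "inhibitor"),
    c("CYP2C19", "s-mephenytoin",       "substrate"),
    c("CYP2C19", "omeprazole",          "substrate"),
    c("CYP2C19", "nootkatone",          "inhibitor"),
    c("CYP2D6",  "dextromethorphan",    "substrate"),
    c("CYP2D6",  "bufuralol",           "substrate"),
    c("CYP2D6",  "quinidine",           "inhibitor"),
    c("CYP2E1",  "chlorzoxazone",       "substrate"),
    c("CYP2E1",  "diethyldithiocarbamate", "inhibitor"),
    c("CYP3A4/5", "midazolam",          "substrate"),
    c("CYP3A4/5", "testosterone",       "substrate"),
    c("CYP3A4/5", "ketoconazole",       "inhibitor"),
    c("CYP3A4/5", "itraconazole",       "inhibitor")
  )
  m <- do.call(rbind, tribble_rows)
  tibble(enzyme = m[, 1], probe = m[, 2], probe_role = m[, 3])
}

#' Myopathy outcome concept set
#'
#' The diagnosis concept names that define the myopathy outcome. Shipped as
#' an editable plain-text file (`extdata/myopathy_concepts.tsv`) so the
#' outcome definition can be swapped without touching code.
#'
#' @param file Path to a TSV with columns `concept_id`, `concept_name`.
#'   Defaults to the packaged concept set.
#' @return A character vector of concept names.
#' @export
myopathy_concepts <- function(file = NULL) {
  file <- file %||% system.file("extdata", "myopathy_concepts.tsv",
                                package = "cypddi", mustWork = TRUE)
  readr::read_tsv(file, show_col_types = FALSE)$concept_name
}

#' Published adjusted risks for five synergistic myopathy DDI pairs
#'
#' Reference summary data from a published statewide-EMR pharmacoepidemiology
#' analysis: the five drug pairs whose joint 30-day exposure showed a
#' synergistic myopathy signal, with their age/sex-adjusted group risks
#' (substrate alone, inhibitor alone, joint), relative risks and group
#' counts. Used as worked-example input for [rr_statistic()].
#'
#' @return A tibble with one row per pair: `drug1`, `drug2`, `enzymes`,
#'   `risk1`, `risk2`, `risk12`, `rr`, `p_value`, `m1`, `n1`, `m2`, `n2`,
#'   `m12`, `n12`.
#' @export
ddi_reference_pairs <- function() {
  file <- system.file("extdata", "myopathy_ddi_published_risks.tsv",
                      package = "cypddi", mustWork = TRUE)
  readr::read_tsv(file, show_col_types = FALSE)
}

#' Published myopathy cohort summary counts
#'
#' Patient counts with and without a myopathy event in the source EMR
#' repository (2004-2009), shipped as reference input for the prevalence
#' arithmetic.
#'
#' @return A tibble with columns `myopathy` (`"yes"`/`"no"`) and
#'   `n_patients`.
#' @export
myopathy_cohort_summary <- function() {
  file <- system.file("extdata", "myopathy_cohort_summary.tsv",
                      package = "cypddi", mustWork = TRUE)
  readr::read_tsv(file, show_col_types = FALSE)
}

#' Myopathy prevalence from cohort summary counts
#'
#' @param counts A tibble as returned by [myopathy_cohort_summary()].
#' @return Prevalence as a percentage: `100 * yes / (yes + no)`.
#' @export
#' @examples
#' myopathy_prevalence(myopathy_cohort_summary())
myopathy_prevalence <- function(counts = myopathy_cohort_summary()) {
  stopifnot(all(c("myopathy", "n_patients") %in% names(counts)))
  yes <- sum(counts$n_patients[counts$myopathy == "yes"])
  no <- sum(counts$n_patients[counts$myopathy == "no"])
  if (yes + no == 0) abort("cohort summary has zero patients")
  100 * yes / (yes + no)
}
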