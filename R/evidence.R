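.valid_systems <- c("human liver microsomes", "human hepatocytes",
                    "recombinant CYP")

#' Extract in vitro substrate/inhibitor evidence from pattern matches
#'
#' A deterministic rule engine standing in for manual curation. An
#' assertion is emitted only when all extraction criteria pass:
#'
#' 1. the assay system is a human liver hepatocyte/microsome preparation or
#'    a recombinantly expressed CYP (`system` annotation);
#' 2. the reported probe is an FDA-listed probe reagent for the enzyme in
#'    question (`probe_used` annotation, checked against [fda_probes()]);
#' 3. the match carries an enzyme slot and a substrate- or
#'    inhibitor-family operator, and is not negated.
#'
#' Substrate-family operators (`O2`) yield substrate assertions; the
#' inhibit operator (`O1`) yields inhibitor assertions; induce-family and
#' interaction matches yield none.
#'
#' @param matches A pattern-match tibble from [scan_patterns()] run on a
#'   corpus (must carry `abstract_id`).
#' @param annotations A tibble with columns `abstract_id`, `system`,
#'   `probe_used` (a corpus tibble works as is).
#' @return An evidence tibble: `drug`, `enzyme`, `assertion`
#'   (`"substrate"`/`"inhibitor"`), `system`, `probe_used`, `source_id`.
#' @export
extract_invitro <- function(matches, annotations) {
  stopifnot("abstract_id" %in% names(matches))
  ann <- as_tibble(annotations) %>%
    select("abstract_id", "system", "probe_used") %>%
    distinct(.data$abstract_id, .keep_all = TRUE)

  cand <- matches %>%
    filter(!.data$negated,
           !is.na(.data$enzyme),
           .data$operator %in% c("O1", "O2")) %>%
    left_join(ann, by = "abstract_id")

  no_system <- cand %>% filter(is.na(.data$system))
  if (nrow(no_system)) {
    warn(sprintf("%d candidate assertion(s) skipped: missing assay system annotation",
                 nrow(no_system)))
  }

  probes <- fda_probes() %>% select("enzyme", probe_ok = "probe")
  out <- cand %>%
    filter(!is.na(.data$system), .data$system %in% .valid_systems) %>%
    semi_join(probes %>% rename(probe_used = "probe_ok"),
              by = c("enzyme", "probe_used")) %>%
    mutate(assertion = if_else(.data$operator == "O2", "substrate", "inhibitor")) %>%
    select(drug = "drug", enzyme = "enzyme", assertion = "assertion",
           system = "system", probe_used = "probe_used",
           source_id = "abstract_id") %>%
    distinct()
  out
}

#' Aggregate in vitro evidence into per-drug enzyme activities
#'
#' Collapses assertion-level evidence to one row per (drug, enzyme) with
#' substrate/inhibitor flags. Metabolism extent and Ki are taken from the
#' curated knowledge base when supplied (the stand-in for full-text
#' review); otherwise extent defaults to `"minor"` for substrates and Ki is
#' missing.
#'
#' @param evidence Output of [extract_invitro()].
#' @param kb Optional knowledge base carrying `extent` and `ki_um`.
#' @return An activity tibble as from [kb_activities()].
#' @export
evidence_to_activities <- function(evidence, kb = NULL) {
  acts <- evidence %>%
    group_by(.data$drug, .data$enzyme) %>%
    summarise(
      is_substrate = any(.data$assertion == "substrate"),
      is_inhibitor = any(.data$assertion == "inhibitor"),
      .groups = "drop"
    )
  if (!is.null(kb)) {
    acts <- acts %>%
      left_join(kb %>% select("drug", "enzyme", "extent", "ki_um"),
                by = c("drug", "enzyme"))
  } else {
    acts$extent <- NA_character_
    acts$ki_um <- NA_real_
  }
  acts %>%
    mutate(
      metabolism_extent = dplyr::case_when(
        !.data$is_substrate ~ "none",
        is.na(.data$extent) | .data$extent == "none" ~ "minor",
        TRUE ~ .data$extent
      ),
      potency_class = if_else(.data$is_inhibitor & !is.na(.data$ki_um),
                              classify_potency(.data$ki_um),
                              if_else(.data$is_inhibitor, NA_character_, "none"))
    ) %>%
    select("drug", "enzyme", "is_substrate", "is_inhibitor",
           "metabolism_extent", "ki_um", "potency_class")
}

#' Conclude in vivo DDI status from study-level evidence
#'
#' Applies the clinical-study decision rules to exposure-change evidence
#' (AUC ratio, Cmax ratio, half-life ratio, metabolic ratio or steady-state
#' ratio). Studies in pregnant women or newborns are excluded outright.
#'
#' Two rule variants are provided. `"methods_fallback"` (default): a DDI is
#' concluded when the reported p-value is below 0.05; when no p-value is
#' reported, a DDI is concluded when the parameter fold-change exceeds 2.0;
#' otherwise no-DDI. `"conjunction"`: a DDI requires both p < 0.05 and
#' fold-change > 2; if either reported criterion fails the verdict is
#' no-DDI, and if a needed value is missing the verdict is indeterminate.
#' With both fields missing the status is `"indeterminate"` under either
#' rule.
#'
#' @param evidence A tibble with columns `p_value`, `fold_change` (numeric,
#'   `NA` when unreported) and optional logical `pregnant`, `newborn`
#'   flags.
#' @param rule `"methods_fallback"` or `"conjunction"`.
#' @return The input with a `conclusion` column:
#'   `"DDI"`, `"no-DDI"`, `"excluded"`, or `"indeterminate"`.
#' @export
#' @examples
#' ev <- tibble::tibble(p_value = c(0.03, NA, 0.001),
#'                      fold_change = c(1.5, 2.5, NA),
#'                      pregnant = c(FALSE, FALSE, TRUE))
#' conclude_invivo(ev)
conclude_invivo <- function(evidence, rule = c("methods_fallback", "conjunction")) {
  rule <- match.arg(rule)
  ev <- as_tibble(evidence)
  pregnant <- if ("pregnant" %in% names(ev)) ev$pregnant else FALSE
  newborn <- if ("newborn" %in% names(ev)) ev$newborn else FALSE
  excluded <- tidyr::replace_na(pregnant, FALSE) | tidyr::replace_na(newborn, FALSE)
  p <- ev$p_value
  f <- ev$fold_change

  concl <- if (rule == "methods_fallback") {
    case_when(
      excluded ~ "excluded",
      is.na(p) & is.na(f) ~ "indeterminate",
      !is.na(p) & p < 0.05 ~ "DDI",
      !is.na(p) ~ "no-DDI",
      f > 2.0 ~ "DDI",
      TRUE ~ "no-DDI"
    )
  } else {
    case_when(
      excluded ~ "excluded",
      is.na(p) & is.na(f) ~ "indeterminate",
      (!is.na(p) & p >= 0.05) | (!is.na(f) & f <= 2.0) ~ "no-DDI",
      is.na(p) | is.na(f) ~ "indeterminate",
      TRUE ~ "DDI"
    )
  }
  ev$conclusion <- concl
  ev
}
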