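# End-to-end orchestration: simulate (or load) inputs, screen the corpus,
# predict pairs, cross-reference co-medication, build cohorts, run both DDI
# tests, correct for multiplicity, run enrichment, render the report.

#' Pipeline configuration
#'
#' Bundles stage parameters and rule switches. Defaults reproduce the
#' published analysis settings: 30-day windows, 6-month run-in exclusion,
#' family-wise alpha 0.05 with Bonferroni correction, age and sex
#' covariates, all-events mode.
#'
#' @param seed Root seed; all stage seeds derive from it.
#' @param out_dir Optional run directory; when given, every stage artifact
#'   (TSVs, report, log) is written there.
#' @param n_drugs,n_pos,n_neg,n_patients Synthetic input scale.
#' @param n_inject Number of predicted pairs to inject as true synergistic
#'   DDIs in the EMR.
#' @param theta Synergy multiplier of the injected pairs.
#' @param drug_risk Per-window risk added by each injected drug.
#' @param exposure_prob Per-drug exposure probability.
#' @param window_days,exclusion_days,alpha,event_mode,covariates Analysis
#'   settings.
#' @param invivo_rule,strong_rule,potency_boundary Rule switches (see
#'   [conclude_invivo()], [predict_pair_potency()]; the Ki boundary policy
#'   is recorded for provenance — values 10/100 uM sit in the moderate bin).
#' @param treatment_drugs Drugs that treat myopathy symptoms; pairs
#'   containing one are excluded from testing.
#' @param kb,corpus,emr Optional pre-built inputs; when supplied the
#'   corresponding simulation stage is skipped.
#' @return A list of class `pipeline_config`.
#' @export
ddi_pipeline_config <- function(seed = 1L,
                                out_dir = NULL,
                                n_drugs = 12,
                                n_pos = 40,
                                n_neg = 20,
                                n_patients = 5000,
                                n_inject = 2,
                                theta = 4,
                                drug_risk = 0.03,
                                exposure_prob = 0.15,
                                window_days = 30,
                                exclusion_days = 183,
                                alpha = 0.05,
                                event_mode = c("all_events", "first_event"),
                                covariates = c("age", "sex"),
                                invivo_rule = "methods_fallback",
                                strong_rule = "methods",
                                potency_boundary = "moderate",
                                treatment_drugs = character(),
                                kb = NULL, corpus = NULL, emr = NULL) {
  event_mode <- match.arg(event_mode)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    abort("`alpha` must be in (0, 1]", class = "cypddi_invalid_argument")
  }
  if (window_days <= 0 || exclusion_days < 0) {
    abort("window/exclusion lengths must be positive", class = "cypddi_invalid_argument")
  }
  structure(
    list(seed = as.integer(seed), out_dir = out_dir,
         n_drugs = n_drugs, n_pos = n_pos, n_neg = n_neg,
         n_patients = n_patients, n_inject = n_inject, theta = theta,
         drug_risk = drug_risk, exposure_prob = exposure_prob,
         window_days = window_days, exclusion_days = exclusion_days,
         alpha = alpha, event_mode = event_mode, covariates = covariates,
         invivo_rule = invivo_rule, strong_rule = strong_rule,
         potency_boundary = potency_boundary,
         treatment_drugs = treatment_drugs,
         kb = kb, corpus = corpus, emr = emr),
    class = "pipeline_config"
  )
}

.stamp <- function(msg) {
  inform(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), msg))
  msg
}

#' Run the DDI discovery and assessment pipeline end to end
#'
#' Stage order: simulate (knowledge base, corpus, EMR) -> screen (template
#' filter + pattern scan + rule-engine extraction) -> predict (pair
#' enumeration + potency) -> crossref (EMR co-medication) -> cohort
#' (episodes + exclusions) -> test (additive and synergistic models) ->
#' enrich -> report. Each stage logs its row counts, so the funnel
#' (predicted -> co-medicated -> tested -> significant) is reproducible
#' from the log. Identical config and seed give identical outputs.
#'
#' @param config A [ddi_pipeline_config()].
#' @return A list of class `ddi_pipeline_run`: `kb`, `corpus`, `screen`,
#'   `evidence`, `activities`, `pairs`, `emr`, `results` (tidied, one row
#'   per pair and model), `threshold`, `enrichment`, `report` (character
#'   lines), `funnel` (stage row counts), `config`.
#' @export
run_ddi_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  funnel <- list()
  note <- function(stage, n, what) {
    funnel[[length(funnel) + 1]] <<- tibble(stage = stage, n = n, what = what)
    .stamp(sprintf("%-9s %6d %s", stage, n, what))
  }

  # --- simulate inputs
  kb <- config$kb %||% simulate_knowledge_base(config$n_drugs,
                                               seed = config$seed + 1L)
  note("simulate", nrow(kb), "knowledge-base activity rows")

  # injected DDI pairs are drawn from the knowledge-base truth; the corpus
  # is guaranteed to carry their substrate/inhibitor assertions so the
  # literature screen can recover them (the truth channel)
  truth_pairs <- predict_pairs(kb_activities(kb))
  if (!nrow(truth_pairs)) {
    abort("stage simulate: the knowledge base admits no DDI pair; increase n_drugs",
          class = "cypddi_stage_error")
  }
  inject <- truth_pairs %>%
    distinct(.data$pair_key, .keep_all = TRUE) %>%
    head(config$n_inject)
  ensure <- bind_rows(
    tibble(drug = inject$substrate_drug,
           enzyme = map_chr(strsplit(inject$enzymes, ";"), 1),
           assertion = "substrate"),
    tibble(drug = inject$inhibitor_drug,
           enzyme = map_chr(strsplit(inject$enzymes, ";"), 1),
           assertion = "inhibitor")
  ) %>% distinct()

  corpus <- config$corpus %||%
    simulate_abstract_corpus(kb, max(config$n_pos, nrow(ensure)), config$n_neg,
                             ensure = ensure, seed = config$seed + 2L)
  note("simulate", nrow(corpus), "abstracts")

  # --- literature screen
  template <- default_screen_template(kb)
  drug_dict <- as_dictionary(unique(kb$drug))
  screen <- screen_corpus(corpus, template, drug_dict)
  note("screen", sum(screen$corpus$retrieved), "abstracts retrieved")
  evidence <- extract_invitro(screen$matches, corpus)
  note("screen", nrow(evidence), "in vitro assertions")
  activities <- evidence_to_activities(evidence, kb)
  note("screen", nrow(activities), "drug-enzyme activities")

  # --- predict pairs
  pairs <- predict_pairs(activities)
  pairs <- predict_pair_potency(pairs, activities, rule = config$strong_rule)
  unordered <- dplyr::n_distinct(pairs$pair_key)
  note("predict", unordered, "predicted DDI pairs (unordered)")
  if (!nrow(pairs)) abort("stage predict: no DDI pairs predicted",
                          class = "cypddi_stage_error")

  # --- EMR with injected effects on the chosen truth pairs
  emr <- config$emr
  if (is.null(emr)) {
    inj_drugs <- unique(c(inject$substrate_drug, inject$inhibitor_drug))
    sim_cfg <- sim_config(
      n_patients = config$n_patients,
      drug_risks = setNames(rep(config$drug_risk, length(inj_drugs)), inj_drugs),
      ddi_effects = tibble(drug1 = inject$substrate_drug,
                           drug2 = inject$inhibitor_drug,
                           theta = rep(config$theta, nrow(inject))),
      exposure_prob = config$exposure_prob,
      seed = config$seed + 3L
    )
    emr <- simulate_emr(sim_cfg, kb)
  }
  note("simulate", nrow(emr$person), "patients")

  # --- crossref
  pairs <- crossref_emr(pairs, emr, window_days = config$window_days)
  testable <- pairs %>%
    distinct(.data$pair_key, .keep_all = TRUE) %>%
    filter(!.data$excluded_from_testing,
           !(.data$substrate_drug %in% config$treatment_drugs),
           !(.data$inhibitor_drug %in% config$treatment_drugs))
  note("crossref", nrow(testable), "co-medicated pairs to test")

  # --- cohort + tests
  threshold <- bonferroni_threshold(config$alpha, max(1, nrow(testable)))
  results <- map_dfr(seq_len(nrow(testable)), function(i) {
    pair <- c(testable$substrate_drug[i], testable$inhibitor_drug[i])
    episodes <- build_episodes(emr, pair, mode = config$event_mode,
                               window_days = config$window_days)
    episodes <- apply_exclusions(episodes, db_start = min(emr$drug_exposure$start_date),
                                 treatment_drugs = config$treatment_drugs,
                                 exclusion_days = config$exclusion_days,
                                 conditions = emr$condition_occurrence)
    fits <- list()
    fits$additive <- tryCatch(
      tidy(fit_additive(episodes, covariates = config$covariates)),
      error = function(e) NULL
    )
    fits$synergistic <- tryCatch(
      tidy(fit_synergistic(episodes, covariates = config$covariates)),
      error = function(e) NULL
    )
    bind_rows(fits) %>% mutate(pair_key = testable$pair_key[i],
                               enzymes = testable$enzymes[i],
                               pair_potency = testable$pair_potency[i])
  })
  note("test", nrow(results), "model fits")
  if (!nrow(results)) abort("stage test: no pair could be tested",
                            class = "cypddi_stage_error")

  syn <- results %>% filter(.data$model == "synergistic")
  n_sig <- sum(!is.na(syn$p_value) & syn$p_value < threshold & syn$rr > 1,
               na.rm = TRUE)
  note("test", n_sig, sprintf("significant synergistic pairs (p < %.3g)", threshold))

  enrichment <- tryCatch(
    enzyme_enrichment(syn, pairs, threshold = threshold),
    error = function(e) tibble()
  )
  note("enrich", nrow(enrichment), "enzymes tested for enrichment")

  report <- render_ddi_report(results, enrichment, threshold = threshold)
  funnel <- bind_rows(funnel)

  run <- structure(
    list(kb = kb, corpus = corpus, screen = screen, evidence = evidence,
         activities = activities, pairs = pairs, emr = emr,
         results = results, threshold = threshold, enrichment = enrichment,
         report = report, funnel = funnel, config = config),
    class = "ddi_pipeline_run"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_knowledge_base(kb, file.path(config$out_dir, "knowledge_base.tsv"))
    readr::write_tsv(pairs %>% mutate(comed_count_in_emr = unlist(.data$comed_count_in_emr)),
                     file.path(config$out_dir, "predicted_pairs.tsv"))
    readr::write_tsv(results, file.path(config$out_dir, "results.tsv"))
    if (nrow(enrichment)) {
      readr::write_tsv(enrichment, file.path(config$out_dir, "enrichment.tsv"))
    }
    writeLines(report, file.path(config$out_dir, "report.md"))
    readr::write_tsv(funnel, file.path(config$out_dir, "funnel_log.tsv"))
    write_emr(emr, file.path(config$out_dir, "emr"))
  }
  run
}

#' @export
print.ddi_pipeline_run <- function(x, ...) {
  cat("<ddi_pipeline_run>\n")
  print(x$funnel, n = nrow(x$funnel))
  invisible(x)
}

#' Render a results report
#'
#' Formats per-pair test results the way the published tables print them:
#' risks to 3 decimals, relative risks to 2 decimals, scientific p-values
#' and group counts as "(m1/n1, m2/n2, m12/n12)".
#'
#' @param results Tidied results tibble (rows from [tidy.ddi_fit()]).
#' @param enrichment Optional [enzyme_enrichment()] output; an empty table
#'   yields a note instead of a section.
#' @param threshold Significance threshold quoted in the header.
#' @param file Optional path; when given the lines are also written there.
#' @return Character vector of markdown lines, invisibly when `file` is
#'   given.
#' @export
render_ddi_report <- function(results, enrichment = NULL, threshold = 0.05,
                              file = NULL) {
  if (!nrow(results)) abort("`results` must be non-empty",
                            class = "cypddi_invalid_argument")
  lines <- c("# DDI myopathy screen", "",
             sprintf("Significance threshold: p < %.3g (Bonferroni).", threshold),
             "", "## Synergistic model", "",
             "| drug 1 | drug 2 | enzymes | Risk1 | Risk2 | Risk12 | RR | p | (m1/n1, m2/n2, m12/n12) |",
             "|---|---|---|---|---|---|---|---|---|")
  syn <- results %>% filter(.data$model == "synergistic")
  for (i in seq_len(nrow(syn))) {
    r <- syn[i, ]
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %.3f | %.3f | %.3f | %.2f | %.2e | %s |",
      r$drug1, r$drug2, r$enzymes %||% "", r$risk1, r$risk2, r$risk12,
      r$rr, r$p_value, r$counts
    ))
  }
  add <- results %>% filter(.data$model == "additive")
  if (nrow(add)) {
    lines <- c(lines, "", "## Additive model", "",
               "| drug 1 | drug 2 | OR (joint vs substrate) | p |",
               "|---|---|---|---|")
    for (i in seq_len(nrow(add))) {
      r <- add[i, ]
      lines <- c(lines, sprintf("| %s | %s | %.2f | %.2e |",
                                r$drug1, r$drug2,
                                r$or_joint_vs_substrate, r$p_value))
    }
  }
  lines <- c(lines, "", "## CYP enrichment", "")
  if (is.null(enrichment) || !nrow(enrichment)) {
    lines <- c(lines, "No enrichment results (no tested pair mapped to an enzyme).")
  } else {
    lines <- c(lines,
               "| enzyme | significant/in | significant/out | p |",
               "|---|---|---|---|",
               map_chr(seq_len(nrow(enrichment)), function(i) {
                 e <- enrichment[i, ]
                 sprintf("| %s | %d/%d | %d/%d | %.2e |", e$enzyme,
                         e$n_sig_in, e$n_in, e$n_sig_out, e$n_out, e$p_value)
               }))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
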