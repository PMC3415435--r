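# Synthetic EMR generator. One 30-day exposure window per patient,
# anchored at a uniformly drawn date; dispensings fall inside the window so
# the cohort builder reconstructs the generated groups exactly.

.window_days_default <- 30

# per-person background window risk: sex-specific marginal, age-adjusted on
# the odds scale centred at the cohort mean age (keeps marginals calibrated)
.base_risk <- function(sex, age, config) {
  base <- if_else(sex == "F", config$sex_risk[["female"]],
                  config$sex_risk[["male"]])
  lo <- qlogis(pmin(pmax(base, 1e-12), 1 - 1e-12)) +
    log(config$age_or_per_year) * (age - config$age_mean)
  pmin(1, plogis(lo) + config$baseline_window_risk)
}

#' Simulate OMOP-like EMR tables with injected drug and DDI effects
#'
#' Generates three tables: `person(person_id, sex, birth_year)`,
#' `drug_exposure(person_id, drug_name, start_date)`,
#' `condition_occurrence(person_id, concept_name, event_date)`. Each
#' patient has one 30-day exposure window ending at an anchor date drawn
#' uniformly over the study span. Exposure to each risk drug is independent
#' with probability `config$exposure_prob`; dispensing dates fall inside
#' the window. Extra risk-free co-medications are Poisson with mean
#' `config$comed_rate`.
#'
#' The window's myopathy probability is the sex-specific, age-adjusted
#' background (`sim_config()` defaults reproduce the published female/male
#' window risks 0.086/0.054 and age odds multiplier 1.0015/year) plus
#' additive per-drug risks; a window jointly exposed to a configured DDI
#' pair gets `theta * (Risk_A + Risk_B)`, capped at 1 with a warning when
#' capping occurs. Myopathy events are dated at the anchor with a concept
#' drawn from the packaged myopathy concept set.
#'
#' @param config A [sim_config()].
#' @param kb Optional knowledge base; when supplied, configured risk drugs
#'   must exist in it.
#' @return A list of class `ddi_emr` with elements `person`,
#'   `drug_exposure`, `condition_occurrence`; generative parameters and the
#'   per-patient truth table are attached as `ground_truth`.
#' @export
#' @examples
#' cfg <- sim_config(500, drug_risks = c(drug_001 = 0.02, drug_002 = 0.02),
#'                   ddi_effects = tibble::tibble(drug1 = "drug_001",
#'                                                drug2 = "drug_002",
#'                                                theta = 3),
#'                   seed = 9)
#' emr <- simulate_emr(cfg)
simulate_emr <- function(config, kb = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(kb) && length(config$drug_risks)) {
    missing <- setdiff(names(config$drug_risks), unique(kb$drug))
    if (length(missing)) {
      abort(paste0("risk drugs absent from kb: ", paste(missing, collapse = ", ")),
            class = "cypddi_invalid_argument")
    }
  }
  set.seed(config$seed)
  n <- config$n_patients
  sex <- if_else(runif(n) < config$female_fraction, "F", "M")
  age <- pmin(100, pmax(0, rnorm(n, config$age_mean, config$age_sd)))

  span <- as.integer(config$study_end - config$study_start)
  anchor_offset <- sample.int(span - .window_days_default, n, replace = TRUE) +
    .window_days_default
  anchor <- config$study_start + anchor_offset
  birth_year <- as.integer(format(anchor, "%Y")) - as.integer(round(age))

  person <- tibble(
    person_id = seq_len(n),
    sex = sex,
    birth_year = birth_year
  )

  risk_drugs <- names(config$drug_risks)
  exposed <- matrix(runif(n * length(risk_drugs)) < config$exposure_prob,
                    nrow = n,
                    dimnames = list(NULL, risk_drugs))

  base <- .base_risk(sex, age, config)
  p_event <- base + if (length(risk_drugs)) {
    as.numeric(exposed %*% config$drug_risks[risk_drugs])
  } else {
    0
  }
  # synergy overrides the additive rule for jointly exposed configured pairs
  if (nrow(config$ddi_effects)) {
    for (k in seq_len(nrow(config$ddi_effects))) {
      d1 <- config$ddi_effects$drug1[k]
      d2 <- config$ddi_effects$drug2[k]
      th <- config$ddi_effects$theta[k]
      joint <- exposed[, d1] & exposed[, d2]
      if (any(joint)) {
        r1 <- base[joint] + config$drug_risks[[d1]]
        r2 <- base[joint] + config$drug_risks[[d2]]
        p_event[joint] <- pmax(p_event[joint], th * (r1 + r2))
      }
    }
  }
  if (any(p_event > 1)) {
    warn(sprintf("%d window risk(s) exceeded 1 and were capped", sum(p_event > 1)))
    p_event <- pmin(1, p_event)
  }
  event <- runif(n) < p_event

  # dispensings: risk drugs where exposed, plus Poisson co-medications,
  # all dated inside the window [anchor - 30, anchor]
  disp_risk <- if (length(risk_drugs)) {
    idx <- which(exposed, arr.ind = TRUE)
    if (nrow(idx)) {
      tibble(
        person_id = idx[, 1],
        drug_name = risk_drugs[idx[, 2]],
        start_date = anchor[idx[, 1]] -
          sample.int(.window_days_default + 1L, nrow(idx), replace = TRUE) + 1L
      )
    } else {
      NULL
    }
  } else {
    NULL
  }
  comed_pool <- sprintf("comed_%02d", 1:40)
  n_comed <- pmin(rpois(n, config$comed_rate), length(comed_pool))
  disp_comed <- if (sum(n_comed)) {
    pid <- rep(seq_len(n), n_comed)
    # distinct names per patient, so the per-window count matches the rate
    names <- unlist(lapply(n_comed[n_comed > 0], sample, x = comed_pool))
    tibble(
      person_id = pid,
      drug_name = names,
      start_date = anchor[pid] -
        sample.int(.window_days_default + 1L, sum(n_comed), replace = TRUE) + 1L
    )
  } else {
    NULL
  }
  drug_exposure <- bind_rows(disp_risk, disp_comed) %>%
    distinct(.data$person_id, .data$drug_name, .keep_all = TRUE) %>%
    arrange(.data$person_id, .data$drug_name)

  concepts <- c("Myalgia and myositis", "Muscle weakness", "Myositis",
                "Rhabdomyolysis")
  condition_occurrence <- tibble(
    person_id = which(event),
    concept_name = sample(concepts, sum(event), replace = TRUE,
                          prob = c(0.8, 0.15, 0.04, 0.01)),
    event_date = anchor[event]
  )

  truth <- tibble(
    person_id = seq_len(n), sex = sex, age = age,
    anchor_date = anchor, p_event = p_event, event = event
  )
  if (length(risk_drugs)) {
    truth <- bind_cols(truth, as_tibble(exposed))
  }
  structure(
    list(person = person, drug_exposure = drug_exposure,
         condition_occurrence = condition_occurrence),
    class = "ddi_emr",
    ground_truth = list(config = config, truth = truth)
  )
}

#' @export
print.ddi_emr <- function(x, ...) {
  cat("<ddi_emr>", nrow(x$person), "persons,",
      nrow(x$drug_exposure), "dispensings,",
      nrow(x$condition_occurrence), "condition rows\n")
  invisible(x)
}

#' Simulate the three exposure groups of one DDI test directly
#'
#' A lightweight generator for calibration and power studies: draws binary
#' myopathy outcomes for the substrate-alone, inhibitor-alone and joint
#' groups with `Risk12 = theta * (Risk1 + Risk2)` (capped at 1), optionally
#' with age/sex covariates acting on the log-odds scale within each group.
#'
#' @param n1,n2,n12 Group sizes.
#' @param risk1,risk2 Single-exposure window risks.
#' @param theta Synergy multiplier (1 = exact additivity, the null).
#' @param covariates If `TRUE`, adds `age_at_anchor` and `sex` columns with
#'   the default demographic effects (odds 1.0015/year, female/male odds
#'   from the default risk pair), recentring each group to its target risk.
#' @param seed Optional integer seed.
#' @return An episode tibble usable by [fit_additive()] /
#'   [fit_synergistic()]: columns `group`, `outcome`, and covariates.
#' @export
simulate_episode_groups <- function(n1, n2, n12, risk1, risk2, theta = 1,
                                    covariates = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  risk12 <- min(1, theta * (risk1 + risk2))
  grp <- c(rep("substrate_alone", n1), rep("inhibitor_alone", n2),
           rep("joint", n12))
  target <- c(rep(risk1, n1), rep(risk2, n2), rep(risk12, n12))
  n <- length(grp)
  if (covariates) {
    age <- pmin(100, pmax(0, rnorm(n, 40.2, 23)))
    sex <- if_else(runif(n) < 0.591, "F", "M")
    sex_shift <- if_else(sex == "F",
                         qlogis(0.086) - qlogis(0.07),
                         qlogis(0.054) - qlogis(0.07))
    lo <- qlogis(pmin(pmax(target, 1e-12), 1 - 1e-12)) +
      log(1.0015) * (age - 40.2) + sex_shift
    p <- plogis(lo)
    out <- tibble(group = grp, outcome = runif(n) < p,
                  age_at_anchor = age, sex = sex)
  } else {
    out <- tibble(group = grp, outcome = runif(n) < target)
  }
  attr(out, "ground_truth") <- list(
    n1 = n1, n2 = n2, n12 = n12, risk1 = risk1, risk2 = risk2,
    theta = theta, risk12 = risk12
  )
  out
}
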