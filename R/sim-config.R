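#' Simulation configuration for synthetic EMR generation
#'
#' Bundles the generative parameters of the synthetic-data world. Defaults
#' reproduce the demographic effects reported for the source EMR cohort:
#' per-window myopathy risk 0.086 for females and 0.054 for males, an odds
#' multiplier of 1.0015 per year of age, a 59.1% female cohort with ages
#' drawn from N(40.2, 23^2) truncated to \[0, 100\], and a mean of 3.8
#' medications per exposure window.
#'
#' Drug effects are additive on the risk scale: a window exposed to drug d
#' has risk `base + drug_risks[d]` (capped at 1), where `base` is the
#' sex-specific, age-adjusted background. A window jointly exposed to a
#' configured DDI pair (A, B) instead gets
#' `theta * (Risk_A + Risk_B)`, the synergy model the pipeline estimates as
#' RR. No unexposed background beyond the sex/age term is assumed
#' (`baseline_window_risk = 0`); it is a free offset because the source
#' study reports no background myopathy rate in unexposed patients.
#'
#' @param n_patients Number of patients.
#' @param study_start,study_end Calendar bounds of the database (`Date`).
#' @param female_fraction Probability a patient is female.
#' @param age_mean,age_sd Age distribution in years (truncated to \[0,100\]).
#' @param baseline_window_risk Extra per-window myopathy risk added to every
#'   window regardless of exposure.
#' @param sex_risk Named numeric, per-window myopathy risk by sex with no
#'   drug effect: `c(female = , male = )`.
#' @param age_or_per_year Odds multiplier per year of age (centred at
#'   `age_mean`, so the sex marginals stay calibrated).
#' @param drug_risks Named numeric: per-window risk added by exposure to
#'   each drug. May be empty.
#' @param ddi_effects Tibble with columns `drug1`, `drug2`, `theta`: the
#'   synergy multiplier applied to jointly exposed windows. May be empty.
#' @param exposure_prob Probability a patient's window is exposed to each
#'   drug in `drug_risks` (independently per drug).
#' @param comed_rate Mean number of extra (risk-free) co-medications per
#'   window (Poisson).
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 1000, seed = 1)
sim_config <- function(n_patients,
                       study_start = as.Date("2004-01-01"),
                       study_end = as.Date("2009-12-31"),
                       female_fraction = 0.591,
                       age_mean = 40.2,
                       age_sd = 23,
                       baseline_window_risk = 0,
                       sex_risk = c(female = 0.086, male = 0.054),
                       age_or_per_year = 1.0015,
                       drug_risks = numeric(0),
                       ddi_effects = tibble(drug1 = character(),
                                            drug2 = character(),
                                            theta = numeric()),
                       exposure_prob = 0.1,
                       comed_rate = 3.8,
                       seed = 1L) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (!is.numeric(n_patients) || n_patients < 1) {
    abort("`n_patients` must be a positive count", class = "cypddi_invalid_argument")
  }
  if (study_end <= study_start) {
    abort("`study_end` must be after `study_start`", class = "cypddi_invalid_argument")
  }
  probs <- c(female_fraction, baseline_window_risk, sex_risk, exposure_prob,
             unname(drug_risks))
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]", class = "cypddi_invalid_argument")
  }
  if (!all(c("female", "male") %in% names(sex_risk))) {
    abort("`sex_risk` must be named c(female=, male=)", class = "cypddi_invalid_argument")
  }
  ddi_effects <- as_tibble(ddi_effects)
  if (nrow(ddi_effects)) {
    stopifnot(all(c("drug1", "drug2", "theta") %in% names(ddi_effects)))
    if (any(ddi_effects$theta <= 0)) {
      abort("synergy multipliers `theta` must be > 0", class = "cypddi_invalid_argument")
    }
    missing_risk <- setdiff(unique(c(ddi_effects$drug1, ddi_effects$drug2)),
                            names(drug_risks))
    if (length(missing_risk)) {
      abort(paste0("ddi_effects drugs lack entries in `drug_risks`: ",
                   paste(missing_risk, collapse = ", ")),
            class = "cypddi_invalid_argument")
    }
  }
  if (age_or_per_year <= 0) {
    abort("`age_or_per_year` must be > 0", class = "cypddi_invalid_argument")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      study_start = study_start, study_end = study_end,
      female_fraction = female_fraction,
      age_mean = age_mean, age_sd = age_sd,
      baseline_window_risk = baseline_window_risk,
      sex_risk = sex_risk,
      age_or_per_year = age_or_per_year,
      drug_risks = drug_risks,
      ddi_effects = ddi_effects,
      exposure_prob = exposure_prob,
      comed_rate = comed_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_patients, "patients,",
      format(x$study_start), "to", format(x$study_end), "\n")
  cat("  sex_risk F/M:", x$sex_risk[["female"]], "/", x$sex_risk[["male"]],
      "; age OR/yr:", x$age_or_per_year, "\n")
  cat("  risk drugs:", length(x$drug_risks),
      "; DDI pairs:", nrow(x$ddi_effects),
      "; seed:", x$seed, "\n")
  invisible(x)
}

#' Extract the generative ground truth attached to a synthetic object
#'
#' @param x An object produced by one of the `simulate_*()` generators.
#' @return The ground-truth record (a list or tibble), or `NULL`.
#' @export
ground_truth <- function(x) attr(x, "ground_truth", exact = TRUE)
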