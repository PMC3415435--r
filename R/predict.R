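#' Classify inhibition potency from the inhibition constant Ki
#'
#' Bins Ki (uM) into potency classes: strong below 10 uM, moderate from 10
#' to 100 uM, weak above 100 uM. The boundary values 10 and 100 fall in the
#' moderate bin (the published bin notation is open, "10 < Ki < 100"; the
#' boundary assignment is a documented package decision).
#'
#' @param ki_um Numeric vector of inhibition constants in uM; must be
#'   positive. `NA` passes through as `NA`.
#' @return Character vector: `"strong"`, `"moderate"`, or `"weak"`.
#' @export
#' @examples
#' classify_potency(c(5, 50, 150))
classify_potency <- function(ki_um) {
  if (any(!is.na(ki_um) & ki_um <= 0)) {
    abort("`ki_um` must be positive", class = "cypddi_invalid_argument")
  }
  case_when(
    is.na(ki_um) ~ NA_character_,
    ki_um < 10 ~ "strong",
    ki_um <= 100 ~ "moderate",
    TRUE ~ "weak"
  )
}

.pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Enumerate predicted DDI pairs from enzyme activities
#'
#' For each enzyme, every (substrate, inhibitor) ordered pair of distinct
#' drugs is a predicted DDI. Pairs sharing several enzymes are merged into
#' one record carrying the enzyme set; output is sorted by (substrate,
#' inhibitor). An unordered `pair_key` column supports deduplicated
#' counting: the published pair counts treat (A, B) and (B, A) as one pair.
#'
#' @param activities An activity tibble (see [kb_activities()] /
#'   [evidence_to_activities()]): columns `drug`, `enzyme`, `is_substrate`,
#'   `is_inhibitor`.
#' @return A tibble of class `ddi_pairs`: `substrate_drug`,
#'   `inhibitor_drug`, `enzymes` (";"-joined, sorted), `pair_key`.
#' @export
#' @examples
#' kb <- simulate_knowledge_base(8, seed = 2)
#' predict_pairs(kb_activities(kb))
predict_pairs <- function(activities) {
  stopifnot(all(c("drug", "enzyme", "is_substrate", "is_inhibitor") %in%
                  names(activities)))
  subs <- activities %>% filter(.data$is_substrate) %>%
    select(substrate_drug = "drug", "enzyme")
  inhs <- activities %>% filter(.data$is_inhibitor) %>%
    select(inhibitor_drug = "drug", "enzyme")
  pairs <- inner_join(subs, inhs, by = "enzyme",
                      relationship = "many-to-many") %>%
    filter(.data$substrate_drug != .data$inhibitor_drug) %>%
    group_by(.data$substrate_drug, .data$inhibitor_drug) %>%
    summarise(enzymes = paste(sort(unique(.data$enzyme)), collapse = ";"),
              .groups = "drop") %>%
    mutate(pair_key = .pair_key(.data$substrate_drug, .data$inhibitor_drug)) %>%
    arrange(.data$substrate_drug, .data$inhibitor_drug)
  class(pairs) <- c("ddi_pairs", class(pairs))
  pairs
}

#' Classify the potency of predicted DDI pairs
#'
#' Combines metabolism extent and inhibition potency on the shared enzymes,
#' evaluated over both drug orderings (either drug may be the substrate).
#'
#' Under `rule = "methods"` a pair is strong when some shared enzyme is a
#' major metabolism route for one drug while the other drug inhibits that
#' enzyme strongly; moderate when a shared enzyme has (major route,
#' moderate inhibition) or (minor route, strong inhibition); otherwise
#' weak. Under `rule = "table5"` strong inhibition of any metabolised route
#' (major or minor) makes the pair strong and moderate inhibition makes it
#' moderate, reproducing the published potency table, which labels a
#' minor-route/strong-inhibitor pair as strong. The two rules disagree on
#' exactly that configuration; both are kept selectable.
#'
#' @param pairs A `ddi_pairs` tibble from [predict_pairs()].
#' @param activities The activity tibble the pairs were derived from (must
#'   carry `metabolism_extent` and `potency_class`).
#' @param rule `"methods"` (default) or `"table5"`.
#' @return `pairs` with a `pair_potency` column
#'   (`"strong"`/`"moderate"`/`"weak"`).
#' @export
predict_pair_potency <- function(pairs, activities,
                                 rule = c("methods", "table5")) {
  rule <- match.arg(rule)
  need <- c("metabolism_extent", "potency_class")
  if (!all(need %in% names(activities))) {
    abort("`activities` must carry metabolism_extent and potency_class",
          class = "cypddi_invalid_argument")
  }
  act <- activities %>%
    select("drug", "enzyme", "metabolism_extent", "potency_class")

  score_pair <- function(substrate_drug, inhibitor_drug, enzymes) {
    enz <- strsplit(enzymes, ";", fixed = TRUE)[[1]]
    combos <- tidyr::expand_grid(
      enzyme = enz,
      sub = c(substrate_drug, inhibitor_drug)
    ) %>%
      mutate(inh = if_else(.data$sub == substrate_drug,
                           inhibitor_drug, substrate_drug)) %>%
      left_join(act %>% select("drug", "enzyme", route = "metabolism_extent"),
                by = c(sub = "drug", "enzyme")) %>%
      left_join(act %>% select("drug", "enzyme", potency = "potency_class"),
                by = c(inh = "drug", "enzyme"))
    if (all(is.na(combos$route) | is.na(combos$potency))) {
      warn("missing metabolism extent or inhibition potency; treating as weak")
    }
    route <- tidyr::replace_na(combos$route, "none")
    potency <- tidyr::replace_na(combos$potency, "none")
    if (rule == "methods") {
      if (any(route == "major" & potency == "strong")) return("strong")
      if (any((route == "major" & potency == "moderate") |
              (route == "minor" & potency == "strong"))) return("moderate")
      "weak"
    } else {
      if (any(route %in% c("major", "minor") & potency == "strong")) return("strong")
      if (any(route %in% c("major", "minor") & potency == "moderate")) return("moderate")
      "weak"
    }
  }

  pairs %>%
    mutate(pair_potency = pmap(
      list(.data$substrate_drug, .data$inhibitor_drug, .data$enzymes),
      score_pair
    ) %>% unlist())
}

#' Cross-reference predicted pairs with EMR co-medication
#'
#' Counts, per predicted pair, the number of patients with dispensings of
#' both drugs at most `window_days` apart. Pairs never co-dispensed are
#' flagged `excluded_from_testing`; only co-medicated pairs proceed to the
#' cohort tests.
#'
#' @param pairs A `ddi_pairs` tibble.
#' @param emr An EMR table list (see [simulate_emr()] / [read_emr()]).
#' @param window_days Maximum days between the two dispensings (closed
#'   bound: exactly `window_days` apart counts, one day more does not).
#' @return `pairs` with `comed_count_in_emr` and `excluded_from_testing`
#'   columns.
#' @export
crossref_emr <- function(pairs, emr, window_days = 30) {
  dx <- emr$drug_exposure
  stopifnot(all(c("person_id", "drug_name", "start_date") %in% names(dx)))
  dx$start_date <- as.Date(dx$start_date)
  known <- unique(dx$drug_name)
  missing <- setdiff(unique(c(pairs$substrate_drug, pairs$inhibitor_drug)), known)
  if (length(missing)) {
    warn(paste0("drugs absent from the EMR vocabulary (count 0): ",
                paste(missing, collapse = ", ")))
  }
  count_one <- function(d1, d2) {
    a <- dx %>% filter(.data$drug_name == d1) %>%
      select("person_id", date1 = "start_date")
    b <- dx %>% filter(.data$drug_name == d2) %>%
      select("person_id", date2 = "start_date")
    if (!nrow(a) || !nrow(b)) return(0L)
    inner_join(a, b, by = "person_id", relationship = "many-to-many") %>%
      filter(abs(as.numeric(.data$date1 - .data$date2)) <= window_days) %>%
      dplyr::pull(.data$person_id) %>%
      dplyr::n_distinct()
  }
  pairs %>%
    mutate(
      comed_count_in_emr = map2(.data$substrate_drug, .data$inhibitor_drug,
                                count_one) %>% unlist(),
      excluded_from_testing = .data$comed_count_in_emr == 0
    )
}
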