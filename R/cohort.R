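# Retrospective-cohort construction: 30-day closed exposure windows
# [anchor - window_days, anchor], anchored at myopathy dates for cases and
# at dispensing dates for controls.

# tolerant ISO-8601 parsing: malformed strings become NA, not errors
.parse_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  suppressWarnings(as.Date(as.character(x), format = "%Y-%m-%d"))
}

#' Build exposure episodes for one drug pair
#'
#' Cases are persons with a myopathy concept: each myopathy date is an
#' anchor, and the window content assigns the group — substrate only in the
#' window gives `substrate_alone`, inhibitor only `inhibitor_alone`, both
#' `joint`; an anchor with neither drug in the window contributes no
#' episode. Controls are persons with no myopathy concept: their episode is
#' anchored at the first substrate dispensing (or, by symmetry, the first
#' inhibitor dispensing when the substrate was never dispensed), and is
#' `joint` when the two drugs were dispensed at most `window_days` apart,
#' anchored at the later of the two dispensings.
#'
#' Windows are date-inclusive closed intervals: a dispensing exactly
#' `window_days` before the anchor is inside, one day earlier is outside.
#' Multiple dispensings of the same drug in a window count once.
#'
#' @param emr An EMR list (`person`, `drug_exposure`,
#'   `condition_occurrence`), e.g. from [simulate_emr()] or [read_emr()].
#' @param pair Character vector of length 2: `(substrate, inhibitor)`.
#' @param concept_set Myopathy concept names defining the outcome.
#' @param mode `"all_events"` keeps every myopathy anchor;
#'   `"first_event"` keeps each person's earliest one only.
#' @param window_days Window length in days (default 30).
#' @return An episode tibble: `person_id`, `drug1`, `drug2`, `group`,
#'   `anchor_date`, `window_start`, `outcome`, `age_at_anchor`, `sex`,
#'   `comed_count`, `event_rank`.
#' @export
build_episodes <- function(emr, pair, concept_set = myopathy_concepts(),
                           mode = c("all_events", "first_event"),
                           window_days = 30) {
  mode <- match.arg(mode)
  if (length(pair) != 2 || pair[1] == pair[2]) {
    abort("`pair` must be two distinct drug names", class = "cypddi_invalid_argument")
  }
  if (!length(concept_set)) {
    abort("`concept_set` must be non-empty", class = "cypddi_invalid_argument")
  }
  person <- emr$person
  dx <- emr$drug_exposure %>% mutate(start_date = .parse_date(.data$start_date))
  cond <- emr$condition_occurrence %>%
    mutate(event_date = .parse_date(.data$event_date)) %>%
    filter(.data$concept_name %in% concept_set)
  bad_dates <- sum(is.na(cond$event_date))
  if (bad_dates) {
    warn(sprintf("%d myopathy row(s) without a parsable date were skipped", bad_dates))
    cond <- cond %>% filter(!is.na(.data$event_date))
  }

  d1 <- dx %>% filter(.data$drug_name == pair[1])
  d2 <- dx %>% filter(.data$drug_name == pair[2])
  myo_persons <- unique(cond$person_id)

  in_window <- function(dates_tbl, pid, anchor) {
    any(dates_tbl$person_id == pid &
          dates_tbl$start_date >= anchor - window_days &
          dates_tbl$start_date <= anchor)
  }

  # ---- cases: anchored at myopathy dates
  anchors <- cond %>%
    select("person_id", anchor_date = "event_date") %>%
    distinct() %>%
    arrange(.data$person_id, .data$anchor_date) %>%
    group_by(.data$person_id) %>%
    mutate(event_rank = if_else(row_number() == 1, "first", "subsequent")) %>%
    ungroup()
  if (mode == "first_event") {
    anchors <- anchors %>% filter(.data$event_rank == "first")
  }
  cases <- anchors %>%
    mutate(
      has1 = map2_lgl_(.data$person_id, .data$anchor_date,
                       function(p, a) in_window(d1, p, a)),
      has2 = map2_lgl_(.data$person_id, .data$anchor_date,
                       function(p, a) in_window(d2, p, a))
    ) %>%
    filter(.data$has1 | .data$has2) %>%
    mutate(
      group = case_when(
        .data$has1 & .data$has2 ~ "joint",
        .data$has1 ~ "substrate_alone",
        TRUE ~ "inhibitor_alone"
      ),
      outcome = TRUE
    ) %>%
    select("person_id", "group", "anchor_date", "outcome", "event_rank")

  # ---- controls: persons with no myopathy, anchored at dispensings
  ctrl_pid <- setdiff(unique(c(d1$person_id, d2$person_id)), myo_persons)
  controls <- map_dfr(ctrl_pid, function(pid) {
    s_dates <- sort(d1$start_date[d1$person_id == pid])
    i_dates <- sort(d2$start_date[d2$person_id == pid])
    if (length(s_dates) && length(i_dates)) {
      gaps <- abs(outer(as.numeric(s_dates), as.numeric(i_dates), "-"))
      if (min(gaps) <= window_days) {
        k <- which(gaps == min(gaps), arr.ind = TRUE)[1, ]
        anchor <- max(s_dates[k[1]], i_dates[k[2]])
        return(tibble(person_id = pid, group = "joint", anchor_date = anchor,
                      outcome = FALSE, event_rank = "control"))
      }
    }
    if (length(s_dates)) {
      tibble(person_id = pid, group = "substrate_alone",
             anchor_date = s_dates[1], outcome = FALSE, event_rank = "control")
    } else {
      tibble(person_id = pid, group = "inhibitor_alone",
             anchor_date = i_dates[1], outcome = FALSE, event_rank = "control")
    }
  })

  episodes <- bind_rows(cases, controls)
  if (!nrow(episodes)) {
    episodes <- tibble(person_id = integer(), group = character(),
                       anchor_date = as.Date(character()), outcome = logical(),
                       event_rank = character())
  }
  episodes <- episodes %>%
    mutate(drug1 = pair[1], drug2 = pair[2]) %>%
    left_join(person, by = "person_id") %>%
    mutate(
      age_at_anchor = as.integer(format(.data$anchor_date, "%Y")) - .data$birth_year,
      window_start = .data$anchor_date - window_days
    ) %>%
    select("person_id", "drug1", "drug2", "group", "anchor_date",
           "window_start", "outcome", "age_at_anchor", "sex", "event_rank") %>%
    arrange(.data$person_id, .data$anchor_date)
  episodes <- count_comeds(emr, episodes, window_days = window_days)
  attr(episodes, "pair") <- pair
  episodes
}

# small wrapper so build_episodes stays readable
map2_lgl_ <- function(x, y, f) purrr::map2_lgl(x, y, f)

#' Count distinct co-medications in each episode window
#'
#' The number of distinct drug names dispensed during the exposure window,
#' used as a comorbidity-surrogate covariate. The index pair drugs are
#' included by default (a window holding only the substrate counts 1);
#' set `include_pair_drugs = FALSE` to count only the others.
#'
#' @param emr An EMR list.
#' @param episodes An episode tibble from [build_episodes()] (columns
#'   `person_id`, `anchor_date`, `window_start`, `drug1`, `drug2`).
#' @param window_days Window length (used only if `window_start` missing).
#' @param include_pair_drugs Count the index pair drugs themselves?
#' @return `episodes` with a `comed_count` column.
#' @export
count_comeds <- function(emr, episodes, window_days = 30,
                         include_pair_drugs = TRUE) {
  dx <- emr$drug_exposure %>% mutate(start_date = as.Date(.data$start_date))
  if (!"window_start" %in% names(episodes)) {
    episodes$window_start <- episodes$anchor_date - window_days
  }
  counts <- purrr::pmap_int(
    list(episodes$person_id, episodes$window_start, episodes$anchor_date,
         episodes$drug1, episodes$drug2),
    function(pid, ws, ae, dr1, dr2) {
      drugs <- dx$drug_name[dx$person_id == pid &
                              dx$start_date >= ws & dx$start_date <= ae]
      if (!include_pair_drugs) drugs <- setdiff(drugs, c(dr1, dr2))
      length(unique(drugs))
    }
  )
  episodes$comed_count <- counts
  episodes
}

#' Apply database-start and treatment-drug exclusions
#'
#' Removes every episode of persons whose first myopathy event falls within
#' `exclusion_days` (default 183, six months) of the database start — an
#' earlier event cannot be ruled out for them. Pairs containing a drug
#' prescribed to treat myopathy symptoms (e.g. analgesics) are flagged
#' `pair_excluded` rather than dropped, so their episodes remain available
#' for other pairs.
#'
#' @param episodes An episode tibble.
#' @param db_start Database start `Date`.
#' @param treatment_drugs Drug names used to treat myopathy symptoms.
#' @param exclusion_days Length of the run-in exclusion period.
#' @param conditions Optional condition_occurrence table; when supplied,
#'   first myopathy dates come from it, otherwise from the case episodes.
#' @return The filtered episodes with a `pair_excluded` column; the
#'   per-reason exclusion counts are attached as attribute
#'   `"exclusion_log"` (a tibble `reason`, `n`).
#' @export
apply_exclusions <- function(episodes, db_start, treatment_drugs = character(),
                             exclusion_days = 183, conditions = NULL) {
  db_start <- as.Date(db_start)
  first_myo <- if (!is.null(conditions)) {
    conditions %>%
      mutate(event_date = as.Date(.data$event_date)) %>%
      group_by(.data$person_id) %>%
      summarise(first_date = min(.data$event_date), .groups = "drop")
  } else {
    episodes %>%
      filter(.data$outcome) %>%
      group_by(.data$person_id) %>%
      summarise(first_date = min(.data$anchor_date), .groups = "drop")
  }
  early <- first_myo$person_id[first_myo$first_date < db_start + exclusion_days]
  kept <- episodes %>% filter(!(.data$person_id %in% early))
  kept <- kept %>%
    mutate(pair_excluded = .data$drug1 %in% treatment_drugs |
             .data$drug2 %in% treatment_drugs)
  log <- tibble(
    reason = c("early_myopathy_person", "treatment_drug_pair_episode"),
    n = c(nrow(episodes) - nrow(kept), sum(kept$pair_excluded))
  )
  attr(kept, "exclusion_log") <- log
  attr(kept, "pair") <- attr(episodes, "pair", exact = TRUE)
  kept
}
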