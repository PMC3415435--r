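# Hand-built 6-person fixture (see helper-fixtures.R):
#   p1 substrate 10 d before myopathy; p2 both drugs 5 d before myopathy;
#   p3 substrate then inhibitor 45 d later, no myopathy;
#   p4 substrate exactly 30 d before myopathy; p5 substrate 31 d before;
#   p6 inhibitor only, no myopathy.
pair <- c("subA", "inhB")

test_that("episode groups follow the window rules on the hand fixture", {
  emr <- make_tiny_emr()
  ep <- build_episodes(emr, pair)

  e1 <- ep[ep$person_id == 1, ]
  expect_identical(e1$group, "substrate_alone")
  expect_true(e1$outcome)

  e2 <- ep[ep$person_id == 2, ]
  expect_identical(e2$group, "joint")
  expect_true(e2$outcome)

  # 45 days apart is not a joint control: substrate-alone, anchored at the
  # substrate dispensing
  e3 <- ep[ep$person_id == 3, ]
  expect_identical(e3$group, "substrate_alone")
  expect_false(e3$outcome)
  expect_identical(e3$anchor_date, as.Date("2004-08-01"))

  # window boundary: exactly 30 days in, 31 days out
  e4 <- ep[ep$person_id == 4, ]
  expect_identical(e4$group, "substrate_alone")
  expect_true(e4$outcome)
  expect_false(5 %in% ep$person_id) # 31 d: no exposure at the anchor

  # inhibitor-alone control anchored at the inhibitor dispensing
  e6 <- ep[ep$person_id == 6, ]
  expect_identical(e6$group, "inhibitor_alone")
  expect_identical(e6$anchor_date, as.Date("2004-10-01"))

  # partition: one group per (person, anchor), all episodes labelled
  expect_identical(anyDuplicated(ep[, c("person_id", "anchor_date")]), 0L)
  expect_true(all(ep$group %in% c("substrate_alone", "inhibitor_alone", "joint")))

  # joint control when dispensings are <= 30 days apart
  emr2 <- make_tiny_emr()
  emr2$drug_exposure$start_date[5] <- as.Date("2004-08-31") # 30 d after subA
  e3b <- build_episodes(emr2, pair)
  expect_identical(e3b$group[e3b$person_id == 3], "joint")
  expect_identical(e3b$anchor_date[e3b$person_id == 3], as.Date("2004-08-31"))
})

test_that("first-event mode keeps one case anchor per person", {
  emr <- make_tiny_emr()
  # give p1 a second myopathy event with exposure
  emr$condition_occurrence <- dplyr::bind_rows(
    emr$condition_occurrence,
    tibble::tibble(person_id = 1L, concept_name = "Muscle weakness",
                   event_date = as.Date("2004-10-05"))
  )
  ep_all <- build_episodes(emr, pair, mode = "all_events")
  expect_identical(sum(ep_all$person_id == 1), 2L)
  expect_setequal(ep_all$event_rank[ep_all$person_id == 1],
                  c("first", "subsequent"))
  ep_first <- build_episodes(emr, pair, mode = "first_event")
  expect_identical(sum(ep_first$person_id == 1), 1L)
  expect_identical(ep_first$event_rank[ep_first$person_id == 1], "first")
})

test_that("myopathy rows without parsable dates are skipped with a warning", {
  emr <- make_tiny_emr()
  emr$condition_occurrence$event_date <- as.character(emr$condition_occurrence$event_date)
  emr$condition_occurrence$event_date[2] <- "not-a-date"
  expect_warning(ep <- build_episodes(emr, pair), "parsable")
  expect_false(any(ep$person_id == 2 & ep$outcome))
})

test_that("co-medication counts are distinct drugs in the window", {
  emr <- make_tiny_emr()
  # p1 window [2004-08-31, 2004-09-30]: add 3 distinct others + 1 duplicate
  emr$drug_exposure <- dplyr::bind_rows(
    emr$drug_exposure,
    tibble::tibble(person_id = 1L,
                   drug_name = c("x1", "x2", "x3", "x1"),
                   start_date = as.Date(c("2004-09-05", "2004-09-10",
                                          "2004-09-28", "2004-09-12")))
  )
  ep <- build_episodes(emr, pair)
  expect_identical(ep$comed_count[ep$person_id == 1], 4L) # subA + x1 + x2 + x3
  expect_identical(ep$comed_count[ep$person_id == 4], 1L) # only the substrate
  ep_excl <- count_comeds(emr, ep, include_pair_drugs = FALSE)
  expect_identical(ep_excl$comed_count[ep_excl$person_id == 1], 3L)
})

test_that("the six-month run-in exclusion removes early myopathy persons", {
  emr <- make_tiny_emr()
  db_start <- as.Date("2004-01-01")
  # day 100 of the database: 2004-04-10 (< 183 d); day 200: 2004-07-19
  emr$condition_occurrence$event_date[1] <- as.Date("2004-04-10")
  emr$drug_exposure$start_date[1] <- as.Date("2004-04-01")
  ep <- build_episodes(emr, pair)
  out <- apply_exclusions(ep, db_start, conditions = emr$condition_occurrence)
  expect_false(1 %in% out$person_id)
  log <- attr(out, "exclusion_log")
  expect_identical(log$n[log$reason == "early_myopathy_person"], 1L)

  emr$condition_occurrence$event_date[1] <- as.Date("2004-07-19")
  emr$drug_exposure$start_date[1] <- as.Date("2004-07-10")
  ep2 <- build_episodes(emr, pair)
  out2 <- apply_exclusions(ep2, db_start, conditions = emr$condition_occurrence)
  expect_true(1 %in% out2$person_id)

  # treatment-drug pairs are flagged but episodes stay available
  out3 <- apply_exclusions(ep2, db_start, treatment_drugs = "inhB",
                           conditions = emr$condition_occurrence)
  expect_true(all(out3$pair_excluded))
  expect_identical(nrow(out3), nrow(out2))
})

test_that("invalid pair and concept-set arguments are rejected", {
  emr <- make_tiny_emr()
  expect_error(build_episodes(emr, c("subA", "subA")),
               class = "cypddi_invalid_argument")
  expect_error(build_episodes(emr, pair, concept_set = character()),
               class = "cypddi_invalid_argument")
})
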