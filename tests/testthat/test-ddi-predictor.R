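test_that("Ki potency bins follow the published cut-points", {
  expect_identical(classify_potency(5), "strong")
  expect_identical(classify_potency(50), "moderate")
  expect_identical(classify_potency(150), "weak")
  # boundary policy: 10 and 100 uM sit in the moderate bin
  expect_identical(classify_potency(c(10, 100)), c("moderate", "moderate"))
  expect_identical(classify_potency(c(9.999, 100.001)), c("strong", "weak"))
  expect_error(classify_potency(0), class = "cypddi_invalid_argument")
  expect_error(classify_potency(-3), class = "cypddi_invalid_argument")
  expect_identical(classify_potency(NA_real_), NA_character_)

  # monotone step function of Ki
  grid <- sort(exp(seq(log(0.1), log(1000), length.out = 60)))
  ranks <- c(strong = 1, moderate = 2, weak = 3)[classify_potency(grid)]
  expect_true(all(diff(ranks) >= 0))
})

test_that("pair prediction emits exactly the substrate x inhibitor pairs", {
  acts <- tibble::tibble(
    drug = c("subS", "inhI"), enzyme = "CYP3A4/5",
    is_substrate = c(TRUE, FALSE), is_inhibitor = c(FALSE, TRUE),
    metabolism_extent = c("major", "none"), ki_um = c(NA, 5),
    potency_class = c("none", "strong")
  )
  pairs <- predict_pairs(acts)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$substrate_drug, "subS")
  expect_identical(pairs$inhibitor_drug, "inhI")
  expect_identical(pairs$enzymes, "CYP3A4/5")

  # a drug that is both substrate and inhibitor of E, alone: no self-pair
  solo <- tibble::tibble(
    drug = "dualD", enzyme = "CYP2D6",
    is_substrate = TRUE, is_inhibitor = TRUE,
    metabolism_extent = "major", ki_um = 4, potency_class = "strong"
  )
  expect_identical(nrow(predict_pairs(solo)), 0L)
})

test_that("pair prediction equals the brute-force oracle on random knowledge bases", {
  for (seed in c(11, 12)) {
    kb <- simulate_knowledge_base(20, seed = seed)
    acts <- kb_activities(kb)
    got <- predict_pairs(acts)
    want <- oracle_pairs(acts)
    expect_identical(
      sort(paste(got$substrate_drug, got$inhibitor_drug, sep = "->")),
      want$directed
    )
    expect_identical(sort(unique(got$pair_key)), want$unordered)
    # multi-enzyme pairs are merged: one row per directed pair
    expect_identical(nrow(got),
                     nrow(dplyr::distinct(got, substrate_drug, inhibitor_drug)))
  }
})

test_that("pair potency combines metabolism route and inhibition strength", {
  acts <- tibble::tibble(
    drug = c("lor", "sim", "dul", "pro", "teg"),
    enzyme = c("CYP3A4/5", "CYP3A4/5", "CYP2D6", "CYP2D6", "CYP2D6"),
    is_substrate = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    is_inhibitor = c(FALSE, TRUE, TRUE, FALSE, TRUE),
    metabolism_extent = c("major", "none", "none", "minor", "none"),
    ki_um = c(NA, 5, 50, NA, 2),
    potency_class = c("none", "strong", "moderate", "none", "strong")
  )
  pairs <- predict_pairs(acts)

  major_strong <- pairs[pairs$pair_key == "lor|sim", ]
  expect_identical(
    predict_pair_potency(major_strong, acts)$pair_potency, "strong"
  )

  # the methods rule and the published-table rule disagree on
  # minor route + strong inhibitor
  minor_strong <- pairs[pairs$pair_key == "pro|teg", ]
  expect_identical(
    predict_pair_potency(minor_strong, acts, rule = "methods")$pair_potency,
    "moderate"
  )
  expect_identical(
    predict_pair_potency(minor_strong, acts, rule = "table5")$pair_potency,
    "strong"
  )

  # major route + moderate inhibitor: moderate under both rules; here the
  # substrate role is on the second drug, so both orderings are evaluated
  acts2 <- dplyr::bind_rows(
    acts,
    tibble::tibble(drug = "lor", enzyme = "CYP2D6", is_substrate = TRUE,
                   is_inhibitor = FALSE, metabolism_extent = "major",
                   ki_um = NA, potency_class = "none")
  )
  pairs2 <- predict_pairs(acts2)
  major_moderate <- pairs2[pairs2$pair_key == "dul|lor", ]
  expect_identical(
    predict_pair_potency(major_moderate, acts2, rule = "methods")$pair_potency,
    "moderate"
  )
  expect_identical(
    predict_pair_potency(major_moderate, acts2, rule = "table5")$pair_potency,
    "moderate"
  )
})

test_that("no pair is called strong without a strong inhibitor on a shared enzyme", {
  for (seed in 31:33) {
    kb <- simulate_knowledge_base(15, seed = seed)
    acts <- kb_activities(kb)
    # blunt every strong inhibitor
    acts$potency_class[acts$potency_class == "strong"] <- "moderate"
    pairs <- predict_pair_potency(predict_pairs(acts), acts)
    expect_false(any(pairs$pair_potency == "strong"))
    pairs5 <- predict_pair_potency(predict_pairs(acts), acts, rule = "table5")
    expect_false(any(pairs5$pair_potency == "strong"))
  }
})

test_that("EMR cross-reference counts co-medicated patients within the window", {
  d <- function(x) as.Date(x)
  emr <- list(drug_exposure = tibble::tibble(
    person_id = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L),
    drug_name = c("a", "b", "a", "b", "a", "b", "a", "b", "a"),
    start_date = d(c("2005-01-01", "2005-01-15",   # 14 d apart -> in
                     "2005-02-01", "2005-03-03",   # 30 d apart -> in (boundary)
                     "2005-04-01", "2005-05-02",   # 31 d apart -> out
                     "2005-06-01", "2005-06-01",   # same day -> in
                     "2005-07-01"))                # never got b
  ))
  pairs <- tibble::tibble(substrate_drug = "a", inhibitor_drug = "b",
                          enzymes = "CYP3A4/5", pair_key = "a|b")
  out <- crossref_emr(pairs, emr, window_days = 30)
  expect_identical(out$comed_count_in_emr, 3L)
  expect_false(out$excluded_from_testing)

  # a drug absent from the EMR vocabulary: count 0 with a warning
  pairs2 <- tibble::tibble(substrate_drug = "a", inhibitor_drug = "zz",
                           enzymes = "CYP2D6", pair_key = "a|zz")
  expect_warning(out2 <- crossref_emr(pairs2, emr), "absent")
  expect_identical(out2$comed_count_in_emr, 0L)
  expect_true(out2$excluded_from_testing)
})
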