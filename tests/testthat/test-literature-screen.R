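drug_dict <- as_dictionary(c("ketoconazole", "midazolam", "st johns wort"))

test_that("scan_patterns recognises the defined pattern forms", {
  m <- scan_patterns("Ketoconazole strongly inhibits CYP3A4.", drug_dict)
  expect_identical(nrow(m), 1L)
  expect_identical(m$pattern_tag, "DOE")
  expect_identical(m$drug, "ketoconazole")
  expect_identical(m$enzyme, "CYP3A4/5")
  expect_identical(m$operator, "O1")
  expect_false(m$negated)

  m <- scan_patterns("midazolam is a known CYP3A4 substrate.", drug_dict)
  expect_identical(m$pattern_tag, "DEO")
  expect_identical(m$operator, "O2")

  m <- scan_patterns("CYP3A4 activity was inhibited by ketoconazole.", drug_dict)
  expect_identical(m$pattern_tag, "EOD")

  # permutation variants share operator semantics
  m <- scan_patterns("inhibition of CYP3A4 by ketoconazole was seen.", drug_dict)
  expect_identical(m$pattern_tag, "OED")
  expect_identical(m$operator, "O1")

  # two-drug forms
  m <- scan_patterns("there is not interaction between ketoconazole and midazolam.",
                     drug_dict)
  expect_identical(m$pattern_tag, "IDD1")
  expect_true(m$negated)
  expect_identical(c(m$drug, m$drug2), c("ketoconazole", "midazolam"))

  m <- scan_patterns("no impact of ketoconazole on midazolam was found.", drug_dict)
  expect_identical(m$pattern_tag, "IDD2")
  expect_true(m$negated)

  m <- scan_patterns("ketoconazole does not interact with midazolam.", drug_dict)
  expect_identical(m$pattern_tag, "DID")
  expect_true(m$negated)

  # negation inside a single-drug pattern
  m <- scan_patterns("midazolam is not a CYP3A4 substrate.", drug_dict)
  expect_true(m$negated)
})

test_that("scan_patterns honours the token-gap limit and dictionaries", {
  # 6 intervening tokens between drug and operator: no match at max_gap 5
  s <- "ketoconazole one two three four five six inhibits CYP3A4."
  expect_identical(nrow(scan_patterns(s, drug_dict)), 0L)
  expect_identical(scan_patterns(s, drug_dict, max_gap = 7)$pattern_tag, "DOE")

  # multi-word dictionary names match as one slot
  m <- scan_patterns("St Johns Wort induces CYP3A4.", drug_dict)
  expect_identical(m$drug, "st johns wort")
  expect_identical(m$operator, "O3")

  # unmatched sentences give an empty, well-formed tibble
  m <- scan_patterns("nothing of note happened here.", drug_dict)
  expect_identical(nrow(m), 0L)
  expect_true(all(c("pattern_tag", "drug", "enzyme", "negated") %in% names(m)))

  expect_error(scan_patterns("x", as_dictionary(character())),
               class = "cypddi_invalid_argument")

  # no duplicate report for the same (tag, slot set)
  m <- scan_patterns("ketoconazole inhibits and inhibits CYP3A4.", drug_dict)
  expect_identical(nrow(m), 1L)
})

test_that("generated positive corpora are fully recovered by the scanner", {
  kb <- simulate_knowledge_base(10, seed = 7)
  corp <- simulate_abstract_corpus(kb, n_pos = 30, n_neg = 15, seed = 21)
  gt <- ground_truth(corp)
  dd <- as_dictionary(unique(kb$drug))
  matches <- scan_patterns(corp, dd)

  pos <- gt[gt$relevant, ]
  # recall is exactly 1 by construction
  expect_identical(mean(pos$abstract_id %in% matches$abstract_id), 1)
  # negatives yield no matches at all
  expect_identical(
    nrow(matches[!matches$abstract_id %in% pos$abstract_id, ]), 0L
  )
  # per-pattern counts equal the ground-truth label counts
  got <- table(matches$pattern_tag[matches$abstract_id %in% pos$abstract_id])
  want <- table(pos$pattern)
  expect_identical(got[sort(names(got))], want[sort(names(want))])
  # slot fidelity: every labelled (drug, pattern) is reported
  lab <- merge(pos, matches,
               by.x = c("abstract_id", "pattern"),
               by.y = c("abstract_id", "pattern_tag"))
  expect_identical(nrow(lab), nrow(pos))
  expect_true(all(lab$drug.x == lab$drug.y))
  expect_identical(lab$negated.x, lab$negated.y)
})

test_that("the template filter retains and rejects as specified", {
  kb <- simulate_knowledge_base(8, seed = 2)
  template <- default_screen_template(kb)
  corp <- simulate_abstract_corpus(kb, n_pos = 15, n_neg = 10, seed = 5)
  out <- filter_abstracts(corp, template)
  gt <- ground_truth(corp)
  # every labelled positive is retained (recall 1 by construction)
  expect_true(all(out$retained[gt$relevant]))

  # a prohibited term rejects an otherwise retained abstract
  hit <- which(out$retained)[1]
  poisoned <- corp
  poisoned$sentences[[hit]] <- c(poisoned$sentences[[hit]],
                                 "findings in a cancer cell line differed.")
  out2 <- filter_abstracts(poisoned, template)
  expect_false(out2$retained[hit])

  # empty abstracts are not retained, with a note
  empty <- corp[1, ]
  empty$sentences <- list(character())
  expect_message(out3 <- filter_abstracts(empty, template), "empty")
  expect_false(out3$retained)

  # monotonicity: extending the prohibited list never retains more, and
  # dropping a required category's terms never retains more either
  wider <- template
  wider$prohibited <- c(wider$prohibited, "monitored", "volunteers")
  narrower <- template
  narrower$required$probes <- "no_such_probe_term"
  r0 <- filter_abstracts(corp, template)$retained
  r1 <- filter_abstracts(corp, wider)$retained
  r2 <- filter_abstracts(corp, narrower)$retained
  expect_true(all(!r1 | r0))
  expect_true(all(!r2 | r0))
})

test_that("template construction enforces disjoint term sets", {
  expect_error(
    screen_template(drugs = "apixaban", enzymes = "cyp3a4",
                    prohibited = c("tumor", "apixaban")),
    class = "cypddi_invalid_argument"
  )
})

test_that("in vitro extraction applies the curation criteria", {
  matches <- tibble::tibble(
    abstract_id = c("a1", "a2", "a3", "a4", "a5"),
    sentence_index = 1L,
    pattern_tag = c("DOE", "DOE", "DOE", "DEO", "DID"),
    drug = "drugX", drug2 = c(NA, NA, NA, NA, "drugY"),
    enzyme = c("CYP2D6", "CYP2D6", "CYP2D6", "CYP3A4/5", NA),
    operator = c("O1", "O1", "O1", "O2", "INT"),
    negated = c(FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  annotations <- tibble::tibble(
    abstract_id = c("a1", "a2", "a3", "a4", "a5"),
    system = c("recombinant CYP", "other", "recombinant CYP",
               "human liver microsomes", "recombinant CYP"),
    probe_used = c("dextromethorphan", "dextromethorphan",
                   "dextromethorphan", "midazolam", NA)
  )
  ev <- extract_invitro(matches, annotations)
  # a1: valid inhibitor evidence; a2 rejected (rat-like system);
  # a3 rejected (negated); a4 valid substrate; a5 no enzyme slot
  expect_identical(nrow(ev), 2L)
  expect_setequal(ev$assertion, c("inhibitor", "substrate"))
  expect_identical(ev$source_id[ev$assertion == "inhibitor"], "a1")

  # wrong probe for the enzyme: no evidence
  bad_probe <- annotations
  bad_probe$probe_used[1] <- "midazolam"
  ev2 <- extract_invitro(matches[1, ], bad_probe)
  expect_identical(nrow(ev2), 0L)

  # missing system annotation: skipped with a warning
  expect_warning(
    ev3 <- extract_invitro(matches[1, ], annotations[-1, ]),
    "missing assay system"
  )
  expect_identical(nrow(ev3), 0L)
})

test_that("in vivo conclusions follow the p-first, fold-fallback rule", {
  ev <- tibble::tibble(
    p_value = c(0.03, NA, 0.001, 0.2, NA, NA),
    fold_change = c(1.5, 2.5, NA, 3.0, 1.8, NA),
    pregnant = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  out <- conclude_invivo(ev)
  expect_identical(out$conclusion,
                   c("DDI", "DDI", "excluded", "no-DDI", "no-DDI",
                     "indeterminate"))
  # the conjunction variant requires both criteria
  out2 <- conclude_invivo(ev, rule = "conjunction")
  expect_identical(out2$conclusion,
                   c("no-DDI", "indeterminate", "excluded", "no-DDI",
                     "no-DDI", "indeterminate"))
  # outcomes partition: one status per row, always
  expect_true(all(out$conclusion %in%
                    c("DDI", "no-DDI", "excluded", "indeterminate")))
})

test_that("recall estimation matches a counting oracle", {
  ids <- sprintf("p%03d", 1:100)
  expect_identical(estimate_recall(ids, ids), 1)
  expect_identical(estimate_recall(character(), ids), 0)
  # misses exactly 3 of 100
  expect_identical(estimate_recall(ids[-(1:3)], ids), 0.97)
  expect_error(estimate_recall(ids, character()),
               class = "cypddi_invalid_argument")
  # functional retrieval over a corpus
  corp <- tibble::tibble(abstract_id = ids, sentences = list("x"))
  f <- function(corpus) corpus$abstract_id[1:50]
  expect_identical(estimate_recall(f, ids, corp), 0.5)
})
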