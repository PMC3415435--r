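# Synthetic abstract corpus with labelled DDI sentence patterns.
#
# Positive abstracts carry exactly one pattern sentence built from a
# template the scanner is guaranteed to match (gaps <= 5 tokens), plus
# support sentences supplying probe / experiment-system / experiment-type
# terms so the retrieval template retains them. Negative abstracts contain
# no pattern; a fraction are prohibited-term decoys.

.pattern_templates <- function() {
  list(
    DEO = list(
      pos = "%s is a known %s substrate in man.",
      neg = "%s is not a %s substrate in man."
    ),
    DOE = list(
      pos = "%s potently inhibits %s in vitro.",
      neg = "%s does not inhibit %s in vitro."
    ),
    EOD = list(
      pos = "%2$s activity was inhibited by %1$s.",
      neg = "%2$s was not inhibited by %1$s."
    ),
    IDD1 = list(
      pos = "a significant interaction between %s and %s was observed.",
      neg = "there is not interaction between %s and %s."
    ),
    IDD2 = list(
      pos = "the impact of %s on %s exposure was substantial.",
      neg = "no impact of %s on %s was detected."
    ),
    DID = list(
      pos = "%s strongly interacts with %s in patients.",
      neg = "%s does not interact with %s."
    )
  )
}

# operator class implied by each generated template
.pattern_operator <- c(DEO = "O2", DOE = "O1", EOD = "O1",
                       IDD1 = "INT", IDD2 = "INT", DID = "INT")

.enzyme_surface <- function(enzyme) {
  # surface form written into sentences; scanner maps it back via synonyms
  if (enzyme == "CYP3A4/5") "cyp3a4" else tolower(enzyme)
}

.support_sentences <- function(enzyme, probe) {
  c(
    sprintf("incubations used %s in pooled human liver microsomes.", probe),
    sprintf("recombinant %s activity was monitored throughout.",
            .enzyme_surface(enzyme)),
    "kinetic parameters were estimated from each incubation."
  )
}

.decoy_sentences <- function() {
  c("the cohort was followed for five years.",
    "gene expression profiles were clustered across samples.",
    "study enrolment criteria were reviewed by the board.",
    "plasma samples were stored at minus eighty degrees.")
}

#' Simulate a labelled abstract corpus
#'
#' Generates `n_pos` DDI-relevant abstracts, each containing exactly one
#' sentence instantiating one of the six defined patterns (`DEO`, `DOE`,
#' `EOD`, `IDD1`, `IDD2`, `DID`) with drug and enzyme names drawn from the
#' knowledge base, plus support sentences carrying the probe,
#' experiment-system and experiment-type terms the retrieval template
#' requires. Single-drug patterns are drawn from knowledge-base rows whose
#' role matches the pattern's operator (substrate rows for `DEO`, inhibitor
#' rows for `DOE`/`EOD`) when such rows exist. `n_neg` negative abstracts
#' contain no pattern; a fraction are prohibited-term decoys.
#'
#' Every positive abstract carries structured assay annotations (`system`,
#' `probe_used`) standing in for manual curation; by default these are
#' valid (human systems, FDA-listed probe for the enzyme).
#'
#' @param kb A knowledge base from [simulate_knowledge_base()] (or any
#'   tibble with `drug`, `enzyme`, `role` columns).
#' @param n_pos,n_neg Number of positive / negative abstracts.
#' @param p_negated Fraction of positive patterns written in negated form.
#' @param p_decoy Fraction of negatives that carry a prohibited term.
#' @param ensure Optional tibble (`drug`, `enzyme`, `assertion` of
#'   `"substrate"`/`"inhibitor"`): assertions guaranteed to appear as
#'   non-negated pattern sentences among the positives (the first rows of
#'   the corpus). Requires `n_pos >= nrow(ensure)`.
#' @param seed Integer seed.
#' @return A corpus tibble with columns `abstract_id`, `sentences`
#'   (list-column), `system`, `probe_used`, and label columns `relevant`,
#'   `pattern`, `drug`, `drug2`, `enzyme`, `negated`. The label sub-table is
#'   also attached as `ground_truth`.
#' @export
#' @examples
#' kb <- simulate_knowledge_base(6, seed = 7)
#' corp <- simulate_abstract_corpus(kb, n_pos = 4, n_neg = 2, seed = 1)
simulate_abstract_corpus <- function(kb, n_pos, n_neg,
                                     p_negated = 0.25, p_decoy = 0.4,
                                     ensure = NULL, seed = 1L) {
  if (!nrow(kb)) abort("`kb` must be non-empty", class = "cypddi_invalid_argument")
  if (n_pos + n_neg == 0) {
    abort("n_pos + n_neg must be positive", class = "cypddi_invalid_argument")
  }
  if (!is.null(ensure) && nrow(ensure) > n_pos) {
    abort("`n_pos` must cover every ensured assertion",
          class = "cypddi_invalid_argument")
  }
  set.seed(seed)
  templates <- .pattern_templates()
  probes <- fda_probes()
  drugs <- unique(kb$drug)
  sub_rows <- kb %>% filter(.data$role %in% c("substrate", "both"))
  inh_rows <- kb %>% filter(.data$role %in% c("inhibitor", "both"))

  pick_row <- function(tbl) {
    if (nrow(tbl)) tbl[sample.int(nrow(tbl), 1), ] else kb[sample.int(nrow(kb), 1), ]
  }

  make_positive <- function(i) {
    forced <- !is.null(ensure) && i <= nrow(ensure)
    tag <- if (forced) {
      if (ensure$assertion[i] == "substrate") "DEO" else "DOE"
    } else {
      sample(names(templates), 1)
    }
    negated <- if (forced) FALSE else runif(1) < p_negated
    tmpl <- templates[[tag]][[if (negated) "neg" else "pos"]]
    if (tag %in% c("DEO", "DOE", "EOD")) {
      row <- if (forced) {
        tibble(drug = ensure$drug[i], enzyme = ensure$enzyme[i])
      } else {
        pick_row(if (tag == "DEO") sub_rows else inh_rows)
      }
      drug <- row$drug; drug2 <- NA_character_; enzyme <- row$enzyme
      sentence <- sprintf(tmpl, drug, .enzyme_surface(enzyme))
    } else {
      pair <- sample(drugs, 2)
      drug <- pair[1]; drug2 <- pair[2]
      enzyme <- sample(unique(kb$enzyme), 1)
      sentence <- sprintf(tmpl, drug, drug2)
    }
    probe <- sample(probes$probe[probes$enzyme == enzyme], 1)
    tibble(
      abstract_id = sprintf("abs_%04d", i),
      sentences = list(c(sentence, .support_sentences(enzyme, probe))),
      system = sample(c("human liver microsomes", "recombinant CYP"), 1),
      probe_used = probe,
      relevant = TRUE, pattern = tag, drug = drug, drug2 = drug2,
      enzyme = if (tag %in% c("DEO", "DOE", "EOD")) enzyme else NA_character_,
      negated = negated
    )
  }

  make_negative <- function(i) {
    decoy <- runif(1) < p_decoy
    sents <- if (decoy) {
      c("tumor cell line proliferation was measured after treatment.",
        sample(.decoy_sentences(), 2))
    } else {
      c(sprintf("%s pharmacokinetics in healthy volunteers were summarized.",
                sample(drugs, 1)),
        "dosing regimens varied across study sites.",
        sample(.decoy_sentences(), 1))
    }
    tibble(
      abstract_id = sprintf("abs_%04d", n_pos + i),
      sentences = list(sents),
      system = NA_character_, probe_used = NA_character_,
      relevant = FALSE, pattern = NA_character_,
      drug = NA_character_, drug2 = NA_character_,
      enzyme = NA_character_, negated = NA
    )
  }

  corpus <- bind_rows(
    if (n_pos > 0) map_dfr(seq_len(n_pos), make_positive),
    if (n_neg > 0) map_dfr(seq_len(n_neg), make_negative)
  )
  structure(
    corpus,
    class = c("ddi_corpus", class(corpus)),
    ground_truth = corpus %>%
      select("abstract_id", "relevant", "pattern", "drug", "drug2",
             "enzyme", "negated") %>%
      as_tibble()
  )
}

#' Spike a labelled corpus with pattern-free decoy abstracts
#'
#' Emulates mixing the true-positive abstract set with a large random
#' sample of unrelated abstracts before estimating retrieval recall. Decoys
#' are drawn from a non-DDI sentence model (no knowledge-base names, no
#' operator tokens).
#'
#' @param positives A corpus tibble with at least one abstract.
#' @param n_decoys Number of decoy abstracts to add.
#' @param seed Integer seed.
#' @return The mixed corpus, with the true-positive ids attached as
#'   attribute `"positive_ids"`.
#' @export
spike_decoy_corpus <- function(positives, n_decoys, seed = 1L) {
  if (!nrow(positives)) {
    abort("`positives` must be non-empty", class = "cypddi_invalid_argument")
  }
  set.seed(seed)
  pos_ids <- positives$abstract_id[
    if ("relevant" %in% names(positives)) positives$relevant else TRUE
  ]
  decoys <- if (n_decoys > 0) {
    map_dfr(seq_len(n_decoys), function(i) {
      tibble(
        abstract_id = sprintf("decoy_%05d", i),
        sentences = list(sample(.decoy_sentences(),
                                sample(2:4, 1), replace = TRUE)),
        system = NA_character_, probe_used = NA_character_,
        relevant = FALSE, pattern = NA_character_,
        drug = NA_character_, drug2 = NA_character_,
        enzyme = NA_character_, negated = NA
      )
    })
  } else {
    NULL
  }
  mixed <- bind_rows(as_tibble(positives), decoys)
  attr(mixed, "positive_ids") <- pos_ids
  mixed
}
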