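# Sentence-pattern scanner for DDI-relevant statements.
#
# Operator lexicon (field symbols):
#   O1 inhibit-family, O2 substrate/metabolize/catalyze/probe family,
#   O3 induce-family, INT interaction verbs/nouns.
# Single-drug patterns are order-generic over {drug, enzyme, operator}
# (tags DEO, DOE, EOD, OED, ODE, EDO by observed token order); two-drug
# patterns are IDD1 (INT between D and D), IDD2 (INT D on D), DID (D INT D).

.op_lexicon <- function() {
  list(
    O1 = c("inhibit", "inhibits", "inhibited", "inhibiting", "inhibition",
           "inhibitor", "inhibitors", "inhibitory"),
    O2 = c("substrate", "substrates", "probe", "metabolized", "metabolised",
           "metabolize", "metabolizes", "metabolise", "metabolises",
           "catalyze", "catalyzes", "catalyzed", "catalysed", "catalyses"),
    O3 = c("induce", "induces", "induced", "inducing", "induction",
           "inducer", "inducers"),
    INT = c("interaction", "interactions", "interact", "interacts",
            "interacted", "interference", "interfere", "interferes",
            "affect", "affects", "affected", "impact", "impacts")
  )
}

.neg_tokens <- c("not", "no")

# lower-case and split on non-word characters, keeping "/" and "-" inside
# tokens so names like cyp3a4/5 survive
.tokenize <- function(sentence) {
  s <- tolower(sentence)
  s <- gsub("[^a-z0-9/\\-]+", " ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[nzchar(toks)]
}

# dictionary longest-match: dict is a tibble(name, synonym); returns
# tibble(start, end, name) of non-overlapping hits, longest first
.dict_hits <- function(tokens, dict) {
  if (!nrow(dict)) return(tibble(start = integer(), end = integer(), name = character()))
  entries <- dict %>%
    mutate(syn_tokens = map(.data$synonym, .tokenize),
           len = lengths(.data$syn_tokens)) %>%
    filter(.data$len > 0) %>%
    arrange(dplyr::desc(.data$len))
  taken <- rep(FALSE, length(tokens))
  out <- list()
  for (i in seq_len(nrow(entries))) {
    st <- entries$syn_tokens[[i]]
    L <- entries$len[i]
    if (L > length(tokens)) next
    for (pos in seq_len(length(tokens) - L + 1)) {
      if (any(taken[pos:(pos + L - 1)])) next
      if (all(tokens[pos:(pos + L - 1)] == st)) {
        taken[pos:(pos + L - 1)] <- TRUE
        out[[length(out) + 1]] <- tibble(start = pos, end = pos + L - 1L,
                                         name = entries$name[i])
      }
    }
  }
  if (!length(out)) return(tibble(start = integer(), end = integer(), name = character()))
  bind_rows(out) %>% arrange(.data$start)
}

.empty_matches <- function() {
  tibble(
    sentence_index = integer(), pattern_tag = character(),
    drug = character(), drug2 = character(), enzyme = character(),
    operator = character(), negated = logical()
  )
}

#' Scan sentences for DDI-relevant token patterns
#'
#' Implements the rule-based sentence filter of the retrieval step: tag
#' dictionary drug and enzyme mentions plus operator tokens
#' (O1 = inhibit-family, O2 = substrate/metabolize family, O3 = induce-family,
#' INT = interaction verbs), then report every pattern instance whose
#' consecutive elements are at most `max_gap` tokens apart.
#'
#' Single drug-enzyme-operator patterns are matched in any token order and
#' tagged by the order observed (`DEO`, `DOE`, `EOD`, `OED`, `ODE`, `EDO`).
#' Two-drug patterns are `IDD1` ("interaction between A and B"), `IDD2`
#' ("impact of A on B"), and `DID` ("A interacts with B"). A match is
#' `negated` when a "not"/"no" token occurs between the pattern's first and
#' last element (window extended two tokens left, so leading negations such
#' as "no impact of A on B" are caught).
#'
#' @param x A character vector of sentences, or a corpus tibble with an
#'   `abstract_id` column and a `sentences` list-column (one character
#'   vector per abstract).
#' @param drug_dict,enzyme_dict Dictionaries: tibbles with columns `name`
#'   (canonical) and `synonym` (surface form). A plain character vector is
#'   promoted to a dictionary with `synonym = tolower(name)`.
#' @param max_gap Maximum number of tokens allowed between consecutive
#'   pattern elements (default 5).
#' @return A tibble of matches: `sentence_index` (and `abstract_id` for
#'   corpus input), `pattern_tag`, `drug`, `drug2` (two-drug patterns),
#'   `enzyme`, `operator` (`O1`/`O2`/`O3`/`INT`), `negated`. Duplicate
#'   reports for the same (tag, slot set) are removed. An unmatched
#'   sentence contributes no rows.
#' @export
#' @examples
#' dd <- as_dictionary(c("ketoconazole", "midazolam"))
#' scan_patterns("Ketoconazole strongly inhibits CYP3A4.", dd)
scan_patterns <- function(x, drug_dict, enzyme_dict = cyp_enzyme_dictionary(),
                          max_gap = 5) {
  drug_dict <- as_dictionary(drug_dict)
  enzyme_dict <- as_dictionary(enzyme_dict)
  if (!nrow(drug_dict) || !nrow(enzyme_dict)) {
    abort("dictionaries must be non-empty", class = "cypddi_invalid_argument")
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("abstract_id", "sentences") %in% names(x)))
    res <- map2(x$abstract_id, x$sentences, function(id, sents) {
      m <- scan_patterns(sents, drug_dict, enzyme_dict, max_gap)
      if (nrow(m)) m$abstract_id <- id
      m
    })
    out <- bind_rows(res)
    if (!nrow(out)) {
      out <- .empty_matches()
      out$abstract_id <- character()
    }
    return(out %>% select("abstract_id", dplyr::everything()))
  }

  out <- imap(x, function(sentence, idx) {
    toks <- .tokenize(sentence)
    if (!length(toks)) return(NULL)
    m <- .scan_tokens(toks, drug_dict, enzyme_dict, max_gap)
    if (is.null(m) || !nrow(m)) return(NULL)
    m$sentence_index <- as.integer(idx)
    m
  })
  out <- bind_rows(out)
  if (!nrow(out)) return(.empty_matches())
  out %>%
    distinct(.data$sentence_index, .data$pattern_tag, .data$drug,
             .data$drug2, .data$enzyme, .data$operator, .data$negated) %>%
    select("sentence_index", "pattern_tag", "drug", "drug2", "enzyme",
           "operator", "negated") %>%
    arrange(.data$sentence_index, .data$pattern_tag)
}

#' Promote a character vector to a scanner dictionary
#'
#' @param x A character vector of names, or an existing dictionary tibble
#'   with columns `name` and `synonym`.
#' @return A tibble with columns `name`, `synonym`.
#' @export
as_dictionary <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("name", "synonym") %in% names(x)))
    return(as_tibble(x[, c("name", "synonym")]))
  }
  tibble(name = x, synonym = tolower(x))
}

.scan_tokens <- function(toks, drug_dict, enzyme_dict, max_gap) {
  ops <- .op_lexicon()
  drugs <- .dict_hits(toks, drug_dict)
  enzymes <- .dict_hits(toks, enzyme_dict)
  op_pos <- imap(ops, function(words, cls) {
    idx <- which(toks %in% words)
    if (!length(idx)) return(NULL)
    tibble(start = idx, end = idx, class = cls)
  }) %>% bind_rows()
  if (!nrow(op_pos)) {
    op_pos <- tibble(start = integer(), end = integer(), class = character())
  }
  neg_idx <- which(toks %in% .neg_tokens)

  gap_ok <- function(a_end, b_start) b_start > a_end && (b_start - a_end - 1) <= max_gap
  negated_in <- function(lo, hi) any(neg_idx >= max(1, lo - 2) & neg_idx <= hi)

  rows <- list()
  add <- function(tag, drug, drug2, enzyme, op, lo, hi) {
    rows[[length(rows) + 1]] <<- tibble(
      pattern_tag = tag, drug = drug, drug2 = drug2, enzyme = enzyme,
      operator = op, negated = negated_in(lo, hi)
    )
  }

  # --- single-drug patterns: any order of (D, E, O), O in {O1, O2, O3}
  deo_ops <- op_pos %>% filter(.data$class %in% c("O1", "O2", "O3"))
  if (nrow(drugs) && nrow(enzymes) && nrow(deo_ops)) {
    for (di in seq_len(nrow(drugs))) {
      for (ei in seq_len(nrow(enzymes))) {
        for (oi in seq_len(nrow(deo_ops))) {
          elems <- list(
            D = c(drugs$start[di], drugs$end[di]),
            E = c(enzymes$start[ei], enzymes$end[ei]),
            O = c(deo_ops$start[oi], deo_ops$end[oi])
          )
          ord <- order(map_dbl(elems, 1))
          sorted <- elems[ord]
          ok <- gap_ok(sorted[[1]][2], sorted[[2]][1]) &&
                gap_ok(sorted[[2]][2], sorted[[3]][1])
          if (!ok) next
          tag <- paste(names(sorted), collapse = "")
          add(tag, drugs$name[di], NA_character_, enzymes$name[ei],
              deo_ops$class[oi], sorted[[1]][1], sorted[[3]][2])
        }
      }
    }
  }

  # --- two-drug patterns need >= 2 distinct drug mentions or one INT token
  ints <- op_pos %>% filter(.data$class == "INT")
  if (nrow(drugs) >= 2 && nrow(ints)) {
    between_idx <- which(toks == "between")
    and_idx <- which(toks == "and")
    on_idx <- which(toks == "on")
    pairs <- expand.grid(a = seq_len(nrow(drugs)), b = seq_len(nrow(drugs)))
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      d1 <- pairs$a[k]; d2 <- pairs$b[k]
      if (drugs$start[d1] >= drugs$start[d2]) next  # keep textual order
      if (drugs$name[d1] == drugs$name[d2]) next
      for (oi in seq_len(nrow(ints))) {
        ipos <- ints$start[oi]
        # IDD1: INT ... between ... D1 ... and ... D2
        if (ipos < drugs$start[d1] &&
            any(between_idx > ipos & between_idx < drugs$start[d1]) &&
            any(and_idx > drugs$end[d1] & and_idx < drugs$start[d2]) &&
            gap_ok(ipos, drugs$start[d1]) &&
            gap_ok(drugs$end[d1], drugs$start[d2])) {
          add("IDD1", drugs$name[d1], drugs$name[d2], NA_character_, "INT",
              ipos, drugs$end[d2])
        }
        # IDD2: INT ... D1 ... on ... D2  (no "between")
        if (ipos < drugs$start[d1] &&
            !any(between_idx > ipos & between_idx < drugs$start[d1]) &&
            any(on_idx > drugs$end[d1] & on_idx < drugs$start[d2]) &&
            gap_ok(ipos, drugs$start[d1]) &&
            gap_ok(drugs$end[d1], drugs$start[d2])) {
          add("IDD2", drugs$name[d1], drugs$name[d2], NA_character_, "INT",
              ipos, drugs$end[d2])
        }
        # DID: D1 ... INT ... D2
        if (ipos > drugs$end[d1] && ipos < drugs$start[d2] &&
            gap_ok(drugs$end[d1], ipos) &&
            gap_ok(ipos, drugs$start[d2])) {
          add("DID", drugs$name[d1], drugs$name[d2], NA_character_, "INT",
              drugs$start[d1], drugs$end[d2])
        }
      }
    }
  }

  bind_rows(rows)
}
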