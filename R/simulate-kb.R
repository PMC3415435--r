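#' Simulate a drug knowledge base with known enzyme roles
#'
#' Draws, for each synthetic drug and each CYP enzyme, a role (none,
#' substrate, inhibitor, or both), a metabolism extent for substrates
#' (major/minor), and an inhibition constant Ki (in uM, log-uniform on
#' \[0.5, 500\]) for inhibitors. The generated table doubles as its own
#' ground truth for downstream recovery tests.
#'
#' @param n_drugs Number of drugs (>= 2 for any DDI pair to exist).
#' @param enzymes Character vector of enzyme names, a subset of
#'   [cyp_enzymes()].
#' @param role_probs Named probabilities for
#'   `c(none=, substrate=, inhibitor=, both=)`; must sum to 1.
#' @param p_major Probability that a substrate's metabolism extent is
#'   `"major"` (else `"minor"`).
#' @param seed Integer seed.
#' @return A tibble of class `ddi_kb` with columns `drug`, `enzyme`, `role`,
#'   `extent`, `ki_um`; rows only for non-`none` roles. The full generative
#'   record is attached as the `"ground_truth"` attribute.
#' @export
#' @examples
#' kb <- simulate_knowledge_base(6, seed = 7)
#' kb
simulate_knowledge_base <- function(n_drugs,
                                    enzymes = cyp_enzymes(),
                                    role_probs = c(none = 0.55, substrate = 0.2,
                                                   inhibitor = 0.15, both = 0.1),
                                    p_major = 0.4,
                                    seed = 1L) {
  if (!is.numeric(n_drugs) || n_drugs < 1) {
    abort("`n_drugs` must be a positive count", class = "cypddi_invalid_argument")
  }
  bad <- setdiff(enzymes, cyp_enzymes())
  if (length(bad)) {
    abort(paste("unknown enzymes:", paste(bad, collapse = ", ")),
          class = "cypddi_invalid_argument")
  }
  roles <- c("none", "substrate", "inhibitor", "both")
  if (!setequal(names(role_probs), roles) || abs(sum(role_probs) - 1) > 1e-8) {
    abort("`role_probs` must be named over {none, substrate, inhibitor, both} and sum to 1",
          class = "cypddi_invalid_argument")
  }
  set.seed(seed)
  drugs <- sprintf("drug_%03d", seq_len(n_drugs))
  grid <- tidyr::expand_grid(drug = drugs, enzyme = enzymes)
  grid$role <- sample(roles, nrow(grid), replace = TRUE, prob = role_probs[roles])
  kb <- grid %>%
    filter(.data$role != "none") %>%
    mutate(
      extent = if_else(.data$role %in% c("substrate", "both"),
                       if_else(runif(n()) < p_major, "major", "minor"),
                       "none"),
      ki_um = if_else(.data$role %in% c("inhibitor", "both"),
                      round(exp(runif(n(), log(0.5), log(500))), 3),
                      NA_real_)
    )
  structure(
    kb,
    class = c("ddi_kb", class(kb)),
    ground_truth = list(
      drugs = drugs, enzymes = enzymes, role_probs = role_probs,
      p_major = p_major, seed = as.integer(seed), kb = as_tibble(kb)
    )
  )
}

#' Convert a knowledge base to per-drug enzyme activities
#'
#' Expands the role column into the flags used by the DDI predictor and
#' derives the Ki-binned inhibition potency class.
#'
#' @param kb A knowledge-base tibble (`drug`, `enzyme`, `role`, `extent`,
#'   `ki_um`).
#' @return A tibble with columns `drug`, `enzyme`, `is_substrate`,
#'   `is_inhibitor`, `metabolism_extent`, `ki_um`, `potency_class`.
#' @export
kb_activities <- function(kb) {
  stopifnot(all(c("drug", "enzyme", "role") %in% names(kb)))
  kb %>%
    mutate(
      is_substrate = .data$role %in% c("substrate", "both"),
      is_inhibitor = .data$role %in% c("inhibitor", "both"),
      metabolism_extent = if_else(.data$is_substrate, .data$extent, "none"),
      potency_class = if_else(.data$is_inhibitor & !is.na(.data$ki_um),
                              classify_potency(.data$ki_um), "none")
    ) %>%
    select("drug", "enzyme", "is_substrate", "is_inhibitor",
           "metabolism_extent", "ki_um", "potency_class") %>%
    as_tibble()
}
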