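#' Tidy a fitted DDI test
#'
#' @param x A `ddi_fit` from [fit_additive()] or [fit_synergistic()].
#' @param ... Unused.
#' @return A one-row tibble: `drug1`, `drug2`, `model`, `risk1`, `risk2`,
#'   `risk12`, `rr`, `or_joint_vs_substrate`, `p_value`, `counts` (the
#'   formatted "(m1/n1, m2/n2, m12/n12)" string), and the raw `m`/`n`
#'   columns per group.
#' @exportS3Method generics::tidy
tidy.ddi_fit <- function(x, ...) {
  pair <- x$pair %||% c(NA_character_, NA_character_)
  wide <- x$counts %>%
    tidyr::pivot_wider(names_from = "group", values_from = c("m", "n"))
  tibble(
    drug1 = pair[1], drug2 = pair[2], model = x$model,
    risk1 = unname(x$risks["risk1"]),
    risk2 = unname(x$risks["risk2"]),
    risk12 = unname(x$risks["risk12"]),
    rr = x$rr,
    or_joint_vs_substrate = x$or_joint_vs_substrate,
    p_value = x$p_value,
    counts = format_counts(x$counts)
  ) %>%
    bind_cols(wide)
}

#' Glance at a fitted DDI test
#'
#' @inheritParams tidy.ddi_fit
#' @return A one-row tibble with the model type, covariates used, p-value
#'   method, total episodes and events, and degeneracy flag.
#' @exportS3Method generics::glance
glance.ddi_fit <- function(x, ...) {
  tibble(
    model = x$model,
    covariates = paste(x$covariates, collapse = "+"),
    p_method = x$p_method,
    n_episodes = sum(x$counts$n),
    n_events = sum(x$counts$m),
    degenerate = x$degenerate
  )
}

#' Forest-style plot of synergistic DDI results
#'
#' Relative risk per pair on a log scale with the additivity line at
#' RR = 1; significant pairs (below `threshold`, RR > 1) are highlighted.
#'
#' @param results A tidied results tibble (rows from [tidy.ddi_fit()],
#'   synergistic model) with `drug1`, `drug2`, `rr`, `p_value`.
#' @param threshold Significance threshold used for the highlight.
#' @return A ggplot object.
#' @export
plot_ddi_results <- function(results, threshold = 0.05) {
  res <- results %>%
    filter(!is.na(.data$rr)) %>%
    mutate(
      pair = paste(.data$drug1, .data$drug2, sep = " + "),
      significant = !is.na(.data$p_value) & .data$p_value < threshold &
        .data$rr > 1
    )
  ggplot2::ggplot(res, ggplot2::aes(x = .data$rr,
                                    y = stats::reorder(.data$pair, .data$rr),
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "RR = Risk12 / (Risk1 + Risk2)", y = NULL,
                  colour = "significant")
}

#' Bar plot of CYP enrichment results
#'
#' @param enrichment Output of [enzyme_enrichment()].
#' @return A ggplot object of -log10 enrichment p-values per enzyme.
#' @export
plot_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = stats::reorder(.data$enzyme, -.data$p_value),
                               y = -log10(.data$p_value))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "-log10 enrichment p")
}

#' @rdname plot_ddi_results
#' @param object A `ddi_fit`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.ddi_fit <- function(object, ...) {
  counts <- object$counts %>%
    mutate(risk = .data$m / .data$n,
           group = factor(.data$group, levels = .group_levels))
  expected <- sum(counts$risk[counts$group != "joint"])
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$group, y = .data$risk)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = expected, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(y = "myopathy risk", x = NULL,
                  subtitle = "dashed line: additive expectation Risk1 + Risk2")
}
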