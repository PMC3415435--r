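# Additive and synergistic DDI tests on exposure episodes.
#
# Adjusted group risks come from covariate standardization (g-computation):
# the fitted model predicts each person's risk under every group
# assignment, and the group risk is the average over the pooled sample.
# With no covariates the three-group logistic model is saturated, its
# standardized risks are exactly the raw proportions m/n, and the
# delta-method variance of log(RR) reduces to the closed form
#   var(log r) = (1-p)/(n p),  var(log(r1+r2)) = (v1+v2)/(r1+r2)^2,
# which the fast path below computes directly (identical to the glm route).

#' Synergistic relative-risk statistic
#'
#' `RR = Risk12 / (Risk1 + Risk2)`: the joint-exposure myopathy risk
#' relative to the sum of the single-exposure risks. RR = 1 is exact
#' additivity; RR > 1 indicates synergy.
#'
#' @param risk1,risk2,risk12 Group risks (probabilities), vectorised.
#' @return The relative risk.
#' @export
#' @examples
#' rr_statistic(0.022, 0.033, 0.093) # 1.69
rr_statistic <- function(risk1, risk2, risk12) {
  risks <- c(risk1, risk2, risk12)
  if (any(risks < 0 | risks > 1, na.rm = TRUE)) {
    abort("risks must lie in [0, 1]", class = "cypddi_invalid_argument")
  }
  if (any(risk1 + risk2 <= 0, na.rm = TRUE)) {
    abort("risk1 + risk2 must be positive", class = "cypddi_undefined_result")
  }
  risk12 / (risk1 + risk2)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 3670) # 1.36e-5
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    abort("`alpha` must be in (0, 1]", class = "cypddi_invalid_argument")
  }
  if (!is.numeric(n_tests) || n_tests < 1) {
    abort("`n_tests` must be >= 1", class = "cypddi_invalid_argument")
  }
  alpha / n_tests
}

.group_levels <- c("substrate_alone", "inhibitor_alone", "joint")

.covariate_columns <- function(covariates) {
  map <- c(age = "age_at_anchor", sex = "sex", comeds = "comed_count")
  bad <- setdiff(covariates, names(map))
  if (length(bad)) {
    abort(paste0("unknown covariates: ", paste(bad, collapse = ", ")),
          class = "cypddi_invalid_argument")
  }
  unname(map[covariates])
}

.group_counts <- function(episodes) {
  episodes %>%
    group_by(group = factor(.data$group, levels = .group_levels)) %>%
    summarise(m = sum(.data$outcome), n = n(), .groups = "drop") %>%
    tidyr::complete(group, fill = list(m = 0L, n = 0L)) %>%
    mutate(group = as.character(.data$group))
}

# closed-form delta-method test from group counts (covariate-free path)
.synergy_counts_test <- function(m1, n1, m2, n2, m12, n12) {
  m1 <- as.numeric(m1); n1 <- as.numeric(n1); m2 <- as.numeric(m2)
  n2 <- as.numeric(n2); m12 <- as.numeric(m12); n12 <- as.numeric(n12)
  r1 <- m1 / n1; r2 <- m2 / n2; r12 <- m12 / n12
  rr <- r12 / (r1 + r2)
  if (m12 == 0 || m1 + m2 == 0 || m12 == n12) {
    return(list(risks = c(risk1 = r1, risk2 = r2, risk12 = r12),
                rr = rr, se_log_rr = NA_real_, p_value = NA_real_,
                degenerate = TRUE))
  }
  v <- (1 - r12) / (n12 * r12) +
    (r1 * (1 - r1) / n1 + r2 * (1 - r2) / n2) / (r1 + r2)^2
  z <- log(rr) / sqrt(v)
  list(risks = c(risk1 = r1, risk2 = r2, risk12 = r12),
       rr = rr, se_log_rr = sqrt(v), p_value = 2 * pnorm(-abs(z)),
       degenerate = FALSE)
}

# standardized group risks and their gradient wrt glm coefficients
.standardized_risks <- function(fit, data, groups = .group_levels) {
  beta <- coef(fit)
  out <- map(groups, function(g) {
    nd <- data
    nd$group <- factor(g, levels = .group_levels)
    X <- stats::model.matrix(stats::delete.response(stats::terms(fit)), nd)
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    list(risk = mean(p), grad = colMeans(p * (1 - p) * X))
  })
  names(out) <- groups
  out
}

.new_ddi_fit <- function(...) structure(list(...), class = "ddi_fit")

#' Fit the synergistic DDI model
#'
#' Three-level exposure logistic regression (substrate alone, inhibitor
#' alone, joint) with optional age/sex/co-medication covariates. Adjusted
#' group risks are obtained by covariate standardization, the synergy
#' statistic is `RR = Risk12/(Risk1+Risk2)`, and the two-sided p-value for
#' H0: `Risk12 = Risk1 + Risk2` is a Wald test of log(RR) by the delta
#' method (default) or by stratified bootstrap. With no covariates the
#' standardized risks equal the raw group proportions exactly.
#'
#' @param episodes Episode tibble with `group`, `outcome`, and any covariate
#'   columns (`age_at_anchor`, `sex`, `comed_count`).
#' @param covariates Character subset of `c("age", "sex", "comeds")`; use
#'   `character()` for an unadjusted fit.
#' @param p_method `"delta"` or `"bootstrap"`.
#' @param n_boot Bootstrap resamples (stratified by group).
#' @param seed Optional seed for the bootstrap.
#' @return A `ddi_fit` object; see [tidy.ddi_fit()].
#' @export
fit_synergistic <- function(episodes, covariates = c("age", "sex"),
                            p_method = c("delta", "bootstrap"),
                            n_boot = 2000, seed = NULL) {
  p_method <- match.arg(p_method)
  missing_groups <- setdiff(.group_levels, unique(episodes$group))
  if (length(missing_groups)) {
    abort(paste0("exposure group(s) empty: ", paste(missing_groups, collapse = ", ")),
          class = "cypddi_missing_group")
  }
  counts <- .group_counts(episodes)
  cn <- setNames(counts$m, counts$group)
  nn <- setNames(counts$n, counts$group)
  cov_cols <- .covariate_columns(covariates)

  if (!length(cov_cols)) {
    res <- .synergy_counts_test(cn["substrate_alone"], nn["substrate_alone"],
                                cn["inhibitor_alone"], nn["inhibitor_alone"],
                                cn["joint"], nn["joint"])
    fit_obj <- NULL
    risks <- res$risks
    rr <- res$rr
    se <- res$se_log_rr
    p <- res$p_value
    degenerate <- res$degenerate
  } else {
    dat <- episodes %>%
      mutate(group = factor(.data$group, levels = .group_levels)) %>%
      select("group", "outcome", all_of(cov_cols)) %>%
      tidyr::drop_na()
    fml <- stats::reformulate(c("group", cov_cols), response = "outcome")
    fit_obj <- glm(fml, family = binomial(), data = dat)
    std <- .standardized_risks(fit_obj, dat)
    risks <- c(risk1 = std$substrate_alone$risk,
               risk2 = std$inhibitor_alone$risk,
               risk12 = std$joint$risk)
    rr <- rr_statistic(risks["risk1"], risks["risk2"], risks["risk12"])
    g <- std$joint$grad / risks["risk12"] -
      (std$substrate_alone$grad + std$inhibitor_alone$grad) /
      (risks["risk1"] + risks["risk2"])
    v <- drop(t(g) %*% vcov(fit_obj) %*% g)
    se <- sqrt(v)
    p <- 2 * pnorm(-abs(log(rr) / se))
    degenerate <- !fit_obj$converged || any(!is.finite(coef(fit_obj)))
    if (degenerate) p <- NA_real_
  }

  boot <- NULL
  if (p_method == "bootstrap" && !degenerate) {
    if (!is.null(seed)) set.seed(seed)
    idx_by_group <- split(seq_len(nrow(episodes)), episodes$group)
    boot <- map_dbl(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(idx_by_group, function(ii) {
        ii[sample.int(length(ii), length(ii), replace = TRUE)]
      }))
      eb <- episodes[idx, ]
      cb <- .group_counts(eb)
      if (!length(cov_cols)) {
        r <- .synergy_counts_test(cb$m[cb$group == "substrate_alone"],
                                  cb$n[cb$group == "substrate_alone"],
                                  cb$m[cb$group == "inhibitor_alone"],
                                  cb$n[cb$group == "inhibitor_alone"],
                                  cb$m[cb$group == "joint"],
                                  cb$n[cb$group == "joint"])
        log(r$rr)
      } else {
        db <- eb %>%
          mutate(group = factor(.data$group, levels = .group_levels)) %>%
          select("group", "outcome", all_of(cov_cols)) %>%
          tidyr::drop_na()
        fb <- suppressWarnings(glm(stats::reformulate(c("group", cov_cols),
                                                      response = "outcome"),
                                   family = binomial(), data = db))
        sb <- .standardized_risks(fb, db)
        log(sb$joint$risk / (sb$substrate_alone$risk + sb$inhibitor_alone$risk))
      }
    })
    boot <- boot[is.finite(boot)]
    se <- sd(boot)
    p <- 2 * pnorm(-abs(log(rr) / se))
  }

  .new_ddi_fit(
    model = "synergistic",
    pair = attr(episodes, "pair", exact = TRUE),
    risks = risks, rr = unname(rr),
    or_joint_vs_substrate = NA_real_,
    se_log_rr = unname(se), p_value = unname(p),
    counts = counts, covariates = covariates,
    p_method = p_method, degenerate = degenerate,
    fit = fit_obj, boot = boot
  )
}

#' Fit the additive DDI model
#'
#' Logistic regression of myopathy on a joint-vs-substrate-alone indicator
#' plus covariates, over the substrate-alone and joint episodes only. The
#' test asks whether adding the inhibitor raises the substrate's myopathy
#' risk; downstream significance additionally requires OR > 1. Complete
#' separation is flagged; when the `glmnet` package is available a
#' ridge-penalized odds ratio is reported as fallback (p-value stays `NA`).
#'
#' @inheritParams fit_synergistic
#' @return A `ddi_fit` object with `or_joint_vs_substrate` and `p_value`.
#' @export
fit_additive <- function(episodes, covariates = c("age", "sex")) {
  dat <- episodes %>% filter(.data$group %in% c("substrate_alone", "joint"))
  counts <- .group_counts(dat) %>% filter(.data$group != "inhibitor_alone")
  if (any(counts$n == 0)) {
    abort("both substrate_alone and joint groups must be non-empty",
          class = "cypddi_missing_group")
  }
  if (length(unique(dat$outcome)) < 2) {
    abort("both outcomes must be represented", class = "cypddi_invalid_argument")
  }
  cov_cols <- .covariate_columns(covariates)
  m1 <- counts$m[counts$group == "substrate_alone"]
  n1 <- counts$n[counts$group == "substrate_alone"]
  m12 <- counts$m[counts$group == "joint"]
  n12 <- counts$n[counts$group == "joint"]

  separation <- FALSE
  if (!length(cov_cols)) {
    if (m1 %in% c(0, n1) || m12 %in% c(0, n12)) {
      separation <- TRUE
      or <- NA_real_; se <- NA_real_; p <- NA_real_
    } else {
      lor <- log(m12 / (n12 - m12)) - log(m1 / (n1 - m1))
      se <- sqrt(1 / m1 + 1 / (n1 - m1) + 1 / m12 + 1 / (n12 - m12))
      or <- exp(lor)
      p <- 2 * pnorm(-abs(lor / se))
    }
    fit_obj <- NULL
  } else {
    dat2 <- dat %>%
      mutate(joint = .data$group == "joint") %>%
      select("joint", "outcome", all_of(cov_cols)) %>%
      tidyr::drop_na()
    fml <- stats::reformulate(c("joint", cov_cols), response = "outcome")
    fit_obj <- suppressWarnings(glm(fml, family = binomial(), data = dat2))
    sm <- summary(fit_obj)$coefficients
    separation <- !fit_obj$converged ||
      any(abs(coef(fit_obj)) > 15, na.rm = TRUE) ||
      max(sm[, "Std. Error"]) > 100
    if (separation) {
      or <- NA_real_; se <- NA_real_; p <- NA_real_
      if (requireNamespace("glmnet", quietly = TRUE)) {
        X <- stats::model.matrix(fml, dat2)[, -1, drop = FALSE]
        pen <- glmnet::glmnet(X, dat2$outcome, family = "binomial",
                              alpha = 0, lambda = 1e-3)
        or <- exp(drop(coef(pen))["jointTRUE"])
      }
      inform("complete separation detected; penalized odds ratio reported, p-value NA")
    } else {
      or <- exp(sm["jointTRUE", "Estimate"])
      se <- sm["jointTRUE", "Std. Error"]
      p <- sm["jointTRUE", "Pr(>|z|)"]
    }
  }

  .new_ddi_fit(
    model = "additive",
    pair = attr(episodes, "pair", exact = TRUE),
    risks = c(risk1 = m1 / n1, risk2 = NA_real_, risk12 = m12 / n12),
    rr = NA_real_,
    or_joint_vs_substrate = unname(or),
    se_log_rr = unname(se), p_value = unname(p),
    counts = counts, covariates = covariates,
    p_method = "wald", degenerate = separation,
    fit = fit_obj, boot = NULL
  )
}

#' @export
print.ddi_fit <- function(x, ...) {
  cat("<ddi_fit>", x$model, "model")
  if (!is.null(x$pair)) cat(" for", paste(x$pair, collapse = " + "))
  cat("\n")
  if (x$model == "synergistic") {
    cat(sprintf("  risks: %.3f / %.3f / %.3f   RR = %.2f   p = %.3g\n",
                x$risks["risk1"], x$risks["risk2"], x$risks["risk12"],
                x$rr, x$p_value))
  } else {
    cat(sprintf("  OR (joint vs substrate) = %.2f   p = %.3g\n",
                x$or_joint_vs_substrate, x$p_value))
  }
  cat("  counts:", format_counts(x$counts), "\n")
  invisible(x)
}

#' Format group counts as "(m1/n1, m2/n2, m12/n12)"
#'
#' @param counts A counts tibble with `group`, `m`, `n`.
#' @return A single string.
#' @export
format_counts <- function(counts) {
  ordered <- counts[match(intersect(.group_levels, counts$group), counts$group), ]
  paste0("(", paste(sprintf("%d/%d", ordered$m, ordered$n), collapse = ", "), ")")
}

#' CYP enzyme over-representation among significant DDI pairs
#'
#' For each enzyme, tests whether significant pairs are over-represented
#' among the pairs attributed to that enzyme versus all remaining pairs,
#' with a one-sided exact test on the 2x2 table (significant vs not, in
#' enzyme vs rest). A pair attributed to several enzymes counts once per
#' enzyme. Significance of a pair requires `p_value < threshold` and effect
#' direction > 1 (RR or OR, whichever the result carries).
#'
#' @param results A results tibble with `pair_key` (or `drug1`/`drug2`),
#'   `p_value`, and `rr` and/or `or_joint_vs_substrate`.
#' @param pair_enzyme_map Tibble mapping pairs to enzymes: `pair_key` plus
#'   `enzyme`, or `enzymes` (";"-joined) as produced by [predict_pairs()].
#' @param threshold Significance threshold in (0, 1), e.g. the Bonferroni
#'   level.
#' @return A tibble: `enzyme`, `n_sig_in`, `n_in`, `n_sig_out`, `n_out`,
#'   `p_value`.
#' @export
enzyme_enrichment <- function(results, pair_enzyme_map, threshold) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be in (0, 1)", class = "cypddi_invalid_argument")
  }
  res <- as_tibble(results)
  if (!"pair_key" %in% names(res)) {
    res$pair_key <- .pair_key(res$drug1, res$drug2)
  }
  effect <- if ("rr" %in% names(res) && any(!is.na(res$rr))) {
    res$rr
  } else {
    res$or_joint_vs_substrate
  }
  res$significant <- !is.na(res$p_value) & res$p_value < threshold &
    !is.na(effect) & effect > 1

  map_tbl <- as_tibble(pair_enzyme_map)
  if (!"pair_key" %in% names(map_tbl)) {
    key_cols <- intersect(c("drug1", "drug2"), names(map_tbl))
    if (length(key_cols) == 2) {
      map_tbl$pair_key <- .pair_key(map_tbl$drug1, map_tbl$drug2)
    } else {
      map_tbl$pair_key <- .pair_key(map_tbl$substrate_drug, map_tbl$inhibitor_drug)
    }
  }
  if (!"enzyme" %in% names(map_tbl)) {
    map_tbl <- map_tbl %>%
      tidyr::separate_rows("enzymes", sep = ";") %>%
      rename(enzyme = "enzymes")
  }
  map_tbl <- map_tbl %>% distinct(.data$pair_key, .data$enzyme)

  joined <- res %>%
    distinct(.data$pair_key, .data$significant) %>%
    inner_join(map_tbl, by = "pair_key")
  if (!nrow(joined)) {
    abort("no tested pair maps to an enzyme", class = "cypddi_invalid_argument")
  }
  total_sig <- joined %>% distinct(.data$pair_key, .data$significant)
  n_all <- nrow(total_sig)
  n_sig_all <- sum(total_sig$significant)

  joined %>%
    group_by(.data$enzyme) %>%
    summarise(n_sig_in = sum(.data$significant), n_in = n(), .groups = "drop") %>%
    mutate(
      n_out = n_all - .data$n_in,
      n_sig_out = n_sig_all - .data$n_sig_in,
      p_value = pmap(list(.data$n_sig_in, .data$n_in,
                          .data$n_sig_out, .data$n_out),
                     function(a, ni, c, no) {
                       tab <- matrix(c(a, ni - a, c, no - c), nrow = 2)
                       fisher.test(tab, alternative = "greater")$p.value
                     }) %>% unlist()
    ) %>%
    select("enzyme", "n_sig_in", "n_in", "n_sig_out", "n_out", "p_value") %>%
    arrange(.data$p_value)
}

#' Monte-Carlo power of the DDI tests
#'
#' Simulates the three-group design and reports the rejection rate.
#' For the synergistic model the joint-group risk is
#' `rr_alt * (risk1 + risk2)` (so `rr_alt = 1` is the null and the power
#' equals the size). For the additive model the joint-group risk is
#' `rr_alt * risk1` (the additive test's own null, joint risk equal to the
#' substrate-alone risk, holds at `rr_alt = 1`).
#'
#' Two rejection rules are reported: `power` applies the pipeline's
#' significance rule (two-sided p below `alpha` and effect direction > 1);
#' `power_two_sided` drops the direction gate and is the test's raw size
#' under the null. Degenerate replicates (e.g. zero joint-group events)
#' count as non-rejections.
#'
#' @param n1,n2,n12 Group sizes (all positive).
#' @param base_risks Numeric length 2: `(risk1, risk2)`.
#' @param rr_alt Alternative effect multiplier (1 = null).
#' @param alpha Significance level.
#' @param n_reps Number of replicates (warned below 100).
#' @param seed Optional integer seed.
#' @param model `"synergistic"` or `"additive"`.
#' @return A one-row tibble: `power`, `power_two_sided`, `mc_se`, `n_reps`,
#'   `mean_rr`.
#' @export
#' @examples
#' power_simulation(2000, 2000, 500, c(0.02, 0.02), rr_alt = 3,
#'                  n_reps = 200, seed = 1)
power_simulation <- function(n1, n2, n12, base_risks, rr_alt, alpha = 0.05,
                             n_reps = 1000, seed = NULL,
                             model = c("synergistic", "additive")) {
  model <- match.arg(model)
  if (any(c(n1, n2, n12) <= 0)) {
    abort("group sizes must be positive", class = "cypddi_invalid_argument")
  }
  if (n_reps < 100) warn("n_reps < 100: power estimate will be unstable")
  if (!is.null(seed)) set.seed(seed)
  r1 <- base_risks[1]; r2 <- base_risks[2]
  r12 <- if (model == "synergistic") {
    min(1, rr_alt * (r1 + r2))
  } else {
    min(1, rr_alt * r1)
  }
  m1 <- rbinom(n_reps, n1, r1)
  m2 <- rbinom(n_reps, n2, r2)
  m12 <- rbinom(n_reps, n12, r12)
  res <- map(seq_len(n_reps), function(i) {
    if (model == "synergistic") {
      t <- .synergy_counts_test(m1[i], n1, m2[i], n2, m12[i], n12)
      c(p = t$p_value, eff = t$rr)
    } else {
      if (m1[i] %in% c(0, n1) || m12[i] %in% c(0, n12)) {
        return(c(p = NA_real_, eff = NA_real_))
      }
      lor <- log(m12[i] / (n12 - m12[i])) - log(m1[i] / (n1 - m1[i]))
      se <- sqrt(1 / m1[i] + 1 / (n1 - m1[i]) + 1 / m12[i] + 1 / (n12 - m12[i]))
      c(p = 2 * pnorm(-abs(lor / se)), eff = exp(lor))
    }
  })
  p <- map_dbl(res, "p")
  eff <- map_dbl(res, "eff")
  reject <- !is.na(p) & p < alpha & !is.na(eff) & eff > 1
  reject2 <- !is.na(p) & p < alpha
  pw <- mean(reject)
  tibble(
    power = pw,
    power_two_sided = mean(reject2),
    mc_se = sqrt(pw * (1 - pw) / n_reps),
    n_reps = as.integer(n_reps),
    mean_rr = mean(eff, na.rm = TRUE)
  )
}
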