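test_that("the RR statistic reproduces the published worked examples", {
  ref <- ddi_reference_pairs()
  rr <- rr_statistic(ref$risk1, ref$risk2, ref$risk12)
  expect_equal(round(rr, 2), c(1.69, 1.86, 1.94, 3.21, 3.00))
  expect_equal(round(rr, 2), ref$rr)

  # exact additivity gives RR 1 at any risk level
  for (r in c(0.01, 0.1, 0.3, 0.5)) {
    expect_equal(rr_statistic(r, r, 2 * r), 1)
  }
  expect_error(rr_statistic(0, 0, 0.1), class = "cypddi_undefined_result")
  expect_error(rr_statistic(-0.1, 0.2, 0.1), class = "cypddi_invalid_argument")
})

test_that("the Bonferroni threshold is alpha over the test count", {
  expect_equal(signif(bonferroni_threshold(0.05, 3670), 3), 1.36e-5)
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  expect_identical(bonferroni_threshold(0.01, 100), 1e-4)
  expect_error(bonferroni_threshold(0.05, 0), class = "cypddi_invalid_argument")
  expect_error(bonferroni_threshold(0, 10), class = "cypddi_invalid_argument")
})

test_that("covariate-free synergistic fits reduce to raw group proportions", {
  ep <- simulate_episode_groups(400, 300, 200, 0.05, 0.08, theta = 2, seed = 42)
  fit <- fit_synergistic(ep, covariates = character())
  counts <- fit$counts
  m <- setNames(counts$m, counts$group)
  n <- setNames(counts$n, counts$group)
  expect_identical(unname(fit$risks["risk1"]),
                   unname(m["substrate_alone"] / n["substrate_alone"]))
  expect_identical(unname(fit$risks["risk2"]),
                   unname(m["inhibitor_alone"] / n["inhibitor_alone"]))
  expect_identical(unname(fit$risks["risk12"]), unname(m["joint"] / n["joint"]))
  expect_equal(fit$rr, rr_statistic(fit$risks["risk1"], fit$risks["risk2"],
                                    fit$risks["risk12"]), ignore_attr = TRUE)
  # the counts string prints in (m1/n1, m2/n2, m12/n12) order
  expect_match(format_counts(counts),
               sprintf("^\\(%d/%d, %d/%d, %d/%d\\)$",
                       m["substrate_alone"], n["substrate_alone"],
                       m["inhibitor_alone"], n["inhibitor_alone"],
                       m["joint"], n["joint"]))
})

test_that("the closed-form fast path equals the glm g-computation route", {
  # dual route: same data through the saturated glm + standardization oracle
  ep <- simulate_episode_groups(500, 500, 300, 0.04, 0.06, theta = 2.5, seed = 7)
  fit <- fit_synergistic(ep, covariates = character())
  oracle <- oracle_standardized_risks(ep, character())
  expect_equal(unname(fit$risks),
               unname(oracle[c("substrate_alone", "inhibitor_alone", "joint")]),
               tolerance = 1e-10)

  # with covariates the standardized risks match the prediction oracle too
  epc <- simulate_episode_groups(800, 800, 400, 0.05, 0.05, theta = 2,
                                 covariates = TRUE, seed = 8)
  fitc <- fit_synergistic(epc, covariates = c("age", "sex"))
  oraclec <- oracle_standardized_risks(epc, c("age_at_anchor", "sex"))
  expect_equal(unname(fitc$risks),
               unname(oraclec[c("substrate_alone", "inhibitor_alone", "joint")]),
               tolerance = 1e-8)
})

test_that("fits demand their exposure groups and report separation", {
  ep <- simulate_episode_groups(100, 100, 50, 0.1, 0.1, theta = 2, seed = 1)
  no_joint <- ep[ep$group != "joint", ]
  expect_error(fit_synergistic(no_joint, covariates = character()), "joint")
  expect_error(fit_additive(no_joint, covariates = character()),
               class = "cypddi_missing_group")

  # all joint episodes are events: separation flagged, p NA
  sep <- ep
  sep$outcome[sep$group == "joint"] <- TRUE
  fa <- fit_additive(sep, covariates = character())
  expect_true(fa$degenerate)
  expect_true(is.na(fa$p_value))
})

test_that("delta-method and bootstrap p-values agree in decision", {
  agree <- vapply(1:20, function(i) {
    ep <- simulate_episode_groups(1000, 1000, 500, 0.05, 0.05,
                                  theta = c(1, 1.8)[i %% 2 + 1], seed = 100 + i)
    fd <- fit_synergistic(ep, covariates = character())
    fb <- fit_synergistic(ep, covariates = character(),
                          p_method = "bootstrap", n_boot = 300, seed = i)
    (fd$p_value < 0.05) == (fb$p_value < 0.05)
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("additive fits detect injected effects and respect direction", {
  ep <- simulate_episode_groups(3000, 3000, 1500, 0.03, 0.03, theta = 3,
                                seed = 33)
  fa <- fit_additive(ep, covariates = character())
  expect_gt(fa$or_joint_vs_substrate, 1)
  expect_lt(fa$p_value, 1e-6)
  # glm route with covariates agrees with the count route on clean data
  epc <- simulate_episode_groups(3000, 3000, 1500, 0.03, 0.03, theta = 3,
                                 covariates = TRUE, seed = 34)
  fac <- fit_additive(epc, covariates = c("age", "sex"))
  expect_gt(fac$or_joint_vs_substrate, 1)
  expect_lt(fac$p_value, 1e-6)
})

test_that("tidy and glance summarise fits as one-row tibbles", {
  ep <- simulate_episode_groups(300, 300, 200, 0.08, 0.08, theta = 2, seed = 2)
  attr(ep, "pair") <- c("drugA", "drugB")
  fit <- fit_synergistic(ep, covariates = character())
  td <- tidy(fit)
  expect_identical(nrow(td), 1L)
  expect_identical(td$drug1, "drugA")
  expect_identical(td$model, "synergistic")
  expect_true(all(c("risk1", "risk12", "rr", "p_value", "counts") %in% names(td)))
  gl <- glance(fit)
  expect_identical(gl$n_episodes, 800L)
  expect_identical(gl$p_method, "delta")
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("enzyme enrichment matches the exact hypergeometric oracle", {
  # hand-built 2x2: 3/10 significant in-enzyme vs 2/90 outside
  results <- tibble::tibble(
    pair_key = sprintf("p%03d", 1:100),
    p_value = c(rep(1e-8, 3), rep(0.5, 7), rep(1e-8, 2), rep(0.5, 88)),
    rr = 2
  )
  map <- tibble::tibble(
    pair_key = results$pair_key,
    enzyme = c(rep("CYP3A4/5", 10), rep("CYP2D6", 90))
  )
  out <- enzyme_enrichment(results, map, threshold = 1e-5)
  row <- out[out$enzyme == "CYP3A4/5", ]
  expect_identical(c(row$n_sig_in, row$n_in, row$n_sig_out, row$n_out),
                   c(3L, 10L, 2L, 90L))
  expect_equal(row$p_value, oracle_enrichment_p(3, 10, 2, 90), tolerance = 1e-12)

  # extreme table: all significant pairs in one enzyme gives it the min p
  results2 <- results
  results2$p_value <- c(rep(1e-8, 5), rep(0.5, 95))
  out2 <- enzyme_enrichment(results2, map, threshold = 1e-5)
  expect_identical(out2$enzyme[which.min(out2$p_value)], "CYP3A4/5")

  expect_error(enzyme_enrichment(results, map, threshold = 0),
               class = "cypddi_invalid_argument")

  # under enzyme-independent significance, per-enzyme enrichment is rarely
  # significant (null simulation)
  set.seed(99)
  hits <- vapply(1:200, function(i) {
    res <- tibble::tibble(pair_key = sprintf("p%02d", 1:60),
                          p_value = ifelse(runif(60) < 0.1, 1e-9, 0.5),
                          rr = 2)
    mp <- tibble::tibble(pair_key = res$pair_key,
                         enzyme = sample(c("CYP3A4/5", "CYP2D6", "CYP2C9"),
                                         60, replace = TRUE))
    min(enzyme_enrichment(res, mp, threshold = 1e-5)$p_value) < 0.05
  }, logical(1))
  # family-wise over 3 enzymes, one-sided conservative exact test
  expect_lt(mean(hits), 0.15)
})

test_that("power simulation sizes the null and orders alternatives", {
  null_pw <- power_simulation(4000, 4000, 1000, c(0.02, 0.02), rr_alt = 1,
                              alpha = 0.05, n_reps = 1500, seed = 5)
  env <- 3 * sqrt(0.05 * 0.95 / 1500)
  expect_lt(abs(null_pw$power_two_sided - 0.05), env)

  # non-decreasing power in the joint-group size
  grid <- vapply(c(300, 1000, 4000), function(n12) {
    power_simulation(20000, 20000, n12, c(0.02, 0.02), rr_alt = 1.6,
                     alpha = 0.001, n_reps = 400, seed = 11)$power
  }, numeric(1))
  expect_true(all(diff(grid) >= 0))

  expect_warning(power_simulation(100, 100, 50, c(0.1, 0.1), 2, n_reps = 50,
                                  seed = 1),
                 "unstable")
  expect_error(power_simulation(0, 10, 10, c(0.1, 0.1), 2),
               class = "cypddi_invalid_argument")
})
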