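# Shared fixtures and independent oracles, built in code at test time.

# hand-built EMR: persons and events laid out on a known calendar
make_tiny_emr <- function() {
  d <- function(x) as.Date(x)
  person <- tibble::tibble(
    person_id = 1:6,
    sex = c("F", "M", "F", "M", "F", "M"),
    birth_year = c(1960, 1970, 1980, 1950, 1990, 1965)
  )
  drug_exposure <- tibble::tibble(
    person_id = c(1L, 2L, 2L, 3L, 3L, 4L, 5L, 6L),
    drug_name = c("subA",        # p1: substrate 10d before myopathy
                  "subA", "inhB",  # p2: both 5d before myopathy
                  "subA", "inhB",  # p3: substrate day 0, inhibitor day 45
                  "subA",          # p4: exactly 30d before myopathy
                  "subA",          # p5: 31d before myopathy
                  "inhB"),         # p6: inhibitor-alone control
    start_date = d(c("2004-09-20",
                     "2004-09-25", "2004-09-25",
                     "2004-08-01", "2004-09-15",
                     "2004-08-31",
                     "2004-08-30",
                     "2004-10-01"))
  )
  condition_occurrence <- tibble::tibble(
    person_id = c(1L, 2L, 4L, 5L),
    concept_name = "Myalgia and myositis",
    event_date = d(c("2004-09-30", "2004-09-30", "2004-09-30", "2004-09-30"))
  )
  structure(list(person = person, drug_exposure = drug_exposure,
                 condition_occurrence = condition_occurrence),
            class = "ddi_emr")
}

# brute-force DDI pair enumeration: independent triple loop over
# (enzyme, substrate, inhibitor); returns sorted unordered keys and the
# directed pair count
oracle_pairs <- function(activities) {
  directed <- list()
  for (e in unique(activities$enzyme)) {
    subs <- activities$drug[activities$enzyme == e & activities$is_substrate]
    inhs <- activities$drug[activities$enzyme == e & activities$is_inhibitor]
    for (s in subs) for (i in inhs) {
      if (s != i) directed[[length(directed) + 1]] <- c(s, i, e)
    }
  }
  if (!length(directed)) {
    return(list(directed = character(), unordered = character()))
  }
  m <- unique(do.call(rbind, directed)[, 1:2, drop = FALSE])
  keys <- paste(m[, 1], m[, 2], sep = "->")
  list(directed = sort(keys),
       unordered = sort(unique(paste(pmin(m[, 1], m[, 2]),
                                     pmax(m[, 1], m[, 2]), sep = "|"))))
}

# one-sided hypergeometric over-representation p, by direct enumeration
# with choose() -- independent of stats::fisher.test
oracle_enrichment_p <- function(n_sig_in, n_in, n_sig_out, n_out) {
  k_total <- n_sig_in + n_sig_out
  n_total <- n_in + n_out
  ks <- n_sig_in:min(n_in, k_total)
  sum(choose(n_in, ks) * choose(n_out, k_total - ks)) /
    choose(n_total, k_total)
}

# independent g-computation oracle: glm + per-group standardized prediction
oracle_standardized_risks <- function(episodes, cov_cols) {
  dat <- episodes
  dat$group <- factor(dat$group,
                      levels = c("substrate_alone", "inhibitor_alone", "joint"))
  fml <- stats::reformulate(c("group", cov_cols), response = "outcome")
  fit <- stats::glm(fml, family = stats::binomial(), data = dat)
  sapply(levels(dat$group), function(g) {
    nd <- dat
    nd$group <- factor(g, levels = levels(dat$group))
    mean(stats::predict(fit, newdata = nd, type = "response"))
  })
}
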