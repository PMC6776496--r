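test_that("simulated histories alternate and honour the overrun rule", {
  st <- sim_settings(n_patients = 500, seed = 3)
  h <- simulate_histories(intensity_matrix(1 / 2.82, 1 / 3.10), st)
  expect_true(all(h$start < st$horizon))
  by_id <- split(h, h$id)
  ok <- vapply(by_id, function(s) {
    all(s$state[1] == 1L, diff(s$start) > 0,
        abs(s$state[-1] - s$state[-nrow(s)]) == 1,
        s$start[nrow(s)] + s$duration[nrow(s)] >= st$horizon)
  }, TRUE)
  expect_true(all(ok))
  # a zero entry rate leaves a single unbroken No-MDA sojourn
  h0 <- simulate_histories(c(0, 1), sim_settings(n_patients = 50,
                                                 seed = 4))
  expect_true(all(h0$state == 1L))
  expect_equal(nrow(h0), 50)
})

test_that("sojourn durations have the exponential mean", {
  st <- sim_settings(n_patients = 1e5, seed = 5)
  h <- simulate_histories(c(1 / 2.82, 1 / 3.10), st)
  first <- h[h$start == 0, ]
  expect_lt(abs(mean(first$duration) - 2.82), 3 * 2.82 / sqrt(1e5))
})

test_that("simulated summaries match the closed forms for random rate pairs", {
  set.seed(6)
  for (i in 1:4) {
    l1 <- runif(1, 0.15, 1); l2 <- runif(1, 0.15, 1)
    st <- sim_settings(n_patients = 3e4, seed = 100 + i)
    sm <- sustained_summary(intensity_matrix(l1, l2), st)
    an <- mdahmm:::.analytic_summary(l1, l2, st)
    # MC standard errors (conservative bounds)
    se_time <- 3.5 / sqrt(3e4)
    expect_lt(abs(sm$estimates[["time_mda"]] - an[["time_mda"]]),
              3 * se_time)
    expect_lt(abs(sm$estimates[["spells_mda"]] - an[["spells_mda"]]),
              3 * 2 / sqrt(3e4))
    expect_lt(abs(sm$estimates[["spells_long_mda"]] -
                    an[["spells_long_mda"]]), 3 * 2 / sqrt(3e4))
    p <- an[["prob_visit_mda"]]
    expect_lt(abs(sm$estimates[["prob_visit_mda"]] - p),
              3 * sqrt(p * (1 - p) / 3e4) + 1e-9)
  }
})

test_that("accounting identities hold on every run", {
  set.seed(7)
  for (i in 1:3) {
    st <- sim_settings(n_patients = 5000, seed = 200 + i,
                       sustain_threshold = runif(1, 0.3, 2))
    e <- sustained_summary(intensity_matrix(runif(1, 0.2, 1),
                                            runif(1, 0.2, 1)),
                           st)$estimates
    expect_equal(e[["time_short_mda"]] + e[["time_long_mda"]],
                 e[["time_mda"]], tolerance = 1e-9)
    expect_equal(e[["time_first_year_mda"]] + e[["time_later_years_mda"]],
                 e[["time_mda"]], tolerance = 1e-9)
    expect_equal(e[["time_sustained_mda"]], e[["time_later_years_mda"]])
    expect_lte(e[["prob_visit_long_mda"]], e[["prob_visit_mda"]])
    expect_true(all(e[c("prob_visit_mda", "prob_visit_long_mda")] >= 0 &
                      e[c("prob_visit_mda", "prob_visit_long_mda")] <= 1))
  }
})

test_that("a vanishing sustain threshold makes all MDA time long", {
  st <- sim_settings(n_patients = 4000, sustain_threshold = 1e-9,
                     seed = 8)
  e <- sustained_summary(intensity_matrix(0.4, 0.3), st)$estimates
  expect_equal(e[["time_long_mda"]], e[["time_mda"]])
  expect_equal(e[["time_short_mda"]], 0)
  expect_equal(e[["spells_short_mda"]], 0)
})

test_that("long-spell counts follow the memorylessness identity", {
  # entries x P(sojourn >= threshold), with the exponential tail
  st <- sim_settings(n_patients = 1e5, seed = 9)
  e <- sustained_summary(intensity_matrix(1 / 2.82, 1 / 3.10),
                         st)$estimates
  expect_equal(e[["spells_long_mda"]],
               e[["spells_mda"]] * exp(-1 / 3.10), tolerance = 0.02)
})

test_that("total MDA time is not sojourn length times entry count", {
  # the horizon truncates the last sojourn, so the naive product
  # overstates the expected total time
  st <- sim_settings(n_patients = 2e4, seed = 10)
  e <- sustained_summary(intensity_matrix(1 / 2.82, 1 / 3.10),
                         st)$estimates
  expect_true(e[["time_mda"]] <
                e[["sojourn_mda"]] * e[["spells_mda"]] - 1)
})

test_that("group summaries share random numbers and ratios behave", {
  m <- intensity_model(0.4, 0.3, beta = 0, gamma = 0,
                       covariates = "female")
  st <- sim_settings(n_patients = 2000, seed = 11)
  gs <- summarize_by_group(m, data.frame(female = c(0, 1)), st)
  # identical rates in both groups + common seed: identical summaries
  expect_equal(gs[[1]]$estimates, gs[[2]]$estimates)
  rel <- relative_measures(gs[[2]], gs[[1]])
  expect_equal(rel$estimate, rep(1, nrow(rel)))
  expect_error(summarize_by_group(m, data.frame(x = 1), st),
               "lacks covariate")
})

test_that("relative measures use odds ratios for visit probabilities", {
  a <- structure(list(estimates = c(sojourn_mda = 2, time_mda = 3,
                                    time_sustained_mda = 2,
                                    spells_mda = 1.5,
                                    spells_long_mda = 1,
                                    prob_visit_mda = 0.94,
                                    prob_visit_long_mda = 0.82),
                      settings = sim_settings()),
                 class = "sustained_summary")
  b <- a
  b$estimates[c("prob_visit_mda", "prob_visit_long_mda")] <- c(0.98, 0.94)
  rel <- relative_measures(a, b)
  or <- (0.94 / 0.06) / (0.98 / 0.02)
  expect_equal(rel$estimate[rel$measure == "odds_prob_visit_mda"], or)
  expect_equal(or, 0.3197, tolerance = 1e-4)
})

test_that("bootstrap intervals cover their own point estimate", {
  coh <- generate_cohort(cohort_design(n_patients = 80), seed = 12)
  fit <- fit_mda(coh$visits, mode = "complete_case", n_starts = 1)
  st <- sim_settings(n_bootstrap = 100, n_patients = 4000, seed = 13)
  bs <- bootstrap_intervals(fit, st, method = "simulation")
  inside <- bs$estimates >= bs$intervals[, "lower"] - 0.05 &
    bs$estimates <= bs$intervals[, "upper"] + 0.05
  expect_true(all(inside))
  # near-degenerate covariance collapses the intervals
  fit0 <- fit
  fit0$vcov <- diag(1e-12, length(fit$theta))
  dimnames(fit0$vcov) <- list(names(fit$theta), names(fit$theta))
  bs0 <- bootstrap_intervals(fit0, sim_settings(n_bootstrap = 50,
                                                seed = 14),
                             method = "closed_form")
  expect_lt(max(bs0$intervals[, "upper"] - bs0$intervals[, "lower"]),
            1e-4)
})
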