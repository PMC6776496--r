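# a minimal hand-built fit object for testing the reporting helpers
fake_fit <- function(lograte = log(c(0.3546, 0.3226)),
                     se = c(0.05, 0.05), covariates = character(0),
                     coefs = numeric(0), coef_se = numeric(0)) {
  nm <- c("log_rate_no_to_mda", "log_rate_mda_to_no")
  th <- setNames(lograte, nm)
  if (length(covariates)) {
    cn <- c(paste0("beta.", covariates), paste0("gamma.", covariates))
    th <- c(th, setNames(coefs, cn))
    se <- c(se, coef_se)
  }
  vc <- diag(se^2, length(th))
  dimnames(vc) <- list(names(th), names(th))
  structure(list(theta = th, vcov = vc,
                 se = setNames(se, names(th)), covariates = covariates,
                 mode = "complete_case", loglik = 0, converged = TRUE),
            class = "mda_fit")
}

test_that("sojourn table applies the log-scale delta method", {
  tab <- sojourn_table(fake_fit())
  expect_equal(tab$sojourn_years, c(1 / 0.3546, 1 / 0.3226),
               tolerance = 1e-6)
  expect_equal(tab$se, tab$sojourn_years * 0.05, tolerance = 1e-12)
  expect_equal(tab$sojourn_years[1], 2.82, tolerance = 1e-3)
  expect_equal(tab$se[1], 0.141, tolerance = 1e-3)
  # zero variance gives zero standard error and a degenerate interval
  tab0 <- sojourn_table(fake_fit(se = c(0, 0)))
  expect_equal(tab0$se, c(0, 0))
  expect_equal(tab0$lower, tab0$upper)
})

test_that("hazard ratios exponentiate coefficients with Wald intervals", {
  f <- fake_fit(covariates = "female", coefs = c(0, log(2)),
                coef_se = c(0.1, 0))
  hr <- hazard_ratios(f)
  expect_equal(hr$hr, c(1, 2))
  expect_equal(hr$lower[1], exp(-1.96 * 0.1))
  expect_equal(hr$lower[2], 2)  # zero SE: degenerate interval
  expect_error(hazard_ratios(fake_fit()), "no covariates")
})

test_that("complete-case fit recovers rates from panel data", {
  coh <- generate_cohort(cohort_design(n_patients = 250,
                                       followup_median = 6), seed = 21)
  fit <- fit_mda(coh$visits, mode = "complete_case", n_starts = 1)
  expect_true(fit$converged)
  # complete-case estimates are consistent for the truth here because
  # determinable visits are a state-independent subsample
  z <- (fit$theta[1:2] - log(c(1 / 2.3, 1 / 4.5))) / fit$se[1:2]
  expect_true(all(abs(z) < 3))
  # likelihood at the MLE is at least the likelihood at the truth
  truth_ll <- total_loglik(coh$visits,
                           mda_parameters(coh$truth$model),
                           mode = "complete_case")
  expect_gte(fit$loglik + 1e-6, truth_ll)
})

test_that("fitted rate maximises its own likelihood profile", {
  coh <- generate_cohort(cohort_design(n_patients = 120), seed = 22)
  fit <- fit_mda(coh$visits, mode = "complete_case", n_starts = 1,
                 hessian = FALSE)
  l2 <- fit$estimates$model$rate_mda_to_no
  prof <- vapply(seq(0.5, 2, by = 0.1), function(mult) {
    m <- intensity_model(fit$estimates$model$rate_no_to_mda * mult, l2)
    total_loglik(coh$visits, mda_parameters(m), mode = "complete_case")
  }, 0)
  expect_gte(fit$loglik + 1e-8, max(prof))
})

test_that("likelihood is equivariant to covariate centering", {
  # shifting a covariate by c and rescaling the baseline rates by
  # exp(c * coef) leaves the likelihood unchanged (exact algebra)
  coh <- generate_cohort(cohort_design(n_patients = 40), seed = 23)
  v <- coh$visits
  beta <- 0.4; gamma <- -0.25; cshift <- 1.7
  m1 <- intensity_model(0.4, 0.3, beta, gamma, "age_c")
  v$age_c <- v$age - mean(v$age)
  ll1 <- total_loglik(v, mda_parameters(m1, c(0.5, 0.5),
                                        default_emission_params()))
  v2 <- v
  v2$age_c <- v$age_c + cshift
  m2 <- intensity_model(0.4 * exp(-cshift * beta),
                        0.3 * exp(-cshift * gamma), beta, gamma, "age_c")
  ll2 <- total_loglik(v2, mda_parameters(m2, c(0.5, 0.5),
                                         default_emission_params()))
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("covariate effects on intensities are recovered", {
  des <- cohort_design(n_patients = 350, followup_median = 6,
                       model = intensity_model(1 / 2.3, 1 / 4.5,
                                               beta = log(1.5), gamma = 0,
                                               covariates = "female"))
  coh <- generate_cohort(des, seed = 24)
  fit <- fit_mda(coh$visits, mode = "complete_case",
                 covariates = "female", n_starts = 1)
  z <- (fit$theta["beta.female"] - log(1.5)) / fit$se["beta.female"]
  expect_lt(abs(z), 3)
  hr <- hazard_ratios(fit)
  expect_gt(hr$hr[hr$transition == "no_to_mda"], 1)
})

test_that("partially hidden fit needs an anchor and respects fixed f", {
  all_ind <- forced_series(c(0, 1, 2),
                           rep("indeterminate", 3))
  expect_error(fit_mda(all_ind, mode = "partially_hidden"),
               "anchored")
  coh <- generate_cohort(cohort_design(n_patients = 25), seed = 26)
  fit <- fit_mda(coh$visits, mode = "partially_hidden", n_starts = 1,
                 fix_f = c(0.5, 0.5), hessian = FALSE,
                 control = list(maxit = 30))
  expect_equal(fit$estimates$f, c(0.5, 0.5))
  expect_false("logit_f_mda" %in% names(fit$theta))
})
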