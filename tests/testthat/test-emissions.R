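params <- default_emission_params()
spec <- emission_spec()

test_that("per-visit emission likelihood follows conditional independence", {
  # empty outcome vector contributes nothing in either state
  empty <- lapply(visit_row(), function(x) NA_real_)
  expect_equal(emission_loglik(empty, "no_mda", params = params), 0)
  expect_equal(emission_loglik(empty, "mda", params = params), 0)

  # single binomial variable: closed form C(10,5) 0.5^10
  p1 <- params
  p1$vars$PTPPAINV$prob <- c(0.5, 0.5)
  v <- c(empty, list()); v$PTPPAINV <- 5
  expect_equal(emission_loglik(v, "mda", params = p1),
               log(choose(10, 5) * 0.5^10))

  # two observed variables: log-likelihoods add
  va <- empty; va$TJC <- 3
  vb <- empty; vb$PTPSA <- 2
  vab <- empty; vab$TJC <- 3; vab$PTPSA <- 2
  for (s in c("no_mda", "mda"))
    expect_equal(emission_loglik(vab, s, params = params),
                 emission_loglik(va, s, params = params) +
                   emission_loglik(vb, s, params = params))
})

test_that("encoded supports and scalings are enforced", {
  # VAS scores are rounded half-to-even before the Binomial(10, p) pmf
  a <- visit_row(PTPPAINV = 2.5)   # rounds to 2
  b <- visit_row(PTPPAINV = 2)
  expect_equal(emission_loglik(a, "mda", params = params),
               emission_loglik(b, "mda", params = params))
  # HAQ is carried as an integer once multiplied by 100
  enc <- mdahmm:::encode_outcomes(as.data.frame(visit_row(HAQ = 1.25)))
  expect_equal(enc$HAQ, 125)
  expect_error(emission_loglik(visit_row(TJC = -1), "mda",
                               params = params), "domain")
})

test_that("pmfs are proper over their supports", {
  for (v in names(spec$vars)) {
    p <- params$vars[[v]]
    for (r in 1:2) {
      mass <- switch(spec$vars[[v]]$family,
        binomial10 = sum(dbinom(0:10, 10, p$prob[r])),
        negative_binomial = pnbinom(50000, size = p$size,
                                    prob = p$prob[r]))
      expect_gte(mass, 1 - 1e-10)
    }
  }
  # beta-binomial of the robust variant, via the hand-computed pmf
  rp <- default_emission_params(emission_spec("robust"))
  bb <- rp$vars$PTPPAINV
  for (r in 1:2)
    expect_equal(sum(exp(mdahmm:::.dbetabinom_log(0:10, 10, bb$shape1[r],
                                                  bb$shape2[r]))), 1)
})

test_that("likelihood decreases away from each family's mode", {
  # unimodality on the encoded scale: walking away from the modal value
  # never increases the log-likelihood
  empty <- lapply(visit_row(), function(x) NA_real_)
  for (v in c("TJC", "PTPSA")) {
    grid <- if (v == "PTPSA") 0:10 else 0:30
    for (r in 1:2) {
      ll <- vapply(grid, function(y) {
        vv <- empty; vv[[v]] <- y
        emission_loglik(vv, r, params = params)
      }, 0)
      mode_at <- which.max(ll)
      expect_true(all(diff(ll[seq_len(mode_at)]) >= 0))
      expect_true(all(diff(ll[mode_at:length(ll)]) <= 0))
    }
  }
})

test_that("simulated outcomes have the configured moments and masks", {
  set.seed(8)
  sim <- simulate_outcomes("mda", spec, params, n = 1e5)
  p <- params$vars$PTPPAINV$prob[2]
  se <- sqrt(10 * p * (1 - p) / 1e5)
  expect_lt(abs(mean(sim$PTPPAINV) - 10 * p), 3 * se)
  # negative binomial mean n(1-p)/p on the encoded scale
  nb <- params$vars$TJC
  m <- nb$size * (1 - nb$prob[2]) / nb$prob[2]
  expect_lt(abs(mean(sim$TJC) - m), 3 * sqrt(m / nb$prob[2] / 1e5))
  # masked components come back missing
  sim <- simulate_outcomes("mda", spec, params,
                           missing = c(HAQ = TRUE), n = 10)
  expect_true(all(is.na(sim$HAQ)))
  expect_true(all(!is.na(sim$TJC)))
})

test_that("discriminability report equals brute-force mass below cutpoints", {
  rep <- discriminability_report(spec, params)
  nb <- params$vars$TJC
  for (r in 1:2)
    expect_equal(rep$p_satisfied_no_mda[rep$variable == "TJC"] * (r == 1) +
                   rep$p_satisfied_mda[rep$variable == "TJC"] * (r == 2),
                 sum(dnbinom(0:1, size = nb$size, prob = nb$prob[r])))
  # degenerate binomial: p ~ 0 always satisfies a VAS <= 2 criterion
  p0 <- params; p0$vars$PTPSA$prob <- c(1e-9, 1e-9)
  rep0 <- discriminability_report(spec, p0)
  expect_equal(rep0$p_satisfied_mda[rep0$variable == "PTPSA"], 1,
               tolerance = 1e-6)
  # identical parameters in both states discriminate nothing
  psym <- params
  for (v in names(psym$vars)) {
    if (!is.null(psym$vars[[v]]$prob))
      psym$vars[[v]]$prob <- rep(mean(psym$vars[[v]]$prob), 2)
  }
  rsym <- discriminability_report(spec, psym)
  expect_equal(rsym$p_satisfied_no_mda, rsym$p_satisfied_mda)
})

test_that("marginal maximum likelihood recovers simulation parameters", {
  set.seed(12)
  n <- 5000
  # binomial VAS: MLE is the mean/10
  p_true <- params$vars$PTPPAINV$prob[1]
  y <- rbinom(n, 10, p_true)
  p_hat <- mean(y) / 10
  se <- sqrt(p_true * (1 - p_true) / (10 * n))
  expect_lt(abs(p_hat - p_true), 3 * se)
  # negative binomial: joint MLE of (log size, logit p)
  nb <- params$vars$TJC
  y <- rnbinom(n, size = nb$size, prob = nb$prob[1])
  # extreme probe points can push dnbinom outside its support; the
  # resulting -Inf is handled by optim, so silence the NaN chatter
  nll <- function(th) suppressWarnings(
    -sum(dnbinom(y, size = exp(th[1]), prob = plogis(th[2]), log = TRUE)))
  opt <- optim(c(log(1), 0), nll, method = "BFGS", hessian = TRUE)
  se <- sqrt(diag(solve(opt$hessian)))
  expect_lt(abs(opt$par[1] - log(nb$size)), 3 * se[1])
  expect_lt(abs(opt$par[2] - qlogis(nb$prob[1])), 3 * se[2])
})

test_that("robust emission variant swaps families as documented", {
  rs <- emission_spec("robust")
  expect_equal(rs$vars$PTPPAINV$family, "beta_binomial10")
  expect_equal(rs$vars$HAQ$family, "bernoulli_criterion")
  expect_equal(rs$vars$PASI$criterion, "skin")
  expect_null(rs$vars$BSA)
  expect_equal(rs$vars$TJC$family, "negative_binomial")
  # the Bernoulli emission scores the decidable criterion indicator
  rp <- default_emission_params(rs)
  v <- visit_row(PASI = 0.5)
  expect_equal(emission_loglik(v, "mda", rs, rp),
               emission_loglik(v, "mda", rs, rp))  # evaluates cleanly
  ll1 <- emission_loglik(visit_row(), "mda", rs, rp)
  expect_true(is.finite(ll1))
})
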