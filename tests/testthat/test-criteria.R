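test_that("fully observed visits classify correctly at the boundaries", {
  st <- evaluate_criteria(forced_visit("mda"))
  expect_equal(st$n_satisfied, 7)
  expect_equal(st$determination, "mda")

  st <- evaluate_criteria(forced_visit("no_mda"))
  expect_equal(st$n_failed, 7)
  expect_equal(st$determination, "no_mda")

  st <- evaluate_criteria(forced_visit("indeterminate"))
  expect_equal(st$n_observed, 0)
  expect_equal(st$determination, "indeterminate")
})

test_that("partially observed visits decide only when the rule is certain", {
  # 5 observed, all satisfied, 2 unobserved -> MDA
  v <- visit_row(HAQ = NA, PTPSA = NA)
  expect_equal(evaluate_criteria(v)$determination, "mda")
  # 3 observed, all failed -> no MDA
  v <- forced_visit("no_mda")
  v[c("PASI", "BSA", "PTPPAINV", "PTPSA", "HAQ")] <- NA
  st <- evaluate_criteria(v)
  expect_equal(st$n_failed, 3)
  expect_equal(st$determination, "no_mda")
  # 4 observed: 2 satisfied, 2 failed -> indeterminate
  v <- forced_visit("no_mda")
  v[c("PASI", "BSA", "PTPSA", "ENTH_TOT")] <- NA
  v$TJC <- 0; v$SJC <- 1
  st <- evaluate_criteria(v)
  expect_equal(c(st$n_satisfied, st$n_failed), c(2, 2))
  expect_equal(st$determination, "indeterminate")
})

test_that("skin OR criterion is failed only when both components rule it out", {
  # only PASI observed and above cutpoint: BSA could still satisfy it
  st <- evaluate_criteria(visit_row(PASI = 5, BSA = NA))
  expect_equal(as.character(st$status["skin"]), "unobserved")
  # only BSA observed and above cutpoint: likewise undecided
  st <- evaluate_criteria(visit_row(PASI = NA, BSA = 10))
  expect_equal(as.character(st$status["skin"]), "unobserved")
  # either component at or below its cutpoint satisfies it on its own
  st <- evaluate_criteria(visit_row(PASI = NA, BSA = 3))
  expect_equal(as.character(st$status["skin"]), "satisfied")
  st <- evaluate_criteria(visit_row(PASI = 1, BSA = NA))
  expect_equal(as.character(st$status["skin"]), "satisfied")
  # both observed, both failing: definitely failed
  st <- evaluate_criteria(visit_row(PASI = 2, BSA = 4))
  expect_equal(as.character(st$status["skin"]), "failed")
})

test_that("thresholds are inclusive and domains enforced", {
  v <- visit_row(TJC = 1, SJC = 1, PASI = 1, PTPPAINV = 1.5, PTPSA = 2,
                 HAQ = 0.5, ENTH_TOT = 1)
  expect_equal(evaluate_criteria(v)$n_satisfied, 7)
  expect_error(evaluate_criteria(visit_row(TJC = 70)), "domain")
  expect_error(evaluate_criteria(visit_row(HAQ = 3.5)), "domain")
  expect_error(mda_criteria(thresholds = c(XYZ = 1)), "unknown variable")
})

test_that("determination rules are exclusive and exhaustive over all count pairs", {
  cfg <- mda_criteria()
  for (ns in 0:7) for (nf in 0:(7 - ns)) {
    det <- as.character(determination_from_counts(ns, nf, cfg))
    expected <- if (ns >= 5) "mda" else if (nf >= 3) "no_mda" else
      "indeterminate"
    expect_equal(det, expected, info = sprintf("ns=%d nf=%d", ns, nf))
  }
  expect_error(determination_from_counts(5, 3, cfg), "exceeds")
})

test_that("with all criteria observed an indeterminate status is impossible", {
  for (ns in 0:7)
    expect_true(as.character(determination_from_counts(ns, 7 - ns)) !=
                  "indeterminate")
})

test_that("adding information never reverses a determination (monotonicity)", {
  # over every reachable count pair: one more satisfied criterion cannot
  # leave MDA, one more failed cannot leave no-MDA
  for (ns in 0:6) for (nf in 0:(6 - ns)) {
    d0 <- as.character(determination_from_counts(ns, nf))
    d_sat <- as.character(determination_from_counts(ns + 1, nf))
    d_fail <- as.character(determination_from_counts(ns, nf + 1))
    if (d0 == "mda") expect_equal(d_sat, "mda")
    if (d0 == "no_mda") expect_equal(d_fail, "no_mda")
  }
})

test_that("determinability tabulation counts every visit exactly once", {
  expect_error(tabulate_determinability(data.frame()), "no visits")
  tab <- tabulate_determinability(as.data.frame(visit_row()))
  expect_equal(sum(tab), 1)
  expect_equal(tab["7", "7", "mda"], 1)
  tab <- tabulate_determinability(
    as.data.frame(lapply(forced_visit("indeterminate"), identity)))
  expect_equal(tab["0", "0", "indeterminate"], 1)

  coh <- generate_cohort(cohort_design(n_patients = 200), seed = 31)
  tab <- tabulate_determinability(coh$visits)
  expect_equal(sum(tab), nrow(coh$visits))
  expect_true(all(tab >= 0))
  # direct count oracle for one cell
  d <- determine_mda(coh$visits)
  expect_equal(unname(tab["7", "7", "mda"]),
               sum(d$n_observed == 7 & d$n_satisfied == 7))
  # cells with an MDA determination require >= 5 satisfied; no-MDA cells
  # require >= 3 observed-and-failed
  mda_cells <- which(tab[, , "mda"] > 0, arr.ind = TRUE)
  expect_true(all(mda_cells[, 2] - 1 >= 5))
  no_cells <- which(tab[, , "no_mda"] > 0, arr.ind = TRUE)
  n_failed <- (no_cells[, 1] - 1) - (no_cells[, 2] - 1)
  expect_true(all(n_failed >= 3))
})

test_that("a configurable m-of-n rule is honoured", {
  cfg <- mda_criteria(m_required = 6)
  v <- visit_row(HAQ = NA, PTPSA = NA)  # 5 satisfied
  expect_equal(as.character(determine_mda(as.data.frame(v),
                                          cfg)$determination),
               "indeterminate")
  expect_error(mda_criteria(m_required = 8), "between 1 and")
})
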