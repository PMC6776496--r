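# shared fixtures: all data built in code, no files

# a visit row with every criterion satisfied unless overridden
visit_row <- function(...) {
  base <- list(TJC = 0, SJC = 0, PASI = 0.4, BSA = 1, PTPPAINV = 1,
               PTPSA = 1, HAQ = 0.25, ENTH_TOT = 0)
  utils::modifyList(base, list(...))
}

# outcome values that force a visit's determination: "mda" satisfies all
# seven criteria, "no_mda" fails them all, "indeterminate" leaves all
# unobserved
forced_visit <- function(kind) {
  switch(kind,
    mda = visit_row(),
    no_mda = visit_row(TJC = 8, SJC = 5, PASI = 6, BSA = 20,
                       PTPPAINV = 6, PTPSA = 7, HAQ = 2, ENTH_TOT = 4),
    indeterminate = lapply(visit_row(), function(x) NA_real_))
}

# one-patient series with forced determinations at given times
forced_series <- function(times, kinds, id = "p1") {
  rows <- lapply(kinds, function(k) as.data.frame(forced_visit(k)))
  d <- do.call(rbind, rows)
  cbind(data.frame(patient_id = id, time_years = times), d)
}

# default emission machinery used across likelihood tests
test_params <- function(rate1 = 1 / 2.3, rate2 = 1 / 4.5,
                        f = c(0.45, 0.55)) {
  mda_parameters(intensity_model(rate1, rate2), f,
                 default_emission_params())
}

# closed-form 2-state transition probability, written independently of
# the package's implementation (the test-side oracle)
oracle_p <- function(l1, l2, t) {
  s <- l1 + l2
  e <- exp(-s * t)
  matrix(c(l2 / s + l1 / s * e, l2 / s * (1 - e),
           l1 / s * (1 - e), l1 / s + l2 / s * e), 2, 2)
}

# oracle for expected time in MDA over [0, T] from a No-MDA start
oracle_occ_mda <- function(l1, l2, T) {
  s <- l1 + l2
  (l1 / s) * (T - (1 - exp(-s * T)) / s)
}
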