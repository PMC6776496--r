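#' Outcome variables defining the MDA composite
#'
#' The eight clinical variables contributing to the seven Minimal Disease
#' Activity criteria: tender joint count (TJC), swollen joint count (SJC),
#' Psoriasis Area and Severity Index (PASI), body surface area affected by
#' psoriasis (BSA, percent), patient pain VAS (PTPPAINV, cm), patient global
#' disease activity VAS (PTPSA, cm), Health Assessment Questionnaire (HAQ)
#' and inflamed entheseal points (ENTH_TOT).
#'
#' @export
mda_variables <- c("TJC", "SJC", "PASI", "BSA", "PTPPAINV", "PTPSA",
                   "HAQ", "ENTH_TOT")

# admissible value ranges per variable (used for validation)
.mda_domains <- list(
  TJC = c(0, 68), SJC = c(0, 66), PASI = c(0, 72), BSA = c(0, 100),
  PTPPAINV = c(0, 10), PTPSA = c(0, 10), HAQ = c(0, 3),
  ENTH_TOT = c(0, Inf)
)

#' Configuration of the MDA composite criteria
#'
#' Builds the 7-criterion Minimal Disease Activity definition: a patient is
#' in MDA when at least \code{m_required} of the criteria are satisfied.
#' The default thresholds are TJC <= 1, SJC <= 1, (PASI <= 1 or BSA <= 3),
#' pain VAS <= 1.5, patient global VAS <= 2, HAQ <= 0.5, entheseal
#' count <= 1.  All thresholds are inclusive.
#'
#' @param m_required number of satisfied criteria defining MDA (default 5).
#' @param thresholds optional named numeric vector overriding any of the
#'   default cutpoints (names among \code{TJC, SJC, PASI, BSA, PTPPAINV,
#'   PTPSA, HAQ, ENTH_TOT}).
#' @return an object of class \code{mda_criteria}.
#' @export
mda_criteria <- function(m_required = 5, thresholds = NULL) {
  cut <- c(TJC = 1, SJC = 1, PASI = 1, BSA = 3, PTPPAINV = 1.5,
           PTPSA = 2, HAQ = 0.5, ENTH_TOT = 1)
  if (!is.null(thresholds)) {
    bad <- setdiff(names(thresholds), names(cut))
    if (length(bad))
      stop("unknown variable in thresholds: ", paste(bad, collapse = ", "))
    cut[names(thresholds)] <- thresholds
  }
  criteria <- list(
    list(name = "tender_joints",  vars = "TJC",      thr = cut[["TJC"]]),
    list(name = "swollen_joints", vars = "SJC",      thr = cut[["SJC"]]),
    list(name = "skin",           vars = c("PASI", "BSA"),
         thr = c(cut[["PASI"]], cut[["BSA"]])),
    list(name = "pain",           vars = "PTPPAINV", thr = cut[["PTPPAINV"]]),
    list(name = "patient_global", vars = "PTPSA",    thr = cut[["PTPSA"]]),
    list(name = "haq",            vars = "HAQ",      thr = cut[["HAQ"]]),
    list(name = "enthesitis",     vars = "ENTH_TOT", thr = cut[["ENTH_TOT"]])
  )
  n_total <- length(criteria)
  if (m_required < 1 || m_required > n_total)
    stop("m_required must be between 1 and ", n_total)
  structure(list(criteria = criteria, m_required = m_required,
                 n_total = n_total, thresholds = cut),
            class = "mda_criteria")
}

.validate_outcomes <- function(y) {
  for (v in intersect(names(y), mda_variables)) {
    val <- y[[v]]
    dom <- .mda_domains[[v]]
    bad <- !is.na(val) & (val < dom[1] | val > dom[2])
    if (any(bad))
      stop("value of ", v, " outside its domain [", dom[1], ", ", dom[2],
           "]: ", paste(utils::head(val[bad], 3), collapse = ", "))
  }
  invisible(TRUE)
}

# Per-criterion status for every row of a visit data frame.
# Returns an integer matrix (rows = visits, cols = 7 criteria):
# 1 = satisfied, 0 = failed, NA = not decidable from observed components.
# The OR criterion (skin) is failed only when BOTH PASI and BSA are observed
# and both exceed their cutpoints: if only one is observed and exceeds its
# cutpoint, the unobserved one could still satisfy the criterion, so its
# status is unknown.
criterion_status <- function(data, config = mda_criteria()) {
  stopifnot(inherits(config, "mda_criteria"))
  data <- as.data.frame(data)
  miss <- setdiff(unique(unlist(lapply(config$criteria, `[[`, "vars"))),
                  names(data))
  if (length(miss))
    stop("outcome column(s) missing from data: ", paste(miss, collapse = ", "))
  .validate_outcomes(data)
  n <- nrow(data)
  out <- matrix(NA_integer_, n, config$n_total,
                dimnames = list(NULL, vapply(config$criteria, `[[`, "",
                                             "name")))
  for (k in seq_along(config$criteria)) {
    cr <- config$criteria[[k]]
    if (length(cr$vars) == 1L) {
      y <- data[[cr$vars]]
      out[, k] <- ifelse(is.na(y), NA_integer_,
                         as.integer(y <= cr$thr))
    } else {
      sat <- mapply(function(v, thr) {
        y <- data[[v]]
        ifelse(is.na(y), NA, y <= thr)
      }, cr$vars, cr$thr, SIMPLIFY = FALSE)
      sat <- do.call(cbind, sat)
      any_sat <- rowSums(sat, na.rm = TRUE) > 0
      all_obs_fail <- rowSums(!sat, na.rm = TRUE) == length(cr$vars)
      out[, k] <- ifelse(any_sat, 1L,
                         ifelse(all_obs_fail, 0L, NA_integer_))
    }
  }
  out
}

#' Classify visits as MDA / No-MDA / indeterminate
#'
#' Applies the composite rule to partially observed criteria: a visit is MDA
#' when at least \code{m_required} criteria are observed and satisfied,
#' No-MDA when at least \code{n_total - m_required + 1} criteria are observed
#' and failed (so that \code{m_required} satisfied criteria are no longer
#' attainable), and indeterminate otherwise.  A criterion counts as observed
#' when its satisfied/failed status is decidable from the recorded
#' components.
#'
#' @param data a data frame of visits with the outcome columns named as in
#'   \code{\link{mda_variables}}; missing values indicate unobserved
#'   components.
#' @param config an \code{\link{mda_criteria}} object.
#' @return a data frame with one row per visit: \code{n_observed},
#'   \code{n_satisfied}, \code{n_failed} and \code{determination} (factor
#'   with levels \code{no_mda}, \code{mda}, \code{indeterminate}).
#' @export
determine_mda <- function(data, config = mda_criteria()) {
  st <- criterion_status(data, config)
  n_sat <- rowSums(st == 1L, na.rm = TRUE)
  n_fail <- rowSums(st == 0L, na.rm = TRUE)
  det <- determination_from_counts(n_sat, n_fail, config)
  data.frame(n_observed = n_sat + n_fail, n_satisfied = n_sat,
             n_failed = n_fail, determination = det)
}

#' Determination from satisfied/failed counts
#'
#' The decision rule of the composite, isolated from criterion evaluation:
#' \code{mda} iff \code{n_satisfied >= m_required}; \code{no_mda} iff
#' \code{n_failed >= n_total - m_required + 1}; otherwise
#' \code{indeterminate}.  The two conditions are mutually exclusive because
#' \code{n_satisfied + n_failed <= n_total}.
#'
#' @param n_satisfied,n_failed integer vectors of counts.
#' @param config an \code{\link{mda_criteria}} object.
#' @return factor with levels \code{no_mda}, \code{mda},
#'   \code{indeterminate}.
#' @export
determination_from_counts <- function(n_satisfied, n_failed,
                                      config = mda_criteria()) {
  if (any(n_satisfied + n_failed > config$n_total))
    stop("n_satisfied + n_failed exceeds the number of criteria")
  factor(ifelse(n_satisfied >= config$m_required, "mda",
                ifelse(n_failed >= config$n_total - config$m_required + 1,
                       "no_mda", "indeterminate")),
         levels = c("no_mda", "mda", "indeterminate"))
}

#' Evaluate the MDA criteria at a single visit
#'
#' @param visit a one-row data frame or named list/vector of outcome values
#'   (missing components \code{NA} or absent).
#' @param config an \code{\link{mda_criteria}} object.
#' @return a list of class \code{mda_status}: per-criterion
#'   \code{status} (\code{satisfied}/\code{failed}/\code{unobserved}),
#'   counts, and the \code{determination}.
#' @export
evaluate_criteria <- function(visit, config = mda_criteria()) {
  if (!is.data.frame(visit)) visit <- as.data.frame(as.list(visit))
  for (v in setdiff(mda_variables, names(visit))) visit[[v]] <- NA_real_
  st <- criterion_status(visit, config)[1, ]
  status <- factor(ifelse(is.na(st), "unobserved",
                          ifelse(st == 1L, "satisfied", "failed")),
                   levels = c("satisfied", "failed", "unobserved"))
  names(status) <- names(st)
  n_sat <- sum(st == 1L, na.rm = TRUE)
  n_fail <- sum(st == 0L, na.rm = TRUE)
  structure(list(status = status, n_observed = n_sat + n_fail,
                 n_satisfied = n_sat, n_failed = n_fail,
                 determination = as.character(
                   determination_from_counts(n_sat, n_fail, config))),
            class = "mda_status")
}

#' @exportS3Method base::print
print.mda_status <- function(x, ...) {
  cat("MDA criteria evaluation\n")
  for (nm in names(x$status))
    cat(sprintf("  %-15s %s\n", nm, as.character(x$status[nm])))
  cat(sprintf("observed %d, satisfied %d, failed %d -> %s\n",
              x$n_observed, x$n_satisfied, x$n_failed, x$determination))
  invisible(x)
}

#' Cross-tabulate determinability of visits
#'
#' Counts visits by number of criteria observed (decidable), number
#' satisfied, and resulting determination, in the layout used to describe
#' how often the composite can be decided under scheduled missingness.
#'
#' @param data a data frame of visits (one row per visit).
#' @param config an \code{\link{mda_criteria}} object.
#' @return a 3-way table: criteria observed (0..7) x criteria satisfied
#'   (0..7) x determination.
#' @export
tabulate_determinability <- function(data, config = mda_criteria()) {
  if (nrow(as.data.frame(data)) == 0L) stop("no visits supplied")
  d <- determine_mda(data, config)
  table(observed = factor(d$n_observed, levels = 0:config$n_total),
        satisfied = factor(d$n_satisfied, levels = 0:config$n_total),
        determination = d$determination)
}
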