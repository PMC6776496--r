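#' Design of a synthetic clinic cohort
#'
#' Describes the observation structure the generator emulates: visits
#' every 6-12 months, follow-up with a median of about 3 years capped at
#' 10, the two patient-completed scores (HAQ and the global VAS)
#' administered on an every-other-visit schedule (about 50\% missing),
#' the remaining outcome variables missing independently at 10-20\% of
#' visits, and latent two-state dynamics with state-dependent count
#' emissions.  Default true parameters are synthetic values chosen to
#' give clinic-like sojourn times and a realistic split of visits into
#' MDA / No-MDA / indeterminate; they are not estimates from any real
#' cohort.
#'
#' @param n_patients number of patients (default 856).
#' @param gap_range min/max years between successive visits (uniform).
#' @param followup_median,followup_max median (exponential) and cap of
#'   per-patient follow-up in years.
#' @param alternating_vars variables on the every-other-visit schedule.
#' @param miss_rate independent missingness probability for the other
#'   outcome variables.
#' @param model true \code{\link{intensity_model}} (may include covariate
#'   effects named after generated covariate columns).
#' @param f true initial-state distribution (No-MDA, MDA).
#' @param spec,emissions true emission specification and parameters.
#' @param config criteria configuration used when reporting
#'   determinability.
#' @return object of class \code{cohort_design}.
#' @export
cohort_design <- function(n_patients = 856, gap_range = c(0.5, 1.0),
                          followup_median = 3, followup_max = 10,
                          alternating_vars = c("HAQ", "PTPSA"),
                          miss_rate = 0.15,
                          model = intensity_model(1 / 2.3, 1 / 4.5),
                          f = c(0.45, 0.55),
                          spec = emission_spec(),
                          emissions = default_emission_params(spec),
                          config = mda_criteria()) {
  if (any(gap_range <= 0) || gap_range[1] > gap_range[2])
    stop("gap_range must be positive and increasing")
  if (miss_rate < 0 || miss_rate > 1) stop("miss_rate must be in [0, 1]")
  structure(list(n_patients = as.integer(n_patients),
                 gap_range = gap_range, followup_median = followup_median,
                 followup_max = followup_max,
                 alternating_vars = alternating_vars,
                 miss_rate = miss_rate, model = model, f = f,
                 spec = spec, emissions = emissions, config = config),
            class = "cohort_design")
}

#' The shipped default clinic-like design
#'
#' A \code{\link{cohort_design}} whose visit counts, follow-up and
#' missingness rates approximate the observation structure of a large
#' psoriatic arthritis clinic cohort (856 patients, median about 6 visits,
#' follow-up median 3 years, maximum 10).
#'
#' @return a \code{cohort_design}.
#' @export
default_clinic_design <- function() cohort_design()

# binary and continuous baseline covariates with clinic-like prevalences
.generate_covariates <- function(n) {
  data.frame(
    female = stats::rbinom(n, 1, 0.46),
    polyarthritis = stats::rbinom(n, 1, 0.50),
    axial = stats::rbinom(n, 1, 0.30),
    elevated_esr = stats::rbinom(n, 1, 0.35),
    prior_damage = stats::rbinom(n, 1, 0.40),
    age = round(stats::rnorm(n, 44, 12), 1),
    disease_duration = round(stats::rexp(n, 1 / 7), 1)
  )
}

#' Generate a synthetic cohort with known truth
#'
#' Simulates, per patient: baseline covariates; a follow-up length and
#' visit schedule; a latent continuous-time two-state path at the
#' patient's covariate-specific intensities; outcome vectors drawn from
#' the state-specific emission distributions at each visit; and
#' missingness applied afterwards (the mask is generated before any
#' outcome value is examined, so missingness is at random by
#' construction: the alternating variables follow a deterministic
#' every-other-visit schedule with a random phase, the rest are masked
#' independently).
#'
#' @param design a \code{\link{cohort_design}}.
#' @param seed optional integer seed; a fixed seed reproduces the cohort
#'   exactly.
#' @return object of class \code{mda_cohort}: \code{visits} (long-format
#'   data frame with \code{patient_id}, \code{time_years}, the eight
#'   outcome columns and the covariates) and \code{truth} (latent state
#'   1/2 at each visit, the true parameters and the design).
#' @export
generate_cohort <- function(design = cohort_design(), seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_patients
  cov <- .generate_covariates(n)
  followup <- pmin(stats::rexp(n, log(2) / design$followup_median),
                   design$followup_max)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    t <- 0
    repeat {
      gap <- stats::runif(1, design$gap_range[1], design$gap_range[2])
      if (t[length(t)] + gap > followup[i]) break
      t <- c(t, t[length(t)] + gap)
    }
    Q <- intensity_at(design$model,
                      as.numeric(cov[i, design$model$covariates]))
    l <- c(Q[1, 2], Q[2, 1])
    # latent alternating-sojourn path read off at the visit times
    state <- integer(length(t))
    cur <- 1L + stats::rbinom(1, 1, design$f[2])
    edge <- stats::rexp(1, l[cur])
    for (j in seq_along(t)) {
      while (edge <= t[j]) {
        cur <- 3L - cur
        edge <- edge + stats::rexp(1, l[cur])
      }
      state[j] <- cur
    }
    rows[[i]] <- data.frame(patient_id = sprintf("P%04d", i),
                            time_years = t, visit = seq_along(t),
                            state = state)
  }
  d <- do.call(rbind, rows)
  # missingness masks drawn before outcomes are generated (MAR by design)
  vars <- names(design$spec$vars)
  phase <- stats::rbinom(n, 1, 0.5)[match(d$patient_id,
                                          sprintf("P%04d", seq_len(n)))]
  mask <- matrix(FALSE, nrow(d), length(vars),
                 dimnames = list(NULL, vars))
  for (v in vars) {
    mask[, v] <- if (v %in% design$alternating_vars)
      (d$visit + phase) %% 2 == 1
    else stats::runif(nrow(d)) < design$miss_rate
  }
  out <- matrix(NA_real_, nrow(d), length(vars),
                dimnames = list(NULL, vars))
  for (r in 1:2) {
    idx <- which(d$state == r)
    if (!length(idx)) next
    sim <- simulate_outcomes(r, design$spec, design$emissions,
                             n = length(idx))
    out[idx, ] <- as.matrix(sim[vars])
  }
  out[mask] <- NA_real_
  visits <- data.frame(patient_id = d$patient_id,
                       time_years = d$time_years, out,
                       cov[match(d$patient_id,
                                 sprintf("P%04d", seq_len(n))), ],
                       row.names = NULL)
  structure(list(visits = visits,
                 truth = list(state = d$state, design = design,
                              model = design$model, f = design$f,
                              emissions = design$emissions)),
            class = "mda_cohort")
}

#' @exportS3Method base::print
print.mda_cohort <- function(x, ...) {
  nv <- nrow(x$visits)
  cat(sprintf("Synthetic cohort: %d patients, %d visits\n",
              length(unique(x$visits$patient_id)), nv))
  det <- determine_mda(x$visits, x$truth$design$config)
  print(round(table(det$determination) / nv, 3))
  invisible(x)
}
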