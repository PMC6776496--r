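#' Settings for the state-history simulation
#'
#' @param horizon follow-up window in years (default 10).
#' @param sustain_threshold minimum full sojourn length, in years, for an
#'   MDA period to count as sustained (default 1).
#' @param n_patients number of simulated histories (default 100000).
#' @param n_bootstrap number of parameter draws for bootstrap intervals
#'   (default 1000).
#' @param start_state state at time zero (default \code{"no_mda"}).
#' @param seed optional integer seed; when set, simulations are
#'   reproducible and groups compared under common random numbers.
#' @return object of class \code{sim_settings}.
#' @export
sim_settings <- function(horizon = 10, sustain_threshold = 1,
                         n_patients = 100000, n_bootstrap = 1000,
                         start_state = c("no_mda", "mda"), seed = NULL) {
  start_state <- match.arg(start_state)
  if (horizon <= 0) stop("horizon must be positive")
  if (sustain_threshold <= 0 || sustain_threshold >= horizon)
    stop("sustain_threshold must lie strictly between 0 and the horizon")
  if (n_patients < 1 || n_bootstrap < 0) stop("counts must be positive")
  structure(list(horizon = horizon, sustain_threshold = sustain_threshold,
                 n_patients = as.integer(n_patients),
                 n_bootstrap = as.integer(n_bootstrap),
                 start_state = start_state, seed = seed),
            class = "sim_settings")
}

#' Simulate alternating-sojourn state histories
#'
#' Draws, for each simulated patient, a series of periods spent
#' alternately in No-MDA and MDA, each with an exponentially distributed
#' duration at the corresponding exit rate, starting from
#' \code{start_state}, and keeps every sojourn that starts before the
#' horizon.  Sojourn durations are always drawn in full, so a sojourn in
#' progress at the horizon carries its complete length (the overrun rule):
#' it can be classified as sustained or not even though time totals are
#' later truncated at the horizon.
#'
#' @param Q 2x2 intensity matrix (or numeric length-2 vector of rates
#'   No-to-MDA, MDA-to-No).
#' @param settings a \code{\link{sim_settings}}.
#' @return object of class \code{sojourn_histories}: data frame with
#'   columns \code{id}, \code{state} (1 No-MDA, 2 MDA), \code{start},
#'   \code{duration}, with the settings and rates attached.
#' @export
simulate_histories <- function(Q, settings = sim_settings()) {
  r <- if (is.matrix(Q)) .check_Q2(Q) else
    c(l1 = unname(Q[1]), l2 = unname(Q[2]))
  if (any(r < 0)) stop("rates must be non-negative")
  if (!is.null(settings$seed)) set.seed(settings$seed)
  n <- settings$n_patients
  horizon <- settings$horizon
  exit_rate <- c(r[["l1"]], r[["l2"]])
  cur_state <- rep(if (settings$start_state == "no_mda") 1L else 2L, n)
  cur_start <- numeric(n)
  active <- rep(TRUE, n)
  acc <- list()
  i <- 0L
  while (any(active)) {
    k <- which(active)
    rate_k <- exit_rate[cur_state[k]]
    dur <- rep(Inf, length(k))
    dur[rate_k > 0] <- stats::rexp(sum(rate_k > 0), rate_k[rate_k > 0])
    i <- i + 1L
    acc[[i]] <- data.frame(id = k, state = cur_state[k],
                           start = cur_start[k], duration = dur)
    cur_start[k] <- cur_start[k] + dur
    cur_state[k] <- 3L - cur_state[k]
    active[k] <- cur_start[k] < horizon
  }
  h <- do.call(rbind, acc)
  h <- h[order(h$id, h$start), ]
  rownames(h) <- NULL
  structure(h, class = c("sojourn_histories", "data.frame"),
            settings = settings, rates = r, n_patients = n)
}

#' Simulate a single state history
#'
#' @inheritParams simulate_histories
#' @return the sojourn records of one simulated patient.
#' @export
simulate_history <- function(Q, settings = sim_settings(n_patients = 1)) {
  settings$n_patients <- 1L
  simulate_histories(Q, settings)
}

#' Occupancy summaries of simulated histories
#'
#' Computes the sustained-MDA prognosis measures over the horizon:
#' \itemize{
#' \item mean sojourn times per state (analytic, \eqn{1/\lambda});
#' \item expected time in MDA, split as time in short vs long spells
#'   (a spell is long when its full duration, including any overrun past
#'   the horizon, is at least the sustain threshold) and as time in the
#'   first threshold-year vs later years of each MDA sojourn ("time in
#'   sustained MDA" = the later-years total);
#' \item expected numbers of No-MDA, MDA, short-MDA and long-MDA spells
#'   starting before the horizon (the initial No-MDA spell included);
#' \item probabilities of at least one MDA spell and of at least one long
#'   MDA spell.
#' }
#' All time totals are truncated at the horizon.
#'
#' @param histories a \code{sojourn_histories} object.
#' @param settings optional override of the settings stored with the
#'   histories.
#' @return object of class \code{sustained_summary}: named estimate
#'   vector plus the settings and rates used.
#' @export
summarize_histories <- function(histories, settings = NULL) {
  stopifnot(inherits(histories, "sojourn_histories"))
  if (is.null(settings)) settings <- attr(histories, "settings")
  n <- attr(histories, "n_patients")
  r <- attr(histories, "rates")
  horizon <- settings$horizon
  thr <- settings$sustain_threshold
  h <- as.data.frame(histories)
  mda <- h[h$state == 2L, ]
  within <- pmin(mda$start + mda$duration, horizon) - mda$start
  long <- mda$duration >= thr
  first_part <- pmin(within, thr)
  est <- c(
    sojourn_no_mda = unname(1 / r["l1"]),
    sojourn_mda = unname(1 / r["l2"]),
    time_mda = sum(within) / n,
    time_sustained_mda = sum(within - first_part) / n,
    time_short_mda = sum(within[!long]) / n,
    time_long_mda = sum(within[long]) / n,
    time_first_year_mda = sum(first_part) / n,
    time_later_years_mda = sum(within - first_part) / n,
    spells_no_mda = sum(h$state == 1L) / n,
    spells_mda = nrow(mda) / n,
    spells_short_mda = sum(!long) / n,
    spells_long_mda = sum(long) / n,
    prob_visit_mda = length(unique(mda$id)) / n,
    prob_visit_long_mda = length(unique(mda$id[long])) / n
  )
  structure(list(estimates = est, settings = settings, rates = r,
                 n_patients = n),
            class = "sustained_summary")
}

#' One-call sustained-MDA summary for a rate pair
#'
#' @inheritParams simulate_histories
#' @return a \code{sustained_summary}.
#' @export
sustained_summary <- function(Q, settings = sim_settings()) {
  summarize_histories(simulate_histories(Q, settings))
}

#' @exportS3Method base::print
print.sustained_summary <- function(x, ...) {
  cat(sprintf("MDA prognosis over %g years (start %s, %d simulated)\n",
              x$settings$horizon, x$settings$start_state, x$n_patients))
  tab <- data.frame(estimate = round(x$estimates, 3))
  if (!is.null(x$intervals)) {
    tab$lower <- round(x$intervals[, 1], 3)
    tab$upper <- round(x$intervals[, 2], 3)
  }
  print(tab)
  invisible(x)
}

# closed-form subset of the summary measures (those with analytic
# expressions): sojourns, time in MDA, spells, long/short spell counts by
# memorylessness of the exponential sojourn, and P(visit MDA).
.analytic_summary <- function(l1, l2, settings) {
  Q <- intensity_matrix(l1, l2)
  occ <- expected_occupancy_window(Q, settings$start_state,
                                   settings$horizon)
  ent <- expected_entries_window(Q, settings$start_state,
                                 settings$horizon)
  thr <- settings$sustain_threshold
  p_long <- exp(-thr * l2)
  c(sojourn_no_mda = 1 / l1, sojourn_mda = 1 / l2,
    time_mda = unname(occ["mda"]), spells_mda = unname(ent["mda"]),
    spells_long_mda = unname(ent["mda"] * p_long),
    spells_short_mda = unname(ent["mda"] * (1 - p_long)),
    prob_visit_mda = if (settings$start_state == "no_mda")
      1 - exp(-settings$horizon * l1) else 1)
}

#' Sustained-MDA summaries for covariate-defined groups
#'
#' Evaluates the intensity model at each covariate pattern and simulates
#' the occupancy summaries per group.  Groups share the random-number
#' stream (the settings seed is re-applied per group), so that relative
#' measures between them are estimated with common random numbers.
#'
#' @param object an \code{\link{intensity_model}} or an \code{mda_fit}.
#' @param patterns data frame of covariate values, one row per group
#'   (columns matching the model's covariates).
#' @param settings a \code{\link{sim_settings}}.
#' @return named list of \code{sustained_summary} objects (row names of
#'   \code{patterns} are used when present).
#' @export
summarize_by_group <- function(object, patterns,
                               settings = sim_settings()) {
  model <- if (inherits(object, "mda_fit")) object$estimates$model
           else object
  stopifnot(inherits(model, "intensity_model"))
  patterns <- as.data.frame(patterns)
  miss <- setdiff(model$covariates, names(patterns))
  if (length(miss))
    stop("pattern lacks covariate(s): ", paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(patterns)), function(i) {
    x <- as.numeric(patterns[i, model$covariates, drop = TRUE])
    sustained_summary(intensity_at(model, x), settings)
  })
  names(out) <- if (!is.null(rownames(patterns)) &&
                    !identical(rownames(patterns),
                               as.character(seq_len(nrow(patterns)))))
    rownames(patterns) else paste0("group", seq_len(nrow(patterns)))
  out
}

#' Relative prognosis between two groups
#'
#' Ratios of time and spell-count measures, and odds ratios for the two
#' visit probabilities (ratios of \eqn{p/(1-p)}), for group A relative to
#' group B.  When both summaries carry bootstrap replicate draws from
#' \code{\link{bootstrap_intervals}} with matching replicate counts, the
#' replicates are paired to give percentile intervals for each relative
#' measure.
#'
#' @param summary_a,summary_b \code{sustained_summary} objects computed
#'   under the same settings.
#' @return data frame of relative measures (with intervals when
#'   available).
#' @export
relative_measures <- function(summary_a, summary_b) {
  stopifnot(inherits(summary_a, "sustained_summary"),
            inherits(summary_b, "sustained_summary"))
  if (!identical(summary_a$settings$horizon, summary_b$settings$horizon))
    stop("summaries use different horizons")
  ratio_measures <- c("sojourn_mda", "time_mda", "time_sustained_mda",
                      "spells_mda", "spells_long_mda")
  or_measures <- c("prob_visit_mda", "prob_visit_long_mda")
  rel_one <- function(a, b) {
    odds <- function(p) ifelse(p >= 1 | p <= 0, NA_real_, p / (1 - p))
    c(a[ratio_measures] / b[ratio_measures],
      stats::setNames(odds(a[or_measures]) / odds(b[or_measures]),
                      paste0("odds_", or_measures)))
  }
  est <- rel_one(summary_a$estimates, summary_b$estimates)
  out <- data.frame(measure = names(est), estimate = unname(est))
  ra <- summary_a$replicates; rb <- summary_b$replicates
  if (!is.null(ra) && !is.null(rb) && nrow(ra) == nrow(rb)) {
    reps <- t(vapply(seq_len(nrow(ra)),
                     function(i) rel_one(ra[i, ], rb[i, ]),
                     numeric(length(est))))
    qs <- apply(reps, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
    out$lower <- qs[1, ]; out$upper <- qs[2, ]
  }
  out
}

#' Parametric-bootstrap intervals for the occupancy summaries
#'
#' Draws parameter vectors from the asymptotic multivariate normal of the
#' fitted working-scale parameters, recomputes the summaries for each draw
#' (by simulation, or by the closed forms for the analytic subset of
#' measures), and reports percentile 95\% intervals around the point
#' summary.
#'
#' @param fit an \code{mda_fit} with a covariance matrix.
#' @param settings a \code{\link{sim_settings}}; \code{n_bootstrap}
#'   controls the number of parameter draws and \code{n_patients} the
#'   (possibly reduced) simulation size per draw.
#' @param x covariate vector at which to evaluate the intensities
#'   (default: baseline).
#' @param method \code{"simulation"} for all 14 measures or
#'   \code{"closed_form"} for the analytic subset (much faster).
#' @return a \code{sustained_summary} with \code{intervals} (2.5\% and
#'   97.5\% percentiles) and the replicate draws in \code{replicates}.
#' @export
bootstrap_intervals <- function(fit, settings = sim_settings(),
                                x = numeric(0),
                                method = c("simulation", "closed_form")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "mda_fit"))
  if (is.null(fit$vcov))
    stop("fit has no covariance matrix; bootstrap intervals unavailable")
  if (!is.null(settings$seed)) set.seed(settings$seed)
  R <- settings$n_bootstrap
  draws <- MASS::mvrnorm(R, fit$theta, fit$vcov)
  if (R == 1) draws <- matrix(draws, 1)
  rates_at <- function(theta) {
    l1 <- unname(exp(theta[1])); l2 <- unname(exp(theta[2]))
    if (length(fit$covariates)) {
      b <- theta[paste0("beta.", fit$covariates)]
      g <- theta[paste0("gamma.", fit$covariates)]
      l1 <- l1 * exp(sum(x * b)); l2 <- l2 * exp(sum(x * g))
    }
    c(l1, l2)
  }
  one <- function(theta, seed) {
    r <- rates_at(theta)
    if (method == "closed_form")
      .analytic_summary(r[1], r[2], settings)
    else {
      s2 <- settings; s2$seed <- seed
      summarize_histories(simulate_histories(r, s2))$estimates
    }
  }
  # per-draw seeds fixed up front so draws are independent of each other
  seeds <- if (is.null(settings$seed)) rep(list(NULL), R) else
    as.list(sample.int(.Machine$integer.max, R))
  point <- one(fit$theta, settings$seed)
  reps <- t(vapply(seq_len(R), function(i) one(draws[i, ], seeds[[i]]),
                   numeric(length(point))))
  colnames(reps) <- names(point)
  ints <- t(apply(reps, 2, stats::quantile, probs = c(0.025, 0.975)))
  colnames(ints) <- c("lower", "upper")
  structure(list(estimates = point, intervals = ints, replicates = reps,
                 settings = settings,
                 rates = stats::setNames(rates_at(fit$theta),
                                         c("l1", "l2")),
                 n_patients = settings$n_patients),
            class = "sustained_summary")
}
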