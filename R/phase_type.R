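#' Two-phase semi-Markov (phase-type) model
#'
#' Each macro state (No-MDA, MDA) is split into two latent phases, giving
#' a four-state hidden Markov chain over phases \code{no_a, no_b, mda_a,
#' mda_b}.  Within a state an individual can progress from phase a to
#' phase b; from either phase they can exit to phase a of the other state.
#' The sojourn in each macro state is then a phase-type (rather than
#' exponential) distribution, letting the exit intensity change with time
#' already spent in the state; six free rates replace the two-state
#' model's two.
#'
#' @param nu_no,nu_mda within-state phase-progression rates (a to b).
#' @param exit_no_a,exit_no_b exit rates from the No-MDA phases to
#'   \code{mda_a}.
#' @param exit_mda_a,exit_mda_b exit rates from the MDA phases to
#'   \code{no_a}.
#' @return object of class \code{phase_type_model} holding the 4x4
#'   intensity matrix (disallowed transitions exactly zero).
#' @export
phase_type_model <- function(nu_no, exit_no_a, exit_no_b,
                             nu_mda, exit_mda_a, exit_mda_b) {
  rates <- c(nu_no = nu_no, exit_no_a = exit_no_a, exit_no_b = exit_no_b,
             nu_mda = nu_mda, exit_mda_a = exit_mda_a,
             exit_mda_b = exit_mda_b)
  if (any(rates < 0)) stop("phase-type rates must be non-negative")
  ph <- c("no_a", "no_b", "mda_a", "mda_b")
  Q <- matrix(0, 4, 4, dimnames = list(ph, ph))
  Q["no_a", "no_b"] <- nu_no
  Q["no_a", "mda_a"] <- exit_no_a
  Q["no_b", "mda_a"] <- exit_no_b
  Q["mda_a", "mda_b"] <- nu_mda
  Q["mda_a", "no_a"] <- exit_mda_a
  Q["mda_b", "no_a"] <- exit_mda_b
  diag(Q) <- -rowSums(Q)
  structure(list(Q = Q, rates = rates, macro = c(1L, 1L, 2L, 2L)),
            class = "phase_type_model")
}

#' Log-likelihood of fully observed macro-state sequences under the
#' phase-type model
#'
#' Hidden-Markov forward recursion over the four phases, where the
#' "emission" is the deterministic phase-to-macro-state map: an observed
#' macro state admits both of its phases.  Conditioning follows the
#' complete-case convention: the recursion starts at the first visit in
#' phase a of the observed state (states are entered through phase a), so
#' with the phase-progression rates at zero the likelihood reduces
#' exactly to the two-state complete-case panel likelihood.
#'
#' @param times strictly increasing visit times (years).
#' @param states observed macro states at the visits (1 = No-MDA,
#'   2 = MDA, or \code{"no_mda"}/\code{"mda"}); no missing values allowed.
#' @param model a \code{\link{phase_type_model}}.
#' @return scalar log-likelihood (zero for a single-visit series).
#' @export
phase_loglik <- function(times, states, model) {
  stopifnot(inherits(model, "phase_type_model"))
  if (is.character(states))
    states <- match(states, c("no_mda", "mda"))
  if (anyNA(states) || !all(states %in% 1:2))
    stop("all macro states must be observed (no indeterminate visits)")
  if (length(times) != length(states)) stop("times/states length mismatch")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  n <- length(times)
  if (n < 2) return(0)
  alpha <- numeric(4)
  alpha[if (states[1] == 1L) 1L else 3L] <- 1  # entry phase a
  dts <- diff(times)
  udts <- unique(dts)
  Pcache <- lapply(udts, function(d) {
    P <- as.matrix(Matrix::expm(Matrix::Matrix(model$Q * d)))
    if (any(!is.finite(P)) || any(P < -1e-8) ||
        any(abs(rowSums(P) - 1) > 1e-6))
      stop("matrix exponential unstable for the supplied rates")
    pmax(P, 0)
  })
  ll <- 0
  for (j in 2:n) {
    P <- Pcache[[match(dts[j - 1], udts)]]
    alpha <- drop(alpha %*% P)
    alpha[model$macro != states[j]] <- 0
    sc <- sum(alpha)
    if (!is.finite(sc) || sc <= 0)
      stop("zero forward mass at visit ", j)
    ll <- ll + log(sc)
    alpha <- alpha / sc
  }
  ll
}

# Cohort-level phase-type likelihood with a single eigendecomposition of
# Q per call: the forward step alpha P(dt) is evaluated for every active
# patient at once as Re((alpha V) e^{D dt} V^{-1}), so distinct interval
# lengths cost no extra matrix exponentials.  Falls back to the expm-based
# per-series evaluation when Q is close to defective, and refuses
# numerically unstable evaluations rather than let an optimiser exploit
# them.
.phase_cohort_loglik <- function(series, model) {
  eg <- eigen(model$Q)
  V <- eg$vectors
  Vi <- try(solve(V), silent = TRUE)
  ok <- !inherits(Vi, "try-error") &&
    max(abs(Re(V %*% (eg$values * Vi)) - model$Q)) < 1e-8
  if (!ok)
    return(sum(vapply(series, function(s)
      phase_loglik(s$time_years, s$state, model), 0)))
  m <- length(series)
  lens <- vapply(series, nrow, 0L)
  maxlen <- max(lens)
  S <- matrix(NA_integer_, m, maxlen)
  DT <- matrix(NA_real_, m, maxlen)
  for (i in seq_len(m)) {
    S[i, seq_len(lens[i])] <- series[[i]]$state
    DT[i, 2:lens[i]] <- diff(series[[i]]$time_years)
  }
  alpha <- matrix(0, m, 4)
  alpha[cbind(seq_len(m), ifelse(S[, 1] == 1L, 1L, 3L))] <- 1
  ll <- numeric(m)
  for (j in 2:maxlen) {
    act <- which(lens >= j)
    a <- alpha[act, , drop = FALSE] %*% V
    a <- a * exp(outer(DT[act, j], eg$values))
    a <- Re(a %*% Vi)
    if (any(!is.finite(a)) || any(a < -1e-8))
      stop("transition matrix evaluation unstable")
    a[a < 0] <- 0
    mda_obs <- S[act, j] == 2L
    a[mda_obs, 1:2] <- 0
    a[!mda_obs, 3:4] <- 0
    sc <- rowSums(a)
    if (any(!is.finite(sc) | sc <= 0 | sc > 1 + 1e-6))
      stop("zero or invalid forward mass in phase recursion")
    ll[act] <- ll[act] + log(sc)
    alpha[act, ] <- a / sc
  }
  sum(ll)
}

#' Phase-type sojourn density
#'
#' Density of the time to leave a macro state entered in phase a, with
#' phase-progression rate \code{nu} and exit rates \code{mu_a},
#' \code{mu_b}: a mixture of the direct exit from phase a and the
#' two-stage route through phase b.
#'
#' @param t non-negative times.
#' @param nu,mu_a,mu_b non-negative rates (\code{mu_a + nu > 0}).
#' @return density values.
#' @export
dphase_sojourn <- function(t, nu, mu_a, mu_b) {
  s1 <- nu + mu_a
  s2 <- mu_b
  pa <- exp(-s1 * t)
  pb <- if (abs(s1 - s2) < 1e-10) nu * t * exp(-s1 * t) else
    nu * (exp(-s2 * t) - exp(-s1 * t)) / (s1 - s2)
  mu_a * pa + mu_b * pb
}

#' Mean macro-state sojourns of a phase-type model
#'
#' Expected time from entry (phase a) to exit:
#' \eqn{1/(\nu+\mu_a) + \nu/((\nu+\mu_a)\,\mu_b)}.
#'
#' @param model a \code{\link{phase_type_model}}.
#' @return named vector of mean sojourn years per macro state.
#' @export
phase_sojourn_means <- function(model) {
  r <- model$rates
  m1 <- 1 / (r["nu_no"] + r["exit_no_a"]) +
    (r["nu_no"] / (r["nu_no"] + r["exit_no_a"])) / r["exit_no_b"]
  m2 <- 1 / (r["nu_mda"] + r["exit_mda_a"]) +
    (r["nu_mda"] / (r["nu_mda"] + r["exit_mda_a"])) / r["exit_mda_b"]
  # nu = 0 makes phase b unreachable; its term is then 0 * Inf -> 0
  if (r["nu_no"] == 0) m1 <- 1 / r["exit_no_a"]
  if (r["nu_mda"] == 0) m2 <- 1 / r["exit_mda_a"]
  c(no_mda = unname(m1), mda = unname(m2))
}

#' Fit the phase-type model to determinable visits
#'
#' Restricts the cohort to visits with a known MDA determination,
#' maximises the phase-type likelihood over the six log rates, and
#' reports the gain in log-likelihood over the nested two-state Markov
#' model fitted to the same visits (non-negative up to optimiser
#' tolerance, since the two-state model is the phase-type model with the
#' phase-progression rates at zero).  Phase labels are fixed by the
#' convention that states are entered through phase a.
#'
#' @param data visit data frame or \code{mda_data} object.
#' @param config criteria configuration used to determine states.
#' @param start optional \code{\link{phase_type_model}} of starting
#'   rates.
#' @param n_starts optimiser starts (jittered after the first).
#' @param control passed to \code{\link[stats]{optim}}.
#' @param hessian compute the working-scale covariance.
#' @return object of class \code{phase_fit}: the fitted model, loglik,
#'   the nested two-state complete-case fit and \code{delta_loglik}.
#' @export
fit_phase_type <- function(data, config = mda_criteria(), start = NULL,
                           n_starts = 3, control = list(),
                           hessian = FALSE) {
  prep <- if (inherits(data, "mda_data")) data else
    prepare_mda_data(data, config, emission_spec())
  keep <- !is.na(prep$state)
  d <- prep$data[keep, c("patient_id", "time_years")]
  d$state <- prep$state[keep]
  series <- split(d, factor(d$patient_id, unique(d$patient_id)))
  series <- Filter(function(s) nrow(s) >= 2, series)
  if (!length(series)) stop("no patient has two determinable visits")
  cc_fit <- fit_mda(prep, config, mode = "complete_case",
                    n_starts = 1, hessian = FALSE)
  cc_rates <- c(cc_fit$estimates$model$rate_no_to_mda,
                cc_fit$estimates$model$rate_mda_to_no)
  cc_rates <- unname(cc_rates)
  if (is.null(start))
    start <- phase_type_model(0.3, cc_rates[1] * 1.2, cc_rates[1] * 0.8,
                              0.3, cc_rates[2] * 1.2, cc_rates[2] * 0.8)
  nll <- function(ltheta) {
    if (any(abs(ltheta) > 12)) return(1e10)  # rates outside (6e-6, 2e5)/yr
    m <- do.call(phase_type_model, as.list(unname(exp(ltheta))))
    ll <- tryCatch(.phase_cohort_loglik(series, m),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  theta0 <- log(pmax(start$rates, 1e-6))
  control <- utils::modifyList(list(maxit = 500, reltol = 1e-10), control)
  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    th <- if (s == 1L) theta0 else
      theta0 + stats::rnorm(length(theta0), sd = 0.4)
    opt <- try(stats::optim(th, nll, method = "BFGS", control = control),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("phase-type optimisation failed")
  model <- do.call(phase_type_model,
                   as.list(stats::setNames(exp(best$par),
                                           names(start$rates))))
  vc <- NULL
  if (hessian) {
    H <- try(stats::optimHess(best$par, nll), silent = TRUE)
    if (!inherits(H, "try-error")) {
      vc <- try(solve(H), silent = TRUE)
      if (inherits(vc, "try-error")) vc <- NULL
    }
  }
  structure(list(model = model, loglik = -best$value,
                 converged = best$convergence == 0,
                 markov_fit = cc_fit,
                 delta_loglik = -best$value - cc_fit$loglik,
                 sojourn_means = phase_sojourn_means(model),
                 vcov = vc, n_series = length(series)),
            class = "phase_fit")
}

#' @exportS3Method base::print
print.phase_fit <- function(x, ...) {
  cat("Two-phase semi-Markov fit (determinable visits only)\n")
  cat(sprintf("  loglik %.2f  (two-state Markov %.2f, gain %.2f)%s\n",
              x$loglik, x$markov_fit$loglik, x$delta_loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(x$model$rates, 4))
  cat(sprintf("  mean sojourns: no MDA %.2f y, MDA %.2f y\n",
              x$sojourn_means["no_mda"], x$sojourn_means["mda"]))
  invisible(x)
}
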