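#' Full parameter set of the partially hidden model
#'
#' Bundles the three blocks of the model: transition intensities (with any
#' covariate effects), the initial-state distribution, and the emission
#' parameters.
#'
#' @param model an \code{\link{intensity_model}}.
#' @param f length-2 probability vector for the state at the first visit
#'   (order \code{no_mda}, \code{mda}); must sum to one.
#' @param emissions an \code{\link{emission_params}} object (may be
#'   \code{NULL} when emissions are not used, e.g. complete-case work).
#' @return object of class \code{mda_parameters}.
#' @export
mda_parameters <- function(model, f = c(0.5, 0.5), emissions = NULL) {
  stopifnot(inherits(model, "intensity_model"))
  if (length(f) != 2 || any(f < 0) || abs(sum(f) - 1) > 1e-8)
    stop("f must be two non-negative probabilities summing to 1")
  structure(list(model = model, f = as.numeric(f), emissions = emissions),
            class = "mda_parameters")
}

#' Assemble a visit table for likelihood work
#'
#' Validates and orders a long-format visit table, computes each visit's
#' MDA determination, encodes outcomes for the emission model, and caches
#' the structures the likelihood evaluators need.
#'
#' @param data data frame with columns \code{patient_id},
#'   \code{time_years}, the outcome columns of \code{\link{mda_variables}}
#'   (any may be absent or \code{NA}) and any covariate columns.
#' @param config an \code{\link{mda_criteria}}.
#' @param spec an \code{\link{emission_spec}}.
#' @param covariates character vector of covariate column names entering
#'   the transition intensities.
#' @return object of class \code{mda_data}.
#' @export
prepare_mda_data <- function(data, config = mda_criteria(),
                             spec = emission_spec(),
                             covariates = character(0)) {
  data <- as.data.frame(data)
  if (!all(c("patient_id", "time_years") %in% names(data)))
    stop("data must contain patient_id and time_years columns")
  for (v in setdiff(mda_variables, names(data))) data[[v]] <- NA_real_
  miss <- setdiff(covariates, names(data))
  if (length(miss))
    stop("covariate column(s) not in data: ", paste(miss, collapse = ", "))
  ord <- order(data$patient_id, data$time_years)
  data <- data[ord, , drop = FALSE]
  pid <- factor(data$patient_id, levels = unique(data$patient_id))
  slot <- as.integer(pid)
  pos <- stats::ave(seq_along(slot), slot, FUN = seq_along)
  dt <- c(NA, diff(data$time_years))
  dt[pos == 1] <- NA
  if (any(pos > 1 & dt <= 0)) {
    bad <- which(pos > 1 & dt <= 0)[1]
    stop("times not strictly increasing for patient ",
         as.character(pid[bad]), " at time ", data$time_years[bad])
  }
  det <- determine_mda(data, config)
  state <- ifelse(det$determination == "no_mda", 1L,
                  ifelse(det$determination == "mda", 2L, NA_integer_))
  X <- if (length(covariates))
    as.matrix(data[, covariates, drop = FALSE]) else
    matrix(0, nrow(data), 0)
  structure(list(data = data, n = nrow(data), pid = pid, slot = slot,
                 pos = pos, dt = dt, state = state, det = det,
                 encoded = encode_outcomes(data, spec, config),
                 X = X, covariates = covariates,
                 config = config, spec = spec),
            class = "mda_data")
}

#' @exportS3Method base::print
print.mda_data <- function(x, ...) {
  cat(sprintf("mda_data: %d visits, %d patients\n", x$n,
              nlevels(x$pid)))
  print(table(x$det$determination))
  invisible(x)
}

# Per-visit transition rates for the interval ending at each visit,
# evaluated at the covariates of the interval's start (previous visit).
.interval_rates <- function(prep, model) {
  l1 <- rep(model$rate_no_to_mda, prep$n)
  l2 <- rep(model$rate_mda_to_no, prep$n)
  if (length(model$covariates)) {
    idx <- match(model$covariates, prep$covariates)
    if (anyNA(idx))
      stop("model covariates not present in prepared data")
    Xp <- prep$X[, idx, drop = FALSE]
    # shift within patient: covariates at the previous visit
    prev <- seq_len(prep$n) - 1L
    Xprev <- Xp
    Xprev[prep$pos > 1L, ] <- Xp[prev[prep$pos > 1L], , drop = FALSE]
    l1 <- l1 * exp(drop(Xprev %*% model$beta))
    l2 <- l2 * exp(drop(Xprev %*% model$gamma))
  }
  list(l1 = l1, l2 = l2)
}

# Core forward pass over an mda_data object.  Returns per-patient
# log-likelihood contributions.  use_emissions = FALSE drops the emission
# factors (every visit then contributes factor 1 apart from transition
# terms and constraints); constrain = FALSE ignores determinations.
.forward_pass <- function(prep, params, use_emissions = TRUE,
                          constrain = TRUE) {
  npat <- nlevels(prep$pid)
  E <- if (use_emissions) {
    if (is.null(params$emissions))
      stop("emission parameters required for the partially hidden likelihood")
    emission_loglik_matrix(prep$encoded, prep$spec, params$emissions)
  } else matrix(0, prep$n, 2)
  rates <- .interval_rates(prep, params$model)
  alpha <- matrix(0, npat, 2)
  ll <- numeric(npat)
  maxpos <- max(prep$pos)
  rows_by_pos <- split(seq_len(prep$n), prep$pos)
  for (j in seq_len(maxpos)) {
    rows <- rows_by_pos[[j]]
    pats <- prep$slot[rows]
    # emission weights, rescaled by their per-visit maximum for stability
    mx <- pmax(E[rows, 1], E[rows, 2])
    w <- exp(E[rows, , drop = FALSE] - mx)
    if (j == 1L) {
      a <- cbind(params$f[1] * w[, 1], params$f[2] * w[, 2])
    } else {
      p <- .p2_entries(rates$l1[rows], rates$l2[rows], prep$dt[rows])
      a0 <- alpha[pats, 1] * p$p11 + alpha[pats, 2] * p$p21
      a1 <- alpha[pats, 1] * p$p12 + alpha[pats, 2] * p$p22
      a <- cbind(a0 * w[, 1], a1 * w[, 2])
    }
    if (constrain) {
      known <- !is.na(prep$state[rows])
      if (any(known)) {
        kr <- which(known)
        a[cbind(kr, 3L - prep$state[rows][kr])] <- 0
      }
    }
    sc <- a[, 1] + a[, 2]
    if (any(!is.finite(sc) | sc <= 0)) {
      bad <- rows[which(!is.finite(sc) | sc <= 0)[1]]
      stop("non-finite or zero forward mass at visit row ", bad,
           " (patient ", as.character(prep$pid[bad]), ")")
    }
    ll[pats] <- ll[pats] + log(sc) + mx
    alpha[pats, ] <- a / sc
  }
  ll
}

#' Forward log-likelihood of one patient series
#'
#' Evaluates the partially hidden Markov likelihood for a single patient by
#' the forward recursion: initialise with the initial-state distribution
#' times the first visit's emission factor, propagate through interval
#' transition-probability matrices and emission factors, and at visits
#' where the MDA determination is known restrict the recursion to that
#' state (the observed composite constrains the latent pathways; it is not
#' itself an extra data factor).  Equivalent to summing the complete-data
#' likelihood over every latent state pathway consistent with the observed
#' determinations.
#'
#' @param series data frame of one patient's visits (columns as in
#'   \code{\link{prepare_mda_data}}), or an \code{mda_data} object built
#'   from them.
#' @param params an \code{\link{mda_parameters}} object.
#' @param spec,config emission specification and criteria configuration
#'   (ignored when \code{series} is already prepared).
#' @return scalar log-likelihood.
#' @export
forward_loglik <- function(series, params, spec = emission_spec(),
                           config = mda_criteria()) {
  prep <- if (inherits(series, "mda_data")) series else
    prepare_mda_data(series, config, spec,
                     covariates = params$model$covariates)
  if (prep$n == 0L) stop("empty series")
  sum(.forward_pass(prep, params, use_emissions = TRUE, constrain = TRUE))
}

#' Brute-force path-enumeration log-likelihood
#'
#' Exact reference evaluation of the same likelihood as
#' \code{\link{forward_loglik}} by explicitly summing over every latent
#' state pathway consistent with the observed determinations.  Cost grows
#' as \eqn{2^{\#indeterminate\ visits}}; intended for short series and
#' cross-checking.
#'
#' @inheritParams forward_loglik
#' @return scalar log-likelihood.
#' @export
enumerate_loglik <- function(series, params, spec = emission_spec(),
                             config = mda_criteria()) {
  prep <- if (inherits(series, "mda_data")) series else
    prepare_mda_data(series, config, spec,
                     covariates = params$model$covariates)
  E <- emission_loglik_matrix(prep$encoded, prep$spec, params$emissions)
  rates <- .interval_rates(prep, params$model)
  total <- 0
  for (s in seq_len(nlevels(prep$pid))) {
    rows <- which(prep$slot == s)
    choices <- lapply(rows, function(r)
      if (is.na(prep$state[r])) 1:2 else prep$state[r])
    paths <- as.matrix(expand.grid(choices))
    lik <- 0
    for (p in seq_len(nrow(paths))) {
      s_path <- paths[p, ]
      lp <- log(params$f[s_path[1]]) + E[rows[1], s_path[1]]
      for (j in seq_along(rows)[-1]) {
        r <- rows[j]
        P <- .p2_entries(rates$l1[r], rates$l2[r], prep$dt[r])
        Pm <- matrix(c(P$p11, P$p21, P$p12, P$p22), 2, 2)
        lp <- lp + log(Pm[s_path[j - 1], s_path[j]]) + E[r, s_path[j]]
      }
      lik <- lik + exp(lp)
    }
    total <- total + log(lik)
  }
  unname(total)
}

#' Complete-case panel log-likelihood
#'
#' The standard panel-data Markov likelihood restricted to visits at which
#' the MDA determination is known: the product over consecutive
#' determinable visits of the transition probability between their states,
#' conditioned on each patient's first determinable observation.  Patients
#' with fewer than two determinable visits contribute zero.
#'
#' @param series data frame of visits (one or several patients) or an
#'   \code{mda_data} object.
#' @param model an \code{\link{intensity_model}}.
#' @param config criteria configuration.
#' @return scalar log-likelihood.
#' @export
complete_case_loglik <- function(series, model, config = mda_criteria()) {
  prep <- if (inherits(series, "mda_data")) series else
    prepare_mda_data(series, config, emission_spec(),
                     covariates = model$covariates)
  keep <- which(!is.na(prep$state))
  if (length(keep) < 2) return(0)
  slot <- prep$slot[keep]
  consec <- which(slot[-1] == slot[-length(slot)])
  if (!length(consec)) return(0)
  from <- keep[consec]
  to <- keep[consec + 1]
  dtcc <- prep$data$time_years[to] - prep$data$time_years[from]
  l1 <- rep(model$rate_no_to_mda, length(from))
  l2 <- rep(model$rate_mda_to_no, length(from))
  if (length(model$covariates)) {
    idx <- match(model$covariates, prep$covariates)
    if (anyNA(idx)) stop("model covariates not present in prepared data")
    Xfrom <- prep$X[from, idx, drop = FALSE]
    l1 <- l1 * exp(drop(Xfrom %*% model$beta))
    l2 <- l2 * exp(drop(Xfrom %*% model$gamma))
  }
  P <- .p2_entries(l1, l2, dtcc)
  Pm <- cbind(P$p11, P$p12, P$p21, P$p22)  # columns indexed 2*(s1-1)+s2
  pr <- Pm[cbind(seq_along(from),
                 2L * (prep$state[from] - 1L) + prep$state[to])]
  sum(log(pr))
}

#' Total log-likelihood of a cohort
#'
#' @param data visit data frame for the whole cohort or an
#'   \code{mda_data} object.
#' @param params an \code{\link{mda_parameters}} object.
#' @param mode \code{"partially_hidden"} (full likelihood with emission
#'   factors and latent-path constraints) or \code{"complete_case"}
#'   (determinable visits only, conditioned on the first).
#' @param spec,config emission specification and criteria configuration.
#' @return scalar log-likelihood (sum over patients).
#' @export
total_loglik <- function(data, params,
                         mode = c("partially_hidden", "complete_case"),
                         spec = emission_spec(), config = mda_criteria()) {
  mode <- match.arg(mode)
  prep <- if (inherits(data, "mda_data")) data else
    prepare_mda_data(data, config, spec,
                     covariates = params$model$covariates)
  if (prep$n == 0L) stop("empty cohort")
  if (mode == "complete_case")
    complete_case_loglik(prep, params$model)
  else
    sum(.forward_pass(prep, params))
}
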