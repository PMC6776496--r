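# --- working-scale parameter packing -------------------------------------
# Optimisation runs on an unconstrained scale: log for rates and negative-
# binomial sizes, logit for probabilities, identity for regression
# coefficients.  Order: log rates (2), beta, gamma, logit f_mda (optional),
# then the emission block variable by variable.

.emission_par_names <- function(spec) {
  out <- character(0)
  for (v in names(spec$vars)) {
    out <- c(out, switch(spec$vars[[v]]$family,
      negative_binomial = paste0(v, c(".log_size", ".logit_p_no",
                                      ".logit_p_mda")),
      binomial10 = paste0(v, c(".logit_p_no", ".logit_p_mda")),
      bernoulli_criterion = paste0(v, c(".logit_p_no", ".logit_p_mda")),
      beta_binomial10 = paste0(v, c(".log_shape1_no", ".log_shape2_no",
                                    ".log_shape1_mda", ".log_shape2_mda"))))
  }
  out
}

.theta_names <- function(spec, covariates, estimate_f, include_emissions) {
  nm <- c("log_rate_no_to_mda", "log_rate_mda_to_no")
  if (length(covariates))
    nm <- c(nm, paste0("beta.", covariates), paste0("gamma.", covariates))
  if (include_emissions) {
    if (estimate_f) nm <- c(nm, "logit_f_mda")
    nm <- c(nm, .emission_par_names(spec))
  }
  nm
}

.clip01 <- function(p, eps = 1e-8) pmin(pmax(p, eps), 1 - eps)

.pack_theta <- function(params, spec, covariates, estimate_f,
                        include_emissions) {
  th <- c(log(params$model$rate_no_to_mda),
          log(params$model$rate_mda_to_no))
  if (length(covariates)) th <- c(th, params$model$beta, params$model$gamma)
  if (include_emissions) {
    if (estimate_f) th <- c(th, stats::qlogis(.clip01(params$f[2])))
    for (v in names(spec$vars)) {
      p <- params$emissions$vars[[v]]
      th <- c(th, switch(spec$vars[[v]]$family,
        negative_binomial = c(log(p$size), stats::qlogis(.clip01(p$prob))),
        binomial10 = stats::qlogis(.clip01(p$prob)),
        bernoulli_criterion = stats::qlogis(.clip01(p$prob)),
        beta_binomial10 = c(log(p$shape1[1]), log(p$shape2[1]),
                            log(p$shape1[2]), log(p$shape2[2]))))
    }
  }
  stats::setNames(th, .theta_names(spec, covariates, estimate_f,
                                   include_emissions))
}

.unpack_theta <- function(theta, spec, covariates, estimate_f,
                          include_emissions, f_fixed = c(0.5, 0.5)) {
  i <- 3L
  k <- length(covariates)
  beta <- gamma <- numeric(0)
  if (k) {
    beta <- theta[i:(i + k - 1)]; i <- i + k
    gamma <- theta[i:(i + k - 1)]; i <- i + k
  }
  model <- intensity_model(exp(theta[1]), exp(theta[2]), beta, gamma,
                           covariates)
  f <- f_fixed
  emissions <- NULL
  if (include_emissions) {
    if (estimate_f) {
      pf <- stats::plogis(theta[i]); i <- i + 1L
      f <- c(1 - pf, pf)
    }
    vars <- list()
    for (v in names(spec$vars)) {
      fam <- spec$vars[[v]]$family
      if (fam == "negative_binomial") {
        vars[[v]] <- list(size = exp(theta[i]),
                          prob = .clip01(stats::plogis(theta[i + 1:2])))
        i <- i + 3L
      } else if (fam %in% c("binomial10", "bernoulli_criterion")) {
        vars[[v]] <- list(prob = .clip01(stats::plogis(theta[i + 0:1])))
        i <- i + 2L
      } else {
        vars[[v]] <- list(shape1 = exp(theta[c(i, i + 2L)]),
                          shape2 = exp(theta[c(i + 1L, i + 3L)]))
        i <- i + 4L
      }
    }
    emissions <- emission_params(vars, spec)
  }
  mda_parameters(model, f, emissions)
}

# --- starting values ------------------------------------------------------

# complete-case rate estimates used to anchor starting values; falls back
# to 0.5/yr when the determinable transitions are too few.
.cc_rate_start <- function(prep) {
  nll <- function(lr) {
    m <- intensity_model(exp(lr[1]), exp(lr[2]))
    -complete_case_loglik(prep, m)
  }
  fit <- try(stats::optim(log(c(0.5, 0.5)), nll, method = "BFGS"),
             silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(fit$value) ||
      fit$value == 0)
    c(0.5, 0.5)
  else exp(fit$par)
}

.moment_emission_start <- function(prep) {
  spec <- prep$spec
  vars <- list()
  for (v in names(spec$vars)) {
    fam <- spec$vars[[v]]$family
    y <- prep$encoded[[v]]
    stats_by <- lapply(1:2, function(r) {
      yr <- y[!is.na(y) & !is.na(prep$state) & prep$state == r]
      if (length(yr) < 5) NULL else c(m = mean(yr), v = stats::var(yr))
    })
    if (fam == "negative_binomial") {
      est <- lapply(stats_by, function(s) {
        if (is.null(s) || s["m"] <= 0) return(NULL)
        if (s["v"] > s["m"] * 1.01) {
          size <- s["m"]^2 / (s["v"] - s["m"])
          list(size = max(size, 0.05), prob = .clip01(s["m"] /
                                                      s["v"], 1e-4))
        } else list(size = 1, prob = .clip01(1 / (1 + s["m"]), 1e-4))
      })
      size <- mean(c(est[[1]]$size, est[[2]]$size, 1), na.rm = TRUE)
      pr <- vapply(1:2, function(r) {
        m <- if (is.null(stats_by[[r]])) c(2, 0.5)[r] else
          max(stats_by[[r]]["m"], 0.01)
        .clip01(size / (size + m), 1e-4)
      }, 0)
      vars[[v]] <- list(size = size, prob = pr)
    } else if (fam == "binomial10") {
      pr <- vapply(1:2, function(r) {
        if (is.null(stats_by[[r]])) c(0.4, 0.1)[r] else
          .clip01(stats_by[[r]]["m"] / 10, 1e-3)
      }, 0)
      vars[[v]] <- list(prob = pr)
    } else if (fam == "bernoulli_criterion") {
      pr <- vapply(1:2, function(r) {
        if (is.null(stats_by[[r]])) c(0.3, 0.8)[r] else
          .clip01(stats_by[[r]]["m"], 1e-3)
      }, 0)
      vars[[v]] <- list(prob = pr)
    } else {
      pm <- vapply(1:2, function(r) {
        if (is.null(stats_by[[r]])) c(0.4, 0.1)[r] else
          .clip01(stats_by[[r]]["m"] / 10, 1e-3)
      }, 0)
      vars[[v]] <- list(shape1 = pm * 5, shape2 = (1 - pm) * 5)
    }
  }
  emission_params(vars, spec)
}

.default_start <- function(prep, covariates, mode, estimate_f) {
  rates <- .cc_rate_start(prep)
  model <- intensity_model(rates[1], rates[2],
                           beta = rep(0, length(covariates)),
                           gamma = rep(0, length(covariates)),
                           covariates = covariates)
  if (mode == "complete_case")
    return(mda_parameters(model))
  first <- prep$pos == 1L & !is.na(prep$state)
  pf <- if (any(first)) .clip01(mean(prep$state[first] == 2L), 0.05)
        else 0.5
  mda_parameters(model, c(1 - pf, pf), .moment_emission_start(prep))
}

# --- maximum likelihood fit ----------------------------------------------

#' Fit the two-state model by maximum likelihood
#'
#' Maximises the partially hidden Markov likelihood (or the complete-case
#' panel likelihood) over transition intensities, covariate effects,
#' the initial-state distribution and the emission parameters, using BFGS
#' on an unconstrained working scale.  The latent-state labels are anchored
#' by the determinable visits (state 2 is MDA), so no label-switching
#' resolution is needed; fitting the partially hidden model to data with no
#' determinable visit at all is refused.
#'
#' @param data long-format visit data frame (see
#'   \code{\link{prepare_mda_data}}) or a prepared \code{mda_data} object.
#' @param config an \code{\link{mda_criteria}}.
#' @param spec an \code{\link{emission_spec}}.
#' @param mode \code{"partially_hidden"} or \code{"complete_case"}.
#' @param covariates character vector of covariate columns entering the
#'   transition intensities log-linearly.
#' @param start optional \code{\link{mda_parameters}} starting values;
#'   defaults to a complete-case rate fit plus state-stratified moment
#'   estimates of the emission parameters.
#' @param fix_f optional length-2 probability vector fixing the
#'   initial-state distribution instead of estimating it.
#' @param n_starts number of optimiser starts (the first at \code{start},
#'   the rest jittered); the best solution is kept.
#' @param jitter_sd standard deviation of the working-scale jitter.
#' @param control list passed to \code{\link[stats]{optim}} (default
#'   \code{maxit = 500, reltol = 1e-10}).
#' @param hessian compute the observed information and its inverse
#'   (working-scale covariance) at the optimum.
#' @return object of class \code{mda_fit}: \code{estimates}
#'   (an \code{mda_parameters}), \code{loglik}, \code{theta} and
#'   \code{vcov} on the working scale, \code{se}, \code{converged},
#'   \code{n_evaluations}.
#' @export
fit_mda <- function(data, config = mda_criteria(), spec = emission_spec(),
                    mode = c("partially_hidden", "complete_case"),
                    covariates = character(0), start = NULL,
                    fix_f = NULL, n_starts = 3, jitter_sd = 0.3,
                    control = list(), hessian = TRUE) {
  mode <- match.arg(mode)
  prep <- if (inherits(data, "mda_data")) data else
    prepare_mda_data(data, config, spec, covariates)
  include_emissions <- mode == "partially_hidden"
  if (include_emissions && all(is.na(prep$state)))
    stop("no determinable visit in the data: latent-state labels cannot ",
         "be anchored")
  estimate_f <- include_emissions && is.null(fix_f)
  f_fixed <- if (is.null(fix_f)) c(0.5, 0.5) else fix_f
  if (is.null(start))
    start <- .default_start(prep, covariates, mode, estimate_f)
  theta0 <- .pack_theta(start, spec, covariates, estimate_f,
                        include_emissions)
  n_eval <- 0L
  nll <- function(theta) {
    n_eval <<- n_eval + 1L
    pars <- .unpack_theta(theta, spec, covariates, estimate_f,
                          include_emissions, f_fixed)
    ll <- tryCatch(total_loglik(prep, pars, mode, spec, config),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  control <- utils::modifyList(list(maxit = 500, reltol = 1e-10), control)
  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    th <- if (s == 1L) theta0 else
      theta0 + stats::rnorm(length(theta0), sd = jitter_sd)
    opt <- try(stats::optim(th, nll, method = "BFGS", control = control),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimisation failed from every start")
  theta_hat <- stats::setNames(best$par, names(theta0))
  vc <- NULL; se <- rep(NA_real_, length(theta_hat))
  if (hessian) {
    H <- try(stats::optimHess(theta_hat, nll), silent = TRUE)
    if (!inherits(H, "try-error")) {
      vc <- try(solve(H), silent = TRUE)
      if (inherits(vc, "try-error") || any(diag(vc) < 0)) {
        warning("observed information singular or not positive definite; ",
                "covariance unavailable")
        vc <- NULL
      } else {
        vc <- (vc + t(vc)) / 2
        se <- sqrt(diag(vc))
        dimnames(vc) <- list(names(theta_hat), names(theta_hat))
      }
    }
  }
  est <- .unpack_theta(theta_hat, spec, covariates, estimate_f,
                       include_emissions, f_fixed)
  structure(list(estimates = est, loglik = -best$value,
                 theta = theta_hat, vcov = vc,
                 se = stats::setNames(se, names(theta_hat)),
                 converged = best$convergence == 0,
                 n_evaluations = n_eval, mode = mode,
                 covariates = covariates, spec = spec, config = config,
                 estimate_f = estimate_f, f_fixed = f_fixed,
                 n_patients = nlevels(prep$pid), n_visits = prep$n,
                 n_determinable = sum(!is.na(prep$state))),
            class = "mda_fit")
}

#' @exportS3Method base::print
print.mda_fit <- function(x, ...) {
  cat(sprintf("Two-state MDA model fit (%s)\n", x$mode))
  cat(sprintf("  %d patients, %d visits (%d determinable); loglik %.2f%s\n",
              x$n_patients, x$n_visits, x$n_determinable, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(sojourn_table(x))
  if (length(x$covariates)) print(hazard_ratios(x))
  invisible(x)
}

#' @exportS3Method stats::logLik
logLik.mda_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}

#' @exportS3Method stats::vcov
vcov.mda_fit <- function(object, ...) object$vcov

#' Mean sojourn times with delta-method standard errors
#'
#' Reports the fitted mean years per period in each state,
#' \eqn{1/\hat\lambda}, with standard errors obtained on the log scale
#' (\eqn{SE(1/\lambda) = 1/\lambda \times SE(\log\lambda)}) and
#' log-scale 95\% intervals.
#'
#' @param fit an \code{mda_fit}.
#' @return data frame: state, rate, mean sojourn, SE, lower and upper
#'   95\% limits (point estimates only when no covariance is available).
#' @export
sojourn_table <- function(fit) {
  stopifnot(inherits(fit, "mda_fit"))
  lograte <- fit$theta[1:2]
  se_log <- if (!is.null(fit$vcov)) sqrt(diag(fit$vcov)[1:2]) else
    c(NA_real_, NA_real_)
  soj <- exp(-lograte)
  data.frame(state = c("no_mda", "mda"), rate = exp(lograte),
             sojourn_years = soj, se = soj * se_log,
             lower = exp(-(lograte + 1.96 * se_log)),
             upper = exp(-(lograte - 1.96 * se_log)),
             row.names = NULL)
}

#' Transition intensity ratios for the fitted covariate effects
#'
#' @param fit an \code{mda_fit} with covariates.
#' @return data frame: covariate, transition, hazard ratio
#'   \eqn{e^{\hat\beta}} and 95\% interval
#'   \eqn{e^{\hat\beta \pm 1.96\,SE}}.
#' @export
hazard_ratios <- function(fit) {
  stopifnot(inherits(fit, "mda_fit"))
  if (!length(fit$covariates)) stop("fit has no covariates")
  nm <- c(paste0("beta.", fit$covariates), paste0("gamma.", fit$covariates))
  co <- fit$theta[nm]
  se <- if (!is.null(fit$vcov)) sqrt(diag(fit$vcov)[nm]) else
    rep(NA_real_, length(nm))
  data.frame(covariate = rep(fit$covariates, 2),
             transition = rep(c("no_to_mda", "mda_to_no"),
                              each = length(fit$covariates)),
             hr = exp(co), lower = exp(co - 1.96 * se),
             upper = exp(co + 1.96 * se), row.names = NULL)
}
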