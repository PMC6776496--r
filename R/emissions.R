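#' Emission model specification for the outcome variables
#'
#' Conditional on the latent state, each defining variable is modelled
#' independently.  In the default specification the two patient VAS scores
#' (pain and global activity), rounded to integers 0-10, follow
#' Binomial(10, p) distributions with state-specific p; the remaining
#' variables, integer-valued once HAQ and PASI are multiplied by 100,
#' follow negative binomial distributions with a size shared across states
#' and a state-specific success probability.  The \code{"robust"} variant
#' replaces the binomials by beta-binomials and coarsens the HAQ and skin
#' variables into Bernoulli indicators of their binary criteria
#' (HAQ <= 0.5; PASI <= 1 or BSA <= 3), guarding against
#' misspecification of the count distributions.
#'
#' @param variant \code{"default"} or \code{"robust"}.
#' @return an object of class \code{emission_spec}: per-variable family
#'   (\code{binomial10}, \code{negative_binomial}, \code{beta_binomial10}
#'   or \code{bernoulli_criterion}), integer scaling factor, and for
#'   Bernoulli emissions the linked criterion.
#' @export
emission_spec <- function(variant = c("default", "robust")) {
  variant <- match.arg(variant)
  base <- list(
    TJC      = list(family = "negative_binomial", scale = 1),
    SJC      = list(family = "negative_binomial", scale = 1),
    PASI     = list(family = "negative_binomial", scale = 100),
    BSA      = list(family = "negative_binomial", scale = 1),
    PTPPAINV = list(family = "binomial10", scale = 1),
    PTPSA    = list(family = "binomial10", scale = 1),
    HAQ      = list(family = "negative_binomial", scale = 100),
    ENTH_TOT = list(family = "negative_binomial", scale = 1)
  )
  if (variant == "robust") {
    base$PTPPAINV$family <- "beta_binomial10"
    base$PTPSA$family <- "beta_binomial10"
    base$HAQ <- list(family = "bernoulli_criterion", scale = 1,
                     criterion = "haq")
    base$PASI <- list(family = "bernoulli_criterion", scale = 1,
                      criterion = "skin")
    base$BSA <- NULL  # absorbed into the skin criterion indicator
  }
  structure(list(vars = base, variant = variant), class = "emission_spec")
}

#' Emission parameters
#'
#' @param vars a named list, one element per variable in the matching
#'   \code{\link{emission_spec}}.  For \code{negative_binomial}:
#'   \code{list(size = n, prob = c(p_no, p_mda))} with mean
#'   \code{n(1-p)/p} (so p near 1 gives low counts); for
#'   \code{binomial10} and \code{bernoulli_criterion}:
#'   \code{list(prob = c(p_no, p_mda))}; for \code{beta_binomial10}:
#'   \code{list(shape1 = c(a_no, a_mda), shape2 = c(b_no, b_mda))}.
#' @param spec the \code{\link{emission_spec}} the parameters belong to.
#' @return object of class \code{emission_params}.
#' @export
emission_params <- function(vars, spec = emission_spec()) {
  stopifnot(inherits(spec, "emission_spec"))
  miss <- setdiff(names(spec$vars), names(vars))
  if (length(miss))
    stop("parameters missing for: ", paste(miss, collapse = ", "))
  for (v in names(spec$vars)) {
    fam <- spec$vars[[v]]$family
    p <- vars[[v]]
    if (fam %in% c("binomial10", "bernoulli_criterion",
                   "negative_binomial")) {
      if (length(p$prob) != 2 || any(p$prob <= 0) || any(p$prob >= 1))
        stop(v, ": prob must be two values in (0, 1)")
    }
    if (fam == "negative_binomial" &&
        (is.null(p$size) || p$size <= 0))
      stop(v, ": negative binomial size must be positive")
    if (fam == "beta_binomial10" &&
        (length(p$shape1) != 2 || length(p$shape2) != 2 ||
         any(c(p$shape1, p$shape2) <= 0)))
      stop(v, ": beta-binomial shapes must be two positive pairs")
  }
  structure(list(vars = vars), class = "emission_params")
}

# beta-binomial pmf on log scale: y successes out of size, shapes a, b
.dbetabinom_log <- function(y, size, a, b) {
  lchoose(size, y) + lbeta(y + a, size - y + b) - lbeta(a, b)
}

# Integer-code an observed outcome vector according to the spec:
# VAS scores rounded (half-to-even) to 0..10; HAQ and PASI scaled by 100
# then rounded; Bernoulli emissions use the criterion satisfaction
# indicator (NA when not decidable).  Input and output are data frames.
encode_outcomes <- function(data, spec = emission_spec(),
                            config = mda_criteria()) {
  data <- as.data.frame(data)
  .validate_outcomes(data)
  st <- NULL
  out <- data.frame(row.names = seq_len(max(nrow(data), 1L)))[
    seq_len(nrow(data)), , drop = FALSE]
  for (v in names(spec$vars)) {
    sv <- spec$vars[[v]]
    if (sv$family == "bernoulli_criterion") {
      if (is.null(st)) st <- criterion_status(data, config)
      out[[v]] <- st[, sv$criterion]
    } else {
      y <- round(data[[v]] * sv$scale)
      if (sv$family %in% c("binomial10", "beta_binomial10") &&
          any(!is.na(y) & (y < 0 | y > 10)))
        stop(v, ": rounded VAS value outside 0..10")
      out[[v]] <- y
    }
  }
  out
}

# n x 2 matrix of per-visit emission log-likelihoods (columns: state
# no_mda, mda), summing observed components only (missing-at-random:
# missing components contribute a factor of one).
emission_loglik_matrix <- function(encoded, spec, params) {
  n <- nrow(encoded)
  ll <- matrix(0, n, 2, dimnames = list(NULL, c("no_mda", "mda")))
  for (v in names(spec$vars)) {
    y <- encoded[[v]]
    obs <- !is.na(y)
    if (!any(obs)) next
    fam <- spec$vars[[v]]$family
    p <- params$vars[[v]]
    for (r in 1:2) {
      lp <- switch(fam,
        binomial10 = stats::dbinom(y[obs], 10, p$prob[r], log = TRUE),
        negative_binomial = stats::dnbinom(y[obs], size = p$size,
                                           prob = p$prob[r], log = TRUE),
        beta_binomial10 = .dbetabinom_log(y[obs], 10, p$shape1[r],
                                          p$shape2[r]),
        bernoulli_criterion = stats::dbinom(y[obs], 1, p$prob[r],
                                            log = TRUE),
        stop("unknown emission family: ", fam))
      ll[obs, r] <- ll[obs, r] + lp
    }
  }
  ll
}

#' Emission log-likelihood of a visit's outcomes given a latent state
#'
#' Sums the per-variable log-probabilities over the observed components
#' only; under missingness at random the unobserved components contribute
#' nothing, so a visit with every component missing returns 0.
#'
#' @param outcomes named list/vector or one-row data frame of outcome
#'   values on their natural scales (\code{NA} = missing).
#' @param state \code{"no_mda"} or \code{"mda"} (or 1/2).
#' @param spec an \code{\link{emission_spec}}.
#' @param params an \code{\link{emission_params}}.
#' @param config criteria configuration (needed for Bernoulli emissions).
#' @return scalar log-likelihood.
#' @export
emission_loglik <- function(outcomes, state, spec = emission_spec(),
                            params, config = mda_criteria()) {
  if (is.character(state))
    state <- match(match.arg(state, c("no_mda", "mda")),
                   c("no_mda", "mda"))
  stopifnot(state %in% 1:2)
  if (!is.data.frame(outcomes)) outcomes <- as.data.frame(as.list(outcomes))
  for (v in setdiff(mda_variables, names(outcomes)))
    outcomes[[v]] <- NA_real_
  enc <- encode_outcomes(outcomes, spec, config)
  unname(emission_loglik_matrix(enc, spec, params)[1, state])
}

#' Simulate an outcome vector given the latent state
#'
#' Draws the observed components from the state-specific emission
#' distributions and masks the components flagged missing.  Values are
#' returned on the natural scales (HAQ and PASI divided back by their
#' integer-scaling factor).
#'
#' @param state \code{"no_mda"} or \code{"mda"} (or 1/2).
#' @param spec,params emission specification and parameters.
#' @param missing named logical vector (TRUE = masked); variables absent
#'   from it are treated as observed.
#' @param n number of vectors to draw.
#' @return data frame with \code{n} rows and one column per variable.
#' @export
simulate_outcomes <- function(state, spec = emission_spec(), params,
                              missing = NULL, n = 1) {
  if (is.character(state))
    state <- match(match.arg(state, c("no_mda", "mda")),
                   c("no_mda", "mda"))
  out <- data.frame(row.names = seq_len(n))
  for (v in names(spec$vars)) {
    sv <- spec$vars[[v]]
    p <- params$vars[[v]]
    y <- switch(sv$family,
      binomial10 = stats::rbinom(n, 10, p$prob[state]),
      negative_binomial = stats::rnbinom(n, size = p$size,
                                         prob = p$prob[state]),
      beta_binomial10 = stats::rbinom(n, 10,
        stats::rbeta(n, p$shape1[state], p$shape2[state])),
      bernoulli_criterion = stats::rbinom(n, 1, p$prob[state]))
    y <- y / sv$scale
    # clinical scores are bounded; cap the unbounded count draws there
    if (sv$family == "negative_binomial" && v %in% names(.mda_domains))
      y <- pmin(y, .mda_domains[[v]][2])
    midx <- match(v, names(missing))
    if (!is.na(midx) && isTRUE(missing[[midx]])) y[] <- NA_real_
    out[[v]] <- y
  }
  out
}

#' Probability of satisfying each criterion under each latent state
#'
#' Summarises how well each modelled variable discriminates the states:
#' the fitted probability that the variable satisfies its binary criterion
#' given the state, obtained by summing the fitted probability mass at or
#' below the (scaled) cutpoint.
#'
#' @param spec,params emission specification and parameters.
#' @param config criteria configuration supplying the cutpoints.
#' @return data frame: variable, family, cutpoint,
#'   \code{p_satisfied_no_mda}, \code{p_satisfied_mda}.
#' @export
discriminability_report <- function(spec = emission_spec(), params,
                                    config = mda_criteria()) {
  rows <- lapply(names(spec$vars), function(v) {
    sv <- spec$vars[[v]]
    p <- params$vars[[v]]
    thr <- config$thresholds[[v]]
    kmax <- if (is.null(thr)) NA else floor(thr * sv$scale)
    ps <- vapply(1:2, function(r) {
      switch(sv$family,
        binomial10 = stats::pbinom(min(kmax, 10), 10, p$prob[r]),
        negative_binomial = stats::pnbinom(kmax, size = p$size,
                                           prob = p$prob[r]),
        beta_binomial10 = sum(exp(.dbetabinom_log(0:min(kmax, 10), 10,
                                                  p$shape1[r],
                                                  p$shape2[r]))),
        bernoulli_criterion = p$prob[r])
    }, 0)
    data.frame(variable = v, family = sv$family,
               cutpoint = if (is.null(thr)) NA_real_ else thr,
               p_satisfied_no_mda = ps[1], p_satisfied_mda = ps[2])
  })
  do.call(rbind, rows)
}

#' Default synthetic emission parameters
#'
#' A set of plausible state-specific emission parameters used by the
#' synthetic-cohort generator and as a fitting test-bed.  They are
#' synthetic: chosen so that low outcome values cluster in the MDA state
#' strongly enough that fully observed visits are almost always decisive,
#' not estimates from any clinic data.
#'
#' @param spec emission specification the parameters should match.
#' @return an \code{\link{emission_params}} object.
#' @export
default_emission_params <- function(spec = emission_spec()) {
  nb <- function(size, mean_no, mean_mda)
    list(size = size, prob = c(size / (size + mean_no),
                               size / (size + mean_mda)))
  vars <- list(
    TJC      = nb(0.7, 5.0, 0.35),
    SJC      = nb(0.6, 2.5, 0.20),
    PASI     = nb(0.5, 300, 55),
    BSA      = nb(0.6, 10, 1.6),
    PTPPAINV = list(prob = c(0.42, 0.08)),
    PTPSA    = list(prob = c(0.45, 0.13)),
    HAQ      = nb(0.8, 95, 22),
    ENTH_TOT = nb(0.5, 1.6, 0.12)
  )
  if (spec$variant == "robust") {
    vars$PTPPAINV <- list(shape1 = c(2.5, 0.5), shape2 = c(3.5, 5.5))
    vars$PTPSA <- list(shape1 = c(2.8, 0.7), shape2 = c(3.4, 4.5))
    vars$HAQ <- list(prob = c(0.30, 0.90))   # P(HAQ <= 0.5 | state)
    vars$PASI <- list(prob = c(0.35, 0.88))  # P(skin criterion | state)
    vars$BSA <- NULL
  }
  emission_params(vars, spec)
}
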