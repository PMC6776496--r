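#' Two-state transition intensity model with log-linear covariate effects
#'
#' The continuous-time chain alternates between No-MDA (state 1) and MDA
#' (state 2).  Transition intensities are
#' \deqn{\lambda_{No\to MDA}(x) = \lambda_{01} e^{x\beta}, \qquad
#'       \lambda_{MDA\to No}(x) = \lambda_{02} e^{x\gamma},}
#' with time measured in years throughout.
#'
#' @param rate_no_to_mda,rate_mda_to_no positive baseline intensities
#'   (per year).
#' @param beta,gamma numeric coefficient vectors (may be empty) for the
#'   No-to-MDA and MDA-to-No transitions.
#' @param covariates character vector of covariate names matching the
#'   coefficient length.
#' @return an object of class \code{intensity_model}.
#' @export
intensity_model <- function(rate_no_to_mda, rate_mda_to_no,
                            beta = numeric(0), gamma = numeric(0),
                            covariates = character(0)) {
  if (rate_no_to_mda <= 0 || rate_mda_to_no <= 0)
    stop("baseline transition rates must be positive")
  if (length(beta) != length(covariates) ||
      length(gamma) != length(covariates))
    stop("beta, gamma and covariates must have equal length")
  structure(list(rate_no_to_mda = rate_no_to_mda,
                 rate_mda_to_no = rate_mda_to_no,
                 beta = as.numeric(beta), gamma = as.numeric(gamma),
                 covariates = covariates),
            class = "intensity_model")
}

#' @exportS3Method base::print
print.intensity_model <- function(x, ...) {
  cat("Two-state intensity model (rates per year)\n")
  cat(sprintf("  No-MDA -> MDA: %.4f   MDA -> No-MDA: %.4f\n",
              x$rate_no_to_mda, x$rate_mda_to_no))
  if (length(x$covariates)) {
    cat("  log-linear effects:\n")
    for (i in seq_along(x$covariates))
      cat(sprintf("    %-12s beta = %+0.4f  gamma = %+0.4f\n",
                  x$covariates[i], x$beta[i], x$gamma[i]))
  }
  invisible(x)
}

#' Intensity matrix at a covariate value
#'
#' @param model an \code{\link{intensity_model}}.
#' @param x covariate vector (length matching \code{model$covariates});
#'   omit or use \code{numeric(0)} for the baseline.
#' @return 2x2 intensity matrix with rows summing to zero; row/column order
#'   is \code{no_mda}, \code{mda}.
#' @export
intensity_at <- function(model, x = numeric(0)) {
  stopifnot(inherits(model, "intensity_model"))
  if (length(x) != length(model$covariates))
    stop("covariate vector has length ", length(x), ", expected ",
         length(model$covariates))
  l1 <- model$rate_no_to_mda * exp(sum(x * model$beta))
  l2 <- model$rate_mda_to_no * exp(sum(x * model$gamma))
  intensity_matrix(l1, l2)
}

#' Build a two-state intensity matrix from the two rates
#'
#' @param rate_no_to_mda,rate_mda_to_no non-negative rates per year.
#' @return 2x2 matrix \code{Q} with \code{Q[1,2] = rate_no_to_mda},
#'   \code{Q[2,1] = rate_mda_to_no}, diagonal minus the row sums.
#' @export
intensity_matrix <- function(rate_no_to_mda, rate_mda_to_no) {
  if (rate_no_to_mda < 0 || rate_mda_to_no < 0)
    stop("rates must be non-negative")
  matrix(c(-rate_no_to_mda, rate_mda_to_no,
           rate_no_to_mda, -rate_mda_to_no), 2, 2,
         dimnames = list(c("no_mda", "mda"), c("no_mda", "mda")))
}

.check_Q2 <- function(Q) {
  stopifnot(is.matrix(Q), all(dim(Q) == 2))
  if (any(Q[row(Q) != col(Q)] < 0) || any(abs(rowSums(Q)) > 1e-12))
    stop("not a valid intensity matrix")
  c(l1 = Q[1, 2], l2 = Q[2, 1])
}

#' Transition probability matrix over an interval
#'
#' For the two-state chain the matrix exponential has the closed form
#' \deqn{P_{12}(t) = \frac{\lambda_1}{\lambda_1+\lambda_2}
#'       \left(1 - e^{-(\lambda_1+\lambda_2)t}\right),}
#' used as the primary evaluation path; \code{method = "expm"} evaluates
#' \eqn{e^{Qt}} numerically for any state space (used by the phase-type
#' model).
#'
#' @param Q intensity matrix.
#' @param t non-negative duration in years.
#' @param method \code{"closed_form"} (2-state only) or \code{"expm"}.
#' @return stochastic matrix \code{P(t)}.
#' @export
transition_probability <- function(Q, t,
                                   method = c("closed_form", "expm")) {
  method <- match.arg(method)
  if (t < 0) stop("duration t must be non-negative")
  if (method == "expm" || nrow(Q) != 2L)
    return(as.matrix(Matrix::expm(Matrix::Matrix(Q * t))))
  r <- .check_Q2(Q)
  s <- r["l1"] + r["l2"]
  if (s == 0) return(diag(2))
  e <- exp(-s * t)
  p12 <- (r["l1"] / s) * (1 - e)
  p21 <- (r["l2"] / s) * (1 - e)
  matrix(c(1 - p12, p21, p12, 1 - p21), 2, 2,
         dimnames = dimnames(Q))
}

# vectorised closed-form entries of P(t) for the 2-state chain;
# l1, l2, t may be vectors (recycled).  Returns a list p11,p12,p21,p22.
.p2_entries <- function(l1, l2, t) {
  s <- l1 + l2
  e <- exp(-s * t)
  frac1 <- ifelse(s > 0, l1 / s, 0)
  frac2 <- ifelse(s > 0, l2 / s, 0)
  p12 <- frac1 * (1 - e)
  p21 <- frac2 * (1 - e)
  list(p11 = 1 - p12, p12 = p12, p21 = p21, p22 = 1 - p21)
}

#' Mean sojourn times of the two states
#'
#' @param Q intensity matrix.
#' @return named vector: mean years per No-MDA period (\code{1/Q[1,2]}) and
#'   per MDA period (\code{1/Q[2,1]}); \code{Inf} where a rate is zero.
#' @export
mean_sojourn <- function(Q) {
  r <- .check_Q2(Q)
  out <- c(no_mda = unname(1 / r["l1"]), mda = unname(1 / r["l2"]))
  if (any(!is.finite(out)))
    warning("zero transition rate: infinite mean sojourn")
  out
}

#' Expected total time per state over a finite window
#'
#' Integrates the occupancy probabilities over \eqn{[0, T]}.  Starting in
#' No-MDA, the expected time in MDA is
#' \deqn{\frac{\lambda_1}{\lambda_1+\lambda_2}
#'   \left[T - \frac{1 - e^{-(\lambda_1+\lambda_2)T}}
#'        {\lambda_1+\lambda_2}\right].}
#'
#' @param Q intensity matrix.
#' @param start_state \code{"no_mda"} or \code{"mda"}.
#' @param horizon window length T in years (> 0).
#' @return named vector of expected years in each state; sums to
#'   \code{horizon}.
#' @export
expected_occupancy_window <- function(Q, start_state = "no_mda",
                                      horizon = 10) {
  r <- .check_Q2(Q)
  if (horizon <= 0) stop("horizon must be positive")
  l1 <- r[["l1"]]; l2 <- r[["l2"]]; s <- l1 + l2
  start_state <- match.arg(start_state, c("no_mda", "mda"))
  if (s == 0) {
    t_mda <- if (start_state == "mda") horizon else 0
    return(c(no_mda = horizon - t_mda, mda = t_mda))
  }
  shrink <- (1 - exp(-s * horizon)) / s
  # stationary part + transient correction from the start state
  t_mda <- (l1 / s) * horizon +
    (if (start_state == "no_mda") -l1 / s else l2 / s) * shrink
  c(no_mda = horizon - t_mda, mda = t_mda)
}

#' Expected number of entries into each state over a window
#'
#' Entries into MDA before T equal \eqn{\lambda_1 \times} expected time in
#' No-MDA over \eqn{[0, T]} (and symmetrically for No-MDA), counting an
#' entry when the transition occurs before T.  The initial sojourn is not
#' an entry.
#'
#' @inheritParams expected_occupancy_window
#' @return named vector of expected entry counts into each state.
#' @export
expected_entries_window <- function(Q, start_state = "no_mda",
                                    horizon = 10) {
  r <- .check_Q2(Q)
  occ <- expected_occupancy_window(Q, start_state, horizon)
  c(no_mda = unname(r["l2"] * occ[["mda"]]),
    mda = unname(r["l1"] * occ[["no_mda"]]))
}
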