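#' Read a long-format visit table
#'
#' One row per clinic visit: \code{patient_id}, \code{time_years}
#' (years since cohort entry), the outcome columns of
#' \code{\link{mda_variables}} (empty cells = missing) and any covariate
#' columns.  Rows are validated and returned sorted by patient and time.
#'
#' @param path CSV file path.
#' @param quiet suppress the row-count and missingness summary written to
#'   stderr.
#' @return a data frame of visits.
#' @export
read_visits <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "time_years")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("required column(s) missing: ", paste(miss, collapse = ", "))
  unknown <- setdiff(names(d), c(req, mda_variables))
  dup <- duplicated(d[, req])
  if (any(dup)) {
    bad <- d[dup, req][1, ]
    stop("duplicated (patient, time) rows, e.g. patient ",
         bad$patient_id, " at time ", bad$time_years)
  }
  d <- d[order(d$patient_id, d$time_years), , drop = FALSE]
  rownames(d) <- NULL
  if (!quiet) {
    present <- intersect(mda_variables, names(d))
    mr <- vapply(present, function(v) mean(is.na(d[[v]])), 0)
    message(sprintf("read %d visits from %d patients", nrow(d),
                    length(unique(d$patient_id))))
    message("missingness: ",
            paste(sprintf("%s %.0f%%", present, 100 * mr),
                  collapse = ", "))
    if (length(unknown))
      message("covariate/extra columns: ",
              paste(unknown, collapse = ", "))
  }
  d
}

#' Write a visit table
#'
#' Missing values are written as empty cells.
#'
#' @param visits data frame of visits (or an \code{mda_cohort}, in which
#'   case its visit table is written).
#' @param path destination CSV path.
#' @export
write_visits <- function(visits, path) {
  if (inherits(visits, "mda_cohort")) visits <- visits$visits
  utils::write.csv(visits, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Default run configuration
#'
#' A single structured configuration covering the criteria definition,
#' emission variant, optimiser settings, simulation settings and seed, as
#' written/read by \code{\link{write_run_config}} and
#' \code{\link{read_run_config}}.
#'
#' @return a nested list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    mode = "partially_hidden",
    criteria = list(m_required = 5L,
                    thresholds = as.list(mda_criteria()$thresholds)),
    emissions = list(variant = "default"),
    covariates = character(0),
    optimizer = list(n_starts = 3L, maxit = 500L, reltol = 1e-10),
    simulation = list(horizon = 10, sustain_threshold = 1,
                      n_patients = 100000L, n_bootstrap = 1000L,
                      start_state = "no_mda")
  )
}

#' @rdname default_run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- utils::modifyList(default_run_config(), yaml::read_yaml(path))
  cfg
}

#' @rdname default_run_config
#' @param config configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# helpers for a run configuration -> package objects
config_criteria <- function(cfg)
  mda_criteria(cfg$criteria$m_required,
               unlist(cfg$criteria$thresholds))
config_spec <- function(cfg) emission_spec(cfg$emissions$variant)
config_sim_settings <- function(cfg, seed = cfg$seed)
  sim_settings(horizon = cfg$simulation$horizon,
               sustain_threshold = cfg$simulation$sustain_threshold,
               n_patients = cfg$simulation$n_patients,
               n_bootstrap = cfg$simulation$n_bootstrap,
               start_state = cfg$simulation$start_state, seed = seed)

# short reproducibility fingerprint of a configuration
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Write a results object as JSON with reproducibility metadata
#'
#' Every artifact embeds the configuration hash, the seed and the package
#' version, so a rerun with the same configuration can be recognised.
#'
#' @param results a list (coerced to JSON).
#' @param path destination file.
#' @param config the run configuration used.
#' @export
write_results <- function(results, path, config = default_run_config()) {
  out <- c(list(meta = list(config_hash = .config_hash(config),
                            seed = config$seed,
                            package_version =
                              as.character(utils::packageVersion("mdahmm")))),
           results)
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"), path)
  invisible(path)
}
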