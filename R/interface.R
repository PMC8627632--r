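# Interface layer: delimited-text IPD adapter, study configuration
# round-tripping, a case-study workflow for user data, and a smoothed
# nonparametric hazard for visual comparison against longer follow-up.

#' Read right-censored individual patient data from delimited text
#'
#' Expects one row per subject with a positive time and a 0/1 event
#' indicator; rows with non-positive or unparseable times are rejected and
#' counted.  With a group column, one dataset per group label is returned.
#'
#' @param path Path to a delimited text file with a header row.
#' @param time_col,event_col,group_col Column names (group optional).
#' @param sep Field separator (default `","`).
#' @return A [survival_data()] frame, or a named list of them when
#'   `group_col` is given.  The number of rejected rows is attached as
#'   attribute `"n_rejected"`.
#' @export
read_ipd <- function(path, time_col = "time", event_col = "event",
                     group_col = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c(time_col, event_col, group_col)
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  time <- suppressWarnings(as.numeric(raw[[time_col]]))
  event <- suppressWarnings(as.numeric(raw[[event_col]]))
  bad <- !is.finite(time) | time <= 0 | !event %in% c(0, 1)
  if (any(bad))
    message(sum(bad), " row(s) rejected (non-positive/unparseable time ",
            "or invalid event indicator)")
  time <- time[!bad]; event <- event[!bad]
  if (is.null(group_col)) {
    out <- survival_data(time, event)
    attr(out, "n_rejected") <- sum(bad)
    return(out)
  }
  grp <- raw[[group_col]][!bad]
  out <- lapply(split(seq_along(time), grp), function(ix)
    survival_data(time[ix], event[ix]))
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write a survival dataset as delimited text
#'
#' @param data A [survival_data()] frame.
#' @param path Output path; header `time,event`.
#' @return `path`, invisibly.
#' @export
write_ipd <- function(data, path) {
  utils::write.csv(data[, c("time", "event")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Study configuration
#'
#' Bundles the knobs of a simulation study or case-study run.  The object
#' round-trips losslessly through its JSON representation
#' ([write_config()] / [read_config()]).
#'
#' @param classes Model classes to run (see [model_classes()]).
#' @param n_replicates Replicates per scenario.
#' @param base_seed Base seed of the deterministic stream.
#' @param horizon Extrapolation horizon in years.
#' @param grid_step Evaluation grid step in years.
#' @param include_gompertz Allow Gompertz into current-practice selection?
#' @param n_intervals FP/GAM split-grid size.
#' @param dsm Named list of [fit_dsm()] arguments (priors, interval width,
#'   MCMC lengths).
#' @param scenario_ids Which of the nine study scenarios to run.
#' @return A list of class `study_config`.
#' @export
study_config <- function(classes = model_classes(), n_replicates = 200L,
                         base_seed = 1L, horizon = 10, grid_step = 0.05,
                         include_gompertz = FALSE, n_intervals = 100L,
                         dsm = list(), scenario_ids = 1:9) {
  structure(list(classes = classes,
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed),
                 horizon = horizon, grid_step = grid_step,
                 include_gompertz = include_gompertz,
                 n_intervals = as.integer(n_intervals), dsm = dsm,
                 scenario_ids = as.integer(scenario_ids)),
            class = "study_config")
}

#' @rdname study_config
#' @param config A `study_config`.
#' @param path File path for the JSON representation.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname study_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(study_config, x)
}

#' Write a reproducibility manifest
#'
#' Records the configuration, seeds and package version alongside a run's
#' outputs, sufficient to reproduce them exactly.
#'
#' @param config A `study_config`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  m <- list(package = "hazext",
            version = as.character(utils::packageVersion("hazext")),
            r_version = R.version.string,
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
            config = unclass(config))
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Kernel-smoothed nonparametric hazard
#'
#' Gaussian-kernel smoothing of crude occurrence/exposure interval hazards
#' — a model-free reference curve for overlaying on extrapolations when a
#' longer data cut is available.
#'
#' @param data A [survival_data()] frame.
#' @param bandwidth Kernel bandwidth in years.
#' @param interval_width Discretisation width for the crude hazards.
#' @return A [hazard_curve] over the interval midpoints.
#' @export
smoothed_hazard <- function(data, bandwidth = 0.25, interval_width = 0.05) {
  iv <- discretise(data, interval_width)
  w <- outer(iv$tmid, iv$tmid, function(a, b)
    stats::dnorm(a - b, sd = bandwidth))
  h <- as.numeric(w %*% iv$events) / as.numeric(w %*% iv$exposure)
  keep <- is.finite(h) & h > 0
  hazard_curve(iv$tmid[keep], log(h[keep]))
}

#' Case-study workflow on user-supplied IPD
#'
#' Fits the requested model classes to each arm of an early data cut,
#' reports AIC and BIC for every candidate, selects per-class models, and
#' predicts extrapolated log-hazard curves.  When a later data cut is
#' supplied, a kernel-smoothed nonparametric hazard of the later data is
#' attached for visual comparison.
#'
#' @param arms Named list of [survival_data()] frames (one per arm), or a
#'   single frame.
#' @param config A [study_config()]; `classes`, `horizon`, `grid_step`,
#'   `n_intervals`, `include_gompertz` and `dsm` are honoured.
#' @param late_arms Optional later-cut data, same shape as `arms`.
#' @return A list of class `case_study` with, per arm: `fits` (per-class
#'   selected fits), `ic_table` (AIC/BIC of all candidates), `curves`
#'   (per-class extrapolation [hazard_curve]s), and optionally
#'   `late_hazard`.
#' @export
run_case_study <- function(arms, config = study_config(), late_arms = NULL) {
  if (inherits(arms, "survival_data")) arms <- list(arm = arms)
  if (!is.null(late_arms) && inherits(late_arms, "survival_data"))
    late_arms <- list(arm = late_arms)
  grid <- seq(config$grid_step, config$horizon, by = config$grid_step)
  out <- lapply(names(arms), function(a) {
    data <- arms[[a]]
    stopifnot(sum(data$event) >= 1)
    fits <- list(); ic <- list()
    for (cl in config$classes) {
      fit <- tryCatch(
        .fit_class(cl, data, config$include_gompertz, config$n_intervals,
                   config$dsm, config$base_seed),
        error = function(e) failed_fit(cl, cl, conditionMessage(e)))
      fits[[cl]] <- fit
      cands <- attr(fit, "candidates") %||% list(fit)
      for (cand in cands) {
        ic[[length(ic) + 1L]] <- data.frame(
          arm = a, class = cl, model = cand$label,
          converged = is_converged(cand),
          aic = if (is_converged(cand)) cand$aic else NA_real_,
          bic = if (is_converged(cand)) cand$bic else NA_real_)
      }
    }
    curves <- lapply(Filter(is_converged, fits), predict, times = grid)
    res <- list(arm = a, fits = fits, ic_table = do.call(rbind, ic),
                curves = curves)
    if (!is.null(late_arms) && !is.null(late_arms[[a]]))
      res$late_hazard <- smoothed_hazard(late_arms[[a]])
    res
  })
  names(out) <- names(arms)
  structure(out, class = "case_study")
}
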