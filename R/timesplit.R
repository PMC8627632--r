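# Piecewise-exponential device: expand right-censored subjects into
# interval rows (exposure + event count), so that hazard-scale regressions
# can be fitted as Poisson models with a log-exposure offset.

#' @importFrom survival Surv
NULL

#' Split subjects at cut points
#'
#' Expands each subject into one row per traversed interval, with the
#' exposure (time at risk) in that interval and the event indicator placed
#' in the final interval.  Exposure and event totals are conserved.
#'
#' @param data A [survival_data()] frame.
#' @param cut_points Strictly increasing positive interior cut times.
#' @return A data frame of class `time_split` with columns `id`, `start`,
#'   `stop`, `exposure`, `event`, `tmid` (interval midpoint).
#' @examples
#' d <- survival_data(1.5, 1)
#' split_time(d, 1)
#' @export
split_time <- function(data, cut_points) {
  stopifnot(nrow(data) > 0)
  cut_points <- as.numeric(cut_points)
  if (any(cut_points <= 0)) stop("cut points must be positive")
  if (is.unsorted(cut_points, strictly = TRUE))
    stop("cut points must be strictly increasing with no duplicates")
  df <- data.frame(id = seq_len(nrow(data)), time = data$time,
                   event = data$event)
  sp <- survival::survSplit(Surv(time, event) ~ .,
                            data = df, cut = cut_points,
                            start = "start", end = "stop")
  out <- data.frame(id = sp$id, start = sp$start, stop = sp$stop,
                    exposure = sp$stop - sp$start, event = sp$event,
                    tmid = (sp$start + sp$stop) / 2)
  out <- out[order(out$id, out$start), ]
  rownames(out) <- NULL
  class(out) <- c("time_split", "data.frame")
  out
}

# Aggregate subject-interval rows to one row per interval (the sufficient
# statistic for time-only hazard regressions).
aggregate_intervals <- function(splits, breaks) {
  k <- findInterval(splits$start, breaks, rightmost.closed = FALSE) + 1L
  K <- length(breaks) + 1L
  events <- tapply(splits$event, factor(k, levels = seq_len(K)), sum)
  expo <- tapply(splits$exposure, factor(k, levels = seq_len(K)), sum)
  events[is.na(events)] <- 0
  expo[is.na(expo)] <- 0
  lo <- c(0, breaks)
  hi <- c(breaks, max(splits$stop))
  out <- data.frame(interval = seq_len(K), start = lo, stop = hi,
                    tmid = (lo + hi) / 2,
                    events = as.numeric(events),
                    exposure = as.numeric(expo))
  out[out$exposure > 0, , drop = FALSE]
}

# Log-uniform (geometric) piecewise-exponential table over (0, upper].
# The split grid is equal-width in log-time from well below the first
# observed time up to the end of follow-up: the fitted model classes are
# all functions of log t, and a grid uniform in log t makes the Poisson
# device's representative-time approximation (geometric interval
# midpoints; log-mean hi/e for the initial (0, lo] piece) second-order
# accurate where an equal-width grid is badly biased near t = 0.
pe_table <- function(data, n_intervals, upper = NULL, floor_frac = 1e-3) {
  if (is.null(upper)) upper <- max(data$time)
  lo <- min(data$time) * floor_frac
  breaks <- exp(seq(log(lo), log(upper),
                    length.out = n_intervals))[-n_intervals]
  pe <- aggregate_intervals(split_time(data, breaks), breaks)
  pe$tref <- ifelse(pe$start == 0, pe$stop / exp(1),
                    sqrt(pe$start * pe$stop))
  pe
}

#' Discretise a dataset onto an equal-width interval grid
#'
#' Partitions (0, follow-up] into intervals of equal width and returns the
#' per-interval event counts and total exposure (occurrence/exposure data),
#' the observation layer of the dynamic survival models.  Exposure and
#' event totals are conserved.
#'
#' @param data A [survival_data()] frame.
#' @param interval_width Interval width in years (> 0, not exceeding the
#'   follow-up limit).
#' @param follow_up Upper limit of the grid; defaults to the dataset's
#'   administrative censoring time, or the maximum observed time.
#' @return A data frame of class `interval_data` with columns `interval`,
#'   `start`, `stop`, `tmid`, `events`, `exposure`.
#' @export
discretise <- function(data, interval_width, follow_up = NULL) {
  stopifnot(interval_width > 0)
  if (is.null(follow_up)) follow_up <- attr(data, "follow_up") %||% max(data$time)
  if (interval_width > follow_up)
    stop("'interval_width' exceeds the follow-up limit")
  K <- ceiling(follow_up / interval_width - 1e-9)
  breaks <- interval_width * seq_len(K - 1L)
  out <- aggregate_intervals(split_time(data, breaks), breaks)
  out$stop[nrow(out)] <- min(out$stop[nrow(out)], K * interval_width)
  out$tmid <- (out$start + out$stop) / 2
  class(out) <- c("interval_data", "data.frame")
  attr(out, "interval_width") <- interval_width
  attr(out, "follow_up") <- follow_up
  out
}
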