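#' Construct a two-arm survival dataset
#'
#' Bundles per-subject follow-up times, event indicators and arm
#' indicators into a validated data frame of class `survival_dataset`.
#' Times are in years throughout the package.  The event flag uses the
#' convention `event = 1` for an observed event and `event = 0` for
#' right censoring (note that some sources code a *censoring* indicator
#' instead; such data must be recoded as `event = 1 - delta` on input).
#'
#' @param time Positive follow-up times in years.
#' @param event Binary event indicators (1 = event, 0 = censored).
#' @param arm Binary arm indicators (0 = control/placebo, 1 = treated).
#' @param label Optional free-text label for the dataset.
#' @param require_two_arms If `TRUE` (default), both arms must be present.
#' @return A data frame with columns `time`, `event`, `arm` and class
#'   `survival_dataset`.
#' @examples
#' ds <- survival_dataset(time = c(1, 2, 3), event = c(1, 0, 1),
#'                        arm = c(0, 1, 0))
#' summarize_arm(ds, 0)
#' @export
survival_dataset <- function(time, event, arm, label = "",
                             require_two_arms = TRUE) {
  n <- length(time)
  if (n == 0L)
    stop("dataset is empty", call. = FALSE)
  if (length(event) != n || length(arm) != n)
    stop("'time', 'event' and 'arm' must have equal length", call. = FALSE)
  time <- as.numeric(time)
  bad <- which(!is.finite(time) | time <= 0)
  if (length(bad))
    stop("non-positive or missing time in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)
  event <- as.integer(event)
  arm <- as.integer(arm)
  if (anyNA(event) || !all(event %in% c(0L, 1L)))
    stop("'event' must be 0/1", call. = FALSE)
  if (anyNA(arm) || !all(arm %in% c(0L, 1L)))
    stop("'arm' must be 0/1", call. = FALSE)
  if (require_two_arms) {
    if (length(unique(arm)) < 2L)
      stop("both arms must be present for a two-arm fit", call. = FALSE)
    if (sum(event) == 0L)
      stop("dataset contains no events", call. = FALSE)
  }
  out <- data.frame(time = time, event = event, arm = arm)
  attr(out, "label") <- as.character(label)
  class(out) <- c("survival_dataset", "data.frame")
  out
}

#' Read individual-patient survival data from CSV
#'
#' Reads a header CSV with one row per subject and maps its columns to
#' the internal `time`/`event`/`arm` scheme.  Times must be positive;
#' an input on a day or month scale can be converted with `time_scale`
#' (observed time is divided by it, e.g. `time_scale = 365.25` for days).
#'
#' @param path Path to a CSV file with a header row.
#' @param column_map Named character vector mapping internal names to
#'   file column names, default `c(time = "time", event = "event",
#'   arm = "arm")`.  Partial maps are merged with the default.
#' @param time_scale Divisor applied to the time column (default 1).
#' @param label Dataset label; defaults to the file name.
#' @param event_is_censoring Set `TRUE` if the mapped event column codes
#'   censoring = 1 (it is complemented on input).
#' @return A [survival_dataset()].
#' @export
read_ipd_csv <- function(path,
                         column_map = c(time = "time", event = "event",
                                        arm = "arm"),
                         time_scale = 1, label = basename(path),
                         event_is_censoring = FALSE) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  cmap <- c(time = "time", event = "event", arm = "arm")
  cmap[names(column_map)] <- column_map
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(cmap), names(raw))
  if (length(missing_cols))
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ev <- raw[[cmap[["event"]]]]
  if (event_is_censoring) ev <- 1L - as.integer(ev)
  survival_dataset(time = raw[[cmap[["time"]]]] / time_scale,
                   event = ev, arm = raw[[cmap[["arm"]]]],
                   label = label)
}

#' Write individual-patient survival data to CSV
#'
#' Inverse of [read_ipd_csv()] with default column names; round-trips a
#' dataset exactly (times written at full precision).
#'
#' @param ds A [survival_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ipd_csv <- function(ds, path) {
  stopifnot(inherits(ds, "survival_dataset"))
  utils::write.csv(format(as.data.frame(ds), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize one arm of a survival dataset
#'
#' @param ds A [survival_dataset()].
#' @param arm 0 or 1.
#' @return A list of class `arm_summary` with `n`, `events`,
#'   `person_years` and the occurrence/exposure `rate`
#'   (events per person-year; the exponential-model hazard estimate).
#' @export
summarize_arm <- function(ds, arm) {
  stopifnot(inherits(ds, "survival_dataset"))
  arm <- as.integer(arm)
  idx <- ds$arm == arm
  if (!any(idx))
    stop("arm ", arm, " not present in dataset", call. = FALSE)
  py <- sum(ds$time[idx])
  out <- list(arm = arm, n = sum(idx), events = sum(ds$event[idx]),
              person_years = py, rate = sum(ds$event[idx]) / py)
  class(out) <- "arm_summary"
  out
}

#' @export
print.arm_summary <- function(x, ...) {
  cat(sprintf("arm %d: n = %d, events = %d, person-years = %.1f, rate = %.5f /PY\n",
              x$arm, x$n, x$events, x$person_years, x$rate))
  invisible(x)
}

#' @export
print.survival_dataset <- function(x, ...) {
  lab <- attr(x, "label")
  cat("Two-arm survival dataset",
      if (nzchar(lab)) paste0(" '", lab, "'") else "", "\n", sep = "")
  for (a in sort(unique(x$arm))) print(summarize_arm(x, a))
  invisible(x)
}
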