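#' Load a slide view log
#'
#' Reads a CSV view log with columns \code{user_id, slide_id, timestamp}
#' (ISO-8601, e.g. \code{2010-03-02T10:15:00}; a space separator is also
#' accepted). Every row must parse: a malformed timestamp raises an error
#' naming the offending line number(s).
#'
#' @param file CSV path.
#' @param tz timezone for parsing (default \code{"UTC"}).
#' @return \code{data.frame(user_id, slide_id, timestamp)} with POSIXct
#'   timestamps, one row per view event.
#' @export
loadViewlog <- function(file, tz = "UTC") {
  df <- utils::read.csv(file, colClasses = "character")
  need <- c("user_id", "slide_id", "timestamp")
  if (!all(need %in% names(df)))
    stopInvalid("view log must have columns ", paste(need, collapse = ", "))
  raw <- gsub("T", " ", df$timestamp, fixed = TRUE)
  ts <- as.POSIXct(raw, tz = tz, format = "%Y-%m-%d %H:%M:%S")
  # minute resolution logs may omit seconds
  miss <- is.na(ts)
  ts[miss] <- as.POSIXct(raw[miss], tz = tz, format = "%Y-%m-%d %H:%M")
  if (anyNA(ts)) {
    bad <- which(is.na(ts)) + 1L   # +1 for the header line
    stop("malformed timestamp(s) on line(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...", call. = FALSE)
  }
  data.frame(user_id = df$user_id, slide_id = df$slide_id, timestamp = ts)
}

todMinutes <- function(timestamp) {
  lt <- as.POSIXlt(timestamp)
  lt$hour * 60 + lt$min + lt$sec / 60
}

#' Views per hour of day
#'
#' @param events view-event \code{data.frame} from [loadViewlog()] or
#'   [synthViewlog()].
#' @return integer vector of length 24: event counts by hour of day (0-23).
#' @export
hourlyCounts <- function(events) {
  hr <- as.POSIXlt(events$timestamp)$hour
  tabulate(hr + 1L, 24L)
}

#' Share of views inside a daily time window
#'
#' Counts events whose time of day falls in the half-open window
#' \code{[start, end)} -- an event at exactly the window end is outside.
#' Percentages are rounded half away from zero at the requested number of
#' decimals, the convention that reproduces course-report figures such as
#' 53\% in-lab / 47\% out-of-lab.
#'
#' @inheritParams hourlyCounts
#' @param window character vector \code{c(start, end)} as \code{"HH:MM"};
#'   default the laboratory hours \code{c("10:00", "12:00")}.
#' @param decimals decimals for the reported percentages (default 0).
#' @return list with \code{in_count}, \code{out_count}, \code{total},
#'   \code{in_pct}, \code{out_pct}, \code{hourly_counts}.
#' @export
windowShare <- function(events, window = c("10:00", "12:00"), decimals = 0) {
  start <- parseHM(window[1]); end <- parseHM(window[2])
  if (start >= end)
    stopInvalid("window start must precede window end within one day")
  tod <- todMinutes(events$timestamp)
  inw <- sum(tod >= start & tod < end)
  total <- nrow(events)
  if (!total) stopInvalid("no events")
  list(in_count = inw, out_count = total - inw, total = total,
       in_pct = roundHalfAway(100 * inw / total, decimals),
       out_pct = roundHalfAway(100 * (total - inw) / total, decimals),
       hourly_counts = hourlyCounts(events))
}

#' Per-student view statistics
#'
#' Views (and unique slides viewed) per student over the log, with the
#' sample standard deviation (n - 1 denominator). Students on a supplied
#' roster with no events count as zero; without a roster only students
#' appearing in the log are counted.
#'
#' @inheritParams hourlyCounts
#' @param roster optional character vector of all enrolled student ids.
#' @return list with \code{n_students}, \code{total_views},
#'   \code{mean_views}, \code{sd_views}, \code{min_views}, \code{max_views},
#'   \code{mean_unique_slides} and the per-student table \code{per_student}.
#' @export
perStudentStats <- function(events, roster = NULL) {
  if (!nrow(events) && is.null(roster))
    stop("no events and no roster: statistics are undefined", call. = FALSE)
  users <- if (is.null(roster)) sort(unique(events$user_id))
           else sort(unique(roster))
  views <- as.integer(table(factor(events$user_id, levels = users)))
  uniq <- vapply(users, function(u)
    length(unique(events$slide_id[events$user_id == u])), 0L)
  list(
    n_students = length(users),
    total_views = nrow(events),
    mean_views = mean(views),
    sd_views = stats::sd(views),
    min_views = min(views),
    max_views = max(views),
    mean_unique_slides = mean(uniq),
    per_student = data.frame(user_id = users, views = views,
                             unique_slides = uniq))
}

#' Estimate per-view dwell times from a view log
#'
#' View logs record when a slide was opened, not for how long it was read,
#' so dwell is estimated by sessionization: a view's duration is the gap to
#' the same user's next event, capped at \code{cap} minutes (a long gap
#' means the user walked away, not that they stared at one slide for hours).
#' Each user's final event -- which has no following gap -- is filled with
#' the median of that user's capped gaps; users with a single event are
#' excluded.
#'
#' @inheritParams hourlyCounts
#' @param cap maximum credited dwell per view, in minutes (default 30).
#' @return list with \code{durations} (data.frame user_id, slide_id,
#'   timestamp, duration_min), \code{mean_seconds}, \code{mean_mmss},
#'   \code{median_seconds}.
#' @export
estimateDurations <- function(events, cap = 30) {
  if (cap <= 0) stopInvalid("cap must be positive minutes")
  ev <- events[order(events$user_id, events$timestamp), , drop = FALSE]
  parts <- split(seq_len(nrow(ev)), ev$user_id)
  dur <- rep(NA_real_, nrow(ev))
  for (idx in parts) {
    if (length(idx) < 2L) next
    gaps <- as.numeric(diff(ev$timestamp[idx]), units = "mins")
    gaps <- pmin(gaps, cap)
    dur[idx] <- c(gaps, stats::median(gaps))
  }
  keep <- !is.na(dur)
  out <- ev[keep, , drop = FALSE]
  out$duration_min <- dur[keep]
  rownames(out) <- NULL
  secs <- out$duration_min * 60
  list(durations = out,
       mean_seconds = mean(secs),
       mean_mmss = formatMMSS(mean(secs)),
       median_seconds = stats::median(secs))
}

#' Marker authorship split between faculty and students
#'
#' @param markers an [AnnotationStore-class] or a marker \code{data.frame}
#'   with an \code{author_role} column.
#' @param decimals decimals for the percentages (default 1, half away from
#'   zero).
#' @return list with \code{n_total}, \code{n_faculty}, \code{n_student},
#'   \code{faculty_pct}, \code{student_pct}.
#' @examples
#' authorshipShare(data.frame(author_role = rep(c("faculty", "student"),
#'                                              c(163, 458))))
#' @export
authorshipShare <- function(markers, decimals = 1) {
  if (is(markers, "AnnotationStore")) markers <- markers@markers
  role <- markers$author_role
  nf <- sum(role == "faculty"); ns <- sum(role == "student")
  n <- nf + ns
  list(n_total = n, n_faculty = nf, n_student = ns,
       faculty_pct = if (n) roundHalfAway(100 * nf / n, decimals) else NA,
       student_pct = if (n) roundHalfAway(100 * ns / n, decimals) else NA)
}

#' Faculty precepting-hours accounting
#'
#' Total precepting time for a course: number of laboratory sessions times
#' preceptors per session times session length. \code{preceptingSaving}
#' reports the before/after pair and their difference, e.g. shortening
#' 15 sessions taught by 14 preceptors from 3 to 2 hours saves 210 hours a
#' year.
#'
#' @param sessions number of laboratory sessions per year.
#' @param preceptors faculty preceptors per session.
#' @param hoursPerSession session length in hours.
#' @return total faculty hours.
#' @examples
#' preceptingHours(15, 14, 3)            # 630
#' preceptingSaving(15, 14, 3, 2)        # saved 210
#' @export
preceptingHours <- function(sessions, preceptors, hoursPerSession) {
  if (any(c(sessions, preceptors, hoursPerSession) <= 0))
    stopInvalid("sessions, preceptors and hoursPerSession must be positive")
  sessions * preceptors * hoursPerSession
}

#' @rdname preceptingHours
#' @param hoursBefore,hoursAfter session length before and after the change.
#' @return \code{preceptingSaving} returns \code{list(before, after, saved)}.
#' @export
preceptingSaving <- function(sessions, preceptors, hoursBefore, hoursAfter) {
  before <- preceptingHours(sessions, preceptors, hoursBefore)
  after <- preceptingHours(sessions, preceptors, hoursAfter)
  list(before = before, after = after, saved = before - after)
}

#' Welch two-sample t-test from summary statistics
#'
#' Compares two cohorts from their printed mean, SD and n alone -- no raw
#' scores needed -- using the unequal-variance (Welch) statistic
#' \deqn{t = (m_1 - m_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}}
#' with Welch-Satterthwaite degrees of freedom, a two-sided p-value and a
#' confidence interval for the mean difference. Useful for comparing exam
#' cohorts across course years when only summary statistics were archived.
#'
#' @param mean1,sd1,n1 first cohort's mean, sample SD and size (n >= 2).
#' @param mean2,sd2,n2 second cohort.
#' @param conf.level confidence level for the interval (default 0.95).
#' @return an object of class \code{"htest"} with \code{statistic} (t),
#'   \code{parameter} (df), \code{p.value}, \code{conf.int} and
#'   \code{estimate}.
#' @examples
#' welchFromSummary(80.1, 5.38, 165, 81.8, 11.9, 164)
#' @export
welchFromSummary <- function(mean1, sd1, n1, mean2, sd2, n2,
                             conf.level = 0.95) {
  if (n1 < 2 || n2 < 2) stopInvalid("both cohorts need n >= 2")
  if (sd1 < 0 || sd2 < 0) stopInvalid("standard deviations must be >= 0")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  se2 <- v1 + v2
  if (se2 == 0) {
    if (mean1 == mean2)
      stop("t is undefined: both cohorts have zero variance and equal means",
           call. = FALSE)
    stop("t is undefined: both cohorts have zero variance", call. = FALSE)
  }
  tstat <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  tcrit <- stats::qt(1 - (1 - conf.level) / 2, df)
  ci <- (mean1 - mean2) + c(-1, 1) * tcrit * sqrt(se2)
  attr(ci, "conf.level") <- conf.level
  structure(list(
    statistic = c(t = tstat),
    parameter = c(df = df),
    p.value = p,
    conf.int = ci,
    estimate = c(`mean difference` = mean1 - mean2),
    method = "Welch two-sample t-test from summary statistics",
    data.name = sprintf("cohort 1 (n=%d) vs cohort 2 (n=%d)", n1, n2),
    alternative = "two.sided"
  ), class = "htest")
}
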