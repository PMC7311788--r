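# Julian-date phenology on a fixed non-leap 365-day calendar. The month-level
# flowering/fruiting windows of floras are converted to a mean date (midpoint
# of the window, rounded half up) and a duration (day span of the window).

.month_days <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.month_end <- cumsum(.month_days)
.month_start <- .month_end - .month_days + 1L

#' Julian day of the first or last day of a month
#'
#' Day-of-year in a non-leap 365-day year: August starts on day 213 and
#' October ends on day 304.
#'
#' @param month Month index 1-12 (vectorized).
#' @param which `"first"` or `"last"` day of the month.
#' @return Integer day-of-year in 1..365.
#' @export
julian_day <- function(month, which = c("first", "last")) {
  which <- match.arg(which)
  if (any(!is.finite(month)) || any(month != as.integer(month)) ||
      any(month < 1) || any(month > 12))
    stop("month must be an integer in 1..12")
  if (which == "first") .month_start[month] else .month_end[month]
}

#' Mean time and duration of a phenology window
#'
#' A species in flower from month `first_month` through `last_month` spans
#' Julian days `julian_day(first_month, "first")` to
#' `julian_day(last_month, "last")`. The mean time is the midpoint of that
#' span rounded half up to an integer day (August-October: (213 + 304)/2 =
#' 258.5, reported as 259) and the duration is the day span (304 - 213 = 91).
#'
#' Windows with `last_month < first_month` denote cross-year phenology
#' (e.g. flowering November through February). These are refused unless
#' `allow_wraparound = TRUE`, in which case the window is unrolled across the
#' year boundary: duration is measured across the wrap and the mean time is
#' mapped back into 1..365.
#'
#' @param first_month,last_month Month indices 1-12 (vectorized).
#' @param allow_wraparound Permit windows that wrap across the year boundary.
#' @return Data frame with integer columns `mean_time` (Julian day) and
#'   `duration` (days).
#' @export
phenology_stats <- function(first_month, last_month, allow_wraparound = FALSE) {
  jd_first <- julian_day(first_month, "first")
  jd_last <- julian_day(last_month, "last")
  wrapped <- last_month < first_month
  if (any(wrapped) && !allow_wraparound)
    stop("cross-year phenology window (last month before first); ",
         "set allow_wraparound = TRUE to unroll it")
  jd_last <- ifelse(wrapped, jd_last + 365L, jd_last)
  mean_time <- floor((jd_first + jd_last) / 2 + 0.5)
  mean_time <- ifelse(mean_time > 365L, mean_time - 365L, mean_time)
  data.frame(mean_time = as.integer(mean_time),
             duration = as.integer(jd_last - jd_first))
}
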