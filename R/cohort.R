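#' Add whole calendar months to a date
#'
#' Day-of-month is preserved, clamped to the last day of shorter target
#' months (e.g. Jan 31 + 1 month -> Feb 28/29).
#'
#' @param date A `Date` (or coercible) vector.
#' @param k Integer number of months (may be negative); recycled.
#' @return A `Date` vector.
#' @export
add_months <- function(date, k) {
  lt <- as.POSIXlt(as.Date(date))
  n <- max(length(lt$mday), length(k))
  day <- rep_len(lt$mday, n)
  m0 <- rep_len(lt$year * 12L + lt$mon, n) + rep_len(as.integer(k), n)
  y <- m0 %/% 12L + 1900L
  m <- m0 %% 12L + 1L
  last <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[m]
  leap <- (y %% 4L == 0L & y %% 100L != 0L) | y %% 400L == 0L
  last[m == 2L & leap] <- 29L
  as.Date(sprintf("%04d-%02d-%02d", y, m, pmin(day, last)))
}

#' Whole months elapsed between two dates
#'
#' Largest integer `k >= 0` such that `add_months(from, k) <= to`.
#'
#' @param from,to Dates with `from <= to`.
#' @return Integer month count.
#' @export
months_between <- function(from, to) {
  from <- as.Date(from)
  to <- as.Date(to)
  if (to < from) stop("'to' must not precede 'from'", call. = FALSE)
  lf <- as.POSIXlt(from)
  lt <- as.POSIXlt(to)
  k <- (lt$year - lf$year) * 12L + (lt$mon - lf$mon)
  while (add_months(from, k) > to) k <- k - 1L
  while (add_months(from, k + 1L) <= to) k <- k + 1L
  as.integer(k)
}

#' Default acuity-circle policy calendar
#'
#' Implementation dates of the acuity-circle allocation policy per organ
#' (lung 2017-11-24, heart 2018-10-18, liver 2020-02-04, kidney 2021-03-15)
#' and the study end date (2023-11-30). Shipped as a YAML config so real
#' runs can override it.
#'
#' @param path Optional path to a YAML file with fields `implementation`
#'   (named organ -> date map) and `study_end`.
#' @return A list with elements `implementation` (named `Date` vector) and
#'   `study_end` (`Date`).
#' @export
default_policy_calendar <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "policy_calendar.yaml",
                        package = "organmiles", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  impl <- vapply(raw$implementation, as.character, character(1))
  cal <- list(
    implementation = stats::setNames(as.Date(unname(impl)), names(impl)),
    study_end = as.Date(raw$study_end)
  )
  if (any(cal$implementation >= cal$study_end))
    stop("every implementation date must precede the study end", call. = FALSE)
  cal
}

#' Construct an observation window around a policy implementation date
#'
#' The post period length is the number of whole months elapsed from the
#' implementation date to the study end; the pre period has the same number
#' of months, so the window is equidistant around the implementation date.
#' Monthly bins are anchored at the implementation day-of-month; the first
#' post bin starts on the implementation date itself (a transplant on that
#' date is post, `elapsed_post = 0`) and the final bin absorbs the partial
#' month up to the study end.
#'
#' @param implementation_date,study_end Dates bounding the post period.
#' @param organ Optional organ label carried in the window.
#' @return An object of class `obs_window`: list with `organ`,
#'   `window_start`, `implementation_date`, `window_end`, `n_pre_months`,
#'   `n_post_months`, and `bin_starts` (Date vector of length
#'   `n_pre_months + n_post_months`).
#' @export
window_from_dates <- function(implementation_date, study_end, organ = NA_character_) {
  impl <- as.Date(implementation_date)
  end <- as.Date(study_end)
  if (impl >= end) stop("implementation date must precede the study end", call. = FALSE)
  n <- months_between(impl, end)
  if (n < 2L) stop("window too short: need at least 2 months per segment", call. = FALSE)
  bin_starts <- add_months(impl, seq.int(-n, n - 1L))
  structure(list(
    organ = organ,
    window_start = bin_starts[1L],
    implementation_date = impl,
    window_end = end,
    n_pre_months = n,
    n_post_months = n,
    bin_starts = bin_starts
  ), class = "obs_window")
}

#' @rdname window_from_dates
#' @param calendar Policy calendar as from [default_policy_calendar()].
#' @export
build_window <- function(organ, calendar = default_policy_calendar()) {
  if (!organ %in% names(calendar$implementation))
    stop("organ '", organ, "' not in policy calendar", call. = FALSE)
  window_from_dates(calendar$implementation[[organ]], calendar$study_end,
                    organ = organ)
}

#' @export
print.obs_window <- function(x, ...) {
  cat(sprintf(
    "Observation window%s: %s .. [%s] .. %s (%d pre + %d post months)\n",
    if (is.na(x$organ)) "" else paste0(" [", x$organ, "]"),
    format(x$window_start), format(x$implementation_date),
    format(x$window_end), x$n_pre_months, x$n_post_months
  ))
  invisible(x)
}

#' Map dates to monthly bin indices within a window
#'
#' @param dates Dates (or coercible).
#' @param window An `obs_window`.
#' @return Integer bin index in `1..(n_pre + n_post)`; `NA` outside the
#'   window.
#' @export
month_index <- function(dates, window) {
  d <- as.Date(dates)
  idx <- findInterval(as.numeric(d), as.numeric(window$bin_starts))
  idx[idx < 1L | d > window$window_end] <- NA_integer_
  as.integer(idx)
}

#' Apply cohort exclusion filters
#'
#' Keeps deceased-donor records with a non-missing transplant center ID
#' whose transplant date falls inside the observation window. Exclusion
#' reasons are applied in order (living donor, then missing center ID, then
#' window membership) and each record is tallied under the first matching
#' reason.
#'
#' @param records Data frame of transplant records.
#' @param window An `obs_window`.
#' @return A list with `records` (kept rows), `tally` (named counts:
#'   `living`, `missing_center_id`), `n_out_of_window`, and `n_kept`.
#' @export
filter_cohort <- function(records, window) {
  living <- !is.na(records$donor_type) & records$donor_type == "living"
  miss_ctr <- !living & (is.na(records$center_id) | records$center_id == "")
  d <- as.Date(records$transplant_date)
  in_win <- d >= window$window_start & d <= window$window_end
  keep <- !living & !miss_ctr & in_win
  list(
    records = records[keep, , drop = FALSE],
    tally = c(living = sum(living), missing_center_id = sum(miss_ctr)),
    n_out_of_window = sum(!living & !miss_ctr & !in_win),
    n_kept = sum(keep)
  )
}
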