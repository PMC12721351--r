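#' Aggregate resolved trips into a monthly mean-distance series
#'
#' Computes the arithmetic mean trip distance and procurement count for each
#' monthly bin of the observation window. Months without trips carry `NA`
#' mean and count 0; they are retained in the series but excluded from the
#' segmented-regression fit.
#'
#' @param trips Data frame of resolved trips (needs `transplant_date` and
#'   `distance_miles`; see [resolve_trips()]).
#' @param window An `obs_window`.
#' @return A `monthly_series`: data.frame with columns `month` (bin index
#'   1..T), `bin_start`, `mean_distance`, `n_procurements`, `is_post`, and
#'   `elapsed_post` (months since implementation, 0 in the implementation
#'   month), with the window attached as attribute `"window"`.
#' @export
aggregate_monthly <- function(trips, window) {
  m <- month_index(trips$transplant_date, window)
  if (anyNA(m)) {
    warning(sum(is.na(m)), " trip(s) outside the window were dropped")
    trips <- trips[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
  }
  T_ <- window$n_pre_months + window$n_post_months
  if (length(m) == 0L) stop("no trips fall inside the window", call. = FALSE)
  n_m <- tabulate(m, nbins = T_)
  mean_m <- rep(NA_real_, T_)
  sums <- vapply(split(trips$distance_miles, factor(m, levels = seq_len(T_))),
                 sum, numeric(1))
  mean_m[n_m > 0L] <- sums[n_m > 0L] / n_m[n_m > 0L]
  is_post <- seq_len(T_) > window$n_pre_months
  out <- data.frame(
    month = seq_len(T_),
    bin_start = window$bin_starts,
    mean_distance = mean_m,
    n_procurements = n_m,
    is_post = is_post,
    elapsed_post = ifelse(is_post, seq_len(T_) - window$n_pre_months - 1L, 0L)
  )
  attr(out, "window") <- window
  class(out) <- c("monthly_series", "data.frame")
  out
}

#' Fit an interrupted time series (segmented regression) to monthly means
#'
#' Ordinary least squares of monthly mean trip distance on
#' `1 + month + post + post * elapsed_post`, i.e. the standard
#' level-and-slope-change segmented regression around a known interruption.
#' Coefficients are reported as `intercept`, `pre_slope` (miles/month),
#' `level_change` (miles, the jump at the start of the post segment) and
#' `slope_change` (miles/month); the post-segment slope
#' `pre_slope + slope_change` is reported alongside so either reading of a
#' "post trend" is inspectable.
#'
#' @param series A `monthly_series` from [aggregate_monthly()] (or any data
#'   frame with `month`, `mean_distance`, `n_procurements`, `is_post`,
#'   `elapsed_post`).
#' @param weighted If `TRUE`, weight months by procurement count; default
#'   `FALSE` (unweighted fit to monthly means).
#' @param robust If `TRUE`, p-values use heteroskedasticity-robust (HC1)
#'   standard errors via the sandwich/lmtest packages; coefficients are
#'   unchanged.
#' @return An object of class `its_fit` with components `coefficients`
#'   (named vector), `post_slope`, `p_level`, `p_slope` (p-value of the
#'   slope-change coefficient), `sigma2`, the underlying `lm` fit, and the
#'   series.
#' @seealso [counterfactual_excess()], [predict.its_fit()]
#' @export
fit_its <- function(series, weighted = FALSE, robust = FALSE) {
  d <- series[series$n_procurements > 0 & !is.na(series$mean_distance), ,
              drop = FALSE]
  d <- as.data.frame(d)
  if (sum(!d$is_post) < 2L || sum(d$is_post) < 2L)
    stop("need at least 2 observed months in each segment", call. = FALSE)
  d$post <- as.numeric(d$is_post)
  d$post_trend <- d$post * d$elapsed_post
  fit <- if (weighted) {
    stats::lm(mean_distance ~ month + post + post_trend, data = d,
              weights = d$n_procurements)
  } else {
    stats::lm(mean_distance ~ month + post + post_trend, data = d)
  }
  ct <- if (robust) {
    if (!requireNamespace("sandwich", quietly = TRUE) ||
        !requireNamespace("lmtest", quietly = TRUE))
      stop("robust = TRUE needs the 'sandwich' and 'lmtest' packages",
           call. = FALSE)
    lmtest::coeftest(fit, vcov. = sandwich::vcovHC(fit, type = "HC1"))
  } else {
    summary(fit)$coefficients
  }
  co <- stats::coef(fit)
  out <- list(
    coefficients = c(
      intercept = unname(co[["(Intercept)"]]),
      pre_slope = unname(co[["month"]]),
      level_change = unname(co[["post"]]),
      slope_change = unname(co[["post_trend"]])
    ),
    post_slope = unname(co[["month"]] + co[["post_trend"]]),
    p_level = unname(ct["post", 4]),
    p_slope = unname(ct["post_trend", 4]),
    sigma2 = summary(fit)$sigma^2,
    weighted = weighted,
    robust = robust,
    lm = fit,
    series = series
  )
  class(out) <- "its_fit"
  out
}

#' @export
coef.its_fit <- function(object, ...) object$coefficients

#' @export
print.its_fit <- function(x, digits = 4, ...) {
  co <- x$coefficients
  cat("Interrupted time series fit (monthly mean trip distance, miles)\n")
  cat(sprintf("  intercept      %10.*f\n", digits, co["intercept"]))
  cat(sprintf("  pre slope      %10.*f mi/month\n", digits, co["pre_slope"]))
  cat(sprintf("  level change   %10.*f mi      (p = %.3g)\n",
              digits, co["level_change"], x$p_level))
  cat(sprintf("  slope change   %10.*f mi/month (p = %.3g)\n",
              digits, co["slope_change"], x$p_slope))
  cat(sprintf("  post slope     %10.*f mi/month\n", digits, x$post_slope))
  invisible(x)
}

#' @export
summary.its_fit <- function(object, ...) {
  s <- summary(object$lm)
  out <- list(
    coefficients = s$coefficients,
    post_slope = object$post_slope,
    sigma = s$sigma,
    r.squared = s$r.squared,
    weighted = object$weighted,
    robust = object$robust
  )
  class(out) <- "summary.its_fit"
  out
}

#' @export
print.summary.its_fit <- function(x, ...) {
  cat("Segmented regression on monthly mean distance\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("post-segment slope: %.4f mi/month; sigma = %.3f; R^2 = %.3f\n",
              x$post_slope, x$sigma, x$r.squared))
  invisible(x)
}

#' Predicted monthly means from an ITS fit
#'
#' @param object An `its_fit`.
#' @param newdata A `monthly_series`-like data frame (defaults to the fitted
#'   series).
#' @param counterfactual If `TRUE`, extrapolate the pre-period trend only
#'   (`intercept + pre_slope * month`), ignoring the level and slope
#'   changes.
#' @param ... Unused.
#' @return Numeric vector of predicted mean distances.
#' @export
predict.its_fit <- function(object, newdata = object$series,
                            counterfactual = FALSE, ...) {
  co <- object$coefficients
  mu <- co[["intercept"]] + co[["pre_slope"]] * newdata$month
  if (!counterfactual) {
    e <- ifelse(newdata$is_post, newdata$elapsed_post, 0)
    mu <- mu + as.numeric(newdata$is_post) *
      (co[["level_change"]] + co[["slope_change"]] * e)
  }
  unname(mu)
}

#' @export
residuals.its_fit <- function(object, ...) {
  object$series$mean_distance - predict(object)
}

#' Observed vs counterfactual monthly distance plot
#'
#' Plots the observed monthly mean trip distances with the fitted segmented
#' lines and the dashed counterfactual (pre-trend extrapolation) over the
#' post period.
#'
#' @param x An `its_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.its_fit <- function(x, ...) {
  s <- x$series
  graphics::plot(s$month, s$mean_distance,
                 xlab = "Month of observation window",
                 ylab = "Mean distance per organ (miles)",
                 pch = 16, col = ifelse(s$is_post, "firebrick", "grey30"), ...)
  fitted_mu <- predict(x)
  graphics::lines(s$month[!s$is_post], fitted_mu[!s$is_post], lwd = 2)
  graphics::lines(s$month[s$is_post], fitted_mu[s$is_post], lwd = 2,
                  col = "firebrick")
  cf <- predict(x, counterfactual = TRUE)
  graphics::lines(s$month[s$is_post], cf[s$is_post], lty = 2)
  graphics::abline(v = sum(!s$is_post) + 0.5, col = "grey60", lty = 3)
  graphics::legend("topleft", bty = "n", lwd = c(2, 2, 1),
                   lty = c(1, 1, 2), col = c("grey30", "firebrick", "black"),
                   legend = c("pre fit", "post fit", "counterfactual"))
  invisible(x)
}

#' Counterfactual excess miles after the policy change
#'
#' For every post month, the counterfactual mean distance is the pre-period
#' trend extrapolated (`intercept + pre_slope * month`); the excess is the
#' observed-minus-predicted delta multiplied by that month's procurement
#' count, summed across the post period. Months without procurements
#' contribute zero excess.
#'
#' @param series A `monthly_series`.
#' @param fit The `its_fit` from the same series.
#' @return An object of class `excess_result`: list with `by_month`
#'   (data.frame: `month`, `bin_start`, `observed_mean`, `predicted_mean`,
#'   `delta`, `n_procurements`, `excess_miles`) and `total_excess_miles`.
#' @export
counterfactual_excess <- function(series, fit) {
  post <- series[series$is_post, , drop = FALSE]
  pred <- fit$coefficients[["intercept"]] +
    fit$coefficients[["pre_slope"]] * post$month
  delta <- post$mean_distance - pred
  excess <- ifelse(post$n_procurements > 0 & !is.na(delta),
                   delta * post$n_procurements, 0)
  by_month <- data.frame(
    month = post$month,
    bin_start = post$bin_start,
    observed_mean = post$mean_distance,
    predicted_mean = pred,
    delta = delta,
    n_procurements = post$n_procurements,
    excess_miles = excess
  )
  structure(list(by_month = by_month, total_excess_miles = sum(excess)),
            class = "excess_result")
}

#' @export
print.excess_result <- function(x, ...) {
  cat(sprintf(
    "Counterfactual excess over %d post months: %.0f organ-miles\n",
    nrow(x$by_month), x$total_excess_miles
  ))
  invisible(x)
}
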