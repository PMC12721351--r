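# Shared fixture builders. Everything is generated in code; no stored data.

toy_window <- function(n = 12L) {
  # n pre + n post months around a mid-month implementation date
  window_from_dates(as.Date("2020-01-10"),
                    add_months(as.Date("2020-01-10"), n),
                    organ = "toy")
}

# Hand-built monthly series following the segmented model exactly.
make_series <- function(n_pre = 8L, n_post = 8L,
                        intercept = 200, pre_slope = -0.5,
                        level = 30, slope_change = 2,
                        noise_sd = 0, n_per_month = 10L,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  T_ <- n_pre + n_post
  m <- seq_len(T_)
  is_post <- m > n_pre
  e <- ifelse(is_post, m - n_pre - 1L, 0L)
  mu <- intercept + pre_slope * m + is_post * (level + slope_change * e)
  if (noise_sd > 0) mu <- mu + rnorm(T_, sd = noise_sd)
  out <- data.frame(
    month = m,
    bin_start = as.Date("2019-01-01") + 30 * (m - 1),
    mean_distance = mu,
    n_procurements = rep_len(n_per_month, T_),
    is_post = is_post,
    elapsed_post = e
  )
  class(out) <- c("monthly_series", "data.frame")
  out
}

# Independent normal-equations solve of the same design (the oracle).
normal_eq_fit <- function(series) {
  d <- series[series$n_procurements > 0 & !is.na(series$mean_distance), ]
  X <- cbind(1, d$month, as.numeric(d$is_post),
             as.numeric(d$is_post) * d$elapsed_post)
  as.numeric(solve(t(X) %*% X, t(X) %*% d$mean_distance))
}

# Small cohort spec around toy dates; defaults noise-free with no
# missingness so distances and counts are fully predictable.
toy_spec <- function(n = 6L, volume = 8L, baseline = 150,
                     pre_slope = 0, level = 20, post_slope = 1,
                     trip_noise = 0, seed = 42L, ...) {
  impl <- as.Date("2020-06-15")
  cohort_spec(
    organ = "heart",
    implementation_date = impl,
    study_end = add_months(impl, n),
    monthly_volume = volume,
    baseline_mean_miles = baseline,
    pre_slope_miles_per_month = pre_slope,
    level_change_miles = level,
    post_slope_miles_per_month = post_slope,
    trip_noise = trip_noise,
    seed = seed,
    ...
  )
}

# Run a cohort through distance resolution and monthly aggregation.
cohort_to_series <- function(g) {
  flt <- filter_cohort(g$records, g$window)
  rsv <- resolve_trips(flt$records, g$gazetteer)
  trips <- rsv$trips
  m <- month_index(trips$transplant_date, g$window)
  trips$month <- m
  trips$is_post <- m > g$window$n_pre_months
  list(trips = trips, series = aggregate_monthly(trips, g$window),
       n_unresolved = rsv$n_unresolved)
}
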