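#' Specification of a synthetic transplant cohort
#'
#' Describes the generating segmented (interrupted time-series) model for
#' monthly mean trip distance and the bookkeeping fractions needed to
#' exercise the cohort filters and endpoint-resolution fallbacks. The
#' observation window is derived from `implementation_date` and `study_end`
#' exactly as in [window_from_dates()], so the generator and the fitting
#' code share one time convention.
#'
#' The generating monthly target mean for bin `m = 1..2n` (with `n` pre
#' months) is
#' `baseline + pre_slope * (m - 1)` before implementation and
#' `baseline + pre_slope * (m - 1) + level_change + (post_slope - pre_slope) * e`
#' after, where `e = m - n - 1` is months elapsed since implementation.
#' Individual trip distances are drawn from a gamma distribution with that
#' mean and coefficient of variation `trip_noise` (degenerate at the mean
#' when `trip_noise = 0`).
#'
#' @param organ One of `"heart"`, `"lung"`, `"liver"`, `"kidney"` (other
#'   labels are allowed for toy cohorts).
#' @param implementation_date,study_end Policy implementation date and study
#'   end date.
#' @param monthly_volume Procurements per month (>= 1).
#' @param baseline_mean_miles Target mean trip distance in the first window
#'   month (> 0).
#' @param pre_slope_miles_per_month Pre-period trend.
#' @param level_change_miles Immediate level change at implementation
#'   (signed).
#' @param post_slope_miles_per_month Post-period segment slope (the
#'   slope-change coefficient is `post_slope - pre_slope`).
#' @param trip_noise Coefficient of variation of per-trip distance around
#'   the monthly target mean (>= 0; 0 = noise-free).
#' @param frac_living Fraction of records flagged as living-donor (excluded
#'   by [filter_cohort()]).
#' @param frac_missing_center_id Fraction with a missing transplant center
#'   ID.
#' @param frac_missing_zip Fraction with a missing recipient ZIP but a
#'   resolvable city-state centroid (exercises the fallback).
#' @param frac_unresolvable Fraction with a missing recipient ZIP *and* a
#'   city-state absent from the gazetteer (exercises the resolution-error
#'   path); default 0.
#' @param volume_growth Optional linear ramp in monthly volume
#'   (records/month per month); default 0 (flat).
#' @param bbox Bounding box `c(lat_min, lat_max, lon_min, lon_max)` from
#'   which recipient centroids are drawn uniformly; default a continental-US
#'   -like box.
#' @param seed Integer seed; generation is fully reproducible given the
#'   spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(organ,
                        implementation_date,
                        study_end,
                        monthly_volume,
                        baseline_mean_miles,
                        pre_slope_miles_per_month = 0,
                        level_change_miles = 0,
                        post_slope_miles_per_month = pre_slope_miles_per_month,
                        trip_noise = 0,
                        frac_living = 0,
                        frac_missing_center_id = 0,
                        frac_missing_zip = 0,
                        frac_unresolvable = 0,
                        volume_growth = 0,
                        bbox = c(30, 47, -120, -75),
                        seed = 1L) {
  stopifnot(
    monthly_volume >= 1,
    baseline_mean_miles > 0,
    trip_noise >= 0,
    frac_living >= 0, frac_living < 1,
    frac_missing_center_id >= 0, frac_missing_center_id < 1,
    frac_missing_zip >= 0, frac_missing_zip < 1,
    frac_unresolvable >= 0, frac_unresolvable < 1,
    length(bbox) == 4, bbox[1] < bbox[2], bbox[3] < bbox[4]
  )
  spec <- structure(list(
    organ = organ,
    implementation_date = as.Date(implementation_date),
    study_end = as.Date(study_end),
    monthly_volume = as.integer(monthly_volume),
    baseline_mean_miles = baseline_mean_miles,
    pre_slope_miles_per_month = pre_slope_miles_per_month,
    level_change_miles = level_change_miles,
    post_slope_miles_per_month = post_slope_miles_per_month,
    trip_noise = trip_noise,
    frac_living = frac_living,
    frac_missing_center_id = frac_missing_center_id,
    frac_missing_zip = frac_missing_zip,
    frac_unresolvable = frac_unresolvable,
    volume_growth = volume_growth,
    bbox = bbox,
    seed = as.integer(seed)
  ), class = "cohort_spec")
  w <- window_from_dates(spec$implementation_date, spec$study_end,
                         organ = spec$organ)
  mu <- monthly_targets(spec, w)
  if (any(mu <= 0))
    stop("generating trend crosses zero inside the window; ",
         "adjust baseline or slopes", call. = FALSE)
  spec
}

#' Generating monthly target means for a cohort spec
#'
#' @param spec A [cohort_spec()].
#' @param window Optional pre-built `obs_window` (derived from the spec when
#'   omitted).
#' @return Numeric vector of target mean distances, one per monthly bin.
#' @export
monthly_targets <- function(spec, window = NULL) {
  if (is.null(window)) {
    window <- window_from_dates(spec$implementation_date, spec$study_end,
                                organ = spec$organ)
  }
  n <- window$n_pre_months
  m <- seq_len(n + window$n_post_months)
  post <- m > n
  e <- ifelse(post, m - n - 1L, 0L)
  slope_change <- spec$post_slope_miles_per_month - spec$pre_slope_miles_per_month
  spec$baseline_mean_miles +
    spec$pre_slope_miles_per_month * (m - 1) +
    post * (spec$level_change_miles + slope_change * e)
}

#' Study-condition presets per organ
#'
#' Reported interrupted-time-series parameters and approximate analyzed
#' monthly volumes per organ from the US acuity-circle registry analysis:
#' pre-period mean distance and slope, immediate level change, and
#' post-segment slope (miles/month). For liver the reported post-period
#' coefficient (0.34) is read as the slope-*change* coefficient, giving a
#' post-segment slope of 0.10; for the other organs the reported trend is
#' the post-segment slope itself.
#'
#' @return A data.frame keyed by organ.
#' @export
organ_presets <- function() {
  data.frame(
    organ = c("heart", "lung", "liver", "kidney"),
    pre_mean_miles = c(212, 245, 189, 251),
    pre_slope_miles_per_month = c(-0.54, -0.39, -0.24, -1.72),
    level_change_miles = c(104, -31, 57, 14),
    post_slope_miles_per_month = c(1.56, 3.40, 0.10, 2.71),
    monthly_volume = c(290L, 198L, 712L, 1543L),
    row.names = c("heart", "lung", "liver", "kidney")
  )
}

#' Cohort spec matching an organ's study conditions
#'
#' Builds a [cohort_spec()] whose generating segmented model reproduces the
#' reported per-organ parameters over that organ's policy window: the
#' baseline is chosen so the *average* pre-period target mean equals the
#' reported pre-period mean distance.
#'
#' @param organ One of the four solid organs.
#' @param calendar Policy calendar (see [default_policy_calendar()]).
#' @param trip_noise Per-trip coefficient of variation; default 0.8
#'   (right-skewed variation typical of registry trip distances). Use 0 for
#'   noise-free series.
#' @param monthly_volume Override the preset analyzed monthly volume.
#' @param frac_living,frac_missing_center_id,frac_missing_zip Registry-like
#'   defaults: about 14% living donors, 0.2% missing center IDs and a
#'   handful of missing recipient ZIPs per hundred thousand records, echoing
#'   the reported exclusion and fallback counts.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
preset_cohort_spec <- function(organ,
                               calendar = default_policy_calendar(),
                               trip_noise = 0.8,
                               monthly_volume = NULL,
                               frac_living = 0.14,
                               frac_missing_center_id = 0.002,
                               frac_missing_zip = 5e-5,
                               seed = 1L, ...) {
  p <- organ_presets()
  if (!organ %in% rownames(p)) stop("no preset for organ '", organ, "'", call. = FALSE)
  p <- p[organ, ]
  w <- build_window(organ, calendar)
  baseline <- p$pre_mean_miles -
    p$pre_slope_miles_per_month * (w$n_pre_months - 1) / 2
  cohort_spec(
    organ = organ,
    implementation_date = calendar$implementation[[organ]],
    study_end = calendar$study_end,
    monthly_volume = if (is.null(monthly_volume)) p$monthly_volume else monthly_volume,
    baseline_mean_miles = baseline,
    pre_slope_miles_per_month = p$pre_slope_miles_per_month,
    level_change_miles = p$level_change_miles,
    post_slope_miles_per_month = p$post_slope_miles_per_month,
    trip_noise = trip_noise,
    frac_living = frac_living,
    frac_missing_center_id = frac_missing_center_id,
    frac_missing_zip = frac_missing_zip,
    seed = seed,
    ...
  )
}

.pseudo_zip <- function(i) formatC(i, width = 5, format = "d", flag = "0")

#' Generate a synthetic registry-like transplant cohort
#'
#' Emits `monthly_volume` transplant records for every monthly bin of the
#' spec's observation window. Each record's recipient centroid is drawn
#' uniformly from the spec bounding box and its donor centroid is placed by
#' [destination_point()] at a uniformly random bearing, so the great-circle
#' distance between the two pseudo-ZIP centroids equals the drawn trip
#' distance exactly. Living-donor, missing-center-ID, missing-ZIP (with
#' resolvable city-state fallback) and unresolvable fractions are honoured
#' with deterministic per-month counts. Fully reproducible given the spec
#' seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list with
#'   \describe{
#'     \item{records}{data.frame: `record_id`, `organ`, `transplant_date`,
#'       `donor_type`, `donor_zip`, `recipient_zip`, `recipient_city_state`,
#'       `center_id`, `region`.}
#'     \item{gazetteer}{data.frame: `kind`, `key`, `lat`, `lon` (pseudo-ZIP
#'       and city-state centroids).}
#'     \item{window}{the `obs_window` used.}
#'     \item{target_means}{generating monthly target means.}
#'   }
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  w <- window_from_dates(spec$implementation_date, spec$study_end,
                         organ = spec$organ)
  T_ <- w$n_pre_months + w$n_post_months
  mu <- monthly_targets(spec, w)
  n_m <- as.integer(round(spec$monthly_volume +
                            spec$volume_growth * (seq_len(T_) - 1)))
  if (any(n_m < 1)) stop("monthly volume must stay >= 1 across the window",
                         call. = FALSE)
  N <- sum(n_m)
  month_of <- rep.int(seq_len(T_), n_m)

  bin_start <- w$bin_starts
  bin_end <- c(bin_start[-1L] - 1L, w$window_end)
  span <- as.integer(bin_end - bin_start)
  dates <- bin_start[month_of] +
    as.integer(floor(stats::runif(N) * (span[month_of] + 1L)))

  mu_i <- mu[month_of]
  dist <- if (spec$trip_noise <= 0) {
    mu_i
  } else {
    shape <- 1 / spec$trip_noise^2
    stats::rgamma(N, shape = shape, scale = mu_i * spec$trip_noise^2)
  }

  rlat <- stats::runif(N, spec$bbox[1], spec$bbox[2])
  rlon <- stats::runif(N, spec$bbox[3], spec$bbox[4])
  dpt <- destination_point(rlat, rlon, stats::runif(N, 0, 360), dist)

  # deterministic per-month counts for each special status, assigned to
  # disjoint random index sets within the month
  living <- logical(N)
  miss_ctr <- logical(N)
  miss_zip <- logical(N)
  unres <- logical(N)
  pos <- split(seq_len(N), month_of)
  for (m in seq_len(T_)) {
    idx <- pos[[m]]
    n <- length(idx)
    take <- function(avail, k) if (k <= 0L) integer(0) else
      avail[sample.int(length(avail), min(k, length(avail)))]
    liv <- take(idx, as.integer(round(n * spec$frac_living)))
    living[liv] <- TRUE
    rest <- setdiff(idx, liv)
    mc <- take(rest, as.integer(round(n * spec$frac_missing_center_id)))
    miss_ctr[mc] <- TRUE
    rest <- setdiff(rest, mc)
    mz <- take(rest, as.integer(round(n * spec$frac_missing_zip)))
    miss_zip[mz] <- TRUE
    rest <- setdiff(rest, mz)
    un <- take(rest, as.integer(round(n * spec$frac_unresolvable)))
    unres[un] <- TRUE
  }

  donor_zip <- .pseudo_zip(2L * seq_len(N) - 1L)
  recip_zip <- .pseudo_zip(2L * seq_len(N))
  city_state <- rep(NA_character_, N)
  no_zip <- miss_zip | unres
  city_state[miss_zip] <- sprintf("Synthville %d, ZZ", which(miss_zip))
  city_state[unres] <- sprintf("Nowhere %d, XX", which(unres))

  records <- data.frame(
    record_id = sprintf("R%06d", seq_len(N)),
    organ = spec$organ,
    transplant_date = dates,
    donor_type = ifelse(living, "living", "deceased"),
    donor_zip = donor_zip,
    recipient_zip = ifelse(no_zip, NA_character_, recip_zip),
    recipient_city_state = city_state,
    center_id = ifelse(miss_ctr, NA_character_,
                       sprintf("C%03d", sample.int(250L, N, replace = TRUE))),
    region = sprintf("Region %d", sample.int(11L, N, replace = TRUE)),
    stringsAsFactors = FALSE
  )

  gazetteer <- rbind(
    data.frame(kind = rep("zip", N), key = donor_zip,
               lat = dpt$lat, lon = dpt$lon, stringsAsFactors = FALSE),
    data.frame(kind = rep("zip", sum(!no_zip)), key = recip_zip[!no_zip],
               lat = rlat[!no_zip], lon = rlon[!no_zip],
               stringsAsFactors = FALSE),
    data.frame(kind = rep("city_state", sum(miss_zip)),
               key = city_state[miss_zip],
               lat = rlat[miss_zip], lon = rlon[miss_zip],
               stringsAsFactors = FALSE)
  )

  list(records = records, gazetteer = gazetteer, window = w,
       target_means = mu)
}

#' Read or write transplant-record CSVs
#'
#' Columns: `record_id`, `organ`, `transplant_date` (ISO-8601),
#' `donor_type`, `donor_zip`, `recipient_zip`, `recipient_city_state`,
#' `center_id`, `region`. ZIP columns are read as character so leading
#' zeros survive.
#'
#' @param path File path.
#' @param records Data frame as returned by [generate_cohort()].
#' @return `read_records_csv()` returns the records data frame;
#'   `write_records_csv()` returns `path` invisibly.
#' @export
read_records_csv <- function(path) {
  out <- utils::read.csv(path, colClasses = c(
    record_id = "character", organ = "character",
    transplant_date = "Date", donor_type = "character",
    donor_zip = "character", recipient_zip = "character",
    recipient_city_state = "character", center_id = "character",
    region = "character"
  ))
  out
}

#' @rdname read_records_csv
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
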