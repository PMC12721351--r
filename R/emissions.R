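#' Default fly-mode assignment per organ class
#'
#' Hearts, lungs and livers fly by dedicated charter when they fly; kidneys
#' travel on scheduled commercial flights.
#'
#' @return Named character vector organ -> fly mode.
#' @export
default_fly_modes <- function() {
  c(heart = "charter", lung = "charter", liver = "charter",
    kidney = "commercial")
}

#' Threshold-based travel-mode scenario
#'
#' An organ flies (by its organ class's fly mode) if and only if its trip
#' distance is strictly greater than the threshold; ties and shorter trips
#' are driven.
#'
#' @param threshold Distance threshold in miles (> 0); the study grid is
#'   25, 50, 100, 150, 200.
#' @param fly_mode_by_organ Named organ -> mode map (see
#'   [default_fly_modes()]).
#' @return An object of class `mode_scenario`.
#' @export
mode_scenario <- function(threshold, fly_mode_by_organ = default_fly_modes()) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  if (!all(fly_mode_by_organ %in% c("charter", "commercial")))
    stop("fly modes must be 'charter' or 'commercial'", call. = FALSE)
  structure(list(threshold = threshold,
                 fly_mode_by_organ = fly_mode_by_organ,
                 ground_mode = "drive"),
            class = "mode_scenario")
}

#' Assign a travel mode to trips under a scenario
#'
#' @param distance Trip distances in miles (>= 0).
#' @param organ Organ labels (recycled against `distance`).
#' @param scenario A [mode_scenario()].
#' @return Character vector of modes in `{drive, charter, commercial}`.
#' @export
assign_mode <- function(distance, organ, scenario) {
  if (any(distance < 0)) stop("distance must be >= 0", call. = FALSE)
  fly <- scenario$fly_mode_by_organ[organ]
  if (anyNA(fly))
    stop("unknown organ(s): ",
         paste(unique(organ[is.na(fly)]), collapse = ", "), call. = FALSE)
  ifelse(distance > scenario$threshold, fly, scenario$ground_mode)
}

#' Emission factors per travel mode
#'
#' kg CO2e per mile by mode. The defaults ship in a versioned YAML config
#' (`inst/extdata/emission_factors.yaml`): a large petrol car for driving, a
#' whole-flight short-haul charter basis assuming two people travelling per
#' procurement (about 200 kg of added weight), and zero for commercial
#' flights because the organ rides on a flight that operates anyway. The
#' factors are inputs, not constants: supply your own vintage for audited
#' analyses.
#'
#' @param drive_kg_per_mile,charter_kg_per_mile,commercial_kg_per_mile
#'   Factors in kg CO2e per mile (all >= 0).
#' @param source,vintage Free-text provenance labels carried along.
#' @return An object of class `emission_factors`.
#' @export
emission_factors <- function(drive_kg_per_mile,
                             charter_kg_per_mile,
                             commercial_kg_per_mile = 0,
                             source = "user",
                             vintage = NA_character_) {
  stopifnot(drive_kg_per_mile >= 0, charter_kg_per_mile >= 0,
            commercial_kg_per_mile >= 0)
  structure(list(
    drive_kg_per_mile = drive_kg_per_mile,
    charter_kg_per_mile = charter_kg_per_mile,
    commercial_kg_per_mile = commercial_kg_per_mile,
    source = source,
    vintage = vintage
  ), class = "emission_factors")
}

#' @rdname emission_factors
#' @param path Optional path to a YAML factor file with keys
#'   `drive_kg_per_mile`, `charter_kg_per_mile`, `commercial_kg_per_mile`,
#'   `source`, `vintage`.
#' @export
default_emission_factors <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "emission_factors.yaml",
                        package = "organmiles", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  emission_factors(
    drive_kg_per_mile = raw$drive_kg_per_mile,
    charter_kg_per_mile = raw$charter_kg_per_mile,
    commercial_kg_per_mile = raw$commercial_kg_per_mile,
    source = raw$source %||% "config",
    vintage = as.character(raw$vintage %||% NA_character_)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Emissions of a trip given distance and mode
#'
#' Linear in distance: `distance * factor(mode)`.
#'
#' @param distance Miles (>= 0), vectorised.
#' @param mode `"drive"`, `"charter"` or `"commercial"` (recycled).
#' @param factors An [emission_factors()] object.
#' @return kg CO2e per trip.
#' @export
trip_emissions <- function(distance, mode, factors) {
  if (any(distance < 0)) stop("distance must be >= 0", call. = FALSE)
  f <- c(drive = factors$drive_kg_per_mile,
         charter = factors$charter_kg_per_mile,
         commercial = factors$commercial_kg_per_mile)
  if (anyNA(f[mode]))
    stop("unknown mode(s): ", paste(unique(mode[is.na(f[mode])]),
                                    collapse = ", "), call. = FALSE)
  unname(distance * f[mode])
}

.split_trips_by_period <- function(trips, window) {
  m <- month_index(trips$transplant_date, window)
  keep <- !is.na(m)
  trips <- trips[keep, , drop = FALSE]
  trips$month <- m[keep]
  trips$is_post <- trips$month > window$n_pre_months
  trips
}

#' Excess transport emissions under a mode scenario
#'
#' Converts the counterfactual excess travel of one organ cohort into kg
#' CO2e. Total post-period emissions sum per-trip emissions at the observed
#' distances with scenario-assigned modes. The counterfactual rescales each
#' post trip's distance by its month's predicted/observed mean ratio (the
#' same counterfactual as [counterfactual_excess()], pushed down to trips).
#' Under the default `method = "observed_mode"` the rescaled trip keeps the
#' mode assigned at its *observed* distance, so excess emissions equal the
#' excess miles of each trip priced at that trip's scenario mode; under
#' `method = "reassign"` modes are re-assigned at the rescaled distance, a
#' sensitivity variant in which mode switches themselves enter the excess.
#'
#' @param trips_post,trips_pre Resolved trips (from [resolve_trips()]) in
#'   the post and pre periods. Trips may also be passed unsplit as
#'   `trips_post` with `trips_pre = NULL`, in which case the window attached
#'   to `series` splits them.
#' @param series The `monthly_series` of the cohort.
#' @param fit The `its_fit` for the series.
#' @param scenario A [mode_scenario()].
#' @param factors An [emission_factors()] object.
#' @param method `"observed_mode"` (default) or `"reassign"`.
#' @return An object of class `scenario_emissions`: list with `organ`,
#'   `threshold`, `method`, `total_post_emissions`,
#'   `counterfactual_post_emissions`, `pre_emissions`, `excess_emissions`
#'   (`= total_post - counterfactual_post`), `excess_per_organ`
#'   (per post-period transplant), `pct_increase_over_pre`
#'   (`100 * excess / pre`), and trip counts.
#' @export
excess_emissions <- function(trips_post, series, fit, scenario, factors,
                             trips_pre = NULL,
                             method = c("observed_mode", "reassign")) {
  method <- match.arg(method)
  window <- attr(series, "window")
  if (is.null(window)) stop("series carries no window attribute", call. = FALSE)
  if (is.null(trips_pre)) {
    all_trips <- .split_trips_by_period(trips_post, window)
    trips_pre <- all_trips[!all_trips$is_post, , drop = FALSE]
    trips_post <- all_trips[all_trips$is_post, , drop = FALSE]
  } else {
    trips_post <- .split_trips_by_period(trips_post, window)
    trips_pre <- .split_trips_by_period(trips_pre, window)
    if (any(!trips_post$is_post) || any(trips_pre$is_post))
      stop("trips_post/trips_pre do not match the window periods", call. = FALSE)
  }
  if (nrow(trips_post) == 0L) stop("no post-period trips", call. = FALSE)

  obs_mean <- series$mean_distance[trips_post$month]
  if (any(is.na(obs_mean) | obs_mean <= 0))
    stop("post month with undefined or zero observed mean; rescale undefined",
         call. = FALSE)
  pred_mean <- fit$coefficients[["intercept"]] +
    fit$coefficients[["pre_slope"]] * trips_post$month
  ratio <- pred_mean / obs_mean

  organ <- trips_post$organ
  d_obs <- trips_post$distance_miles
  d_cf <- d_obs * ratio
  mode_obs <- assign_mode(d_obs, organ, scenario)
  total_post <- sum(trip_emissions(d_obs, mode_obs, factors))
  mode_cf <- if (method == "reassign") assign_mode(d_cf, organ, scenario) else mode_obs
  counterfactual_post <- sum(trip_emissions(d_cf, mode_cf, factors))

  pre_emissions <- if (nrow(trips_pre) > 0L) {
    sum(trip_emissions(trips_pre$distance_miles,
                       assign_mode(trips_pre$distance_miles, trips_pre$organ,
                                   scenario),
                       factors))
  } else {
    NA_real_
  }

  excess <- total_post - counterfactual_post
  structure(list(
    organ = if (length(unique(organ)) == 1L) organ[1L] else "mixed",
    threshold = scenario$threshold,
    method = method,
    total_post_emissions = total_post,
    counterfactual_post_emissions = counterfactual_post,
    pre_emissions = pre_emissions,
    excess_emissions = excess,
    excess_per_organ = excess / nrow(trips_post),
    pct_increase_over_pre = 100 * excess / pre_emissions,
    n_post_trips = nrow(trips_post),
    n_pre_trips = nrow(trips_pre)
  ), class = "scenario_emissions")
}

#' @export
print.scenario_emissions <- function(x, ...) {
  cat(sprintf(
    paste0("Scenario fly if > %g mi [%s, %s]: excess %.2f kg CO2e ",
           "(%.2f kg/organ, %.1f%% over pre-period)\n"),
    x$threshold, x$organ, x$method, x$excess_emissions, x$excess_per_organ,
    x$pct_increase_over_pre
  ))
  invisible(x)
}

#' Scenario grid of excess emissions across thresholds
#'
#' Runs [excess_emissions()] for each threshold and stacks the results.
#'
#' @param trips Resolved trips of one organ cohort (pre and post together).
#' @param series,fit,factors As in [excess_emissions()].
#' @param thresholds Numeric vector of mode thresholds in miles.
#' @param fly_mode_by_organ Organ -> fly-mode map.
#' @param method Counterfactual method, see [excess_emissions()].
#' @return Data frame with one row per threshold: `organ`, `threshold`,
#'   emissions totals, `excess_emissions`, `excess_per_organ`,
#'   `pct_increase_over_pre`.
#' @export
scenario_grid <- function(trips, series, fit, factors,
                          thresholds = c(25, 50, 100, 150, 200),
                          fly_mode_by_organ = default_fly_modes(),
                          method = c("observed_mode", "reassign")) {
  method <- match.arg(method)
  rows <- lapply(thresholds, function(th) {
    se <- excess_emissions(trips, series, fit,
                           mode_scenario(th, fly_mode_by_organ), factors,
                           method = method)
    data.frame(
      organ = se$organ, threshold = th,
      total_post_emissions = se$total_post_emissions,
      counterfactual_post_emissions = se$counterfactual_post_emissions,
      pre_emissions = se$pre_emissions,
      excess_emissions = se$excess_emissions,
      excess_per_organ = se$excess_per_organ,
      pct_increase_over_pre = se$pct_increase_over_pre
    )
  })
  do.call(rbind, rows)
}

#' Most-liberal and most-conservative all-organ emission totals
#'
#' Composes per-organ scenario excess totals into the two bounding
#' assumption sets. For charter organs the most liberal composition takes
#' the lowest threshold (most flying, highest emissions); for
#' commercial-fly organs (kidney) flying carries zero added emissions, so
#' the most liberal composition takes the *highest* threshold (most
#' driving). The most conservative composition is the reverse.
#'
#' @param grid Data frame with columns `organ`, `threshold`,
#'   `excess_emissions` covering every organ x threshold cell.
#' @param fly_mode_by_organ Organ -> fly-mode map used to orient each organ.
#' @return List with `most_liberal_total`, `most_conservative_total`, and
#'   the per-organ cell choices (`liberal`, `conservative` data frames).
#' @export
compose_bounds <- function(grid, fly_mode_by_organ = default_fly_modes()) {
  organs <- unique(grid$organ)
  thresholds <- sort(unique(grid$threshold))
  complete <- all(vapply(organs, function(o) {
    setequal(grid$threshold[grid$organ == o], thresholds)
  }, logical(1)))
  if (!complete || anyNA(grid$excess_emissions))
    stop("grid must cover every organ x threshold cell", call. = FALSE)
  pick <- function(liberal) {
    th <- vapply(organs, function(o) {
      fly <- unname(fly_mode_by_organ[o])
      if (is.na(fly)) stop("no fly mode for organ '", o, "'", call. = FALSE)
      commercial <- fly == "commercial"
      if (xor(liberal, commercial)) min(thresholds) else max(thresholds)
    }, numeric(1))
    cells <- mapply(function(o, t) {
      grid$excess_emissions[grid$organ == o & grid$threshold == t]
    }, organs, th)
    data.frame(organ = organs, threshold = th, excess_emissions = cells,
               row.names = NULL)
  }
  liberal <- pick(TRUE)
  conservative <- pick(FALSE)
  list(
    most_liberal_total = sum(liberal$excess_emissions),
    most_conservative_total = sum(conservative$excess_emissions),
    liberal = liberal,
    conservative = conservative
  )
}

#' Proportion of trips under a distance cutoff
#'
#' Fraction of trips with distance strictly below `cutoff`, overall and per
#' group, split into pre and post periods when the trips carry an `is_post`
#' column. Empty groups are reported as `NA`, not 0.
#'
#' @param trips Data frame with `distance_miles`, optionally `is_post` and a
#'   grouping column.
#' @param cutoff Distance cutoff in miles.
#' @param group_by Optional name of a grouping column (e.g. `"region"`).
#' @return Data frame with columns `group`, `period`, `n`, `proportion`.
#' @export
proportion_under <- function(trips, cutoff, group_by = NULL) {
  stopifnot(is.numeric(cutoff), cutoff > 0)
  periods <- if (!is.null(trips$is_post)) {
    list(pre = !trips$is_post, post = trips$is_post)
  } else {
    list(all = rep(TRUE, nrow(trips)))
  }
  groups <- list(overall = rep(TRUE, nrow(trips)))
  if (!is.null(group_by)) {
    if (is.null(trips[[group_by]]))
      stop("no column '", group_by, "' in trips", call. = FALSE)
    for (g in sort(unique(trips[[group_by]]))) {
      groups[[g]] <- trips[[group_by]] == g
    }
  }
  out <- expand.grid(group = names(groups), period = names(periods),
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_
  out$proportion <- NA_real_
  for (i in seq_len(nrow(out))) {
    sel <- groups[[out$group[i]]] & periods[[out$period[i]]]
    out$n[i] <- sum(sel)
    out$proportion[i] <- if (any(sel)) {
      mean(trips$distance_miles[sel] < cutoff)
    } else {
      NA_real_
    }
  }
  out
}

#' Published all-organ scenario excess table
#'
#' Reported excess transport emissions (kg CO2e) by mode-assignment
#' threshold and organ from the national-registry acuity-circle analysis,
#' shipped as a plain-text fixture for composition-bound consistency
#' checks. These values derive from restricted registry data and are used
#' as *inputs* (e.g. to [compose_bounds()]), never as quantities this
#' package claims to recompute.
#'
#' @return Data frame in long form: `organ`, `threshold`,
#'   `excess_emissions`.
#' @export
published_excess_table <- function() {
  path <- system.file("extdata", "published_scenario_excess_kgco2e.csv",
                      package = "organmiles", mustWork = TRUE)
  wide <- utils::read.csv(path)
  organs <- setdiff(names(wide), "threshold")
  out <- do.call(rbind, lapply(organs, function(o) {
    data.frame(organ = o, threshold = wide$threshold,
               excess_emissions = wide[[o]])
  }))
  rownames(out) <- NULL
  out
}
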