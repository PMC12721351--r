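#' Run the full travel-distance and emissions pipeline
#'
#' For each organ: build the observation window, apply cohort filters,
#' resolve trip distances, aggregate to a monthly series, fit the
#' interrupted time series, estimate counterfactual excess miles, price the
#' excess under every mode-threshold scenario, and compute distance-cutoff
#' proportions. Across organs, composes the most-liberal and
#' most-conservative all-organ emission bounds. A stage error aborts that
#' organ with a logged diagnostic; other organs proceed.
#'
#' @param records Transplant records data frame (see [read_records_csv()]).
#' @param gazetteer Centroid gazetteer data frame (see
#'   [read_gazetteer_csv()]).
#' @param calendar Policy calendar, see [default_policy_calendar()].
#' @param organs Organs to run; defaults to those present in both the
#'   records and the calendar.
#' @param thresholds Mode thresholds in miles.
#' @param factors Emission factors, see [default_emission_factors()].
#' @param cutoffs Named per-organ distance cutoffs (miles) for the
#'   proportion-under summaries.
#' @param weighted,robust Passed to [fit_its()].
#' @param method Counterfactual pricing method, see [excess_emissions()].
#' @param out_dir Optional output directory; when given, writes per-organ
#'   fit JSONs and excess-by-month CSVs, a threshold x organ excess table
#'   CSV, a bounds JSON and a run manifest JSON.
#' @return An object of class `ac_run`: per-organ results (`window`,
#'   `tally`, `n_unresolved`, `series`, `fit`, `excess`, `grid`,
#'   `proportions`), plus `bounds` and `manifest`.
#' @export
run_pipeline <- function(records, gazetteer,
                         calendar = default_policy_calendar(),
                         organs = intersect(names(calendar$implementation),
                                            unique(records$organ)),
                         thresholds = c(25, 50, 100, 150, 200),
                         factors = default_emission_factors(),
                         cutoffs = c(heart = 50, lung = 50, liver = 100,
                                     kidney = 200),
                         weighted = FALSE, robust = FALSE,
                         method = c("observed_mode", "reassign"),
                         out_dir = NULL) {
  method <- match.arg(method)
  per_organ <- list()
  errors <- list()
  for (organ in organs) {
    res <- tryCatch({
      w <- build_window(organ, calendar)
      flt <- filter_cohort(records[records$organ == organ, , drop = FALSE], w)
      rsv <- resolve_trips(flt$records, gazetteer)
      trips <- .split_trips_by_period(rsv$trips, w)
      series <- aggregate_monthly(trips, w)
      fit <- fit_its(series, weighted = weighted, robust = robust)
      excess <- counterfactual_excess(series, fit)
      grid <- scenario_grid(trips, series, fit, factors,
                            thresholds = thresholds, method = method)
      cutoff <- if (organ %in% names(cutoffs)) cutoffs[[organ]] else 50
      props <- proportion_under(trips, cutoff,
                                group_by = if (!is.null(trips$region)) "region")
      list(window = w, tally = flt$tally,
           n_out_of_window = flt$n_out_of_window,
           n_unresolved = rsv$n_unresolved, trips = trips, series = series,
           fit = fit, excess = excess, grid = grid, cutoff = cutoff,
           proportions = props)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("organ '", organ, "' failed: ", conditionMessage(res),
              call. = FALSE)
      errors[[organ]] <- conditionMessage(res)
    } else {
      per_organ[[organ]] <- res
    }
  }

  bounds <- NULL
  if (length(per_organ) > 0L) {
    grid_all <- do.call(rbind, lapply(per_organ, `[[`, "grid"))
    bounds <- tryCatch(compose_bounds(grid_all), error = function(e) NULL)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("organmiles")),
    r_version = R.version.string,
    organs = names(per_organ),
    failed_organs = errors,
    thresholds = thresholds,
    method = method,
    emission_factors = unclass(factors),
    study_end = format(calendar$study_end),
    exclusions = lapply(per_organ, function(x)
      c(as.list(x$tally), out_of_window = x$n_out_of_window,
        unresolved = x$n_unresolved)),
    totals = lapply(per_organ, function(x)
      list(total_excess_miles = x$excess$total_excess_miles,
           n_trips = nrow(x$trips)))
  )

  run <- structure(list(per_organ = per_organ, bounds = bounds,
                        manifest = manifest),
                   class = "ac_run")
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

#' Write pipeline artifacts to a directory
#'
#' Machine-readable outputs keep full precision; the threshold x organ
#' excess table is the human-facing summary (kg CO2e rounded to 2 decimals).
#'
#' @param run An `ac_run` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (organ in names(run$per_organ)) {
    x <- run$per_organ[[organ]]
    fit_json <- list(
      organ = organ,
      coefficients = as.list(x$fit$coefficients),
      post_slope = x$fit$post_slope,
      p_level = x$fit$p_level,
      p_slope = x$fit$p_slope,
      total_excess_miles = x$excess$total_excess_miles
    )
    jsonlite::write_json(fit_json, file.path(out_dir, paste0(organ, "_fit.json")),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(x$excess$by_month,
                     file.path(out_dir, paste0(organ, "_excess_by_month.csv")),
                     row.names = FALSE)
    utils::write.csv(x$proportions,
                     file.path(out_dir, paste0(organ, "_proportions.csv")),
                     row.names = FALSE)
  }
  grids <- lapply(run$per_organ, `[[`, "grid")
  if (length(grids) > 0L) {
    long <- do.call(rbind, grids)
    wide <- data.frame(threshold = sort(unique(long$threshold)))
    for (o in unique(long$organ)) {
      sub <- long[long$organ == o, ]
      wide[[o]] <- round(sub$excess_emissions[match(wide$threshold,
                                                    sub$threshold)], 2)
    }
    utils::write.csv(wide, file.path(out_dir, "scenario_excess_table.csv"),
                     row.names = FALSE)
  }
  if (!is.null(run$bounds)) {
    jsonlite::write_json(run$bounds, file.path(out_dir, "bounds.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.ac_run <- function(x, ...) {
  cat("Acuity-circle travel/emissions run\n")
  for (organ in names(x$per_organ)) {
    o <- x$per_organ[[organ]]
    co <- o$fit$coefficients
    cat(sprintf(
      paste0("  %-6s level change %8.2f mi, post slope %6.2f mi/mo, ",
             "excess %12.0f organ-miles\n"),
      organ, co[["level_change"]], o$fit$post_slope,
      o$excess$total_excess_miles
    ))
  }
  if (!is.null(x$bounds)) {
    cat(sprintf("  bounds: %.3g (conservative) .. %.3g (liberal) kg CO2e\n",
                x$bounds$most_conservative_total,
                x$bounds$most_liberal_total))
  }
  invisible(x)
}
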