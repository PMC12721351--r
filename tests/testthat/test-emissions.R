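test_that("mode assignment is strict-greater-than with organ-class fly modes", {
  sc100 <- mode_scenario(100)
  expect_equal(assign_mode(150, "liver", sc100), "charter")
  expect_equal(assign_mode(c(300, 10), "kidney", mode_scenario(200)),
               c("commercial", "drive"))
  # ties drive, for every organ
  for (o in c("heart", "lung", "liver", "kidney")) {
    expect_equal(assign_mode(100, o, sc100), "drive")
    expect_equal(assign_mode(100 + 1e-9, o, sc100),
                 unname(default_fly_modes()[o]))
  }
  expect_error(assign_mode(50, "pancreas", sc100), "unknown organ")
  expect_error(mode_scenario(0), "threshold")
})

test_that("trip emissions are linear in distance and zero for commercial", {
  f <- emission_factors(drive_kg_per_mile = 0.5, charter_kg_per_mile = 2,
                        commercial_kg_per_mile = 0)
  expect_equal(trip_emissions(100, "drive", f), 50)
  expect_equal(trip_emissions(0, "charter", f), 0)
  expect_equal(trip_emissions(c(10, 1e4), "commercial", f), c(0, 0))
  # degree-1 homogeneity in distance for fixed mode
  d <- c(3, 77, 410)
  expect_equal(trip_emissions(2 * d, "charter", f),
               2 * trip_emissions(d, "charter", f))
  expect_error(trip_emissions(-1, "drive", f), "distance")
  expect_error(emission_factors(-0.1, 1), "drive_kg_per_mile")
})

test_that("excess emissions match an exhaustive per-trip enumeration on a toy cohort", {
  spec <- toy_spec(n = 4L, volume = 12L, baseline = 120, pre_slope = 2,
                   level = 40, post_slope = 6, trip_noise = 0.5, seed = 15L)
  g <- generate_cohort(spec)
  out <- cohort_to_series(g)
  s <- out$series
  fit <- fit_its(s)
  fac <- emission_factors(0.44, 2.06, 0)
  for (method in c("observed_mode", "reassign")) {
    se <- excess_emissions(out$trips, s, fit, mode_scenario(150), fac,
                           method = method)
    # independent enumeration straight from the definitions
    ef <- function(d, mode) d * c(drive = 0.44, charter = 2.06,
                                  commercial = 0)[mode]
    md <- function(d) if (d > 150) "charter" else "drive"
    tp <- out$trips[out$trips$is_post, ]
    tq <- out$trips[!out$trips$is_post, ]
    total <- 0; cf <- 0; pre <- 0
    for (i in seq_len(nrow(tp))) {
      d <- tp$distance_miles[i]
      m <- tp$month[i]
      pred <- coef(fit)[["intercept"]] + coef(fit)[["pre_slope"]] * m
      dcf <- d * pred / s$mean_distance[m]
      total <- total + ef(d, md(d))
      cf <- cf + if (method == "reassign") ef(dcf, md(dcf)) else
        ef(dcf, md(d))
    }
    for (i in seq_len(nrow(tq))) {
      d <- tq$distance_miles[i]
      pre <- pre + ef(d, md(d))
    }
    expect_equal(se$total_post_emissions, unname(total), tolerance = 1e-9)
    expect_equal(se$counterfactual_post_emissions, unname(cf),
                 tolerance = 1e-9)
    expect_equal(se$pre_emissions, unname(pre), tolerance = 1e-9)
    expect_equal(se$excess_emissions, unname(total - cf), tolerance = 1e-9)
    expect_equal(se$excess_per_organ, se$excess_emissions / nrow(tp))
    expect_equal(se$pct_increase_over_pre,
                 100 * se$excess_emissions / se$pre_emissions)
  }
})

test_that("excess emissions conserve and vanish under a null policy effect", {
  spec <- toy_spec(n = 5L, volume = 10L, baseline = 150, pre_slope = 1,
                   level = 0, post_slope = 1, trip_noise = 0, seed = 3L)
  g <- generate_cohort(spec)
  out <- cohort_to_series(g)
  fit <- suppressWarnings(fit_its(out$series))
  fac <- default_emission_factors()
  se <- excess_emissions(out$trips, out$series, fit, mode_scenario(100), fac)
  expect_equal(se$excess_emissions, 0, tolerance = 1e-6)
  # conservation holds exactly in general (noisy cohort, both methods)
  spec2 <- toy_spec(n = 5L, volume = 20L, baseline = 180, level = 35,
                    post_slope = 3, trip_noise = 0.7, seed = 21L)
  g2 <- generate_cohort(spec2)
  out2 <- cohort_to_series(g2)
  fit2 <- fit_its(out2$series)
  for (method in c("observed_mode", "reassign")) {
    se2 <- excess_emissions(out2$trips, out2$series, fit2,
                            mode_scenario(50), fac, method = method)
    expect_equal(se2$excess_emissions + se2$counterfactual_post_emissions,
                 se2$total_post_emissions)
  }
})

test_that("excess emissions are monotone in threshold: non-increasing for charter organs, non-decreasing for kidney", {
  fac <- default_emission_factors()
  base <- list(n = 10L, volume = 30L, baseline = 150, pre_slope = 0.5,
               level = 60, post_slope = 4, trip_noise = 0.8, seed = 99L)
  for (organ in c("heart", "kidney")) {
    spec <- cohort_spec(
      organ = organ,
      implementation_date = as.Date("2020-06-15"),
      study_end = add_months(as.Date("2020-06-15"), base$n),
      monthly_volume = base$volume, baseline_mean_miles = base$baseline,
      pre_slope_miles_per_month = base$pre_slope,
      level_change_miles = base$level,
      post_slope_miles_per_month = base$post_slope,
      trip_noise = base$trip_noise, seed = base$seed
    )
    g <- generate_cohort(spec)
    out <- cohort_to_series(g)
    fit <- fit_its(out$series)
    grid <- scenario_grid(out$trips, out$series, fit, fac,
                          thresholds = c(25, 50, 100, 150, 200))
    diffs <- diff(grid$excess_emissions)
    if (organ == "kidney") {
      expect_true(all(diffs >= -1e-9))
    } else {
      expect_true(all(diffs <= 1e-9))
    }
    expect_true(all(grid$total_post_emissions >= 0))
  }
})

test_that("compose_bounds picks the documented compositions and brackets every mixed composition", {
  # toy grids from one charter cohort replicated per organ, plus kidney
  fac <- default_emission_factors()
  grids <- lapply(c("heart", "lung", "liver", "kidney"), function(organ) {
    spec <- cohort_spec(
      organ = organ, implementation_date = as.Date("2020-06-15"),
      study_end = add_months(as.Date("2020-06-15"), 8L),
      monthly_volume = 40L, baseline_mean_miles = 140,
      pre_slope_miles_per_month = 1, level_change_miles = 60,
      post_slope_miles_per_month = 5, trip_noise = 0.4,
      seed = match(organ, c("heart", "lung", "liver", "kidney"))
    )
    g <- generate_cohort(spec)
    out <- cohort_to_series(g)
    scenario_grid(out$trips, out$series, fit_its(out$series), fac)
  })
  grid <- do.call(rbind, grids)
  b <- compose_bounds(grid)
  # liberal: charter organs at the lowest threshold, kidney at the highest
  expect_equal(b$liberal$threshold[b$liberal$organ == "heart"], 25)
  expect_equal(b$liberal$threshold[b$liberal$organ == "kidney"], 200)
  expect_equal(b$conservative$threshold[b$conservative$organ == "lung"], 200)
  expect_equal(b$conservative$threshold[b$conservative$organ == "kidney"], 25)
  # exhaustive 5^4 composition sweep is bracketed by the two bounds
  th <- c(25, 50, 100, 150, 200)
  organs <- c("heart", "lung", "liver", "kidney")
  combos <- expand.grid(heart = th, lung = th, liver = th, kidney = th)
  totals <- apply(combos, 1, function(row) {
    sum(vapply(organs, function(o) {
      grid$excess_emissions[grid$organ == o & grid$threshold == row[[o]]]
    }, numeric(1)))
  })
  expect_true(all(totals <= b$most_liberal_total + 1e-6))
  expect_true(all(totals >= b$most_conservative_total - 1e-6))
  # degenerate inputs
  zero <- grid
  zero$excess_emissions <- 0
  bz <- compose_bounds(zero)
  expect_equal(bz$most_liberal_total, 0)
  expect_equal(bz$most_conservative_total, 0)
  expect_error(compose_bounds(grid[-1, ]), "every organ x threshold")
  # single-organ grid: bounds equal that organ's own extreme cells
  gh <- grid[grid$organ == "heart", ]
  bh <- compose_bounds(gh)
  expect_equal(bh$most_liberal_total, max(gh$excess_emissions))
  expect_equal(bh$most_conservative_total, min(gh$excess_emissions))
})

test_that("proportion_under counts strictly-below fractions per period and group", {
  trips <- data.frame(
    distance_miles = c(30, 60, 90, 10, 10, 49, 50, 51),
    is_post = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    region = c("A", "A", "A", "B", "B", "A", "A", "A")
  )
  out <- proportion_under(trips, 50, group_by = "region")
  get <- function(g, p) out$proportion[out$group == g & out$period == p]
  expect_equal(get("overall", "pre"), 2 / 4)
  expect_equal(get("A", "pre"), 1 / 3)
  # strict inequality: 50 is not under 50
  expect_equal(get("A", "post"), 1 / 3)
  expect_equal(get("B", "post"), 1)
  # empty group is NA, not zero
  trips2 <- trips[trips$region == "A", ]
  trips2$region[1] <- "C"
  out2 <- proportion_under(trips2, 50, group_by = "region")
  expect_true(is.na(out2$proportion[out2$group == "C" &
                                      out2$period == "post"]))
  # all under
  expect_equal(proportion_under(data.frame(distance_miles = rep(10, 5)),
                                50)$proportion, 1)
  # brute-force cross-check on random trips
  set.seed(6)
  tr <- data.frame(distance_miles = runif(300, 0, 300),
                   is_post = sample(c(TRUE, FALSE), 300, replace = TRUE))
  o <- proportion_under(tr, 120)
  expect_equal(o$proportion[o$period == "pre"],
               sum(tr$distance_miles < 120 & !tr$is_post) / sum(!tr$is_post))
  expect_equal(o$proportion[o$period == "post"],
               sum(tr$distance_miles < 120 & tr$is_post) / sum(tr$is_post))
})
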