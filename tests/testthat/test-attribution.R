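test_that("far and rr obey their defining identities and flag edge cases", {
  p <- c(0.01, 0.1, 0.5, 1)
  expect_equal(far(p, p), rep(0, 4))
  expect_equal(rr(p, p), rep(1, 4))
  expect_equal(far(0.05, 0.10), 0.5)
  expect_equal(rr(0.10, 1.00), 10)

  # division-by-zero edges come back flagged, never thrown
  expect_true(is.na(far(0.2, 0)))
  expect_equal(rr(0, 0.5), Inf)
  expect_true(is.na(rr(0, 0)))

  expect_error(far(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(rr(0.5, 1.2), "\\[0, 1\\]")
})

test_that("attribution curves on the fixture reproduce headline statistics", {
  pair <- las_conchas()
  curve <- attribution_curves(pair)

  far_at <- approx(curve$grid, curve$far, 86000)$y
  expect_equal(far_at, 0.90, tolerance = 0.05 / 0.90)

  expect_true(all(curve$rr[curve$valid] >= 1))
  expect_true(all(curve$far[curve$valid] <= 1))

  # identity scenario: same sizes under two labels
  same <- scenario_pair(fire_ensemble(published_actual, "a"),
                        fire_ensemble(published_actual, "b"))
  id_curve <- attribution_curves(same)
  expect_equal(id_curve$far[id_curve$valid],
               rep(0, sum(id_curve$valid)))
  expect_equal(id_curve$rr[id_curve$valid],
               rep(1, sum(id_curve$valid)))
})

test_that("far_crossing returns the first attainment, interpolated", {
  pair <- las_conchas()
  curve <- attribution_curves(pair)
  expect_equal(far_crossing(curve, 0.5), 81450, tolerance = 0.03)

  # exact-grid-point fixed point on a hand-built monotone curve
  toy <- structure(
    list(grid = c(10, 20, 30, 40), p0 = c(1, .75, .5, .25),
         p1 = c(1, 1, 1, 1), far = c(0, .25, .5, .75), rr = c(1, 4 / 3, 2, 4),
         valid = rep(TRUE, 4), labels = c(p0 = "a", p1 = "b"),
         direction_note = "", estimator = "kde", settings = list()),
    class = "attribution_curve"
  )
  expect_equal(far_crossing(toy, 0.5), 30)
  expect_equal(far_crossing(toy, 0.375), 25) # midpoint interpolation

  same <- scenario_pair(fire_ensemble(published_actual, "a"),
                        fire_ensemble(published_actual, "b"))
  expect_error(far_crossing(attribution_curves(same), 0.5), "never attains")
})

test_that("bootstrap bands are deterministic and cover the point estimate", {
  pair <- las_conchas()
  b1 <- bootstrap_bands(pair, replicates = 150, seed = 99)
  b2 <- bootstrap_bands(pair, replicates = 150, seed = 99)
  expect_identical(b1, b2)
  b3 <- bootstrap_bands(pair, replicates = 150, seed = 100)
  expect_false(identical(b1$far_lo, b3$far_lo))

  curve <- attribution_curves(pair)
  ok <- b1$available & curve$valid & is.finite(curve$far)
  inside <- curve$far[ok] >= b1$far_lo[ok] & curve$far[ok] <= b1$far_hi[ok]
  expect_gte(mean(inside), 0.95)

  expect_error(bootstrap_bands(pair, replicates = 50, seed = 1), "at least 100")
  expect_error(bootstrap_bands(pair, replicates = 150), "seed")
})

test_that("bootstrap bands tighten as ensembles grow", {
  make_pair <- function(n, seed) {
    scenario_pair(
      lognormal_ensemble(n, log(8e4), 0.05, "ref", seed),
      lognormal_ensemble(n, log(1e5), 0.05, "cf", seed + 1)
    )
  }
  width <- function(n, seed) {
    b <- bootstrap_bands(make_pair(n, seed), replicates = 120, seed = 5,
                         n_points = 256)
    stats::median((b$far_hi - b$far_lo)[b$available], na.rm = TRUE)
  }
  expect_lt(width(1000, 21), width(10, 21))
})

test_that("reports aggregate the analysis and regenerate identically", {
  pair <- las_conchas()
  report <- build_report(pair, thresholds = 86000,
                         percentiles = c(0.5, 0.9), far_levels = 0.5)
  expect_equal(report$event_threshold, 86000)
  expect_equal(report$rr_at_threshold, 10, tolerance = 2 / 10)
  expect_equal(unname(report$percentile_events$p1[["0.5"]]), 104200,
               tolerance = 0.03)
  expect_equal(unname(report$far_crossings[["0.5"]]), 81450, tolerance = 0.03)

  expect_equal(rebuild_report(report), report)
})

test_that("report JSON round-trips losslessly, with explicit null/Inf conventions", {
  pair <- las_conchas()
  report <- build_report(pair, thresholds = 86000,
                         bootstrap = list(replicates = 120, seed = 3))
  path <- tempfile(fileext = ".json")
  write_report(report, path)
  expect_equal(read_report(path), report)

  # no bootstrap: section absent from the file, reload still succeeds
  plain <- build_report(pair, thresholds = 86000)
  path2 <- tempfile(fileext = ".json")
  write_report(plain, path2)
  expect_false(grepl("bootstrap", paste(readLines(path2), collapse = "")))
  expect_equal(read_report(path2), plain)

  # an infinite RR (empirical estimator beyond the p0 maximum) serializes
  # as an explicit marker, not a bare non-JSON token
  emp <- build_report(pair, thresholds = c(86000, 90000), estimator = "empirical")
  expect_equal(emp$thresholds$rr[2], Inf)
  path3 <- tempfile(fileext = ".json")
  write_report(emp, path3)
  txt <- paste(readLines(path3), collapse = "")
  expect_false(grepl("NaN", txt))
  expect_equal(read_report(path3), emp)
})
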