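test_that("bandwidth rules follow their formulas", {
  x <- published_actual
  expect_equal(fire_bandwidth(x, "scott"), sd(x) * 10^(-1 / 5))
  expect_equal(fire_bandwidth(x, "silverman"), bw.nrd0(x))
  expect_equal(fire_bandwidth(x, 1500), 1500)
  expect_error(fire_bandwidth(x, -2), "positive")
  expect_error(fire_bandwidth(rep(5, 4), "scott"), "zero-variance")
})

test_that("shared grid spans and pads the pooled sample range", {
  pair <- las_conchas()
  grid <- make_shared_grid(pair, n_points = 512)
  expect_length(grid, 512)
  expect_true(all(diff(grid) > 0))
  expect_lt(min(grid), 74034)
  expect_gt(max(grid), 112049)

  tight <- make_shared_grid(pair, n_points = 64, pad_bandwidths = 0)
  expect_equal(range(tight), c(74034, 112049))

  degenerate <- fire_ensemble(c(10, 10, 10), "flat")
  expect_error(make_shared_grid(list(degenerate)), "flat")
  expect_error(make_shared_grid(pair, n_points = 1), "at least 2")
})

test_that("two-point kernel density matches the closed form", {
  a <- 1000
  b <- 3000
  h <- 400
  e <- fire_ensemble(c(a, b), "pair")
  grid <- seq(0, 5000, length.out = 512)
  d <- estimate_density(e, grid, bandwidth = h)
  expect_equal(d$bandwidth, h)
  # renormalization over the grid is a near-identity here; compare against
  # the exact mean-of-two-Gaussians at several sizes including the midpoint
  at <- function(s) approx(d$grid, d$density, s)$y
  for (s in c(mean(c(a, b)), a, b, 1500)) {
    expect_equal(at(s), (dnorm(s, a, h) + dnorm(s, b, h)) / 2, tolerance = 1e-3)
  }
})

test_that("density normalizes to unit mass and tracks the sample mean", {
  pair <- las_conchas()
  grid <- make_shared_grid(pair)
  d <- estimate_density(pair$p0_ensemble, grid)
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(trapz(d$grid, d$density), 1, tolerance = 0.01)
  expect_true(all(d$density >= 0))
  kde_mean <- trapz(d$grid, d$grid * d$density)
  expect_lt(abs(kde_mean - 80848.7), sd(pair$p0_ensemble$sizes))
})

test_that("kde exceedance is monotone with full-mass and empty-tail ends", {
  pair <- las_conchas()
  grid <- make_shared_grid(pair)
  for (e in list(pair$p0_ensemble, pair$p1_ensemble)) {
    curve <- exceedance_from_density(estimate_density(e, grid))
    expect_gte(curve$prob[1], 0.99)
    expect_lte(curve$prob[length(grid)], 0.01)
    expect_true(all(diff(curve$prob) <= 0))
    expect_true(all(curve$prob >= 0 & curve$prob <= 1))
  }
})

test_that("empirical exceedance counts exactly, with the strict convention", {
  pair <- las_conchas()
  grid <- make_shared_grid(pair)
  e0 <- empirical_exceedance(pair$p0_ensemble, grid)
  e1 <- empirical_exceedance(pair$p1_ensemble, grid)
  expect_equal(exceedance_at(e0, 86000), 0.10) # one of ten actual values above
  expect_equal(exceedance_at(e1, 86000), 1.00) # all counterfactual values above
  expect_equal(exceedance_at(e0, 50000), 1.00) # below the sample minimum

  # strictness: a threshold exactly at a sample value excludes that value
  fine <- seq(74000, 87000, by = 1)
  ef <- empirical_exceedance(pair$p0_ensemble, fine)
  expect_equal(exceedance_at(ef, 86471), 0)
  expect_equal(exceedance_at(ef, 86470), 0.1)
})

test_that("percentile_event_size interpolates monotonically", {
  pair <- las_conchas()
  grid <- make_shared_grid(pair)
  curve <- exceedance_from_density(estimate_density(pair$p0_ensemble, grid))

  # interpolation fixed point: a target sitting exactly on a grid point
  i <- 250
  expect_equal(percentile_event_size(curve, 1 - curve$prob[i]), curve$grid[i])

  sizes <- vapply(seq(0.1, 0.9, by = 0.1),
                  function(p) percentile_event_size(curve, p), numeric(1))
  expect_true(all(diff(sizes) > 0))

  expect_error(percentile_event_size(curve, 1.5), "between 0 and 1")
  emp <- empirical_exceedance(pair$p0_ensemble, seq(75000, 80000, by = 100))
  expect_error(percentile_event_size(emp, 0.99), "attainable range")
})

test_that("exceedance curves export to CSV", {
  pair <- las_conchas()
  grid <- make_shared_grid(pair)
  curve <- empirical_exceedance(pair$p0_ensemble, grid)
  path <- tempfile(fileext = ".csv")
  write_exceedance_csv(curve, path)
  df <- read.csv(path)
  expect_named(df, c("size_ha", "prob", "estimator_kind"))
  expect_equal(df$prob, curve$prob)
})
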