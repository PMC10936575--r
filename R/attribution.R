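# Denominator floor separating true zeros of the empirical estimator from
# KDE tail dust; values at or below it are flagged rather than divided by.
FAR_FLOOR <- 1e-12

#' Fraction of attributable risk
#'
#' `FAR = 1 - p0/p1`, the fraction of the event's probability in the
#' comparison world (p1) attributable to the condition that differs between
#' the worlds. A FAR of 0 means no relationship; 0.5 means the event is
#' twice as likely in the p1 world; values approaching 1 mean the event
#' essentially cannot occur without the antecedent.
#'
#' Where `p1` does not exceed the numerical floor the ratio is undefined and
#' the result is flagged as `NA` (an explicit marker, never a silent
#' number), so curves built from these values stay total.
#'
#' @param p0 Exceedance probability in the reference world, in \[0, 1\].
#' @param p1 Exceedance probability in the comparison world, in \[0, 1\].
#' @param floor Denominator floor (default `1e-12`).
#' @return Numeric vector of FAR values, `NA` where undefined. FAR never
#'   exceeds 1.
#' @examples
#' far(0.05, 0.10) # 0.5: the event probability doubled
#' @export
far <- function(p0, p1, floor = FAR_FLOOR) {
  check_prob(p0, "p0")
  check_prob(p1, "p1")
  out <- 1 - p0 / p1
  out[p1 <= floor] <- NA_real_
  out
}

#' Relative risk
#'
#' `RR = p1/p0`: how many times more likely the event is in the comparison
#' world than in the reference world. RR of 1 means identical probabilities;
#' RR above (below) 1 means increased (decreased) risk.
#'
#' Edge cases are flagged, never thrown: `Inf` when only the denominator is
#' at or below the floor, `NA` when both probabilities are.
#'
#' @inheritParams far
#' @return Numeric vector of RR values (`Inf`/`NA` flags at degenerate
#'   points).
#' @examples
#' rr(0.10, 1.00) # 10: a 10-fold probability increase
#' @export
rr <- function(p0, p1, floor = FAR_FLOOR) {
  check_prob(p0, "p0")
  check_prob(p1, "p1")
  out <- p1 / p0
  out[p0 <= floor & p1 > floor] <- Inf
  out[p0 <= floor & p1 <= floor] <- NA_real_
  out
}

check_prob <- function(p, name) {
  if (!is.numeric(p) || any(!is.na(p) & (p < 0 | p > 1))) {
    stop(sprintf("`%s` must contain probabilities in [0, 1]", name),
         call. = FALSE)
  }
  invisible(p)
}

#' Compute aligned p0/p1/FAR/RR curves for a scenario pair
#'
#' Builds one shared grid, estimates both exceedance curves with identical
#' settings, and applies [far()] and [rr()] pointwise. Points where p1 does
#' not exceed the numerical floor are marked invalid rather than dropped, so
#' the curve stays aligned with its grid.
#'
#' @param pair A [scenario_pair()].
#' @param n_points,pad_bandwidths Grid settings; see [make_shared_grid()].
#' @param bandwidth Bandwidth rule or value; see [fire_bandwidth()].
#' @param estimator `"kde"` (smoothed pathway, default) or `"empirical"`
#'   (exact counting oracle).
#' @param grid Optional pre-built grid overriding the grid settings (used by
#'   the bootstrap to hold the grid fixed across replicates).
#' @return An object of class `attribution_curve` with elements `grid`,
#'   `p0`, `p1`, `far`, `rr`, `valid`, labels and settings.
#' @export
attribution_curves <- function(pair, n_points = 512, pad_bandwidths = 3,
                               bandwidth = "scott",
                               estimator = c("kde", "empirical"),
                               grid = NULL) {
  stopifnot(inherits(pair, "scenario_pair"))
  estimator <- match.arg(estimator)
  if (is.null(grid)) {
    grid <- make_shared_grid(pair, n_points = n_points,
                             pad_bandwidths = pad_bandwidths,
                             bandwidth_rule = bandwidth)
  } else {
    check_grid(grid)
  }
  curves <- lapply(list(pair$p0_ensemble, pair$p1_ensemble), function(e) {
    if (estimator == "kde") {
      exceedance_from_density(estimate_density(e, grid, bandwidth = bandwidth))
    } else {
      empirical_exceedance(e, grid)
    }
  })
  p0 <- curves[[1]]$prob
  p1 <- curves[[2]]$prob
  structure(
    list(
      grid = grid,
      p0 = p0,
      p1 = p1,
      far = far(p0, p1),
      rr = rr(p0, p1),
      valid = p1 > FAR_FLOOR,
      labels = c(p0 = pair$p0_ensemble$label, p1 = pair$p1_ensemble$label),
      direction_note = pair$direction_note,
      estimator = estimator,
      settings = list(n_points = length(grid), pad_bandwidths = pad_bandwidths,
                      bandwidth = bandwidth)
    ),
    class = "attribution_curve"
  )
}

#' @export
print.attribution_curve <- function(x, ...) {
  cat(sprintf(
    "<attribution_curve> p0='%s' vs p1='%s' (%s), %d grid points, %d valid\n",
    x$labels[["p0"]], x$labels[["p1"]], x$estimator,
    length(x$grid), sum(x$valid)
  ))
  invisible(x)
}

#' @export
as.data.frame.attribution_curve <- function(x, ...) {
  data.frame(size_ha = x$grid, p0 = x$p0, p1 = x$p1, far = x$far, rr = x$rr,
             valid = x$valid)
}

#' Export attribution curves to CSV
#'
#' Columns: `size_ha`, `p0`, `p1`, `far`, `rr`.
#'
#' @param curve An `attribution_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curve, path) {
  stopifnot(inherits(curve, "attribution_curve"))
  df <- as.data.frame(curve)[, c("size_ha", "p0", "p1", "far", "rr")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fire size at which the FAR curve first reaches a level
#'
#' Scans upward in fire size over the valid region and returns the smallest
#' size (linear interpolation between the bracketing grid points) where FAR
#' first attains the level. FAR curves need not be monotone, hence "first
#' attainment" rather than inversion.
#'
#' @param curve An `attribution_curve`.
#' @param level FAR level in (0, 1\].
#' @return Fire size in hectares.
#' @export
far_crossing <- function(curve, level) {
  stopifnot(inherits(curve, "attribution_curve"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level > 1) {
    stop("`level` must lie in (0, 1]", call. = FALSE)
  }
  ok <- curve$valid & is.finite(curve$far)
  f <- curve$far
  hit <- which(ok & f >= level)
  if (length(hit) == 0L) {
    rng <- range(f[ok])
    stop(sprintf(
      "FAR never attains %.4g; attained range is [%.4g, %.4g]",
      level, rng[1], rng[2]
    ), call. = FALSE)
  }
  i <- hit[1]
  if (f[i] == level || i == 1L || !ok[i - 1L]) {
    return(curve$grid[i])
  }
  frac <- (level - f[i - 1L]) / (f[i] - f[i - 1L])
  curve$grid[i - 1L] + frac * (curve$grid[i] - curve$grid[i - 1L])
}

#' Pointwise bootstrap bands for FAR and RR curves
#'
#' Nonparametric bootstrap: each ensemble is resampled with replacement
#' independently, the attribution curve is recomputed per replicate with the
#' same settings on the same fixed grid, and pointwise percentile intervals
#' are taken at the requested coverage. The seed is mandatory; identical
#' seeds give identical bands.
#'
#' Grid points whose replicate curves are undefined (p1 at or below the
#' floor, or a degenerate resample) in more than 50% of replicates have
#' their band flagged unavailable (`NA`).
#'
#' @inheritParams attribution_curves
#' @param replicates Number of bootstrap replicates (at least 100; default
#'   1000).
#' @param seed Integer seed, required explicitly.
#' @param band_level Coverage of the percentile interval (default 0.95).
#' @return An object of class `attribution_bands`: grid, `far_lo`/`far_hi`,
#'   `rr_lo`/`rr_hi`, availability mask, and the settings used.
#' @export
bootstrap_bands <- function(pair, replicates = 1000, seed,
                            band_level = 0.95, n_points = 512,
                            pad_bandwidths = 3, bandwidth = "scott",
                            estimator = c("kde", "empirical")) {
  stopifnot(inherits(pair, "scenario_pair"))
  estimator <- match.arg(estimator)
  if (missing(seed)) stop("`seed` must be supplied explicitly", call. = FALSE)
  if (replicates < 100) {
    stop("`replicates` must be at least 100", call. = FALSE)
  }
  grid <- make_shared_grid(pair, n_points = n_points,
                           pad_bandwidths = pad_bandwidths,
                           bandwidth_rule = bandwidth)
  n_grid <- length(grid)
  x0 <- pair$p0_ensemble$sizes
  x1 <- pair$p1_ensemble$sizes

  far_mat <- matrix(NA_real_, nrow = replicates, ncol = n_grid)
  rr_mat <- matrix(NA_real_, nrow = replicates, ncol = n_grid)
  defined <- matrix(FALSE, nrow = replicates, ncol = n_grid)

  with_seed(seed, for (r in seq_len(replicates)) {
    b0 <- sample(x0, replace = TRUE)
    b1 <- sample(x1, replace = TRUE)
    if (estimator == "kde" && (stats::sd(b0) == 0 || stats::sd(b1) == 0)) {
      next # degenerate resample: leave the replicate undefined everywhere
    }
    e0 <- replicate_exceedance(b0, grid, estimator, bandwidth)
    e1 <- replicate_exceedance(b1, grid, estimator, bandwidth)
    ok <- e1 > FAR_FLOOR
    defined[r, ] <- ok
    far_mat[r, ok] <- 1 - e0[ok] / e1[ok]
    rrv <- e1 / e0
    rrv[e0 <= FAR_FLOOR] <- Inf
    rr_mat[r, ok] <- rrv[ok]
  })

  available <- colMeans(defined) > 0.5
  alpha <- (1 - band_level) / 2
  band_q <- function(m, probs) {
    apply(m, 2, function(col) {
      v <- col[!is.na(col)]
      if (length(v) == 0L) return(NA_real_)
      stats::quantile(v, probs, names = FALSE, type = 7)
    })
  }
  far_lo <- band_q(far_mat, alpha)
  far_hi <- band_q(far_mat, 1 - alpha)
  rr_lo <- band_q(rr_mat, alpha)
  rr_hi <- band_q(rr_mat, 1 - alpha)
  far_lo[!available] <- far_hi[!available] <- NA_real_
  rr_lo[!available] <- rr_hi[!available] <- NA_real_

  structure(
    list(grid = grid, band_level = band_level, replicates = replicates,
         seed = seed, far_lo = far_lo, far_hi = far_hi,
         rr_lo = rr_lo, rr_hi = rr_hi, available = available,
         settings = list(n_points = n_points, pad_bandwidths = pad_bandwidths,
                         bandwidth = bandwidth, estimator = estimator)),
    class = "attribution_bands"
  )
}

replicate_exceedance <- function(x, grid, estimator, bandwidth) {
  e <- fire_ensemble(x, label = "replicate")
  if (estimator == "kde") {
    exceedance_from_density(estimate_density(e, grid, bandwidth = bandwidth))$prob
  } else {
    empirical_exceedance(e, grid)$prob
  }
}

# Evaluate `code` under a fixed RNG seed, restoring any pre-existing RNG
# state afterwards. `code` is a promise evaluated in the caller's frame, so
# assignments inside it land there.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  invisible(force(code))
}

#' Build a full attribution report for a scenario pair
#'
#' Aggregates the headline statistics of one analysis: exceedance
#' probabilities, FAR and RR at each requested fire-size threshold;
#' percentile event sizes on both curves; fire sizes at which FAR first
#' reaches each requested level; and (optionally) bootstrap bands. All
#' settings and the input fire sizes are stored in the report so every
#' statistic can be recomputed from it (see [rebuild_report()]).
#'
#' @inheritParams attribution_curves
#' @param thresholds Fire-size thresholds (ha); the first is the report's
#'   event threshold.
#' @param percentiles Percentiles in (0, 1) at which event sizes are read
#'   off both curves.
#' @param far_levels FAR levels whose first crossing sizes are reported;
#'   unattained levels are recorded as `NA`.
#' @param bootstrap `NULL` (skip) or a list with `replicates`, `seed` and
#'   optionally `band_level`, passed to [bootstrap_bands()].
#' @return An object of class `attribution_report`.
#' @export
build_report <- function(pair, thresholds, percentiles = c(0.5, 0.9),
                         far_levels = 0.5, bootstrap = NULL,
                         n_points = 512, pad_bandwidths = 3,
                         bandwidth = "scott",
                         estimator = c("kde", "empirical")) {
  stopifnot(inherits(pair, "scenario_pair"))
  estimator <- match.arg(estimator)
  if (missing(thresholds) || length(thresholds) < 1L) {
    stop("at least one fire-size threshold is required", call. = FALSE)
  }
  curve <- attribution_curves(pair, n_points = n_points,
                              pad_bandwidths = pad_bandwidths,
                              bandwidth = bandwidth, estimator = estimator)
  e0 <- structure(list(grid = curve$grid, prob = curve$p0,
                       estimator_kind = estimator,
                       source_label = curve$labels[["p0"]]),
                  class = "exceedance_curve")
  e1 <- structure(list(grid = curve$grid, prob = curve$p1,
                       estimator_kind = estimator,
                       source_label = curve$labels[["p1"]]),
                  class = "exceedance_curve")

  thr <- data.frame(
    size_ha = as.numeric(thresholds),
    p0 = exceedance_at(e0, thresholds),
    p1 = exceedance_at(e1, thresholds)
  )
  thr$far <- far(thr$p0, thr$p1)
  thr$rr <- rr(thr$p0, thr$p1)

  pct <- function(curve_) {
    v <- vapply(percentiles, function(p) {
      tryCatch(percentile_event_size(curve_, p), error = function(e) NA_real_)
    }, numeric(1))
    stats::setNames(v, format(percentiles))
  }
  crossings <- vapply(far_levels, function(l) {
    tryCatch(far_crossing(curve, l), error = function(e) NA_real_)
  }, numeric(1))

  bands <- NULL
  if (!is.null(bootstrap)) {
    bands <- bootstrap_bands(
      pair,
      replicates = bootstrap$replicates %||% 1000,
      seed = bootstrap$seed,
      band_level = bootstrap$band_level %||% 0.95,
      n_points = n_points, pad_bandwidths = pad_bandwidths,
      bandwidth = bandwidth, estimator = estimator
    )
  }

  out <- list(
      labels = as.list(curve$labels),
      direction_note = pair$direction_note,
      event_threshold = thr$size_ha[1],
      far_at_threshold = thr$far[1],
      rr_at_threshold = thr$rr[1],
      thresholds = thr,
      percentile_events = list(p0 = pct(e0), p1 = pct(e1)),
      far_crossings = stats::setNames(crossings, format(far_levels)),
      bootstrap = if (!is.null(bands)) {
        list(band_level = bands$band_level, replicates = bands$replicates,
             seed = bands$seed,
             bands = data.frame(size_ha = bands$grid,
                                far_lo = bands$far_lo, far_hi = bands$far_hi,
                                rr_lo = bands$rr_lo, rr_hi = bands$rr_hi))
      },
      settings = list(n_points = n_points, pad_bandwidths = pad_bandwidths,
                      bandwidth = bandwidth, estimator = estimator,
                      percentiles = percentiles, far_levels = far_levels,
                      bootstrap = if (!is.null(bootstrap)) {
                        list(replicates = bootstrap$replicates %||% 1000,
                             seed = bootstrap$seed,
                             band_level = bootstrap$band_level %||% 0.95)
                      }),
      inputs = list(p0 = pair$p0_ensemble$sizes, p1 = pair$p1_ensemble$sizes)
  )
  # optional sections are absent, not NULL placeholders, so serialization
  # omits them cleanly
  if (is.null(out$bootstrap)) out$bootstrap <- NULL
  if (is.null(out$settings$bootstrap)) out$settings$bootstrap <- NULL
  structure(out, class = "attribution_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recompute a report from its stored settings and inputs
#'
#' Every statistic in an [build_report()] result is a function of the stored
#' input fire sizes and settings; this reruns that computation and returns a
#' fresh report, which must equal the original.
#'
#' @param report An `attribution_report`.
#' @return A new `attribution_report`.
#' @export
rebuild_report <- function(report) {
  stopifnot(inherits(report, "attribution_report"))
  pair <- scenario_pair(
    fire_ensemble(report$inputs$p0, label = report$labels$p0),
    fire_ensemble(report$inputs$p1, label = report$labels$p1),
    direction_note = report$direction_note
  )
  s <- report$settings
  build_report(pair,
               thresholds = report$thresholds$size_ha,
               percentiles = s$percentiles,
               far_levels = s$far_levels,
               bootstrap = s$bootstrap,
               n_points = s$n_points, pad_bandwidths = s$pad_bandwidths,
               bandwidth = s$bandwidth, estimator = s$estimator)
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("<attribution_report> p0='%s' vs p1='%s'\n", x$labels$p0,
              x$labels$p1))
  cat(sprintf("  event threshold: %s ha | FAR = %.3f | RR = %.3f\n",
              format(x$event_threshold, big.mark = ","),
              x$far_at_threshold, x$rr_at_threshold))
  invisible(x)
}
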