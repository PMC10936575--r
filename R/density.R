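#' Kernel bandwidth for a fire-size sample
#'
#' Scott's rule for a one-dimensional Gaussian kernel, `sd(x) * n^(-1/5)`,
#' is the default; Silverman's rule ([stats::bw.nrd0()]) and explicit
#' numeric bandwidths are also accepted.
#'
#' @param x Numeric sample (fire sizes, ha).
#' @param rule `"scott"`, `"silverman"`, or a single positive number taken
#'   as the bandwidth itself (ha).
#' @return Bandwidth in hectares.
#' @export
fire_bandwidth <- function(x, rule = "scott") {
  if (is.numeric(rule)) {
    if (length(rule) != 1L || !is.finite(rule) || rule <= 0) {
      stop("explicit bandwidth must be a single positive number", call. = FALSE)
    }
    return(as.numeric(rule))
  }
  rule <- match.arg(rule, c("scott", "silverman"))
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) {
    stop("zero-variance sample: bandwidth rules require sd(x) > 0", call. = FALSE)
  }
  switch(rule,
    scott = s * length(x)^(-1 / 5),
    silverman = stats::bw.nrd0(x)
  )
}

#' Build one evaluation grid shared by every curve in an analysis
#'
#' FAR and RR are pointwise ratios of exceedance curves, so all curves in
#' one analysis must be evaluated on a single grid. The grid spans the
#' pooled sample range of all ensembles, padded by a multiple of the largest
#' per-ensemble kernel bandwidth (so essentially all kernel mass is covered)
#' and floored at zero (fire sizes cannot be negative).
#'
#' @param ensembles A `fire_ensemble`, a `scenario_pair`, or a list of
#'   ensembles.
#' @param n_points Number of grid points (default 512).
#' @param pad_bandwidths Padding beyond the pooled range, in units of the
#'   largest per-ensemble bandwidth (default 3, covering >= 99.7% of the
#'   mass of edge kernels). `0` makes the grid span exactly the pooled range.
#' @param bandwidth_rule Passed to [fire_bandwidth()] for the padding
#'   computation.
#' @return Strictly increasing numeric vector of fire sizes (ha).
#' @export
make_shared_grid <- function(ensembles, n_points = 512, pad_bandwidths = 3,
                             bandwidth_rule = "scott") {
  ensembles <- as_ensemble_list(ensembles)
  if (!is.numeric(n_points) || n_points < 2) {
    stop("`n_points` must be at least 2", call. = FALSE)
  }
  for (e in ensembles) {
    if (stats::sd(e$sizes) == 0) {
      stop(sprintf(
        "degenerate ensemble '%s': all fire sizes identical, no density can be estimated",
        e$label
      ), call. = FALSE)
    }
  }
  h_max <- if (is.numeric(bandwidth_rule)) {
    fire_bandwidth(NULL, bandwidth_rule)
  } else {
    max(vapply(ensembles, function(e) fire_bandwidth(e$sizes, bandwidth_rule),
               numeric(1)))
  }
  pooled <- unlist(lapply(ensembles, `[[`, "sizes"))
  lo <- max(0, min(pooled) - pad_bandwidths * h_max)
  hi <- max(pooled) + pad_bandwidths * h_max
  seq(lo, hi, length.out = as.integer(n_points))
}

as_ensemble_list <- function(x) {
  if (inherits(x, "fire_ensemble")) return(list(x))
  if (inherits(x, "scenario_pair")) return(list(x$p0_ensemble, x$p1_ensemble))
  if (is.list(x) && length(x) > 0 &&
      all(vapply(x, inherits, logical(1), "fire_ensemble"))) {
    return(x)
  }
  stop("expected a fire_ensemble, scenario_pair, or list of fire_ensembles",
       call. = FALSE)
}

#' Gaussian kernel density estimate of the fire-size distribution
#'
#' Sums Gaussian kernels centred at the sample points and evaluates them on
#' the supplied grid. Kernel mass falling outside the grid — in particular
#' any mass below fire size zero — is removed by truncation and the density
#' renormalised so its trapezoidal integral over the grid is exactly 1.
#'
#' @param ensemble A [fire_ensemble()] with at least 2 points and positive
#'   sample standard deviation.
#' @param grid Strictly increasing fire-size grid (ha) with at least 256
#'   points, e.g. from [make_shared_grid()].
#' @param bandwidth Bandwidth rule or explicit value; see [fire_bandwidth()].
#' @return An object of class `fire_density`: list with `grid`, `density`
#'   (per-ha), `bandwidth` (ha) and `source_label`.
#' @export
estimate_density <- function(ensemble, grid, bandwidth = "scott") {
  stopifnot(inherits(ensemble, "fire_ensemble"))
  check_grid(grid, min_points = 256)
  if (stats::sd(ensemble$sizes) == 0) {
    stop(sprintf("degenerate ensemble '%s': zero sample variance", ensemble$label),
         call. = FALSE)
  }
  h <- fire_bandwidth(ensemble$sizes, bandwidth)
  d <- kernel_sum(grid, ensemble$sizes, h)
  total <- trapz(grid, d)
  if (total <= 0) {
    stop("kernel density carries no mass on the supplied grid", call. = FALSE)
  }
  structure(
    list(grid = grid, density = d / total, bandwidth = h,
         source_label = ensemble$label),
    class = "fire_density"
  )
}

# Mean of Gaussian kernels; chunked so n = 10^4 samples on a 512-point grid
# stays within a few tens of MB.
kernel_sum <- function(grid, x, h) {
  n <- length(x)
  out <- numeric(length(grid))
  chunk <- 2000L
  for (i in seq(1L, n, by = chunk)) {
    xi <- x[i:min(n, i + chunk - 1L)]
    out <- out + rowSums(outer(grid, xi, function(g, v) stats::dnorm(g, v, h)))
  }
  out / n
}

check_grid <- function(grid, min_points = 2) {
  if (!is.numeric(grid) || length(grid) < min_points) {
    stop(sprintf("grid must be numeric with at least %d points", min_points),
         call. = FALSE)
  }
  if (any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  invisible(grid)
}

# Composite trapezoid integral over an (arbitrary-spacing) grid.
trapz <- function(x, y) {
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

#' Exceedance-probability curve from a kernel density
#'
#' Empirically integrates the density from each grid point upward:
#' `prob(s) = integral of the density from s to the grid maximum`, by the
#' composite trapezoid rule on the fixed grid, then clamps to \[0, 1\]. The
#' result is non-increasing by construction and estimates the strict
#' exceedance probability P(size > s).
#'
#' @param density A `fire_density` from [estimate_density()].
#' @return An object of class `exceedance_curve`: list with `grid`, `prob`,
#'   `estimator_kind = "kde"` and `source_label`.
#' @export
exceedance_from_density <- function(density) {
  stopifnot(inherits(density, "fire_density"))
  g <- density$grid
  d <- density$density
  seg <- diff(g) * (d[-length(d)] + d[-1]) / 2
  prob <- rev(cumsum(rev(c(seg, 0))))
  prob <- pmin(1, pmax(0, prob))
  structure(
    list(grid = g, prob = prob, estimator_kind = "kde",
         source_label = density$source_label),
    class = "exceedance_curve"
  )
}

#' Empirical (step-function) exceedance curve
#'
#' The plain counting estimator `prob(s) = #(sizes > s) / n`, sampled on the
#' grid. Exact on finite samples, it serves as the oracle against which the
#' smoothed KDE pathway is checked; both use the strict-exceedance
#' convention.
#'
#' @param ensemble A [fire_ensemble()].
#' @param grid Strictly increasing fire-size grid (ha).
#' @return An `exceedance_curve` with `estimator_kind = "empirical"`.
#' @export
empirical_exceedance <- function(ensemble, grid) {
  stopifnot(inherits(ensemble, "fire_ensemble"))
  check_grid(grid)
  xs <- sort(ensemble$sizes)
  # findInterval counts values <= s, so the strict complement is exact even
  # when grid points coincide with sample values.
  prob <- 1 - findInterval(grid, xs) / ensemble$n
  structure(
    list(grid = grid, prob = prob, estimator_kind = "empirical",
         source_label = ensemble$label),
    class = "exceedance_curve"
  )
}

#' @export
print.exceedance_curve <- function(x, ...) {
  cat(sprintf(
    "<exceedance_curve> '%s' (%s): %d grid points over [%s, %s] ha\n",
    x$source_label, x$estimator_kind, length(x$grid),
    format(round(min(x$grid)), big.mark = ","),
    format(round(max(x$grid)), big.mark = ",")
  ))
  invisible(x)
}

#' Evaluate an exceedance curve at arbitrary fire sizes
#'
#' Linear interpolation between grid points; sizes below the grid return the
#' first probability, sizes above it the last.
#'
#' @param curve An `exceedance_curve`.
#' @param size Fire sizes (ha) at which to evaluate.
#' @return Exceedance probabilities.
#' @export
exceedance_at <- function(curve, size) {
  stopifnot(inherits(curve, "exceedance_curve"))
  stats::approx(curve$grid, curve$prob, xout = size, rule = 2,
                ties = "ordered")$y
}

#' Fire size of a given percentile event
#'
#' The s-th percentile event is the fire size whose exceedance probability
#' is `1 - s`; e.g. a 90th-percentile event has exceedance 0.10. The size is
#' found by monotone linear interpolation on the curve.
#'
#' @param curve An `exceedance_curve`.
#' @param percentile Quantile in (0, 1).
#' @return Fire size in hectares.
#' @export
percentile_event_size <- function(curve, percentile) {
  stopifnot(inherits(curve, "exceedance_curve"))
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile >= 1) {
    stop("`percentile` must lie strictly between 0 and 1", call. = FALSE)
  }
  target <- 1 - percentile
  prob <- curve$prob
  lo <- min(prob)
  hi <- max(prob)
  if (target > hi || target < lo) {
    stop(sprintf(
      "target exceedance %.4g outside the attainable range [%.4g, %.4g] of curve '%s'",
      target, lo, hi, curve$source_label
    ), call. = FALSE)
  }
  i <- max(which(prob >= target))
  if (prob[i] == target) {
    return(curve$grid[i])
  }
  # prob[i] > target > prob[i + 1]; interpolate within the bracketing segment
  frac <- (prob[i] - target) / (prob[i] - prob[i + 1])
  curve$grid[i] + frac * (curve$grid[i + 1] - curve$grid[i])
}

#' Export an exceedance curve to CSV
#'
#' Columns: `size_ha`, `prob`, `estimator_kind`.
#'
#' @param curve An `exceedance_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exceedance_csv <- function(curve, path) {
  stopifnot(inherits(curve, "exceedance_curve"))
  utils::write.csv(
    data.frame(size_ha = curve$grid, prob = curve$prob,
               estimator_kind = curve$estimator_kind),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
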