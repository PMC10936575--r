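# Fuel-state codes for landscape rasters.
FUEL_NONBURNABLE <- 0L
FUEL_UNTREATED <- 1L
FUEL_TREATED <- 2L

#' Construct a raster fuel landscape
#'
#' A minimal landscape for the stochastic spread model: a width x height
#' grid of cells, each untreated, treated, or nonburnable, with a fixed
#' area per cell.
#'
#' @param width,height Cell counts (>= 1).
#' @param cell_area Hectares per cell (> 0; default 10).
#' @param fuel_state Optional integer matrix (`height` rows x `width`
#'   columns) of fuel codes: 0 nonburnable, 1 untreated, 2 treated.
#'   Defaults to all untreated.
#' @return An object of class `landscape_grid`.
#' @export
landscape_grid <- function(width = 64, height = 64, cell_area = 10,
                           fuel_state = NULL) {
  stopifnot(width >= 1, height >= 1, cell_area > 0)
  if (is.null(fuel_state)) {
    fuel_state <- matrix(FUEL_UNTREATED, nrow = height, ncol = width)
  }
  fuel_state <- matrix(as.integer(fuel_state), nrow = height, ncol = width)
  if (!all(fuel_state %in% c(FUEL_NONBURNABLE, FUEL_UNTREATED, FUEL_TREATED))) {
    stop("fuel_state codes must be 0 (nonburnable), 1 (untreated) or 2 (treated)",
         call. = FALSE)
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         cell_area = cell_area, fuel_state = fuel_state),
    class = "landscape_grid"
  )
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf(
    "<landscape_grid> %dx%d cells (%g ha each): %d burnable, %.1f%% treated\n",
    x$width, x$height, x$cell_area, sum(x$fuel_state != FUEL_NONBURNABLE),
    100 * treated_fraction(x)
  ))
  invisible(x)
}

#' Fraction of burnable cells currently treated
#'
#' @param landscape A [landscape_grid()].
#' @return Proportion in \[0, 1\].
#' @export
treated_fraction <- function(landscape) {
  burnable <- landscape$fuel_state != FUEL_NONBURNABLE
  if (!any(burnable)) return(0)
  sum(landscape$fuel_state[burnable] == FUEL_TREATED) / sum(burnable)
}

#' Stochastic spread-model parameters
#'
#' @param p_spread_untreated Per-neighbour ignition probability into
#'   untreated fuel, in (0, 1).
#' @param treatment_multiplier Factor in \[0, 1\] applied to the spread
#'   probability into treated cells (treatment slows fire entering treated
#'   fuel).
#' @param weather_sigma Standard deviation of the log of a per-fire
#'   lognormal multiplier (median 1) on spread probability, emulating
#'   between-event fire-weather variability. Effective probabilities are
#'   clamped to \[0, 1\].
#' @param max_steps Hard cap on spread iterations.
#' @return An object of class `spread_params`.
#' @export
spread_params <- function(p_spread_untreated = 0.35,
                          treatment_multiplier = 0.3,
                          weather_sigma = 0.5,
                          max_steps = 10000L) {
  stopifnot(
    p_spread_untreated > 0, p_spread_untreated < 1,
    treatment_multiplier >= 0, treatment_multiplier <= 1,
    weather_sigma >= 0,
    max_steps >= 1
  )
  structure(
    list(p_spread_untreated = p_spread_untreated,
         treatment_multiplier = treatment_multiplier,
         weather_sigma = weather_sigma,
         max_steps = as.integer(max_steps)),
    class = "spread_params"
  )
}

#' Simulation-run configuration
#'
#' @param n_fires Ensemble size (>= 1).
#' @param seed Integer seed governing every random draw of the run.
#' @param ignition_policy `"random"` (uniform over burnable cells) or a
#'   fixed cell index (column-major into the fuel matrix).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_fires = 2000, seed, ignition_policy = "random") {
  stopifnot(n_fires >= 1)
  if (missing(seed)) stop("`seed` must be supplied explicitly", call. = FALSE)
  if (!(identical(ignition_policy, "random") ||
        (is.numeric(ignition_policy) && length(ignition_policy) == 1L))) {
    stop("`ignition_policy` must be \"random\" or a single cell index",
         call. = FALSE)
  }
  structure(
    list(n_fires = as.integer(n_fires), seed = as.integer(seed),
         ignition_policy = ignition_policy),
    class = "sim_config"
  )
}

#' Randomly treat a fraction of the burnable landscape
#'
#' Returns a copy of the landscape in which exactly
#' `round(fraction * number of burnable cells)` burnable cells, chosen
#' uniformly at random under the seed, are switched to the treated state.
#' The input landscape is not modified.
#'
#' @param landscape A [landscape_grid()].
#' @param fraction Proportion of burnable cells to treat, in \[0, 1\].
#' @param seed Integer seed for the placement draw.
#' @return A new `landscape_grid`.
#' @export
apply_random_treatment <- function(landscape, fraction, seed) {
  stopifnot(inherits(landscape, "landscape_grid"))
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    stop("`fraction` must lie in [0, 1]", call. = FALSE)
  }
  fuel <- landscape$fuel_state
  burnable_idx <- which(fuel != FUEL_NONBURNABLE)
  k <- round(fraction * length(burnable_idx))
  if (k > 0) {
    chosen <- with_seed(seed,
                        burnable_idx[sample.int(length(burnable_idx), k)])
    fuel[chosen] <- FUEL_TREATED
  }
  landscape_grid(landscape$width, landscape$height, landscape$cell_area, fuel)
}

#' Simulate one stochastic fire on a landscape
#'
#' Discrete-time percolation spread: starting from the ignition cell, each
#' burning cell attempts — once — to ignite each of its four edge
#' neighbours. The attempt succeeds with the effective spread probability of
#' the *target* cell's fuel state (untreated: `p_spread_untreated`; treated:
#' times `treatment_multiplier`; nonburnable: 0), multiplied by the fire's
#' weather multiplier and clamped to \[0, 1\]. Burned cells never reburn;
#' spread stops when no new cells ignite or `max_steps` is reached.
#'
#' Because every directed cell-to-neighbour attempt happens at most once,
#' the randomness of a whole fire can be summarised by one uniform draw per
#' (cell, direction). Supplying that matrix as `edge_uniforms` makes paired
#' scenario comparisons use common random numbers with a monotone coupling:
#' lowering any cell's spread probability can only shrink the burned set.
#'
#' @param landscape A [landscape_grid()].
#' @param params A [spread_params()].
#' @param ignition Cell index (column-major) or `c(row, col)`; must be
#'   burnable.
#' @param weather Per-fire weather multiplier (default 1, i.e. median
#'   weather).
#' @param edge_uniforms Optional `ncell x 4` matrix of uniforms (directions
#'   ordered up, down, left, right); drawn from the current RNG when `NULL`.
#' @param return_mask If `TRUE`, also return the logical burned matrix.
#' @return Fire size in hectares (burned cells x cell area); with
#'   `return_mask = TRUE`, a list with `size_ha` and `burned`.
#' @export
simulate_fire <- function(landscape, params, ignition, weather = 1,
                          edge_uniforms = NULL, return_mask = FALSE) {
  stopifnot(inherits(landscape, "landscape_grid"),
            inherits(params, "spread_params"))
  h <- landscape$height
  w <- landscape$width
  ncell <- h * w
  if (length(ignition) == 2L) {
    ignition <- (ignition[2] - 1L) * h + ignition[1]
  }
  ignition <- as.integer(ignition)
  if (ignition < 1L || ignition > ncell) {
    stop("ignition cell index out of range", call. = FALSE)
  }
  fuel <- landscape$fuel_state
  if (fuel[ignition] == FUEL_NONBURNABLE) {
    stop("ignition cell is nonburnable", call. = FALSE)
  }
  if (is.null(edge_uniforms)) {
    edge_uniforms <- matrix(stats::runif(ncell * 4L), nrow = ncell, ncol = 4L)
  }
  p_cell <- numeric(ncell)
  p_cell[fuel == FUEL_UNTREATED] <- params$p_spread_untreated
  p_cell[fuel == FUEL_TREATED] <-
    params$p_spread_untreated * params$treatment_multiplier
  p_cell <- pmin(1, pmax(0, p_cell * weather))

  burned <- logical(ncell)
  burned[ignition] <- TRUE
  frontier <- ignition
  # direction offsets in column-major order: up, down, left, right
  steps <- 0L
  while (length(frontier) > 0L && steps < params$max_steps) {
    steps <- steps + 1L
    rows <- (frontier - 1L) %% h + 1L
    cols <- (frontier - 1L) %/% h + 1L
    new_cells <- integer(0)
    for (d in 1:4) {
      valid <- switch(d,
        rows > 1L,   # up
        rows < h,    # down
        cols > 1L,   # left
        cols < w     # right
      )
      if (!any(valid)) next
      src <- frontier[valid]
      tgt <- src + switch(d, -1L, 1L, -h, h)
      hit <- !burned[tgt] & edge_uniforms[cbind(src, d)] < p_cell[tgt]
      if (any(hit)) new_cells <- c(new_cells, tgt[hit])
    }
    new_cells <- unique(new_cells)
    burned[new_cells] <- TRUE
    frontier <- new_cells
  }
  size <- sum(burned) * landscape$cell_area
  if (return_mask) {
    list(size_ha = size, burned = matrix(burned, nrow = h, ncol = w))
  } else {
    size
  }
}

#' Run a paired treatment experiment
#'
#' Simulates `n_fires` fires on a family of landscapes that differ only in
#' their random treatment extent, using common random numbers: each fire
#' index shares its ignition site, weather multiplier, and per-edge spread
#' uniforms across all scenarios, so treatment effects are not drowned by
#' between-fire noise. With the shared edge uniforms the coupling is
#' monotone — per fire, a scenario with more treatment can never burn more
#' cells than one with less.
#'
#' @param base A [landscape_grid()] describing the untreated condition.
#' @param fractions Treatment proportions, one scenario each; `0` is the
#'   untreated baseline.
#' @param params A [spread_params()].
#' @param config A [sim_config()].
#' @return Named list of [fire_ensemble()] objects, labelled `"untreated"`
#'   for fraction 0 and `"randN"` for a fraction of N percent.
#' @export
run_paired_experiment <- function(base, fractions, params, config) {
  stopifnot(inherits(base, "landscape_grid"),
            inherits(params, "spread_params"),
            inherits(config, "sim_config"))
  if (length(fractions) < 1L) {
    stop("at least one treatment fraction is required", call. = FALSE)
  }
  labels <- scenario_label(fractions)
  # distinct placement seed per scenario, derived from the run seed
  landscapes <- lapply(seq_along(fractions), function(i) {
    if (fractions[i] == 0) base
    else apply_random_treatment(base, fractions[i],
                                seed = (config$seed + i) %% .Machine$integer.max)
  })
  burnable_idx <- which(base$fuel_state != FUEL_NONBURNABLE)
  ncell <- base$height * base$width
  n <- config$n_fires

  sizes <- matrix(NA_real_, nrow = n, ncol = length(fractions))
  with_seed(config$seed, {
    ignitions <- if (identical(config$ignition_policy, "random")) {
      burnable_idx[sample.int(length(burnable_idx), n, replace = TRUE)]
    } else {
      rep(as.integer(config$ignition_policy), n)
    }
    weathers <- if (params$weather_sigma > 0) {
      exp(stats::rnorm(n, 0, params$weather_sigma))
    } else {
      rep(1, n)
    }
    for (i in seq_len(n)) {
      edge_u <- matrix(stats::runif(ncell * 4L), nrow = ncell, ncol = 4L)
      for (s in seq_along(landscapes)) {
        sizes[i, s] <- simulate_fire(landscapes[[s]], params, ignitions[i],
                                     weather = weathers[i],
                                     edge_uniforms = edge_u)
      }
    }
  })
  out <- lapply(seq_along(fractions), function(s) {
    fire_ensemble(sizes[, s], label = labels[s])
  })
  stats::setNames(out, labels)
}

scenario_label <- function(fractions) {
  labels <- ifelse(fractions == 0, "untreated",
                   sprintf("rand%g", round(100 * fractions)))
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels, sep = "_")
  }
  labels
}
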