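#' Construct a fire-size ensemble
#'
#' A fire-size ensemble is a labelled sample of final fire sizes (hectares)
#' produced by repeated stochastic simulation of fire growth under one
#' landscape scenario. It is the raw input to density estimation and risk
#' attribution.
#'
#' @param sizes Numeric vector of final fire sizes in hectares. All values
#'   must be finite and strictly positive, and at least two are required so
#'   that a kernel density can be estimated downstream.
#' @param label Free-text scenario name (e.g. `"actual"`, `"untreated"`).
#' @return An object of class `fire_ensemble`: a list with elements `label`,
#'   `sizes` (in input order) and `n`.
#' @examples
#' fire_ensemble(c(74034, 86471, 82179), label = "actual")
#' @export
fire_ensemble <- function(sizes, label) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("`label` must be a single non-empty string", call. = FALSE)
  }
  if (!is.numeric(sizes)) {
    stop("fire sizes must be numeric (hectares)", call. = FALSE)
  }
  sizes <- as.numeric(sizes)
  bad <- which(!is.finite(sizes) | sizes <= 0)
  if (length(bad) > 0L) {
    stop(sprintf(
      "fire sizes must be strictly positive and finite; offending row(s): %s",
      paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  if (length(sizes) < 2L) {
    stop("ensemble too small: at least 2 fire sizes are required", call. = FALSE)
  }
  structure(
    list(label = label, sizes = sizes, n = length(sizes)),
    class = "fire_ensemble"
  )
}

#' @export
print.fire_ensemble <- function(x, ...) {
  cat(sprintf(
    "<fire_ensemble> '%s': n = %d, range = [%s, %s] ha\n",
    x$label, x$n,
    format(min(x$sizes), big.mark = ","),
    format(max(x$sizes), big.mark = ",")
  ))
  invisible(x)
}

#' Read a fire-size ensemble from CSV
#'
#' Reads a comma-separated, UTF-8 file with a required header column
#' `fire_size_ha`. An optional `scenario` column allows one file to hold
#' several ensembles; use `scenario` to select one.
#'
#' @param path Path to the CSV file.
#' @param label Scenario name for the returned ensemble. Defaults to the
#'   selected `scenario` value if present, otherwise the file name without
#'   extension.
#' @param scenario If the file has a `scenario` column, the value to select.
#'   Required when the column holds more than one distinct value.
#' @return A [fire_ensemble()] with rows in file order.
#' @export
read_ensemble <- function(path, label = NULL, scenario = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("ensemble file not found: '%s'", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!"fire_size_ha" %in% names(df)) {
    stop(sprintf(
      "'%s' is missing the required header column 'fire_size_ha'", path
    ), call. = FALSE)
  }
  if ("scenario" %in% names(df)) {
    present <- unique(df$scenario)
    if (is.null(scenario)) {
      if (length(present) > 1L) {
        stop(sprintf(
          "file holds multiple scenarios (%s); pass `scenario` to select one",
          paste(present, collapse = ", ")
        ), call. = FALSE)
      }
      scenario <- present
    } else if (!scenario %in% present) {
      stop(sprintf(
        "scenario '%s' not found in '%s' (present: %s)",
        scenario, path, paste(present, collapse = ", ")
      ), call. = FALSE)
    }
    df <- df[df$scenario == scenario, , drop = FALSE]
  }
  raw <- df$fire_size_ha
  if (is.character(raw)) {
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(parsed) & !is.na(raw))
    if (length(bad) > 0L) {
      stop(sprintf(
        "non-numeric fire_size_ha value(s) at data row(s): %s",
        paste(bad, collapse = ", ")
      ), call. = FALSE)
    }
    raw <- parsed
  }
  if (anyNA(raw)) {
    stop(sprintf(
      "missing fire_size_ha value(s) at data row(s): %s",
      paste(which(is.na(raw)), collapse = ", ")
    ), call. = FALSE)
  }
  if (is.null(label)) {
    label <- if (!is.null(scenario)) scenario else sub("\\.[^.]*$", "", basename(path))
  }
  fire_ensemble(raw, label = label)
}

#' Write one or more ensembles to CSV
#'
#' Inverse of [read_ensemble()]: writes `fire_size_ha` plus a `scenario`
#' column when more than one ensemble is given.
#'
#' @param x A `fire_ensemble` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(x, path) {
  if (inherits(x, "fire_ensemble")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "fire_ensemble")))
  df <- do.call(rbind, lapply(x, function(e) {
    data.frame(scenario = e$label, fire_size_ha = e$sizes)
  }))
  if (length(x) == 1L) df$scenario <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pair two ensembles under an explicit exceedance-role convention
#'
#' Risk attribution compares exceedance probabilities between two worlds:
#' `p0` for the reference (typically mitigated/treated) landscape and `p1`
#' for the comparison (typically unmitigated/counterfactual) landscape. In a
#' post-event reanalysis the factual landscape plays p0 and the untreated
#' counterfactual plays p1; in a prospective treatment evaluation the roles
#' reverse, with the hypothetically treated landscape as p0 and the present
#' untreated landscape as p1. Because both conventions are legitimate, the
#' caller must always declare which ensemble plays which role; nothing is
#' inferred from the data.
#'
#' @param p0_ensemble [fire_ensemble()] whose exceedance curve is p0.
#' @param p1_ensemble [fire_ensemble()] whose exceedance curve is p1.
#' @param direction_note Free text recording which real-world landscape plays
#'   which role, stored verbatim in reports.
#' @return An object of class `scenario_pair`.
#' @export
scenario_pair <- function(p0_ensemble, p1_ensemble,
                          direction_note = "caller-declared: first ensemble is p0") {
  stopifnot(
    inherits(p0_ensemble, "fire_ensemble"),
    inherits(p1_ensemble, "fire_ensemble")
  )
  if (identical(p0_ensemble$label, p1_ensemble$label)) {
    stop("the two ensembles of a scenario pair must carry distinct labels",
         call. = FALSE)
  }
  structure(
    list(
      p0_ensemble = p0_ensemble,
      p1_ensemble = p1_ensemble,
      direction_note = direction_note
    ),
    class = "scenario_pair"
  )
}

#' @export
print.scenario_pair <- function(x, ...) {
  cat(sprintf(
    "<scenario_pair> p0: '%s' (n=%d) | p1: '%s' (n=%d)\n  %s\n",
    x$p0_ensemble$label, x$p0_ensemble$n,
    x$p1_ensemble$label, x$p1_ensemble$n,
    x$direction_note
  ))
  invisible(x)
}

# Final fire sizes (ha) for the 2011 Las Conchas Fire, 10 FARSITE replicates
# per landscape, sorted smallest to largest. Bundled verbatim.
.las_conchas_actual <- c(
  74034, 76379, 78883, 79492, 82179,
  82263, 82428, 83019, 83339, 86471
)
.las_conchas_counterfactual <- c(
  93697, 97847, 99808, 100588, 103237,
  105645, 105974, 108534, 111411, 112049
)

#' The Las Conchas Fire counterfactual ensemble pair
#'
#' Final fire sizes for ten simulated replays of the 2011 Las Conchas Fire
#' (New Mexico, USA) on the actual landscape, and ten replays of the same
#' fire on a counterfactual landscape without previously treated or burned
#' areas. Replicates differ through stochastic spot-fire behaviour. The
#' actual landscape plays p0 (reference) and the counterfactual untreated
#' landscape plays p1, the post-event attribution convention.
#'
#' The same data ship as a CSV at
#' `system.file("extdata", "las_conchas.csv", package = "firefar")`.
#'
#' @return A [scenario_pair()] with ensembles labelled `"actual"` (n = 10)
#'   and `"counterfactual"` (n = 10).
#' @examples
#' pair <- las_conchas()
#' sum(pair$p0_ensemble$sizes) # 808487
#' @export
las_conchas <- function() {
  scenario_pair(
    fire_ensemble(.las_conchas_actual, label = "actual"),
    fire_ensemble(.las_conchas_counterfactual, label = "counterfactual"),
    direction_note = paste(
      "post-event reanalysis: actual (previously treated/burned) landscape",
      "is p0; counterfactual untreated landscape is p1"
    )
  )
}
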