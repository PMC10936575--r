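#' Write an attribution report to JSON
#'
#' Serializes an [build_report()] result to structured JSON that round-trips
#' losslessly through [read_report()]. Undefined statistics (`NA`/`NaN`) are
#' written as JSON `null`; infinite relative risks are written as the
#' explicit strings `"Inf"`/`"-Inf"` (JSON has no infinity token) and
#' restored on read.
#'
#' @param report An `attribution_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "attribution_report"))
  jsonlite::write_json(
    encode_inf(unclass(report)), path,
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}

# Recursively replace infinite numerics by marker strings jsonlite can
# carry, and turn named atomic vectors into named lists (jsonlite writes
# atomic vectors as plain arrays, dropping names).
encode_inf <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    return(lapply(x, encode_inf))
  }
  if (is.data.frame(x)) {
    x[] <- lapply(x, encode_inf)
    return(x)
  }
  if (is.numeric(x) && (any(is.infinite(x)) || !is.null(names(x)))) {
    out <- as.list(x)
    out[is.infinite(x)] <- ifelse(x[is.infinite(x)] > 0, "Inf", "-Inf")
    names(out) <- names(x)
    return(out)
  }
  x
}

#' Read an attribution report written by [write_report()]
#'
#' @param path Path to the JSON file.
#' @return An `attribution_report`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("report file not found: '%s'", path), call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)

  num <- function(x) {
    if (is.null(x)) return(NA_real_)
    v <- vapply(x, function(el) {
      if (is.null(el)) return(NA_real_)
      if (identical(el, "Inf")) return(Inf)
      if (identical(el, "-Inf")) return(-Inf)
      as.numeric(el)
    }, numeric(1))
    if (!is.null(names(x))) names(v) <- names(x) else names(v) <- NULL
    v
  }
  num1 <- function(x) unname(num(list(x)))
  rows_df <- function(rows, cols) {
    out <- lapply(cols, function(cn) num(lapply(rows, `[[`, cn)))
    names(out) <- cols
    as.data.frame(out)
  }

  out <- list(
    labels = list(p0 = raw$labels$p0, p1 = raw$labels$p1),
    direction_note = raw$direction_note,
    event_threshold = num1(raw$event_threshold),
    far_at_threshold = num1(raw$far_at_threshold),
    rr_at_threshold = num1(raw$rr_at_threshold),
    thresholds = rows_df(raw$thresholds, c("size_ha", "p0", "p1", "far", "rr")),
    percentile_events = list(p0 = num(raw$percentile_events$p0),
                             p1 = num(raw$percentile_events$p1)),
    far_crossings = num(raw$far_crossings)
  )
  if (!is.null(raw$bootstrap)) {
    out$bootstrap <- list(
      band_level = num1(raw$bootstrap$band_level),
      replicates = num1(raw$bootstrap$replicates),
      seed = num1(raw$bootstrap$seed),
      bands = rows_df(raw$bootstrap$bands,
                      c("size_ha", "far_lo", "far_hi", "rr_lo", "rr_hi"))
    )
  }
  out$settings <- list(
    n_points = num1(raw$settings$n_points),
    pad_bandwidths = num1(raw$settings$pad_bandwidths),
    bandwidth = if (is.character(raw$settings$bandwidth)) {
      raw$settings$bandwidth
    } else {
      num1(raw$settings$bandwidth)
    },
    estimator = raw$settings$estimator,
    percentiles = unname(num(raw$settings$percentiles)),
    far_levels = unname(num(raw$settings$far_levels))
  )
  if (!is.null(raw$settings$bootstrap)) {
    out$settings$bootstrap <- list(
      replicates = num1(raw$settings$bootstrap$replicates),
      seed = num1(raw$settings$bootstrap$seed),
      band_level = num1(raw$settings$bootstrap$band_level)
    )
  }
  out$inputs <- list(p0 = unname(num(raw$inputs$p0)),
                     p1 = unname(num(raw$inputs$p1)))
  structure(out, class = "attribution_report")
}
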