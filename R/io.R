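#' Read and write pipeline tables
#'
#' CSV readers/writers for the pipeline's tabular artifacts. Dates are
#' ISO-8601 (`YYYY-MM-DD`) and missing values are empty fields.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return The input (writers, invisibly) or a tibble (readers).
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(x)
}

#' @rdname pipeline_io
#' @export
read_persons_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  tibble::as_tibble(raw) |>
    dplyr::mutate(
      death_month = as.Date(.data$death_month),
      imd_quintile = as.integer(.data$imd_quintile),
      months_followup = as.integer(.data$months_followup)
    )
}

#' @rdname pipeline_io
#' @export
read_events_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  tibble::as_tibble(raw) |>
    dplyr::mutate(
      event_date = as.Date(.data$event_date),
      value = as.numeric(.data$value)
    )
}

#' Save or load a scenario configuration as JSON
#'
#' Serializes every field of a [scenario_config()] to a self-describing JSON
#' file and reconstructs (and re-validates) the object on read.
#'
#' @param config A `scenario_config`.
#' @param path JSON file path.
#' @return `read_scenario()` returns a validated `scenario_config`.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  ser <- unclass(config)
  ser$date_range <- format(ser$date_range, "%Y-%m-%d")
  for (v in c(
    "factor_log_rate", "seasonal_amplitude", "seasonal_phase",
    "contaminant_probs", "death_hazard"
  )) {
    ser[[v]] <- as.list(ser[[v]])
  }
  ser$subgroup_mix <- lapply(ser$subgroup_mix, as.list)
  ser$subgroup_log_effects <- lapply(ser$subgroup_log_effects, as.list)
  ser$disruption <- lapply(ser$disruption, function(d) {
    d$onset <- format(first_of_month(d$onset), "%Y-%m-%d")
    d$half_life <- if (is.infinite(d$half_life)) "Inf" else d$half_life
    d
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  ser$date_range <- as.Date(ser$date_range)
  ser$factors <- as.character(ser$factors)
  for (v in c(
    "factor_log_rate", "seasonal_amplitude", "seasonal_phase",
    "contaminant_probs", "death_hazard"
  )) {
    ser[[v]] <- unlist(ser[[v]])
  }
  ser$subgroup_mix <- lapply(ser$subgroup_mix, unlist)
  ser$subgroup_log_effects <- lapply(ser$subgroup_log_effects, unlist)
  ser$disruption <- lapply(ser$disruption, function(d) {
    list(
      depth = d$depth, onset = as.Date(d$onset),
      half_life = if (identical(d$half_life, "Inf")) Inf else as.numeric(d$half_life),
      offset = d$offset
    )
  })
  do.call(scenario_config, ser)
}

#' Save or load a fitted trend model as JSON
#'
#' Persists a `trend_fit` (coefficients, covariance, dispersion, smoothing
#' state, basis specification, constraint projection and fit window) as a
#' self-describing JSON artifact, and restores it for prediction.
#'
#' @param fit A `trend_fit`.
#' @param path JSON file path.
#' @return `read_trend_fit()` returns a `trend_fit` usable with
#'   [predict_eta()] and the projection functions.
#' @export
write_trend_fit <- function(fit, path) {
  stopifnot(inherits(fit, "trend_fit"))
  ser <- list(
    coefficients = as.list(fit$coefficients),
    cov = list(values = as.vector(fit$cov), dim = dim(fit$cov)),
    phi = fit$phi, lambda = fit$lambda, edf = fit$edf,
    deviance = fit$deviance, pearson = fit$pearson, n = fit$n,
    iterations = fit$iterations, converged = fit$converged,
    fit_window = if (!is.null(fit$fit_window)) format(fit$fit_window, "%Y-%m-%d"),
    meta = list(
      by = fit$meta$by,
      levels = fit$meta$levels,
      basis = unclass(fit$meta$basis),
      Z = list(values = as.vector(fit$meta$Z), dim = dim(fit$meta$Z)),
      penalty_order = fit$meta$penalty_order,
      reference = format(fit$meta$reference, "%Y-%m-%d"),
      fit_months = format(fit$meta$fit_months, "%Y-%m-%d")
    ),
    rows = as.data.frame(dplyr::mutate(
      fit$rows,
      month = format(.data$month, "%Y-%m-%d")
    ))
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fit)
}

#' @rdname write_trend_fit
#' @export
read_trend_fit <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- unlist(ser$coefficients)
  cov <- matrix(ser$cov$values, ser$cov$dim[1], ser$cov$dim[2],
    dimnames = list(names(coefs), names(coefs))
  )
  meta <- list(
    by = as.character(ser$meta$by %||% character(0)),
    levels = lapply(ser$meta$levels, as.character),
    basis = cyclic_basis_spec(ser$meta$basis$k, ser$meta$basis$degree, ser$meta$basis$period),
    Z = matrix(ser$meta$Z$values, ser$meta$Z$dim[1], ser$meta$Z$dim[2]),
    penalty_order = ser$meta$penalty_order,
    reference = as.Date(ser$meta$reference),
    fit_months = as.Date(ser$meta$fit_months)
  )
  rows <- tibble::as_tibble(ser$rows)
  rows$month <- as.Date(rows$month)
  structure(
    list(
      coefficients = coefs, cov = cov, phi = ser$phi, lambda = ser$lambda,
      edf = ser$edf, deviance = ser$deviance, pearson = ser$pearson,
      n = ser$n, iterations = ser$iterations, converged = ser$converged,
      fit_window = if (!is.null(ser$fit_window)) as.Date(ser$fit_window),
      flagged_strata = tibble::tibble(), meta = meta, rows = rows
    ),
    class = "trend_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
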