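#' Counterfactual rate projections
#'
#' `project_continued()` projects the fitted trend model directly: the rate
#' per 1,000 is `exp(eta) * 1000` with the trend index at its true value for
#' each month, and the 95% confidence interval is `exp(eta +/- z * se) *
#' 1000`. `project_frozen()` instead holds the long-term trend at its level
#' at the reference month by zeroing the trend index (and its subgroup
#' interactions) for months after the reference; months at or before the
#' reference are identical to the continued projection.
#'
#' @param model A `trend_fit` from [fit_trend_model()].
#' @param newdata Tibble of `month` plus the fit's stratification variables.
#' @param level Confidence level for the interval.
#' @return `newdata` with columns `rate`, `lower`, `upper` (per 1,000).
#' @export
project_continued <- function(model, newdata, level = 0.95) {
  project_rate(model, newdata, freeze_trend = FALSE, level = level)
}

#' @rdname project_continued
#' @export
project_frozen <- function(model, newdata, level = 0.95) {
  project_rate(model, newdata, freeze_trend = TRUE, level = level)
}

project_rate <- function(model, newdata, freeze_trend, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  predict_eta(model, newdata, freeze_trend = freeze_trend) |>
    dplyr::mutate(
      rate = exp(.data$eta) * 1000,
      lower = exp(.data$eta - z * .data$se_eta) * 1000,
      upper = exp(.data$eta + z * .data$se_eta) * 1000
    ) |>
    dplyr::select(-"eta", -"se_eta")
}

#' Composite expectation band
#'
#' Combines two confidence intervals into the composite band: the lower
#' bound is the minimum of the two lower bounds, the upper bound the maximum
#' of the two upper bounds, and the point estimate the midpoint of the
#' combined band. Taking the union of the two projection intervals yields a
#' deliberately conservative range of expected values.
#'
#' @param lower_a,upper_a,lower_b,upper_b Interval endpoints (vectorized).
#' @return A tibble with `lower`, `upper`, `expected` (the midpoint).
#' @examples
#' composite_band(-36.9, -10.0, -20.0, -0.5) # band (-36.9, -0.5)
#' @export
composite_band <- function(lower_a, upper_a, lower_b, upper_b) {
  if (any(lower_a > upper_a) || any(lower_b > upper_b)) {
    stop("inverted interval: lower bound exceeds upper bound", call. = FALSE)
  }
  lower <- pmin(lower_a, lower_b)
  upper <- pmax(upper_a, upper_b)
  tibble::tibble(lower = lower, upper = upper, expected = band_midpoint(lower, upper))
}

#' Midpoint of an expectation band
#'
#' @param lower,upper Band endpoints with `lower <= upper`.
#' @return `(lower + upper) / 2`.
#' @examples
#' band_midpoint(-36.9, -0.5) # -18.7
#' @export
band_midpoint <- function(lower, upper) {
  if (any(lower > upper)) stop("`lower` must not exceed `upper`", call. = FALSE)
  (lower + upper) / 2
}

#' Per-month composite expectation band for a fitted model
#'
#' Runs both counterfactual projections over the requested months and
#' subgroup cells and combines them into the composite band. When `observed`
#' is supplied (a [monthly_rates()] table), the observed rate is joined on
#' so deviations can be computed directly.
#'
#' @param model A `trend_fit`.
#' @param months `Date` vector of months to project (default: the months of
#'   `observed`).
#' @param observed Optional monthly rate table to join observed rates from.
#' @param level Confidence level of each component interval.
#' @return A tibble with one row per subgroup-month: stratification columns,
#'   `month`, the two component intervals (`lower_cont`, `upper_cont`,
#'   `lower_froz`, `upper_froz`), the band (`lower`, `upper`, `expected`)
#'   and, if available, `rate` and `denominator` from `observed`.
#' @export
expectation_band <- function(model, months = NULL, observed = NULL, level = 0.95) {
  by <- model$meta$by
  if (is.null(months)) {
    if (is.null(observed)) {
      stop("supply `months` or `observed` to define the projection window",
        call. = FALSE
      )
    }
    months <- sort(unique(observed$month))
  }
  cells <- dplyr::distinct(model$rows, dplyr::across(dplyr::all_of(by)))
  newdata <- tidyr::expand_grid(cells, month = sort(unique(first_of_month(months))))
  cont <- project_continued(model, newdata, level = level) |>
    dplyr::rename(rate_cont = "rate", lower_cont = "lower", upper_cont = "upper")
  froz <- project_frozen(model, newdata, level = level) |>
    dplyr::rename(rate_froz = "rate", lower_froz = "lower", upper_froz = "upper")
  band <- dplyr::inner_join(cont, froz, by = c(by, "month"))
  band <- dplyr::bind_cols(
    band,
    composite_band(band$lower_cont, band$upper_cont, band$lower_froz, band$upper_froz)
  )
  if (!is.null(observed)) {
    obs_cols <- intersect(c("factor", by, "month", "count", "denominator", "rate"),
      names(observed)
    )
    band <- dplyr::left_join(
      band, dplyr::select(observed, dplyr::all_of(obs_cols)),
      by = c(by, "month")
    )
  }
  dplyr::arrange(band, dplyr::across(dplyr::all_of(by)), .data$month)
}

#' Absolute and relative deviation from the expectation band
#'
#' The absolute deviation is observed minus expected (per 1,000) with
#' interval `(observed - upper, observed - lower)`; the relative deviation
#' is `100 * (observed - expected) / expected` with interval endpoints
#' evaluated against the corresponding band bounds,
#' `(100 (O - U) / U, 100 (O - L) / L)`. The relative deviation requires a
#' strictly positive expected midpoint.
#'
#' @param observed Observed rate(s) per 1,000.
#' @param lower,upper Expectation band bounds per 1,000.
#' @return Tibble with `d_abs`, `d_abs_lower`, `d_abs_upper`, `d_rel`,
#'   `d_rel_lower`, `d_rel_upper`.
#' @examples
#' deviation(84, 95, 105) # observed below a (95, 105) band
#' @export
deviation <- function(observed, lower, upper) {
  expected <- band_midpoint(lower, upper)
  if (any(expected <= 0)) {
    stop("relative deviation undefined: expected midpoint must be positive",
      call. = FALSE
    )
  }
  tibble::tibble(
    observed = observed, lower = lower, upper = upper, expected = expected,
    d_abs = observed - expected,
    d_abs_lower = observed - upper,
    d_abs_upper = observed - lower,
    d_rel = 100 * (observed - expected) / expected,
    d_rel_lower = 100 * (observed - upper) / upper,
    d_rel_upper = 100 * (observed - lower) / lower
  )
}

#' Default reporting periods
#'
#' The three post-onset summary windows used for reporting: the two years of
#' pandemic restrictions, the following year, and the final thirteen months
#' of the study window.
#'
#' @return Tibble with `label`, `start`, `end`.
#' @export
summary_periods <- function() {
  tibble::tibble(
    label = c("Mar 2020-Feb 2022", "Mar 2022-Feb 2023", "Mar 2023-Mar 2024"),
    start = c(ym(2020, 3), ym(2022, 3), ym(2023, 3)),
    end = c(ym(2022, 2), ym(2023, 2), ym(2024, 3))
  )
}

#' Period-level deviation summaries
#'
#' Averages the monthly observed rate and the monthly band (bounds and
#' midpoint) over each reporting period, then computes the absolute and
#' relative deviation of the period means. Every month of a period must be
#' present.
#'
#' @param band_tbl Output of [expectation_band()] including observed `rate`.
#' @param periods Tibble of `label`, `start`, `end` (default
#'   [summary_periods()]).
#' @return One row per subgroup cell and period with period means and the
#'   deviation columns of [deviation()].
#' @export
period_summary <- function(band_tbl, periods = summary_periods()) {
  by <- setdiff(
    intersect(
      c("age_band", "sex", "ethnicity", "imd_quintile"),
      names(band_tbl)
    ),
    character(0)
  )
  if (!"rate" %in% names(band_tbl)) {
    stop("`band_tbl` must carry the observed `rate` column", call. = FALSE)
  }
  purrr::pmap(periods, function(label, start, end) {
    wanted <- month_seq(start, end)
    sub <- dplyr::filter(band_tbl, .data$month %in% wanted)
    got <- sub |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::summarise(n_months = dplyr::n_distinct(.data$month), .groups = "drop")
    if (nrow(sub) == 0 || any(got$n_months < length(wanted))) {
      missing <- setdiff(format(wanted, "%Y-%m"), format(unique(sub$month), "%Y-%m"))
      stop(sprintf(
        "period '%s' is missing month(s): %s", label,
        paste(if (length(missing)) missing else "(subgroup gaps)", collapse = ", ")
      ), call. = FALSE)
    }
    sub |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::summarise(
        observed = mean(.data$rate),
        lower = mean(.data$lower),
        upper = mean(.data$upper),
        .groups = "drop"
      ) |>
      dplyr::mutate(period = label, .before = 1) |>
      dplyr::mutate(deviation(.data$observed, .data$lower, .data$upper)[-(1:3)])
  }) |> purrr::list_rbind()
}

#' Aggregate subgroup expectations to an overall series
#'
#' Collapses subgroup-level observed rates and band bounds to an overall
#' series by count-space aggregation: each per-1,000 quantity is multiplied
#' by its subgroup denominator, summed over the complete subgroup partition,
#' and divided by the total denominator. The subgroup set must be identical
#' in every month.
#'
#' @param band_tbl Output of [expectation_band()] with observed `rate` and
#'   `denominator` columns.
#' @return One row per month with aggregated `rate`, `lower`, `upper`,
#'   `expected`, and `denominator`.
#' @export
aggregate_overall <- function(band_tbl) {
  by <- intersect(c("age_band", "sex", "ethnicity", "imd_quintile"), names(band_tbl))
  if (length(by) == 0) {
    return(dplyr::select(
      band_tbl, dplyr::any_of(c("factor", "month", "denominator", "rate")),
      "lower", "upper", "expected"
    ))
  }
  if (!all(c("rate", "denominator") %in% names(band_tbl))) {
    stop("`band_tbl` must carry observed `rate` and `denominator`", call. = FALSE)
  }
  key_sets <- band_tbl |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(
      key = paste(sort(do.call(paste, c(dplyr::pick(dplyr::all_of(by)), sep = "|"))),
        collapse = ";"
      ),
      .groups = "drop"
    )
  if (dplyr::n_distinct(key_sets$key) > 1) {
    stop("subgroup sets differ across months; cannot aggregate", call. = FALSE)
  }
  band_tbl |>
    dplyr::group_by(dplyr::across(dplyr::any_of("factor")), .data$month) |>
    dplyr::summarise(
      rate = sum(.data$rate * .data$denominator) / sum(.data$denominator),
      lower = sum(.data$lower * .data$denominator) / sum(.data$denominator),
      upper = sum(.data$upper * .data$denominator) / sum(.data$denominator),
      denominator = sum(.data$denominator),
      .groups = "drop"
    ) |>
    dplyr::mutate(expected = band_midpoint(.data$lower, .data$upper))
}
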