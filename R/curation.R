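#' Apply the cohort eligibility cascade
#'
#' Filters a person table with the fixed exclusion sequence: under 18 years
#' at the index date, then unknown recorded sex, then no valid area of
#' residence (missing deprivation quintile), then less than one month of
#' follow-up. Each person is attributed to the first rule they fail, so the
#' buckets partition the exclusions and the tally conserves the input total.
#'
#' @param persons Person tibble with `age_at_index`, `sex`, `imd_quintile`
#'   and `months_followup` columns.
#' @param index_date Index date at which age applies (default 1 November
#'   2018). Recorded in the tally attributes; ages are taken as already
#'   computed at this date.
#' @return A list with `eligible` (the retained persons, unchanged columns)
#'   and `tally` (an [exclusion_tally()]).
#' @examples
#' p <- tibble::tibble(
#'   age_at_index = c(10, 30, 40), sex = c("male", "unknown", "female"),
#'   imd_quintile = c(1, 2, 3), months_followup = c(12, 12, 12)
#' )
#' apply_exclusions(p)$tally
#' @export
apply_exclusions <- function(persons, index_date = as.Date("2018-11-01")) {
  fail_u18 <- persons$age_at_index < 18
  fail_sex <- !fail_u18 & !(persons$sex %in% c("female", "male"))
  fail_area <- !fail_u18 & !fail_sex & is.na(persons$imd_quintile)
  fail_fup <- !fail_u18 & !fail_sex & !fail_area & persons$months_followup < 1
  keep <- !(fail_u18 | fail_sex | fail_area | fail_fup)
  tally <- exclusion_tally(
    input_total = nrow(persons),
    excluded_under18 = sum(fail_u18),
    excluded_unknown_sex = sum(fail_sex),
    excluded_no_area = sum(fail_area),
    excluded_short_followup = sum(fail_fup)
  )
  attr(tally, "index_date") <- index_date
  list(eligible = persons[keep, , drop = FALSE], tally = tally)
}

#' Exclusion tally arithmetic
#'
#' One-row tibble recording the eligibility cascade: the input total, the
#' count excluded by each rule (first failing rule only) and the implied
#' included count. `included = input_total - sum(exclusions)` always holds.
#'
#' @param input_total Total persons entering the cascade.
#' @param excluded_under18,excluded_unknown_sex,excluded_no_area,excluded_short_followup
#'   Counts excluded by each rule, in cascade order.
#' @return A tibble of class `exclusion_tally`.
#' @examples
#' exclusion_tally(66007910, 16447895, 2005, 248230, 6370)$included
#' @export
exclusion_tally <- function(input_total, excluded_under18 = 0,
                            excluded_unknown_sex = 0, excluded_no_area = 0,
                            excluded_short_followup = 0) {
  counts <- c(
    input_total, excluded_under18, excluded_unknown_sex,
    excluded_no_area, excluded_short_followup
  )
  if (any(counts < 0)) stop("tally counts must be non-negative", call. = FALSE)
  included <- input_total - excluded_under18 - excluded_unknown_sex -
    excluded_no_area - excluded_short_followup
  if (included < 0) stop("exclusions exceed the input total", call. = FALSE)
  out <- tibble::tibble(
    input_total = input_total,
    excluded_under18 = excluded_under18,
    excluded_unknown_sex = excluded_unknown_sex,
    excluded_no_area = excluded_no_area,
    excluded_short_followup = excluded_short_followup,
    included = included
  )
  class(out) <- c("exclusion_tally", class(out))
  out
}

#' Cohort composition percentages
#'
#' One-decimal percentage breakdown of a cohort characteristic from its
#' level counts, as printed in baseline-characteristics tables (rounding
#' half away from zero).
#'
#' @param counts Named numeric vector of level counts.
#' @param total Denominator (defaults to `sum(counts)`).
#' @return Tibble with `level`, `count`, `pct`.
#' @examples
#' cohort_composition(c(female = 24785815, male = 24517595))
#' @export
cohort_composition <- function(counts, total = sum(counts)) {
  tibble::tibble(
    level = names(counts),
    count = unname(counts),
    pct = round_half_away(100 * unname(counts) / total, 1)
  )
}

#' Remove same-day duplicate records
#'
#' Keeps at most one record per (person, factor cluster, calendar day);
#' repeated recordings of the same cluster on a single day are artefacts of
#' code entry, not extra measurements. The retained record is the first in
#' input order for its key (stable), so the operation is deterministic and
#' idempotent.
#'
#' @param events Event tibble with `person_id`, `factor`, `event_date`.
#' @return The deduplicated event tibble.
#' @export
dedup_events <- function(events) {
  dplyr::distinct(events, .data$person_id, .data$factor, .data$event_date,
    .keep_all = TRUE
  )
}

#' Drop records without a value
#'
#' Removes events whose `value` is missing, except for factors whose
#' recording is inherently categorical/codified (smoking habit and alcohol
#' consumption), which are retained regardless.
#'
#' @param events Event tibble with `factor` and `value`.
#' @param exempt Factors exempt from the rule.
#' @return Filtered event tibble.
#' @export
drop_valueless <- function(events, exempt = valueless_exempt_factors()) {
  dplyr::filter(events, !is.na(.data$value) | .data$factor %in% exempt)
}

#' Monthly measurement rates per 1,000 by subgroup
#'
#' Tabulates curated events into monthly observed counts, eligible-person
#' denominators and rates per 1,000, for every cell of the requested
#' stratification crossed with calendar month. The denominator for month m
#' counts eligible persons whose follow-up covers any part of m: a person
#' who dies contributes through their death month and to no later month.
#'
#' @param events Curated events (already deduplicated and value-filtered).
#' @param persons Eligible persons, with `months_followup` counted from the
#'   first month of `date_range`.
#' @param by Character vector of stratification variables among `age_band`,
#'   `sex`, `ethnicity`, `imd_quintile`; `character(0)` (default) for an
#'   overall series.
#' @param date_range Length-2 `Date`: first and last month to tabulate.
#' @return A tibble with columns `factor`, the `by` variables, `month`,
#'   `count`, `denominator`, `rate`. Months are contiguous per series and
#'   every reported month has a positive denominator (otherwise an error
#'   names the offending month and subgroup).
#' @export
monthly_rates <- function(events, persons, by = character(0),
                          date_range = range(first_of_month(events$event_date))) {
  stopifnot(all(by %in% c("age_band", "sex", "ethnicity", "imd_quintile")))
  months <- month_seq(date_range[1], date_range[2])
  persons <- dplyr::mutate(persons, .midx_max = .data$months_followup)

  # denominator: persons alive (in follow-up) during each month
  month_tbl <- tibble::tibble(month = months, .midx = seq_along(months))
  denom <- persons |>
    dplyr::cross_join(month_tbl) |>
    dplyr::filter(.data$.midx <= .data$.midx_max) |>
    dplyr::count(dplyr::across(dplyr::all_of(by)), .data$month, name = "denominator")

  ev <- events |>
    dplyr::mutate(month = first_of_month(.data$event_date)) |>
    dplyr::filter(.data$month >= date_range[1], .data$month <= date_range[2]) |>
    dplyr::inner_join(
      dplyr::select(persons, "person_id", dplyr::all_of(by), ".midx_max"),
      by = "person_id"
    ) |>
    dplyr::inner_join(month_tbl, by = "month") |>
    dplyr::filter(.data$.midx <= .data$.midx_max) |>
    dplyr::count(.data$factor, dplyr::across(dplyr::all_of(by)), .data$month,
      name = "count"
    )

  grid <- tidyr::expand_grid(
    factor = sort(unique(events$factor)),
    dplyr::distinct(denom, dplyr::across(dplyr::all_of(by))),
    month = months
  )
  out <- grid |>
    dplyr::left_join(ev, by = c("factor", by, "month")) |>
    dplyr::left_join(denom, by = c(by, "month")) |>
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      denominator = dplyr::coalesce(.data$denominator, 0L)
    )
  if (any(out$denominator <= 0)) {
    bad <- out[out$denominator <= 0, , drop = FALSE][1, ]
    stop(sprintf(
      "zero denominator in %s for subgroup {%s}",
      format(bad$month, "%b %Y"),
      paste(sprintf("%s=%s", by, as.character(bad[by])), collapse = ", ")
    ), call. = FALSE)
  }
  out |>
    dplyr::mutate(rate = .data$count / .data$denominator * 1000) |>
    dplyr::arrange(.data$factor, dplyr::across(dplyr::all_of(by)), .data$month)
}
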