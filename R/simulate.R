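#' Simulate a synthetic primary-care cohort
#'
#' Draws `n_persons` person records from the scenario's subgroup mix, with
#' eligibility contaminants (under-18 at index, unknown sex, missing area
#' deprivation quintile) injected at the configured probabilities and deaths
#' simulated from a constant monthly hazard per age band. Follow-up runs
#' from the first month of the scenario window to the death month or the end
#' of the window, whichever is earlier; a person who dies contributes the
#' month of death.
#'
#' @param config A [scenario_config()].
#' @return A tibble with one row per person: `person_id`, `age_at_index`,
#'   `age_band` (`NA` for under-18 contaminants), `sex`, `ethnicity`,
#'   `imd_quintile`, `death_month` (`NA` if alive at window end) and
#'   `months_followup`.
#' @seealso [simulate_events()], [true_expected_rate()]
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_persons
  months <- month_seq(config$date_range[1], config$date_range[2])
  n_months <- length(months)
  if (n == 0) {
    return(tibble::tibble(
      person_id = character(), age_at_index = integer(), age_band = character(),
      sex = character(), ethnicity = character(), imd_quintile = integer(),
      death_month = as.Date(character()), months_followup = integer()
    ))
  }
  with_seed(config$seed, {
    mix <- config$subgroup_mix
    age_band <- sample(names(mix$age_band), n, TRUE, prob = mix$age_band)
    sex <- sample(names(mix$sex), n, TRUE, prob = mix$sex)
    ethnicity <- sample(names(mix$ethnicity), n, TRUE, prob = mix$ethnicity)
    imd <- as.integer(sample(names(mix$imd_quintile), n, TRUE, prob = mix$imd_quintile))

    lo <- c("18-39" = 18L, "40-59" = 40L, "60-79" = 60L, "80+" = 80L)
    hi <- c("18-39" = 39L, "40-59" = 59L, "60-79" = 79L, "80+" = 99L)
    age <- lo[age_band] + floor(runif(n) * (hi[age_band] - lo[age_band] + 1L))

    cp <- config$contaminant_probs
    u18 <- runif(n) < cp["under18"]
    age[u18] <- sample(0:17, sum(u18), TRUE)
    unk_sex <- runif(n) < cp["unknown_sex"]
    sex[unk_sex] <- "unknown"
    no_area <- runif(n) < cp["missing_area"]
    imd[no_area] <- NA_integer_

    # hazard keyed on the sampled adult band; under-18 contaminants carry the
    # youngest band's hazard
    hz <- config$death_hazard[age_band]
    death_idx <- rep(NA_integer_, n)
    pos <- hz > 0
    if (any(pos)) {
      k <- stats::qgeom(runif(sum(pos)), hz[pos]) + 1L
      k[k > n_months] <- NA_integer_
      death_idx[pos] <- k
    }
    followup <- ifelse(is.na(death_idx), n_months, death_idx)

    tibble::tibble(
      person_id = sprintf("P%07d", seq_len(n)),
      age_at_index = as.integer(age),
      age_band = ifelse(u18, NA_character_, age_band),
      sex = sex,
      ethnicity = ethnicity,
      imd_quintile = imd,
      death_month = months[death_idx],
      months_followup = as.integer(followup)
    )
  })
}

#' Simulate measurement events for a cohort
#'
#' For every person-month within follow-up and every configured factor, a
#' monthly event count is drawn with mean given by the scenario's generative
#' model and variance `phi * mu` (Poisson-gamma mixture when `phi > 1`).
#' Counts are expanded to individual records with a uniformly drawn day
#' within the month; a fraction of records is duplicated on the same day
#' (same factor cluster) and a fraction carries no value. No event is ever
#' emitted after a person's death month.
#'
#' @param persons Output of [simulate_population()] (or a compatible tibble).
#' @param config The matching [scenario_config()].
#' @return A tibble with one row per raw record: `person_id`, `event_date`,
#'   `factor`, `value` (`NA` when unrecorded).
#' @export
simulate_events <- function(persons, config) {
  stopifnot(inherits(config, "scenario_config"))
  if (nrow(persons) == 0) stop("`persons` is empty; nothing to simulate", call. = FALSE)
  months <- month_seq(config$date_range[1], config$date_range[2])
  with_seed(config$seed + 1L, {
    # person-month grid: months 1..months_followup for each person
    pm_person <- rep(seq_len(nrow(persons)), persons$months_followup)
    pm_midx <- sequence(persons$months_followup)
    base_eff <- subgroup_log_effect(persons, config)[pm_person]

    m_pos <- month_position(months)
    t_idx <- trend_index(months)
    out <- vector("list", length(config$factors))
    for (i in seq_along(config$factors)) {
      f <- config$factors[i]
      d <- config$disruption[[f]]
      dm <- disruption_mult(months, d)
      log_mu_month <- config$factor_log_rate[[f]] +
        config$seasonal_amplitude[[f]] * cos(2 * pi * (m_pos - config$seasonal_phase[[f]]) / 12) +
        config$annual_trend * t_idx + log(dm)
      mu <- exp(log_mu_month[pm_midx] + base_eff)
      counts <- draw_overdispersed(mu, config$dispersion_phi)
      keep <- which(counts > 0L)
      if (length(keep) == 0) next
      ev_person <- rep(pm_person[keep], counts[keep])
      ev_midx <- rep(pm_midx[keep], counts[keep])
      n_ev <- length(ev_person)
      day <- 1L + floor(runif(n_ev) * days_in_month_vec(months)[ev_midx])
      ev <- tibble::tibble(
        person_id = persons$person_id[ev_person],
        event_date = months[ev_midx] + (day - 1L),
        factor = f,
        value = draw_values(f, n_ev, config$valueless_prob)
      )
      dup <- runif(n_ev) < config$dup_prob
      if (any(dup)) ev <- dplyr::bind_rows(ev, ev[dup, ])
      out[[i]] <- ev
    }
    res <- dplyr::bind_rows(out)
    if (nrow(res) == 0) {
      res <- tibble::tibble(
        person_id = character(), event_date = as.Date(character()),
        factor = character(), value = numeric()
      )
    }
    res
  })
}

# additive log-rate effect of a person's subgroup; unknown/contaminant levels
# contribute the reference effect 0
subgroup_log_effect <- function(persons, config) {
  eff <- rep(0, nrow(persons))
  for (v in names(config$subgroup_log_effects)) {
    e <- config$subgroup_log_effects[[v]]
    lev <- as.character(persons[[v]])
    hit <- !is.na(lev) & lev %in% names(e)
    eff[hit] <- eff[hit] + e[lev[hit]]
  }
  eff
}

# counts with mean mu and variance phi*mu; NB parameterized so both moments
# match at the cell's own mu
draw_overdispersed <- function(mu, phi) {
  if (phi > 1) {
    stats::rnbinom(length(mu), mu = mu, size = mu / (phi - 1))
  } else {
    stats::rpois(length(mu), mu)
  }
}

measurement_value_params <- function() {
  list(
    bmi = c(27, 5), smoking = c(1, 0.5), alcohol = c(8, 6), bp = c(130, 15),
    hba1c = c(42, 10), fasting_glucose = c(5.5, 1),
    total_cholesterol = c(5.2, 1), ldl_cholesterol = c(3.1, 0.9),
    hdl_cholesterol = c(1.4, 0.4), triglycerides = c(1.5, 0.8),
    lft = c(30, 12), egfr = c(85, 18)
  )
}

draw_values <- function(factor, n, valueless_prob) {
  p <- measurement_value_params()[[factor]]
  v <- round(stats::rnorm(n, p[1], p[2]), 1)
  v[stats::runif(n) < valueless_prob] <- NA_real_
  v
}

# multiplicative disruption profile: 1 before onset; drop to `depth` at
# onset, exponential return towards 1 + offset at the given half-life
disruption_mult <- function(months, d) {
  s <- months_between(d$onset, first_of_month(months))
  target <- 1 + d$offset
  decay <- if (is.infinite(d$half_life)) rep(1, length(s)) else 0.5^(s / d$half_life)
  ifelse(s < 0, 1, target - (target - d$depth) * decay)
}

#' Ground-truth expected monthly rate per 1,000
#'
#' Deterministic closed-form evaluation of the generative mean for a given
#' subgroup cell, factor and calendar month, scaled to measurements per
#' 1,000 persons per month. This is the oracle against which rates and model
#' recoveries computed from simulated data are checked.
#'
#' @param config A [scenario_config()].
#' @param subgroup Named character vector or list giving any of `age_band`,
#'   `sex`, `ethnicity`, `imd_quintile`; omitted variables sit at their
#'   reference (zero-effect) level. Unknown names or levels raise an error.
#' @param factor One of the scenario's factors.
#' @param month Calendar month (`Date`), within the scenario window.
#' @return Expected measurements per 1,000 persons in that month (numeric).
#' @examples
#' cfg <- scenario_config(n_persons = 10, factors = "bp")
#' true_expected_rate(cfg, c(age_band = "60-79", sex = "female"), "bp", ym(2019, 6))
#' @export
true_expected_rate <- function(config, subgroup, factor, month) {
  stopifnot(inherits(config, "scenario_config"))
  month <- first_of_month(month)
  if (any(month < config$date_range[1] | month > config$date_range[2])) {
    stop("`month` outside the scenario date range", call. = FALSE)
  }
  if (!factor %in% config$factors) {
    stop(sprintf("unknown factor `%s` for this scenario", factor), call. = FALSE)
  }
  eff <- 0
  for (v in names(subgroup)) {
    e <- config$subgroup_log_effects[[v]]
    if (is.null(e)) stop(sprintf("unknown subgroup variable `%s`", v), call. = FALSE)
    lev <- as.character(subgroup[[v]])
    if (!lev %in% names(e)) {
      stop(sprintf("unknown level `%s` for subgroup variable `%s`", lev, v), call. = FALSE)
    }
    eff <- eff + e[[lev]]
  }
  d <- config$disruption[[factor]]
  log_mu <- config$factor_log_rate[[factor]] + eff +
    config$seasonal_amplitude[[factor]] *
      cos(2 * pi * (month_position(month) - config$seasonal_phase[[factor]]) / 12) +
    config$annual_trend * trend_index(month) +
    log(disruption_mult(month, d))
  1000 * exp(unname(log_mu))
}

# evaluate code with a temporary RNG state so generators are reproducible
# without clobbering the caller's stream
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    }
  })
  set.seed(seed)
  force(code)
}
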