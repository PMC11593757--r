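#' The twelve cardiometabolic risk-factor measurement clusters
#'
#' Canonical identifiers for the measurement clusters tracked by the
#' pipeline: body mass index, smoking habit, alcohol consumption, blood
#' pressure, glycated haemoglobin, fasting glucose, total/LDL/HDL
#' cholesterol, triglycerides, liver function tests, and estimated
#' glomerular filtration rate.
#'
#' @return Character vector of length 12.
#' @export
risk_factors <- function() {
  c(
    "bmi", "smoking", "alcohol", "bp", "hba1c", "fasting_glucose",
    "total_cholesterol", "ldl_cholesterol", "hdl_cholesterol",
    "triglycerides", "lft", "egfr"
  )
}

#' Factors whose records are kept even without a recorded value
#' @return Character vector.
#' @export
valueless_exempt_factors <- function() c("smoking", "alcohol")

age_bands <- function() c("18-39", "40-59", "60-79", "80+")
sex_levels <- function() c("female", "male")
ethnicity_levels <- function() c("White", "Asian", "Black", "Mixed", "Other/Unknown")
imd_levels <- function() as.character(1:5)

# order-of-magnitude plausible monthly measurement rates per person, one per
# factor; synthetic values (no published per-factor baselines exist)
default_factor_rates <- function() {
  c(
    bmi = 0.060, smoking = 0.050, alcohol = 0.040, bp = 0.120,
    hba1c = 0.060, fasting_glucose = 0.010, total_cholesterol = 0.050,
    ldl_cholesterol = 0.030, hdl_cholesterol = 0.050,
    triglycerides = 0.040, lft = 0.070, egfr = 0.080
  )
}

#' Build a synthetic-data scenario configuration
#'
#' Defines every knob of the synthetic primary-care generator: the cohort
#' size and composition, the per-factor generative rate model (baseline
#' log-rate plus additive subgroup log-effects, a cosine seasonal term, a
#' linear long-term trend and a multiplicative post-onset disruption
#' profile), the overdispersion of monthly counts, and the curation
#' contaminants (same-day duplicates, valueless records, ineligible persons,
#' deaths).
#'
#' The generative mean for a person in subgroup g, factor f, calendar month
#' with month-of-year position m and trend index t (years relative to the
#' disruption onset) is
#' \deqn{\mu = \exp(b_f + a_g + A_f \cos(2\pi (m - p_f)/12) + \beta t +
#'   \log d_f(t))}
#' where \eqn{d_f(t)} is the disruption multiplier (1 before onset, a drop to
#' `depth` at onset with exponential recovery towards
#' `1 + post_recovery_offset` at the configured half-life). Monthly counts
#' are drawn with variance `dispersion_phi * mu` via a Poisson-gamma
#' (negative binomial) mixture.
#'
#' @param n_persons Number of persons to simulate.
#' @param date_range Length-2 `Date` vector, first and last calendar month
#'   of the study window (default November 2018 to March 2024).
#' @param factors Subset of [risk_factors()] to simulate.
#' @param subgroup_mix Named list with elements `age_band`, `sex`,
#'   `ethnicity`, `imd_quintile`: marginal probabilities over the subgroup
#'   levels (sampled independently). Each must sum to 1.
#' @param factor_log_rate Named numeric, log baseline measurements per
#'   person-month for each simulated factor.
#' @param subgroup_log_effects Named list of named numerics: additive
#'   log-rate effects for `age_band`, `sex`, `ethnicity`, `imd_quintile`
#'   levels (reference levels 0).
#' @param seasonal_amplitude,seasonal_phase Named numeric per factor:
#'   dimensionless cosine amplitude and phase (months).
#' @param annual_trend Log-rate change per year (scalar, applied to all
#'   factors and subgroups).
#' @param disruption Named list per factor with `depth` (multiplicative drop
#'   in (0, 1]; 1 = no disruption), `onset` (calendar month), `half_life`
#'   (months; `Inf` = sustained), `offset` (post-recovery level minus 1).
#' @param dispersion_phi Quasi-Poisson dispersion of monthly counts (>= 1;
#'   1 = Poisson).
#' @param dup_prob Probability a recorded event is accompanied by a same-day
#'   duplicate record.
#' @param valueless_prob Probability an event carries no value.
#' @param contaminant_probs Named numeric with `under18`, `unknown_sex`,
#'   `missing_area`: probabilities a simulated person is ineligible in each
#'   way.
#' @param death_hazard Named numeric: monthly death probability per age band.
#' @param seed Integer seed; identical configurations reproduce identical
#'   data byte for byte.
#' @return An object of class `scenario_config` (a validated list).
#' @examples
#' cfg <- scenario_config(n_persons = 100, factors = "bp")
#' @export
scenario_config <- function(
    n_persons = 10000,
    date_range = c(ym(2018, 11), ym(2024, 3)),
    factors = risk_factors(),
    subgroup_mix = list(
      age_band = c("18-39" = 0.416, "40-59" = 0.324, "60-79" = 0.210, "80+" = 0.050),
      sex = c(female = 0.503, male = 0.497),
      ethnicity = c(
        White = 0.777, Asian = 0.110, Black = 0.042,
        Mixed = 0.017, "Other/Unknown" = 0.054
      ),
      imd_quintile = c("1" = 0.201, "2" = 0.213, "3" = 0.205, "4" = 0.196, "5" = 0.185)
    ),
    factor_log_rate = log(default_factor_rates()[factors]),
    subgroup_log_effects = list(
      age_band = c("18-39" = 0, "40-59" = 0.6, "60-79" = 1.1, "80+" = 1.4),
      sex = c(female = 0, male = -0.1),
      ethnicity = c(White = 0, Asian = 0.05, Black = 0.05, Mixed = 0, "Other/Unknown" = -0.1),
      imd_quintile = c("1" = 0.1, "2" = 0.05, "3" = 0, "4" = -0.02, "5" = -0.05)
    ),
    seasonal_amplitude = stats::setNames(rep(0.10, length(factors)), factors),
    seasonal_phase = stats::setNames(rep(10, length(factors)), factors),
    annual_trend = 0.02,
    disruption = default_disruption(factors),
    dispersion_phi = 1.5,
    dup_prob = 0.02,
    valueless_prob = 0.03,
    contaminant_probs = c(under18 = 0.249, unknown_sex = 3e-05, missing_area = 0.0038),
    death_hazard = c("18-39" = 4e-05, "40-59" = 2e-04, "60-79" = 1.2e-03, "80+" = 8e-03),
    seed = 1L) {
  cfg <- list(
    n_persons = n_persons, date_range = first_of_month(date_range),
    factors = factors, subgroup_mix = subgroup_mix,
    factor_log_rate = factor_log_rate,
    subgroup_log_effects = subgroup_log_effects,
    seasonal_amplitude = seasonal_amplitude, seasonal_phase = seasonal_phase,
    annual_trend = annual_trend, disruption = disruption,
    dispersion_phi = dispersion_phi, dup_prob = dup_prob,
    valueless_prob = valueless_prob, contaminant_probs = contaminant_probs,
    death_hazard = death_hazard, seed = as.integer(seed)
  )
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

#' @rdname scenario_config
#' @param depth,onset,half_life,offset Shared disruption parameters applied
#'   to every factor by `default_disruption()`.
#' @export
default_disruption <- function(factors = risk_factors(), depth = 1, onset = ym(2020, 3),
                               half_life = 12, offset = 0) {
  stats::setNames(
    lapply(factors, function(f) {
      list(depth = depth, onset = onset, half_life = half_life, offset = offset)
    }),
    factors
  )
}

validate_scenario_config <- function(cfg) {
  bad <- function(field, msg) {
    stop(sprintf("invalid scenario_config field `%s`: %s", field, msg), call. = FALSE)
  }
  if (!is.numeric(cfg$n_persons) || length(cfg$n_persons) != 1 ||
    cfg$n_persons < 0 || cfg$n_persons != floor(cfg$n_persons)) {
    bad("n_persons", "must be a single non-negative integer")
  }
  if (length(cfg$date_range) != 2 || cfg$date_range[2] < cfg$date_range[1]) {
    bad("date_range", "must be two ordered calendar months")
  }
  if (!all(cfg$factors %in% risk_factors())) {
    bad("factors", paste(
      "unknown factor(s):",
      paste(setdiff(cfg$factors, risk_factors()), collapse = ", ")
    ))
  }
  expected_levels <- list(
    age_band = age_bands(), sex = sex_levels(),
    ethnicity = ethnicity_levels(), imd_quintile = imd_levels()
  )
  for (v in names(expected_levels)) {
    p <- cfg$subgroup_mix[[v]]
    if (is.null(p) || !setequal(names(p), expected_levels[[v]])) {
      bad("subgroup_mix", sprintf("`%s` must name levels %s", v,
        paste(expected_levels[[v]], collapse = ", ")))
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      bad("subgroup_mix", sprintf("`%s` proportions must be >= 0 and sum to 1", v))
    }
  }
  for (f in cfg$factors) {
    if (is.na(cfg$factor_log_rate[f])) bad("factor_log_rate", paste("missing", f))
    if (is.na(cfg$seasonal_amplitude[f])) bad("seasonal_amplitude", paste("missing", f))
    if (is.na(cfg$seasonal_phase[f])) bad("seasonal_phase", paste("missing", f))
    d <- cfg$disruption[[f]]
    if (is.null(d)) bad("disruption", paste("missing", f))
    if (!is.numeric(d$depth) || d$depth <= 0 || d$depth > 1) {
      bad("disruption", sprintf("`%s` depth must lie in (0, 1]", f))
    }
    if (d$half_life <= 0) bad("disruption", sprintf("`%s` half_life must be > 0", f))
  }
  if (cfg$dispersion_phi < 1) bad("dispersion_phi", "must be >= 1")
  probs <- c(
    dup_prob = cfg$dup_prob, valueless_prob = cfg$valueless_prob,
    cfg$contaminant_probs, cfg$death_hazard
  )
  if (any(probs < 0 | probs > 1)) {
    bad(names(probs)[which(probs < 0 | probs > 1)[1]], "must lie in [0, 1]")
  }
  if (!setequal(names(cfg$contaminant_probs), c("under18", "unknown_sex", "missing_area"))) {
    bad("contaminant_probs", "must name under18, unknown_sex, missing_area")
  }
  if (!setequal(names(cfg$death_hazard), age_bands())) {
    bad("death_hazard", "must name every age band")
  }
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  persons: %d   months: %s to %s\n", x$n_persons,
    format(x$date_range[1], "%b %Y"), format(x$date_range[2], "%b %Y")))
  cat(sprintf("  factors: %s\n", paste(x$factors, collapse = ", ")))
  cat(sprintf("  annual trend: %+.3f / yr   dispersion phi: %.2f   seed: %d\n",
    x$annual_trend, x$dispersion_phi, x$seed))
  depths <- vapply(x$disruption[x$factors], function(d) d$depth, numeric(1))
  if (any(depths < 1)) {
    cat(sprintf("  disruption depth: %s\n",
      paste(sprintf("%s=%.2f", names(depths)[depths < 1], depths[depths < 1]),
        collapse = ", ")))
  } else {
    cat("  no disruption (all depths 1)\n")
  }
  invisible(x)
}
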