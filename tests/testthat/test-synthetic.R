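homogeneous_effects <- list(
  age_band = c("18-39" = 0, "40-59" = 0, "60-79" = 0, "80+" = 0),
  sex = c(female = 0, male = 0),
  ethnicity = c(White = 0, Asian = 0, Black = 0, Mixed = 0, "Other/Unknown" = 0),
  imd_quintile = c("1" = 0, "2" = 0, "3" = 0, "4" = 0, "5" = 0)
)

flat_config <- function(n, rate = 0.1, phi = 1, seed = 1, trend = 0, amp = 0,
                        date_range = c(ym(2018, 11), ym(2024, 3)),
                        depth = 1, half_life = 12, offset = 0,
                        dup = 0, valueless = 0) {
  scenario_config(
    n_persons = n, date_range = date_range, factors = "bp",
    factor_log_rate = c(bp = log(rate)),
    subgroup_log_effects = homogeneous_effects,
    seasonal_amplitude = c(bp = amp), seasonal_phase = c(bp = 10),
    annual_trend = trend,
    disruption = default_disruption("bp", depth = depth, half_life = half_life,
      offset = offset),
    dispersion_phi = phi, dup_prob = dup, valueless_prob = valueless,
    contaminant_probs = c(under18 = 0, unknown_sex = 0, missing_area = 0),
    death_hazard = c("18-39" = 0, "40-59" = 0, "60-79" = 0, "80+" = 0),
    seed = seed
  )
}

test_that("empty and contaminant-free cohorts behave by construction", {
  empty <- flat_config(0)
  expect_equal(nrow(simulate_population(empty)), 0)
  expect_error(simulate_events(simulate_population(empty), empty), "empty")

  clean <- flat_config(500, seed = 5)
  persons <- simulate_population(clean)
  excl <- apply_exclusions(persons)
  expect_equal(excl$tally$included, 500)
  expect_equal(
    excl$tally$excluded_under18 + excl$tally$excluded_unknown_sex +
      excl$tally$excluded_no_area + excl$tally$excluded_short_followup, 0
  )
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(flat_config(10, phi = 0.5), "dispersion_phi")
  expect_error(flat_config(10, depth = 0), "depth")
  expect_error(flat_config(10, depth = 1.2), "depth")
  expect_error(flat_config(-1), "n_persons")
  expect_error(flat_config(10, dup = 1.5), "dup_prob")
  expect_error(
    scenario_config(n_persons = 10, factors = "cholesterol"),
    "unknown factor"
  )
})

test_that("subgroup frequencies converge to the configured mix", {
  cfg <- scenario_config(
    n_persons = 50000,
    subgroup_mix = list(
      age_band = c("18-39" = 0.40, "40-59" = 0.30, "60-79" = 0.25, "80+" = 0.05),
      sex = c(female = 0.5, male = 0.5),
      ethnicity = c(White = 0.8, Asian = 0.1, Black = 0.05, Mixed = 0.02,
        "Other/Unknown" = 0.03),
      imd_quintile = c("1" = 0.2, "2" = 0.2, "3" = 0.2, "4" = 0.2, "5" = 0.2)
    ),
    factors = "bp",
    contaminant_probs = c(under18 = 0, unknown_sex = 0, missing_area = 0),
    seed = 11
  )
  persons <- simulate_population(cfg)
  expect_equal(nrow(persons), 50000)
  p <- cfg$subgroup_mix$age_band
  freq <- table(persons$age_band)[names(p)] / nrow(persons)
  bound <- 3 * sqrt(p * (1 - p) / nrow(persons))
  expect_true(all(abs(freq - p) <= bound))
})

test_that("identical configuration gives byte-identical output; seeds differ", {
  cfg <- flat_config(200, seed = 9, dup = 0.05, valueless = 0.05)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1, p2)
  e1 <- simulate_events(p1, cfg)
  e2 <- simulate_events(p2, cfg)
  expect_identical(e1, e2)
  cfg2 <- flat_config(200, seed = 10, dup = 0.05, valueless = 0.05)
  expect_false(identical(simulate_population(cfg2), p1))
})

test_that("no event postdates its person's death month", {
  cfg <- scenario_config(
    n_persons = 400, factors = "bp",
    factor_log_rate = c(bp = log(0.3)),
    subgroup_log_effects = homogeneous_effects,
    seasonal_amplitude = c(bp = 0), seasonal_phase = c(bp = 0),
    annual_trend = 0,
    disruption = default_disruption("bp"),
    contaminant_probs = c(under18 = 0, unknown_sex = 0, missing_area = 0),
    death_hazard = c("18-39" = 0.03, "40-59" = 0.03, "60-79" = 0.03, "80+" = 0.05),
    seed = 21
  )
  persons <- simulate_population(cfg)
  expect_gt(sum(!is.na(persons$death_month)), 0)
  events <- simulate_events(persons, cfg)
  joined <- dplyr::inner_join(events, persons, by = "person_id")
  died <- joined[!is.na(joined$death_month), ]
  e_month <- as.Date(format(died$event_date, "%Y-%m-01"))
  expect_true(all(e_month <= died$death_month))
  # death months lie inside the window and follow-up is consistent
  months <- month_seq(cfg$date_range[1], cfg$date_range[2])
  dead <- persons[!is.na(persons$death_month), ]
  expect_true(all(dead$death_month %in% months))
  expect_equal(
    dead$months_followup,
    12L * (as.integer(format(dead$death_month, "%Y")) - 2018L) +
      as.integer(format(dead$death_month, "%m")) - 10L
  )
})

test_that("monthly event counts match the generative mean within MC error", {
  # 10,000 person-months at mu = 0.1, phi = 1
  cfg <- flat_config(10000, rate = 0.1, phi = 1, seed = 31,
    date_range = c(ym(2019, 6), ym(2019, 6))
  )
  persons <- simulate_population(cfg)
  events <- simulate_events(persons, cfg)
  mean_count <- nrow(events) / 10000
  expect_lt(abs(mean_count - 0.1), 3 * sqrt(0.1 / 10000))
})

test_that("overdispersion phi is recovered from the variance/mean ratio", {
  cfg <- flat_config(2000, rate = 0.1, phi = 2, seed = 41)
  persons <- simulate_population(cfg)
  events <- simulate_events(persons, cfg)
  n_months <- length(month_seq(cfg$date_range[1], cfg$date_range[2]))
  n_pm <- 2000 * n_months
  expect_gte(n_pm, 1e5)
  key <- paste(events$person_id, format(events$event_date, "%Y-%m"))
  counts <- c(table(key), rep(0L, n_pm - length(unique(key))))
  ratio <- stats::var(counts) / mean(counts)
  expect_lt(abs(ratio - 2) / 2, 0.10)
})

test_that("empirical rates are stationary across years at matched months", {
  cfg <- flat_config(3000, rate = 0.15, phi = 1.5, seed = 51, amp = 0.1,
    date_range = c(ym(2018, 11), ym(2020, 2)))
  # no trend, no disruption before onset: Dec 2018 and Dec 2019 share a mean
  persons <- simulate_population(cfg)
  events <- simulate_events(persons, cfg)
  rates <- monthly_rates(events, persons, date_range = cfg$date_range)
  for (mon in c(12, 1)) {
    yrs <- rates[as.integer(format(rates$month, "%m")) == mon, ]
    expect_equal(nrow(yrs), 2)
    mu <- mean(yrs$rate)
    mc_sd <- sqrt(sum(1.5 * mu * 1000 / yrs$denominator)) # var of a per-1,000 rate
    expect_lt(abs(diff(yrs$rate)), 3 * mc_sd)
  }
})

test_that("true_expected_rate matches brute-force term-by-term evaluation", {
  cfg <- scenario_config(
    n_persons = 10, factors = c("bp", "hba1c"),
    annual_trend = -0.03,
    disruption = default_disruption(c("bp", "hba1c"),
      depth = 0.7, half_life = 6, offset = 0.05
    ),
    seed = 2
  )
  months <- c(ym(2019, 2), ym(2020, 3), ym(2020, 9), ym(2023, 7))
  sub <- c(age_band = "60-79", sex = "male", ethnicity = "Asian", imd_quintile = "2")
  for (f in cfg$factors) {
    for (m in months) {
      got <- true_expected_rate(cfg, sub, f, m)
      # independent re-evaluation
      s <- 12 * (as.integer(format(as.Date(m), "%Y")) - 2020) +
        as.integer(format(as.Date(m), "%m")) - 3
      mult <- if (s < 0) 1 else (1.05 - (1.05 - 0.7) * 0.5^(s / 6))
      expected <- 1000 * exp(
        cfg$factor_log_rate[[f]] +
          cfg$subgroup_log_effects$age_band[["60-79"]] +
          cfg$subgroup_log_effects$sex[["male"]] +
          cfg$subgroup_log_effects$ethnicity[["Asian"]] +
          cfg$subgroup_log_effects$imd_quintile[["2"]] +
          cfg$seasonal_amplitude[[f]] *
            cos(2 * pi * ((as.integer(format(as.Date(m), "%m")) - 1) -
              cfg$seasonal_phase[[f]]) / 12) +
          cfg$annual_trend * (s / 12) + log(mult)
      )
      expect_equal(got, expected, tolerance = 1e-12)
    }
  }
  # disruption multiplier is 1 before onset
  pre <- true_expected_rate(cfg, sub, "bp", ym(2019, 6))
  cfg_nodisr <- cfg
  cfg_nodisr$disruption <- default_disruption(c("bp", "hba1c"), depth = 1)
  expect_equal(pre, true_expected_rate(cfg_nodisr, sub, "bp", ym(2019, 6)))
  # flat baseline with no seasonality/trend: log(0.1) maps to 100 per 1,000
  flat <- flat_config(10, rate = 0.1)
  expect_equal(
    true_expected_rate(flat, c(sex = "female"), "bp", ym(2019, 6)), 100
  )
  # lookup errors
  expect_error(true_expected_rate(cfg, sub, "egfr", ym(2019, 6)), "unknown factor")
  expect_error(
    true_expected_rate(cfg, c(age_band = "17-20"), "bp", ym(2019, 6)),
    "unknown level"
  )
  expect_error(true_expected_rate(cfg, sub, "bp", ym(2030, 1)), "date range")
})

test_that("duplicates and valueless records appear at configured rates", {
  cfg <- flat_config(2000, rate = 0.2, seed = 61, dup = 0.10, valueless = 0.20)
  persons <- simulate_population(cfg)
  events <- simulate_events(persons, cfg)
  n_dedup <- nrow(dedup_events(events))
  dup_frac <- (nrow(events) - n_dedup) / n_dedup
  expect_lt(abs(dup_frac - 0.10), 0.02)
  expect_lt(abs(mean(is.na(events$value)) - 0.20), 0.02)
})
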