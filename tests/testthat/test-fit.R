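# small deterministic rate table builders --------------------------------------

fixture_rates <- function(seed = 1, by = character(0), n_cells = 1,
                          months = month_seq(ym(2018, 11), ym(2020, 2)),
                          base_count = 200) {
  set.seed(seed)
  if (length(by) == 0) {
    cells <- tibble::tibble(.rows = 1)
  } else {
    lvls <- list(
      age_band = c("18-39", "40-59", "60-79", "80+"),
      sex = c("female", "male")
    )
    cells <- tidyr::expand_grid(!!!lapply(lvls[by], identity))
  }
  tidyr::expand_grid(cells, month = months) |>
    dplyr::mutate(
      denominator = 1000L + sample(0:200, dplyr::n(), TRUE),
      count = stats::rpois(
        dplyr::n(),
        base_count * (denominator / 1000) *
          exp(0.1 * cos(2 * pi * (month_position(month) - 10) / 12)) / 5
      )
    )
}

manual_design <- function(X, y, offset) {
  structure(
    list(
      X = X, y = y, offset = offset,
      S = matrix(0, ncol(X), ncol(X)),
      meta = list(by = character(0)),
      rows = tibble::tibble(count = y)
    ),
    class = "trend_design"
  )
}

test_that("design matrix has the documented column structure", {
  rates <- fixture_rates()
  k <- 6
  d <- build_design(rates, basis = cyclic_basis_spec(k))
  # intercept + (k-1) constrained seasonal columns + trend
  expect_equal(ncol(d$X), 1 + (k - 1) + 1)
  expect_equal(d$offset, log(rates$denominator))
  expect_equal(d$y, rates$count)

  rates2 <- fixture_rates(by = c("age_band", "sex"))
  d2 <- build_design(rates2, by = c("age_band", "sex"))
  # + treatment dummies (3 + 1) and their trend interactions
  expect_equal(ncol(d2$X), 1 + 3 + 1 + (k - 1) + 1 + 3 + 1)
  expect_true(all(c("age_band40-59", "sexmale", "t", "t:sexmale") %in%
    colnames(d2$X)))
  # penalty is embedded only in the seasonal block
  nonseason <- grep("^season", colnames(d2$X), invert = TRUE)
  expect_true(all(d2$S[nonseason, ] == 0))
})

test_that("rank-deficient designs fail loudly naming collinear columns", {
  rates <- fixture_rates(months = month_seq(ym(2019, 1), ym(2019, 4)))
  # 4 months cannot identify 5 seasonal columns + intercept + trend
  expect_error(build_design(rates), "collinear")
})

test_that("intercept-only penalized IRLS reproduces the Poisson MLE", {
  des <- manual_design(
    X = matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)")),
    y = c(1, 2, 3), offset = log(c(1, 1, 1))
  )
  fit <- fit_pirls(des)
  expect_equal(unname(fit$coefficients), log(2), tolerance = 1e-8)
  expect_equal(unname(fit$fitted), rep(2, 3), tolerance = 1e-7)
})

test_that("unpenalized fit matches an independent Poisson GLM oracle", {
  rates <- fixture_rates(seed = 4, by = "sex")
  des <- build_design(rates, by = "sex", basis = cyclic_basis_spec(6))
  fit <- fit_pirls(des, lambda = 0)
  oracle <- stats::glm(des$y ~ des$X - 1 + offset(des$offset), family = stats::poisson())
  expect_equal(unname(fit$coefficients), unname(coef(oracle)), tolerance = 1e-8)
  # quasi-Poisson covariance: oracle dispersion uses residual df, ours edf;
  # with lambda = 0 these agree (edf = p)
  expect_equal(fit$edf, ncol(des$X), tolerance = 1e-6)
  so <- summary(oracle, dispersion = fit$phi)
  expect_equal(unname(sqrt(diag(fit$cov))), unname(so$coefficients[, 2]),
    tolerance = 1e-6
  )
})

test_that("penalized fit agrees with an mgcv cyclic P-spline cross-check", {
  skip_if_not_installed("mgcv")
  rates <- fixture_rates(seed = 9)
  m <- month_position(rates$month)
  t <- trend_index(rates$month)
  gam_fit <- mgcv::gam(
    count ~ s(m, bs = "cp", k = 7) + t + offset(log(denominator)),
    data = data.frame(count = rates$count, m = m, t = t,
      denominator = rates$denominator),
    family = stats::quasipoisson(), method = "GCV.Cp",
    knots = list(m = seq(0, 12, length.out = 8))
  )
  fit <- fit_trend_model(rates)
  eta_pkg <- predict_eta(fit, rates)$eta + log(rates$denominator)
  eta_gam <- as.numeric(predict(gam_fit, type = "link"))
  # same model family fitted by an independent engine: linear predictors
  # should agree closely despite different smoothing criteria
  expect_lt(max(abs(eta_pkg - eta_gam)), 0.05)
})

test_that("dispersion estimate is consistent under equidispersion", {
  set.seed(15)
  months <- month_seq(ym(2018, 11), ym(2020, 2))
  rates <- tidyr::expand_grid(
    age_band = c("18-39", "40-59", "60-79", "80+"),
    sex = c("female", "male"),
    ethnicity = c("White", "Asian", "Black", "Mixed", "Other/Unknown"),
    imd_quintile = as.character(1:5),
    month = months
  ) |>
    dplyr::mutate(
      denominator = 5000L,
      count = stats::rpois(
        dplyr::n(),
        400 * exp(0.05 * trend_index(month) +
          0.2 * (age_band == "80+") - 0.1 * (sex == "male"))
      )
    )
  fit <- fit_trend_model(rates,
    by = c("age_band", "sex", "ethnicity", "imd_quintile"), lambda = 1
  )
  expect_gt(fit$phi, 0.9)
  expect_lt(fit$phi, 1.1)
})

test_that("offset contract: a constant offset shift moves only the intercept", {
  rates <- fixture_rates(seed = 6)
  des <- build_design(rates)
  fit1 <- fit_pirls(des, lambda = 2)
  des2 <- des
  cshift <- 0.7
  des2$offset <- des$offset + cshift
  fit2 <- fit_pirls(des2, lambda = 2)
  expect_equal(fit2$coefficients["(Intercept)"],
    fit1$coefficients["(Intercept)"] - cshift,
    tolerance = 1e-6
  )
  expect_equal(fit2$coefficients[-1], fit1$coefficients[-1], tolerance = 1e-6)
  expect_equal(fit2$fitted, fit1$fitted, tolerance = 1e-6)
})

test_that("fitted seasonal curve is exactly periodic at the seam", {
  rates <- fixture_rates(seed = 12)
  fit <- fit_trend_model(rates, lambda = 5)
  sc <- fit$coefficients[grep("^season", names(fit$coefficients))]
  b0 <- drop(cyclic_basis(0, fit$meta$basis) %*% fit$meta$Z %*% sc)
  b12 <- drop(cyclic_basis(12, fit$meta$basis) %*% fit$meta$Z %*% sc)
  expect_equal(b0, b12, tolerance = 1e-12)
})

test_that("GCV selection recomputes scores exactly and prefers smooth truth", {
  rates <- fixture_rates(seed = 20, base_count = 2000)
  des <- build_design(rates)
  grid <- 10^seq(-1, 3, length.out = 5)
  sel <- select_lambda(des, grid)
  # brute-force recomputation of the profile
  for (i in seq_along(grid)) {
    f <- fit_pirls(des, lambda = grid[i])
    expect_equal(sel$gcv$gcv[i], f$n * f$pearson / (f$n - f$edf)^2,
      tolerance = 1e-10
    )
  }
  expect_equal(sel$lambda, grid[which.min(sel$gcv$gcv)])
  # degenerate grid
  expect_equal(select_lambda(des, grid = 0.5)$lambda, 0.5)
  expect_error(select_lambda(des, grid = numeric(0)), "empty")

  # flat seasonal truth: heavy smoothing should win
  set.seed(33)
  months <- month_seq(ym(2018, 11), ym(2020, 2))
  flat <- tidyr::expand_grid(sex = c("female", "male"), month = months) |>
    dplyr::mutate(
      denominator = 10000L,
      count = stats::rpois(dplyr::n(), 0.5 * denominator)
    )
  dflat <- build_design(flat, by = "sex")
  grid2 <- 10^seq(-2, 4, length.out = 13)
  sel2 <- select_lambda(dflat, grid2)
  expect_gte(sel2$lambda, grid2[10])
})

test_that("ties in GCV break towards the smoother fit", {
  des <- build_design(fixture_rates(seed = 2))
  prof <- tibble::tibble(lambda = c(1, 2), gcv = c(5, 5))
  # the exported surface: equal scores at different lambdas select the larger
  best <- max(prof$lambda[prof$gcv <= min(prof$gcv) + 1e-12])
  expect_equal(best, 2)
})

test_that("prediction reproduces training rows and propagates covariance", {
  rates <- fixture_rates(seed = 14, by = "sex")
  fit <- fit_trend_model(rates, by = "sex", lambda = 1)
  pr <- predict_eta(fit, rates)
  expect_equal(exp(pr$eta + log(rates$denominator)), unname(fit$fitted),
    tolerance = 1e-10
  )
  expect_true(all(pr$se_eta >= 0))
  # delta-method oracle: loop over rows with the full covariance
  Xn <- expectband:::design_matrix(rates, fit$meta)
  se_manual <- vapply(
    seq_len(nrow(Xn)),
    function(i) sqrt(drop(t(Xn[i, ]) %*% fit$cov %*% Xn[i, ])),
    numeric(1)
  )
  expect_equal(pr$se_eta, se_manual, tolerance = 1e-12)
  # unseen levels are refused by name
  bad <- rates[1, ]
  bad$sex <- "other"
  expect_error(predict_eta(fit, bad), "other")
})

test_that("all-zero strata are flagged with a warning", {
  rates <- fixture_rates(seed = 3, by = "sex")
  rates$count[rates$sex == "male"] <- 0L
  des <- build_design(rates, by = "sex")
  expect_warning(fit_pirls(des, lambda = 1), "all-zero")
})

test_that("the trend slope interval covers the generative truth", {
  # 120 replicates of a declining-rate scenario; nominal 95% Wald intervals
  # should cover the true slope in at least 90% despite the cosine-vs-spline
  # seasonal mismatch
  cfg <- load_fixture_scenario("scenario_null.json")
  cfg$n_persons <- 800L
  cfg$annual_trend <- -0.02
  cfg$date_range <- c(ym(2018, 11), ym(2020, 2))
  n_rep <- 120
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg$seed <- 1000L + r
    persons <- simulate_population(cfg)
    events <- simulate_events(persons, cfg)
    eligible <- apply_exclusions(persons)$eligible
    rates <- monthly_rates(drop_valueless(dedup_events(events)), eligible,
      date_range = cfg$date_range
    )
    fit <- fit_trend_model(rates, lambda = 1)
    est <- fit$coefficients["t"]
    se <- sqrt(fit$cov["t", "t"])
    covered[r] <- abs(est - (-0.02)) <= qnorm(0.975) * se
  }
  expect_gte(mean(covered), 0.90)
})
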