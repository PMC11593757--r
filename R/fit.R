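#' Build the trend-model design matrix
#'
#' Assembles the quasi-Poisson trend model design from a monthly rate table
#' (one row per subgroup cell and month): an intercept, treatment-coded
#' categorical effects for the stratification variables, the cyclic seasonal
#' spline block, the linear trend index t (years relative to the reference
#' month) and t-by-subgroup interaction columns. The log of the eligible
#' population is the model offset.
#'
#' The raw cyclic basis sums to one across columns, which is collinear with
#' the intercept; the spline block is therefore reparameterized under a
#' sum-to-zero constraint (projection onto the null space of its column
#' means over the fit rows), leaving `k - 1` identifiable columns and
#' letting the intercept carry the seasonal level.
#'
#' @param data Tibble with columns `month`, `count`, `denominator` and the
#'   stratification variables in `by`.
#' @param by Character vector of stratification variables (may be empty).
#' @param basis A [cyclic_basis_spec()].
#' @param penalty_order Difference order of the seasonal roughness penalty.
#' @param reference Reference month for the trend index.
#' @return A list of class `trend_design`: `X` (design matrix), `y`
#'   (counts), `offset` (log denominators), `S` (penalty matrix embedded in
#'   the full coefficient space), and `meta` (levels, constraint projection,
#'   basis spec, column roles) used to rebuild rows at prediction time.
#' @export
build_design <- function(data, by = character(0), basis = cyclic_basis_spec(),
                         penalty_order = 2, reference = as.Date("2020-03-01")) {
  stopifnot(all(c("month", "count", "denominator") %in% names(data)))
  if (any(data$denominator <= 0)) {
    stop("all rows must have positive denominators", call. = FALSE)
  }
  levels_list <- lapply(by, function(v) {
    lv <- data[[v]]
    if (is.factor(lv)) levels(lv) else sort(unique(as.character(lv)))
  })
  names(levels_list) <- by

  B_raw <- cyclic_basis(month_position(data$month), basis)
  Cm <- colMeans(B_raw)
  qrC <- qr(matrix(Cm, ncol = 1))
  Z <- qr.Q(qrC, complete = TRUE)[, -1, drop = FALSE] # k x (k-1), null space of Cm

  meta <- list(
    by = by, levels = levels_list, basis = basis, Z = Z,
    penalty_order = penalty_order, reference = reference,
    fit_months = sort(unique(data$month))
  )
  X <- design_matrix(data, meta)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf(
      "design matrix is rank deficient; collinear column(s): %s",
      paste(dropped, collapse = ", ")
    ), call. = FALSE)
  }

  spline_cols <- grep("^season", colnames(X))
  S <- matrix(0, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  Sk <- cyclic_penalty(basis, penalty_order)
  S[spline_cols, spline_cols] <- t(Z) %*% Sk %*% Z

  structure(
    list(
      X = X, y = data$count, offset = log(data$denominator), S = S,
      meta = meta, rows = dplyr::select(
        data, dplyr::all_of(by), "month", "count", "denominator"
      )
    ),
    class = "trend_design"
  )
}

# shared row builder for fitting and prediction; `freeze` zeroes the trend
# index (and its interactions) for months after the reference
design_matrix <- function(data, meta, freeze = FALSE) {
  n <- nrow(data)
  t_raw <- trend_index(data$month, meta$reference)
  t_eff <- if (freeze) ifelse(t_raw > 0, 0, t_raw) else t_raw

  blocks <- list(`(Intercept)` = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  cat_dummies <- list()
  for (v in meta$by) {
    lev <- meta$levels[[v]]
    val <- as.character(data[[v]])
    unseen <- setdiff(unique(val), lev)
    if (length(unseen) > 0) {
      stop(sprintf(
        "level(s) %s of `%s` were not seen during fitting",
        paste(sprintf("`%s`", unseen), collapse = ", "), v
      ), call. = FALSE)
    }
    if (length(lev) < 2) next
    Dm <- vapply(lev[-1], function(l) as.numeric(val == l), numeric(n))
    Dm <- matrix(Dm, nrow = n, dimnames = list(NULL, paste0(v, lev[-1])))
    cat_dummies[[v]] <- Dm
    blocks[[v]] <- Dm
  }
  Bc <- cyclic_basis(month_position(data$month), meta$basis) %*% meta$Z
  colnames(Bc) <- paste0("season", seq_len(ncol(Bc)))
  blocks[["season"]] <- Bc
  blocks[["t"]] <- matrix(t_eff, ncol = 1, dimnames = list(NULL, "t"))
  for (v in names(cat_dummies)) {
    Dm <- cat_dummies[[v]] * t_eff
    colnames(Dm) <- paste0("t:", colnames(cat_dummies[[v]]))
    blocks[[paste0("t:", v)]] <- Dm
  }
  do.call(cbind, blocks)
}

#' Fit the penalized quasi-Poisson trend model by penalized IRLS
#'
#' Iteratively reweighted least squares with a log link, Poisson working
#' weights and the cyclic difference penalty on the seasonal block.
#' Convergence is declared when the relative change in deviance falls below
#' `tol`. The dispersion is estimated from the Pearson statistic divided by
#' the residual effective degrees of freedom, and the coefficient covariance
#' is the penalized information inverse scaled by the dispersion.
#'
#' @param design A `trend_design` from [build_design()].
#' @param lambda Smoothing parameter (>= 0) multiplying the seasonal
#'   penalty.
#' @param tol Relative deviance convergence tolerance.
#' @param maxit Maximum IRLS iterations.
#' @return An object of class `trend_fit` with elements `coefficients`,
#'   `cov`, `phi`, `lambda`, `edf`, `deviance`, `pearson`, `fitted`,
#'   `iterations`, `converged`, `flagged_strata` and the design `meta`.
#' @export
fit_pirls <- function(design, lambda = 0, tol = 1e-8, maxit = 100L) {
  stopifnot(inherits(design, "trend_design"), lambda >= 0)
  X <- design$X
  y <- design$y
  off <- design$offset
  if (any(y < 0) || any(y != floor(y))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  flagged <- flag_zero_strata(design)

  n <- nrow(X)
  P <- lambda * design$S
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  dev <- poisson_deviance(y, mu)
  beta <- NULL
  converged <- FALSE
  trace <- numeric(0)
  for (it in seq_len(maxit)) {
    w <- mu # Poisson working weights under log link
    z <- (eta - off) + (y - mu) / mu
    XtW <- t(X * w)
    A <- XtW %*% X + P
    beta_new <- tryCatch(solve(A, XtW %*% z), error = function(e) {
      stop(sprintf(
        "penalized IRLS failed at iteration %d: %s", it, conditionMessage(e)
      ), call. = FALSE)
    })
    eta <- drop(X %*% beta_new) + off
    mu <- exp(eta)
    dev_new <- poisson_deviance(y, mu)
    trace <- c(trace, dev_new)
    if (!is.finite(dev_new)) {
      stop(sprintf(
        "penalized IRLS diverged at iteration %d (deviance trace: %s)",
        it, paste(signif(trace, 6), collapse = ", ")
      ), call. = FALSE)
    }
    beta <- beta_new
    if (abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol) {
      converged <- TRUE
      dev <- dev_new
      break
    }
    dev <- dev_new
  }
  if (!converged) {
    warning(sprintf("penalized IRLS did not converge in %d iterations", maxit))
  }

  w <- mu
  XtW <- t(X * w)
  Fisher <- XtW %*% X
  A <- Fisher + P
  Ainv <- solve(A)
  edf <- sum(diag(Ainv %*% Fisher))
  pearson <- sum((y - mu)^2 / mu)
  phi <- pearson / (n - edf)
  cov <- phi * Ainv
  cov <- (cov + t(cov)) / 2

  coef <- drop(beta)
  names(coef) <- colnames(X)
  dimnames(cov) <- list(colnames(X), colnames(X))
  structure(
    list(
      coefficients = coef, cov = cov, phi = phi, lambda = lambda, edf = edf,
      deviance = dev, pearson = pearson, fitted = mu, n = n,
      iterations = it, converged = converged, flagged_strata = flagged,
      meta = design$meta, rows = design$rows
    ),
    class = "trend_fit"
  )
}

flag_zero_strata <- function(design) {
  by <- design$meta$by
  if (length(by) == 0) {
    if (all(design$y == 0)) warning("all counts are zero in the overall series")
    return(tibble::tibble())
  }
  zero <- design$rows |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(all_zero = all(.data$count == 0), .groups = "drop") |>
    dplyr::filter(.data$all_zero)
  if (nrow(zero) > 0) {
    warning(sprintf(
      "%d stratum/strata have all-zero counts in the fit window", nrow(zero)
    ))
  }
  zero
}

poisson_deviance <- function(y, mu) {
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(term - (y - mu))
}

#' Select the smoothing parameter by generalized cross-validation
#'
#' Fits the penalized model at every value of a smoothing grid and returns
#' the minimizer of the GCV score `n * PearsonChi2 / (n - edf)^2`. Ties are
#' broken towards the larger (smoother) value.
#'
#' @inheritParams fit_pirls
#' @param grid Numeric vector of candidate `lambda` values (>= 0).
#' @return A list with `lambda` (the selected value) and `gcv` (a tibble of
#'   the profile: lambda, edf, pearson, gcv).
#' @export
select_lambda <- function(design, grid = 10^seq(-2, 4, length.out = 13)) {
  if (length(grid) == 0) stop("`grid` of lambda values is empty", call. = FALSE)
  grid <- sort(grid)
  prof <- purrr::map(grid, function(l) {
    fit <- suppressWarnings(fit_pirls(design, lambda = l))
    tibble::tibble(
      lambda = l, edf = fit$edf, pearson = fit$pearson,
      gcv = fit$n * fit$pearson / (fit$n - fit$edf)^2
    )
  }) |> purrr::list_rbind()
  best <- max(prof$lambda[prof$gcv <= min(prof$gcv) + 1e-12])
  list(lambda = best, gcv = prof)
}

#' Fit the monthly-rate trend model on the pre-disruption window
#'
#' High-level wrapper: restricts a monthly rate table to the fit window,
#' builds the design, selects the seasonal smoothing parameter by GCV
#' (unless a numeric `lambda` is given) and runs penalized IRLS.
#'
#' @param data Monthly rate tibble from [monthly_rates()] for a single
#'   factor (columns `month`, `count`, `denominator` plus stratification).
#' @param by Stratification variables crossed in `data`.
#' @param fit_window Length-2 `Date`: first and last month used for fitting
#'   (default November 2018 to February 2020).
#' @param basis,penalty_order Seasonal basis and penalty, see
#'   [build_design()].
#' @param lambda `"gcv"` (default) or a fixed numeric smoothing parameter.
#' @param lambda_grid Grid searched when `lambda = "gcv"`.
#' @param reference Reference month of the trend index.
#' @return A `trend_fit` object; see [fit_pirls()].
#' @examples
#' cfg <- scenario_config(n_persons = 300, factors = "bp", seed = 7)
#' rates <- simulate_events(simulate_population(cfg), cfg) |>
#'   dedup_events() |>
#'   drop_valueless() |>
#'   monthly_rates(simulate_population(cfg),
#'     date_range = cfg$date_range
#'   )
#' fit <- fit_trend_model(rates)
#' glance(fit)
#' @export
fit_trend_model <- function(data, by = character(0),
                            fit_window = c(ym(2018, 11), ym(2020, 2)),
                            basis = cyclic_basis_spec(), penalty_order = 2,
                            lambda = "gcv",
                            lambda_grid = 10^seq(-2, 4, length.out = 13),
                            reference = as.Date("2020-03-01")) {
  if ("factor" %in% names(data) && length(unique(data$factor)) > 1) {
    stop("`data` holds several factors; fit one model per factor", call. = FALSE)
  }
  fit_data <- dplyr::filter(
    data, .data$month >= fit_window[1], .data$month <= fit_window[2]
  )
  if (nrow(fit_data) == 0) stop("no rows fall inside the fit window", call. = FALSE)
  design <- build_design(fit_data,
    by = by, basis = basis,
    penalty_order = penalty_order, reference = reference
  )
  gcv_profile <- NULL
  if (identical(lambda, "gcv")) {
    sel <- select_lambda(design, lambda_grid)
    lambda <- sel$lambda
    gcv_profile <- sel$gcv
  }
  fit <- fit_pirls(design, lambda = lambda)
  fit$gcv_profile <- gcv_profile
  fit$fit_window <- fit_window
  fit
}

#' Linear predictor and standard error for new subgroup-months
#'
#' Evaluates the fitted linear predictor (excluding the offset) and its
#' delta-method standard error for new rows of `month` plus stratification
#' variables. With `freeze_trend = TRUE` the trend index and its subgroup
#' interactions are set to zero for months after the reference month,
#' giving the frozen-trend counterfactual; earlier months are unchanged.
#'
#' @param object A `trend_fit`.
#' @param newdata Tibble with a `month` column and the fit's stratification
#'   variables. Levels unseen during fitting raise an error.
#' @param freeze_trend Logical; zero the post-reference trend columns.
#' @return `newdata` with columns `eta` and `se_eta` appended.
#' @export
predict_eta <- function(object, newdata, freeze_trend = FALSE) {
  stopifnot(inherits(object, "trend_fit"))
  missing_vars <- setdiff(c("month", object$meta$by), names(newdata))
  if (length(missing_vars) > 0) {
    stop(sprintf(
      "`newdata` lacks column(s): %s", paste(missing_vars, collapse = ", ")
    ), call. = FALSE)
  }
  X <- design_matrix(newdata, object$meta, freeze = freeze_trend)
  eta <- drop(X %*% object$coefficients)
  se <- sqrt(pmax(rowSums((X %*% object$cov) * X), 0))
  dplyr::mutate(tibble::as_tibble(newdata), eta = eta, se_eta = se)
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("<trend_fit> penalized quasi-Poisson trend model\n")
  cat(sprintf(
    "  %d rows, %d coefficients, edf %.2f, dispersion %.3f, lambda %.4g\n",
    x$n, length(x$coefficients), x$edf, x$phi, x$lambda
  ))
  cat(sprintf(
    "  converged: %s in %d iterations (deviance %.4g)\n",
    x$converged, x$iterations, x$deviance
  ))
  invisible(x)
}
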