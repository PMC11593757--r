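#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted trend model
#'
#' One row per model coefficient with its penalized standard error, Wald
#' statistic and normal-theory p-value, plus a `role` column classifying the
#' term (intercept, subgroup, season, trend, trend interaction).
#'
#' @param x A `trend_fit`.
#' @param conf.int Add normal-theory confidence bounds.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$cov))
  out <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * stats::pnorm(-abs(unname(est / se))),
    role = dplyr::case_when(
      names(est) == "(Intercept)" ~ "intercept",
      grepl("^t:", names(est)) ~ "trend interaction",
      names(est) == "t" ~ "trend",
      grepl("^season", names(est)) ~ "season",
      TRUE ~ "subgroup"
    )
  )
  if (conf.int) {
    z <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  out
}

#' One-row model summary
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return A tibble with `nobs`, `edf`, `dispersion`, `lambda`, `deviance`,
#'   `pearson`, `iterations`, `converged`.
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$n, edf = x$edf, dispersion = x$phi, lambda = x$lambda,
    deviance = x$deviance, pearson = x$pearson,
    iterations = x$iterations, converged = x$converged
  )
}

#' @export
coef.trend_fit <- function(object, ...) object$coefficients

#' @export
vcov.trend_fit <- function(object, ...) object$cov
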