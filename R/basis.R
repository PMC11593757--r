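#' Trend index: years relative to the reference month
#'
#' Maps a calendar month to a signed time in years relative to the pandemic
#' reference month (March 2020 by default), computed as an exact rational
#' number of months divided by 12. March 2020 maps to 0, March 2019 to -1,
#' and May 2022 to 2 + 2/12 (printed as 2.17). The index enters the trend
#' model linearly, with subgroup interactions.
#'
#' @param month `Date` vector (any day; snapped to the first of the month).
#' @param reference Reference month (`Date`).
#' @return Numeric vector of years relative to `reference`.
#' @examples
#' trend_index(ym(2022, 5)) # 2 + 2/12
#' @export
trend_index <- function(month, reference = as.Date("2020-03-01")) {
  months_between(reference, first_of_month(month)) / 12
}

#' Cyclic B-spline basis specification
#'
#' Describes the periodic seasonal basis: `k` B-spline basis functions of
#' the given degree on equally spaced knots wrapped on a 12-month period.
#' `k` defaults to 6: the fit window holds only 16 months, so the seasonal
#' basis must stay parsimonious.
#'
#' @param k Number of basis functions (must satisfy `k >= degree + 1`).
#' @param degree Spline degree (default cubic).
#' @param period Period in months (fixed at 12 for month-of-year).
#' @return An object of class `cyclic_basis_spec`.
#' @export
cyclic_basis_spec <- function(k = 6, degree = 3, period = 12) {
  if (k < degree + 1) {
    stop("`k` must be at least degree + 1 for a valid cyclic basis", call. = FALSE)
  }
  structure(list(k = as.integer(k), degree = as.integer(degree), period = period),
    class = "cyclic_basis_spec"
  )
}

#' Evaluate the cyclic B-spline basis
#'
#' Evaluates the `k` wrapped B-spline basis functions at month-of-year
#' positions `m`. The basis is built on equally spaced knots spanning the
#' period extended by `degree` knots on each side; the `degree` leading
#' unwrapped functions are folded onto their periodic images, so the
#' resulting functions and their derivatives up to `degree - 1` are
#' continuous across the December-to-January seam. Values outside
#' `[0, period)` are reduced modulo the period. The basis is a partition of
#' unity: rows sum to 1 exactly (to numerical precision).
#'
#' @param m Numeric vector of month-of-year positions (0 = January).
#' @param spec A [cyclic_basis_spec()].
#' @return A `length(m)` by `k` matrix of basis values.
#' @export
cyclic_basis <- function(m, spec = cyclic_basis_spec()) {
  stopifnot(inherits(spec, "cyclic_basis_spec"))
  k <- spec$k
  d <- spec$degree
  h <- spec$period / k
  x <- m %% spec$period
  knots <- h * ((-d):(k + d))
  B <- splines::splineDesign(knots, x, ord = d + 1)
  if (d > 0) {
    B[, seq_len(d)] <- B[, seq_len(d), drop = FALSE] + B[, k + seq_len(d), drop = FALSE]
  }
  B <- B[, seq_len(k), drop = FALSE]
  colnames(B) <- paste0("season", seq_len(k))
  B
}

#' Cyclic difference penalty matrix
#'
#' Builds the P-spline roughness penalty S = D'D where D is the order-th
#' cyclic (wrapped) difference operator on the `k` spline coefficients. S is
#' symmetric positive semidefinite and annihilates constant coefficient
#' vectors, so the penalty shrinks the seasonal curve towards flatness
#' without penalising its level.
#'
#' @param spec A [cyclic_basis_spec()].
#' @param order Difference order (default 2); must be smaller than `k`.
#' @return A `k` by `k` penalty matrix.
#' @export
cyclic_penalty <- function(spec = cyclic_basis_spec(), order = 2) {
  stopifnot(inherits(spec, "cyclic_basis_spec"))
  k <- spec$k
  if (order >= k) {
    stop("penalty difference `order` must be smaller than the basis dimension `k`",
      call. = FALSE
    )
  }
  D1 <- diag(-1, k)
  D1[cbind(seq_len(k), c(2:k, 1))] <- 1
  D <- diag(k)
  for (i in seq_len(order)) D <- D1 %*% D
  S <- t(D) %*% D
  (S + t(S)) / 2
}
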