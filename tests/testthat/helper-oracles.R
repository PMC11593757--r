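# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the B-spline oracle is a direct de Boor
# recursion, the tabulation oracles are explicit per-person loops.

# de Boor recursion for one B-spline basis function over a knot vector
deboor_bspline <- function(x, knots, i, ord) {
  if (ord == 1) {
    return(as.numeric(knots[i] <= x & x < knots[i + 1]))
  }
  left <- 0
  d1 <- knots[i + ord - 1] - knots[i]
  if (d1 > 0) left <- (x - knots[i]) / d1 * deboor_bspline(x, knots, i, ord - 1)
  right <- 0
  d2 <- knots[i + ord] - knots[i + 1]
  if (d2 > 0) right <- (knots[i + ord] - x) / d2 * deboor_bspline(x, knots, i + 1, ord - 1)
  left + right
}

# wrapped cyclic basis via de Boor on a knot vector unrolled over 3 periods:
# wrapped function j sums the unwrapped splines congruent to j modulo k
deboor_cyclic_basis <- function(x, k, degree, period = 12) {
  ord <- degree + 1
  h <- period / k
  knots <- h * ((-degree - k):(2 * k + degree))
  n_spl <- length(knots) - ord
  B <- matrix(0, length(x), k)
  for (i in seq_len(n_spl)) {
    j <- ((i - 1) %% k) + 1 # unwrapped spline i starts at h*(i - 1 - degree - k)
    B[, j] <- B[, j] + deboor_bspline(x %% period, knots, i, ord)
  }
  B
}

# per-person-per-month tabulation of events into counts and denominators
brute_monthly_rates <- function(events, persons, months) {
  out <- NULL
  for (f in sort(unique(events$factor))) {
    for (m in seq_along(months)) {
      alive <- persons$months_followup >= m
      n_alive <- sum(alive)
      cnt <- 0L
      for (i in seq_len(nrow(events))) {
        e_month <- as.Date(format(events$event_date[i], "%Y-%m-01"))
        if (events$factor[i] != f || e_month != months[m]) next
        p <- match(events$person_id[i], persons$person_id)
        if (is.na(p) || !alive[p]) next
        cnt <- cnt + 1L
      }
      out <- rbind(out, data.frame(
        factor = f, month = months[m], count = cnt,
        denominator = n_alive, rate = cnt / n_alive * 1000
      ))
    }
  }
  tibble::as_tibble(out)
}

# first-in-input-order dedup by explicit grouping
brute_dedup <- function(events) {
  key <- paste(events$person_id, events$factor, events$event_date, sep = "\r")
  events[!duplicated(key), , drop = FALSE]
}

load_fixture_scenario <- function(name) {
  read_scenario(system.file("extdata", name, package = "expectband"))
}

# one end-to-end replicate: simulate, curate, fit, band
run_replicate <- function(cfg, seed, by = character(0), lambda = "gcv") {
  cfg$seed <- as.integer(seed)
  persons <- simulate_population(cfg)
  events <- simulate_events(persons, cfg)
  eligible <- apply_exclusions(persons)$eligible
  ev <- drop_valueless(dedup_events(events))
  rates <- monthly_rates(ev, eligible, by = by, date_range = cfg$date_range)
  fit <- fit_trend_model(rates, by = by, lambda = lambda)
  expectation_band(fit, observed = rates)
}
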