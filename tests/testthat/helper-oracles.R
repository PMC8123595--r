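# Shared fixtures and independent oracles for the test suite.

# Scaled-down calendar: same shape and mix as the defaults but calibrated to
# a small hourly peak so that generated streams stay small in unit tests.
small_calendar <- function(peak_payload_g = 800) {
  activity_calendar(peak_payload_g = peak_payload_g)
}

# Constant-intensity calendar (lambda orders/min at every minute of the
# week), bypassing the trapezoidal profile.
flat_calendar <- function(lambda) {
  cal <- activity_calendar(peak_payload_g = NA)
  cal$intensity[] <- lambda
  cal
}

# Random small stream for batching property tests.
random_stream <- function(n, horizon = 300, weights = c(7, 9, 60, 166),
                          seed = 1) {
  set.seed(seed)
  df <- data.frame(
    sample_id = seq_len(n),
    arrival_min = sort(round(runif(n, 0, horizon), 2)),
    weight_g = sample(weights, n, replace = TRUE)
  )
  df
}

# Brute-force oracle for the strict-FIFO capacity-feasible assignment on
# tiny instances: enumerate every mapping of samples to departures and keep
# the ones that are (a) feasible -- departure at or after arrival, payload
# within capacity on every flight, departures non-decreasing in arrival
# (FIFO) -- and (b) non-delaying: no single sample can be moved to any
# earlier departure without breaking (a). The surviving assignment must be
# unique.
brute_force_assignment <- function(arrival, weight, interval, capacity,
                                   max_flights = 6) {
  n <- length(arrival)
  deps <- interval * seq_len(max_flights)
  grids <- rep(list(seq_along(deps)), n)
  combos <- as.matrix(expand.grid(grids))
  feasible <- function(idx) {
    d <- deps[idx]
    if (any(d < arrival)) return(FALSE)
    if (is.unsorted(d)) return(FALSE) # FIFO in arrival order
    loads <- tapply(weight, factor(d, levels = deps), sum)
    all(is.na(loads) | loads <= capacity)
  }
  ok <- apply(combos, 1, feasible)
  cand <- combos[ok, , drop = FALSE]
  non_delaying <- apply(cand, 1, function(idx) {
    for (i in seq_len(n)) {
      for (k in seq_len(idx[i] - 1)) {
        alt <- idx
        alt[i] <- k
        if (feasible(alt)) return(FALSE)
      }
    }
    TRUE
  })
  cand <- cand[non_delaying, , drop = FALSE]
  stopifnot(nrow(cand) == 1L)
  deps[cand[1, ]]
}

# Numeric-integration oracle for the probability that a truncated-lognormal
# component time, multiplied by an independent factor uniform on
# [1, 1 + inc], exceeds a threshold.
exceedance_oracle <- function(spec, threshold, inc) {
  p_upper <- function(t) {
    num <- stats::plnorm(spec$upper, spec$mu, spec$sigma) -
      stats::plnorm(pmin(t, spec$upper), spec$mu, spec$sigma)
    den <- stats::plnorm(spec$upper, spec$mu, spec$sigma) -
      stats::plnorm(spec$lower, spec$mu, spec$sigma)
    pmax(num, 0) / den
  }
  stats::integrate(function(f) p_upper(threshold / f), 1, 1 + inc)$value / inc
}
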