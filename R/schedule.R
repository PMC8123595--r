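#' Fixed-interval drone schedule
#'
#' Departures at \code{interval, 2*interval, ...} minutes with a fixed
#' payload capacity per flight.
#'
#' @param interval minutes between departures, a positive whole number of
#'   minutes (the model works on a 1-minute grid).
#' @param capacity payload capacity per flight, grams; default 3500.
#'   \code{Inf} disables the capacity constraint.
#' @return A \code{schedule_spec} object.
#' @export
schedule_spec <- function(interval = 15, capacity = 3500) {
  stopifnot(is.numeric(interval), length(interval) == 1L,
            is.finite(interval), interval > 0, interval == round(interval),
            is.numeric(capacity), length(capacity) == 1L, capacity > 0)
  structure(list(interval = interval, capacity = capacity),
            class = "schedule_spec")
}

#' Assign an order stream to fixed-interval flights
#'
#' Samples queue at the loading site from their arrival time
#' (\code{order_time + clinical + pts}) and board flights strictly first
#' in, first out: each departure loads the head of the queue until the next
#' sample would exceed the remaining capacity, and that sample — with
#' everything behind it — carries over to the following departure. All
#' samples on a flight share its departure time (batching); emergency and
#' routine samples share flights, since batch departure makes priority
#' reordering pointless. A sample arriving exactly at a departure time
#' boards that flight. Loading and box exchange are treated as
#' instantaneous; a trailing partial flight always departs, with extra
#' departures appended past the horizon until the queue is empty.
#'
#' @param stream an \code{order_stream} (or data.frame with
#'   \code{arrival_min} and \code{weight_g}); sorted by arrival internally
#'   (stable, so ties keep input order).
#' @param schedule a \code{schedule_spec}.
#' @return An \code{assignment_result}: list with \code{flights} (data.frame
#'   \code{departure_min, n_samples, payload_g, fill_fraction}),
#'   \code{assignment} (data.frame \code{sample_id, arrival_min,
#'   departure_min, wait_min}), \code{carryover_count} (samples deferred at
#'   least once past the first departure they were eligible for), and the
#'   \code{schedule}.
#' @export
assign_to_flights <- function(stream, schedule) {
  stopifnot(inherits(schedule, "schedule_spec"), is.data.frame(stream))
  if (!all(c("arrival_min", "weight_g") %in% names(stream))) {
    stop_dronelab("stream needs arrival_min and weight_g columns",
                  "dronelab_invalid_input")
  }
  iv <- schedule$interval
  cap <- schedule$capacity
  n <- nrow(stream)
  ids <- if ("sample_id" %in% names(stream)) stream$sample_id else seq_len(n)

  if (n == 0L) {
    return(structure(
      list(flights = data.frame(departure_min = numeric(0),
                                n_samples = integer(0),
                                payload_g = numeric(0),
                                fill_fraction = numeric(0)),
           assignment = data.frame(sample_id = integer(0),
                                   arrival_min = numeric(0),
                                   departure_min = numeric(0),
                                   wait_min = numeric(0)),
           carryover_count = 0L, schedule = schedule),
      class = "assignment_result"))
  }

  ord <- order(stream$arrival_min) # stable: ties keep input order
  arr <- stream$arrival_min[ord]
  w <- stream$weight_g[ord]
  ids <- ids[ord]

  heavy <- which(w > cap)
  if (length(heavy) > 0L) {
    stop_dronelab(
      sprintf("sample %s (%.0f g) exceeds the flight capacity of %.0f g",
              ids[heavy[1]], w[heavy[1]], cap),
      "dronelab_unshippable_sample",
      data = list(sample_id = ids[heavy[1]], weight_g = w[heavy[1]])
    )
  }

  first_eligible <- pmax(iv * ceiling(arr / iv), iv)

  if (is.infinite(cap)) {
    # no capacity constraint: every sample boards its first eligible flight
    dep_assign <- first_eligible
  } else {
    dep_assign <- numeric(n)
    p <- 1L # head of the FIFO queue
    k <- 0L
    while (p <= n) {
      k <- k + 1L
      d <- k * iv
      load <- 0
      while (p <= n && arr[p] <= d && load + w[p] <= cap) {
        dep_assign[p] <- d
        load <- load + w[p]
        p <- p + 1L
      }
    }
  }
  departures <- seq(iv, max(dep_assign, iv * ceiling(max(arr) / iv)), by = iv)

  fidx <- match(dep_assign, departures)
  payload <- numeric(length(departures))
  agg <- rowsum(w, fidx)
  payload[as.integer(rownames(agg))] <- agg[, 1]
  flights <- data.frame(
    departure_min = departures,
    n_samples = tabulate(fidx, nbins = length(departures)),
    payload_g = payload,
    fill_fraction = if (is.finite(cap)) payload / cap else NA_real_
  )

  assignment <- data.frame(
    sample_id = ids,
    arrival_min = arr,
    departure_min = dep_assign,
    wait_min = dep_assign - arr
  )
  structure(
    list(flights = flights, assignment = assignment,
         carryover_count = sum(dep_assign > first_eligible),
         schedule = schedule),
    class = "assignment_result"
  )
}

#' @export
print.assignment_result <- function(x, ...) {
  fl <- x$flights[x$flights$n_samples > 0, , drop = FALSE]
  cat(sprintf(
    "Flight assignment: %d samples on %d flights (every %d min, cap %s g)\n",
    nrow(x$assignment), nrow(fl), x$schedule$interval,
    format(x$schedule$capacity)))
  if (nrow(fl) > 0) {
    cat(sprintf("  payload per flight: mean %.0f g, max %.0f g\n",
                mean(fl$payload_g), max(fl$payload_g)))
  }
  if (nrow(x$assignment) > 0) {
    cat(sprintf("  wait: mean %.1f min, max %.1f min; carried over: %d\n",
                mean(x$assignment$wait_min), max(x$assignment$wait_min),
                x$carryover_count))
  }
  invisible(x)
}

#' Payload totals per time bin
#'
#' Sums flight payloads into consecutive bins of \code{bin} minutes; a
#' flight departing at time \code{d} falls in bin \code{ceiling(d / bin)}
#' (bins are left-open, right-closed). The series total equals the total
#' stream weight.
#'
#' @param result an \code{assignment_result}.
#' @param bin bin width in minutes (e.g. 60 for hourly payloads).
#' @return Numeric vector of per-bin payloads in grams.
#' @export
payload_series <- function(result, bin = 60) {
  stopifnot(inherits(result, "assignment_result"),
            is.numeric(bin), bin > 0)
  fl <- result$flights
  if (nrow(fl) == 0L) return(numeric(0))
  b <- ceiling(fl$departure_min / bin)
  n_bins <- max(b)
  out <- numeric(n_bins)
  agg <- rowsum(fl$payload_g, b)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Drone filling fractions over sliding windows
#'
#' For \code{count} windows of \code{window} minutes starting \code{step}
#' minutes apart (first window starting at \code{origin}), the fraction of
#' one flight's capacity accumulated by sample arrivals within the window.
#' Raw accumulation: fractions above 1 are truncated to 1 and flagged via
#' the \code{overflow} column.
#'
#' @param stream an \code{order_stream} (needs \code{arrival_min},
#'   \code{weight_g}).
#' @param schedule a \code{schedule_spec} (capacity is used).
#' @param window,step,count window length, spacing and number of windows,
#'   minutes on the 1-min grid.
#' @param origin start of the first window, minutes.
#' @return data.frame \code{start_min, end_min, weight_g, fill_fraction,
#'   overflow}.
#' @export
filling_windows <- function(stream, schedule, window = 15, step = 5,
                            count = 20, origin = 0) {
  stopifnot(is.data.frame(stream), inherits(schedule, "schedule_spec"),
            is_count(window), is_count(step), is_count(count),
            is.numeric(origin), origin >= 0)
  starts <- origin + (seq_len(count) - 1) * step
  weight <- vapply(starts, function(s) {
    sel <- stream$arrival_min > s & stream$arrival_min <= s + window
    sum(stream$weight_g[sel])
  }, numeric(1))
  frac <- weight / schedule$capacity
  data.frame(start_min = starts, end_min = starts + window,
             weight_g = weight,
             fill_fraction = pmin(frac, 1),
             overflow = frac > 1)
}

#' Largest feasible departure interval
#'
#' Searches a grid of candidate departure intervals for the largest one
#' that keeps the worst-case emergency turnaround inside the budget:
#' mean clinical + mean transport + worst-case drone wait (a sample
#' arriving just after a departure waits the full interval) + drone flight
#' time + mean laboratory time must not exceed the emergency limit.
#' With \code{wait = "mean"} the expected wait (interval/2) is used
#' instead.
#'
#' @param grid candidate intervals in minutes, e.g. \code{c(15, 30, 45,
#'   60)}.
#' @param budget a \code{time_budget}.
#' @param component_means numeric length-3 \code{c(clinical, transport,
#'   lab)} mean minutes.
#' @param dft drone flight time, minutes.
#' @param wait \code{"max"} (default, worst case) or \code{"mean"}.
#' @return The largest feasible interval (minutes), with attribute
#'   \code{margin} (slack in minutes at that interval). If no candidate is
#'   feasible an error of class \code{dronelab_infeasible} is raised whose
#'   condition carries the violating margins per candidate.
#' @examples
#' feasible_max_interval(c(15, 30, 45, 60),
#'                       component_means = c(3.5, 3.2, 28.1), dft = 8)
#' @export
feasible_max_interval <- function(grid, budget = time_budget(),
                                  component_means, dft,
                                  wait = c("max", "mean")) {
  wait <- match.arg(wait)
  stopifnot(is.numeric(grid), length(grid) >= 1L, all(grid > 0),
            inherits(budget, "time_budget"),
            is.numeric(component_means), length(component_means) == 3L,
            all(component_means >= 0), is_number(dft), dft >= 0)
  wait_time <- if (wait == "max") grid else grid / 2
  total <- sum(component_means) + wait_time + dft
  margin <- budget$t_em - total
  feasible <- margin >= 0
  if (!any(feasible)) {
    stop_dronelab(
      sprintf("no candidate interval keeps the turnaround within %g min",
              budget$t_em),
      "dronelab_infeasible",
      data = list(grid = grid, margin = margin)
    )
  }
  best <- max(grid[feasible])
  structure(best, margin = margin[grid == best][1])
}
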