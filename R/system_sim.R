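#' Configuration for the end-to-end Monte Carlo study
#'
#' Bundles everything one replicate of the turnaround simulation needs:
#' event count, the random-increment size, the time budget whose
#' allowances double as violation thresholds, the departure schedule, the
#' flight parameters and the three service-time components.
#'
#' @param n_events events per replicate; default 10000.
#' @param increment_max maximum of the per-component random increment as a
#'   proportion; default 0.20 (each drawn component time is multiplied by
#'   an independent factor uniform on \code{[1, 1 + increment_max]},
#'   reflecting that observed demand never exceeded its mean maximum by
#'   more than 20\%).
#' @param n_replicates replicates for the summary table; default 10.
#' @param seed root seed; replicates use derived child seeds.
#' @param budget a \code{time_budget}.
#' @param schedule a \code{schedule_spec}.
#' @param flight a \code{flight_params}.
#' @param components named list of \code{dist_spec}s (\code{clinical},
#'   \code{pts}, \code{lab}).
#' @param increment_mode \code{"multiplicative"} (default) applies the
#'   factor to each component; \code{"additive"} adds
#'   \code{U(0, increment_max)} times the component instead — numerically
#'   identical here but kept as an explicit switch for other increments.
#' @return A \code{sim_config} object.
#' @export
sim_config <- function(n_events = 10000, increment_max = 0.20,
                       n_replicates = 10, seed = 1L,
                       budget = time_budget(), schedule = schedule_spec(),
                       flight = flight_params(),
                       components = default_components(),
                       increment_mode = c("multiplicative", "additive")) {
  stopifnot(is_count(n_events),
            is_number(increment_max), increment_max >= 0, increment_max <= 1,
            is_count(n_replicates),
            inherits(budget, "time_budget"),
            inherits(schedule, "schedule_spec"),
            inherits(flight, "flight_params"))
  increment_mode <- match.arg(increment_mode)
  stopifnot(all(c("clinical", "pts", "lab") %in% names(components)))
  structure(list(n_events = n_events, increment_max = increment_max,
                 n_replicates = n_replicates, seed = seed, budget = budget,
                 schedule = schedule, flight = flight,
                 components = components, increment_mode = increment_mode),
            class = "sim_config")
}

#' Simulate end-to-end transport events
#'
#' Each event is one emergency sample's journey: clinical, tube-transport
#' and laboratory times drawn from their components, each multiplied by an
#' independent random increment factor uniform on
#' \code{[1, 1 + increment_max]}; a queue wait uniform on
#' \code{[0, interval)} (the sample arrives at a uniformly random point of
#' the departure cycle); and the drone service time — the flight time
#' scaled by its own increment factor. The total is the exact sum of all
#' parts, wait included. The drone service time deliberately excludes the
#' queue wait: the wait is a property of the schedule, counted in the
#' total, while the service time measures the drone leg itself.
#'
#' @param config a \code{sim_config}.
#' @param n number of events; defaults to \code{config$n_events}.
#' @param seed seed for this batch; defaults to \code{config$seed}.
#' @return data.frame with one row per event: \code{clinical_min, pts_min,
#'   wait_min, drone_service_min, drone_min} (wait + service),
#'   \code{lab_min, total_min}.
#' @export
simulate_events <- function(config, n = config$n_events,
                            seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  dft <- compute_dft(config$flight)
  iv <- config$schedule$interval
  inc <- config$increment_max

  set.seed(child_seed(seed, 11L))
  c_t <- dist_draw(config$components$clinical, n)
  set.seed(child_seed(seed, 12L))
  t_t <- dist_draw(config$components$pts, n)
  set.seed(child_seed(seed, 13L))
  l_t <- dist_draw(config$components$lab, n)
  set.seed(child_seed(seed, 14L))
  f <- matrix(stats::runif(4L * n, 0, 1), ncol = 4L)
  set.seed(child_seed(seed, 15L))
  wait <- stats::runif(n, 0, iv)

  scale_by <- function(x, u) {
    if (config$increment_mode == "multiplicative") x * (1 + inc * u)
    else x + x * inc * u
  }
  c_t <- scale_by(c_t, f[, 1])
  t_t <- scale_by(t_t, f[, 2])
  l_t <- scale_by(l_t, f[, 3])
  drone_service <- scale_by(rep(dft, n), f[, 4])

  data.frame(
    clinical_min = c_t,
    pts_min = t_t,
    wait_min = wait,
    drone_service_min = drone_service,
    drone_min = wait + drone_service,
    lab_min = l_t,
    total_min = c_t + t_t + wait + drone_service + l_t
  )
}

#' Run the replicated Monte Carlo turnaround study
#'
#' Runs \code{n_replicates} independent batches of \code{n_events} events
#' and, per replicate, records the fraction of events violating each
#' allowance of the time budget: tube transport above
#' \code{transport_limit}, clinical time above \code{pre_limit},
#' laboratory time above \code{post_limit}, drone service time above
#' \code{drone_limit}, and total turnaround above \code{t_em}.
#'
#' @param config a \code{sim_config}.
#' @return A \code{violation_report}: list with \code{replicates} (matrix
#'   of fractions, one row per replicate), \code{summary} (per-fraction
#'   mean/sd/min/max), \code{thresholds} and the \code{config}.
#' @export
run_simulation <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  b <- config$budget
  thresholds <- c(total = b$t_em, pts = b$transport_limit,
                  clinical = b$pre_limit, lab = b$post_limit,
                  drone = b$drone_limit)
  reps <- vapply(seq_len(config$n_replicates), function(r) {
    ev <- simulate_events(config, seed = child_seed(config$seed, 100L + r))
    c(frac_total_gt_limit = mean(ev$total_min > thresholds["total"]),
      frac_pts_gt_5 = mean(ev$pts_min > thresholds["pts"]),
      frac_clinical_gt_15 = mean(ev$clinical_min > thresholds["clinical"]),
      frac_lab_gt_15 = mean(ev$lab_min > thresholds["lab"]),
      frac_drone_gt_15 = mean(ev$drone_service_min > thresholds["drone"]))
  }, numeric(5))
  reps <- t(reps)
  rownames(reps) <- paste0("replicate_", seq_len(nrow(reps)))
  structure(
    list(replicates = reps,
         summary = summarize_replicates(reps),
         thresholds = thresholds,
         config = config),
    class = "violation_report"
  )
}

#' Summarise violation fractions across replicates
#'
#' @param reports matrix of per-replicate fractions (rows = replicates) as
#'   in \code{violation_report$replicates}, or a \code{violation_report}.
#' @return data.frame with one row per fraction and columns
#'   \code{mean, sd, min, max}. With a single replicate the sd column is
#'   \code{NA} and flagged via attribute \code{single_replicate}.
#' @export
summarize_replicates <- function(reports) {
  if (inherits(reports, "violation_report")) reports <- reports$replicates
  stopifnot(is.matrix(reports), nrow(reports) >= 1L)
  out <- data.frame(
    mean = colMeans(reports),
    sd = apply(reports, 2, stats::sd),
    min = apply(reports, 2, min),
    max = apply(reports, 2, max)
  )
  if (nrow(reports) < 2L) {
    out$sd <- NA_real_
    attr(out, "single_replicate") <- TRUE
  }
  out
}

#' @export
print.violation_report <- function(x, ...) {
  lab <- c(
    frac_total_gt_limit = sprintf("Total time > %g min",
                                  x$thresholds["total"]),
    frac_pts_gt_5 = sprintf("PTS time > %g min", x$thresholds["pts"]),
    frac_clinical_gt_15 = sprintf("Clinical time > %g min",
                                  x$thresholds["clinical"]),
    frac_lab_gt_15 = sprintf("Laboratory time > %g min",
                             x$thresholds["lab"]),
    frac_drone_gt_15 = sprintf("Drone service time > %g min",
                               x$thresholds["drone"])
  )
  cat(sprintf(
    "Turnaround violation study: %d replicates x %d events (interval %d min)\n",
    nrow(x$replicates), x$config$n_events, x$config$schedule$interval))
  s <- x$summary
  for (nm in rownames(s)) {
    cat(sprintf("  %-28s mean %5.1f%%  sd %4.1f%%  min %5.1f%%  max %5.1f%%\n",
                lab[[nm]], 100 * s[nm, "mean"], 100 * s[nm, "sd"],
                100 * s[nm, "min"], 100 * s[nm, "max"]))
  }
  invisible(x)
}

#' @export
summary.violation_report <- function(object, ...) {
  object$summary
}
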